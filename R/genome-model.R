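#' Genome annotation container
#'
#' Bundles chromosome sizes with strand-aware gene models. All coordinates
#' are 0-based half-open (BED convention); GTF input is converted on read.
#' Gene models carry exon structure as list-columns and optional CDS bounds
#' from which UTR features are derived.
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `strand` (`+`/`-`),
#'   `start`, `end` (0-based half-open), and optionally list-columns
#'   `exon_starts`/`exon_ends` (sorted, disjoint, within the gene span) and
#'   `cds_start`/`cds_end` (NA when the gene is non-coding).
#' @param chromosomes Tibble with columns `chrom` and `length` (bp).
#' @return An object of class `genome_annotation`: a list with elements
#'   `genes` and `chromosomes`, both tibbles.
#' @examples
#' chroms <- tibble::tibble(chrom = "2L", length = 10000L)
#' genes <- tibble::tibble(gene_id = "g1", chrom = "2L", strand = "+",
#'                         start = 1000L, end = 4000L)
#' genome_annotation(genes, chroms)
#' @export
genome_annotation <- function(genes, chromosomes) {
  chromosomes <- as_tibble(chromosomes)
  genes <- as_tibble(genes)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
  if (any(chromosomes$length <= 0)) abort("chromosome lengths must be > 0")
  if (anyDuplicated(chromosomes$chrom)) abort("chromosome names must be unique")

  need <- c("gene_id", "chrom", "strand", "start", "end")
  missing <- setdiff(need, names(genes))
  if (length(missing) > 0) {
    abort(sprintf("`genes` lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!"exon_starts" %in% names(genes)) {
    genes$exon_starts <- map2(genes$start, genes$end, ~.x)
    genes$exon_ends <- map2(genes$start, genes$end, ~.y)
  }
  if (!"cds_start" %in% names(genes)) {
    genes$cds_start <- NA_integer_
    genes$cds_end <- NA_integer_
  }
  if (nrow(genes) > 0) {
    if (!all(genes$strand %in% c("+", "-"))) abort("gene strand must be '+' or '-'")
    if (any(genes$start >= genes$end)) abort("gene models require start < end")
    unknown <- setdiff(genes$chrom, chromosomes$chrom)
    if (length(unknown) > 0) {
      abort(sprintf("gene(s) on unknown chromosome(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    len <- chrom_lengths(list(chromosomes = chromosomes))
    if (any(genes$end > len[genes$chrom])) {
      abort("gene interval extends beyond chromosome length")
    }
    ok_exons <- pmap(list(genes$exon_starts, genes$exon_ends, genes$start, genes$end),
                     function(es, ee, s, e) {
                       length(es) == length(ee) && length(es) > 0 &&
                         all(es < ee) && !is.unsorted(es, strictly = TRUE) &&
                         all(head(ee, -1) <= tail(es, -1)) &&
                         min(es) >= s && max(ee) <= e
                     })
    if (!all(unlist(ok_exons))) {
      abort("exons must be sorted, disjoint intervals within the gene span")
    }
    has_cds <- !is.na(genes$cds_start)
    if (any(has_cds)) {
      bad <- has_cds & (genes$cds_start >= genes$cds_end |
                          genes$cds_start < genes$start | genes$cds_end > genes$end)
      if (any(bad, na.rm = TRUE)) abort("CDS interval must lie within the gene span")
    }
  }
  structure(list(genes = genes, chromosomes = chromosomes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d gene(s) on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$chromosomes)))
  invisible(x)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path Path to a TSV with chromosome name and length (no header).
#' @return Tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "length"),
                  col_types = readr::cols(chrom = "c", length = "i"),
                  progress = FALSE)
}

#' Read gene annotation from GTF or BED12
#'
#' Multiple transcripts sharing a `gene_id` are collapsed to one model per
#' gene: the union of transcript spans, the union of exons, and the outer
#' hull of CDS intervals (set `collapse = FALSE` to keep one model per
#' BED12/transcript record). GTF's 1-based closed coordinates are converted
#' to 0-based half-open on read.
#'
#' @param path Path to the annotation file.
#' @param format `"gtf"` or `"bed12"`.
#' @param chromosomes Optional chromosome-sizes tibble (`chrom`, `length`).
#'   When omitted, lengths are inferred as the maximum annotated coordinate
#'   per chromosome.
#' @param collapse Collapse multi-transcript genes to union-span models
#'   (default `TRUE`).
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, format = c("gtf", "bed12"),
                            chromosomes = NULL, collapse = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  check_annotation_lines(path, format)
  genes <- switch(format,
    gtf = read_genes_gtf(path),
    bed12 = read_genes_bed12(path)
  )
  if (collapse && nrow(genes) > 0) genes <- collapse_gene_models(genes)
  if (is.null(chromosomes)) {
    if (nrow(genes) == 0) {
      chromosomes <- tibble(chrom = character(), length = integer())
    } else {
      chromosomes <- genes |>
        group_by(chrom = .data$chrom) |>
        summarise(length = as.integer(max(.data$end)), .groups = "drop")
    }
  }
  genome_annotation(genes, chromosomes)
}

# Cheap structural pre-scan so malformed input fails with a line number.
check_annotation_lines <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  fields <- vapply(strsplit(lines, "\t", fixed = TRUE), length, integer(1))
  min_fields <- if (format == "gtf") 8L else 12L
  bad <- which(keep & fields < min_fields)
  if (length(bad) > 0) {
    abort(sprintf("malformed %s line %d in %s: expected >= %d tab-separated fields, found %d",
                  format, bad[1], path, min_fields, fields[bad[1]]))
  }
  invisible(TRUE)
}

read_genes_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  if (nrow(df) == 0) return(empty_genes())
  if (!"gene_id" %in% names(df)) abort("GTF records lack gene_id attribute")
  df <- df |>
    mutate(chrom = as.character(.data$seqnames),
           strand = as.character(.data$strand),
           start0 = .data$start - 1L,   # to 0-based half-open
           end0 = .data$end,
           type = as.character(.data$type))
  exons <- df |> filter(.data$type == "exon")
  if (nrow(exons) == 0) {
    # fall back to transcript/gene records as single-exon models
    exons <- df |> filter(.data$type %in% c("transcript", "gene"))
  }
  cds <- df |> filter(.data$type == "CDS")
  per_gene_exons <- exons |>
    group_by(gene_id = .data$gene_id) |>
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              exon_starts = list(sort(.data$start0)),
              exon_ends = list(.data$end0[order(.data$start0)]),
              start = min(.data$start0), end = max(.data$end0),
              .groups = "drop")
  if (nrow(cds) > 0) {
    per_gene_cds <- cds |>
      group_by(gene_id = .data$gene_id) |>
      summarise(cds_start = min(.data$start0), cds_end = max(.data$end0),
                .groups = "drop")
    out <- left_join(per_gene_exons, per_gene_cds, by = "gene_id")
  } else {
    out <- per_gene_exons
    out$cds_start <- NA_integer_
    out$cds_end <- NA_integer_
  }
  out |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end),
           cds_start = as.integer(.data$cds_start),
           cds_end = as.integer(.data$cds_end)) |>
    fix_exon_lists() |>
    select("gene_id", "chrom", "strand", "start", "end",
           "exon_starts", "exon_ends", "cds_start", "cds_end")
}

# Merge overlapping/adjacent intervals given parallel start/end vectors.
merge_intervals <- function(starts, ends) {
  if (length(starts) == 0) return(list(starts = integer(), ends = integer()))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  list(starts = as.integer(IRanges::start(ir) - 1L),
       ends = as.integer(IRanges::end(ir)))
}

fix_exon_lists <- function(genes) {
  merged <- map2(genes$exon_starts, genes$exon_ends, merge_intervals)
  genes$exon_starts <- map(merged, "starts")
  genes$exon_ends <- map(merged, "ends")
  genes
}

empty_genes <- function() {
  tibble(gene_id = character(), chrom = character(), strand = character(),
         start = integer(), end = integer(),
         exon_starts = list(), exon_ends = list(),
         cds_start = integer(), cds_end = integer())
}

read_genes_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0) return(empty_genes())
  df <- tibble(
    gene_id = gr$name,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  blocks <- gr$blocks  # IRangesList, 1-based relative to feature start
  df$exon_starts <- map2(as.list(IRanges::start(blocks)), df$start,
                         function(rel, s) as.integer(s + rel - 1L))
  df$exon_ends <- map2(as.list(IRanges::end(blocks)), df$start,
                       function(rel, s) as.integer(s + rel))
  thick <- gr$thick
  cs <- as.integer(IRanges::start(thick) - 1L)
  ce <- as.integer(IRanges::end(thick))
  # BED convention: thickStart == thickEnd marks a non-coding record
  none <- IRanges::width(thick) <= 0
  cs[none] <- NA_integer_
  ce[none] <- NA_integer_
  df$cds_start <- cs
  df$cds_end <- ce
  if (anyDuplicated(df$gene_id)) {
    df  # duplicates collapsed by caller when collapse = TRUE
  }
  df
}

# Union-span collapse of multi-transcript genes: span = union of transcript
# spans, exons = merged union, CDS = outer hull across coding transcripts.
collapse_gene_models <- function(genes) {
  genes |>
    group_by(gene_id = .data$gene_id) |>
    summarise(
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      start = as.integer(min(.data$start)),
      end = as.integer(max(.data$end)),
      exon_starts = list(unlist(.data$exon_starts)),
      exon_ends = list(unlist(.data$exon_ends)),
      cds_start = if (all(is.na(.data$cds_start))) NA_integer_ else
        as.integer(min(.data$cds_start, na.rm = TRUE)),
      cds_end = if (all(is.na(.data$cds_end))) NA_integer_ else
        as.integer(max(.data$cds_end, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    fix_exon_lists()
}

#' Write an annotation to BED12
#'
#' Inverse of [read_annotation()] for the BED12 dialect; round-trips gene
#' models exactly.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed12 <- function(annotation, path) {
  g <- annotation$genes
  lines <- pmap(list(g$chrom, g$start, g$end, g$gene_id, g$strand,
                     g$exon_starts, g$exon_ends, g$cds_start, g$cds_end),
                function(chrom, start, end, id, strand, es, ee, cs, ce) {
                  sizes <- ee - es
                  rel <- es - start
                  thick_s <- if (is.na(cs)) start else cs
                  thick_e <- if (is.na(cs)) start else ce
                  sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                          chrom, start, end, id, strand, thick_s, thick_e,
                          length(es),
                          paste0(paste(sizes, collapse = ","), ","),
                          paste0(paste(rel, collapse = ","), ","))
                })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Transcription start / end sites
#'
#' Strand-aware TSS and TES coordinates (0-based positions). For a `+`
#' strand gene the TSS is `start` and the TES is `end - 1`; for a `-`
#' strand gene the two are mirrored.
#'
#' @param genes Gene-model tibble (as in [genome_annotation()]) or a
#'   `genome_annotation`.
#' @return Integer vector of positions, one per gene, named by `gene_id`.
#' @examples
#' genes <- tibble::tibble(gene_id = c("a", "b"), chrom = "2L",
#'                         strand = c("+", "-"), start = 5000L, end = 8000L)
#' tss_of(genes)  # a: 5000, b: 7999
#' @export
tss_of <- function(genes) {
  genes <- as_gene_table(genes)
  setNames(as.integer(if_else(genes$strand == "+", genes$start, genes$end - 1L)),
           genes$gene_id)
}

#' @rdname tss_of
#' @export
tes_of <- function(genes) {
  genes <- as_gene_table(genes)
  setNames(as.integer(if_else(genes$strand == "+", genes$end - 1L, genes$start)),
           genes$gene_id)
}

as_gene_table <- function(x) {
  if (inherits(x, "genome_annotation")) x$genes else as_tibble(x)
}
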