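# Peak I/O, enrichment filtering, replicate concordance, reciprocal
# overlap comparison, and peak-to-gene assignment.

#' Read a peak set from narrowPeak or BED
#'
#' ENCODE narrowPeak carries fold enrichment over input in column 7 and
#' -log10(P) in column 8; plain BED3/BED6 peaks get `fold_enrichment = NA`.
#' Peaks with identical coordinates are deduplicated with a warning.
#'
#' @param path Path to the peak file.
#' @param format `"narrowPeak"` or `"bed"`.
#' @param source_label Label recorded in the `source_label` column
#'   (defaults to the file name).
#' @return Tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `fold_enrichment`, `neg_log10_p`, `source_label`, sorted by
#'   (chrom, start).
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed"),
                       source_label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("peak file not found: %s", path))
  if (format == "narrowPeak") {
    gr <- rtracklayer::import(
      path, format = "BED",
      extraCols = c(signalValue = "numeric", pValue = "numeric",
                    qValue = "numeric", peak = "integer"))
    peaks <- tibble(
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      name = if (!is.null(gr$name)) gr$name else NA_character_,
      fold_enrichment = gr$signalValue,
      neg_log10_p = gr$pValue,
      source_label = source_label
    )
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    peaks <- tibble(
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      name = if (!is.null(gr$name)) gr$name else NA_character_,
      fold_enrichment = NA_real_,
      neg_log10_p = NA_real_,
      source_label = source_label
    )
  }
  dup <- duplicated(peaks[, c("chrom", "start", "end")])
  if (any(dup)) {
    warn(sprintf("%d duplicate peak coordinate(s) removed from %s",
                 sum(dup), path))
    peaks <- peaks[!dup, ]
  }
  arrange(peaks, .data$chrom, .data$start)
}

#' Write a peak set as narrowPeak
#'
#' @param peaks Peak tibble (see [read_peaks()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_narrowpeak <- function(peaks, path) {
  check_peaks(peaks)
  name <- if ("name" %in% names(peaks)) peaks$name else
    sprintf("peak_%d", seq_len(nrow(peaks)))
  fe <- if ("fold_enrichment" %in% names(peaks)) peaks$fold_enrichment else 0
  lp <- if ("neg_log10_p" %in% names(peaks)) peaks$neg_log10_p else -1
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%g\t%g\t-1\t-1",
                   peaks$chrom, peaks$start, peaks$end, name, fe,
                   ifelse(is.na(lp), -1, lp))
  writeLines(lines, path)
  invisible(path)
}

#' Filter peaks by fold enrichment over input
#'
#' Retains peaks at least `min_fold`-fold enriched over the input sample
#' (inclusive boundary). Order is preserved.
#'
#' @param peaks Peak tibble.
#' @param min_fold Positive minimum fold enrichment (default 3, the usual
#'   "three fold or more over input" rule).
#' @return Filtered peak tibble.
#' @examples
#' pk <- tibble::tibble(chrom = "2L", start = c(0, 100, 200),
#'                      end = c(50, 150, 250),
#'                      fold_enrichment = c(2.9, 3, 10))
#' nrow(filter_by_fold(pk, 3))  # 2
#' @export
filter_by_fold <- function(peaks, min_fold = 3) {
  stopifnot(min_fold > 0)
  check_peaks(peaks)
  filter(peaks, .data$fold_enrichment >= min_fold)
}

#' Replicate-concordance filter
#'
#' Retains peaks of `rep1` for which some single `rep2` peak covers at
#' least `min_frac` of the `rep1` peak's length. This is a simple
#' reproducibility filter applied between biological replicates before
#' peak sets are compared or assigned to genes.
#'
#' @param rep1,rep2 Peak tibbles on the same genome.
#' @param min_frac Required covered fraction of each `rep1` peak, in (0, 1]
#'   (inclusive boundary; default 0.5).
#' @return The concordant subset of `rep1`, order preserved.
#' @export
replicate_concordant <- function(rep1, rep2, min_frac = 0.5) {
  stopifnot(min_frac > 0, min_frac <= 1)
  check_peaks(rep1, "rep1"); check_peaks(rep2, "rep2")
  if (nrow(rep1) == 0 || nrow(rep2) == 0) return(rep1[0, ])
  gr1 <- intervals_to_granges(rep1)
  gr2 <- intervals_to_granges(rep2)
  hits <- GenomicRanges::findOverlaps(gr1, gr2)
  ov <- IRanges::width(IRanges::pintersect(
    gr1[S4Vectors::queryHits(hits)], gr2[S4Vectors::subjectHits(hits)]))
  best <- rep(0, nrow(rep1))
  if (length(hits) > 0) {
    agg <- tapply(ov, S4Vectors::queryHits(hits), max)
    best[as.integer(names(agg))] <- agg
  }
  keep <- best >= min_frac * (rep1$end - rep1$start)
  rep1[keep, ]
}

#' Reciprocal overlap report between two peak sets
#'
#' A peak of set A counts as overlapping when the summed overlap with
#' (merged) set-B peaks is at least `min_frac` of the A peak's own length,
#' and symmetrically for B. The two directions are measured relative to
#' each set's own peak lengths, so the two percentages generally differ.
#'
#' @param a,b Peak tibbles on the same genome.
#' @param min_frac Required overlap fraction in (0, 1] (inclusive; default
#'   0.5, the "minimum of 50 % overlap" criterion).
#' @return An `overlap_report` object: list with `label_a`, `label_b`,
#'   `n_a`, `n_b`, `n_a_overlapping`, `n_b_overlapping`, `pct_a`, `pct_b`,
#'   `min_frac`.
#' @examples
#' a <- tibble::tibble(chrom = "2L", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "2L", start = 50, end = 150)
#' compare_peaksets(a, b)$pct_a  # 100
#' @export
compare_peaksets <- function(a, b, min_frac = 0.5) {
  stopifnot(min_frac > 0, min_frac <= 1)
  check_peaks(a, "a"); check_peaks(b, "b")
  label_of <- function(x, fallback) {
    if ("source_label" %in% names(x) && nrow(x) > 0 &&
        !is.na(x$source_label[1])) x$source_label[1] else fallback
  }
  res <- structure(list(
    label_a = label_of(a, "A"),
    label_b = label_of(b, "B"),
    n_a = nrow(a), n_b = nrow(b),
    n_a_overlapping = count_fraction_overlapping(a, b, min_frac),
    n_b_overlapping = count_fraction_overlapping(b, a, min_frac),
    min_frac = min_frac
  ), class = "overlap_report")
  res$pct_a <- pct_of(res$n_a_overlapping, res$n_a)
  res$pct_b <- pct_of(res$n_b_overlapping, res$n_b)
  res
}

# Number of `x` peaks whose summed overlap with merged `y` peaks is
# >= min_frac of the x peak's length.
count_fraction_overlapping <- function(x, y, min_frac) {
  if (nrow(x) == 0 || nrow(y) == 0) return(0L)
  grx <- intervals_to_granges(x)
  gry <- GenomicRanges::reduce(intervals_to_granges(y))
  hits <- GenomicRanges::findOverlaps(grx, gry)
  if (length(hits) == 0) return(0L)
  ov <- IRanges::width(IRanges::pintersect(
    grx[S4Vectors::queryHits(hits)], gry[S4Vectors::subjectHits(hits)]))
  summed <- rep(0, nrow(x))
  agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
  summed[as.integer(names(agg))] <- agg
  sum(summed >= min_frac * (x$end - x$start))
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> min_frac = %g\n", x$min_frac))
  cat(sprintf("  %s: %d / %d peaks overlapping (%d%%)\n",
              x$label_a, x$n_a_overlapping, x$n_a, x$pct_a))
  cat(sprintf("  %s: %d / %d peaks overlapping (%d%%)\n",
              x$label_b, x$n_b_overlapping, x$n_b, x$pct_b))
  invisible(x)
}

#' @export
tidy.overlap_report <- function(x, ...) {
  tibble(set = c(x$label_a, x$label_b),
         n = c(x$n_a, x$n_b),
         n_overlapping = c(x$n_a_overlapping, x$n_b_overlapping),
         pct = c(x$pct_a, x$pct_b))
}

#' @export
glance.overlap_report <- function(x, ...) {
  tibble(n_a = x$n_a, n_b = x$n_b,
         n_a_overlapping = x$n_a_overlapping,
         n_b_overlapping = x$n_b_overlapping,
         pct_a = x$pct_a, pct_b = x$pct_b, min_frac = x$min_frac)
}

#' Assign peaks to genes through promoter-to-terminator windows
#'
#' A peak is assigned to a gene when it overlaps, by at least one base,
#' the strand-aware window running from `upstream` bp before the TSS to
#' `downstream` bp past the TES. One peak may be assigned to several
#' genes; a gene is "bound" when at least one peak is assigned to it.
#'
#' @param peaks Peak tibble.
#' @param annotation A [genome_annotation()].
#' @param upstream Window extension upstream of the TSS in bp (default
#'   1000).
#' @param downstream Window extension downstream of the TES in bp
#'   (default 100).
#' @return Tibble with one row per (peak, gene) assignment: `peak_id`
#'   (row index into `peaks`), `name`, `gene_id`.
#' @export
assign_peaks_to_genes <- function(peaks, annotation,
                                  upstream = 1000, downstream = 100) {
  stopifnot(upstream >= 0, downstream >= 0)
  check_peaks(peaks)
  genes <- annotation$genes
  if (nrow(peaks) == 0 || nrow(genes) == 0) {
    return(tibble(peak_id = integer(), name = character(), gene_id = character()))
  }
  win <- gene_windows(genes, chrom_lengths(annotation), upstream, downstream)
  grp <- intervals_to_granges(peaks)
  grw <- intervals_to_granges(win)
  GenomicRanges::strand(grw) <- "*"
  hits <- GenomicRanges::findOverlaps(grp, grw)
  tibble(
    peak_id = S4Vectors::queryHits(hits),
    name = if ("name" %in% names(peaks)) peaks$name[S4Vectors::queryHits(hits)]
           else NA_character_,
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)]
  ) |> arrange(.data$peak_id, .data$gene_id)
}

# Strand-aware promoter-to-terminator windows, clipped to chromosome bounds.
gene_windows <- function(genes, lengths, upstream, downstream) {
  genes |>
    mutate(
      w_start = if_else(.data$strand == "+",
                        .data$start - upstream, .data$start - downstream),
      w_end = if_else(.data$strand == "+",
                      .data$end + downstream, .data$end + upstream),
      start = pmax(0L, as.integer(.data$w_start)),
      end = pmin(as.integer(lengths[.data$chrom]), as.integer(.data$w_end))
    ) |>
    select("gene_id", "chrom", "strand", "start", "end")
}

#' Gene-level bound flags from peak assignments
#'
#' @param assignments Output of [assign_peaks_to_genes()].
#' @param annotation A [genome_annotation()] supplying the gene universe.
#' @return Tibble `gene_id`, `bound` (logical), one row per annotated gene.
#' @export
bound_genes <- function(assignments, annotation) {
  tibble(gene_id = annotation$genes$gene_id,
         bound = annotation$genes$gene_id %in% assignments$gene_id)
}
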