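# Chromosomal-distribution enrichment, eight-category genomic-feature
# annotation, and gene-body-scaled metagene profiles.

#' Chromosomal distribution of peaks with binomial enrichment
#'
#' For each chromosome, tests whether more peaks fall on it than expected
#' from its share of the genome: with `k` of `n` peaks on a chromosome
#' covering fraction `p0` of the genome, the one-sided binomial tail
#' P(X >= k), X ~ Binomial(n, p0).
#'
#' @param peaks Peak tibble.
#' @param annotation A [genome_annotation()] supplying chromosome lengths.
#' @return Tibble with columns `chrom`, `k`, `n`, `p0`, `p_value`, one row
#'   per annotated chromosome.
#' @export
chrom_distribution <- function(peaks, annotation) {
  check_peaks(peaks)
  n <- nrow(peaks)
  if (n == 0) abort("chrom_distribution requires at least one peak")
  chroms <- annotation$chromosomes
  unknown <- setdiff(peaks$chrom, chroms$chrom)
  if (length(unknown) > 0) {
    abort(sprintf("peaks on unknown chromosome(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  counts <- table(factor(peaks$chrom, levels = chroms$chrom))
  tibble(
    chrom = chroms$chrom,
    k = as.integer(counts),
    n = n,
    p0 = chroms$length / sum(chroms$length),
    p_value = pbinom(as.integer(counts) - 1L, size = n,
                     prob = chroms$length / sum(chroms$length),
                     lower.tail = FALSE)
  )
}

#' Fraction of peaks on a designated euchromatic chromosome subset
#'
#' @param peaks Peak tibble.
#' @param arms Character vector of euchromatic chromosome names (default
#'   the Drosophila euchromatic arms 2L, 2R, 3L, 3R, X).
#' @return Tibble with `n_euchromatic`, `n_total`, `fraction`, `percent`.
#' @export
euchromatic_fraction <- function(peaks, arms = c("2L", "2R", "3L", "3R", "X")) {
  check_peaks(peaks)
  k <- sum(peaks$chrom %in% arms)
  tibble(n_euchromatic = k, n_total = nrow(peaks),
         fraction = ifelse(nrow(peaks) == 0, NA_real_, k / nrow(peaks)),
         percent = pct_of(k, nrow(peaks)))
}

# Feature categories in precedence order: when a peak midpoint lies in
# overlapping annotations of different genes, the first matching category
# wins (promoter-proximal first, consistent with TSS-centred binding).
feature_levels <- c("promoter_le1kb", "utr5", "utr3", "coding_exon",
                    "intron", "promoter_1to2kb", "promoter_2to3kb",
                    "distal_intergenic")

# Display order for tables/plots (promoter tiers together).
feature_display_levels <- c("promoter_le1kb", "promoter_1to2kb",
                            "promoter_2to3kb", "utr5", "coding_exon",
                            "intron", "utr3", "distal_intergenic")

#' Annotate peaks with one of eight genomic-feature categories
#'
#' Each peak is categorized by the location of its midpoint:
#' promoter tiers (<=1 kb, 1-2 kb, 2-3 kb upstream of a TSS, strand-aware),
#' 5'UTR, coding exon, intron, 3'UTR, or distal intergenic. UTRs are
#' derived from CDS bounds; genes without a CDS contribute no UTR
#' intervals. When the midpoint falls in overlapping annotations of
#' different genes the category is resolved by the precedence
#' promoter_le1kb > utr5 > utr3 > coding_exon > intron > promoter_1to2kb >
#' promoter_2to3kb > distal_intergenic.
#'
#' @param peaks Peak tibble.
#' @param annotation A [genome_annotation()] with exon (and, where
#'   available, CDS) structure.
#' @return The peak tibble with an added `category` factor column.
#' @export
annotate_features <- function(peaks, annotation) {
  check_peaks(peaks)
  if (nrow(peaks) == 0) {
    peaks$category <- factor(character(), levels = feature_display_levels)
    return(peaks)
  }
  mid <- peaks$start + (peaks$end - peaks$start) %/% 2L
  midpoints <- tibble(chrom = peaks$chrom, start = mid, end = mid + 1L)
  grm <- intervals_to_granges(midpoints)

  feats <- feature_intervals(annotation)
  cat_idx <- rep(match("distal_intergenic", feature_levels), nrow(peaks))
  for (i in seq_along(feature_levels)) {
    fl <- feature_levels[i]
    if (fl == "distal_intergenic") next
    fi <- feats[[fl]]
    if (is.null(fi) || nrow(fi) == 0) next
    hit <- GenomicRanges::countOverlaps(grm, intervals_to_granges(fi)) > 0
    cat_idx <- ifelse(hit & i < cat_idx, i, cat_idx)
  }
  peaks$category <- factor(feature_levels[cat_idx],
                           levels = feature_display_levels)
  peaks
}

# Build the category interval tables from gene models.
feature_intervals <- function(annotation) {
  genes <- annotation$genes
  if (nrow(genes) == 0) return(list())
  lengths <- chrom_lengths(annotation)
  tss <- tss_of(genes)
  plus <- genes$strand == "+"

  prom_tier <- function(lo, hi) {
    s <- ifelse(plus, tss - hi, tss + lo + 1L)
    e <- ifelse(plus, tss - lo, tss + hi + 1L)
    tibble(chrom = genes$chrom,
           start = pmax(0L, as.integer(s)),
           end = pmin(as.integer(lengths[genes$chrom]), as.integer(e))) |>
      filter(.data$start < .data$end)
  }

  # true introns: per-gene gaps between consecutive exons
  introns <- tibble(
    chrom = rep(genes$chrom, pmax(0L, lengths(genes$exon_starts) - 1L)),
    start = as.integer(unlist(map(genes$exon_ends, ~head(.x, -1)))),
    end = as.integer(unlist(map(genes$exon_starts, ~tail(.x, -1))))
  ) |> filter(.data$start < .data$end)

  has_cds <- !is.na(genes$cds_start)
  utr5 <- utr3 <- cexon <- tibble(chrom = character(), start = integer(),
                                  end = integer())
  if (any(has_cds)) {
    g <- genes[has_cds, ]
    gx <- tibble(
      gene = rep(seq_len(nrow(g)), lengths(g$exon_starts)),
      chrom = rep(g$chrom, lengths(g$exon_starts)),
      strand = rep(g$strand, lengths(g$exon_starts)),
      start = as.integer(unlist(g$exon_starts)),
      end = as.integer(unlist(g$exon_ends)),
      cds_start = rep(g$cds_start, lengths(g$exon_starts)),
      cds_end = rep(g$cds_end, lengths(g$exon_starts))
    )
    # exonic sequence before the CDS (5' side) and after it (3' side),
    # swapped for minus-strand genes
    left <- gx |>
      mutate(end = pmin(.data$end, .data$cds_start)) |>
      filter(.data$start < .data$end)
    right <- gx |>
      mutate(start = pmax(.data$start, .data$cds_end)) |>
      filter(.data$start < .data$end)
    utr5 <- bind_rows(filter(left, .data$strand == "+"),
                      filter(right, .data$strand == "-")) |>
      select("chrom", "start", "end")
    utr3 <- bind_rows(filter(right, .data$strand == "+"),
                      filter(left, .data$strand == "-")) |>
      select("chrom", "start", "end")
    cexon <- gx |>
      mutate(start = pmax(.data$start, .data$cds_start),
             end = pmin(.data$end, .data$cds_end)) |>
      filter(.data$start < .data$end) |>
      select("chrom", "start", "end")
  }

  list(
    promoter_le1kb = prom_tier(0L, 1000L),
    promoter_1to2kb = prom_tier(1000L, 2000L),
    promoter_2to3kb = prom_tier(2000L, 3000L),
    utr5 = utr5,
    utr3 = utr3,
    coding_exon = cexon,
    intron = introns
  )
}

#' Feature-category count and percentage table
#'
#' @param annotated Output of [annotate_features()].
#' @return Tibble `category`, `n`, `pct` covering all eight categories;
#'   percentages sum to 100 up to rounding.
#' @export
feature_summary <- function(annotated) {
  stopifnot("category" %in% names(annotated))
  tab <- table(annotated$category)
  tibble(category = factor(names(tab), levels = feature_display_levels),
         n = as.integer(tab),
         pct = 100 * as.integer(tab) / max(1L, nrow(annotated)))
}

#' Read a signal track (bedGraph or fixed-step wiggle)
#'
#' @param path Path to the track.
#' @param format `"bedGraph"` or `"wig"`.
#' @return Tibble `chrom`, `start`, `end` (0-based half-open), `value`.
#' @export
read_signal <- function(path, format = c("bedGraph", "wig")) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = format)
  tibble(chrom = as.character(GenomeInfoDb::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         value = as.numeric(gr$score))
}

#' Write a signal track as bedGraph
#'
#' @param signal Signal tibble (`chrom`, `start`, `end`, `value`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_bedgraph <- function(signal, path) {
  writeLines(sprintf("%s\t%d\t%d\t%g", signal$chrom, signal$start,
                     signal$end, signal$value), path)
  invisible(path)
}

#' Metagene average-signal profile
#'
#' Averages a signal track over genes after aligning their TSSs and TESs:
#' fixed-width flanks of `flank` bp on each side are binned into
#' `upstream_bins` and `downstream_bins` bins, and each gene body is
#' rescaled to `body_bins` bins (per-bin base averaging for genes at least
#' `body_bins` bp long, linear interpolation for shorter genes). Minus
#' strand genes are reversed before averaging so that bin 1 is always the
#' 5' flank; every gene carries equal weight. Signal is taken as 0 where
#' the track is undefined.
#'
#' @param signal Signal tibble (`chrom`, `start`, `end`, `value`),
#'   non-overlapping intervals.
#' @param genes Gene-model tibble or [genome_annotation()].
#' @param flank Flank size in bp (default 2000, i.e. -2 kb of the TSS to
#'   +2 kb of the TES).
#' @param upstream_bins,body_bins,downstream_bins Bin counts (defaults
#'   100/200/100).
#' @return A `metagene_profile`: tibble with `bin`, `segment`
#'   (upstream/body/downstream), `value`; attributes `n_genes`, `flank`
#'   and the bin counts.
#' @export
metagene <- function(signal, genes, flank = 2000,
                     upstream_bins = 100, body_bins = 200,
                     downstream_bins = 100) {
  genes <- as_gene_table(genes)
  if (nrow(genes) == 0) abort("metagene requires at least one gene")
  stopifnot(flank > 0, upstream_bins > 0, body_bins > 0, downstream_bins > 0)

  cov <- signal_coverage(signal)
  nb <- upstream_bins + body_bins + downstream_bins
  acc <- numeric(nb)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    vals <- extract_values(cov, g$chrom, g$start - flank, g$end + flank)
    if (g$strand == "-") vals <- rev(vals)
    up <- bin_means(vals[seq_len(flank)], upstream_bins)
    body <- rescale_body(vals[(flank + 1):(flank + (g$end - g$start))],
                         body_bins)
    down <- bin_means(vals[(flank + (g$end - g$start) + 1):length(vals)],
                      downstream_bins)
    acc <- acc + c(up, body, down)
  }
  profile <- tibble(
    bin = seq_len(nb),
    segment = factor(rep(c("upstream", "body", "downstream"),
                         c(upstream_bins, body_bins, downstream_bins)),
                     levels = c("upstream", "body", "downstream")),
    value = acc / nrow(genes)
  )
  structure(profile, class = c("metagene_profile", class(profile)),
            n_genes = nrow(genes), flank = flank,
            upstream_bins = upstream_bins, body_bins = body_bins,
            downstream_bins = downstream_bins)
}

# Per-chromosome run-length encodings of the signal for fast extraction.
signal_coverage <- function(signal) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(signal)))
  split_sig <- split(signal, signal$chrom)
  lapply(split_sig, function(s) {
    IRanges::coverage(
      IRanges::IRanges(start = s$start + 1L, end = s$end),
      weight = s$value, width = max(s$end))
  })
}

# Per-base values over [start, end), 0-padded outside the defined track.
extract_values <- function(cov, chrom, start, end) {
  n <- end - start
  out <- numeric(n)
  rle <- cov[[chrom]]
  if (is.null(rle)) return(out)
  lo <- max(start, 0L)
  hi <- min(end, length(rle))
  if (hi > lo) {
    out[(lo - start + 1):(hi - start)] <-
      as.numeric(S4Vectors::window(rle, start = lo + 1L, end = hi))
  }
  out
}

# Mean signal per bin: bases are dealt to bins by floor((i-1)*bins/n);
# when fewer bases than bins, fall back to linear interpolation.
bin_means <- function(vals, bins) {
  n <- length(vals)
  if (n < bins) {
    return(stats::approx(x = seq_len(n), y = vals,
                         xout = seq(1, n, length.out = bins), rule = 2)$y)
  }
  idx <- pmin(bins, 1L + ((seq_len(n) - 1L) * bins) %/% n)
  as.numeric(tapply(vals, factor(idx, levels = seq_len(bins)), mean))
}

# Gene-body rescaling: base averaging for long genes, linear interpolation
# at body-bin midpoints for genes shorter than the bin count.
rescale_body <- function(vals, bins) {
  if (length(vals) >= bins) return(bin_means(vals, bins))
  stats::approx(x = seq_along(vals), y = vals,
                xout = seq(1, length(vals), length.out = bins),
                rule = 2)$y
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %d bins over %d gene(s), flank %d bp\n",
              nrow(x), attr(x, "n_genes"), attr(x, "flank")))
  NextMethod()
}

#' @export
tidy.metagene_profile <- function(x, ...) {
  as_tibble(x)
}
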