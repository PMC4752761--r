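# Internal helpers shared across modules.

#' Integer-rounded percentage
#'
#' The rounding rule used everywhere a percentage is reported:
#' `round(100 * numerator / denominator)` to the nearest integer
#' (round-half-even, R's default). A zero denominator yields `NA`
#' (undefined), never 0.
#'
#' @param numerator,denominator Non-negative numeric vectors, recycled.
#' @return Integer vector of percentages; `NA` where `denominator == 0`.
#' @examples
#' pct_of(243, 263)  # 92
#' pct_of(83, 133)   # 62
#' @export
pct_of <- function(numerator, denominator) {
  stopifnot(all(numerator >= 0, na.rm = TRUE), all(denominator >= 0, na.rm = TRUE))
  out <- ifelse(denominator == 0, NA_real_, round(100 * numerator / denominator))
  as.integer(out)
}

# Validate a peak tibble: required columns, half-open coordinates.
check_peaks <- function(peaks, arg = "peaks") {
  need <- c("chrom", "start", "end")
  missing <- setdiff(need, names(peaks))
  if (length(missing) > 0) {
    abort(sprintf("`%s` lacks required column(s): %s", arg,
                  paste(missing, collapse = ", ")))
  }
  if (nrow(peaks) > 0 && any(peaks$end <= peaks$start)) {
    abort(sprintf("`%s` contains intervals with end <= start", arg))
  }
  invisible(peaks)
}

# Convert a tibble of 0-based half-open intervals to GRanges (1-based closed).
intervals_to_granges <- function(x, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) x$strand else "*"
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

# Inverse of intervals_to_granges: GRanges to 0-based half-open tibble.
granges_to_intervals <- function(gr) {
  tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

# Named vector of chromosome lengths from an annotation.
chrom_lengths <- function(annotation) {
  setNames(annotation$chromosomes$length, annotation$chromosomes$chrom)
}
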