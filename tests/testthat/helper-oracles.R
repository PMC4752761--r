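# Brute-force oracles, independent of the package's interval machinery
# (plain sorting/looping in base R), plus small random-instance factories.

# overlap width of [s1,e1) and [s2,e2)
ov_width <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

oracle_filter <- function(peaks, min_fold) {
  peaks[peaks$fold_enrichment >= min_fold, ]
}

# rep1 peaks with >= min_frac of their length overlapped by some single
# rep2 peak
oracle_concordant <- function(rep1, rep2, min_frac) {
  keep <- vapply(seq_len(nrow(rep1)), function(i) {
    j <- which(rep2$chrom == rep1$chrom[i])
    if (length(j) == 0) return(FALSE)
    best <- max(ov_width(rep1$start[i], rep1$end[i],
                         rep2$start[j], rep2$end[j]))
    best >= min_frac * (rep1$end[i] - rep1$start[i])
  }, logical(1))
  rep1[keep, ]
}

# merge intervals by plain sort/scan
merge_scan <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

# count x peaks whose summed overlap with merged y covers >= min_frac of
# the x peak
oracle_overlap_count <- function(x, y, min_frac) {
  n <- 0L
  for (i in seq_len(nrow(x))) {
    j <- which(y$chrom == x$chrom[i])
    if (length(j) == 0) next
    m <- merge_scan(y$start[j], y$end[j])
    covered <- sum(ov_width(x$start[i], x$end[i], m$start, m$end))
    if (covered >= min_frac * (x$end[i] - x$start[i])) n <- n + 1L
  }
  n
}

# gene ids bound by >= 1 peak under the strand-aware window rule
oracle_bound_set <- function(peaks, genes, lengths, upstream, downstream) {
  bound <- character(0)
  for (g in seq_len(nrow(genes))) {
    if (genes$strand[g] == "+") {
      ws <- genes$start[g] - upstream
      we <- genes$end[g] + downstream
    } else {
      ws <- genes$start[g] - downstream
      we <- genes$end[g] + upstream
    }
    ws <- max(0, ws)
    we <- min(lengths[[genes$chrom[g]]], we)
    j <- which(peaks$chrom == genes$chrom[g])
    if (any(ov_width(peaks$start[j], peaks$end[j], ws, we) > 0)) {
      bound <- c(bound, genes$gene_id[g])
    }
  }
  bound
}

# per-peak feature category by exhaustive rule evaluation at the midpoint
oracle_feature <- function(peak_start, peak_end, peak_chrom, annotation) {
  mid <- peak_start + (peak_end - peak_start) %/% 2
  genes <- annotation$genes
  in_iv <- function(pos, s, e) pos >= s & pos < e
  hits <- character(0)
  for (g in seq_len(nrow(genes))) {
    if (genes$chrom[g] != peak_chrom) next
    plus <- genes$strand[g] == "+"
    tss <- if (plus) genes$start[g] else genes$end[g] - 1
    prom <- function(lo, hi) {
      if (plus) in_iv(mid, tss - hi, tss - lo) else in_iv(mid, tss + lo + 1, tss + hi + 1)
    }
    es <- genes$exon_starts[[g]]; ee <- genes$exon_ends[[g]]
    in_exon <- any(in_iv(mid, es, ee))
    in_tx <- in_iv(mid, genes$start[g], genes$end[g])
    cs <- genes$cds_start[g]; ce <- genes$cds_end[g]
    if (prom(0, 1000)) hits <- c(hits, "promoter_le1kb")
    if (!is.na(cs)) {
      before <- in_exon && mid < cs
      after <- in_exon && mid >= ce
      if ((plus && before) || (!plus && after)) hits <- c(hits, "utr5")
      if ((plus && after) || (!plus && before)) hits <- c(hits, "utr3")
      if (in_exon && mid >= cs && mid < ce) hits <- c(hits, "coding_exon")
    }
    if (in_tx && !in_exon) hits <- c(hits, "intron")
    if (prom(1000, 2000)) hits <- c(hits, "promoter_1to2kb")
    if (prom(2000, 3000)) hits <- c(hits, "promoter_2to3kb")
  }
  precedence <- c("promoter_le1kb", "utr5", "utr3", "coding_exon", "intron",
                  "promoter_1to2kb", "promoter_2to3kb")
  for (p in precedence) if (p %in% hits) return(p)
  "distal_intergenic"
}

# one-sided binomial tail by direct pmf summation
binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(stats::dbinom(k:n, n, p))
}

# one-sided hypergeometric tail by direct pmf summation:
# N genes, n with the term, draw K, observe >= k
hyper_tail <- function(k, N, n, K) {
  if (k <= 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  sum(choose(n, k:hi) * choose(N - n, K - (k:hi))) / choose(N, K)
}

# random peak tibble on a small genome
random_peaks <- function(n, chroms = c("2L", "2R"), max_pos = 50000,
                         max_width = 600) {
  w <- sample(10:max_width, n, replace = TRUE)
  s <- sample(0:(max_pos - max_width - 1), n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = s, end = s + w,
                 name = sprintf("p%04d", seq_len(n)),
                 fold_enrichment = stats::runif(n, 0.5, 12),
                 neg_log10_p = stats::runif(n, 0, 50),
                 source_label = "rand")
}

# random gene models (no exon structure beyond single exon)
random_genes <- function(n, chroms = c("2L", "2R"), max_pos = 50000) {
  w <- sample(200:3000, n, replace = TRUE)
  s <- sample(0:(max_pos - 3001), n, replace = TRUE)
  tibble::tibble(gene_id = sprintf("g%04d", seq_len(n)),
                 chrom = sample(chroms, n, replace = TRUE),
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 start = s, end = s + w)
}

small_annotation <- function(genes, chrom_len = 60000,
                             chroms = c("2L", "2R")) {
  genome_annotation(genes, tibble::tibble(chrom = chroms,
                                          length = chrom_len))
}

# a small, fast, zero-noise bundle for pipeline-level tests
tiny_bundle <- function(seed = 11, ...) {
  cfg <- simulate_config(
    seed = seed,
    n_genes = 120L,
    class_counts = c(A_r = 8L, A_a = 6L, B_r = 4L, B_a = 4L, C_r = 7L,
                     C_a = 6L, D = 4L),
    n_indirect = c(kd_up = 3L, kd_down = 4L, oe_up = 3L, oe_down = 4L),
    n_bound_only = c(iso187 = 10L, iso220 = 12L, both = 20L),
    n_extra_peaks = 40L,
    n_noise_peaks = 10L,
    ...)
  simulate_bundle(cfg)
}

as_pipeline_input <- function(bundle) {
  list(annotation = bundle$annotation, peaks = bundle$peaks,
       de = bundle$de, signal = bundle$signal, terms = bundle$terms,
       pool_map = bundle$pool_map)
}
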