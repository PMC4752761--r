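make_toy_annotation <- function() {
  # three genes with exon/CDS structure on one chromosome
  genes <- tibble::tibble(
    gene_id = c("gp", "gm", "gn"),
    chrom = "2L",
    strand = c("+", "-", "+"),
    start = c(10000L, 30000L, 50000L),
    end = c(16000L, 36000L, 52000L),
    exon_starts = list(c(10000L, 14000L), c(30000L, 34000L), 50000L),
    exon_ends = list(c(11500L, 16000L), c(31500L, 36000L), 52000L),
    cds_start = c(10800L, 30800L, NA),
    cds_end = c(15200L, 35200L, NA)
  )
  genome_annotation(genes, tibble::tibble(chrom = c("2L", "4"),
                                          length = c(80000L, 20000L)))
}

test_that("binomial chromosome enrichment matches closed forms", {
  ann <- make_toy_annotation()
  # all peaks on 2L: P(X >= n) = p0^n
  pk <- tibble::tibble(chrom = "2L", start = seq(0, 900, 100),
                       end = seq(50, 950, 100))
  cd <- chrom_distribution(pk, ann)
  p0_2L <- 80000 / 100000
  expect_equal(cd$p_value[cd$chrom == "2L"], p0_2L^10)
  # zero peaks on chromosome 4: tail at k = 0 is 1
  expect_equal(cd$p_value[cd$chrom == "4"], 1)
  expect_equal(sum(cd$k), nrow(pk))
  expect_error(chrom_distribution(pk[0, ], ann), "at least one peak")
})

test_that("binomial tail equals exhaustive pmf summation and is monotone in k", {
  ps <- c()
  for (k in c(10, 20, 30, 40)) {
    got <- pbinom(k - 1, 100, 0.2, lower.tail = FALSE)
    expect_equal(got, binom_tail(k, 100, 0.2), tolerance = 1e-12)
    ps <- c(ps, got)
  }
  expect_true(all(diff(ps) < 0))
})

test_that("euchromatic fraction recovers a planted 99/1 split", {
  pk <- tibble::tibble(
    chrom = c(rep(c("2L", "2R", "3L", "3R", "X"), length.out = 99), "4"),
    start = 0L, end = 100L)
  ef <- euchromatic_fraction(pk)
  expect_equal(ef$n_euchromatic, 99L)
  expect_equal(ef$percent, 99L)
})

test_that("feature categories follow the midpoint rules", {
  ann <- make_toy_annotation()
  cases <- tibble::tibble(
    chrom = "2L",
    # midpoints: 500 bp upstream of gp TSS; inside gp intron; gp 5'UTR;
    # gp coding exon; gp 3'UTR side; 1-2kb upstream; far away
    start = c(9400L, 12000L, 10400L, 11000L, 15500L, 8400L, 70000L),
    end = c(9600L, 12002L, 10402L, 11002L, 15502L, 8602L, 70002L))
  got <- annotate_features(cases, ann)$category
  expect_equal(as.character(got),
               c("promoter_le1kb", "intron", "utr5", "coding_exon", "utr3",
                 "promoter_1to2kb", "distal_intergenic"))
})

test_that("every peak gets exactly one category and percentages sum to 100", {
  ann <- make_toy_annotation()
  set.seed(707)
  pk <- tibble::tibble(chrom = "2L",
                       start = sample(0:79000, 300, replace = TRUE))
  pk$end <- pk$start + 200L
  annotated <- annotate_features(pk, ann)
  expect_false(any(is.na(annotated$category)))
  fs <- feature_summary(annotated)
  expect_equal(sum(fs$n), 300L)
  expect_equal(sum(fs$pct), 100)
})

test_that("feature categories match the exhaustive-rule oracle", {
  ann <- make_toy_annotation()
  set.seed(808)
  pk <- tibble::tibble(chrom = "2L",
                       start = sample(0:79000, 300, replace = TRUE))
  pk$end <- pk$start + sample(50:500, 300, replace = TRUE)
  got <- as.character(annotate_features(pk, ann)$category)
  want <- vapply(seq_len(nrow(pk)), function(i) {
    oracle_feature(pk$start[i], pk$end[i], pk$chrom[i], ann)
  }, character(1))
  expect_equal(got, want)
})

test_that("bedGraph and fixed-step wiggle tracks read to the same signal", {
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("2L\t100\t110\t1.5", "2L\t110\t120\t2.5"), bg)
  wig <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=2L start=101 step=10 span=10",
               "1.5", "2.5"), wig)
  s1 <- read_signal(bg, "bedGraph")
  s2 <- read_signal(wig, "wig")
  expect_equal(s1$start, s2$start)
  expect_equal(s1$end, s2$end)
  expect_equal(s1$value, s2$value)
})

test_that("constant signal yields a flat metagene profile", {
  genes <- tibble::tibble(gene_id = c("a", "b"), chrom = "2L",
                          strand = c("+", "-"),
                          start = c(10000L, 30000L), end = c(14000L, 33000L))
  signal <- tibble::tibble(chrom = "2L", start = 0L, end = 60000L,
                           value = 1.0)
  prof <- metagene(signal, genes, flank = 2000)
  expect_equal(prof$value, rep(1, 400))
  expect_error(metagene(signal, genes[0, ]), "at least one gene")
})

test_that("a rectangular bump over one gene body maps to body bins only", {
  genes <- tibble::tibble(gene_id = "a", chrom = "2L", strand = "+",
                          start = 10000L, end = 14000L)
  signal <- tibble::tibble(chrom = "2L", start = 10000L, end = 14000L,
                           value = 1.0)
  prof <- metagene(signal, genes, flank = 2000)
  expect_equal(prof$value[prof$segment == "body"], rep(1, 200))
  expect_equal(prof$value[prof$segment != "body"], rep(0, 200))
})

test_that("planted TSS bumps localize to the TSS bin across simulated genes", {
  set.seed(909)
  n <- 20
  starts <- seq(10000L, by = 10000L, length.out = n)
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:n), chrom = "2L",
                          strand = sample(c("+", "-"), n, replace = TRUE),
                          start = starts,
                          end = starts + sample(2000:4000, n, replace = TRUE))
  tss <- tss_of(genes)
  sig <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    x <- seq(tss[i] - 600, tss[i] + 600, by = 20)
    tibble::tibble(chrom = "2L", start = as.integer(x),
                   end = as.integer(x + 20),
                   value = exp(-(x + 10 - tss[i])^2 / (2 * 150^2)))
  }))
  prof <- metagene(sig, genes, flank = 2000)
  # TSS sits at the boundary between upstream flank and body: bin 100/101
  expect_true(which.max(prof$value) %in% c(100, 101))
})

test_that("metagene is invariant to gene order and equivariant to scaling", {
  b <- tiny_bundle(seed = 5)
  genes <- b$annotation$genes[1:10, ]
  sig <- b$signal$iso220
  p1 <- metagene(sig, genes, flank = 1000, upstream_bins = 20,
                 body_bins = 40, downstream_bins = 20)
  p2 <- metagene(sig, genes[sample(10), ], flank = 1000, upstream_bins = 20,
                 body_bins = 40, downstream_bins = 20)
  expect_equal(p1$value, p2$value)
  sig3 <- dplyr::mutate(sig, value = 3 * value)
  p3 <- metagene(sig3, genes, flank = 1000, upstream_bins = 20,
                 body_bins = 40, downstream_bins = 20)
  expect_equal(p3$value, 3 * p1$value)
})
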