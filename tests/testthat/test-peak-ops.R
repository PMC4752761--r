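test_that("fold filtering keeps the inclusive boundary and preserves order", {
  pk <- tibble::tibble(chrom = "2L", start = c(0, 100, 200),
                       end = c(50, 150, 250), name = c("a", "b", "c"),
                       fold_enrichment = c(2.9, 3.0, 10.0))
  out <- filter_by_fold(pk, 3)
  expect_equal(out$name, c("b", "c"))
  expect_equal(nrow(filter_by_fold(pk[0, ], 3)), 0)
})

test_that("fold filtering matches the one-line oracle on random sets", {
  set.seed(101)
  for (i in 1:10) {
    pk <- random_peaks(50)
    expect_equal(filter_by_fold(pk, 3), oracle_filter(pk, 3))
  }
})

test_that("replicate concordance keeps identical and drops disjoint replicates", {
  pk <- random_peaks(20)
  expect_equal(nrow(replicate_concordant(pk, pk, 0.5)), nrow(pk))
  shifted <- dplyr::mutate(pk, start = start + 100000, end = end + 100000)
  expect_equal(nrow(replicate_concordant(pk, shifted, 0.5)), 0)
})

test_that("replicate concordance matches the all-pairs oracle", {
  set.seed(202)
  for (i in 1:10) {
    r1 <- random_peaks(30, max_pos = 5000)
    r2 <- random_peaks(30, max_pos = 5000)
    got <- replicate_concordant(r1, r2, 0.5)
    want <- oracle_concordant(r1, r2, 0.5)
    expect_equal(got$name, want$name)
  }
})

test_that("50% reciprocal overlap boundaries behave as documented", {
  a <- tibble::tibble(chrom = "2L", start = 0, end = 100)
  b <- tibble::tibble(chrom = "2L", start = 50, end = 150)
  rep1 <- compare_peaksets(a, b, 0.5)
  expect_equal(rep1$n_a_overlapping, 1L)  # exactly 50% counts (inclusive)
  expect_equal(rep1$n_b_overlapping, 1L)
  b2 <- tibble::tibble(chrom = "2L", start = 90, end = 400)
  rep2 <- compare_peaksets(a, b2, 0.5)
  expect_equal(rep2$n_a_overlapping, 0L)  # 10% of a, ~3% of b
  expect_equal(rep2$n_b_overlapping, 0L)
})

test_that("summed overlap across several partners counts toward the fraction", {
  a <- tibble::tibble(chrom = "2L", start = 0, end = 100)
  b <- tibble::tibble(chrom = "2L", start = c(0, 60), end = c(30, 90))
  # two partners cover 30 + 30 = 60 bp of the 100 bp peak
  expect_equal(compare_peaksets(a, b, 0.5)$n_a_overlapping, 1L)
})

test_that("compare_peaksets is symmetric under argument swap", {
  set.seed(303)
  a <- random_peaks(80, max_pos = 20000)
  b <- random_peaks(60, max_pos = 20000)
  ab <- compare_peaksets(a, b, 0.5)
  ba <- compare_peaksets(b, a, 0.5)
  expect_equal(ab$pct_a, ba$pct_b)
  expect_equal(ab$pct_b, ba$pct_a)
  expect_equal(ab$n_a_overlapping, ba$n_b_overlapping)
  # and indifferent to input row order
  shuffled <- compare_peaksets(a[sample(nrow(a)), ], b[sample(nrow(b)), ], 0.5)
  expect_equal(shuffled$n_a_overlapping, ab$n_a_overlapping)
  expect_equal(shuffled$n_b_overlapping, ab$n_b_overlapping)
})

test_that("directional overlap counts match the quadratic oracle", {
  set.seed(404)
  for (i in 1:10) {
    a <- random_peaks(60, max_pos = 8000)
    b <- random_peaks(60, max_pos = 8000)
    got <- compare_peaksets(a, b, 0.5)
    expect_equal(got$n_a_overlapping, oracle_overlap_count(a, b, 0.5))
    expect_equal(got$n_b_overlapping, oracle_overlap_count(b, a, 0.5))
  }
})

test_that("peak-to-gene assignment respects the strand-aware window", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "2L", strand = "+",
                          start = 5000L, end = 8000L)
  ann <- small_annotation(genes, chrom_len = 20000, chroms = "2L")
  inside <- tibble::tibble(chrom = "2L", start = 3900, end = 4100,
                           name = "p1")
  expect_equal(assign_peaks_to_genes(inside, ann)$gene_id, "g1")
  beyond <- tibble::tibble(chrom = "2L", start = 8100, end = 8200,
                           name = "p2")
  expect_equal(nrow(assign_peaks_to_genes(beyond, ann)), 0)
  # minus strand: the 1 kb extension flips to the right of the gene
  genes_m <- dplyr::mutate(genes, strand = "-")
  ann_m <- small_annotation(genes_m, chrom_len = 20000, chroms = "2L")
  expect_equal(nrow(assign_peaks_to_genes(inside, ann_m)), 0)
  expect_equal(assign_peaks_to_genes(beyond, ann_m)$gene_id, "g1")
})

test_that("bound-gene sets match the quadratic window oracle", {
  set.seed(505)
  for (i in 1:8) {
    genes <- random_genes(50)
    ann <- small_annotation(genes)
    pk <- random_peaks(200)
    asg <- assign_peaks_to_genes(pk, ann)
    got <- sort(unique(asg$gene_id))
    want <- sort(oracle_bound_set(pk, genes, c(`2L` = 60000, `2R` = 60000),
                                  1000, 100))
    expect_equal(got, want)
  }
})

test_that("enlarging the window never unbinds a gene", {
  set.seed(606)
  genes <- random_genes(40)
  ann <- small_annotation(genes)
  pk <- random_peaks(150)
  small <- bound_genes(assign_peaks_to_genes(pk, ann, 500, 50), ann)
  big <- bound_genes(assign_peaks_to_genes(pk, ann, 2000, 500), ann)
  expect_true(all(big$bound[small$bound]))
})

test_that("duplicate peak coordinates are removed on read with a warning", {
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("2L\t100\t200\tp1\t0\t.\t5\t10\t-1\t-1",
               "2L\t100\t200\tp1dup\t0\t.\t6\t11\t-1\t-1",
               "2L\t300\t400\tp2\t0\t.\t4\t9\t-1\t-1"), path)
  expect_warning(pk <- read_peaks(path), "duplicate")
  expect_equal(nrow(pk), 2)
  expect_equal(pk$fold_enrichment, c(5, 4))
})

test_that("narrowPeak files round-trip through write/read", {
  pk <- random_peaks(25)
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  write_peaks_narrowpeak(pk, path)
  back <- read_peaks(path, source_label = "rand")
  orig <- dplyr::arrange(pk, chrom, start)
  expect_equal(back$chrom, orig$chrom)
  expect_equal(back$start, as.integer(orig$start))
  expect_equal(back$end, as.integer(orig$end))
  expect_equal(back$fold_enrichment, orig$fold_enrichment,
               tolerance = 1e-5)
})
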