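make_annotation_table <- function(N = 20, terms = 3, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(N))
  dplyr::bind_rows(lapply(seq_len(terms), function(t) {
    tibble::tibble(gene_id = sample(genes, sample(5:N, 1)),
                   term_id = sprintf("T%02d", t),
                   term_name = sprintf("term %d", t))
  }))
}

test_that("hypergeometric enrichment matches closed forms", {
  genes <- sprintf("g%02d", 1:10)
  ann <- tibble::tibble(gene_id = genes, term_id = rep(c("T1", "T2"), 5))
  # k = 0 for a term: p = 1
  sel0 <- genes[seq(2, 10, 2)]  # all T2
  res <- enrich(sel0, genes, ann, method = "hypergeometric")
  expect_equal(res$p_value[res$term_id == "T1"], 1)
  # N=10, n=5, K=5, k=5: p = 1/C(10,5)
  ann2 <- tibble::tibble(gene_id = genes,
                         term_id = rep(c("T1", "T2"), each = 5))
  res2 <- enrich(genes[1:5], genes, ann2, method = "hypergeometric")
  expect_equal(res2$p_value[res2$term_id == "T1"], 1 / choose(10, 5))
})

test_that("hypergeometric tails equal exhaustive summation on all small configs", {
  for (N in c(20, 40, 60)) {
    for (n in c(5, N / 2)) {
      for (K in c(4, 10)) {
        for (k in 0:min(n, K)) {
          got <- phyper(k - 1, n, N - n, K, lower.tail = FALSE)
          expect_equal(got, hyper_tail(k, N, n, K), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("enrichment p-values decrease in k and EASE is conservative", {
  genes <- sprintf("g%03d", 1:100)
  ann <- tibble::tibble(gene_id = genes[1:20], term_id = "T1")
  ann_all <- dplyr::bind_rows(ann, tibble::tibble(gene_id = genes,
                                                  term_id = "T0"))
  ps <- vapply(2:10, function(k) {
    sel <- c(genes[1:k], genes[21:30])  # k with term, 10 without
    res <- enrich(sel, genes, ann_all, method = "hypergeometric")
    res$p_value[res$term_id == "T1"]
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  set.seed(33)
  for (i in 1:20) {
    ann_r <- make_annotation_table(seed = i)
    universe <- sprintf("g%03d", 1:20)
    sel <- sample(universe, 8)
    if (!any(sel %in% ann_r$gene_id)) next
    hyp <- enrich(sel, universe, ann_r, method = "hypergeometric")
    ease <- enrich(sel, universe, ann_r, method = "ease")
    m <- dplyr::inner_join(hyp, ease, by = "term_id")
    expect_true(all(m$p_value.y >= m$p_value.x - 1e-12))
  }
})

test_that("selected genes outside the universe are rejected", {
  ann <- tibble::tibble(gene_id = c("a", "b"), term_id = "T1")
  expect_error(enrich(c("a", "zzz"), c("a", "b"), ann), "subset")
})

test_that("annotated fractions report integer percentages", {
  ann <- tibble::tibble(gene_id = sprintf("g%03d", 1:126), term_id = "T1")
  sel <- sprintf("g%03d", 1:243)
  af <- annotated_fraction(sel, ann)
  expect_equal(af$n_annotated, 126L)
  expect_equal(af$percent, 52L)
  empty <- annotated_fraction(character(0), ann)
  expect_equal(empty$n_annotated, 0L)
  expect_true(is.na(empty$percent))
})

test_that("pooling is strict at the cutoff and preserves member p-values", {
  res <- tibble::tibble(term_id = c("a1", "a2", "a3", "b1", "c1"),
                        term_name = NA_character_,
                        k = 1, K = 1, n = 1, N = 1,
                        p_value = c(0.001, 0.01, 0.049, 0.05, 0.2))
  mapping <- tibble::tibble(term_id = c("a1", "a2", "a3"),
                            broad_label = "Aging")
  pooled <- pool_categories(res, mapping, cutoff = 0.05)
  # b1 at exactly 0.05 is excluded; c1 above; a1-a3 pool into Aging
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$broad_label, "Aging")
  expect_equal(pooled$n_members, 3L)
  expect_equal(pooled$member_p_values[[1]], c(0.001, 0.01, 0.049))
  # unmapped sub-cutoff terms pass through as singletons
  mapping2 <- mapping[1:2, ]
  pooled2 <- pool_categories(res, mapping2, cutoff = 0.05)
  expect_setequal(pooled2$broad_label, c("Aging", "a3"))
  expect_equal(sum(pooled2$n_members), 3L)
  # nothing below cutoff: empty result
  expect_equal(nrow(pool_categories(res, mapping, cutoff = 1e-4)), 0)
})
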