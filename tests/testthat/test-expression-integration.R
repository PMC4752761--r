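test_that("DE thresholds are inclusive on both boundaries", {
  de <- de_table(c("a", "b", "c", "d"),
                 fold_change = c(1.5, 1.4, 2.0, 1.5),
                 fdr = c(0.05, 0.001, 0.050001, 0.05),
                 contrast = "kd_vs_ctrl", log2 = FALSE)
  out <- filter_de(de, min_fold = 1.5, max_fdr = 0.05)
  expect_equal(out$status[out$gene_id == "a"], "up")    # both at boundary
  expect_equal(out$status[out$gene_id == "b"], "none")  # fold below
  expect_equal(out$status[out$gene_id == "c"], "none")  # fdr above
  expect_equal(out$status[out$gene_id == "d"], "up")
  # perturbing a boundary gene's fdr past the cutoff removes exactly it
  de2 <- dplyr::mutate(de, fdr = ifelse(gene_id == "a", 0.05 + 1e-9, fdr))
  out2 <- filter_de(de2, 1.5, 0.05)
  expect_equal(out2$status[out2$gene_id == "a"], "none")
  expect_equal(out2$status[-1], out$status[-1])
})

test_that("linear and log2 fold-change inputs agree", {
  lin <- de_table(c("a", "b"), c(2, 0.25), c(0.01, 0.01),
                  "kd_vs_ctrl", log2 = FALSE)
  lg <- de_table(c("a", "b"), c(1, -2), c(0.01, 0.01),
                 "kd_vs_ctrl", log2 = TRUE)
  expect_equal(lin$fold_change, lg$fold_change)
  expect_equal(lin$direction, lg$direction)
})

test_that("duplicate gene ids in one contrast are an error", {
  expect_error(de_table(c("a", "a"), c(1, 2), c(0.1, 0.1), "kd_vs_ctrl"),
               "duplicate")
})

test_that("direct-target direction semantics invert between contrasts", {
  de <- tibble::tibble(gene_id = c("u", "d", "un", "dn"),
                       status = c("up", "down", "up", "down"))
  bound <- tibble::tibble(gene_id = c("u", "d", "un", "dn"),
                          bound = c(TRUE, TRUE, FALSE, FALSE))
  d220 <- call_direct_targets(de, bound, "220")
  expect_equal(d220$direct, c("repressed", "activated", "none", "none"))
  d187 <- call_direct_targets(de, bound, "187")
  expect_equal(d187$direct, c("activated", "repressed", "none", "none"))
  # the 187 rule is the 220 rule composed with direction inversion
  de_flip <- dplyr::mutate(de, status = dplyr::recode(status, up = "down",
                                                      down = "up"))
  expect_equal(call_direct_targets(de_flip, bound, "220")$direct,
               d187$direct)
})

test_that("classification follows the A/B/C/D partition rules", {
  mk <- function(d220, d187) {
    classify_genes(
      tibble::tibble(gene_id = "g", status = "up", bound = TRUE,
                     direct = d220),
      tibble::tibble(gene_id = "g", status = "up", bound = TRUE,
                     direct = d187))$class_label
  }
  expect_equal(mk("repressed", "none"), "A_r")
  expect_equal(mk("activated", "none"), "A_a")
  expect_equal(mk("repressed", "repressed"), "B_r")
  expect_equal(mk("activated", "activated"), "B_a")
  expect_equal(mk("none", "repressed"), "C_r")
  expect_equal(mk("none", "activated"), "C_a")
  expect_equal(mk("repressed", "activated"), "D")
  expect_equal(mk("activated", "repressed"), "D")
  expect_equal(mk("none", "none"), "none")
})

test_that("class labels partition the union of direct-target sets", {
  b <- tiny_bundle(seed = 21)
  res <- run_pipeline(as_pipeline_input(b))
  calls <- res$calls
  n_direct_union <- sum(calls$direct_220 != "none" |
                          calls$direct_187 != "none")
  expect_equal(sum(calls$class_label != "none"), n_direct_union)
  expect_equal(res$summary$n_direct_union, n_direct_union)
})

test_that("summarize_counts reproduces ratio arithmetic and handles zero denominators", {
  expect_equal(pct_of(243, 263), 92L)
  expect_equal(pct_of(0, 100), 0L)
  expect_true(is.na(pct_of(0, 0)))
  calls <- classify_genes(
    tibble::tibble(gene_id = c("a", "b", "c"),
                   status = c("up", "up", "down"),
                   bound = c(TRUE, FALSE, TRUE),
                   direct = c("repressed", "none", "activated")),
    tibble::tibble(gene_id = c("a", "b", "c"),
                   status = "none", bound = FALSE, direct = "none"))
  s <- summarize_counts(calls)
  expect_equal(s$kd_up, 2L)
  expect_equal(s$pct_direct_220_repressed, 50L)
  expect_equal(s$pct_direct_220_activated, 100L)
  expect_true(is.na(s$pct_direct_187_repressed))  # no oe-regulated genes
  expect_equal(unname(s$class_counts[c("A_r", "A_a")]), c(1L, 1L))
})
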