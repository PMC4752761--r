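test_that("the same seed produces byte-identical bundles on disk", {
  b1 <- tiny_bundle(seed = 17)
  b2 <- tiny_bundle(seed = 17)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(b1, d1)
  write_bundle(b2, d2)
  files <- sort(list.files(d1))
  expect_equal(files, sort(list.files(d2)))
  for (f in files) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
  b3 <- tiny_bundle(seed = 18)
  expect_false(identical(b1$peaks$iso187$rep1, b3$peaks$iso187$rep1))
})

test_that("infeasible configurations fail before anything is generated", {
  expect_error(simulate_config(n_genes = 10L), "infeasible")
  expect_error(simulate_config(intergenic_gap = 1500), "intergenic_gap")
  expect_error(
    simulate_config(class_counts = c(A_r = 2L, A_a = 1L, B_r = 1L,
                                     B_a = 1L, C_r = 3L, C_a = 2L, D = 3L),
                    d_split = c(1L, 1L),
                    n_indirect = c(kd_up = 0L, kd_down = 0L, oe_up = 0L,
                                   oe_down = 0L),
                    n_bound_only = c(iso187 = 0L, iso220 = 0L, both = 0L),
                    n_genes = 100L),
    "d_split")
})

test_that("bundles parse under the standard dialects after writing", {
  b <- tiny_bundle(seed = 19)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  back <- read_bundle(dir)
  expect_equal(nrow(back$annotation$genes), nrow(b$annotation$genes))
  expect_equal(nrow(back$peaks$iso187$rep1), nrow(b$peaks$iso187$rep1))
  expect_equal(back$peaks$iso220$rep1$start, b$peaks$iso220$rep1$start)
  expect_equal(back$de$kd$gene_id, b$de$kd$gene_id)
  # the re-read bundle drives the pipeline to the same classes
  res_disk <- run_pipeline(back)
  res_mem <- run_pipeline(as_pipeline_input(b))
  expect_equal(res_disk$calls$class_label, res_mem$calls$class_label)
})

test_that("zero-noise bundles are recovered exactly through the real pipeline", {
  cls <- c(A_r = 2L, A_a = 1L, B_r = 1L, B_a = 1L, C_r = 3L, C_a = 2L,
           D = 1L)
  b <- simulate_bundle(simulate_config(
    seed = 23, n_genes = 60L, class_counts = cls,
    n_indirect = c(kd_up = 2L, kd_down = 2L, oe_up = 2L, oe_down = 2L),
    n_bound_only = c(iso187 = 3L, iso220 = 3L, both = 5L),
    n_extra_peaks = 10L, n_noise_peaks = 5L))
  res <- run_pipeline(as_pipeline_input(b))
  got <- table(factor(res$calls$class_label, levels = names(cls)))
  expect_equal(as.integer(got), unname(cls))
})

test_that("planted peak-overlap fractions are recovered by the comparison", {
  # 500 peaks per isoform, 70% planted as shared
  b <- simulate_bundle(simulate_config(
    seed = 29, n_genes = 650L,
    class_counts = c(A_r = 0L, A_a = 0L, B_r = 0L, B_a = 0L, C_r = 0L,
                     C_a = 0L, D = 0L),
    n_indirect = c(kd_up = 0L, kd_down = 0L, oe_up = 0L, oe_down = 0L),
    n_bound_only = c(iso187 = 150L, iso220 = 150L, both = 350L),
    n_extra_peaks = 0L, n_noise_peaks = 0L, frac_euchromatic = 1))
  res <- run_pipeline(as_pipeline_input(b))
  expect_equal(res$overlap$n_a, 500L)
  expect_equal(res$overlap$n_b, 500L)
  expect_lte(abs(res$overlap$pct_a - 70), 3)
  expect_lte(abs(res$overlap$pct_b - 70), 3)
  # zero-jitter generation makes the recovery exact, not merely close
  expect_equal(res$overlap$pct_a, 70L)
})

test_that("class recovery degrades monotonically in expectation with DE noise", {
  dev_at <- function(flip) {
    devs <- vapply(1:3, function(s) {
      b <- tiny_bundle(seed = 100 + s, de_flip_rate = flip)
      res <- run_pipeline(as_pipeline_input(b))
      truth_counts <- table(factor(b$truth$class_label,
                                   levels = c("A_r", "A_a", "B_r", "B_a",
                                              "C_r", "C_a", "D")))
      got <- table(factor(res$calls$class_label,
                          levels = c("A_r", "A_a", "B_r", "B_a", "C_r",
                                     "C_a", "D")))
      sum(abs(as.integer(got) - as.integer(truth_counts)))
    }, numeric(1))
    mean(devs)
  }
  d0 <- dev_at(0)
  d2 <- dev_at(0.2)
  d5 <- dev_at(0.5)
  expect_equal(d0, 0)
  expect_lte(d0, d2)
  expect_lte(d2, d5)
})

test_that("the study-scale preset reports its anchor totals", {
  cfg <- config_study_scale(seed = 31)
  expect_equal(sum(cfg$class_counts[c("A_r", "B_r")]) + cfg$d_split[1] +
                 cfg$n_indirect[["kd_up"]], 263)
  expect_equal(sum(cfg$class_counts[c("A_a", "B_a")]) + cfg$d_split[2] +
                 cfg$n_indirect[["kd_down"]], 349)
})
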