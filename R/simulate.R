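# Synthetic-data generator: genome annotation, isoform peak sets with
# replicates, TSS-centred signal tracks, two DE tables and term
# annotations, all internally consistent with a planted ground truth so
# the full pipeline can be validated without external downloads.

#' Simulation configuration
#'
#' Defines a complete synthetic study: a genome of non-overlapping genes
#' laid out on five euchromatic arms plus one small heterochromatic
#' chromosome, per-isoform binding, two differential-expression contrasts
#' (knockdown and overexpression) and a planted A/B/C/D class structure.
#' Genes are spaced so that the minimum intergenic gap exceeds the
#' promoter window plus the maximum peak width, making planted binding
#' unambiguous. All randomness flows from `seed`; the same seed produces
#' byte-identical bundles.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of genes.
#' @param class_counts Named integer vector with planted class sizes
#'   `A_r`, `A_a`, `B_r`, `B_a`, `C_r`, `C_a`, `D`.
#' @param d_split Optional length-2 split of class D into (kd-up & oe-up,
#'   kd-down & oe-down); defaults to an even split.
#' @param n_indirect Named counts of regulated-but-unbound genes:
#'   `kd_up`, `kd_down`, `oe_up`, `oe_down`.
#' @param n_bound_only Named counts of bound-but-unregulated genes:
#'   `iso187`, `iso220`, `both`.
#' @param frac_a_bound_187 Length-2 fractions of class `A_r`/`A_a` genes
#'   also bound by isoform 187 (defaults 0.95 and 0.62).
#' @param frac_c_bound_220 Length-2 fractions of class `C_r`/`C_a` genes
#'   also bound by isoform 220 (defaults 0.95 and 0.90).
#' @param gene_length_mean,gene_length_sd,gene_length_min Gene length
#'   model (bp).
#' @param intergenic_gap Minimum intergenic gap (bp); must exceed the
#'   assignment window plus the maximum peak width.
#' @param peak_width_mean,peak_width_sd,peak_width_min Peak width model
#'   (bp).
#' @param peak_fold_extra_meanlog,peak_fold_extra_sdlog Log-normal excess
#'   of bound-peak fold enrichment above `peak_min_fold`.
#' @param peak_min_fold Enrichment threshold separating real peaks from
#'   sub-threshold noise peaks (default 3).
#' @param n_noise_peaks Sub-threshold (fold < `peak_min_fold`) peaks per
#'   isoform, placed on the heterochromatic chromosome.
#' @param n_extra_peaks Additional real intergenic peaks per isoform, used
#'   to control peak totals and the inter-isoform overlap fraction.
#' @param extra_overlap_frac Fraction of the extra peaks shared between
#'   the isoforms.
#' @param replicate_jitter_sd Standard deviation (bp) of the edge jitter
#'   applied to replicate 2 (0 = identical replicates).
#' @param frac_euchromatic Planted fraction of real peaks on the
#'   euchromatic arms (default 0.99); the remainder are placed on the
#'   heterochromatic chromosome.
#' @param kd_min_fold,kd_max_fdr Knockdown DE regime (defaults 1.5 and
#'   0.05).
#' @param oe_min_fold,oe_max_fdr Overexpression DE regime (defaults 2 and
#'   0.001).
#' @param de_effect_meanlog,de_effect_sdlog Log-normal excess of planted
#'   fold changes above the regime threshold.
#' @param de_flip_rate Fraction of null genes given passing DE statistics
#'   (0 = noise-free; used to study degradation of class recovery).
#' @param signal_amplitude,signal_bump_sd Gaussian signal bump height and
#'   width (bp) at bound TSSs.
#' @param signal_background Uniform background signal level.
#' @param signal_bin Signal track bin width (bp).
#' @param make_signal Emit signal tracks (disable for very large genomes).
#' @param term_frac Fraction of each class's genes annotated with that
#'   class's marker term.
#' @param background_term_rate Fraction of all genes annotated with each
#'   term as background.
#' @return A validated `sim_config` list.
#' @export
simulate_config <- function(
    seed = 1L,
    n_genes = 1000L,
    class_counts = c(A_r = 60L, A_a = 40L, B_r = 25L, B_a = 25L,
                     C_r = 50L, C_a = 55L, D = 16L),
    d_split = NULL,
    n_indirect = c(kd_up = 20L, kd_down = 30L, oe_up = 25L, oe_down = 20L),
    n_bound_only = c(iso187 = 80L, iso220 = 100L, both = 250L),
    frac_a_bound_187 = c(0.95, 0.62),
    frac_c_bound_220 = c(0.95, 0.90),
    gene_length_mean = 2000, gene_length_sd = 500, gene_length_min = 600,
    intergenic_gap = 6000,
    peak_width_mean = 400, peak_width_sd = 100, peak_width_min = 150,
    peak_fold_extra_meanlog = log(5), peak_fold_extra_sdlog = 0.5,
    peak_min_fold = 3,
    n_noise_peaks = 50L,
    n_extra_peaks = 1200L,
    extra_overlap_frac = 0.8,
    replicate_jitter_sd = 0,
    frac_euchromatic = 0.99,
    kd_min_fold = 1.5, kd_max_fdr = 0.05,
    oe_min_fold = 2, oe_max_fdr = 0.001,
    de_effect_meanlog = 0, de_effect_sdlog = 0.75,
    de_flip_rate = 0,
    signal_amplitude = 10, signal_bump_sd = 150,
    signal_background = 0.2, signal_bin = 25L,
    make_signal = TRUE,
    term_frac = 0.6, background_term_rate = 0.02) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  cls <- c("A_r", "A_a", "B_r", "B_a", "C_r", "C_a", "D")
  if (!all(cls %in% names(cfg$class_counts))) {
    abort("class_counts must name A_r, A_a, B_r, B_a, C_r, C_a, D")
  }
  if (any(cfg$class_counts < 0) || any(cfg$n_indirect < 0) ||
      any(cfg$n_bound_only < 0)) {
    abort("planted counts must be non-negative")
  }
  needed <- sum(cfg$class_counts) + sum(cfg$n_indirect) + sum(cfg$n_bound_only)
  if (needed > cfg$n_genes) {
    abort(sprintf("infeasible config: %d genes required for planted roles but n_genes = %d",
                  needed, cfg$n_genes))
  }
  if (!is.null(cfg$d_split) &&
      sum(cfg$d_split) != cfg$class_counts[["D"]]) {
    abort("d_split must sum to class_counts['D']")
  }
  # windows may extend up to 1000 bp into a gap from both flanking genes,
  # and a gap must host three non-overlapping intergenic peak slots
  max_width <- min(cfg$peak_width_mean + 4 * cfg$peak_width_sd, 800)
  gap_needed <- max(2 * 1100 + 3 * max_width, (1100 + max_width / 2) / 0.3)
  if (cfg$intergenic_gap < gap_needed) {
    abort(sprintf("intergenic_gap must be >= %d so gene windows and intergenic peak slots cannot collide",
                  ceiling(gap_needed)))
  }
  fr <- c(cfg$frac_a_bound_187, cfg$frac_c_bound_220, cfg$frac_euchromatic,
          cfg$extra_overlap_frac, cfg$de_flip_rate)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  invisible(cfg)
}

#' Study-scale simulation preset
#'
#' A configuration whose expected totals anchor to a genome-scale
#' two-isoform study: 4903 and 5810 peaks for isoforms 187 and 220, a
#' knockdown contrast with 263 up- and 349 downregulated genes (1.5-fold,
#' FDR 0.05), an overexpression contrast with 605 up- and 669
#' downregulated genes (2-fold, FDR 0.001), printed class-A and class-C
#' sizes, and an inter-isoform peak overlap of 86 % / 73 %. Signal-track
#' generation is disabled by default at this scale.
#'
#' @param seed Integer RNG seed.
#' @param make_signal Emit signal tracks (default `FALSE` at this scale).
#' @return A `sim_config`.
#' @export
config_study_scale <- function(seed = 1L, make_signal = FALSE) {
  simulate_config(
    seed = seed,
    n_genes = 14540L,
    class_counts = c(A_r = 226L, A_a = 133L, B_r = 10L, B_a = 20L,
                     C_r = 248L, C_a = 301L, D = 16L),
    d_split = c(7L, 9L),
    n_indirect = c(kd_up = 20L, kd_down = 187L, oe_up = 277L,
                   oe_down = 402L),
    # bound-only counts chosen so that, with the class-driven binding,
    # isoform totals are 4854/5752 euchromatic peaks (4903/5810 with the
    # 1% heterochromatic complement) sharing 4229 peaks: 86% of 4903 and
    # 73% of 5810.
    n_bound_only = c(iso187 = 583L, iso220 = 1461L, both = 3379L),
    n_extra_peaks = 0L,
    n_noise_peaks = 200L,
    make_signal = make_signal
  )
}

#' Generate a synthetic study bundle with planted ground truth
#'
#' @param config A [simulate_config()].
#' @return A `sim_bundle` list: `config`, `annotation`
#'   ([genome_annotation()]), `peaks` (per isoform, two replicate peak
#'   tibbles each), `signal` (per-isoform bedGraph tibbles or `NULL`),
#'   `de` (`kd`, `oe` tibbles as written to disk), `terms`, `pool_map`,
#'   `truth` (per-gene planted flags and class labels) and `peak_truth`
#'   (per-peak origin and overlap-partner flags).
#' @export
simulate_bundle <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config

  plan <- plan_genes(cfg)
  layout <- layout_genome(cfg, plan)
  annotation <- layout$annotation
  plan <- layout$plan

  pk <- build_peaks(cfg, plan, annotation)
  signal <- if (cfg$make_signal) build_signal(cfg, plan, annotation) else NULL
  de <- build_de_tables(cfg, plan)
  tm <- build_terms(cfg, plan)

  truth <- plan |>
    select("gene_id", "bound_187", "bound_220", "de_kd", "de_oe",
           "class_label")
  structure(list(config = cfg, annotation = annotation, peaks = pk$peaks,
                 signal = signal, de = de, terms = tm$terms,
                 pool_map = tm$pool_map, truth = truth,
                 peak_truth = pk$peak_truth),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("<sim_bundle> %d genes, %d + %d peaks (seed %d)\n",
              nrow(x$truth), nrow(x$peaks$iso187$rep1),
              nrow(x$peaks$iso220$rep1), x$config$seed))
  invisible(x)
}

# Assign planted roles (class labels, DE directions, bound flags) to gene
# ids. Counts are deterministic so zero-noise recovery is exact.
plan_genes <- function(cfg) {
  n <- cfg$n_genes
  ids <- sprintf("g%05d", seq_len(n))
  plan <- tibble(gene_id = ids, bound_187 = FALSE, bound_220 = FALSE,
                 de_kd = "none", de_oe = "none", class_label = "none")
  cls <- cfg$class_counts
  d_split <- cfg$d_split %||% c(ceiling(cls[["D"]] / 2), floor(cls[["D"]] / 2))

  # roles are dealt over a seeded permutation of the gene ids so that
  # planted classes are scattered across the genome
  perm <- sample.int(n)
  cursor <- 0L
  take <- function(k) {
    idx <- perm[cursor + seq_len(k)]
    cursor <<- cursor + k
    idx
  }

  i <- take(cls[["A_r"]])
  plan$class_label[i] <- "A_r"; plan$bound_220[i] <- TRUE
  plan$de_kd[i] <- "up"
  plan$bound_187[i[seq_len(round(cfg$frac_a_bound_187[1] * length(i)))]] <- TRUE

  i <- take(cls[["A_a"]])
  plan$class_label[i] <- "A_a"; plan$bound_220[i] <- TRUE
  plan$de_kd[i] <- "down"
  plan$bound_187[i[seq_len(round(cfg$frac_a_bound_187[2] * length(i)))]] <- TRUE

  i <- take(cls[["B_r"]])
  plan$class_label[i] <- "B_r"
  plan$bound_220[i] <- TRUE; plan$bound_187[i] <- TRUE
  plan$de_kd[i] <- "up"; plan$de_oe[i] <- "down"

  i <- take(cls[["B_a"]])
  plan$class_label[i] <- "B_a"
  plan$bound_220[i] <- TRUE; plan$bound_187[i] <- TRUE
  plan$de_kd[i] <- "down"; plan$de_oe[i] <- "up"

  i <- take(cls[["C_r"]])
  plan$class_label[i] <- "C_r"; plan$bound_187[i] <- TRUE
  plan$de_oe[i] <- "down"
  plan$bound_220[i[seq_len(round(cfg$frac_c_bound_220[1] * length(i)))]] <- TRUE

  i <- take(cls[["C_a"]])
  plan$class_label[i] <- "C_a"; plan$bound_187[i] <- TRUE
  plan$de_oe[i] <- "up"
  plan$bound_220[i[seq_len(round(cfg$frac_c_bound_220[2] * length(i)))]] <- TRUE

  i <- take(d_split[1])  # repressed by 220, activated by 187
  plan$class_label[i] <- "D"
  plan$bound_220[i] <- TRUE; plan$bound_187[i] <- TRUE
  plan$de_kd[i] <- "up"; plan$de_oe[i] <- "up"

  i <- take(d_split[2])  # activated by 220, repressed by 187
  plan$class_label[i] <- "D"
  plan$bound_220[i] <- TRUE; plan$bound_187[i] <- TRUE
  plan$de_kd[i] <- "down"; plan$de_oe[i] <- "down"

  plan$de_kd[take(cfg$n_indirect[["kd_up"]])] <- "up"
  plan$de_kd[take(cfg$n_indirect[["kd_down"]])] <- "down"
  plan$de_oe[take(cfg$n_indirect[["oe_up"]])] <- "up"
  plan$de_oe[take(cfg$n_indirect[["oe_down"]])] <- "down"

  plan$bound_187[take(cfg$n_bound_only[["iso187"]])] <- TRUE
  plan$bound_220[take(cfg$n_bound_only[["iso220"]])] <- TRUE
  i <- take(cfg$n_bound_only[["both"]])
  plan$bound_187[i] <- TRUE; plan$bound_220[i] <- TRUE
  plan
}

euchromatic_arms <- c("2L", "2R", "3L", "3R", "X")

# Lay genes out sequentially on the five arms with fixed intergenic gaps;
# derive exon/CDS structure. Returns the annotation and the plan extended
# with coordinates.
layout_genome <- function(cfg, plan) {
  n <- nrow(plan)
  len <- pmax(cfg$gene_length_min,
              round(rnorm(n, cfg$gene_length_mean, cfg$gene_length_sd)))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  arm <- rep(euchromatic_arms, length.out = n)
  gap <- cfg$intergenic_gap

  # first gene of each arm starts at `gap`, then previous end + gap
  genes <- tibble(gene_id = plan$gene_id, chrom = arm, strand = strand,
                  length = as.integer(len)) |>
    group_by(.data$chrom) |>
    mutate(start = as.integer(gap + c(0L, head(cumsum(.data$length + gap), -1))),
           end = .data$start + .data$length) |>
    ungroup()

  e1_end <- genes$start + pmax(100L, as.integer(round(0.3 * genes$length)))
  e2_start <- genes$start + as.integer(round(0.6 * genes$length))
  genes$exon_starts <- map2(genes$start, e2_start, ~c(.x, .y))
  genes$exon_ends <- map2(e1_end, genes$end, ~c(.x, .y))
  genes$cds_start <- genes$start + as.integer(round(0.15 * genes$length))
  genes$cds_end <- genes$start + as.integer(round(0.85 * genes$length))

  chroms <- genes |>
    group_by(chrom = .data$chrom) |>
    summarise(length = as.integer(max(.data$end) + gap), .groups = "drop")
  # heterochromatic chromosome sized for noise peaks plus the ~1% off-arm
  # complement of real peaks
  n_het_slots <- cfg$n_noise_peaks +
    ceiling(0.02 * (cfg$n_genes + cfg$n_extra_peaks)) + 50
  het_len <- as.integer(max(50000, 2000 * (n_het_slots + cfg$n_noise_peaks + 10)))
  chroms <- bind_rows(chroms, tibble(chrom = "4", length = het_len))

  annotation <- genome_annotation(
    genes |> select("gene_id", "chrom", "strand", "start", "end",
                    "exon_starts", "exon_ends", "cds_start", "cds_end"),
    chroms)
  plan <- left_join(plan,
                    genes |> select("gene_id", "chrom", "strand", "start",
                                    "end"),
                    by = "gene_id")
  list(annotation = annotation, plan = plan)
}

# Peaks per isoform and replicate, plus the per-peak ground truth.
build_peaks <- function(cfg, plan, annotation) {
  tss <- tss_of(annotation$genes)
  gene_width <- pmax(cfg$peak_width_min,
                     round(rnorm(nrow(plan), cfg$peak_width_mean,
                                 cfg$peak_width_sd)))
  names(gene_width) <- plan$gene_id

  bound_peaks <- function(iso_col, iso) {
    g <- plan[plan[[iso_col]], ]
    w <- gene_width[g$gene_id]
    center <- tss[g$gene_id]
    tibble(chrom = g$chrom,
           start = as.integer(pmax(0, center - w %/% 2)),
           end = as.integer(center - w %/% 2 + w),
           gene_id = g$gene_id,
           kind = "bound",
           shared = g$bound_187 & g$bound_220,
           isoform = iso)
  }
  pk187 <- bound_peaks("bound_187", "iso187")
  pk220 <- bound_peaks("bound_220", "iso220")

  # extra intergenic peaks: shared ones at gap slot 1, isoform-unique at
  # slots 2 and 3, so none enters any gene's assignment window
  if (cfg$n_extra_peaks > 0) {
    slots <- gap_slots(cfg, annotation)
    n_shared <- round(cfg$extra_overlap_frac * cfg$n_extra_peaks)
    n_unique <- cfg$n_extra_peaks - n_shared
    if (n_shared > nrow(slots) || n_unique > nrow(slots)) {
      abort("not enough intergenic gaps for n_extra_peaks")
    }
    # widths capped so slots never overlap each other or a gene window
    w_cap <- floor(min(0.2 * cfg$intergenic_gap - 10,
                       2 * (0.3 * cfg$intergenic_gap - 1100)))
    w <- pmax(cfg$peak_width_min,
              pmin(w_cap,
                   round(rnorm(n_shared + 2 * n_unique, cfg$peak_width_mean,
                               cfg$peak_width_sd))))
    mk <- function(centers, chroms, w, shared, iso) {
      tibble(chrom = chroms,
             start = as.integer(centers - w %/% 2),
             end = as.integer(centers - w %/% 2 + w),
             gene_id = NA_character_, kind = "extra", shared = shared,
             isoform = iso)
    }
    sh <- slots[seq_len(n_shared), ]
    u1 <- slots[seq_len(n_unique), ]
    u2 <- slots[seq_len(n_unique), ]
    w_sh <- w[seq_len(n_shared)]
    w_u1 <- w[n_shared + seq_len(n_unique)]
    w_u2 <- w[n_shared + n_unique + seq_len(n_unique)]
    pk187 <- bind_rows(pk187,
                       mk(sh$slot1, sh$chrom, w_sh, TRUE, "iso187"),
                       mk(u1$slot2, u1$chrom, w_u1, FALSE, "iso187"))
    pk220 <- bind_rows(pk220,
                       mk(sh$slot1, sh$chrom, w_sh, TRUE, "iso220"),
                       mk(u2$slot3, u2$chrom, w_u2, FALSE, "iso220"))
  }

  # heterochromatic complement so that a planted fraction of real peaks
  # sits on the euchromatic arms; positions are isoform-specific
  add_het <- function(pk, iso, offset) {
    n_eu <- nrow(pk)
    n_het <- round(n_eu * (1 - cfg$frac_euchromatic) / cfg$frac_euchromatic)
    if (n_het == 0) return(pk)
    centers <- offset + 2000L * seq_len(n_het)
    w <- pmax(cfg$peak_width_min,
              round(rnorm(n_het, cfg$peak_width_mean, cfg$peak_width_sd)))
    bind_rows(pk, tibble(chrom = "4",
                         start = as.integer(centers - w %/% 2),
                         end = as.integer(centers - w %/% 2 + w),
                         gene_id = NA_character_, kind = "het",
                         shared = FALSE, isoform = iso))
  }
  het_base <- 2000L * (cfg$n_noise_peaks + 2L)
  pk187 <- add_het(pk187, "iso187", het_base)
  pk220 <- add_het(pk220, "iso220", het_base + 1000L)

  # sub-threshold noise peaks (filtered out by the fold-enrichment rule)
  add_noise <- function(pk, iso) {
    if (cfg$n_noise_peaks == 0) return(pk)
    centers <- 1000L + 2000L * seq_len(cfg$n_noise_peaks)
    w <- pmax(cfg$peak_width_min,
              round(rnorm(cfg$n_noise_peaks, cfg$peak_width_mean,
                          cfg$peak_width_sd)))
    bind_rows(pk, tibble(chrom = "4",
                         start = as.integer(centers - w %/% 2),
                         end = as.integer(centers - w %/% 2 + w),
                         gene_id = NA_character_, kind = "noise",
                         shared = FALSE, isoform = iso))
  }
  pk187 <- add_noise(pk187, "iso187")
  pk220 <- add_noise(pk220, "iso220")

  finish <- function(pk, iso) {
    pk <- arrange(pk, .data$chrom, .data$start)
    pk$name <- sprintf("%s_p%05d", iso, seq_len(nrow(pk)))
    real <- pk$kind != "noise"
    fold <- numeric(nrow(pk))
    fold[real] <- cfg$peak_min_fold +
      rlnorm(sum(real), cfg$peak_fold_extra_meanlog, cfg$peak_fold_extra_sdlog)
    fold[!real] <- runif(sum(!real), 1, cfg$peak_min_fold * 0.99)
    pk$fold_enrichment <- fold
    pk$neg_log10_p <- runif(nrow(pk), 20, 120)
    pk$source_label <- iso
    pk
  }
  pk187 <- finish(pk187, "iso187")
  pk220 <- finish(pk220, "iso220")

  jitter_rep <- function(pk) {
    if (cfg$replicate_jitter_sd == 0) return(pk)
    d <- as.integer(round(rnorm(nrow(pk), 0, cfg$replicate_jitter_sd)))
    mutate(pk, start = pmax(0L, .data$start + d), end = .data$end + d)
  }
  cols <- c("chrom", "start", "end", "name", "fold_enrichment",
            "neg_log10_p", "source_label")
  peak_truth <- bind_rows(pk187, pk220) |>
    select("name", "isoform", "kind", "gene_id", "shared")
  list(
    peaks = list(
      iso187 = list(rep1 = pk187[cols], rep2 = jitter_rep(pk187)[cols]),
      iso220 = list(rep1 = pk220[cols], rep2 = jitter_rep(pk220)[cols])
    ),
    peak_truth = peak_truth
  )
}

# Three well-separated peak slots per intergenic gap, each far enough from
# both flanking gene windows.
gap_slots <- function(cfg, annotation) {
  genes <- annotation$genes
  gap <- cfg$intergenic_gap
  genes |>
    group_by(.data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(gap_start = .data$end,
           gap_end = dplyr::lead(.data$start)) |>
    filter(!is.na(.data$gap_end)) |>
    ungroup() |>
    mutate(slot1 = .data$gap_start + as.integer(round(0.3 * gap)),
           slot2 = .data$gap_start + as.integer(round(0.5 * gap)),
           slot3 = .data$gap_start + as.integer(round(0.7 * gap))) |>
    select("chrom", "slot1", "slot2", "slot3")
}

# Binned signal tracks: uniform background plus Gaussian bumps at bound
# TSSs, one track per isoform.
build_signal <- function(cfg, plan, annotation) {
  bin <- cfg$signal_bin
  lengths <- chrom_lengths(annotation)
  tss <- tss_of(annotation$genes)

  one_track <- function(iso_col) {
    g <- plan[plan[[iso_col]], ]
    reach <- 4 * cfg$signal_bump_sd
    bumps <- map(seq_len(nrow(g)), function(i) {
      center <- tss[g$gene_id[i]]
      lo <- max(0L, (as.integer(center) - as.integer(reach)) %/% bin * bin)
      hi <- min(lengths[[g$chrom[i]]],
                ((as.integer(center) + as.integer(reach)) %/% bin + 1L) * bin)
      starts <- seq(lo, hi - bin, by = bin)
      mids <- starts + bin / 2
      tibble(chrom = g$chrom[i], start = as.integer(starts),
             end = as.integer(starts + bin),
             value = cfg$signal_background + cfg$signal_amplitude *
               exp(-(mids - center)^2 / (2 * cfg$signal_bump_sd^2)))
    })
    bumps <- bind_rows(bumps)
    # background fills the gaps between bump windows
    bg <- map(names(lengths), function(ch) {
      used <- bumps |> filter(.data$chrom == ch)
      ir <- IRanges::IRanges(start = used$start + 1L, end = used$end)
      free <- IRanges::gaps(IRanges::reduce(ir), start = 1L,
                            end = lengths[[ch]])
      tibble(chrom = ch, start = IRanges::start(free) - 1L,
             end = IRanges::end(free), value = cfg$signal_background)
    })
    bind_rows(bumps, bind_rows(bg)) |>
      arrange(.data$chrom, .data$start)
  }
  list(iso187 = one_track("bound_187"), iso220 = one_track("bound_220"))
}

# DE tables for the two contrasts, one row per gene, written on the
# signed-log2 scale.
build_de_tables <- function(cfg, plan) {
  one_table <- function(dir_col, min_fold, max_fdr, contrast) {
    dir <- plan[[dir_col]]
    n <- nrow(plan)
    planted <- dir != "none"
    flip <- !planted & (runif(n) < cfg$de_flip_rate)
    fold <- numeric(n)
    fdr <- numeric(n)
    fold[planted] <- min_fold + rlnorm(sum(planted), cfg$de_effect_meanlog,
                                       cfg$de_effect_sdlog)
    fdr[planted] <- runif(sum(planted), 0, max_fdr)
    fold[!planted] <- runif(sum(!planted), 1, min_fold * 0.999)
    fdr[!planted] <- runif(sum(!planted), min(1, max_fdr * 1.001), 1)
    fold[flip] <- min_fold + rlnorm(sum(flip), cfg$de_effect_meanlog,
                                    cfg$de_effect_sdlog)
    fdr[flip] <- runif(sum(flip), 0, max_fdr)
    sign <- ifelse(dir == "down", -1, 1)
    sign[!planted] <- sample(c(-1, 1), sum(!planted), replace = TRUE)
    tibble(gene_id = plan$gene_id,
           log2_fold_change = sign * log2(fold),
           q_value = fdr)
  }
  list(kd = one_table("de_kd", cfg$kd_min_fold, cfg$kd_max_fdr, "kd_vs_ctrl"),
       oe = one_table("de_oe", cfg$oe_min_fold, cfg$oe_max_fdr, "oe_vs_ctrl"))
}

# Gene-to-term annotation with one planted marker term per class plus
# three poolable "aging" terms, and the pooling map.
build_terms <- function(cfg, plan) {
  classes <- c("A_r", "A_a", "B_r", "B_a", "C_r", "C_a", "D")
  rows <- map(classes, function(cl) {
    g <- plan$gene_id[plan$class_label == cl]
    if (length(g) == 0) return(NULL)
    marked <- g[seq_len(max(1, round(cfg$term_frac * length(g))))]
    bg <- sample(setdiff(plan$gene_id, marked),
                 max(1, round(cfg$background_term_rate * nrow(plan))))
    tibble(gene_id = c(marked, bg),
           term_id = paste0("GO_", cl),
           term_name = paste0("process marked in class ", cl))
  })
  aging_pool <- plan$gene_id[plan$de_oe == "up"]
  if (length(aging_pool) < 5) aging_pool <- plan$gene_id
  aging <- map(1:3, function(i) {
    tibble(gene_id = sample(aging_pool,
                            max(2, round(0.3 * length(aging_pool)))),
           term_id = paste0("GO_aging_", i),
           term_name = c("determination of adult lifespan",
                         "multicellular organismal aging", "aging")[i])
  })
  terms <- bind_rows(c(rows, aging)) |>
    distinct(.data$gene_id, .data$term_id, .keep_all = TRUE) |>
    arrange(.data$term_id, .data$gene_id)
  pool_map <- tibble(term_id = paste0("GO_aging_", 1:3),
                     broad_label = "Aging")
  list(terms = terms, pool_map = pool_map)
}

#' Write a simulated bundle to disk
#'
#' Emits the standard-format files a real study would provide: BED12
#' annotation, chromosome sizes, narrowPeak files (two replicates per
#' isoform), bedGraph signal tracks, DE TSVs on the signed-log2 scale,
#' term-annotation and pooling-map TSVs, ground-truth TSVs and a JSON
#' manifest.
#'
#' @param bundle A [simulate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_annotation_bed12(bundle$annotation, p("annotation.bed12"))
  readr::write_tsv(bundle$annotation$chromosomes, p("chrom.sizes"),
                   col_names = FALSE)
  for (iso in names(bundle$peaks)) {
    for (rep in names(bundle$peaks[[iso]])) {
      write_peaks_narrowpeak(bundle$peaks[[iso]][[rep]],
                             p(sprintf("peaks_%s_%s.narrowPeak", iso, rep)))
    }
  }
  if (!is.null(bundle$signal)) {
    for (iso in names(bundle$signal)) {
      write_signal_bedgraph(bundle$signal[[iso]],
                            p(sprintf("signal_%s.bedGraph", iso)))
    }
  }
  readr::write_tsv(bundle$de$kd, p("de_kd.tsv"))
  readr::write_tsv(bundle$de$oe, p("de_oe.tsv"))
  readr::write_tsv(bundle$terms, p("terms.tsv"))
  readr::write_tsv(bundle$pool_map, p("pool_map.tsv"))
  readr::write_tsv(bundle$truth, p("truth_genes.tsv"))
  readr::write_tsv(bundle$peak_truth, p("truth_peaks.tsv"))
  manifest <- list(
    files = list(annotation = "annotation.bed12", chrom_sizes = "chrom.sizes",
                 peaks = sprintf("peaks_%s_%s.narrowPeak",
                                 rep(names(bundle$peaks), each = 2),
                                 c("rep1", "rep2")),
                 signal = if (!is.null(bundle$signal))
                   sprintf("signal_%s.bedGraph", names(bundle$signal)),
                 de = c("de_kd.tsv", "de_oe.tsv"),
                 terms = "terms.tsv", pool_map = "pool_map.tsv",
                 truth = c("truth_genes.tsv", "truth_peaks.tsv")),
    seed = bundle$config$seed)
  jsonlite::write_json(manifest, p("MANIFEST.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' Read a bundle directory back into memory
#'
#' @param dir Directory written by [write_bundle()].
#' @return A list shaped like a [simulate_bundle()] (without `config`).
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  chroms <- read_chrom_sizes(p("chrom.sizes"))
  annotation <- read_annotation(p("annotation.bed12"), format = "bed12",
                                chromosomes = chroms)
  peaks <- list()
  for (iso in c("iso187", "iso220")) {
    peaks[[iso]] <- list(
      rep1 = read_peaks(p(sprintf("peaks_%s_rep1.narrowPeak", iso)),
                        source_label = iso),
      rep2 = read_peaks(p(sprintf("peaks_%s_rep2.narrowPeak", iso)),
                        source_label = iso))
  }
  signal <- NULL
  if (file.exists(p("signal_iso187.bedGraph"))) {
    signal <- list(iso187 = read_signal(p("signal_iso187.bedGraph")),
                   iso220 = read_signal(p("signal_iso220.bedGraph")))
  }
  de <- list(kd = readr::read_tsv(p("de_kd.tsv"), col_types = "cdd",
                                  progress = FALSE),
             oe = readr::read_tsv(p("de_oe.tsv"), col_types = "cdd",
                                  progress = FALSE))
  terms <- readr::read_tsv(p("terms.tsv"), col_types = "ccc",
                           progress = FALSE)
  pool_map <- readr::read_tsv(p("pool_map.tsv"), col_types = "cc",
                              progress = FALSE)
  truth <- if (file.exists(p("truth_genes.tsv")))
    readr::read_tsv(p("truth_genes.tsv"), col_types = "cllccc",
                    progress = FALSE) else NULL
  list(annotation = annotation, peaks = peaks, signal = signal, de = de,
       terms = terms, pool_map = pool_map, truth = truth)
}
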