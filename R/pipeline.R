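# End-to-end orchestration: peak filtering -> concordance -> comparison ->
# assignment -> profiling -> DE integration -> classification -> enrichment,
# with a JSON-able summary of every count and rounded percentage.

#' Pipeline parameters
#'
#' Defaults reproduce the standard two-regime parameterization: 3-fold
#' input enrichment, 50 % replicate concordance and peak-to-peak overlap,
#' a -1 kb TSS / +100 bp TES assignment window, 1.5-fold / FDR 0.05 for
#' the knockdown contrast, 2-fold / FDR 0.001 for the overexpression
#' contrast, and a 0.05 enrichment cutoff. Every default is overridable.
#'
#' @param min_fold Minimum peak fold enrichment over input.
#' @param concordance_min_frac Replicate-concordance overlap fraction.
#' @param overlap_min_frac Peak-to-peak comparison overlap fraction.
#' @param upstream,downstream Assignment window around genes (bp).
#' @param kd_min_fold,kd_max_fdr Knockdown DE thresholds.
#' @param oe_min_fold,oe_max_fdr Overexpression DE thresholds.
#' @param go_cutoff Strict p-value cutoff for term pooling and annotated
#'   fractions.
#' @param enrich_method `"ease"` or `"hypergeometric"`.
#' @param metagene_flank,metagene_bins Metagene flank (bp) and
#'   upstream/body/downstream bin counts.
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(min_fold = 3, concordance_min_frac = 0.5,
                            overlap_min_frac = 0.5,
                            upstream = 1000, downstream = 100,
                            kd_min_fold = 1.5, kd_max_fdr = 0.05,
                            oe_min_fold = 2, oe_max_fdr = 0.001,
                            go_cutoff = 0.05,
                            enrich_method = c("ease", "hypergeometric"),
                            metagene_flank = 2000,
                            metagene_bins = c(100, 200, 100)) {
  enrich_method <- match.arg(enrich_method)
  params <- as.list(environment())
  stopifnot(min_fold > 0, upstream >= 0, downstream >= 0,
            kd_min_fold >= 1, oe_min_fold >= 1,
            kd_max_fdr > 0, oe_max_fdr > 0, go_cutoff > 0)
  structure(params, class = "pipeline_params")
}

#' Run the full integration pipeline
#'
#' Stages, in order: fold-enrichment filtering of each replicate,
#' replicate-concordance filtering (replicate 1 against replicate 2),
#' reciprocal overlap comparison of the two isoform peak sets,
#' peak-to-gene assignment and bound-gene flags, chromosomal-distribution
#' enrichment, genomic-feature annotation, metagene profiles over each
#' isoform's direct targets (when signal is available), DE thresholding
#' per contrast, direct-target calling, A/B/C/D classification, count
#' summaries, and term enrichment per direct-target list. Deterministic
#' given its inputs.
#'
#' @param bundle A [simulate_bundle()] result, a [read_bundle()] list, or
#'   any list with elements `annotation`, `peaks`
#'   (`iso187`/`iso220`, each `rep1`/`rep2`), `de` (`kd`, `oe` TSV-shaped
#'   tibbles), and optionally `signal`, `terms`, `pool_map`.
#' @param params A [pipeline_params()].
#' @return A `pipeline_result` list with elements `peaks` (filtered,
#'   concordant sets), `overlap`, `assignments`, `bound`,
#'   `chrom_dist`, `euchromatic`, `features`, `metagene`, `de`, `direct`,
#'   `calls`, `summary`, `enrichment`, `params`.
#' @export
run_pipeline <- function(bundle, params = pipeline_params()) {
  stopifnot(inherits(params, "pipeline_params"))
  for (el in c("annotation", "peaks", "de")) {
    if (is.null(bundle[[el]])) {
      abort(sprintf("pipeline stage 'inputs': bundle element '%s' is missing", el))
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  filtered <- stage("peak filtering", lapply(bundle$peaks, function(iso) {
    lapply(iso, filter_by_fold, min_fold = params$min_fold)
  }))
  concordant <- stage("replicate concordance", lapply(filtered, function(iso) {
    replicate_concordant(iso$rep1, iso$rep2, params$concordance_min_frac)
  }))

  overlap <- stage("peak-set comparison",
                   compare_peaksets(concordant$iso187, concordant$iso220,
                                    params$overlap_min_frac))

  assignments <- stage("peak-to-gene assignment", lapply(concordant, function(pk) {
    assign_peaks_to_genes(pk, bundle$annotation,
                          upstream = params$upstream,
                          downstream = params$downstream)
  }))
  bound <- lapply(assignments, bound_genes, annotation = bundle$annotation)

  chrom_dist <- stage("chromosomal distribution",
                      lapply(concordant, chrom_distribution,
                             annotation = bundle$annotation))
  euchrom <- lapply(concordant, euchromatic_fraction)

  features <- stage("feature annotation", lapply(concordant, function(pk) {
    feature_summary(annotate_features(pk, bundle$annotation))
  }))

  de <- stage("DE thresholds", list(
    kd = filter_de(de_table(bundle$de$kd$gene_id,
                            bundle$de$kd$log2_fold_change,
                            bundle$de$kd$q_value, "kd_vs_ctrl"),
                   params$kd_min_fold, params$kd_max_fdr),
    oe = filter_de(de_table(bundle$de$oe$gene_id,
                            bundle$de$oe$log2_fold_change,
                            bundle$de$oe$q_value, "oe_vs_ctrl"),
                   params$oe_min_fold, params$oe_max_fdr)
  ))

  direct <- stage("direct-target calling", list(
    iso220 = call_direct_targets(de$kd, bound$iso220, "220"),
    iso187 = call_direct_targets(de$oe, bound$iso187, "187")
  ))
  calls <- stage("classification",
                 classify_genes(direct$iso220, direct$iso187,
                                bound_220 = bound$iso220,
                                bound_187 = bound$iso187))
  summary <- summarize_counts(calls)

  prof <- NULL
  if (!is.null(bundle$signal)) {
    prof <- stage("metagene", {
      genes <- bundle$annotation$genes
      mb <- params$metagene_bins
      one <- function(sig, ids) {
        g <- genes[genes$gene_id %in% ids, ]
        if (nrow(g) == 0) return(NULL)  # no direct targets at these thresholds
        metagene(sig, g, flank = params$metagene_flank,
                 upstream_bins = mb[1], body_bins = mb[2],
                 downstream_bins = mb[3])
      }
      list(
        iso187 = one(bundle$signal$iso187,
                     calls$gene_id[calls$direct_187 != "none"]),
        iso220 = one(bundle$signal$iso220,
                     calls$gene_id[calls$direct_220 != "none"])
      )
    })
  }

  enrichment <- NULL
  if (!is.null(bundle$terms)) {
    enrichment <- stage("term enrichment", {
      universe <- bundle$annotation$genes$gene_id
      lists <- list(
        repressed_220 = calls$gene_id[calls$direct_220 == "repressed"],
        activated_220 = calls$gene_id[calls$direct_220 == "activated"],
        repressed_187 = calls$gene_id[calls$direct_187 == "repressed"],
        activated_187 = calls$gene_id[calls$direct_187 == "activated"]
      )
      lapply(lists, function(sel) {
        if (length(sel) == 0 || !any(sel %in% bundle$terms$gene_id)) {
          return(NULL)
        }
        res <- enrich(sel, universe, bundle$terms,
                      method = params$enrich_method)
        pooled <- if (!is.null(bundle$pool_map)) {
          pool_categories(res, bundle$pool_map, cutoff = params$go_cutoff)
        }
        list(results = res,
             pooled = pooled,
             annotated = annotated_fraction(sel, bundle$terms, res,
                                            params$go_cutoff))
      })
    })
  }

  structure(list(peaks = concordant, overlap = overlap,
                 assignments = assignments, bound = bound,
                 chrom_dist = chrom_dist, euchromatic = euchrom,
                 features = features, metagene = prof, de = de,
                 direct = direct, calls = calls, summary = summary,
                 enrichment = enrichment, params = params),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  peaks: %d (iso187), %d (iso220); overlap %d%% / %d%%\n",
              nrow(x$peaks$iso187), nrow(x$peaks$iso220),
              x$overlap$pct_a, x$overlap$pct_b))
  print(x$summary)
  invisible(x)
}

#' Pipeline summary as a flat named list
#'
#' Collects every count and integer-rounded percentage the pipeline
#' reports (peak totals, overlap report, euchromatic fractions, DE
#' partition sizes, direct-target counts and ratios, class counts,
#' annotated fractions) into one JSON-ready list; ratios appear in
#' numerator/denominator/percent form.
#'
#' @param result A [run_pipeline()] result.
#' @return Named list of scalars (and a named `class_counts` vector).
#' @export
pipeline_summary <- function(result) {
  s <- result$summary
  out <- list(
    n_peaks_187 = nrow(result$peaks$iso187),
    n_peaks_220 = nrow(result$peaks$iso220),
    overlap = glance(result$overlap),
    euchromatic_pct_187 = result$euchromatic$iso187$percent,
    euchromatic_pct_220 = result$euchromatic$iso220$percent,
    n_bound_187 = sum(result$bound$iso187$bound),
    n_bound_220 = sum(result$bound$iso220$bound)
  )
  out <- c(out, unclass(s)[setdiff(names(s), "class_counts")])
  out$class_counts <- as.list(s$class_counts)
  if (!is.null(result$enrichment)) {
    for (nm in names(result$enrichment)) {
      e <- result$enrichment[[nm]]
      if (is.null(e)) next
      out[[paste0("annotated_", nm)]] <- as.list(e$annotated)
    }
  }
  out
}

#' Write a pipeline report bundle
#'
#' Writes the per-gene regulation calls, the overlap report, feature and
#' chromosome tables, metagene profiles and enrichment tables as TSV, and
#' the full count/percentage summary as JSON.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(result$calls, p("regulation_calls.tsv"))
  readr::write_tsv(tidy(result$overlap), p("overlap_report.tsv"))
  for (iso in names(result$chrom_dist)) {
    readr::write_tsv(result$chrom_dist[[iso]],
                     p(sprintf("chrom_distribution_%s.tsv", iso)))
    readr::write_tsv(result$features[[iso]],
                     p(sprintf("feature_summary_%s.tsv", iso)))
  }
  if (!is.null(result$metagene)) {
    for (iso in names(result$metagene)) {
      readr::write_tsv(as_tibble(result$metagene[[iso]]),
                       p(sprintf("metagene_%s.tsv", iso)))
    }
  }
  if (!is.null(result$enrichment)) {
    for (nm in names(result$enrichment)) {
      e <- result$enrichment[[nm]]
      if (is.null(e)) next
      readr::write_tsv(e$results, p(sprintf("enrichment_%s.tsv", nm)))
    }
  }
  jsonlite::write_json(pipeline_summary(result), p("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
glance.pipeline_result <- function(x, ...) {
  tibble(n_peaks_187 = nrow(x$peaks$iso187),
         n_peaks_220 = nrow(x$peaks$iso220),
         pct_overlap_187 = x$overlap$pct_a,
         pct_overlap_220 = x$overlap$pct_b,
         n_bound_187 = sum(x$bound$iso187$bound),
         n_bound_220 = sum(x$bound$iso220$bound),
         kd_regulated = x$summary$kd_regulated,
         oe_regulated = x$summary$oe_regulated,
         n_direct_union = x$summary$n_direct_union)
}
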