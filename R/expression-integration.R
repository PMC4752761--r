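# Differential-expression filtering, direct-target calling under the two
# perturbation contrasts, and the A/B/C/D regulatory partition.

#' Read a differential-expression table
#'
#' Expects a TSV with header columns `gene_id`, a fold-change column and a
#' `q_value` column. Fold changes may be signed log2 (the usual cuffdiff /
#' DESeq-style output; default) or linear, where values below 1 encode
#' downregulation. Internally fold changes are stored on the linear scale
#' (>= 1) with an explicit direction flag.
#'
#' @param path Path to the TSV.
#' @param contrast `"kd_vs_ctrl"` (regulator knockdown) or `"oe_vs_ctrl"`
#'   (isoform overexpression).
#' @param log2 Is the fold-change column signed log2 (default `TRUE`)?
#' @return Tibble `gene_id`, `fold_change` (linear, >= 1), `direction`
#'   (`up`/`down`), `fdr`, `contrast`.
#' @export
read_de_table <- function(path, contrast = c("kd_vs_ctrl", "oe_vs_ctrl"),
                          log2 = TRUE) {
  contrast <- match.arg(contrast)
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  fc_col <- intersect(c("log2_fold_change", "fold_change", "log2fc", "lfc"),
                      names(raw))[1]
  q_col <- intersect(c("q_value", "fdr", "qval"), names(raw))[1]
  if (is.na(fc_col) || is.na(q_col) || !"gene_id" %in% names(raw)) {
    abort(sprintf("DE table %s must have gene_id, fold-change and q_value columns",
                  path))
  }
  de_table(raw$gene_id, raw[[fc_col]], raw[[q_col]], contrast, log2 = log2)
}

#' Construct a DE tibble from vectors
#'
#' @param gene_id Character vector of gene ids (unique within a contrast).
#' @param fold_change Signed log2 fold changes (default) or linear fold
#'   changes where values < 1 encode downregulation.
#' @param fdr Q-values in \[0, 1\].
#' @param contrast `"kd_vs_ctrl"` or `"oe_vs_ctrl"`.
#' @param log2 Interpret `fold_change` as signed log2 (default `TRUE`).
#' @return Tibble as documented in [read_de_table()].
#' @export
de_table <- function(gene_id, fold_change, fdr,
                     contrast = c("kd_vs_ctrl", "oe_vs_ctrl"), log2 = TRUE) {
  contrast <- match.arg(contrast)
  if (anyDuplicated(gene_id)) {
    abort(sprintf("duplicate gene_id in %s DE table: %s", contrast,
                  gene_id[duplicated(gene_id)][1]))
  }
  if (any(fdr < 0 | fdr > 1, na.rm = TRUE)) abort("fdr must lie in [0, 1]")
  if (log2) {
    dir <- if_else(fold_change >= 0, "up", "down")
    fc <- 2^abs(fold_change)
  } else {
    if (any(fold_change <= 0)) abort("linear fold changes must be positive")
    dir <- if_else(fold_change >= 1, "up", "down")
    fc <- ifelse(fold_change >= 1, fold_change, 1 / fold_change)
  }
  tibble(gene_id = as.character(gene_id), fold_change = fc, direction = dir,
         fdr = fdr, contrast = contrast)
}

#' Threshold a DE table into up / down / unchanged
#'
#' A gene is called up- or downregulated when `fold_change >= min_fold`
#' and `fdr <= max_fdr`, both boundaries inclusive; all other genes are
#' `none`. The defaults used in two-regime analyses are 1.5-fold at
#' FDR 0.05 (knockdown) and 2-fold at FDR 0.001 (overexpression).
#'
#' @param de DE tibble from [read_de_table()] or [de_table()].
#' @param min_fold Minimum linear fold change (>= 1).
#' @param max_fdr Maximum FDR, in (0, 1].
#' @return The DE tibble with a `status` column (`up`/`down`/`none`).
#' @export
filter_de <- function(de, min_fold = 1.5, max_fdr = 0.05) {
  stopifnot(min_fold >= 1, max_fdr > 0, max_fdr <= 1)
  if (anyDuplicated(de$gene_id)) abort("duplicate gene_id in DE table")
  mutate(de, status = if_else(.data$fold_change >= min_fold &
                                .data$fdr <= max_fdr,
                              .data$direction, "none"))
}

#' Call direct targets of one isoform
#'
#' A direct target responds to the perturbation and is bound by the
#' isoform. The direction semantics differ by contrast because the two
#' perturbations are opposite: under knockdown of the predominant isoform
#' (220), genes UP upon knockdown are directly repressed and genes DOWN
#' are directly activated; under overexpression of the other isoform
#' (187), genes DOWN upon overexpression are directly repressed and genes
#' UP are directly activated.
#'
#' @param de_status DE tibble with a `status` column ([filter_de()]).
#' @param bound Tibble `gene_id`, `bound` ([bound_genes()]), or a character
#'   vector of bound gene ids.
#' @param isoform `"220"` (knockdown contrast) or `"187"` (overexpression
#'   contrast).
#' @return Tibble `gene_id`, `status`, `bound`, `direct`
#'   (`repressed`/`activated`/`none`) covering every gene in `de_status`.
#' @export
call_direct_targets <- function(de_status, bound, isoform = c("220", "187")) {
  isoform <- match.arg(isoform)
  stopifnot("status" %in% names(de_status))
  bound_ids <- if (is.character(bound)) bound else
    bound$gene_id[bound$bound]
  repress_status <- if (isoform == "220") "up" else "down"
  activate_status <- if (isoform == "220") "down" else "up"
  de_status |>
    mutate(bound = .data$gene_id %in% bound_ids,
           direct = dplyr::case_when(
             .data$bound & .data$status == repress_status ~ "repressed",
             .data$bound & .data$status == activate_status ~ "activated",
             TRUE ~ "none")) |>
    select("gene_id", "status", "bound", "direct")
}

#' Classify genes into the four regulatory classes
#'
#' Combines direct-target calls for the two isoforms into the A/B/C/D
#' partition: A (`A_r`/`A_a`) direct targets of isoform 220 only, B
#' (`B_r`/`B_a`) direct targets of both isoforms in the same direction, C
#' (`C_r`/`C_a`) direct targets of isoform 187 only, and D direct targets
#' of both isoforms in opposing directions; `none` otherwise. The seven
#' labels partition the union of the two direct-target sets.
#'
#' @param direct_220,direct_187 Outputs of [call_direct_targets()] for the
#'   two isoforms. Gene universes may differ; genes absent from one call
#'   set are treated as `direct = none` there.
#' @param bound_220,bound_187 Optional bound-flag tibbles ([bound_genes()])
#'   carried through to the output for cross-isoform binding summaries.
#' @return Tibble with one row per gene in either universe: `gene_id`,
#'   `bound_220`, `bound_187`, `de_kd`, `de_oe`, `direct_220`,
#'   `direct_187`, `class_label`.
#' @export
classify_genes <- function(direct_220, direct_187,
                           bound_220 = NULL, bound_187 = NULL) {
  d220 <- direct_220 |>
    select("gene_id", de_kd = "status", b220 = "bound", direct_220 = "direct")
  d187 <- direct_187 |>
    select("gene_id", de_oe = "status", b187 = "bound", direct_187 = "direct")
  calls <- dplyr::full_join(d220, d187, by = "gene_id") |>
    mutate(de_kd = tidyr::replace_na(.data$de_kd, "none"),
           de_oe = tidyr::replace_na(.data$de_oe, "none"),
           direct_220 = tidyr::replace_na(.data$direct_220, "none"),
           direct_187 = tidyr::replace_na(.data$direct_187, "none"),
           b220 = tidyr::replace_na(.data$b220, FALSE),
           b187 = tidyr::replace_na(.data$b187, FALSE))
  if (!is.null(bound_220)) {
    calls <- calls |>
      left_join(rename(bound_220, bb220 = "bound"), by = "gene_id") |>
      mutate(b220 = .data$b220 | tidyr::replace_na(.data$bb220, FALSE)) |>
      select(-"bb220")
  }
  if (!is.null(bound_187)) {
    calls <- calls |>
      left_join(rename(bound_187, bb187 = "bound"), by = "gene_id") |>
      mutate(b187 = .data$b187 | tidyr::replace_na(.data$bb187, FALSE)) |>
      select(-"bb187")
  }
  calls |>
    mutate(class_label = dplyr::case_when(
      direct_220 == "repressed" & direct_187 == "repressed" ~ "B_r",
      direct_220 == "activated" & direct_187 == "activated" ~ "B_a",
      direct_220 != "none" & direct_187 != "none" ~ "D",
      direct_220 == "repressed" ~ "A_r",
      direct_220 == "activated" ~ "A_a",
      direct_187 == "repressed" ~ "C_r",
      direct_187 == "activated" ~ "C_a",
      TRUE ~ "none")) |>
    rename(bound_220 = "b220", bound_187 = "b187") |>
    select("gene_id", "bound_220", "bound_187", "de_kd", "de_oe",
           "direct_220", "direct_187", "class_label") |>
    arrange(.data$gene_id)
}

#' Summarize regulation calls into counts and rounded percentages
#'
#' Reports the DE partition sizes per contrast, direct/indirect target
#' counts with direct-over-regulated percentages, class sizes, and the
#' fraction of class-A genes also bound by the other isoform. All
#' percentages use [pct_of()] (nearest integer; undefined for zero
#' denominators).
#'
#' @param calls Output of [classify_genes()].
#' @return A `regulation_summary` object (a list of named counts and
#'   percentages; see [tidy.regulation_summary()]).
#' @export
summarize_counts <- function(calls) {
  cls <- table(factor(calls$class_label,
                      levels = c("A_r", "A_a", "B_r", "B_a", "C_r", "C_a",
                                 "D", "none")))
  kd_up <- sum(calls$de_kd == "up")
  kd_down <- sum(calls$de_kd == "down")
  oe_up <- sum(calls$de_oe == "up")
  oe_down <- sum(calls$de_oe == "down")
  dir_220_rep <- sum(calls$direct_220 == "repressed")
  dir_220_act <- sum(calls$direct_220 == "activated")
  dir_187_rep <- sum(calls$direct_187 == "repressed")
  dir_187_act <- sum(calls$direct_187 == "activated")
  a_r <- calls$class_label == "A_r"
  a_a <- calls$class_label == "A_a"
  out <- list(
    n_genes = nrow(calls),
    kd_up = kd_up, kd_down = kd_down, kd_regulated = kd_up + kd_down,
    oe_up = oe_up, oe_down = oe_down, oe_regulated = oe_up + oe_down,
    direct_220_repressed = dir_220_rep,
    direct_220_activated = dir_220_act,
    direct_187_repressed = dir_187_rep,
    direct_187_activated = dir_187_act,
    pct_direct_220_repressed = pct_of(dir_220_rep, kd_up),
    pct_direct_220_activated = pct_of(dir_220_act, kd_down),
    pct_direct_187_repressed = pct_of(dir_187_rep, oe_down),
    pct_direct_187_activated = pct_of(dir_187_act, oe_up),
    class_counts = setNames(as.integer(cls), names(cls)),
    n_direct_union = sum(calls$class_label != "none"),
    a_r_bound_187 = sum(a_r & calls$bound_187),
    a_a_bound_187 = sum(a_a & calls$bound_187),
    pct_a_r_bound_187 = pct_of(sum(a_r & calls$bound_187), sum(a_r)),
    pct_a_a_bound_187 = pct_of(sum(a_a & calls$bound_187), sum(a_a))
  )
  structure(out, class = "regulation_summary")
}

#' @export
print.regulation_summary <- function(x, ...) {
  cat("<regulation_summary>\n")
  cat(sprintf("  knockdown: %d up / %d down; direct %d repressed (%s%%), %d activated (%s%%)\n",
              x$kd_up, x$kd_down, x$direct_220_repressed,
              x$pct_direct_220_repressed, x$direct_220_activated,
              x$pct_direct_220_activated))
  cat(sprintf("  overexpression: %d up / %d down; direct %d repressed (%s%%), %d activated (%s%%)\n",
              x$oe_up, x$oe_down, x$direct_187_repressed,
              x$pct_direct_187_repressed, x$direct_187_activated,
              x$pct_direct_187_activated))
  cat("  classes:", paste(sprintf("%s=%d", names(x$class_counts),
                                  x$class_counts), collapse = " "), "\n")
  invisible(x)
}

#' Tidy a regulation summary
#'
#' @param x A `regulation_summary`.
#' @param ... Unused.
#' @return One row per reported quantity: `statistic`, `value`.
#' @export
tidy.regulation_summary <- function(x, ...) {
  flat <- c(x[setdiff(names(x), "class_counts")],
            as.list(setNames(as.integer(x$class_counts),
                             paste0("class_", names(x$class_counts)))))
  tibble(statistic = names(flat), value = as.numeric(unlist(flat)))
}

#' @export
glance.regulation_summary <- function(x, ...) {
  tibble(n_genes = x$n_genes, kd_regulated = x$kd_regulated,
         oe_regulated = x$oe_regulated, n_direct_union = x$n_direct_union)
}
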