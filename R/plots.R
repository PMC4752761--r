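# ggplot2 views of the main result types.

#' Plot a metagene profile
#'
#' Average signal across scaled gene bodies with flanks; vertical guides
#' mark the TSS and TES.
#'
#' @param profile A [metagene()] result (or a named list of them, drawn as
#'   coloured lines).
#' @return A ggplot object.
#' @export
plot_metagene <- function(profile) {
  if (inherits(profile, "metagene_profile")) profile <- list(signal = profile)
  ub <- attr(profile[[1]], "upstream_bins")
  bb <- attr(profile[[1]], "body_bins")
  df <- bind_rows(lapply(profile, as_tibble), .id = "track")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$value,
                                   colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(ub + 0.5, ub + bb + 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_continuous(
      breaks = c(1, ub + 0.5, ub + bb + 0.5, nrow(profile[[1]])),
      labels = c("-flank", "TSS", "TES", "+flank")) +
    ggplot2::labs(x = NULL, y = "average signal", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_metagene
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.metagene_profile <- function(object, ...) plot_metagene(object)

#' Bar plot of genomic-feature categories
#'
#' @param features A [feature_summary()] tibble, or a named list of them
#'   for side-by-side comparison.
#' @return A ggplot object.
#' @export
plot_features <- function(features) {
  if (is.data.frame(features)) features <- list(peaks = features)
  df <- bind_rows(features, .id = "set")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$pct,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of peaks", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar plot of regulatory class counts
#'
#' @param calls A [classify_genes()] tibble or a `regulation_summary`.
#' @return A ggplot object.
#' @export
plot_classes <- function(calls) {
  counts <- if (inherits(calls, "regulation_summary")) {
    tibble(class_label = names(calls$class_counts),
           n = as.integer(calls$class_counts))
  } else {
    calls |> count(class_label = .data$class_label)
  }
  counts <- filter(counts, .data$class_label != "none")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$class_label, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "regulatory class", y = "genes") +
    ggplot2::theme_minimal()
}

#' Binding/expression scatter plot for one isoform
#'
#' Log2 fold change against DE status, coloured by binding, mirroring the
#' bound-vs-regulated scatter view: regulated-not-bound (indirect),
#' regulated and bound by both isoforms, and uniquely bound.
#'
#' @param calls A [classify_genes()] tibble.
#' @param de A `filter_de()` tibble for the matching contrast.
#' @param isoform `"220"` or `"187"`.
#' @return A ggplot object.
#' @export
plot_direct_targets <- function(calls, de, isoform = c("220", "187")) {
  isoform <- match.arg(isoform)
  direct_col <- paste0("direct_", isoform)
  own_bound <- paste0("bound_", isoform)
  other_bound <- paste0("bound_", if (isoform == "220") "187" else "220")
  df <- de |>
    filter(.data$status != "none") |>
    inner_join(calls, by = "gene_id") |>
    mutate(group = dplyr::case_when(
      !.data[[own_bound]] ~ "regulated, not bound",
      .data[[other_bound]] ~ "bound by both isoforms",
      TRUE ~ "uniquely bound"),
      lfc = if_else(.data$direction == "up", log2(.data$fold_change),
                    -log2(.data$fold_change)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lfc,
                                   y = -log10(pmax(.data$fdr, 1e-300)),
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(
      "regulated, not bound" = "forestgreen",
      "bound by both isoforms" = "firebrick",
      "uniquely bound" = "black")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR", colour = NULL) +
    ggplot2::theme_minimal()
}
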