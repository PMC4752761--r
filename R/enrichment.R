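# Term over-representation testing (hypergeometric / EASE) and pooling of
# related categories into broader labels.

#' Term over-representation test on a gene list
#'
#' For each term, counts `k` selected genes carrying the term out of `K`
#' selected annotated genes, against `n` universe genes with the term out
#' of `N` annotated universe genes, and computes the one-sided
#' hypergeometric tail P(X >= k), X ~ Hypergeom(N, n, K). The `"ease"`
#' method is the conservative DAVID-style variant with `k` replaced by
#' `k - 1` (floored at 0). Genes without any annotation are excluded from
#' `K` and `N`.
#'
#' @param selected Character vector of selected gene ids (must be a subset
#'   of `universe`).
#' @param universe Character vector: the background gene universe.
#' @param annotation Tibble `gene_id`, `term_id` and optionally
#'   `term_name`.
#' @param method `"ease"` (default) or `"hypergeometric"`.
#' @param p_adjust Apply Benjamini-Hochberg correction in an extra
#'   `p_adjusted` column (default `FALSE`; raw p-values are what the
#'   pooling step consumes).
#' @return Tibble `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p_value`
#'   sorted by ascending `p_value`.
#' @export
enrich <- function(selected, universe, annotation,
                   method = c("ease", "hypergeometric"), p_adjust = FALSE) {
  method <- match.arg(method)
  selected <- unique(as.character(selected))
  universe <- unique(as.character(universe))
  if (!all(selected %in% universe)) {
    abort("`selected` must be a subset of `universe`")
  }
  ann <- annotation |>
    filter(.data$gene_id %in% universe) |>
    distinct(.data$gene_id, .data$term_id, .keep_all = TRUE)
  if (!any(selected %in% ann$gene_id)) {
    abort("annotation covers no selected gene")
  }
  N <- dplyr::n_distinct(ann$gene_id)
  K <- dplyr::n_distinct(intersect(selected, ann$gene_id))
  term_names <- if ("term_name" %in% names(ann)) {
    ann |> distinct(.data$term_id, .data$term_name)
  } else {
    ann |> distinct(.data$term_id) |> mutate(term_name = .data$term_id)
  }
  res <- ann |>
    group_by(term_id = .data$term_id) |>
    summarise(k = sum(unique(.data$gene_id) %in% selected),
              n = dplyr::n_distinct(.data$gene_id), .groups = "drop") |>
    mutate(K = K, N = N,
           k_eff = if (method == "ease") pmax(.data$k - 1L, 0L) else .data$k,
           p_value = phyper(.data$k_eff - 1L, .data$n, N - .data$n, K,
                            lower.tail = FALSE)) |>
    select(-"k_eff") |>
    left_join(term_names, by = "term_id") |>
    select("term_id", "term_name", "k", "K", "n", "N", "p_value") |>
    arrange(.data$p_value, .data$term_id)
  if (p_adjust) res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Fraction of selected genes carrying at least one enriched term
#'
#' @param selected Character vector of selected gene ids.
#' @param annotation Gene-to-term tibble (`gene_id`, `term_id`).
#' @param results Optional [enrich()] output; when supplied, only terms
#'   with `p_value < cutoff` count as enriched.
#' @param cutoff Strict p-value cutoff used with `results` (default 0.05).
#' @return Tibble `n_annotated`, `n_selected`, `percent` (integer-rounded;
#'   `NA` for an empty selection).
#' @export
annotated_fraction <- function(selected, annotation, results = NULL,
                               cutoff = 0.05) {
  selected <- unique(as.character(selected))
  ann <- annotation
  if (!is.null(results)) {
    keep <- results$term_id[results$p_value < cutoff]
    ann <- filter(ann, .data$term_id %in% keep)
  }
  k <- sum(selected %in% ann$gene_id)
  tibble(n_annotated = k, n_selected = length(selected),
         percent = pct_of(k, length(selected)))
}

#' Pool enriched terms into broader categories
#'
#' Retains results with `p_value < cutoff` (strict inequality) and groups
#' them by a term-to-broad-label mapping; terms without a mapping pass
#' through as singleton categories labelled by their own `term_id`.
#' Member p-values are carried through unchanged.
#'
#' @param results [enrich()] output.
#' @param mapping Tibble `term_id`, `broad_label`.
#' @param cutoff Strict p-value cutoff (default 0.05).
#' @return Tibble `broad_label`, `n_members`, `member_terms` (list),
#'   `member_p_values` (list), `min_p`, sorted by `min_p`.
#' @export
pool_categories <- function(results, mapping, cutoff = 0.05) {
  stopifnot(cutoff > 0, cutoff <= 1)
  hits <- filter(results, .data$p_value < cutoff)
  if (nrow(hits) == 0) {
    return(tibble(broad_label = character(), n_members = integer(),
                  member_terms = list(), member_p_values = list(),
                  min_p = numeric()))
  }
  hits |>
    left_join(distinct(mapping, .data$term_id, .data$broad_label),
              by = "term_id") |>
    mutate(broad_label = dplyr::coalesce(.data$broad_label, .data$term_id)) |>
    group_by(broad_label = .data$broad_label) |>
    summarise(n_members = n(),
              member_terms = list(.data$term_id),
              member_p_values = list(.data$p_value),
              min_p = min(.data$p_value), .groups = "drop") |>
    arrange(.data$min_p, .data$broad_label)
}
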