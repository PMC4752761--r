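# ChIP-qPCR percent-of-input and RT-qPCR 2^-ddCt quantification with
# replicate summaries.

#' ChIP-qPCR percent of input
#'
#' Standard percent-of-input quantification: the input Ct is first
#' adjusted to represent 100 % of the chromatin,
#' `ct_input_adj = ct_input - log2(1 / input_dilution)`, and the
#' immunoprecipitated fraction is `100 * 2^(ct_input_adj - ct_ip)`.
#' Amplification efficiency is taken as perfect doubling. The result is
#' invariant to a common Ct shift of IP and input.
#'
#' @param ct_ip Ct of the immunoprecipitated sample.
#' @param ct_input Ct of the input sample.
#' @param input_dilution Fraction of chromatin used as input, in (0, 1]
#'   (e.g. 0.01 for a 1 % input).
#' @return Percent of input (vectorized).
#' @examples
#' percent_input(25, 25, input_dilution = 1)     # 100
#' percent_input(25, 25, input_dilution = 0.01)  # 1
#' @export
percent_input <- function(ct_ip, ct_input, input_dilution = 1) {
  stopifnot(all(input_dilution > 0), all(input_dilution <= 1))
  ct_input_adj <- ct_input - log2(1 / input_dilution)
  100 * 2^(ct_input_adj - ct_ip)
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (ct_target_exp - ct_ref_exp) - (ct_target_ctrl - ct_ref_ctrl)`
#' and the fold change is `2^-ddCt`, normalizing the target gene to a
#' reference gene (e.g. Taf1) in both the experimental and the control
#' condition. Amplification efficiency is fixed at 2 (perfect doubling).
#'
#' @param ct_target_exp,ct_ref_exp Target and reference Cts in the
#'   experimental condition.
#' @param ct_target_ctrl,ct_ref_ctrl Target and reference Cts in the
#'   control condition.
#' @return Linear fold change (vectorized); 1 means no change.
#' @examples
#' ddct_fold(24, 20, 22, 20)  # 0.25
#' @export
ddct_fold <- function(ct_target_exp, ct_ref_exp, ct_target_ctrl,
                      ct_ref_ctrl) {
  ddct <- (ct_target_exp - ct_ref_exp) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Replicate summary with unpaired t-test
#'
#' Per-condition mean and standard error of the mean, plus a two-sided
#' unpaired Student's t-test (pooled variance by default) between the two
#' conditions.
#'
#' @param data Data frame with a numeric value column and a condition
#'   column.
#' @param value,condition Column names (tidy-eval).
#' @param var_equal Pooled-variance (classic Student) t-test (default
#'   `TRUE`); `FALSE` gives Welch.
#' @return A `qpcr_summary`: tibble `condition`, `n`, `mean`, `sem` with
#'   attributes `t_statistic`, `df`, `p_value` when exactly two conditions
#'   with >= 2 replicates each are present.
#' @export
replicate_summary <- function(data, value = value, condition = condition,
                              var_equal = TRUE) {
  value <- rlang::enquo(value)
  condition <- rlang::enquo(condition)
  df <- tibble(value = dplyr::pull(data, !!value),
               condition = as.character(dplyr::pull(data, !!condition)))
  smry <- df |>
    group_by(condition = .data$condition) |>
    summarise(n = n(), mean = mean(.data$value),
              sem = if (n() >= 2) sd(.data$value) / sqrt(n()) else NA_real_,
              .groups = "drop")
  out <- structure(smry, class = c("qpcr_summary", class(smry)))
  groups <- split(df$value, df$condition)
  if (length(groups) == 2) {
    if (any(lengths(groups) < 2)) {
      abort("the t-test requires at least 2 values per condition")
    }
    tt <- t.test(groups[[1]], groups[[2]], var.equal = var_equal)
    attr(out, "t_statistic") <- unname(tt$statistic)
    attr(out, "df") <- unname(tt$parameter)
    attr(out, "p_value") <- tt$p.value
  }
  out
}

#' @export
print.qpcr_summary <- function(x, ...) {
  cat("<qpcr_summary>\n")
  NextMethod()
  if (!is.null(attr(x, "p_value"))) {
    cat(sprintf("t = %.4g, df = %.4g, two-sided p = %.4g\n",
                attr(x, "t_statistic"), attr(x, "df"), attr(x, "p_value")))
  }
  invisible(x)
}

#' @export
tidy.qpcr_summary <- function(x, ...) as_tibble(x)

#' @export
glance.qpcr_summary <- function(x, ...) {
  tibble(t_statistic = attr(x, "t_statistic") %||% NA_real_,
         df = attr(x, "df") %||% NA_real_,
         p_value = attr(x, "p_value") %||% NA_real_)
}
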