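#' F-test comparison of two RMSEP values
#'
#' Variance-ratio test of whether two models' prediction errors differ:
#' `F = (max(RMSEP_a, RMSEP_b) / min(RMSEP_a, RMSEP_b))^2` referred to an F
#' distribution with `(n_val - 1, n_val - 1)` degrees of freedom. Two-tailed
#' by default (95% confidence reads `p < 0.05` as a significant difference);
#' symmetric in its arguments.
#'
#' @param rmsep_a,rmsep_b Positive RMSEP values.
#' @param n_val Validation-set size both RMSEPs were computed on (`>= 2`).
#' @param method_a,method_b Optional method labels for the output row.
#' @param tails 2 (default) or 1.
#' @return A one-row tibble: `method_a`, `method_b`, `f_statistic`,
#'   `p_value`, `n_val`.
#' @export
f_test_rmsep <- function(rmsep_a, rmsep_b, n_val, method_a = "a",
                         method_b = "b", tails = 2) {
  if (rmsep_a <= 0 || rmsep_b <= 0) stop("RMSEP values must be positive")
  if (n_val < 2) stop("n_val must be at least 2")
  f <- (max(rmsep_a, rmsep_b) / min(rmsep_a, rmsep_b))^2
  df <- n_val - 1
  p_upper <- stats::pf(f, df, df, lower.tail = FALSE)
  p <- if (tails == 2) min(1, 2 * p_upper) else p_upper
  tibble::tibble(
    method_a = method_a, method_b = method_b,
    f_statistic = f, p_value = p, n_val = as.integer(n_val)
  )
}

#' Comparison table across selection results
#'
#' Collects one metrics row per selector and, when a B-NMI row is present,
#' appends the pairwise F-test p-value of every other method's RMSEP against
#' B-NMI's. The minimal-RMSEP row is flagged in `best`.
#'
#' @param results List of `selection_result` objects (order preserved).
#' @param n_val Validation-set size (taken from the first result's model
#'   context if supplied explicitly).
#' @param reference_method Row the F-tests compare against (default
#'   `"B-NMI"`; skipped when absent).
#' @return A tibble with the columns
#'   `method, r2_cal, r2_pred, rmsec, rmsecv, rmsep, rpd, bias, n_vars,
#'   n_lv, p_vs_reference, best`.
#' @export
comparison_table <- function(results, n_val, reference_method = "B-NMI") {
  if (length(results) == 0) stop("no results to compare")
  rows <- purrr::map_dfr(results, function(res) {
    dplyr::mutate(res$metrics, method = res$method, .before = 1)
  })
  ref <- which(rows$method == reference_method)
  rows$p_vs_reference <- NA_real_
  if (length(ref) == 1 && nrow(rows) > 1) {
    for (i in setdiff(seq_len(nrow(rows)), ref)) {
      rows$p_vs_reference[i] <- f_test_rmsep(
        rows$rmsep[ref], rows$rmsep[i], n_val
      )$p_value
    }
  }
  rows$best <- seq_len(nrow(rows)) == which.min(rows$rmsep)
  rows
}
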