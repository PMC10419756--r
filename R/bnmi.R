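# Internal: LOOCV-tuned PLS fit on a variable subset, returning the model and
# the curve. lv_cap is clamped to what the subset supports.
fit_tuned_pls <- function(cal_X, cal_y, lv_cap, lv_rule, lv_tol = 0.02) {
  max_lv <- min(lv_cap, nrow(cal_X) - 2L, ncol(cal_X))
  curve <- loocv_curve(cal_X, cal_y, max_lv)
  k <- select_lv(curve, lv_rule, lv_tol)
  list(model = fit_pls(cal_X, cal_y, k), curve = curve, n_lv = k)
}

#' Forward accumulation of ranked wavelengths into a PLS model
#'
#' Builds PLS models on growing prefixes of a variable ranking: step `k` fits
#' on the first `k` variables (latent-variable count re-tuned by LOOCV at
#' every step, capped) and records the validation RMSEP. The prefix with the
#' smallest objective (smallest `k` on ties) is the selected subset.
#'
#' @param cal,val Lists with elements `X` and `y` (calibration and validation
#'   blocks over the full wavelength axis).
#' @param order Integer permutation of `1..n` — the ranking, best first.
#' @param lv_cap Cap on latent variables at every step (default 10).
#' @param lv_rule Latent-variable rule passed to [select_lv()].
#' @param objective `"rmsep"` (validation error, the default) or `"rmsecv"`
#'   (leakage-free alternative: tune on cross-validation error only).
#' @param rmse_divisor RMSE divisor convention, see [calibration_metrics()].
#' @param max_steps Optional cap on the number of accumulation steps
#'   (default: all `n`).
#' @return A list with `curve` (tibble: `k`, `n_lv`, `rmsep`, `rmsecv`) and
#'   `best_k`.
#' @export
forward_accumulation <- function(cal, val, order, lv_cap = 10,
                                 lv_rule = c("parsimonious", "global_min"),
                                 objective = c("rmsep", "rmsecv"),
                                 rmse_divisor = c("m", "m-1"),
                                 max_steps = NULL) {
  lv_rule <- match.arg(lv_rule)
  objective <- match.arg(objective)
  rmse_divisor <- match.arg(rmse_divisor)
  n <- ncol(cal$X)
  if (length(order) == 0) stop("empty variable order")
  if (!setequal(order, seq_len(n)) || length(order) != n) {
    stop("order must be a permutation of 1..n")
  }
  n_steps <- if (is.null(max_steps)) n else min(max_steps, n)
  ks <- seq_len(n_steps)
  rmsep_k <- numeric(n_steps)
  rmsecv_k <- numeric(n_steps)
  nlv_k <- integer(n_steps)
  for (k in ks) {
    vars <- order[seq_len(k)]
    tuned <- fit_tuned_pls(cal$X[, vars, drop = FALSE], cal$y, lv_cap, lv_rule)
    pred <- predict(tuned$model, val$X[, vars, drop = FALSE])
    rmsep_k[k] <- rmse(val$y, pred, rmse_divisor)
    rmsecv_k[k] <- tuned$curve$rmsecv[tuned$n_lv]
    nlv_k[k] <- tuned$n_lv
  }
  obj <- if (objective == "rmsep") rmsep_k else rmsecv_k
  list(
    curve = tibble::tibble(k = ks, n_lv = nlv_k, rmsep = rmsep_k,
                           rmsecv = rmsecv_k),
    best_k = which.min(obj) # first minimum = smallest k on ties
  )
}

# Descending-NMI ranking with deterministic ties (ascending variable index).
rank_by_nmi <- function(nmi_values) {
  order(-nmi_values, seq_along(nmi_values))
}

#' B-NMI wavelength selection
#'
#' The binning-normalized-mutual-information procedure: for every candidate
#' equal-interval bin count `B` in a grid (by default 2 up to twice the
#' calibration sample count — the "maximum iteration" reading of the bin
#' budget), compute the per-wavelength NMI profile against the reference,
#' sort wavelengths by descending NMI, forward-accumulate them into PLS
#' models, and keep the `(B, k)` pair with the globally smallest prediction
#' error. Exhaustive over the grid, not greedy.
#'
#' @param ds A `spectra_dataset` with calibration and validation roles
#'   assigned (e.g. via [ks_assign()]).
#' @param bin_grid Integer vector of candidate bin counts; default
#'   `seq(2, 2 * m_cal, by = stride)`.
#' @param stride Grid stride used when `bin_grid` is NULL (default 1; larger
#'   strides trade a slightly coarser search for speed).
#' @param lv_cap,lv_rule,objective,rmse_divisor See [forward_accumulation()].
#' @return A `selection_result` whose `selected` set is the best prefix of
#'   the NMI ranking at the winning bin count.
#' @export
bnmi_select <- function(ds, bin_grid = NULL, stride = 1L, lv_cap = 10,
                        lv_rule = c("parsimonious", "global_min"),
                        objective = c("rmsep", "rmsecv"),
                        rmse_divisor = c("m", "m-1")) {
  lv_rule <- match.arg(lv_rule)
  objective <- match.arg(objective)
  rmse_divisor <- match.arg(rmse_divisor)
  cal <- spectra_block(ds, "calibration")
  val <- spectra_block(ds, "validation")
  if (max(cal$y) == min(cal$y)) {
    stop("reference carries no information: constant reference values")
  }
  if (is.null(bin_grid)) {
    bin_grid <- seq(2L, 2L * length(cal$y), by = as.integer(stride))
  }
  best <- NULL
  for (B in bin_grid) {
    profile <- nmi_profile(cal$X, cal$y, B)
    if (all(profile$nmi == 0)) next
    ord <- rank_by_nmi(profile$nmi)
    acc <- forward_accumulation(cal, val, ord, lv_cap, lv_rule, objective,
                                rmse_divisor)
    obj_val <- if (objective == "rmsep") acc$curve$rmsep[acc$best_k] else
      acc$curve$rmsecv[acc$best_k]
    if (is.null(best) || obj_val < best$obj) {
      best <- list(obj = obj_val, B = B, profile = profile, order = ord,
                   acc = acc)
    }
  }
  if (is.null(best)) {
    stop("reference carries no information: all NMI profiles are zero")
  }
  selected <- best$order[seq_len(best$acc$best_k)]
  tuned <- fit_tuned_pls(cal$X[, selected, drop = FALSE], cal$y, lv_cap,
                         lv_rule)
  metrics <- calibration_metrics(
    tuned$model,
    list(X = cal$X[, selected, drop = FALSE], y = cal$y),
    list(X = val$X[, selected, drop = FALSE], y = val$y),
    tuned$curve, rmse_divisor
  )
  new_selection_result(
    method = "B-NMI",
    ranked_order = best$order,
    selected = selected,
    rmsep_curve = best$acc$curve,
    metrics = metrics,
    model = tuned$model,
    wavelengths = ds$wavelengths,
    chosen_bin_count = best$B,
    nmi_profile = tibble::add_column(best$profile,
                                     wavelength = ds$wavelengths,
                                     .after = "index")
  )
}

# Shared constructor for every selector's output.
new_selection_result <- function(method, ranked_order, selected, rmsep_curve,
                                 metrics, model, wavelengths,
                                 chosen_bin_count = NA_integer_,
                                 nmi_profile = NULL, extra = list()) {
  structure(
    c(
      list(
        method = method, ranked_order = ranked_order, selected = selected,
        rmsep_curve = rmsep_curve, metrics = metrics, model = model,
        wavelengths = wavelengths, chosen_bin_count = chosen_bin_count,
        nmi_profile = nmi_profile
      ),
      extra
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> method: ", x$method, "\n", sep = "")
  cat("  selected ", length(x$selected), " of ", length(x$wavelengths),
      " wavelengths", sep = "")
  if (!is.na(x$chosen_bin_count)) cat(" (bin count ", x$chosen_bin_count, ")",
                                      sep = "")
  cat("\n  RMSEP ", signif(x$metrics$rmsep, 4), ", RPD ",
      signif(x$metrics$rpd, 4), ", ", x$metrics$n_lv, " LV\n", sep = "")
  invisible(x)
}

#' Full-spectrum PLS baseline
#'
#' Fits the LOOCV-tuned PLS model on every wavelength — the reference row the
#' selectors are compared against.
#'
#' @inheritParams bnmi_select
#' @return A `selection_result` with all wavelengths selected.
#' @export
full_spectrum_pls <- function(ds, lv_cap = 10,
                              lv_rule = c("parsimonious", "global_min"),
                              rmse_divisor = c("m", "m-1")) {
  lv_rule <- match.arg(lv_rule)
  rmse_divisor <- match.arg(rmse_divisor)
  cal <- spectra_block(ds, "calibration")
  val <- spectra_block(ds, "validation")
  tuned <- fit_tuned_pls(cal$X, cal$y, lv_cap, lv_rule)
  metrics <- calibration_metrics(tuned$model, cal, val, tuned$curve,
                                 rmse_divisor)
  new_selection_result(
    method = "Full-PLSR",
    ranked_order = seq_along(ds$wavelengths),
    selected = seq_along(ds$wavelengths),
    rmsep_curve = NULL, metrics = metrics, model = tuned$model,
    wavelengths = ds$wavelengths
  )
}
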