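# Run expr under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Final tuned fit + metrics on a selected subset, wrapped as a result.
finalize_selection <- function(method, ds, cal, val, ranked_order, selected,
                               rmsep_curve, lv_cap, lv_rule, rmse_divisor,
                               extra = list()) {
  tuned <- fit_tuned_pls(cal$X[, selected, drop = FALSE], cal$y, lv_cap,
                         lv_rule)
  metrics <- calibration_metrics(
    tuned$model,
    list(X = cal$X[, selected, drop = FALSE], y = cal$y),
    list(X = val$X[, selected, drop = FALSE], y = val$y),
    tuned$curve, rmse_divisor
  )
  new_selection_result(
    method = method, ranked_order = ranked_order, selected = selected,
    rmsep_curve = rmsep_curve, metrics = metrics, model = tuned$model,
    wavelengths = ds$wavelengths, extra = extra
  )
}

#' Correlation-coefficient (CC) wavelength selection
#'
#' Ranks wavelengths by the absolute Pearson correlation between each
#' absorbance column and the reference on the calibration rows. With a
#' `threshold`, keeps every wavelength whose `|r|` exceeds it; without one,
#' the kept count is optimized by forward accumulation of the ranking.
#'
#' @inheritParams bnmi_select
#' @param threshold Optional absolute-correlation cutoff in `[0, 1)`.
#' @return A `selection_result`.
#' @export
cc_select <- function(ds, threshold = NULL, lv_cap = 10,
                      lv_rule = c("parsimonious", "global_min"),
                      rmse_divisor = c("m", "m-1")) {
  lv_rule <- match.arg(lv_rule)
  rmse_divisor <- match.arg(rmse_divisor)
  cal <- spectra_block(ds, "calibration")
  val <- spectra_block(ds, "validation")
  r <- abs(apply(cal$X, 2, function(col) {
    if (stats::sd(col) == 0) 0 else stats::cor(col, cal$y)
  }))
  ord <- order(-r, seq_along(r))
  if (is.null(threshold)) {
    acc <- forward_accumulation(cal, val, ord, lv_cap, lv_rule,
                                rmse_divisor = rmse_divisor)
    selected <- ord[seq_len(acc$best_k)]
    curve <- acc$curve
  } else {
    selected <- ord[seq_len(sum(r > threshold))]
    if (length(selected) == 0) stop("no wavelength exceeds |r| threshold ", threshold)
    curve <- NULL
  }
  finalize_selection("CC", ds, cal, val, ord, selected, curve, lv_cap,
                     lv_rule, rmse_divisor, extra = list(correlation = r))
}

# VIP scores of a fitted PLS1 model over its original variables.
vip_scores <- function(model) {
  W <- model$weights
  q <- model$y_loadings
  n <- nrow(W)
  ssy <- q^2 # scores are orthonormal, so explained y-variance per LV is q_a^2
  if (sum(ssy) == 0) stop("model explains no response variance: VIP undefined")
  wnorm2 <- colSums(W^2)
  contrib <- sweep(W^2, 2, wnorm2, `/`)
  sqrt(n * drop(contrib %*% ssy) / sum(ssy))
}

#' Variable-importance-in-projection (VIP) selection
#'
#' Fits the LOOCV-tuned full-spectrum PLS model and keeps every wavelength
#' whose VIP score exceeds the threshold (conventionally 1.0; the mean
#' squared VIP is 1 by construction).
#'
#' @inheritParams bnmi_select
#' @param threshold VIP cutoff (default 1.0).
#' @return A `selection_result` with the per-wavelength scores in `$vip`.
#' @export
vip_select <- function(ds, threshold = 1.0, lv_cap = 10,
                       lv_rule = c("parsimonious", "global_min"),
                       rmse_divisor = c("m", "m-1")) {
  lv_rule <- match.arg(lv_rule)
  rmse_divisor <- match.arg(rmse_divisor)
  cal <- spectra_block(ds, "calibration")
  val <- spectra_block(ds, "validation")
  tuned <- fit_tuned_pls(cal$X, cal$y, lv_cap, lv_rule)
  vip <- vip_scores(tuned$model)
  ord <- order(-vip, seq_along(vip))
  selected <- ord[seq_len(sum(vip > threshold))]
  if (length(selected) == 0) stop("no wavelength exceeds the VIP threshold")
  finalize_selection("VIP", ds, cal, val, ord, sort(selected), NULL, lv_cap,
                     lv_rule, rmse_divisor, extra = list(vip = vip))
}

#' Uninformative-variable elimination (UVE)
#'
#' Appends artificial low-amplitude uniform-noise variables to the
#' calibration block, refits the PLS model with each calibration sample left
#' out in turn, and scores every variable by the stability of its regression
#' coefficient, `mean(b) / sd(b)` over the refits. The cutoff is the largest
#' absolute stability observed in the noise block (times `noise_multiplier`);
#' real wavelengths below it are judged uninformative and dropped.
#'
#' @inheritParams bnmi_select
#' @param noise_multiplier Safety factor on the noise-block cutoff.
#' @param noise_amplitude Noise amplitude relative to `max(abs(X))`
#'   (default 1e-10, the customary near-null perturbation).
#' @param seed RNG seed for the noise block.
#' @return A `selection_result` with stabilities in `$stability` and the
#'   cutoff in `$cutoff`.
#' @export
uve_select <- function(ds, noise_multiplier = 1.0, noise_amplitude = 1e-10,
                       seed = 1L, lv_cap = 10,
                       lv_rule = c("parsimonious", "global_min"),
                       rmse_divisor = c("m", "m-1")) {
  lv_rule <- match.arg(lv_rule)
  rmse_divisor <- match.arg(rmse_divisor)
  cal <- spectra_block(ds, "calibration")
  val <- spectra_block(ds, "validation")
  m <- nrow(cal$X)
  n <- ncol(cal$X)
  if (m < 3) stop("UVE needs at least 3 calibration samples")
  noise <- with_local_seed(seed, {
    matrix(stats::runif(m * n), m, n) * noise_amplitude * max(abs(cal$X))
  })
  Xa <- cbind(cal$X, noise)
  n_lv <- select_lv(loocv_curve(cal$X, cal$y, min(lv_cap, m - 2, n)), lv_rule)
  betas <- matrix(0, m, 2 * n)
  for (i in seq_len(m)) {
    fit <- fit_pls(Xa[-i, , drop = FALSE], cal$y[-i], n_lv)
    betas[i, ] <- fit$beta
  }
  stab <- colMeans(betas) / apply(betas, 2, stats::sd)
  stab[is.na(stab)] <- 0
  cutoff <- noise_multiplier * max(abs(stab[(n + 1):(2 * n)]))
  real_stab <- stab[seq_len(n)]
  selected <- which(abs(real_stab) > cutoff)
  if (length(selected) == 0) stop("UVE eliminated every wavelength")
  ord <- order(-abs(real_stab), seq_len(n))
  finalize_selection("UVE", ds, cal, val, ord, selected, NULL, lv_cap,
                     lv_rule, rmse_divisor,
                     extra = list(stability = real_stab, cutoff = cutoff))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte-Carlo wavelength competition: each run fits a PLS model on a random
#' subset of calibration samples, retains the wavelengths with the largest
#' absolute regression coefficients under an exponentially decreasing
#' retention ratio (`r_i = a exp(-k i)` with `r_1 = 1` and `r_N = 2/n`), then
#' resamples the survivors with probability proportional to `|beta|`
#' (adaptive reweighted sampling). The run whose retained set attains the
#' smallest RMSECV on the full calibration set wins.
#'
#' @inheritParams bnmi_select
#' @param n_runs Number of Monte-Carlo runs (default 50).
#' @param mc_fraction Fraction of calibration samples drawn per run.
#' @param seed RNG seed.
#' @return A `selection_result` with the per-run trace in `$runs`.
#' @export
cars_select <- function(ds, n_runs = 50, mc_fraction = 0.8, seed = 1L,
                        lv_cap = 10,
                        lv_rule = c("parsimonious", "global_min"),
                        rmse_divisor = c("m", "m-1")) {
  lv_rule <- match.arg(lv_rule)
  rmse_divisor <- match.arg(rmse_divisor)
  if (n_runs < 2) stop("n_runs must be at least 2")
  cal <- spectra_block(ds, "calibration")
  val <- spectra_block(ds, "validation")
  m <- nrow(cal$X)
  n <- ncol(cal$X)
  # exponentially decreasing retention: r_1 = 1, r_N = 2/n
  k_edf <- log(n / 2) / (n_runs - 1)
  a_edf <- exp(k_edf)
  ratios <- a_edf * exp(-k_edf * seq_len(n_runs))
  with_local_seed(seed, {
    retained <- seq_len(n)
    trace <- vector("list", n_runs)
    for (i in seq_len(n_runs)) {
      sub <- sort(sample(m, max(3, round(mc_fraction * m))))
      Xs <- cal$X[sub, retained, drop = FALSE]
      ys <- cal$y[sub]
      max_lv <- min(lv_cap, length(sub) - 2L, length(retained))
      nlv <- select_lv(loocv_curve(Xs, ys, max_lv), lv_rule)
      b <- abs(fit_pls(Xs, ys, nlv)$beta)
      n_keep <- max(2L, min(round(ratios[i] * n), length(retained)))
      edf_keep <- retained[order(-b, seq_along(b))][seq_len(n_keep)]
      w <- b[match(edf_keep, retained)]
      draws <- sample(edf_keep, n_keep, replace = TRUE,
                      prob = if (sum(w) > 0) w else NULL)
      retained <- sort(unique(draws))
      if (length(retained) < 2) retained <- sort(edf_keep[seq_len(2)])
      cv <- loocv_curve(cal$X[, retained, drop = FALSE], cal$y,
                        min(lv_cap, m - 2L, length(retained)))
      nlv_full <- select_lv(cv, lv_rule)
      trace[[i]] <- list(run = i, n_retained = length(retained),
                         rmsecv = cv$rmsecv[nlv_full], vars = retained)
    }
    runs <- tibble::tibble(
      run = vapply(trace, `[[`, integer(1), "run"),
      n_retained = vapply(trace, `[[`, numeric(1), "n_retained"),
      rmsecv = vapply(trace, `[[`, numeric(1), "rmsecv")
    )
    best <- which.min(runs$rmsecv)
    selected <- trace[[best]]$vars
    ord <- c(selected, setdiff(seq_len(n), selected))
    finalize_selection("CARS", ds, cal, val, ord, selected, NULL, lv_cap,
                       lv_rule, rmse_divisor,
                       extra = list(runs = runs, best_run = best))
  })
}

# Partition 1..n into n_intervals contiguous chunks, sizes differing by <= 1.
make_intervals <- function(n, n_intervals) {
  split(seq_len(n), ceiling(seq_len(n) * n_intervals / n))
}

#' Backward-interval PLS (BIPLS)
#'
#' Splits the wavelength axis into equal-width contiguous intervals and
#' performs backward elimination: at each round the interval whose omission
#' yields the smallest RMSECV is dropped, until no removal improves RMSECV
#' (or one interval remains). Selected wavelengths are the union of the
#' surviving intervals.
#'
#' @inheritParams bnmi_select
#' @param n_intervals Number of intervals (default 20).
#' @return A `selection_result` with the elimination trace in `$trace`.
#' @export
bipls_select <- function(ds, n_intervals = 20, lv_cap = 10,
                         lv_rule = c("parsimonious", "global_min"),
                         rmse_divisor = c("m", "m-1")) {
  lv_rule <- match.arg(lv_rule)
  rmse_divisor <- match.arg(rmse_divisor)
  cal <- spectra_block(ds, "calibration")
  val <- spectra_block(ds, "validation")
  m <- nrow(cal$X)
  n <- ncol(cal$X)
  if (n_intervals < 2) stop("n_intervals must be at least 2")
  if (n_intervals > n) stop("n_intervals may not exceed the variable count")
  intervals <- make_intervals(n, n_intervals)
  rmsecv_of <- function(vars) {
    cv <- loocv_curve(cal$X[, vars, drop = FALSE], cal$y,
                      min(lv_cap, m - 2L, length(vars)))
    cv$rmsecv[select_lv(cv, lv_rule)]
  }
  alive <- seq_along(intervals)
  current <- rmsecv_of(unlist(intervals[alive]))
  trace <- list(tibble::tibble(round = 0L, removed = NA_integer_,
                               rmsecv = current))
  round_i <- 1L
  while (length(alive) > 1) {
    cand <- vapply(alive, function(j) {
      rmsecv_of(unlist(intervals[setdiff(alive, j)]))
    }, numeric(1))
    best <- which.min(cand)
    if (cand[best] >= current) break
    current <- cand[best]
    trace[[length(trace) + 1]] <- tibble::tibble(
      round = round_i, removed = alive[best], rmsecv = current
    )
    alive <- setdiff(alive, alive[best])
    round_i <- round_i + 1L
  }
  selected <- sort(unlist(intervals[alive]))
  ord <- c(selected, setdiff(seq_len(n), selected))
  finalize_selection("BIPLS", ds, cal, val, ord, selected, NULL, lv_cap,
                     lv_rule, rmse_divisor,
                     extra = list(trace = dplyr::bind_rows(trace),
                                  intervals = intervals))
}
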