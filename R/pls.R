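# SIMPLS core on pre-centered data. Returns rotations R (n x A), y-loadings q,
# X-loadings P, scores T (orthonormal), and beta_all whose column k is the
# regression vector using the first k latent variables. Extraction stops early
# if the X rank is exhausted (ncomp attribute records the count achieved).
simpls_pls1 <- function(Xc, yc, ncomp, tol = 1e-12) {
  n <- ncol(Xc)
  m <- nrow(Xc)
  s <- crossprod(Xc, yc)
  R <- matrix(0, n, ncomp)
  V <- matrix(0, n, ncomp)
  P <- matrix(0, n, ncomp)
  TT <- matrix(0, m, ncomp)
  q <- numeric(ncomp)
  a_done <- 0L
  scale0 <- sqrt(sum(s^2))
  for (a in seq_len(ncomp)) {
    r <- s
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (nt <= tol * max(scale0, 1)) break
    t <- t / nt
    r <- r / nt
    p <- crossprod(Xc, t)
    q[a] <- sum(yc * t)
    v <- p
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p)
    }
    nv <- sqrt(sum(v^2))
    if (nv <= tol) break
    v <- v / nv
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r
    V[, a] <- v
    P[, a] <- p
    TT[, a] <- t
    a_done <- a
  }
  if (a_done == 0L) stop("zero-variance response or degenerate X: no latent variable extractable")
  R <- R[, seq_len(a_done), drop = FALSE]
  P <- P[, seq_len(a_done), drop = FALSE]
  TT <- TT[, seq_len(a_done), drop = FALSE]
  q <- q[seq_len(a_done)]
  # beta for every prefix of latent variables: cumulative sum of R[,a] q[a],
  # realized as a product with an upper-triangular matrix of ones
  Bq <- R * rep(q, each = n)
  U <- upper.tri(diag(a_done), diag = TRUE) * 1
  beta_all <- Bq %*% U
  dim(beta_all) <- c(n, a_done)
  list(R = R, P = P, scores = TT, q = q, beta_all = beta_all, ncomp = a_done)
}

#' Fit a PLS1 regression model
#'
#' SIMPLS partial least squares with a single response. Mean centering of both
#' blocks is learned here (calibration rows only) and undone at prediction; at
#' full rank the fit reproduces ordinary least squares.
#'
#' @param X Calibration absorbance matrix, `m` by `n`.
#' @param y Calibration reference vector.
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(m - 1, n)`.
#' @return An object of class `pls_model` with elements `n_lv`, `beta`
#'   (length-`n` coefficient vector in centered variable space), `weights`
#'   (SIMPLS rotations), `loadings`, `y_loadings`, `scores`, `centering`
#'   (a `centering_state`).
#' @export
fit_pls <- function(X, y, n_lv) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  m <- nrow(X)
  n <- ncol(X)
  if (n_lv < 1 || n_lv > min(m - 1, n)) {
    stop("n_lv must lie in [1, min(m - 1, n)] = [1, ", min(m - 1, n), "]")
  }
  if (stats::var(y) == 0) stop("zero-variance reference: nothing to regress")
  ctr <- mean_center(X, y)
  fit <- simpls_pls1(ctr$Xc, ctr$yc, n_lv)
  k <- min(n_lv, fit$ncomp)
  structure(
    list(
      n_lv = k, beta = fit$beta_all[, k],
      weights = fit$R[, seq_len(k), drop = FALSE],
      loadings = fit$P[, seq_len(k), drop = FALSE],
      y_loadings = fit$q[seq_len(k)],
      scores = fit$scores[, seq_len(k), drop = FALSE],
      centering = ctr[c("column_means", "target_mean")]
    ),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", length(x$beta), " variables, ", x$n_lv,
      " latent variable(s)\n", sep = "")
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix with the training column count.
#' @param ... Unused.
#' @return Numeric vector of predictions in reference units.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$beta)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$beta))
  }
  Xc <- sweep(newdata, 2, object$centering$column_means)
  drop(Xc %*% object$beta) + object$centering$target_mean
}

#' Leave-one-out cross-validation error curve
#'
#' For each left-out sample the centering and the SIMPLS fit are rebuilt from
#' the remaining `m - 1` rows; entry `k` of the curve is the RMSECV using `k`
#' latent variables.
#'
#' @param X Calibration matrix (`m >= 3` rows).
#' @param y Calibration reference vector.
#' @param max_lv Largest latent-variable count, `<= min(m - 2, n)`.
#' @return A tibble of class `cv_curve` with columns `n_lv` and `rmsecv`.
#' @export
loocv_curve <- function(X, y, max_lv) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  m <- nrow(X)
  if (m < 3) stop("LOOCV needs at least 3 samples")
  if (max_lv < 1 || max_lv > min(m - 2, ncol(X))) {
    stop("max_lv must lie in [1, min(m - 2, n)] = [1, ", min(m - 2, ncol(X)), "]")
  }
  sse <- numeric(max_lv)
  for (i in seq_len(m)) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    mu <- colMeans(Xi)
    ybar <- mean(yi)
    fit <- simpls_pls1(sweep(Xi, 2, mu), yi - ybar, max_lv)
    xc <- X[i, ] - mu
    pred <- drop(crossprod(fit$beta_all, xc)) + ybar
    if (fit$ncomp < max_lv) { # rank exhausted: higher-LV fits coincide
      pred <- c(pred, rep(pred[fit$ncomp], max_lv - fit$ncomp))
    }
    sse <- sse + (pred - y[i])^2
  }
  structure(
    tibble::tibble(n_lv = seq_len(max_lv), rmsecv = sqrt(sse / m)),
    class = c("cv_curve", class(tibble::tibble()))
  )
}

#' Choose the latent-variable count from a cross-validation curve
#'
#' `"global_min"` returns the argmin (lowest LV on ties). `"parsimonious"`
#' returns the smallest LV whose RMSECV is within `tol` (relative) of the
#' minimum — the usual "smallest error or its inflection point" reading.
#'
#' @param curve A `cv_curve` (or bare numeric RMSECV vector).
#' @param rule `"parsimonious"` (default) or `"global_min"`.
#' @param tol Relative tolerance for the parsimonious rule (default 0.02).
#' @return Integer latent-variable count.
#' @export
select_lv <- function(curve, rule = c("parsimonious", "global_min"), tol = 0.02) {
  rule <- match.arg(rule)
  r <- if (is.data.frame(curve)) curve$rmsecv else as.numeric(curve)
  if (length(r) == 0) stop("empty cross-validation curve")
  if (rule == "global_min") {
    return(which.min(r))
  }
  best <- min(r)
  which(r <= (1 + tol) * best)[1]
}

# Root mean square error; divisor "m" (number of predicted samples, the
# conventional definition) or "m-1".
rmse <- function(actual, predicted, divisor = c("m", "m-1")) {
  divisor <- match.arg(divisor)
  denom <- if (divisor == "m") length(actual) else length(actual) - 1
  sqrt(sum((actual - predicted)^2) / denom)
}

# Coefficient of determination: 1 - SSE / SST about the actuals' mean.
r_squared <- function(actual, predicted) {
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) stop("zero variance in actual values: R^2 undefined")
  1 - sum((actual - predicted)^2) / sst
}

#' Calibration and prediction metrics of a fitted model
#'
#' The standard chemometric report for one calibration: determination
#' coefficients on the calibration and validation sets, RMSEC / RMSECV /
#' RMSEP, the ratio of performance to deviation
#' `RPD = sd(validation references) / RMSEP`, and the validation bias
#' (mean of predicted minus actual).
#'
#' @param model A fitted `pls_model`.
#' @param cal,val Lists with elements `X` and `y` (e.g. from
#'   [spectra_block()]), possibly column-subset to the model's variables.
#' @param cv_curve Optional `cv_curve`; its value at the model's LV count is
#'   reported as RMSECV.
#' @param rmse_divisor `"m"` (default) or `"m-1"`.
#' @return A one-row tibble: `r2_cal`, `r2_pred`, `rmsec`, `rmsecv`, `rmsep`,
#'   `rpd`, `bias`, `n_vars`, `n_lv`.
#' @export
calibration_metrics <- function(model, cal, val, cv_curve = NULL,
                                rmse_divisor = c("m", "m-1")) {
  rmse_divisor <- match.arg(rmse_divisor)
  if (length(cal$y) == 0 || length(val$y) == 0) stop("empty calibration or validation set")
  pred_cal <- predict(model, cal$X)
  pred_val <- predict(model, val$X)
  rmsecv <- if (!is.null(cv_curve)) {
    r <- if (is.data.frame(cv_curve)) cv_curve$rmsecv else as.numeric(cv_curve)
    r[min(model$n_lv, length(r))]
  } else {
    NA_real_
  }
  rmsep <- rmse(val$y, pred_val, rmse_divisor)
  tibble::tibble(
    r2_cal = r_squared(cal$y, pred_cal),
    r2_pred = r_squared(val$y, pred_val),
    rmsec = rmse(cal$y, pred_cal, rmse_divisor),
    rmsecv = rmsecv,
    rmsep = rmsep,
    rpd = stats::sd(val$y) / rmsep,
    bias = mean(pred_val - val$y),
    n_vars = length(model$beta),
    n_lv = model$n_lv
  )
}
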