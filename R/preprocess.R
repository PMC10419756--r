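#' Learn mean-centering from a calibration block
#'
#' Mean centering is the default pretreatment before PLS regression: column
#' means of the calibration absorbances and the calibration reference mean are
#' learned on calibration rows only and later applied unchanged to validation
#' rows.
#'
#' @param cal_X Calibration absorbance matrix (>= 2 rows).
#' @param cal_y Calibration reference vector.
#' @return A list of class `centering_state` with `column_means`,
#'   `target_mean`, and the centered blocks `Xc`, `yc`.
#' @export
mean_center <- function(cal_X, cal_y) {
  cal_X <- as.matrix(cal_X)
  if (nrow(cal_X) < 2) stop("mean centering needs at least 2 calibration rows")
  if (length(cal_y) != nrow(cal_X)) stop("cal_y length must match cal_X rows")
  mu <- colMeans(cal_X)
  ybar <- mean(cal_y)
  structure(
    list(
      column_means = mu, target_mean = ybar,
      Xc = sweep(cal_X, 2, mu), yc = cal_y - ybar
    ),
    class = "centering_state"
  )
}

#' Apply a learned centering to new rows
#'
#' @param state A `centering_state` from [mean_center()].
#' @param X New absorbance rows (same column count as training).
#' @return Centered matrix.
#' @export
apply_centering <- function(state, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(state$column_means)) {
    stop("column count does not match the centering state")
  }
  sweep(X, 2, state$column_means)
}

#' Standard normal variate (SNV) transform
#'
#' Per-spectrum normalization that removes baseline offset and multiplicative
#' scatter: each row is centered to mean 0 and scaled to sample standard
#' deviation 1 (divisor n-1).
#'
#' @param X Absorbance matrix; every row must be non-constant.
#' @return Matrix of the same shape with row means 0 and row sds 1.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  mu <- rowMeans(X)
  s <- apply(X, 1, stats::sd)
  if (any(s == 0)) {
    stop("SNV undefined for constant spectrum (row ", which(s == 0)[1], ")")
  }
  sweep(sweep(X, 1, mu), 1, s, `/`)
}

#' Apply the configured preprocessing to a dataset
#'
#' @param ds A `spectra_dataset`.
#' @param method One of `"none"`, `"mean_center"`, `"snv+mean_center"`. SNV
#'   (when enabled) acts per spectrum before model-level mean centering, which
#'   is always handled inside the PLS fit.
#' @return The dataset with `X` transformed (SNV only; centering is a model
#'   concern, not a data transform).
#' @export
preprocess <- function(ds, method = c("mean_center", "none", "snv+mean_center")) {
  method <- match.arg(method)
  if (method == "snv+mean_center") ds$X <- snv(ds$X)
  ds
}
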