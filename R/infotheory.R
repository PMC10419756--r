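#' Equal-interval binning scheme
#'
#' Divides the range of a data column into `bin_count` contiguous intervals of
#' equal width `(d_max - d_min) / bin_count`; interior boundaries sit at
#' `d_min + width, d_min + 2 width, ...`. Discretizing continuous absorbances
#' this way damps minor measurement error before entropy estimation.
#'
#' @param values Numeric vector the scheme is fitted to.
#' @param bin_count Integer number of bins, `>= 1`.
#' @return A list of class `binning_scheme` with `bin_count`, `d_min`,
#'   `d_max`, `bin_width`, `edges` (length `bin_count + 1`).
#' @export
#' @examples
#' make_binning(c(2, 7, 12), 5) # width 2, edges 2,4,...,12
make_binning <- function(values, bin_count) {
  if (length(bin_count) != 1 || is.na(bin_count) || bin_count < 1 ||
      bin_count != round(bin_count)) {
    stop("bin_count must be a positive integer")
  }
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values)) stop("values must be non-empty, no NA")
  d_min <- min(values)
  d_max <- max(values)
  if (d_max == d_min && bin_count > 1) {
    stop("constant vector: degenerate range for bin_count > 1")
  }
  bin_width <- (d_max - d_min) / bin_count
  edges <- d_min + bin_width * 0:bin_count
  edges[bin_count + 1] <- d_max # guard the top edge against rounding drift
  structure(
    list(
      bin_count = as.integer(bin_count), d_min = d_min, d_max = d_max,
      bin_width = bin_width,
      edges = edges
    ),
    class = "binning_scheme"
  )
}

#' Discretize values under a binning scheme
#'
#' Label `k` (0-based) covers `[edge_k, edge_{k+1})`; the last interval is
#' closed above so `d_max` maps to bin `bin_count - 1`.
#'
#' @param values Numeric vector within `[d_min, d_max]` of the scheme (set
#'   `clamp = TRUE` to push out-of-range values into the outer bins instead of
#'   erroring, e.g. for validation rows under calibration-fitted bins).
#' @param scheme A `binning_scheme`.
#' @param clamp Clamp out-of-range values instead of raising an error.
#' @return A list of class `discrete_series` with integer `labels` in
#'   `[0, bin_count - 1]` and `bin_count`.
#' @export
discretize <- function(values, scheme, clamp = FALSE) {
  stopifnot(inherits(scheme, "binning_scheme"))
  values <- as.numeric(values)
  out_of_range <- values < scheme$d_min | values > scheme$d_max
  if (any(out_of_range)) {
    if (!clamp) {
      stop("value out of binning range at position ", which(out_of_range)[1])
    }
    values <- pmin(pmax(values, scheme$d_min), scheme$d_max)
  }
  if (scheme$bin_width == 0) {
    labels <- integer(length(values))
  } else {
    labels <- as.integer(floor((values - scheme$d_min) / scheme$bin_width))
    labels <- pmin(labels, scheme$bin_count - 1L) # top edge closed
  }
  structure(
    list(labels = labels, bin_count = scheme$bin_count),
    class = "discrete_series"
  )
}

#' Joint histogram of two discrete series
#'
#' @param x,y `discrete_series` objects of equal length.
#' @return A list of class `joint_histogram` with the count matrix `counts`
#'   (`bin_count(x)` by `bin_count(y)`), `total`, and derived probabilities
#'   `p_xy`, `p_x`, `p_y`.
#' @export
joint_histogram <- function(x, y) {
  stopifnot(inherits(x, "discrete_series"), inherits(y, "discrete_series"))
  if (length(x$labels) != length(y$labels)) {
    stop("series lengths differ")
  }
  counts <- matrix(0L, x$bin_count, y$bin_count)
  tab <- table(factor(x$labels, levels = 0:(x$bin_count - 1L)),
               factor(y$labels, levels = 0:(y$bin_count - 1L)))
  counts[] <- as.integer(tab)
  joint_from_counts(counts)
}

#' Build a joint histogram directly from a count table
#'
#' @param counts Nonnegative integer matrix of joint bin counts.
#' @return A `joint_histogram`.
#' @export
joint_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  total <- sum(counts)
  if (total == 0) stop("empty joint histogram")
  p_xy <- counts / total
  structure(
    list(
      counts = counts, total = total, p_xy = p_xy,
      p_x = rowSums(p_xy), p_y = colSums(p_xy)
    ),
    class = "joint_histogram"
  )
}

#' Shannon entropy of a probability vector, in bits
#'
#' Plug-in estimator with the 0 log 0 = 0 convention.
#'
#' @param p Probability vector: nonnegative, summing to 1 (tolerance 1e-9).
#' @return Entropy in bits (nonnegative scalar).
#' @export
shannon_entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("negative probability")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Conditional entropy H(X | Y) of a joint histogram, in bits
#'
#' `H(X|Y) = -sum_j p(y_j) sum_i p(x_i|y_j) log2 p(x_i|y_j)`; columns with
#' zero marginal mass contribute nothing.
#'
#' @param joint A `joint_histogram` (X indexes rows, Y columns).
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(joint) {
  stopifnot(inherits(joint, "joint_histogram"))
  h <- 0
  for (j in seq_along(joint$p_y)) {
    py <- joint$p_y[j]
    if (py == 0) next
    pc <- joint$p_xy[, j] / py
    pc <- pc[pc > 0]
    h <- h - py * sum(pc * log2(pc))
  }
  h
}

#' Mutual information of a joint histogram, in bits
#'
#' Two algebraically equivalent routes are implemented: the entropy
#' difference `H(X) - H(X|Y)` and the double sum
#' `sum_ij p_ij log2(p_ij / (p_i p_j))`. Both are exposed so each can check
#' the other; they agree to 1e-9 on any valid joint.
#'
#' @param joint A `joint_histogram`.
#' @param method `"conditional"` (entropy difference) or `"double_sum"`.
#' @return Mutual information in bits (nonnegative).
#' @export
mutual_information <- function(joint, method = c("conditional", "double_sum")) {
  stopifnot(inherits(joint, "joint_histogram"))
  method <- match.arg(method)
  if (method == "conditional") {
    mi <- shannon_entropy(joint$p_x) - conditional_entropy(joint)
  } else {
    p <- joint$p_xy
    outer_p <- outer(joint$p_x, joint$p_y)
    nz <- p > 0
    mi <- sum(p[nz] * log2(p[nz] / outer_p[nz]))
  }
  max(mi, 0) # clip tiny negative rounding
}

#' Normalized mutual information (symmetrical uncertainty)
#'
#' `NMI(X, Y) = 2 MI(X, Y) / (H(X) + H(Y))`, rescaling mutual information to
#' `[0, 1]` to remove its bias towards high-cardinality variables: 1 for a
#' fully dependent pair, 0 for an independent one. Returns 0 when both series
#' are constant (`H(X) + H(Y) = 0`).
#'
#' @param x,y `discrete_series` objects of equal length.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(x, y) {
  joint <- joint_histogram(x, y)
  hx <- shannon_entropy(joint$p_x)
  hy <- shannon_entropy(joint$p_y)
  if (hx + hy == 0) return(0)
  val <- 2 * mutual_information(joint) / (hx + hy)
  min(max(val, 0), 1)
}

#' NMI profile of a spectrum against the reference
#'
#' For each wavelength, discretizes that column of the calibration absorbance
#' block and the reference vector with the same equal-interval bin count (each
#' on its own min-max range) and computes their normalized mutual information.
#' This is the per-wavelength relevance profile the B-NMI ranking sorts.
#'
#' Constant (dead) spectral channels get NMI 0 with a warning rather than an
#' error, so full instrument spectra still process.
#'
#' @param X Calibration absorbance matrix (or a `spectra_dataset`, whose
#'   calibration block is used).
#' @param y Calibration reference vector (ignored when `X` is a dataset).
#' @param bin_count Equal-interval bin count shared by every column and `y`.
#' @return A tibble with columns `index`, `wavelength` (if known) and `nmi`.
#' @export
nmi_profile <- function(X, y = NULL, bin_count) {
  wavelengths <- NULL
  if (inherits(X, "spectra_dataset")) {
    cal <- spectra_block(X, "calibration")
    wavelengths <- cal$wavelengths
    y <- cal$y
    X <- cal$X
  }
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("y length must match rows of X")
  dy <- discretize(y, make_binning(y, bin_count))
  vals <- vapply(seq_len(ncol(X)), function(j) {
    col <- X[, j]
    if (max(col) == min(col)) {
      warning("constant spectral column ", j, ": NMI set to 0")
      return(0)
    }
    nmi(discretize(col, make_binning(col, bin_count)), dy)
  }, numeric(1))
  out <- tibble::tibble(index = seq_len(ncol(X)), nmi = vals)
  if (!is.null(wavelengths)) {
    out <- tibble::add_column(out, wavelength = wavelengths, .after = "index")
  }
  out
}
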