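#' Construct a spectral calibration dataset
#'
#' Bundles an absorbance matrix (samples in rows, wavelengths in columns), its
#' wavelength axis, the reference property vector and per-sample roles into a
#' `spectra_dataset` object, the container every selector in this package
#' consumes.
#'
#' @param X Numeric matrix, `m` samples by `n` wavelengths, no missing values.
#' @param wavelengths Length-`n` numeric vector (nm or cm^-1), strictly
#'   monotone (increasing or decreasing; preserved as given).
#' @param y Length-`m` numeric reference vector (property units, e.g. mass
#'   fraction, % moisture, octane number).
#' @param sample_ids Optional length-`m` character labels; defaults to row
#'   numbers.
#' @param role Optional length-`m` character vector with entries in
#'   `"calibration"`, `"validation"`, `"unassigned"`; defaults to
#'   `"unassigned"`.
#' @return A `spectra_dataset` object.
#' @export
#' @examples
#' X <- matrix(runif(12), 3, 4)
#' spectra_dataset(X, wavelengths = c(1100, 1102, 1104, 1106), y = c(1, 2, 3))
spectra_dataset <- function(X, wavelengths, y, sample_ids = NULL, role = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("absorbance matrix contains missing values")
  m <- nrow(X)
  n <- ncol(X)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != n) {
    stop("length(wavelengths) must equal ncol(X)")
  }
  if (n >= 2) {
    d <- diff(wavelengths)
    if (!(all(d > 0) || all(d < 0))) {
      stop("wavelengths must be strictly monotone")
    }
  }
  y <- as.numeric(y)
  if (length(y) != m) stop("length(y) must equal nrow(X)")
  if (anyNA(y)) stop("reference vector contains missing values")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(m))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != m) stop("length(sample_ids) must equal nrow(X)")
  if (is.null(role)) role <- rep("unassigned", m)
  role <- as.character(role)
  if (length(role) != m) stop("length(role) must equal nrow(X)")
  bad <- setdiff(unique(role), c("calibration", "validation", "unassigned"))
  if (length(bad) > 0) {
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(
      X = unname(X), wavelengths = wavelengths, y = y,
      sample_ids = sample_ids, role = role
    ),
    class = "spectra_dataset"
  )
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(
    "<spectra_dataset> ", length(x$y), " samples x ",
    length(x$wavelengths), " wavelengths\n",
    sep = ""
  )
  cat(
    "  wavelength range: ", min(x$wavelengths), "-", max(x$wavelengths), "\n",
    "  roles: ", sum(x$role == "calibration"), " calibration, ",
    sum(x$role == "validation"), " validation, ",
    sum(x$role == "unassigned"), " unassigned\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$X)

#' Long-format view of a spectral dataset
#'
#' @param x A `spectra_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per (sample, wavelength) pair and columns
#'   `sample_id`, `role`, `reference`, `wavelength`, `absorbance`.
#' @importFrom tibble as_tibble
#' @method as_tibble spectra_dataset
#' @export
as_tibble.spectra_dataset <- function(x, ...) {
  m <- length(x$y)
  n <- length(x$wavelengths)
  tibble::tibble(
    sample_id = rep(x$sample_ids, each = n),
    role = rep(x$role, each = n),
    reference = rep(x$y, each = n),
    wavelength = rep(x$wavelengths, times = m),
    absorbance = as.vector(t(x$X))
  )
}

#' Extract the calibration or validation block
#'
#' @param ds A `spectra_dataset`.
#' @param role `"calibration"` or `"validation"`.
#' @return A list with elements `X`, `y`, `sample_ids`, `wavelengths`.
#' @export
spectra_block <- function(ds, role = c("calibration", "validation")) {
  role <- match.arg(role)
  idx <- which(ds$role == role)
  if (length(idx) == 0) stop("no samples with role '", role, "'")
  list(
    X = ds$X[idx, , drop = FALSE], y = ds$y[idx],
    sample_ids = ds$sample_ids[idx], wavelengths = ds$wavelengths
  )
}

#' Read a spectral dataset from a delimited text file
#'
#' Expects one header row in which the spectral columns are named by their
#' numeric wavelength, one column holding the reference property, and an
#' optional id column; every other column must parse as a wavelength.
#'
#' @param path File path of a comma-separated table.
#' @param reference_column Name of the reference column.
#' @param id_column Optional name of the sample-id column.
#' @return A `spectra_dataset` with all roles `"unassigned"`.
#' @export
read_spectra_csv <- function(path, reference_column, id_column = NULL) {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         name_repair = "minimal", progress = FALSE)
  headers <- names(tab)
  if (sum(headers == reference_column) != 1) {
    stop("reference column '", reference_column, "' not found in ", path)
  }
  spec_pos <- which(!headers %in% c(reference_column, id_column))
  wl <- suppressWarnings(as.numeric(headers[spec_pos]))
  if (anyNA(wl)) {
    stop(
      "non-numeric wavelength header(s): ",
      paste(headers[spec_pos][is.na(wl)], collapse = ", ")
    )
  }
  if (anyDuplicated(wl)) stop("duplicate wavelength header in ", path)
  X <- matrix(NA_real_, nrow(tab), length(spec_pos))
  for (j in seq_along(spec_pos)) {
    v <- suppressWarnings(as.numeric(tab[[spec_pos[j]]]))
    if (anyNA(v)) {
      stop(
        "non-numeric absorbance in column '", headers[spec_pos[j]],
        "', row ", which(is.na(v))[1]
      )
    }
    X[, j] <- v
  }
  y <- suppressWarnings(as.numeric(tab[[which(headers == reference_column)]]))
  if (anyNA(y)) {
    stop("non-numeric reference value in row ", which(is.na(y))[1])
  }
  ids <- if (!is.null(id_column) && id_column %in% headers) {
    as.character(tab[[which(headers == id_column)[1]]])
  } else {
    NULL
  }
  spectra_dataset(X, wl, y, sample_ids = ids)
}

#' Write a spectral dataset to a delimited text file
#'
#' Inverse of [read_spectra_csv()]: wavelengths become column headers, the
#' reference goes into `ref`, sample ids into `id`.
#'
#' @param ds A `spectra_dataset`.
#' @param path Output file path.
#' @param reference_column Header for the reference column.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(ds, path, reference_column = "ref") {
  tab <- tibble::as_tibble(
    as.data.frame(ds$X) |> stats::setNames(format(ds$wavelengths, trim = TRUE))
  )
  tab <- dplyr::bind_cols(tibble::tibble(id = ds$sample_ids), tab)
  tab[[reference_column]] <- ds$y
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Kennard-Stone calibration/validation split
#'
#' Deterministic max-min Euclidean split: the first two picks are the most
#' mutually distant pair of samples; every later pick maximizes its minimum
#' distance to the already-selected calibration set. Ties are broken towards
#' the lower original row index.
#'
#' @param X Numeric sample-by-variable matrix (or a `spectra_dataset`, whose
#'   raw absorbances are used).
#' @param n_cal Number of calibration samples, `2 <= n_cal < nrow(X)`.
#' @return A list with integer vectors `calibration` and `validation`
#'   (row indices).
#' @export
kennard_stone_split <- function(X, n_cal) {
  if (inherits(X, "spectra_dataset")) X <- X$X
  X <- as.matrix(X)
  m <- nrow(X)
  if (n_cal != round(n_cal) || n_cal < 2 || n_cal > m) {
    stop("n_cal must be an integer with 2 <= n_cal <= number of samples (",
         m, ")")
  }
  d <- as.matrix(stats::dist(X))
  # most distant pair, lowest indices on ties
  best <- which(d == max(d), arr.ind = TRUE)
  best <- best[order(pmin(best[, 1], best[, 2]), pmax(best[, 1], best[, 2])), ,
               drop = FALSE]
  sel <- sort(c(best[1, 1], best[1, 2]))
  while (length(sel) < n_cal) {
    remaining <- setdiff(seq_len(m), sel)
    mind <- apply(d[remaining, sel, drop = FALSE], 1, min)
    pick <- remaining[which.max(mind)] # which.max takes first = lowest index
    sel <- c(sel, pick)
  }
  list(calibration = sel, validation = setdiff(seq_len(m), sel))
}

#' Assign calibration/validation roles by Kennard-Stone
#'
#' @param ds A `spectra_dataset`.
#' @param fraction Fraction of samples assigned to calibration (default 0.75).
#' @param n_cal Alternatively, the exact calibration count.
#' @return The dataset with roles filled in.
#' @export
ks_assign <- function(ds, fraction = 0.75, n_cal = NULL) {
  if (is.null(n_cal)) n_cal <- round(fraction * nrow(ds$X))
  split <- kennard_stone_split(ds$X, n_cal)
  ds$role[split$calibration] <- "calibration"
  ds$role[split$validation] <- "validation"
  ds
}

#' Average replicate spectra
#'
#' Collapses replicate measurements of the same physical sample to their
#' arithmetic mean spectrum. All members of a group must share one reference
#' value.
#'
#' @param ds A `spectra_dataset`.
#' @param groups Length-`m` replicate-group labels.
#' @return A `spectra_dataset` with one row per group, in order of first
#'   appearance.
#' @export
average_replicates <- function(ds, groups) {
  groups <- as.character(groups)
  if (length(groups) != nrow(ds$X)) {
    stop("groups must have one label per sample")
  }
  levels <- unique(groups)
  Xout <- matrix(0, length(levels), ncol(ds$X))
  yout <- numeric(length(levels))
  for (g in seq_along(levels)) {
    idx <- which(groups == levels[g])
    yg <- unique(ds$y[idx])
    if (length(yg) != 1) {
      stop("group '", levels[g], "' has conflicting reference values")
    }
    Xout[g, ] <- colMeans(ds$X[idx, , drop = FALSE])
    yout[g] <- yg
  }
  spectra_dataset(Xout, ds$wavelengths, yout, sample_ids = levels)
}

#' Descriptive statistics of a reference vector
#'
#' Count, mean, sample standard deviation (divisor n-1) and range, the
#' summary conventionally tabulated for calibration and validation reference
#' sets. The validation-set sd is the numerator of the RPD.
#'
#' @param values Non-empty numeric vector.
#' @return A one-row tibble with columns `count`, `mean`, `sd`, `min`, `max`.
#' @export
descriptive_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values)) {
    stop("values must be non-empty and free of NA")
  }
  tibble::tibble(
    count = length(values),
    mean = mean(values),
    sd = if (length(values) > 1) stats::sd(values) else 0,
    min = min(values),
    max = max(values)
  )
}
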