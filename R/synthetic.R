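#' Specification of a synthetic Beer-Lambert mixture dataset
#'
#' Describes a mixture system whose spectra are bilinear in concentration and
#' Gaussian-band pure-component spectra, plus a per-sample linear baseline and
#' iid Gaussian noise — the statistical skeleton of a liquid NIR calibration.
#' The ground-truth informative wavelengths (within `mask_width` standard
#' deviations of any target-component band center) are recorded so selector
#' recovery can be scored.
#'
#' @param n_wavelengths Number of spectral points.
#' @param wavelength_range Length-2 numeric range (nm).
#' @param components List of components; each is a list of peaks
#'   `(center, sigma, amplitude)`.
#' @param target Index of the component whose concentration is the reference.
#' @param conc_ranges List of length-2 concentration ranges per component;
#'   under `closure` the last component takes the remainder to total 1.
#' @param closure Keep the total concentration constant at 1 (last component
#'   as filler), mimicking constant-total-volume mixture designs.
#' @param baseline_offset_sd,baseline_slope_sd Per-sample baseline offset and
#'   slope scales (AU; slope applied over the full wavelength span).
#' @param noise_sd Absorbance noise standard deviation (AU).
#' @param n_samples Number of mixtures.
#' @param replicates Replicate spectra per mixture (same concentrations,
#'   fresh noise/baseline).
#' @param mask_width Half-width of the informative mask in band sigmas.
#' @param seed RNG seed; generation is bit-for-bit replayable.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_wavelengths = 200,
                           wavelength_range = c(1000, 2500),
                           components,
                           target = 1,
                           conc_ranges,
                           closure = TRUE,
                           baseline_offset_sd = 0.01,
                           baseline_slope_sd = 0.005,
                           noise_sd = 0.002,
                           n_samples = 60,
                           replicates = 1,
                           mask_width = 2,
                           seed = 7L) {
  stopifnot(length(components) >= 1, target >= 1, target <= length(components))
  if (length(conc_ranges) != length(components)) {
    stop("one concentration range per component is required")
  }
  for (r in conc_ranges) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0) {
      stop("invalid concentration range")
    }
  }
  wl <- seq(wavelength_range[1], wavelength_range[2],
            length.out = n_wavelengths)
  mask <- rep(FALSE, n_wavelengths)
  for (pk in components[[target]]) {
    mask <- mask | abs(wl - pk$center) <= mask_width * pk$sigma
  }
  structure(
    list(
      n_wavelengths = n_wavelengths, wavelengths = wl,
      components = components, target = target, conc_ranges = conc_ranges,
      closure = closure, baseline_offset_sd = baseline_offset_sd,
      baseline_slope_sd = baseline_slope_sd, noise_sd = noise_sd,
      n_samples = n_samples, replicates = replicates,
      mask_width = mask_width, informative_mask = mask, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' The default two-band mixture fixture
#'
#' A 3-component liquid mixture on 1000-2500 nm (200 points, 60 samples):
#' the target component absorbs in two bands centered at 1450 and 1940 nm
#' (the classic water O-H first overtone and combination bands), two
#' interferents absorb elsewhere, concentrations close to a constant total,
#' noise 0.002 AU.
#'
#' @param seed RNG seed (default 7).
#' @param noise_sd Absorbance noise sd (default 0.002 AU).
#' @param n_samples Number of mixtures (default 60).
#' @return A `synthetic_spec`.
#' @export
two_band_spec <- function(seed = 7L, noise_sd = 0.002, n_samples = 60) {
  synthetic_spec(
    n_wavelengths = 200,
    wavelength_range = c(1000, 2500),
    components = list(
      list( # target, water-like
        list(center = 1450, sigma = 35, amplitude = 1.0),
        list(center = 1940, sigma = 45, amplitude = 1.2)
      ),
      list( # interferent 1
        list(center = 1210, sigma = 30, amplitude = 0.5),
        list(center = 1695, sigma = 35, amplitude = 0.6),
        list(center = 2270, sigma = 40, amplitude = 0.45)
      ),
      list( # interferent 2 / filler solvent
        list(center = 1130, sigma = 30, amplitude = 0.4),
        list(center = 1730, sigma = 35, amplitude = 0.5),
        list(center = 2150, sigma = 45, amplitude = 0.5)
      )
    ),
    target = 1,
    conc_ranges = list(c(0.02, 0.12), c(0.01, 0.11), c(0, 1)),
    closure = TRUE,
    noise_sd = noise_sd,
    n_samples = n_samples,
    seed = seed
  )
}

# Pure-component spectra matrix (components x wavelengths).
pure_spectra <- function(spec) {
  S <- matrix(0, length(spec$components), spec$n_wavelengths)
  for (c_i in seq_along(spec$components)) {
    for (pk in spec$components[[c_i]]) {
      S[c_i, ] <- S[c_i, ] +
        pk$amplitude * exp(-(spec$wavelengths - pk$center)^2 / (2 * pk$sigma^2))
    }
  }
  S
}

#' Generate a synthetic spectral dataset
#'
#' Draws concentrations uniformly within their ranges (last component as the
#' closure remainder when enabled), builds `X = C S + baseline + noise` with
#' Gaussian-band pure spectra `S`, and returns the target concentration as
#' the reference. Roles are left unassigned; use [ks_assign()].
#'
#' @param spec A `synthetic_spec`.
#' @return A `spectra_dataset` of `n_samples * replicates` rows.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  S <- pure_spectra(spec)
  nc <- length(spec$components)
  with_local_seed(spec$seed, {
    free <- if (spec$closure) seq_len(nc - 1) else seq_len(nc)
    C <- matrix(0, spec$n_samples, nc)
    for (c_i in free) {
      r <- spec$conc_ranges[[c_i]]
      C[, c_i] <- stats::runif(spec$n_samples, r[1], r[2])
    }
    if (spec$closure) {
      C[, nc] <- 1 - rowSums(C[, free, drop = FALSE])
      if (any(C[, nc] < 0)) stop("closure infeasible: free ranges exceed total")
    }
    reps <- spec$replicates
    m <- spec$n_samples * reps
    Crep <- C[rep(seq_len(spec$n_samples), each = reps), , drop = FALSE]
    X <- Crep %*% S
    span <- (spec$wavelengths - spec$wavelengths[1]) /
      diff(range(spec$wavelengths))
    offset <- stats::rnorm(m, 0, spec$baseline_offset_sd)
    slope <- stats::rnorm(m, 0, spec$baseline_slope_sd)
    X <- X + outer(offset, rep(1, spec$n_wavelengths)) + outer(slope, span)
    X <- X + matrix(stats::rnorm(m * spec$n_wavelengths, 0, spec$noise_sd),
                    m, spec$n_wavelengths)
    ids <- paste0(rep(seq_len(spec$n_samples), each = reps), ".",
                  rep(seq_len(reps), times = spec$n_samples))
    spectra_dataset(X, spec$wavelengths, Crep[, spec$target],
                    sample_ids = ids)
  })
}

#' Precision and recall of a selection against the ground-truth mask
#'
#' Scores a selector's output on synthetic data: precision is the fraction of
#' selected wavelengths lying inside the informative mask, recall the
#' fraction of informative wavelengths captured.
#'
#' @param result A `selection_result`.
#' @param spec The `synthetic_spec` that generated the data.
#' @return A one-row tibble: `n_selected`, `n_informative`, `precision`,
#'   `recall`.
#' @export
recovery_score <- function(result, spec) {
  stopifnot(inherits(result, "selection_result"),
            inherits(spec, "synthetic_spec"))
  if (length(result$wavelengths) != spec$n_wavelengths) {
    stop("result and spec wavelength axes differ")
  }
  if (length(result$selected) == 0) stop("empty selection")
  informative <- which(spec$informative_mask)
  hit <- intersect(result$selected, informative)
  tibble::tibble(
    n_selected = length(result$selected),
    n_informative = length(informative),
    precision = length(hit) / length(result$selected),
    recall = length(hit) / length(informative)
  )
}
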