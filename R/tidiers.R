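#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a selection result into one row per wavelength
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return A tibble with `index`, `wavelength`, `rank` (position in the
#'   method's ranking), `selected`, and `nmi` when the method computed a
#'   profile.
#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) {
  n <- length(x$wavelengths)
  out <- tibble::tibble(
    index = seq_len(n),
    wavelength = x$wavelengths,
    rank = match(seq_len(n), x$ranked_order),
    selected = seq_len(n) %in% x$selected
  )
  if (!is.null(x$nmi_profile)) out$nmi <- x$nmi_profile$nmi
  out
}

#' One-row summary of a selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return The metrics row augmented with `method` and (for B-NMI)
#'   `chosen_bin_count`.
#' @method glance selection_result
#' @export
glance.selection_result <- function(x, ...) {
  dplyr::mutate(x$metrics,
    method = x$method,
    chosen_bin_count = x$chosen_bin_count,
    .before = 1
  )
}

#' Tidy PLS coefficients
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return A tibble with `term` (variable position) and `estimate` (the
#'   regression coefficient in centered variable space).
#' @method tidy pls_model
#' @export
tidy.pls_model <- function(x, ...) {
  tibble::tibble(term = seq_along(x$beta), estimate = x$beta)
}

#' One-row summary of a PLS model
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return A tibble with `n_vars` and `n_lv`.
#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(n_vars = length(x$beta), n_lv = x$n_lv)
}
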