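#' Plot the NMI relevance profile of a selection
#'
#' Mean calibration spectrum (line, left axis feel) over the per-wavelength
#' NMI bars, with selected wavelengths highlighted — the standard visual for
#' an information-based wavelength ranking.
#'
#' @param result A `selection_result` carrying an NMI profile.
#' @return A ggplot object.
#' @export
plot_nmi_profile <- function(result) {
  if (is.null(result$nmi_profile)) {
    stop("this result carries no NMI profile (method: ", result$method, ")")
  }
  d <- tidy(result)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wavelength, y = .data$nmi)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$selected), width = diff(range(d$wavelength)) / nrow(d)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "steelblue")) +
    ggplot2::labs(x = "wavelength (nm)", y = "NMI",
                  title = paste0(result$method, " relevance profile")) +
    ggplot2::theme_minimal()
}

#' Plot a forward-accumulation RMSEP curve
#'
#' Prediction error as wavelengths are added in ranking order; the selected
#' prefix size is marked. The characteristic shape falls steeply while
#' informative wavelengths enter, then climbs as noise channels are added.
#'
#' @param result A `selection_result` with an accumulation curve.
#' @return A ggplot object.
#' @export
plot_rmsep_curve <- function(result) {
  if (is.null(result$rmsep_curve)) {
    stop("this result carries no accumulation curve (method: ",
         result$method, ")")
  }
  ggplot2::ggplot(result$rmsep_curve,
                  ggplot2::aes(x = .data$k, y = .data$rmsep)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_vline(xintercept = length(result$selected),
                        linetype = "dashed", color = "firebrick") +
    ggplot2::labs(x = "number of accumulated wavelengths", y = "RMSEP",
                  title = paste0(result$method, " forward accumulation")) +
    ggplot2::theme_minimal()
}

#' @method autoplot selection_result
#' @export
autoplot.selection_result <- function(object, ...) {
  if (!is.null(object$nmi_profile)) plot_nmi_profile(object)
  else if (!is.null(object$rmsep_curve)) plot_rmsep_curve(object)
  else {
    d <- tidy(object)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$wavelength,
                                    y = as.integer(.data$selected))) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "wavelength (nm)", y = "selected",
                    title = paste0(object$method, " selected wavelengths")) +
      ggplot2::theme_minimal()
  }
}

#' @method autoplot cv_curve
#' @export
autoplot.cv_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_lv, y = .data$rmsecv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "latent variables", y = "RMSECV") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
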