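# Diagnostic figures: flow curves, master-curve collapse, fit overlays.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot viscosity sweeps
#'
#' Log-log flow curves colored by temperature, faceted by drug fraction
#' when several are present.
#'
#' @param curves Measurement tibble (columns `rate`, `viscosity`,
#'   `temperature_C`; optional `drug_fraction`).
#' @return A ggplot object.
#' @export
plot_viscosity_curves <- function(curves) {
  check_curve_df(curves)
  gg <- ggplot2::ggplot(curves,
                        ggplot2::aes(.data$rate, .data$viscosity,
                                     colour = factor(.data$temperature_C))) +
    ggplot2::geom_point(size = 0.9, alpha = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rate (1/s or rad/s)", y = "viscosity (Pa s)",
                  colour = "T (degC)") +
    ggplot2::theme_bw()
  if ("drug_fraction" %in% names(curves) &&
      length(unique(curves$drug_fraction)) > 1)
    gg <- gg + ggplot2::facet_wrap(~drug_fraction, labeller = "label_both")
  gg
}

#' Plot a master curve
#'
#' Reduced viscosity against reduced rate on log-log axes, colored by the
#' source temperature; a tight single curve indicates a successful
#' time-temperature superposition.
#'
#' @param object A `master_curve` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.master_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$reduced_rate, .data$reduced_viscosity,
                               colour = factor(.data$source_temperature_C))) +
    ggplot2::geom_point(size = 0.9, alpha = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "reduced rate (1/s)",
                  y = "reduced viscosity (Pa s)",
                  colour = "T (degC)",
                  title = sprintf("Master curve at Tref = %g degC",
                                  attr(object, "tref_C"))) +
    ggplot2::theme_bw()
}

#' Plot a Carreau--Arrhenius fit over its master curve
#'
#' Overlays the fitted reference-temperature Carreau curve (line) on the
#' reduced data (points).
#'
#' @param object A `carreau_arrhenius_fit` object.
#' @param curves The measurement tibble the fit was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.carreau_arrhenius_fit <- function(object, curves, ...) {
  check_curve_df(curves)
  shifts <- tibble::tibble(
    temperature_C = sort(unique(curves$temperature_C)),
    shift_factor = arrhenius_shift(object$params$arrhenius,
                                   sort(unique(curves$temperature_C))))
  mc <- build_master_curve(curves, object$tref_C, shifts = shifts)
  rr <- 10^seq(log10(min(mc$reduced_rate)), log10(max(mc$reduced_rate)),
               length.out = 200)
  model <- tibble::tibble(reduced_rate = rr,
                          reduced_viscosity = carreau_viscosity(
                            object$params$carreau, rr))
  autoplot(mc) +
    ggplot2::geom_line(data = model,
                       ggplot2::aes(.data$reduced_rate,
                                    .data$reduced_viscosity),
                       inherit.aes = FALSE, linewidth = 0.6)
}
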