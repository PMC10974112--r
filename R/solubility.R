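# Phase coupling: a user-supplied temperature-solubility table drives the
# split between dissolved (plasticizing) and suspended (filler) drug.

#' Tabulated drug-in-polymer solubility curve
#'
#' Wraps a table of (temperature, solubility weight fraction) pairs with a
#' monotone piecewise-linear interpolation contract. Temperatures must be
#' strictly increasing and the solubility non-decreasing with temperature,
#' as for a dissolution phase boundary. The curve is an input (typically a
#' literature phase diagram), never a fitted object.
#'
#' @param df Data frame with columns `temperature_C` and `ws_fraction`.
#' @return An object of class `solubility_curve` (a tibble with the two
#'   columns, validated and ordered).
#' @examples
#' solubility_curve(data.frame(temperature_C = c(130, 160, 200),
#'                             ws_fraction  = c(0.05, 0.15, 0.35)))
#' @export
solubility_curve <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("temperature_C", "ws_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("solubility table missing column(s): ", paste(miss, collapse = ", "))
  tbl <- tibble::as_tibble(df)[need]
  if (nrow(tbl) < 2) stop("solubility table needs at least 2 rows")
  if (any(!is.finite(tbl$temperature_C)) || any(!is.finite(tbl$ws_fraction)))
    stop("solubility table contains non-finite values")
  if (is.unsorted(tbl$temperature_C, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  if (any(tbl$ws_fraction < 0 | tbl$ws_fraction > 1))
    stop("`ws_fraction` must lie in [0, 1]")
  if (is.unsorted(tbl$ws_fraction))
    stop("`ws_fraction` must be non-decreasing with temperature")
  class(tbl) <- c("solubility_curve", class(tbl))
  tbl
}

#' Interpolate solubility at a temperature
#'
#' Monotone piecewise-linear interpolation of the tabulated solubility.
#' Extrapolation beyond the tabulated temperature range is refused because
#' phase boundaries are strongly nonlinear near the glass transition.
#'
#' @param curve A [solubility_curve()] object.
#' @param T_C Temperature, degC, vectorized; must lie within the table range.
#' @return Solubility weight fraction(s) `w_s`.
#' @examples
#' sc <- solubility_curve(data.frame(temperature_C = c(130, 200),
#'                                   ws_fraction  = c(0.1, 0.3)))
#' solubility_at(sc, 165)
#' @export
solubility_at <- function(curve, T_C) {
  stopifnot(inherits(curve, "solubility_curve"), is.numeric(T_C))
  rng <- range(curve$temperature_C)
  out_of_range <- T_C < rng[1] | T_C > rng[2]
  if (any(out_of_range))
    stop(sprintf(
      "temperature(s) %s degC outside the tabulated solubility range [%g, %g] degC; extrapolation is refused",
      paste(T_C[out_of_range], collapse = ", "), rng[1], rng[2]))
  stats::approx(curve$temperature_C, curve$ws_fraction, xout = T_C,
                method = "linear", ties = "ordered")$y
}

#' Predict two-phase melt viscosity from a phase diagram
#'
#' Couples the tabulated solubility curve to the global viscosity model:
#' at temperature T the dissolved fraction is `min(w_s(T), w_drug)` and the
#' remainder is suspended filler, so the drug shift factor follows the
#' two-phase form. The prediction is continuous in temperature across the
#' full-dissolution boundary where `w_s(T) = w_drug`.
#'
#' @param p A [carreau_arrhenius_params()] object for the pure polymer.
#' @param d A [drug_shift_params()] object (finite `s_filler`).
#' @param curve A [solubility_curve()] object.
#' @param w_drug Total drug weight fraction in \[0, 1\].
#' @param shear_rate Shear rate, 1/s, vectorized.
#' @param T_C Temperature, degC (scalar or same length as `shear_rate`).
#' @return Viscosity in Pa·s.
#' @examples
#' p <- reference_polymer_params("SOL")
#' d <- drug_shift_params(-4, 4)
#' sc <- solubility_curve(data.frame(temperature_C = c(130, 200),
#'                                   ws_fraction  = c(0.05, 0.4)))
#' predict_two_phase_viscosity(p, d, sc, w_drug = 0.3,
#'                             shear_rate = 6.28, T_C = 170)
#' @export
predict_two_phase_viscosity <- function(p, d, curve, w_drug, shear_rate, T_C) {
  w_s <- solubility_at(curve, T_C)
  global_viscosity(p, d, shear_rate, T_C, w_drug, w_s = pmin(w_s, w_drug))
}
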