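# Drug shift factors from data: the zero-shear viscosity ratio, the
# plasticizing/filler slope regression, temperature-resolved shift-factor
# estimation, and the solubility extraction that inverts the two-phase model.

#' Drug shift factor from zero-shear viscosities
#'
#' Ratio of a mixture's zero-shear-rate viscosity to the pure-polymer
#' reference: `a_drug = eta0(w_drug) / eta0(0)`. Below 1 indicates a
#' plasticizing drug, above 1 a filler effect.
#'
#' @param eta0_mix Zero-shear viscosity of the mixture, Pa·s, > 0 (vectorized).
#' @param eta0_ref Zero-shear viscosity of the pure polymer, Pa·s, > 0.
#' @return Dimensionless shift factor(s).
#' @examples
#' drug_shift_factor(500, 1000)
#' @export
drug_shift_factor <- function(eta0_mix, eta0_ref) {
  if (any(eta0_mix <= 0) || any(eta0_ref <= 0))
    stop("zero-shear viscosities must be positive")
  eta0_mix / eta0_ref
}

#' Fit the drug-shift slope on weight fraction
#'
#' Through-origin least squares of `ln a_drug` on drug weight fraction.
#' The regression is forced through the origin because the shift factor is
#' 1 at w = 0 by construction of the reference. Observations flagged as
#' opaque (suspected suspended drug, i.e. two-phase specimens) are excluded
#' and counted, since they do not follow the single-phase plasticizing line.
#' The same routine fits a filler slope from an insoluble-additive series,
#' where the slope comes out positive.
#'
#' @param obs Data frame with columns `w_drug` and `a_drug`; optional
#'   logical `opaque_flag`.
#' @return A one-row tibble with `slope`, `std_error`, `n_used`,
#'   `n_excluded`, `residual_rms` (on the `ln a` scale).
#' @examples
#' fit_shift_slope(data.frame(w_drug = c(0, 0.1, 0.2),
#'                            a_drug = exp(-5 * c(0, 0.1, 0.2))))
#' @export
fit_shift_slope <- function(obs) {
  stopifnot(is.data.frame(obs))
  miss <- setdiff(c("w_drug", "a_drug"), names(obs))
  if (length(miss) > 0)
    stop("shift observations missing column(s): ", paste(miss, collapse = ", "))
  if (any(obs$a_drug <= 0)) stop("`a_drug` must be positive")
  if (any(obs$w_drug < 0 | obs$w_drug > 1)) stop("`w_drug` must lie in [0, 1]")
  n_total <- nrow(obs)
  if (!"opaque_flag" %in% names(obs)) obs$opaque_flag <- FALSE
  kept <- obs[!obs$opaque_flag, , drop = FALSE]
  n_excluded <- n_total - nrow(kept)
  if (nrow(kept) == 0)
    stop("all observations are flagged opaque; no single-phase data to fit")
  if (all(kept$w_drug == 0))
    stop("all usable observations are at w = 0; the slope is unidentifiable")
  fit <- stats::lm(log(a_drug) ~ 0 + w_drug, data = kept)
  # summary.lm warns on exact (zero-residual) data; that case is legitimate
  # here (noise-free generators) and its se of 0 is correct
  sm <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  tibble::tibble(slope = unname(sm[1, 1]),
                 std_error = unname(sm[1, 2]),
                 n_used = nrow(kept),
                 n_excluded = n_excluded,
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)))
}

#' Solubility from a temperature-specific drug shift factor
#'
#' Inverts the two-phase shift factor: given the observed `ln a_drug` at
#' total fraction `w_drug`, the dissolved fraction solves
#' `ln a = w_s * s_plast + (w_drug - w_s) * s_filler`, i.e.
#' \deqn{w_s = (\ln a - w_{drug} s_{filler}) / (s_{plast} - s_{filler}).}
#' Geometrically this is the intersection of the plasticizing line with the
#' filler line translated through the observed shift factor. Results outside
#' \[0, w_drug\] are clamped with a warning.
#'
#' @param a_T Observed drug shift factor(s) at the temperature of interest,
#'   > 0 (vectorized).
#' @param d A [drug_shift_params()] object with `s_plast != s_filler`.
#' @param w_drug Total drug weight fraction.
#' @return Dissolved fraction(s) `w_s` in \[0, w_drug\].
#' @examples
#' d <- drug_shift_params(s_plast = -5, s_filler = 4)
#' a <- drug_shift_two_phase(d, w_drug = 0.3, w_s = 0.12)
#' solubility_from_shift(a, d, w_drug = 0.3)
#' @export
solubility_from_shift <- function(a_T, d, w_drug) {
  stopifnot(inherits(d, "drug_shift_params"))
  if (any(a_T <= 0)) stop("`a_T` must be positive")
  if (!is.finite(d$s_filler) || d$s_plast == d$s_filler)
    stop("degenerate geometry: `s_plast` and `s_filler` must be distinct ",
         "and finite to locate the intersection")
  w_s <- (log(a_T) - w_drug * d$s_filler) / (d$s_plast - d$s_filler)
  out <- w_s < -1e-10 | w_s > w_drug + 1e-10
  if (any(out))
    warning(sum(out), " shift factor(s) imply a dissolved fraction outside ",
            "[0, w_drug]; clamped")
  pmin(pmax(w_s, 0), w_drug)
}

# model-curve interpolation table for the pure polymer at Tref
model_ref_table <- function(p, lr_range = c(-5, 7), step = 0.02) {
  lr <- seq(lr_range[1], lr_range[2], by = step)
  data.frame(lr = lr, x = log10(carreau_viscosity(p$carreau, 10^lr)))
}

#' Temperature-resolved drug shift factors for a mixture
#'
#' For each (drug fraction, temperature) group of mixture sweeps, estimates
#' the total shift factor that superposes the group onto the fitted
#' pure-polymer flow curve at the reference temperature (constant-stress
#' shifting, least squares in log-log space), then divides out the
#' pure-polymer Arrhenius factor to isolate the drug contribution:
#' `a_drug(w, T) = a_total / a_T(T)`.
#'
#' @param curves Data frame of mixture measurement rows (columns
#'   `temperature_C`, `drug_fraction`, `rate`, `viscosity`; optional
#'   `opaque_flag`).
#' @param polymer_fit A `carreau_arrhenius_fit` of the pure polymer (or a
#'   [carreau_arrhenius_params()] object).
#' @return A tibble with columns `drug_fraction`, `temperature_C`,
#'   `a_drug`, `opaque_flag`.
#' @examples
#' des <- sweep_design(replicates = 1, noise_sigma = 0,
#'                     temperatures = c(150, 160, 170))
#' p <- reference_polymer_params("SOL")
#' mix <- simulate_mixture_series(des, p, drug_shift_params(-4),
#'                                drug_fractions = c(0.1, 0.2))
#' estimate_drug_shift_factors(mix, p)
#' @export
estimate_drug_shift_factors <- function(curves, polymer_fit) {
  check_curve_df(curves)
  if (!"drug_fraction" %in% names(curves))
    stop("curves need a `drug_fraction` column")
  p <- if (inherits(polymer_fit, "carreau_arrhenius_fit")) polymer_fit$params
       else polymer_fit
  stopifnot(inherits(p, "carreau_arrhenius_params"))
  tab_ref <- model_ref_table(p)
  df <- tibble::as_tibble(curves)
  if (!"opaque_flag" %in% names(df)) df$opaque_flag <- FALSE
  df |>
    dplyr::group_by(.data$drug_fraction, .data$temperature_C) |>
    dplyr::group_modify(function(g, key) {
      a_tot <- fit_one_shift(tab_ref, g, key$temperature_C)
      aT <- arrhenius_shift(p$arrhenius, key$temperature_C)
      tibble::tibble(a_drug = a_tot / aT, opaque_flag = any(g$opaque_flag))
    }) |>
    dplyr::ungroup()
}

#' Extract the solubility line from temperature-resolved shift factors
#'
#' The full rheology-to-solubility chain for a two-phase drug/polymer melt:
#' estimate the drug shift factor of the mixture at each temperature (via
#' [estimate_drug_shift_factors()]), then invert the two-phase shift model
#' with known plasticizing and filler slopes ([solubility_from_shift()]) to
#' obtain the dissolved fraction `w_s(T)`.
#'
#' @param curves Mixture measurement rows at a single drug fraction.
#' @param polymer_fit Pure-polymer fit or parameter object.
#' @param d A [drug_shift_params()] object with both slopes finite.
#' @return A tibble with columns `temperature_C`, `a_drug`, `w_s`.
#' @export
estimate_solubility <- function(curves, polymer_fit, d) {
  if (!"drug_fraction" %in% names(curves))
    stop("curves need a `drug_fraction` column")
  w <- unique(curves$drug_fraction)
  if (length(w) != 1)
    stop("solubility extraction expects a single drug fraction; got ",
         paste(w, collapse = ", "))
  shifts <- estimate_drug_shift_factors(curves, polymer_fit)
  tibble::tibble(temperature_C = shifts$temperature_C,
                 a_drug = shifts$a_drug,
                 w_s = solubility_from_shift(shifts$a_drug, d, w))
}
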