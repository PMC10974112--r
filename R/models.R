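# Closed-form forward evaluations of the viscosity model family:
# Carreau shear thinning, Arrhenius temperature shift, log-linear mixing,
# drug shift factors (single- and two-phase), and the global model.

# ideal gas constant, J/(mol.K)
GAS_CONSTANT <- 8.314

celsius_to_kelvin <- function(T_C) {
  if (any(T_C <= -273.15)) stop("temperature at or below absolute zero: ",
                                paste(T_C[T_C <= -273.15], collapse = ", "), " degC")
  T_C + 273.15
}

#' Carreau shear-thinning viscosity
#'
#' Evaluates the Carreau model
#' \deqn{\eta(\dot\gamma) = \eta_0 / (1 + \dot\gamma/\dot\gamma_c)^{c}}
#' giving the Newtonian plateau `eta0` at vanishing shear rate and a
#' power-law branch of log-log slope `-c` at high rates.
#'
#' @param p A [carreau_params()] object.
#' @param shear_rate Shear rate (or angular frequency under Cox--Merz),
#'   1/s, vectorized, each >= 0.
#' @return Viscosity in Pa·s, same length as `shear_rate`.
#' @examples
#' p <- carreau_params(1000, 10, 0.5)
#' carreau_viscosity(p, c(0, 10, 1000))
#' @export
carreau_viscosity <- function(p, shear_rate) {
  stopifnot(inherits(p, "carreau_params"), is.numeric(shear_rate))
  if (any(shear_rate < 0)) stop("`shear_rate` must be non-negative")
  p$eta0 / (1 + shear_rate / p$gamma_c)^p$c
}

#' Arrhenius temperature shift factor
#'
#' Time-temperature superposition shift factor
#' \deqn{a_T(T, T_{ref}) = \exp[(E_A/R)(1/T_K - 1/T_{ref,K})]}
#' with temperatures converted from Celsius to Kelvin internally. Equals 1
#' at the reference temperature and decreases with temperature for EA > 0.
#'
#' @param a An [arrhenius_params()] object.
#' @param T_C Temperature, degrees Celsius, vectorized.
#' @return Dimensionless shift factor(s).
#' @examples
#' a <- arrhenius_params(122498, 160)
#' arrhenius_shift(a, c(130, 160, 200))
#' @export
arrhenius_shift <- function(a, T_C) {
  stopifnot(inherits(a, "arrhenius_params"), is.numeric(T_C))
  TK <- celsius_to_kelvin(T_C)
  Tref_K <- celsius_to_kelvin(a$Tref_C)
  exp(a$EA / GAS_CONSTANT * (1 / TK - 1 / Tref_K))
}

#' Carreau--Arrhenius viscosity
#'
#' Combined shear-rate and temperature dependence:
#' \deqn{\eta(\dot\gamma, T) = \eta_0 a_T / (1 + a_T \dot\gamma/\dot\gamma_c)^{c}}
#' The shift factor rescales the effective shear rate, so curves at all
#' temperatures collapse to the reference-temperature Carreau curve.
#'
#' @param p A [carreau_arrhenius_params()] object.
#' @param shear_rate Shear rate, 1/s, >= 0, vectorized.
#' @param T_C Temperature, degC (scalar or same length as `shear_rate`).
#' @return Viscosity in Pa·s.
#' @examples
#' p <- reference_polymer_params("bBMA")
#' carreau_arrhenius_viscosity(p, shear_rate = c(1, 10, 100), T_C = 190)
#' @export
carreau_arrhenius_viscosity <- function(p, shear_rate, T_C) {
  stopifnot(inherits(p, "carreau_arrhenius_params"))
  if (any(shear_rate < 0)) stop("`shear_rate` must be non-negative")
  aT <- arrhenius_shift(p$arrhenius, T_C)
  pc <- p$carreau
  pc$eta0 * aT / (1 + aT * shear_rate / pc$gamma_c)^pc$c
}

#' Log-linear liquid--liquid mixing rule
#'
#' Viscosity of a miscible drug/polymer mixture from the pure-component
#' viscosities: \eqn{\ln \eta_{mix} = w_{drug} \ln \eta_{drug} +
#' (1 - w_{drug}) \ln \eta_{polymer}}. The result is bounded between the
#' two pure viscosities.
#'
#' @param w_drug Drug weight fraction in \[0, 1\], vectorized.
#' @param eta_drug,eta_polymer Pure-component viscosities, Pa·s, > 0.
#' @return Mixture viscosity, Pa·s.
#' @examples
#' mixing_rule_viscosity(0.5, eta_drug = 1, eta_polymer = 100)
#' @export
mixing_rule_viscosity <- function(w_drug, eta_drug, eta_polymer) {
  if (any(w_drug < 0 | w_drug > 1)) stop("`w_drug` must lie in [0, 1]")
  if (any(eta_drug <= 0) || any(eta_polymer <= 0))
    stop("pure-component viscosities must be positive")
  exp(w_drug * log(eta_drug) + (1 - w_drug) * log(eta_polymer))
}

#' Single-phase drug shift factor
#'
#' For a fully dissolved drug the shift factor is
#' \eqn{a_{drug}(w) = \exp(w \, s_{plast})}: 1 at w = 0 and below 1 for a
#' plasticizer (`s_plast < 0`).
#'
#' @param d A [drug_shift_params()] object.
#' @param w_drug Drug weight fraction in \[0, 1\], vectorized.
#' @return Dimensionless shift factor(s).
#' @examples
#' drug_shift_single_phase(drug_shift_params(-5), w_drug = c(0, 0.2))
#' @export
drug_shift_single_phase <- function(d, w_drug) {
  stopifnot(inherits(d, "drug_shift_params"))
  if (any(w_drug < 0 | w_drug > 1)) stop("`w_drug` must lie in [0, 1]")
  exp(w_drug * d$s_plast)
}

#' Two-phase drug shift factor
#'
#' When the total drug fraction exceeds the dissolved limit `w_s`, the
#' dissolved part plasticizes and the suspended remainder acts as filler:
#' \deqn{a_{drug}(w, w_s) = \exp[w_s s_{plast} + (w - w_s) s_{filler}]}
#' `w_s` is clamped to `w_drug` (the dissolved fraction cannot exceed the
#' total), so the expression reduces to [drug_shift_single_phase()] when
#' `w_s >= w_drug` and to a pure filler term when `w_s = 0`.
#'
#' @param d A [drug_shift_params()] object with finite `s_filler`.
#' @param w_drug Total drug weight fraction in \[0, 1\].
#' @param w_s Dissolved-limit (solubility) weight fraction, >= 0.
#' @return Dimensionless shift factor(s).
#' @examples
#' d <- drug_shift_params(s_plast = -5, s_filler = 4)
#' drug_shift_two_phase(d, w_drug = 0.3, w_s = c(0, 0.1, 0.3))
#' @export
drug_shift_two_phase <- function(d, w_drug, w_s) {
  stopifnot(inherits(d, "drug_shift_params"))
  if (any(w_drug < 0 | w_drug > 1)) stop("`w_drug` must lie in [0, 1]")
  if (any(w_s < 0)) stop("`w_s` must be non-negative")
  if (any(w_s < w_drug) && !is.finite(d$s_filler))
    stop("`s_filler` must be finite for a two-phase (w_s < w_drug) evaluation")
  ws_eff <- pmin(w_s, w_drug)
  sf <- ifelse(w_drug > ws_eff, d$s_filler, 0)
  exp(ws_eff * d$s_plast + (w_drug - ws_eff) * sf)
}

#' Global melt-viscosity model
#'
#' Viscosity of a drug/polymer melt as a function of shear rate, temperature
#' and drug content:
#' \deqn{\eta = \eta_0 a_T a_{drug} /
#'   (1 + \dot\gamma a_T a_{drug} / \dot\gamma_c)^{c}}
#' The drug shift factor is the single-phase form when `w_s` is `NULL`
#' (fully dissolved) and the two-phase form otherwise. At `w_drug = 0` the
#' model reduces to [carreau_arrhenius_viscosity()].
#'
#' @param p A [carreau_arrhenius_params()] object.
#' @param d A [drug_shift_params()] object.
#' @param shear_rate Shear rate, 1/s, >= 0, vectorized.
#' @param T_C Temperature, degC.
#' @param w_drug Total drug weight fraction in \[0, 1\].
#' @param w_s Optional dissolved-limit fraction; `NULL` means fully dissolved.
#' @return Viscosity in Pa·s.
#' @examples
#' p <- reference_polymer_params("SOL")
#' d <- drug_shift_params(-4, 4)
#' global_viscosity(p, d, shear_rate = 6.28, T_C = 160, w_drug = 0.2)
#' @export
global_viscosity <- function(p, d, shear_rate, T_C, w_drug, w_s = NULL) {
  stopifnot(inherits(p, "carreau_arrhenius_params"),
            inherits(d, "drug_shift_params"))
  if (any(shear_rate < 0)) stop("`shear_rate` must be non-negative")
  aT <- arrhenius_shift(p$arrhenius, T_C)
  a_drug <- if (is.null(w_s)) drug_shift_single_phase(d, w_drug)
            else drug_shift_two_phase(d, w_drug, w_s)
  pc <- p$carreau
  a <- aT * a_drug
  pc$eta0 * a / (1 + shear_rate * a / pc$gamma_c)^pc$c
}
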