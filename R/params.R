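#' Carreau shear-thinning parameters
#'
#' Bundles the three Carreau parameters of a polymer melt: the zero-shear-rate
#' viscosity plateau `eta0` (Pa·s), the critical shear rate `gamma_c` (1/s) at
#' which shear thinning sets in, and the flow index `c`, the negative log-log
#' slope of the shear-thinning branch.
#'
#' @param eta0 Zero-shear-rate viscosity, Pa·s. Must be > 0.
#' @param gamma_c Critical shear rate, 1/s. Must be > 0.
#' @param c Flow index, dimensionless, in (0, 1).
#' @return An object of class `carreau_params`.
#' @examples
#' carreau_params(eta0 = 1011, gamma_c = 26.8, c = 0.433)
#' @export
carreau_params <- function(eta0, gamma_c, c) {
  stopifnot(is.numeric(eta0), length(eta0) == 1L, is.finite(eta0),
            is.numeric(gamma_c), length(gamma_c) == 1L, is.finite(gamma_c),
            is.numeric(c), length(c) == 1L, is.finite(c))
  if (eta0 <= 0) stop("`eta0` must be positive (Pa·s), got ", eta0)
  if (gamma_c <= 0) stop("`gamma_c` must be positive (1/s), got ", gamma_c)
  if (c <= 0 || c >= 1) stop("flow index `c` must lie in (0, 1), got ", c)
  structure(list(eta0 = eta0, gamma_c = gamma_c, c = c),
            class = "carreau_params")
}

#' Arrhenius temperature-shift parameters
#'
#' Activation energy and reference temperature for the Arrhenius
#' time-temperature superposition shift factor. Temperatures are given in
#' degrees Celsius at every interface and converted to Kelvin internally.
#' `EA` enters only in the ratio `EA / R` with the ideal gas constant
#' R = 8.314 J/(mol·K); it is treated numerically as J/mol.
#'
#' @param EA Activation energy, J/mol. Must be > 0.
#' @param Tref_C Reference temperature, degrees Celsius, in \[20, 300\].
#' @return An object of class `arrhenius_params`.
#' @examples
#' arrhenius_params(EA = 122498, Tref_C = 160)
#' @export
arrhenius_params <- function(EA, Tref_C) {
  stopifnot(is.numeric(EA), length(EA) == 1L, is.finite(EA),
            is.numeric(Tref_C), length(Tref_C) == 1L, is.finite(Tref_C))
  if (EA <= 0) stop("`EA` must be positive, got ", EA)
  if (Tref_C < 20 || Tref_C > 300)
    stop("`Tref_C` outside the physically sensible range [20, 300] degC: ", Tref_C)
  structure(list(EA = EA, Tref_C = Tref_C), class = "arrhenius_params")
}

#' Combined Carreau--Arrhenius parameter set
#'
#' One material system: Carreau parameters at the reference temperature plus
#' Arrhenius activation energy for time-temperature superposition.
#'
#' @param eta0,gamma_c,c Carreau parameters; see [carreau_params()].
#' @param EA,Tref_C Arrhenius parameters; see [arrhenius_params()].
#' @return An object of class `carreau_arrhenius_params` with elements
#'   `carreau` and `arrhenius`.
#' @examples
#' carreau_arrhenius_params(1011, 26.8, 0.433, EA = 122498, Tref_C = 160)
#' @export
carreau_arrhenius_params <- function(eta0, gamma_c, c, EA, Tref_C = 160) {
  structure(list(carreau = carreau_params(eta0, gamma_c, c),
                 arrhenius = arrhenius_params(EA, Tref_C)),
            class = "carreau_arrhenius_params")
}

#' @export
print.carreau_arrhenius_params <- function(x, ...) {
  cat("Carreau-Arrhenius parameters (Tref =", x$arrhenius$Tref_C, "degC)\n")
  cat(sprintf("  eta0    = %g Pa.s\n", x$carreau$eta0))
  cat(sprintf("  gamma_c = %g 1/s\n", x$carreau$gamma_c))
  cat(sprintf("  c       = %g\n", x$carreau$c))
  cat(sprintf("  EA      = %g J/mol\n", x$arrhenius$EA))
  invisible(x)
}

#' Drug shift-factor parameters
#'
#' Slopes of the log drug shift factor on drug weight fraction. `s_plast`
#' describes the plasticizing effect of dissolved drug (negative for a
#' plasticizer), `s_filler` the viscosity increase from suspended solid
#' (positive). The reference fraction is fixed at w = 0 (pure polymer),
#' where the shift factor is 1 by construction.
#'
#' @param s_plast Plasticizing slope of `ln a_drug` per unit weight fraction.
#' @param s_filler Filler slope of `ln a_drug` per unit weight fraction.
#'   May be `NA` when only single-phase behavior is modeled.
#' @return An object of class `drug_shift_params` with `w_ref = 0`.
#' @examples
#' drug_shift_params(s_plast = -5.2, s_filler = 4.1)
#' @export
drug_shift_params <- function(s_plast, s_filler = NA_real_) {
  stopifnot(is.numeric(s_plast), length(s_plast) == 1L, is.finite(s_plast),
            is.numeric(s_filler), length(s_filler) == 1L)
  structure(list(s_plast = s_plast, s_filler = s_filler, w_ref = 0),
            class = "drug_shift_params")
}

#' @export
print.drug_shift_params <- function(x, ...) {
  cat("Drug shift parameters (w_ref = 0)\n")
  cat(sprintf("  s_plast  = %g\n", x$s_plast))
  cat(sprintf("  s_filler = %g\n", x$s_filler))
  invisible(x)
}

#' Reference Carreau--Arrhenius parameter sets for three pharmaceutical polymers
#'
#' Literature parameter sets (reference temperature 160 degC) for three
#' hot-melt-extrusion carrier polymers: a basic butylated methacrylate
#' copolymer (bBMA, Eudragit E PO), Soluplus (SOL), and copovidone
#' (PVPVA, Plasdone S-630). Useful as realistic generators for the
#' synthetic-data module and as fitting fixtures.
#'
#' @param system Optional polymer label (`"bBMA"`, `"SOL"`, `"PVPVA"`). When
#'   given, the single `carreau_arrhenius_params` object is returned; when
#'   `NULL` (default) a tibble of all three systems is returned.
#' @return A tibble with columns `system`, `eta0`, `gamma_c`, `c`, `EA`,
#'   `Tref_C`, or a single parameter object when `system` is given.
#' @examples
#' reference_polymer_params()
#' reference_polymer_params("bBMA")
#' @export
reference_polymer_params <- function(system = NULL) {
  tbl <- tibble::tibble(
    system  = c("bBMA", "SOL", "PVPVA"),
    eta0    = c(1011, 5146, 18296),
    gamma_c = c(26.8, 2.5, 1.0),
    c       = c(0.433, 0.363, 0.368),
    EA      = c(122498, 130846, 184119),
    Tref_C  = 160
  )
  if (is.null(system)) return(tbl)
  row <- tbl[tbl$system == system, ]
  if (nrow(row) != 1L)
    stop("unknown system '", system, "'; available: ",
         paste(tbl$system, collapse = ", "))
  carreau_arrhenius_params(row$eta0, row$gamma_c, row$c, row$EA, row$Tref_C)
}
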