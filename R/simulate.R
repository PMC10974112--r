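# Synthetic rheometry sweeps with the statistical structure the analysis
# assumes: log-spaced rates, multiplicative log-normal noise, triplicates.

with_seed_ <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(force(code))
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Rheometry sweep design
#'
#' Describes one simulated measurement campaign. The defaults mirror a
#' typical oscillatory protocol for pharmaceutical polymer melts: angular
#' frequencies 0.628--628 rad/s at 10 log-spaced points per decade,
#' temperatures 130--200 degC in 10 K steps, triplicate runs, and small
#' multiplicative log-normal noise. Rotational sweeps are truncated above
#' `rotational_cutoff` where plate--plate gap emptying makes measurements
#' unusable.
#'
#' @param rate_min,rate_max Sweep range, rad/s (oscillatory) or 1/s
#'   (rotational); `rate_min < rate_max`, both > 0.
#' @param points_per_decade Number of log-spaced rates per decade.
#' @param temperatures Melt temperatures, degC.
#' @param replicates Number of replicate sweeps per condition, >= 1.
#' @param noise_sigma Standard deviation of the additive noise on log
#'   viscosity (multiplicative on viscosity), >= 0.
#' @param seed Integer seed; generation is deterministic given the design.
#' @param mode `"oscillatory"` or `"rotational"`.
#' @param rotational_cutoff Maximum usable shear rate for rotational mode, 1/s.
#' @return An object of class `sweep_design`.
#' @examples
#' sweep_design(replicates = 3, noise_sigma = 0.02, seed = 7)
#' @export
sweep_design <- function(rate_min = 0.628, rate_max = 628,
                         points_per_decade = 10,
                         temperatures = seq(130, 200, by = 10),
                         replicates = 3, noise_sigma = 0.02, seed = 1,
                         mode = c("oscillatory", "rotational"),
                         rotational_cutoff = 10) {
  mode <- match.arg(mode)
  if (!(rate_min > 0 && rate_max > rate_min))
    stop("need 0 < rate_min < rate_max")
  if (points_per_decade < 1) stop("`points_per_decade` must be >= 1")
  if (length(temperatures) < 1 || any(!is.finite(temperatures)))
    stop("`temperatures` must be finite degC values")
  if (replicates < 1) stop("`replicates` must be >= 1")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  structure(list(rate_min = rate_min, rate_max = rate_max,
                 points_per_decade = points_per_decade,
                 temperatures = as.numeric(temperatures),
                 replicates = as.integer(replicates),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 mode = mode, rotational_cutoff = rotational_cutoff),
            class = "sweep_design")
}

design_rates <- function(design) {
  lo <- log10(design$rate_min); hi <- log10(design$rate_max)
  lg <- seq(lo, hi, by = 1 / design$points_per_decade)
  if (utils::tail(lg, 1) < hi - 1e-12) lg <- c(lg, hi)
  r <- 10^lg
  if (design$mode == "rotational") r <- r[r <= design$rotational_cutoff]
  r
}

simulate_block <- function(design, rates, eta_true, system, w_drug, opaque) {
  n <- length(rates)
  purrr::map_dfr(seq_len(design$replicates), function(rep_id) {
    eps <- if (design$noise_sigma > 0) stats::rnorm(n, 0, design$noise_sigma)
           else rep(0, n)
    tibble::tibble(
      system = system, mode = design$mode,
      temperature_C = NA_real_, drug_fraction = w_drug,
      replicate = rep_id, rate = rates,
      viscosity = eta_true * exp(eps), opaque_flag = opaque
    )
  })
}

#' Simulate pure-polymer viscosity sweeps
#'
#' Generates replicate sweeps at each design temperature from the
#' Carreau--Arrhenius model, with independent multiplicative log-normal
#' noise per point and replicate. Deterministic given the design seed.
#'
#' @param design A [sweep_design()] object.
#' @param p A [carreau_arrhenius_params()] object.
#' @param system Label for the material system.
#' @return A tibble of measurement rows with columns `system`, `mode`,
#'   `temperature_C`, `drug_fraction`, `replicate`, `rate`, `viscosity`,
#'   `opaque_flag`.
#' @examples
#' d <- sweep_design(replicates = 1, noise_sigma = 0, temperatures = c(160, 190))
#' simulate_pure_polymer(d, reference_polymer_params("bBMA"))
#' @export
simulate_pure_polymer <- function(design, p, system = "polymer") {
  stopifnot(inherits(design, "sweep_design"),
            inherits(p, "carreau_arrhenius_params"))
  rates <- design_rates(design)
  with_seed_(design$seed, {
    purrr::map_dfr(design$temperatures, function(T_C) {
      eta <- carreau_arrhenius_viscosity(p, rates, T_C)
      out <- simulate_block(design, rates, eta, system, 0, FALSE)
      out$temperature_C <- T_C
      out
    })
  })
}

#' Simulate a drug-load series of viscosity sweeps
#'
#' Generates sweeps for a series of drug weight fractions from the global
#' viscosity model. When a [solubility_curve()] is supplied, fractions above
#' the dissolved limit at a given temperature follow the two-phase shift
#' factor and the affected sweeps are marked `opaque_flag = TRUE`
#' (the visual signature of suspended drug); without a curve the drug is
#' treated as fully dissolved. With `drug_fractions = 0` the output is
#' identical to [simulate_pure_polymer()].
#'
#' @param design A [sweep_design()] object.
#' @param p A [carreau_arrhenius_params()] object for the pure polymer.
#' @param d A [drug_shift_params()] object.
#' @param curve Optional [solubility_curve()]; `NULL` means single-phase.
#' @param drug_fractions Numeric vector of drug weight fractions in \[0, 1\].
#' @param system Label for the material system.
#' @return A tibble with the same columns as [simulate_pure_polymer()].
#' @examples
#' des <- sweep_design(replicates = 1, noise_sigma = 0, temperatures = 160)
#' p <- reference_polymer_params("SOL")
#' simulate_mixture_series(des, p, drug_shift_params(-4),
#'                         drug_fractions = c(0, 0.2))
#' @export
simulate_mixture_series <- function(design, p, d, curve = NULL,
                                    drug_fractions = c(0, 0.1, 0.2, 0.3),
                                    system = "mixture") {
  stopifnot(inherits(design, "sweep_design"),
            inherits(p, "carreau_arrhenius_params"),
            inherits(d, "drug_shift_params"))
  if (any(drug_fractions < 0 | drug_fractions > 1))
    stop("`drug_fractions` must lie in [0, 1]")
  if (!is.null(curve)) stopifnot(inherits(curve, "solubility_curve"))
  rates <- design_rates(design)
  with_seed_(design$seed, {
    purrr::map_dfr(drug_fractions, function(w) {
      purrr::map_dfr(design$temperatures, function(T_C) {
        if (is.null(curve) || w == 0) {
          w_s <- NULL
          opaque <- FALSE
        } else {
          w_s <- solubility_at(curve, T_C)
          opaque <- w_s < w
        }
        eta <- global_viscosity(p, d, rates, T_C, w, w_s = w_s)
        out <- simulate_block(design, rates, eta, system, w, opaque)
        out$temperature_C <- T_C
        out
      })
    })
  })
}
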