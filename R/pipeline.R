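# End-to-end analysis: master curve -> Carreau-Arrhenius fit -> drug shift
# factors -> slope regression -> optional solubility extraction and
# two-phase prediction, with a human-readable report.

#' Pipeline configuration
#'
#' @param tref_C Reference temperature for superposition and fitting, degC.
#' @param alpha Significance level for zero-shear viscosity comparisons.
#' @param seed Integer seed used for the optimizer's jittered starts.
#' @param bounds Fit bounds, see [default_fit_bounds()].
#' @param rotational_cutoff Maximum trustworthy rotational rate, 1/s.
#' @param n_starts Optimizer starts per fit.
#' @return An object of class `run_config`.
#' @export
run_config <- function(tref_C = 160, alpha = 0.05, seed = 1,
                       bounds = default_fit_bounds(),
                       rotational_cutoff = 10, n_starts = 3) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  structure(list(tref_C = tref_C, alpha = alpha, seed = as.integer(seed),
                 bounds = bounds, rotational_cutoff = rotational_cutoff,
                 n_starts = n_starts),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full melt-viscosity analysis pipeline
#'
#' Executes, in order: master-curve construction and Carreau--Arrhenius
#' fitting on the pure-polymer sweeps (`drug_fraction == 0`);
#' temperature-resolved drug shift factors for every mixture fraction;
#' through-origin slope regression of `ln a_drug` on weight fraction
#' (plasticizing slope, opaque sweeps excluded); per-fraction zero-shear
#' viscosity comparisons against the pure polymer (when replicated); and,
#' when both drug-shift slopes are available, solubility extraction for
#' opaque fractions plus two-phase viscosity prediction when a
#' [solubility_curve()] is supplied.
#'
#' @param curves Measurement tibble (or path to a CSV readable by
#'   [read_curves()]) containing the pure polymer and optionally mixtures.
#' @param config A [run_config()] object.
#' @param drug_params Optional [drug_shift_params()] with a finite
#'   `s_filler` (for example fitted from an insoluble-additive series);
#'   required for the solubility and prediction stages. Its `s_plast` is
#'   replaced by the slope fitted here when mixtures are present.
#' @param solubility Optional [solubility_curve()] used for two-phase
#'   prediction at the mixture conditions.
#' @return An object of class `rheomelt_report`: a list with elements
#'   `config`, `master_curve`, `polymer_fit`, `shift_observations`,
#'   `plast_slope`, `comparisons`, `solubility`, `predictions`.
#' @export
run_pipeline <- function(curves, config = run_config(), drug_params = NULL,
                         solubility = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(curves))
    curves <- read_curves(curves, config$rotational_cutoff)
  check_curve_df(curves)
  df <- tibble::as_tibble(curves)
  if (!"drug_fraction" %in% names(df)) df$drug_fraction <- 0
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  pure <- df[df$drug_fraction == 0, , drop = FALSE]
  mix <- df[df$drug_fraction > 0, , drop = FALSE]
  if (nrow(pure) == 0)
    stop("pipeline needs pure-polymer sweeps (drug_fraction == 0) as reference")

  mc <- stage("mastercurve", build_master_curve(pure, config$tref_C))
  fit <- stage("fit", fit_carreau_arrhenius(pure, config$tref_C,
                                            config$bounds, config$n_starts,
                                            config$seed))

  shift_obs <- NULL; plast <- NULL; comparisons <- NULL
  sol <- NULL; preds <- NULL
  if (nrow(mix) > 0) {
    shift_obs <- stage("shift", estimate_drug_shift_factors(mix, fit))
    plast <- stage("slope", fit_shift_slope(
      dplyr::rename(shift_obs, w_drug = "drug_fraction")))
    if (fit$n_replicates >= 2) {
      comparisons <- stage("compare", purrr::map_dfr(
        sort(unique(mix$drug_fraction)), function(w) {
          sub <- mix[mix$drug_fraction == w, ]
          if (length(unique(sub$replicate)) < 2 ||
              length(unique(sub$temperature_C)) < 2)
            return(tibble::tibble())
          fw <- fit_carreau_arrhenius(sub, config$tref_C, config$bounds,
                                      config$n_starts, config$seed)
          dplyr::bind_cols(tibble::tibble(drug_fraction = w,
                                          eta0 = fw$params$carreau$eta0),
                           compare_zero_shear(fw, fit, config$alpha))
        }))
    }
    if (!is.null(drug_params) && is.finite(drug_params$s_filler)) {
      d_full <- drug_shift_params(plast$slope, drug_params$s_filler)
      opaque_w <- sort(unique(mix$drug_fraction[mix$opaque_flag %in% TRUE]))
      if (length(opaque_w) > 0) {
        sol <- stage("solubility", purrr::map_dfr(opaque_w, function(w) {
          dplyr::mutate(
            estimate_solubility(mix[mix$drug_fraction == w, ], fit, d_full),
            drug_fraction = w, .before = 1)
        }))
      }
      if (!is.null(solubility)) {
        conds <- dplyr::distinct(mix, .data$drug_fraction, .data$temperature_C)
        rates <- sort(unique(mix$rate))
        preds <- stage("predict", purrr::map_dfr(seq_len(nrow(conds)),
          function(i) {
            tibble::tibble(
              drug_fraction = conds$drug_fraction[i],
              temperature_C = conds$temperature_C[i],
              rate = rates,
              viscosity_pred = predict_two_phase_viscosity(
                fit$params, d_full, solubility, conds$drug_fraction[i],
                rates, conds$temperature_C[i]))
          }))
      }
    }
  }

  structure(list(config = config, master_curve = mc, polymer_fit = fit,
                 shift_observations = shift_obs, plast_slope = plast,
                 comparisons = comparisons, solubility = sol,
                 predictions = preds),
            class = "rheomelt_report")
}

#' @export
print.rheomelt_report <- function(x, ...) {
  cat("== rheomelt pipeline report ==\n")
  cat(sprintf("config: tref = %g degC, alpha = %g, seed = %d\n",
              x$config$tref_C, x$config$alpha, x$config$seed))
  cat("\n-- master curve --\n")
  print(glance(x$master_curve))
  cat("\n-- pure polymer Carreau-Arrhenius fit (mean +/- sd over replicates) --\n")
  print(tidy(x$polymer_fit))
  if (!is.null(x$shift_observations)) {
    cat("\n-- drug shift factors --\n")
    print(x$shift_observations, n = 20)
    cat("\n-- plasticizing slope (through origin, opaque excluded) --\n")
    print(x$plast_slope)
  }
  if (!is.null(x$comparisons) && nrow(x$comparisons) > 0) {
    cat("\n-- zero-shear viscosity vs pure polymer --\n")
    print(x$comparisons)
  }
  if (!is.null(x$solubility)) {
    cat("\n-- solubility extracted from shift factors --\n")
    print(x$solubility)
  }
  if (!is.null(x$predictions)) {
    cat("\n-- two-phase predictions: ", nrow(x$predictions), " rows --\n")
  }
  invisible(x)
}
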