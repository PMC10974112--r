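# Simultaneous Carreau-Arrhenius parameter estimation by bounded
# Levenberg-Marquardt least squares on log10 viscosity, fitted per replicate
# (mean +/- sd, as instrument triplicates are summarized) and pooled.

#' Default parameter bounds for the Carreau--Arrhenius fit
#'
#' @return A list with elements `eta0`, `gamma_c`, `c`, `EA`, each a
#'   length-2 numeric `c(lower, upper)`.
#' @export
default_fit_bounds <- function() {
  list(eta0 = c(1e-1, 1e8), gamma_c = c(1e-3, 1e4),
       c = c(0.01, 0.99), EA = c(1e3, 1e6))
}

# parameters are optimized as (log10 eta0, log10 gamma_c, c, log10 EA)
pack_theta <- function(eta0, gamma_c, c, EA)
  c(log10(eta0), log10(gamma_c), c, log10(EA))
unpack_theta <- function(th)
  list(eta0 = 10^th[1], gamma_c = 10^th[2], c = th[3], EA = 10^th[4])

model_log10_eta <- function(th, rate, T_C, tref_C) {
  p <- unpack_theta(th)
  aT <- exp(p$EA / GAS_CONSTANT *
              (1 / (T_C + 273.15) - 1 / (tref_C + 273.15)))
  log10(p$eta0 * aT) - p$c * log10(1 + aT * rate / p$gamma_c)
}

# data-driven starting point: Arrhenius slope at the lowest rate, then
# plateau and knee of the reduced curve
init_theta <- function(df, tref_C, bounds) {
  low <- df |>
    dplyr::group_by(.data$temperature_C) |>
    dplyr::slice_min(.data$rate, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  EA0 <- 1.5e5
  if (nrow(low) >= 2) {
    sl <- stats::coef(stats::lm(log(low$viscosity) ~ I(1 / (low$temperature_C + 273.15))))[2]
    if (is.finite(sl) && sl > 0) EA0 <- sl * GAS_CONSTANT
  }
  EA0 <- min(max(EA0, bounds$EA[1] * 1.01), bounds$EA[2] * 0.99)
  aT <- exp(EA0 / GAS_CONSTANT *
              (1 / (df$temperature_C + 273.15) - 1 / (tref_C + 273.15)))
  red_rate <- df$rate * aT
  red_visc <- df$viscosity / aT
  eta0_0 <- max(red_visc)
  c0 <- 0.4
  below <- red_rate[red_visc < eta0_0 / 2^c0]
  gc0 <- if (length(below) > 0) min(below) else exp(mean(log(red_rate)))
  eta0_0 <- min(max(eta0_0, bounds$eta0[1] * 1.01), bounds$eta0[2] * 0.99)
  gc0 <- min(max(gc0, bounds$gamma_c[1] * 1.01), bounds$gamma_c[2] * 0.99)
  pack_theta(eta0_0, gc0, c0, EA0)
}

fit_one_replicate <- function(df, tref_C, bounds, n_starts, seed) {
  lower <- c(log10(bounds$eta0[1]), log10(bounds$gamma_c[1]),
             bounds$c[1], log10(bounds$EA[1]))
  upper <- c(log10(bounds$eta0[2]), log10(bounds$gamma_c[2]),
             bounds$c[2], log10(bounds$EA[2]))
  lv <- log10(df$viscosity)
  resid_fn <- function(th) model_log10_eta(th, df$rate, df$temperature_C, tref_C) - lv
  th0 <- init_theta(df, tref_C, bounds)
  starts <- with_seed_(seed, {
    c(list(th0),
      purrr::map(seq_len(max(n_starts - 1, 0)), function(i) {
        j <- th0 + stats::rnorm(4, 0, c(0.15, 0.3, 0.05, 0.05))
        pmin(pmax(j, lower), upper)
      }))
  })
  fits <- purrr::map(starts, function(st) {
    tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0)
    stop("Carreau-Arrhenius optimization failed to converge from every start")
  best <- fits[[which.min(purrr::map_dbl(fits, ~ .x$deviance))]]
  th <- best$par
  at_bound <- any(abs(th - lower) < 1e-8) || any(abs(th - upper) < 1e-8)
  if (at_bound)
    warning("fit terminated at a parameter bound; estimates may be unreliable")
  p <- unpack_theta(th)
  tibble::tibble(eta0 = p$eta0, gamma_c = p$gamma_c, c = p$c, EA = p$EA,
                 rms_log10 = sqrt(best$deviance / nrow(df)),
                 at_bound = at_bound)
}

#' Fit the Carreau--Arrhenius model to multi-temperature sweeps
#'
#' Estimates (`eta0`, `gamma_c`, `c`, `EA`) simultaneously by constrained
#' nonlinear least squares on log10 viscosity with equal point weights
#' (viscosities span decades, so the fit is done on the log scale). Each
#' replicate is fitted separately and the parameters are summarized as
#' mean +/- sd across replicates; a pooled fit over all points is reported
#' as well. A multi-start strategy (the data-driven start plus seeded
#' jittered starts) guards against local minima. Sweeps at a single
#' temperature cannot identify the activation energy and raise an error.
#'
#' @param curves Data frame of measurement rows (columns `temperature_C`,
#'   `rate`, `viscosity`; optional `replicate`, `drug_fraction`).
#' @param tref_C Reference temperature for `eta0`, `gamma_c`, `c`, degC.
#' @param bounds Parameter bounds, as from [default_fit_bounds()].
#' @param n_starts Number of optimizer starts (>= 1).
#' @param seed Seed for the jittered starts.
#' @return An object of class `carreau_arrhenius_fit`: a list with
#'   `params` (pooled [carreau_arrhenius_params()]), `per_replicate`
#'   (tibble of per-replicate estimates), `mean_sd` (per-parameter mean and
#'   sd over replicates), `residual` (pooled root-mean-square log10
#'   residual), `tref_C` and `n_replicates`.
#' @examples
#' des <- sweep_design(replicates = 2, noise_sigma = 0.02, seed = 3,
#'                     temperatures = c(140, 160, 180))
#' cur <- simulate_pure_polymer(des, reference_polymer_params("bBMA"))
#' fit <- fit_carreau_arrhenius(cur, tref_C = 160)
#' tidy(fit)
#' @export
fit_carreau_arrhenius <- function(curves, tref_C = 160,
                                  bounds = default_fit_bounds(),
                                  n_starts = 3, seed = 1) {
  check_curve_df(curves)
  if (length(unique(curves$temperature_C)) < 2)
    stop("activation energy is unidentifiable from a single temperature; ",
         "provide sweeps at >= 2 temperatures")
  if ("drug_fraction" %in% names(curves) &&
      length(unique(curves$drug_fraction)) > 1)
    stop("curves mix compositions; fit one drug fraction at a time")
  df <- tibble::as_tibble(curves)
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  rep_ids <- sort(unique(df$replicate))
  per_rep <- purrr::map_dfr(rep_ids, function(r) {
    one <- fit_one_replicate(df[df$replicate == r, ], tref_C, bounds,
                             n_starts, seed)
    dplyr::bind_cols(tibble::tibble(replicate = r), one)
  })
  pooled <- fit_one_replicate(df, tref_C, bounds, n_starts, seed)
  mean_sd <- per_rep |>
    tidyr::pivot_longer(dplyr::all_of(c("eta0", "gamma_c", "c", "EA")),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
                     .groups = "drop") |>
    dplyr::arrange(match(.data$parameter, c("eta0", "gamma_c", "c", "EA")))
  structure(list(
    params = carreau_arrhenius_params(pooled$eta0, pooled$gamma_c, pooled$c,
                                      pooled$EA, tref_C),
    per_replicate = per_rep,
    mean_sd = mean_sd,
    residual = pooled$rms_log10,
    tref_C = tref_C,
    n_replicates = length(rep_ids)
  ), class = "carreau_arrhenius_fit")
}

#' @export
print.carreau_arrhenius_fit <- function(x, ...) {
  cat(sprintf("Carreau-Arrhenius fit (Tref = %g degC, %d replicate%s)\n",
              x$tref_C, x$n_replicates, if (x$n_replicates > 1) "s" else ""))
  print(x$mean_sd)
  cat(sprintf("pooled RMS log10 residual: %.4g\n", x$residual))
  invisible(x)
}

#' Tidy a Carreau--Arrhenius fit
#'
#' @param x A `carreau_arrhenius_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: pooled `estimate` plus
#'   replicate `mean` and `sd`.
#' @exportS3Method generics::tidy
tidy.carreau_arrhenius_fit <- function(x, ...) {
  pooled <- c(eta0 = x$params$carreau$eta0, gamma_c = x$params$carreau$gamma_c,
              c = x$params$carreau$c, EA = x$params$arrhenius$EA)
  dplyr::mutate(x$mean_sd, estimate = unname(pooled[.data$parameter]),
                .before = "mean")
}

#' One-row summary of a Carreau--Arrhenius fit
#'
#' @param x A `carreau_arrhenius_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the pooled parameters, the RMS log10
#'   residual, the replicate count and the reference temperature.
#' @exportS3Method generics::glance
glance.carreau_arrhenius_fit <- function(x, ...) {
  tibble::tibble(eta0 = x$params$carreau$eta0,
                 gamma_c = x$params$carreau$gamma_c,
                 c = x$params$carreau$c,
                 EA = x$params$arrhenius$EA,
                 residual_rms_log10 = x$residual,
                 n_replicates = x$n_replicates,
                 tref_C = x$tref_C)
}

#' Compare zero-shear viscosities of two fitted systems
#'
#' Welch two-sample t test on the per-replicate zero-shear-rate viscosity
#' estimates of two fits, the standard check that two formulations differ
#' at the zero-shear plateau.
#'
#' @param fit_a,fit_b `carreau_arrhenius_fit` objects with >= 2 replicates.
#' @param alpha Significance level in (0, 1).
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `alpha`,
#'   `significant`.
#' @export
compare_zero_shear <- function(fit_a, fit_b, alpha = 0.05) {
  stopifnot(inherits(fit_a, "carreau_arrhenius_fit"),
            inherits(fit_b, "carreau_arrhenius_fit"))
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (fit_a$n_replicates < 2 || fit_b$n_replicates < 2)
    stop("both fits need >= 2 replicates to compare zero-shear viscosities")
  tt <- stats::t.test(fit_a$per_replicate$eta0, fit_b$per_replicate$eta0,
                      var.equal = FALSE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, alpha = alpha,
                 significant = tt$p.value < alpha)
}
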