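# Time-temperature superposition: collapse multi-temperature sweeps onto a
# reference-temperature master curve, and the Cox-Merz equivalence check.

curve_cols <- c("temperature_C", "rate", "viscosity")

check_curve_df <- function(df, what = "curves") {
  stopifnot(is.data.frame(df))
  miss <- setdiff(curve_cols, names(df))
  if (length(miss) > 0)
    stop(what, " missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$rate <= 0)) stop(what, ": rates must be positive")
  if (any(df$viscosity <= 0)) stop(what, ": viscosities must be positive")
  invisible(df)
}

# mean log10 viscosity per unique log10 rate -> interpolation table
loglog_table <- function(df) {
  agg <- stats::aggregate(log10(df$viscosity), list(lr = log10(df$rate)), mean)
  agg[order(agg$lr), ]
}

interp_loglog <- function(tab, lr) {
  stats::approx(tab$lr, tab$x, xout = lr, method = "linear", ties = "ordered",
                rule = 1)$y
}

#' Reduce a viscosity curve by a shift factor
#'
#' Maps each measured point (rate, viscosity) to the reduced point
#' (rate * a, viscosity / a). This is a shift along lines of constant shear
#' stress: the product rate * viscosity is unchanged for every point.
#'
#' @param curve Data frame with columns `rate` and `viscosity` (one sweep).
#' @param a Shift factor, > 0.
#' @return A tibble: the input columns plus `reduced_rate` and
#'   `reduced_viscosity`.
#' @examples
#' reduce_curve(data.frame(temperature_C = 200, rate = 10, viscosity = 100), a = 2)
#' @export
reduce_curve <- function(curve, a) {
  stopifnot(is.data.frame(curve), is.numeric(a), length(a) == 1L)
  if (!is.finite(a) || a <= 0) stop("shift factor `a` must be positive, got ", a)
  dplyr::mutate(tibble::as_tibble(curve),
                reduced_rate = .data$rate * a,
                reduced_viscosity = .data$viscosity / a)
}

# 1-D least-squares shift of one curve onto the reference interpolation table
fit_one_shift <- function(tab_ref, curve, T_C) {
  lr <- log10(curve$rate)
  lv <- log10(curve$viscosity)
  obj <- function(la) {
    pred <- interp_loglog(tab_ref, lr + la)
    resid <- (lv - la) - pred
    ok <- !is.na(resid)
    if (!any(ok)) return(NA_real_)
    sum(resid[ok]^2) / sum(ok)
  }
  # require overlap somewhere in the search bracket
  if (is.na(obj(0)) && is.na(obj(-4)) && is.na(obj(4))) {
    grid <- seq(-8, 8, by = 0.25)
    vals <- vapply(grid, obj, numeric(1))
    if (all(is.na(vals)))
      stop("no reduced-rate overlap with the reference curve for temperature ",
           T_C, " degC; cannot estimate its shift factor")
  }
  # coarse grid then local refinement; NA (no overlap) treated as +Inf
  grid <- seq(-8, 8, by = 0.1)
  vals <- vapply(grid, function(g) { v <- obj(g); if (is.na(v)) Inf else v },
                 numeric(1))
  if (all(!is.finite(vals)))
    stop("no reduced-rate overlap with the reference curve for temperature ",
         T_C, " degC; cannot estimate its shift factor")
  la0 <- grid[which.min(vals)]
  opt <- stats::optimize(function(g) { v <- obj(g); if (is.na(v)) Inf else v },
                         interval = c(la0 - 0.15, la0 + 0.15), tol = 1e-10)
  10^opt$minimum
}

#' Estimate temperature shift factors by curve superposition
#'
#' For each temperature, finds the shift factor that moves the sweep along
#' lines of constant shear stress onto the reference-temperature sweep,
#' minimizing the mean squared log-viscosity distance over the overlapping
#' reduced-rate range (linear interpolation in log-log space). The factor at
#' the reference temperature is fixed at 1. When no sweep is measured
#' exactly at `tref_C`, the nearest temperature is used as reference and a
#' warning is issued.
#'
#' @param curves Data frame of measurement rows (columns `temperature_C`,
#'   `rate`, `viscosity`; replicates are pooled).
#' @param tref_C Reference temperature, degC (default 160).
#' @return A tibble with columns `temperature_C` and `shift_factor`.
#' @examples
#' des <- sweep_design(replicates = 1, noise_sigma = 0,
#'                     temperatures = c(140, 160, 180))
#' cur <- simulate_pure_polymer(des, reference_polymer_params("bBMA"))
#' estimate_shift_factors(cur, tref_C = 160)
#' @export
estimate_shift_factors <- function(curves, tref_C = 160) {
  check_curve_df(curves)
  temps <- sort(unique(curves$temperature_C))
  ref_T <- if (tref_C %in% temps) tref_C else {
    nearest <- temps[which.min(abs(temps - tref_C))]
    warning("no curve measured at tref = ", tref_C,
            " degC; using nearest temperature ", nearest, " degC as reference")
    nearest
  }
  tab_ref <- loglog_table(curves[curves$temperature_C == ref_T, ])
  shifts <- purrr::map_dbl(temps, function(T_C) {
    if (T_C == ref_T) return(1)
    fit_one_shift(tab_ref, curves[curves$temperature_C == T_C, ], T_C)
  })
  tibble::tibble(temperature_C = temps, shift_factor = shifts)
}

#' Build a reference-temperature master curve
#'
#' Reduces every sweep by its temperature shift factor (estimated with
#' [estimate_shift_factors()] unless supplied) so that all temperatures
#' collapse onto the reference-temperature flow curve.
#'
#' @param curves Data frame of measurement rows.
#' @param tref_C Reference temperature, degC.
#' @param shifts Optional tibble (`temperature_C`, `shift_factor`) to use
#'   instead of estimating; must cover every temperature present.
#' @return A tibble of class `master_curve` with columns `reduced_rate`,
#'   `reduced_viscosity`, `source_temperature_C`, `shift_factor` (plus any
#'   grouping columns present), sorted by reduced rate. The reference
#'   temperature and shift table are attached as attributes `tref_C` and
#'   `shifts`.
#' @examples
#' des <- sweep_design(replicates = 1, noise_sigma = 0,
#'                     temperatures = c(140, 160, 180))
#' cur <- simulate_pure_polymer(des, reference_polymer_params("bBMA"))
#' mc <- build_master_curve(cur, tref_C = 160)
#' head(mc)
#' @export
build_master_curve <- function(curves, tref_C = 160, shifts = NULL) {
  check_curve_df(curves)
  if (is.null(shifts)) shifts <- estimate_shift_factors(curves, tref_C)
  missing_T <- setdiff(unique(curves$temperature_C), shifts$temperature_C)
  if (length(missing_T) > 0)
    stop("no shift factor for temperature(s): ", paste(missing_T, collapse = ", "))
  out <- curves |>
    dplyr::inner_join(shifts, by = "temperature_C") |>
    dplyr::mutate(reduced_rate = .data$rate * .data$shift_factor,
                  reduced_viscosity = .data$viscosity / .data$shift_factor) |>
    dplyr::rename(source_temperature_C = "temperature_C") |>
    dplyr::arrange(.data$reduced_rate)
  out <- tibble::as_tibble(out)
  attr(out, "tref_C") <- tref_C
  attr(out, "shifts") <- shifts
  class(out) <- c("master_curve", class(out))
  out
}

#' Summarize a master curve
#'
#' One-row summary of the collapse quality: number of points and source
#' temperatures, and the mean within-bin standard deviation of log10
#' reduced viscosity over log-spaced reduced-rate bins (small values mean a
#' tight collapse; for model-generated data it is bounded by the injected
#' noise).
#'
#' @param x A `master_curve` object.
#' @param bins_per_decade Number of reduced-rate bins per decade.
#' @param ... Unused.
#' @return A one-row tibble with `tref_C`, `n_points`, `n_temperatures`,
#'   `binned_log10_sd`.
#' @exportS3Method generics::glance
glance.master_curve <- function(x, bins_per_decade = 5, ...) {
  lr <- log10(x$reduced_rate)
  lv <- log10(x$reduced_viscosity)
  bin <- floor(lr * bins_per_decade)
  # residual sd around a local linear trend, so within-bin curvature of the
  # flow curve does not masquerade as replicate scatter
  sds <- vapply(split(seq_along(lr), bin), function(ix) {
    if (length(ix) < 3 || length(unique(lr[ix])) < 2) return(NA_real_)
    r <- stats::residuals(stats::lm(lv[ix] ~ lr[ix]))
    sqrt(sum(r^2) / (length(ix) - 2))
  }, numeric(1))
  tibble::tibble(
    tref_C = attr(x, "tref_C"),
    n_points = nrow(x),
    n_temperatures = length(unique(x$source_temperature_C)),
    binned_log10_sd = mean(sds, na.rm = TRUE)
  )
}

#' Cox--Merz deviation between rotational and oscillatory sweeps
#'
#' The Cox--Merz rule states that the steady-shear viscosity at shear rate
#' gamma-dot equals the complex viscosity at the numerically equal angular
#' frequency. This computes the median relative deviation
#' |eta_rot - eta_osc| / eta_osc over the overlapping rate range, with the
#' oscillatory curve interpolated in log-log space at the rotational rates.
#' A value near 0 supports using the two modes interchangeably.
#'
#' @param rotational,oscillatory Data frames with columns `rate` and
#'   `viscosity` at the same temperature and composition.
#' @return Median relative deviation (dimensionless scalar).
#' @examples
#' x <- data.frame(temperature_C = 160, rate = c(1, 2, 5), viscosity = c(90, 80, 60))
#' cox_merz_deviation(x, x)
#' @export
cox_merz_deviation <- function(rotational, oscillatory) {
  check_curve_df(rotational, "rotational")
  check_curve_df(oscillatory, "oscillatory")
  tab <- loglog_table(oscillatory)
  rot <- stats::aggregate(log10(rotational$viscosity),
                          list(lr = log10(rotational$rate)), mean)
  pred <- interp_loglog(tab, rot$lr)
  ok <- !is.na(pred)
  if (!any(ok))
    stop("rotational and oscillatory sweeps have disjoint rate ranges")
  eta_rot <- 10^rot$x[ok]
  eta_osc <- 10^pred[ok]
  stats::median(abs(eta_rot - eta_osc) / eta_osc)
}
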