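# Drug-shift slope regression, solubility inversion, and the phase-coupled
# two-phase viscosity prediction.

test_that("fit_shift_slope recovers an exact through-origin line", {
  w <- c(0, 0.1, 0.2, 0.3)
  res <- fit_shift_slope(data.frame(w_drug = w, a_drug = exp(-5 * w)))
  expect_equal(res$slope, -5, tolerance = 1e-12)
  expect_equal(res$std_error, 0, tolerance = 1e-10)
  expect_equal(res$residual_rms, 0, tolerance = 1e-12)
  # a single non-zero observation determines the slope through the origin
  one <- fit_shift_slope(data.frame(w_drug = 0.2, a_drug = exp(-1)))
  expect_equal(one$slope, -5, tolerance = 1e-12)
})

test_that("opaque observations are excluded and degenerate inputs refused", {
  obs <- data.frame(w_drug = c(0, 0.1, 0.2, 0.3),
                    a_drug = c(1, exp(-0.5), exp(-1), 9),
                    opaque_flag = c(FALSE, FALSE, FALSE, TRUE))
  res <- fit_shift_slope(obs)
  expect_equal(res$slope, -5, tolerance = 1e-12)
  expect_equal(res$n_excluded, 1L)
  expect_error(fit_shift_slope(data.frame(w_drug = 0, a_drug = 1)),
               "unidentifiable")
  expect_error(fit_shift_slope(
    data.frame(w_drug = 0.2, a_drug = 2, opaque_flag = TRUE)), "opaque")
})

test_that("noisy shift observations recover the slope within 2 se", {
  s_true <- -4.2
  set.seed(31)
  w <- rep(c(0.05, 0.1, 0.15, 0.2, 0.25), each = 3)
  a <- exp(s_true * w + rnorm(length(w), 0, 0.03))
  res <- fit_shift_slope(data.frame(w_drug = w, a_drug = a))
  expect_lt(abs(res$slope - s_true), 2 * res$std_error + 1e-12)
})

test_that("solubility_from_shift inverts the two-phase shift factor exactly", {
  d <- drug_shift_params(-5, 4)
  w_drug <- 0.3
  for (ws in seq(0, w_drug, length.out = 7)) {
    a <- drug_shift_two_phase(d, w_drug, ws)
    expect_equal(solubility_from_shift(a, d, w_drug), ws, tolerance = 1e-12)
  }
  # boundaries: fully dissolved and fully suspended
  expect_equal(solubility_from_shift(exp(w_drug * d$s_plast), d, w_drug),
               w_drug, tolerance = 1e-12)
  expect_equal(solubility_from_shift(exp(w_drug * d$s_filler), d, w_drug),
               0, tolerance = 1e-12)
  expect_error(solubility_from_shift(1, drug_shift_params(2, 2), 0.3),
               "degenerate")
  expect_warning(solubility_from_shift(exp(1), drug_shift_params(-5, 1), 0.3),
                 "clamped")
})

test_that("solubility curve interpolation: knots exact, midpoints linear, monotone", {
  sc <- solubility_curve(data.frame(temperature_C = c(130, 160, 200),
                                    ws_fraction  = c(0.05, 0.15, 0.35)))
  expect_equal(solubility_at(sc, c(130, 160, 200)), c(0.05, 0.15, 0.35))
  expect_equal(solubility_at(sc, 145), mean(c(0.05, 0.15)))
  expect_error(solubility_at(sc, 129), "extrapolation")
  expect_error(solubility_at(sc, 201), "extrapolation")
  # monotone over random admissible tables
  set.seed(12)
  for (i in 1:10) {
    temps <- sort(runif(5, 100, 220))
    ws <- sort(runif(5, 0, 1))
    sci <- solubility_curve(data.frame(temperature_C = temps, ws_fraction = ws))
    Ts <- sort(runif(20, min(temps), max(temps)))
    expect_true(all(diff(solubility_at(sci, Ts)) >= -1e-12))
  }
  expect_error(solubility_curve(data.frame(temperature_C = c(160, 130),
                                           ws_fraction = c(0.1, 0.2))),
               "increasing")
  expect_error(solubility_curve(data.frame(temperature_C = c(130, 160),
                                           ws_fraction = c(0.3, 0.2))),
               "non-decreasing")
})

test_that("two-phase prediction reduces correctly and is continuous at dissolution", {
  sc <- two_phase_scenario()
  p <- sc$p; d <- sc$d; curve <- sc$curve
  g <- 10^seq(-0.2, 2.8, length.out = 9)
  # fully dissolved everywhere -> identical to the single-phase global model
  rich <- solubility_curve(data.frame(temperature_C = c(120, 210),
                                      ws_fraction = c(0.9, 0.95)))
  expect_equal(predict_two_phase_viscosity(p, d, rich, 0.3, g, 170),
               global_viscosity(p, d, g, 170, 0.3))
  # insoluble additive -> above the pure-polymer curve at all rates
  none <- solubility_curve(data.frame(temperature_C = c(120, 210),
                                      ws_fraction = c(0, 0)))
  expect_true(all(predict_two_phase_viscosity(p, d, none, 0.3, g, 170) >
                    carreau_arrhenius_viscosity(p, g, 170)))
  # continuity at the temperature where w_s(T*) = w_drug = 0.3 (T* = 200)
  eps <- 1e-6
  expect_equal(predict_two_phase_viscosity(p, d, curve, 0.3, g, 200 - eps),
               predict_two_phase_viscosity(p, d, curve, 0.3, g, 200 + eps),
               tolerance = 1e-4)
  # viscosity decreases as more drug dissolves (s_plast < 0 < s_filler)
  etas <- vapply(c(0, 0.1, 0.2, 0.3),
                 function(ws) global_viscosity(p, d, 1, 160, 0.3, w_s = ws),
                 numeric(1))
  expect_true(all(diff(etas) < 0))
  # matches the hand-evaluated two-phase closed form
  ws160 <- solubility_at(curve, 160)
  a_hand <- exp(ws160 * d$s_plast + (0.3 - ws160) * d$s_filler)
  aT <- arrhenius_shift(p$arrhenius, 160)
  eta_hand <- p$carreau$eta0 * aT * a_hand /
    (1 + 6.28 * aT * a_hand / p$carreau$gamma_c)^p$carreau$c
  expect_equal(predict_two_phase_viscosity(p, d, curve, 0.3, 6.28, 160),
               eta_hand, tolerance = 1e-12)
})

test_that("temperature-resolved shift factors isolate the drug contribution", {
  sc <- two_phase_scenario()
  des <- sweep_design(replicates = 1, noise_sigma = 0, seed = 3,
                      temperatures = c(140, 160, 180))
  mix <- simulate_mixture_series(des, sc$p, sc$d, curve = sc$curve,
                                 drug_fractions = 0.3)
  est <- estimate_drug_shift_factors(mix, sc$p)
  truth <- drug_shift_two_phase(sc$d, 0.3,
                                solubility_at(sc$curve, est$temperature_C))
  expect_equal(est$a_drug, truth, tolerance = 0.005)
  expect_true(all(est$opaque_flag))
})
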