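# Closed-form model evaluations against independently hand-computed values,
# plus the structural identities that tie the equations together.

test_that("Carreau viscosity matches hand-evaluated values and limits", {
  p <- carreau_params(1000, 10, 0.5)
  expect_equal(carreau_viscosity(p, 0), 1000)
  expect_equal(carreau_viscosity(p, 10), 1000 * 2^(-0.5), tolerance = 1e-12)
  # bBMA parameter set at ten times its critical rate
  pb <- carreau_params(1011, 26.8, 0.433)
  expect_equal(carreau_viscosity(pb, 268), 357.9547443, tolerance = 1e-8)
  expect_error(carreau_viscosity(p, -1), "non-negative")
})

test_that("Carreau viscosity is non-increasing with a -c log-log tail", {
  p <- carreau_params(5146, 2.5, 0.363)
  rates <- 10^seq(-2, 5, length.out = 60)
  eta <- carreau_viscosity(p, rates)
  expect_true(all(diff(eta) <= 0))
  # local log-log slope near 1e4 * gamma_c approaches -c within 1%
  g <- p$gamma_c * 1e4
  slope <- (log10(carreau_viscosity(p, g * 1.01)) -
              log10(carreau_viscosity(p, g))) / log10(1.01)
  expect_equal(slope, -p$c, tolerance = 0.01)
})

test_that("Arrhenius shift equals hand oracle, is 1 at Tref, log-linear in 1/T", {
  a <- arrhenius_params(122498, 160)
  expect_identical(arrhenius_shift(a, 160), 1)
  expect_equal(arrhenius_shift(a, 200), 0.05637732326, tolerance = 1e-9)
  expect_equal(arrhenius_shift(a, 130), 12.56922316, tolerance = 1e-9)
  # ln a is linear in 1/T_K with slope EA/R
  TC <- c(130, 145, 160, 175, 190)
  la <- log(arrhenius_shift(a, TC))
  x <- 1 / (TC + 273.15)
  expect_equal(unname(coef(lm(la ~ x))[2]), 122498 / 8.314, tolerance = 1e-9)
  expect_error(arrhenius_shift(a, -300), "absolute zero")
})

test_that("Carreau-Arrhenius reduces to Carreau at Tref and matches oracle", {
  p <- bbma_params()
  expect_equal(carreau_arrhenius_viscosity(p, 0, 160), 1011)
  g <- c(0.5, 5, 50)
  expect_equal(carreau_arrhenius_viscosity(p, g, 160),
               carreau_viscosity(p$carreau, g))
  expect_equal(carreau_arrhenius_viscosity(p, 1, 190), 111.4505603,
               tolerance = 1e-8)
})

test_that("mixing rule is bounded, symmetric, and log-linear in w", {
  expect_equal(mixing_rule_viscosity(0, 2, 5146), 5146)
  expect_equal(mixing_rule_viscosity(1, 2, 5146), 2)
  expect_equal(mixing_rule_viscosity(0.5, 1, 100), 10)
  w <- seq(0, 1, by = 0.1)
  lmix <- log(mixing_rule_viscosity(w, 3, 4000))
  expect_equal(max(abs(diff(diff(lmix)))), 0, tolerance = 1e-12)
  expect_true(all(mixing_rule_viscosity(w, 3, 4000) >= 3 - 1e-12 &
                    mixing_rule_viscosity(w, 3, 4000) <= 4000 + 1e-9))
  expect_error(mixing_rule_viscosity(0.5, -1, 10), "positive")
})

test_that("drug shift factors: reference value 1, signs, two-phase reductions", {
  d <- drug_shift_params(-5, 4)
  expect_equal(drug_shift_single_phase(d, 0), 1)
  expect_equal(drug_shift_single_phase(d, 0.2), exp(-1), tolerance = 1e-12)
  dfill <- drug_shift_params(3)
  expect_equal(drug_shift_single_phase(dfill, 0.1), exp(0.3), tolerance = 1e-12)
  expect_gt(drug_shift_single_phase(dfill, 0.1), 1)
  # fully dissolved: two-phase collapses onto single-phase
  expect_equal(drug_shift_two_phase(d, 0.2, 0.5),
               drug_shift_single_phase(d, 0.2))
  # fully suspended: pure filler term
  expect_equal(drug_shift_two_phase(d, 0.3, 0), exp(1.2), tolerance = 1e-12)
  expect_equal(drug_shift_two_phase(d, 0, 0.1), 1)
  expect_error(drug_shift_single_phase(d, 1.2), "\\[0, 1\\]")
  expect_error(drug_shift_two_phase(d, 0.2, -0.1), "non-negative")
})

test_that("global model reduces to Carreau-Arrhenius at w = 0 and matches oracle", {
  p <- sol_params()
  d <- drug_shift_params(-4, 4)
  expect_equal(global_viscosity(p, d, 0, 160, 0), 5146)
  g <- 10^seq(-1, 2, length.out = 7)
  for (T_C in c(130, 160, 200))
    expect_equal(global_viscosity(p, d, g, T_C, 0),
                 carreau_arrhenius_viscosity(p, g, T_C))
  expect_equal(global_viscosity(p, d, 6.28, 160, 0.2), 1757.630515,
               tolerance = 1e-8)
})

test_that("shifting property: global model is a rescaled reference Carreau curve", {
  p <- bbma_params()
  d <- drug_shift_params(-3.5, 4.2)
  g <- 10^seq(-1, 3, length.out = 9)
  for (T_C in c(140, 160, 185)) {
    for (w in c(0, 0.15, 0.3)) {
      a <- arrhenius_shift(p$arrhenius, T_C) * drug_shift_single_phase(d, w)
      expect_equal(global_viscosity(p, d, g, T_C, w),
                   a * carreau_viscosity(p$carreau, a * g),
                   tolerance = 1e-12)
    }
  }
})

test_that("parameter constructors enforce their invariants", {
  expect_error(carreau_params(-1, 10, 0.5), "eta0")
  expect_error(carreau_params(10, 0, 0.5), "gamma_c")
  expect_error(carreau_params(10, 10, 1.2), "flow index")
  expect_error(arrhenius_params(-5, 160), "EA")
  expect_error(arrhenius_params(1e5, 400), "range")
})
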