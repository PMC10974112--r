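# Time-temperature superposition: constant-stress reduction, shift-factor
# recovery, collapse quality, and the Cox-Merz equivalence check.

test_that("reduce_curve preserves shear stress exactly", {
  cur <- data.frame(temperature_C = 200, rate = c(1, 10, 100),
                    viscosity = c(900, 500, 100))
  red <- reduce_curve(cur, a = 2)
  expect_equal(red$reduced_rate, c(2, 20, 200))
  expect_equal(red$reduced_viscosity, c(450, 250, 50))
  expect_equal(red$reduced_rate * red$reduced_viscosity,
               cur$rate * cur$viscosity)
  expect_identical(reduce_curve(cur, 1)$reduced_rate, cur$rate)
  expect_error(reduce_curve(cur, 0), "positive")
})

test_that("shift factors estimated from model curves match the Arrhenius closed form", {
  p <- bbma_params()
  des <- sweep_design(replicates = 1, noise_sigma = 0, seed = 1)
  cur <- simulate_pure_polymer(des, p)
  sf <- estimate_shift_factors(cur, tref_C = 160)
  truth <- arrhenius_shift(p$arrhenius, sf$temperature_C)
  expect_equal(sf$shift_factor[sf$temperature_C == 160], 1)
  expect_lt(max(abs(sf$shift_factor / truth - 1)), 0.005)
})

test_that("shift estimation is equivariant to a global viscosity scale", {
  p <- sol_params()
  des <- sweep_design(replicates = 1, noise_sigma = 0.02, seed = 5,
                      temperatures = c(140, 160, 180))
  cur <- simulate_pure_polymer(des, p)
  sf1 <- estimate_shift_factors(cur, 160)
  cur2 <- dplyr::mutate(cur, viscosity = viscosity * 37.5)
  sf2 <- estimate_shift_factors(cur2, 160)
  expect_equal(sf1$shift_factor, sf2$shift_factor, tolerance = 1e-6)
})

test_that("degenerate and edge reference handling", {
  p <- bbma_params()
  des <- sweep_design(replicates = 1, noise_sigma = 0, temperatures = 160)
  cur <- simulate_pure_polymer(des, p)
  sf <- estimate_shift_factors(cur, 160)
  expect_equal(sf, tibble::tibble(temperature_C = 160, shift_factor = 1))
  # two identical curves labeled with different temperatures -> both 1
  twin <- dplyr::bind_rows(cur, dplyr::mutate(cur, temperature_C = 170))
  sf2 <- estimate_shift_factors(twin, 160)
  expect_equal(sf2$shift_factor, c(1, 1), tolerance = 1e-6)
  # nearest temperature used (with a warning) when Tref is not measured
  expect_warning(estimate_shift_factors(cur, 162), "nearest")
})

test_that("disjoint reduced-rate ranges raise an estimation error naming the temperature", {
  a <- data.frame(temperature_C = 160, rate = c(1, 2, 4), viscosity = c(3, 2, 1))
  # rates so far away that no shift inside the search bracket creates overlap
  b <- data.frame(temperature_C = 190, rate = 1e12 * c(1, 2, 4),
                  viscosity = c(3, 2, 1))
  expect_error(estimate_shift_factors(dplyr::bind_rows(a, b), 160), "190")
})

test_that("master-curve collapse: stress conserved, scatter bounded by noise", {
  p <- sol_params()
  sigma <- 0.02
  des <- sweep_design(replicates = 3, noise_sigma = sigma, seed = 11)
  cur <- simulate_pure_polymer(des, p)
  mc <- build_master_curve(cur, 160)
  expect_equal(mc$reduced_rate * mc$reduced_viscosity,
               mc$rate * mc$viscosity, tolerance = 1e-12)
  g <- glance(mc)
  expect_equal(g$n_temperatures, 8L)
  # binned sd of log10 viscosity <= injected log10-scale noise
  expect_lte(g$binned_log10_sd, sigma / log(10))
  # model-generated curve reduced with the exact Arrhenius factor overlays
  # the reference curve pointwise
  des0 <- sweep_design(replicates = 1, noise_sigma = 0,
                       temperatures = c(160, 200))
  cur0 <- simulate_pure_polymer(des0, p)
  hot <- cur0[cur0$temperature_C == 200, ]
  red <- reduce_curve(hot, arrhenius_shift(p$arrhenius, 200))
  expect_equal(red$reduced_viscosity,
               carreau_viscosity(p$carreau, red$reduced_rate),
               tolerance = 1e-12)
})

test_that("Cox-Merz deviation: zero on identical curves, offset and noise scale", {
  p <- bbma_params()
  des <- sweep_design(replicates = 1, noise_sigma = 0, temperatures = 160,
                      rate_min = 0.1, rate_max = 10, mode = "rotational")
  rot <- simulate_pure_polymer(des, p)
  osc <- dplyr::mutate(rot, mode = "oscillatory")
  expect_equal(cox_merz_deviation(rot, osc), 0)
  expect_equal(cox_merz_deviation(rot, dplyr::mutate(osc, viscosity = viscosity * 1.10)),
               0.1 / 1.10, tolerance = 1e-6)
  # 2% multiplicative noise on both modes -> deviation of the noise order
  desn <- sweep_design(replicates = 1, noise_sigma = 0.02, seed = 9,
                       temperatures = 160, rate_min = 0.1, rate_max = 10)
  rotn <- simulate_pure_polymer(desn, p)
  oscn <- simulate_pure_polymer(sweep_design(replicates = 1, noise_sigma = 0.02,
                                             seed = 10, temperatures = 160,
                                             rate_min = 0.1, rate_max = 10), p)
  dev <- cox_merz_deviation(rotn, oscn)
  expect_gt(dev, 0.001)
  expect_lt(dev, 0.1)
  disjoint <- dplyr::mutate(osc, rate = rate * 1e6)
  expect_error(cox_merz_deviation(rot, disjoint), "disjoint")
})
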