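# Reverse dosimetry: background subtraction, HDI calibration,
# Metropolis-Hastings inversion, and sector Monte Carlo integration.

test_that("background subtraction clamps at zero", {
  expect_equal(subtract_background(0.4, 0.2), 0.2)
  expect_equal(subtract_background(0.1, 0.2), 0)
  expect_equal(subtract_background(c(0, 0.5, 3), 0), c(0, 0.5, 3))
  expect_equal(default_background(), 0.2)
  expect_error(subtract_background(-1), ">= 0")
})

test_that("HDI calibration evaluates and inverts the published equation", {
  cal <- hdi_calibration()
  # log identity: intercept alone corresponds to 1 ug HDI/m3
  expect_equal(as.numeric(hdi_air_from_hda(10 ^ cal$intercept)), 1,
               tolerance = 1e-12)
  # forward at 10 ug/m3, then back
  expect_equal(hda_from_hdi_air(10), 10 ^ (cal$slope + cal$intercept),
               tolerance = 1e-12)
  expect_equal(hda_from_hdi_air(10), 7.962, tolerance = 1e-3)
  expect_equal(as.numeric(hdi_air_from_hda(hda_from_hdi_air(10))), 10,
               tolerance = 1e-10)
})

test_that("calibration round-trip is the identity across its air range", {
  hdi <- exp(seq(log(0.3), log(97.7), length.out = 60))
  back <- as.numeric(hdi_air_from_hda(hda_from_hdi_air(hdi)))
  expect_equal(back, hdi, tolerance = 1e-10)
  expect_false(any(attr(hdi_air_from_hda(hda_from_hdi_air(hdi)),
                        "extrapolated")))
})

test_that("values outside the calibration ranges carry the extrapolation flag", {
  out <- hdi_air_from_hda(0.5)  # below the 1.36 ug/g lower urine bound
  expect_true(attr(out, "extrapolated"))
  out_hi <- hdi_air_from_hda(100)  # above the 27.7 ug/g upper urine bound
  expect_true(attr(out_hi, "extrapolated"))
  expect_error(hdi_air_from_hda(0), "> 0")
})

test_that("the MH posterior recovers a noise-free observation", {
  sc <- exposure_scenario()
  pp <- kinetic_parameters("MDI", error_gsd = 1.05)
  u_obs <- kinetic_forward(1.0, sc, pp)
  cfg <- reconstruction_config(mh_iterations = 4000, mh_burn_in = 500,
                               proposal_scale = 0.15, seed = 2)
  draws <- reverse_dosimetry_mh(u_obs, sc, pp, cfg)
  expect_true(all(draws > 0))
  expect_equal(median(draws), 1.0, tolerance = 0.05)
  rate <- attr(draws, "acceptance_rate")
  expect_gt(rate, 0.05)
  expect_lt(rate, 0.95)
})

test_that("MH posterior quantiles match the dense-grid Bayes oracle", {
  sc <- exposure_scenario()
  pp <- kinetic_parameters("MDI")  # error_gsd 1.5
  cfg <- reconstruction_config(mh_iterations = 200000, mh_burn_in = 20000,
                               proposal_scale = 0.7, prior_scale = 100,
                               seed = 31)
  u_unit <- kinetic_forward(1, sc, pp)
  probs <- seq(0.05, 0.95, by = 0.05)
  for (u_obs in c(0.2, 2)) {
    draws <- reverse_dosimetry_mh(u_obs, sc, pp, cfg)
    got <- unname(quantile(draws, probs, type = 7))
    want <- grid_posterior_quantiles(u_obs, u_unit, pp$error_gsd, 100, probs)
    expect_lt(max(abs(got / want - 1)), 0.03, label = paste("u_obs", u_obs))
  }
})

test_that("a degenerate chain raises a diagnostic warning", {
  sc <- exposure_scenario()
  pp <- kinetic_parameters("MDI", error_gsd = 1.001)
  cfg <- reconstruction_config(mh_iterations = 300, mh_burn_in = 100,
                               proposal_scale = 40, seed = 4)
  expect_warning(reverse_dosimetry_mh(kinetic_forward(1, sc, pp), sc, pp, cfg),
                 "acceptance")
})

test_that("a degenerate urinary distribution reduces to single-value inversion", {
  urine <- measurements("HDA", value = rep(5, 6), loq = 0.2,
                        below_loq = FALSE, creatinine = 1.36)
  cfg <- reconstruction_config(n_mc = 500, seed = 9)
  res <- reconstruct_sector(urine, "HDI", config = cfg)
  cal <- hdi_calibration()
  hda_per_g <- (5 - 0.2) / 1.36
  want <- convert_di_to_nco(
    10 ^ ((log10(hda_per_g) - cal$intercept) / cal$slope), "HDI")
  expect_equal(res$gm, want, tolerance = 1e-10)
  expect_equal(res$am, want, tolerance = 1e-10)
  expect_equal(res$p95, want, tolerance = 1e-10)
})

test_that("sector reconstruction is permutation-invariant and GM <= AM", {
  fixture <- table4_like_fixture("motor_vehicle", metabolites = "HDA")
  cfg <- reconstruction_config(n_mc = 2000, seed = 14)
  res <- reconstruct_sector(fixture, "HDI", config = cfg)
  shuffled <- fixture[sample(nrow(fixture)), ]
  res2 <- reconstruct_sector(shuffled, "HDI", config = cfg)
  expect_equal(res2$gm, res$gm)
  expect_equal(res2$am, res$am)
  expect_lte(res$gm, res$am)
  # MDI path: MH-based draws, same invariant
  mdi <- table4_like_fixture("motor_vehicle", metabolites = "MDA")
  cfg2 <- reconstruction_config(n_mc = 1000, mh_iterations = 150,
                                mh_burn_in = 50, seed = 15)
  res_mdi <- reconstruct_sector(mdi, "MDI", config = cfg2)
  expect_lte(res_mdi$gm, res_mdi$am)
  expect_true(all(res_mdi$draws >= 0))
})

test_that("a distribution entirely below background is rejected", {
  urine <- measurements("MDA", value = rep(0.05, 5), loq = 0.2,
                        below_loq = TRUE)
  expect_error(reconstruct_sector(urine, "MDI",
                                  config = reconstruction_config(n_mc = 100)),
               "background")
})

test_that("reconstruction recovers a known exposure from simulated urine", {
  # forward-simulate urine at a known air level, add observation noise and
  # background, then reconstruct
  truth <- 0.5
  sc <- exposure_scenario()
  pp <- kinetic_parameters("MDI")
  withr::local_seed(123)
  u_true <- kinetic_forward(truth, sc, pp)
  u_obs <- u_true * rlnorm(200, 0, log(pp$error_gsd)) + 0.2
  urine <- measurements("MDA", value = u_obs, loq = 0.1, below_loq = FALSE)
  cfg <- reconstruction_config(n_mc = 10000, mh_iterations = 400,
                               mh_burn_in = 150, seed = 77)
  res <- reconstruct_sector(urine, "MDI", scenario = sc, params = pp,
                            config = cfg)
  expect_equal(res$am, truth, tolerance = 0.25)
})
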