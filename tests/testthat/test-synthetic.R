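# Synthetic biomonitoring generator: censoring behaviour, determinism,
# mixture properties, and the packaged registry-like fixture.

test_that("censored share matches the lognormal CDF oracle", {
  # background only: P(value < loq) = plnorm(loq, log gm, log gsd)
  cfg <- generator_config(n = 1000, background_gm = 0.05,
                          background_gsd = 2, exposed_fraction = 0,
                          loq = 0.2, seed = 5)
  d <- generate_urine_samples(cfg)
  want <- plnorm(0.2, log(0.05), log(2))
  expect_gt(want, 0.95)
  expect_gt(mean(d$below_loq), 0.95)
  expect_equal(mean(d$below_loq), want, tolerance = 0.02)
  # fully exposed far above the LOQ: essentially nothing censored
  cfg2 <- generator_config(n = 1000, background_gm = 0.05,
                           background_gsd = 2, exposed_fraction = 1,
                           exposed_gm = 10, exposed_gsd = 2, loq = 0.2,
                           seed = 5)
  expect_lt(mean(generate_urine_samples(cfg2)$below_loq), 0.01)
})

test_that("the generator is deterministic given its seed", {
  cfg <- generator_config(n = 200, background_gm = 0.1, exposed_fraction = 0.3,
                          exposed_gm = 2, seed = 99)
  expect_identical(generate_urine_samples(cfg), generate_urine_samples(cfg))
  expect_identical(generate_air_samples(cfg, "MDI"),
                   generate_air_samples(cfg, "MDI"))
})

test_that("censoring flags never alter the retained truth values", {
  cfg <- generator_config(n = 500, background_gm = 0.1, exposed_fraction = 0.2,
                          exposed_gm = 1, loq = 0.3, seed = 3)
  d <- generate_urine_samples(cfg)
  expect_equal(d$value, d$true_value)
  expect_equal(d$below_loq, d$true_value < cfg$loq)
  sub <- substitute_below_loq(d)
  expect_equal(sub$true_value, d$true_value)
})

test_that("mixture GM is monotone in exposed fraction and exposed level", {
  gm_at <- function(p, ex_gm) {
    cfg <- generator_config(n = 4000, background_gm = 0.1,
                            exposed_fraction = p, exposed_gm = ex_gm,
                            loq = 0.01, seed = 17)
    geometric_mean(generate_urine_samples(cfg)$true_value)
  }
  fracs <- c(0, 0.25, 0.5, 1)
  expect_true(all(diff(vapply(fracs, gm_at, 1, ex_gm = 2)) > 0))
  gms <- c(0.5, 1, 4, 16)
  expect_true(all(diff(vapply(gms, gm_at, 1, p = 0.5)) > 0))
})

test_that("censored share converges to the numeric mixture-CDF complement", {
  cfg <- generator_config(n = 1e5, background_gm = 0.1, background_gsd = 2,
                          exposed_fraction = 0.3, exposed_gm = 0.5,
                          exposed_gsd = 3, loq = 0.3, seed = 21)
  d <- generate_urine_samples(cfg)
  # oracle: P(bg + occ < loq) by 1-D numeric convolution over bg
  p_sum_below <- integrate(function(b) {
    dlnorm(b, log(0.1), log(2)) * plnorm(0.3 - b, log(0.5), log(3))
  }, 0, 0.3, rel.tol = 1e-9)$value
  p_below <- 0.7 * plnorm(0.3, log(0.1), log(2)) + 0.3 * p_sum_below
  expect_lt(abs(100 * mean(!d$below_loq) - 100 * (1 - p_below)), 1)
})

test_that("air generator labels species and produces nonnegative NCO values", {
  cfg <- generator_config(n = 100, background_gm = 0.02, background_gsd = 3,
                          exposed_fraction = 0.2, exposed_gm = 2, seed = 12)
  d <- generate_air_samples(cfg, "TDI")
  expect_equal(unique(d$analyte), "TDI")
  expect_equal(unique(d$matrix), "air")
  expect_true(all(d$value >= 0))
})

test_that("registry-like fixture lands in the reference ranges", {
  mv <- table4_like_fixture("motor_vehicle", metabolites = "MDA")
  expect_equal(nrow(mv), 54)
  pct <- 100 * mean(!mv$below_loq)
  expect_true(abs(pct - 19) <= 10)
  cs <- table4_like_fixture("construction", metabolites = "MDA")
  s <- summarize_levels(substitute_below_loq(cs))
  expect_gte(s$gm, 0.15)
  expect_lte(s$gm, 0.6)
  # regeneration is identical
  expect_identical(table4_like_fixture("construction"),
                   table4_like_fixture("construction"))
  expect_error(table4_like_fixture("mining"), "unknown sector")
})
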