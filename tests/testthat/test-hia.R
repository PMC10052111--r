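# Worker counts and excess-case arithmetic.

test_that("mean exposed workers is the midpoint rounded to hundreds", {
  expect_equal(mean_exposed_workers(800, 1000), 900)
  expect_equal(mean_exposed_workers(500, 1000), 800)
  expect_equal(mean_exposed_workers(1500, 1500), 1500)
  expect_error(mean_exposed_workers(-1, 5), "nonnegative")
  expect_error(mean_exposed_workers(10, 5), "<=")
})

test_that("the packaged workforce table sums to the published totals", {
  wf <- sector_workforce()
  expect_equal(sum(wf$mean_exposed), 18200)
  expect_equal(sum(wf$total_workers), 71200)
  expect_equal(round_half_away(100 * sum(wf$mean_exposed) /
                                 sum(wf$total_workers)), 26)
  hw <- hia_workforce()
  expect_setequal(hw$sector,
                  c("construction", "motor_vehicle", "polyurethane",
                    "assembly"))
  expect_equal(hw$mean_exposed[hw$sector == "polyurethane"], 1700)
})

test_that("excess cases round half away from zero and are monotone", {
  expect_equal(excess_cases(6200, 1.5), 93)
  expect_equal(excess_cases(3100, 2.6), 81)  # 80.6 rounds up
  expect_equal(excess_cases(12345, 0), 0)
  n <- seq(0, 10000, by = 500)
  expect_true(all(diff(excess_cases(n, 2)) >= 0))
  r <- seq(0, 7.5, by = 0.5)
  expect_true(all(diff(excess_cases(5000, r)) >= 0))
})

test_that("the task-split scenario sums per-task cases", {
  res <- task_split_scenario(9300, data.frame(
    fraction = c(2 / 3, 1 / 3), analyte = c("HDI", "MDI"),
    risk_pct = c(1.5, 2.6)))
  expect_equal(res$per_task$cases, c(93, 81))
  expect_equal(res$combined, 174)
  # a single full split reduces to excess_cases
  one <- task_split_scenario(5000, data.frame(fraction = 1, analyte = "MDI",
                                              risk_pct = 2))
  expect_equal(one$combined, excess_cases(5000, 2))
  # empty split list and over-allocated fractions
  expect_equal(task_split_scenario(5000, data.frame())$combined, 0)
  expect_error(task_split_scenario(5000, data.frame(
    fraction = c(0.7, 0.6), analyte = c("A", "B"), risk_pct = c(1, 1))),
    "more than 1")
})

test_that("annual-case projection is a plain product", {
  expect_equal(project_annual_cases(4, 40), 160)
  expect_equal(project_annual_cases(0, 40), 0)
  expect_equal(project_annual_cases(4, 1), 4)
})

test_that("run_hia composes risk lookup and case counting", {
  fake <- structure(list(draws = rep(0.3, 200)),
                    class = "reconstruction_result")
  wf <- data.frame(sector = "construction", mean_exposed = 1000)
  curve <- rac_curve()
  out <- run_hia(list("construction/MDI" = fake), workforce = wf,
                 interpolator = function(e) lookup_rac_band(e, curve))
  expect_equal(out$excess_risk_pct, 3)
  expect_equal(out$excess_cases, 30)
  # draws all at zero exposure give zero cases
  zero <- structure(list(draws = rep(0, 50)), class = "reconstruction_result")
  out0 <- run_hia(list("construction/MDI" = zero), workforce = wf)
  expect_equal(out0$excess_cases, 0)
})

test_that("run_hia logs exclusions and rejects unknown sectors", {
  fake <- structure(list(draws = rep(0.1, 10)),
                    class = "reconstruction_result")
  wf <- data.frame(sector = c("a", "b"), mean_exposed = c(100, 200))
  excl <- data.frame(sector = "b", analyte = "TDI", reason = "too few data")
  out <- run_hia(list("a/MDI" = fake), workforce = wf, exclusions = excl)
  expect_equal(attr(out, "exclusions")$sector, "b")
  expect_false("b" %in% out$sector)
  expect_error(run_hia(list("zz/MDI" = fake), workforce = wf),
               "no workforce record")
})

test_that("run_hia totals are invariant to sector ordering", {
  fake1 <- structure(list(draws = rep(0.3, 50)),
                     class = "reconstruction_result")
  fake2 <- structure(list(draws = rep(0.15, 50)),
                     class = "reconstruction_result")
  wf <- data.frame(sector = c("a", "b"), mean_exposed = c(1000, 2000))
  o1 <- run_hia(list("a/MDI" = fake1, "b/TDI" = fake2), workforce = wf)
  o2 <- run_hia(list("b/TDI" = fake2, "a/MDI" = fake1), workforce = wf)
  expect_equal(sum(o1$excess_cases), sum(o2$excess_cases))
  expect_equal(o1, o2)
})
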