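# Independent oracles used across the suite. These deliberately avoid the
# package's own closed-form / sampler code paths.

# Naive fine-step Euler integration of the one-compartment kinetics over
# the working schedule; returns the urinary concentration at the end of
# the final shift.
euler_urine <- function(c_air, scenario, params, dt = 0.001) {
  k <- log(2) / params$elimination_half_life
  intake <- params$absorbed_fraction * params$ventilation_rate * c_air
  shift <- scenario$hours_per_day
  burden <- 0
  n_shift <- round(shift / dt)
  decay_gap <- function(burden, hours) {
    n <- round(hours / dt)
    for (i in seq_len(n)) burden <- burden - dt * k * burden
    burden
  }
  for (w in seq_len(scenario$weeks)) {
    for (d in seq_len(scenario$days_per_week)) {
      for (i in seq_len(n_shift)) {
        burden <- burden + dt * (intake - k * burden)
      }
      last <- w == scenario$weeks && d == scenario$days_per_week
      if (!last) {
        gap <- if (d == scenario$days_per_week) {
          (24 - shift) + 24 * (7 - scenario$days_per_week)
        } else {
          24 - shift
        }
        burden <- decay_gap(burden, gap)
      }
    }
  }
  params$urinary_excretion_fraction * k * burden / params$urine_flow
}

# Dense-grid Bayes posterior for the scalar air concentration: lognormal
# likelihood around c * u_unit, half-normal prior; trapezoid-normalised
# CDF, quantiles by interpolation.
grid_posterior_quantiles <- function(u_obs, u_unit, error_gsd, prior_scale,
                                     probs) {
  centre <- u_obs / u_unit
  grid <- exp(seq(log(centre) - 8 * log(error_gsd),
                  log(centre) + 8 * log(error_gsd), length.out = 40000))
  lp <- stats::dlnorm(u_obs, log(grid * u_unit), log(error_gsd),
                      log = TRUE) - grid^2 / (2 * prior_scale^2)
  w <- exp(lp - max(lp))
  dx <- diff(grid)
  seg <- (w[-1] + w[-length(w)]) / 2 * dx
  cdf <- c(0, cumsum(seg)) / sum(seg)
  stats::approx(cdf, grid, xout = probs, ties = "ordered")$y
}

# Tiny urine measurement table for plumbing tests.
tiny_urine <- function() {
  measurements(analyte = "MDA", value = c(0.4, 0.1, 1.2),
               loq = 0.2, below_loq = c(FALSE, TRUE, FALSE),
               matrix = "urine", sector = "construction",
               creatinine = c(1.2, NA, 1.5))
}
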