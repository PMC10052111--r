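# One-compartment linear kinetics linking inhaled NCO mass to the urinary
# diamine concentration. During a shift the body burden accumulates at a
# constant intake rate (absorbed fraction x ventilation rate x air
# concentration) while eliminating first-order; between shifts it only
# decays. Both phases have exact exponential solutions, so the burden at
# the sampling time is a finite piecewise-exponential composition - no
# numerical ODE solver is involved - and the model is exactly linear in
# the air concentration, the property the Bayesian inversion relies on.

#' Exposure scenario for reverse dosimetry
#'
#' Sub-chronic repeated-exposure pattern assumed when inverting the kinetic
#' model: `weeks` working weeks of `days_per_week` consecutive shifts of
#' `hours_per_day` hours, urine sampled post-shift on the last working day,
#' no respiratory protection assumed.
#'
#' @param weeks,days_per_week,hours_per_day positive counts/hours; defaults
#'   12 weeks, 5 days, 8 h.
#' @return an `exposure_scenario` list.
#' @export
exposure_scenario <- function(weeks = 12, days_per_week = 5,
                              hours_per_day = 8) {
  stop_if_not_scalar_number(weeks, "weeks", positive = TRUE)
  stop_if_not_scalar_number(days_per_week, "days_per_week", positive = TRUE)
  stop_if_not_scalar_number(hours_per_day, "hours_per_day", positive = TRUE)
  if (hours_per_day > 24 || days_per_week > 7) {
    stop("scenario exceeds calendar bounds")
  }
  structure(list(weeks = as.integer(weeks),
                 days_per_week = as.integer(days_per_week),
                 hours_per_day = hours_per_day),
            class = "exposure_scenario")
}

#' Kinetic parameters for a diisocyanate species
#'
#' Parameters of the linear one-compartment model. Packaged defaults for
#' MDI and TDI are physiologically plausible configurable values (see the
#' methods vignette); every one of them can be overridden.
#'
#' @param species `"MDI"` or `"TDI"` to load packaged defaults, or `NULL`
#'   when all values are given explicitly.
#' @param absorbed_fraction fraction of inhaled mass absorbed (0-1).
#' @param ventilation_rate breathing rate, m3/h.
#' @param elimination_half_life apparent urinary-elimination half-life, h.
#' @param urinary_excretion_fraction fraction of the absorbed dose excreted
#'   in urine as the diamine (0-1).
#' @param urine_flow urine production, L/h.
#' @param error_gsd geometric standard deviation of the lognormal
#'   observation error around the model prediction (> 1).
#' @return a `kinetic_parameters` list.
#' @export
kinetic_parameters <- function(species = NULL, absorbed_fraction = NULL,
                               ventilation_rate = NULL,
                               elimination_half_life = NULL,
                               urinary_excretion_fraction = NULL,
                               urine_flow = NULL, error_gsd = NULL) {
  defaults <- list()
  if (!is.null(species)) {
    all_defaults <- yaml::read_yaml(pkg_extdata("defaults.yaml"))$kinetics
    if (!toupper(species) %in% names(all_defaults)) {
      stop("no packaged kinetic defaults for species '", species,
           "' (available: ", paste(names(all_defaults), collapse = ", "), ")")
    }
    defaults <- all_defaults[[toupper(species)]]
  }
  pick <- function(given, name) if (is.null(given)) defaults[[name]] else given
  p <- list(absorbed_fraction = pick(absorbed_fraction, "absorbed_fraction"),
            ventilation_rate = pick(ventilation_rate, "ventilation_rate"),
            elimination_half_life = pick(elimination_half_life,
                                         "elimination_half_life"),
            urinary_excretion_fraction = pick(urinary_excretion_fraction,
                                              "urinary_excretion_fraction"),
            urine_flow = pick(urine_flow, "urine_flow"),
            error_gsd = pick(error_gsd, "error_gsd"))
  if (any(vapply(p, is.null, TRUE))) {
    stop("kinetic parameters incomplete: provide a species with packaged ",
         "defaults or all parameter values")
  }
  for (nm in names(p)) stop_if_not_scalar_number(p[[nm]], nm, positive = TRUE)
  if (p$absorbed_fraction > 1 || p$urinary_excretion_fraction > 1) {
    stop("absorbed_fraction and urinary_excretion_fraction must be <= 1")
  }
  if (p$error_gsd <= 1) stop("error_gsd must be > 1")
  structure(p, class = "kinetic_parameters")
}

#' Forward kinetic model: air concentration to urinary level
#'
#' Predicts the urinary diamine concentration (ug/L) at the post-shift
#' sampling time of the final working day, for continuous exposure at
#' `c_air` ug NCO/m3 during every shift of the scenario. The burden is
#' propagated analytically: over a shift of length T with intake rate R
#' and elimination rate k, A <- A e^(-kT) + (R/k)(1 - e^(-kT)); between
#' shifts A decays by e^(-k * gap). The urinary concentration is the renal
#' excretion rate divided by urine flow:
#' u = urinary_excretion_fraction x k x A / urine_flow.
#' The model is homogeneous of degree one: doubling `c_air` doubles `u`.
#'
#' @param c_air air concentration(s), ug NCO/m3 (>= 0); vectorised.
#' @param scenario an [exposure_scenario()].
#' @param params a [kinetic_parameters()].
#' @return urinary concentration(s), ug/L.
#' @export
#' @examples
#' kinetic_forward(1, exposure_scenario(), kinetic_parameters("MDI"))
kinetic_forward <- function(c_air, scenario = exposure_scenario(),
                            params = kinetic_parameters("MDI")) {
  if (any(c_air < 0, na.rm = TRUE)) stop("c_air must be >= 0")
  c_air * urinary_level_per_unit_air(scenario, params)
}

# Urinary level (ug/L) produced by 1 ug NCO/m3, at the post-shift sampling
# time of the last working day. Exact piecewise-exponential propagation.
urinary_level_per_unit_air <- function(scenario, params) {
  stopifnot(inherits(scenario, "exposure_scenario"),
            inherits(params, "kinetic_parameters"))
  k <- log(2) / params$elimination_half_life
  intake <- params$absorbed_fraction * params$ventilation_rate  # ug/h per unit c_air
  shift <- scenario$hours_per_day
  overnight <- 24 - shift
  weekend <- overnight + 24 * (7 - scenario$days_per_week)
  burden <- 0
  for (w in seq_len(scenario$weeks)) {
    for (d in seq_len(scenario$days_per_week)) {
      burden <- burden * exp(-k * shift) + (intake / k) * (1 - exp(-k * shift))
      last <- w == scenario$weeks && d == scenario$days_per_week
      if (!last) {
        gap <- if (d == scenario$days_per_week) weekend else overnight
        burden <- burden * exp(-k * gap)
      }
    }
  }
  params$urinary_excretion_fraction * k * burden / params$urine_flow
}
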