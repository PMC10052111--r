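# Health impact assessment: exposed-worker counts per sector and excess
# BHR case arithmetic over the reconstructed exposure distributions.

#' Packaged workforce table
#'
#' Estimated numbers of workers exposed to diisocyanates per occupation
#' group: total workers, the range of exposed-worker estimates from the
#' national job-exposure matrix and the EU restriction dossier, and the
#' published mean estimate. The published means are shipped verbatim (their
#' rounding differs slightly from the arithmetic midpoint);
#' [mean_exposed_workers()] computes midpoints for new data.
#'
#' @return data.frame with columns `sector`, `total_workers`,
#'   `exposed_low`, `exposed_high`, `mean_exposed`.
#' @export
sector_workforce <- function() {
  tab <- utils::read.csv(pkg_extdata("sector_workforce.csv"),
                         stringsAsFactors = FALSE)
  stopifnot(all(tab$exposed_low <= tab$exposed_high),
            all(tab$exposed_low >= 0))
  tab
}

#' Workforce aggregated to the biomonitoring sectors
#'
#' The biomonitoring data pool polyurethane/plastic-product and furniture
#' manufacture into one sector; this helper returns the four
#' biomonitoring sectors with their mean exposed-worker counts
#' (`polyurethane` = furniture + plastic products).
#'
#' @return data.frame with columns `sector`, `mean_exposed`.
#' @export
hia_workforce <- function() {
  tab <- sector_workforce()
  pick <- function(s) tab$mean_exposed[tab$sector == s]
  data.frame(
    sector = c("construction", "motor_vehicle", "polyurethane", "assembly"),
    mean_exposed = c(pick("construction"), pick("motor_vehicle"),
                     pick("furniture") + pick("plastic_products"),
                     pick("assembly")))
}

#' Mean exposed-worker estimate from a range
#'
#' Midpoint of the (low, high) exposed-worker range, rounded to the
#' nearest hundred with ties away from zero.
#'
#' @param low,high nonnegative counts with `low <= high`.
#' @return rounded midpoint.
#' @export
#' @examples
#' mean_exposed_workers(800, 1000)  # 900
#' mean_exposed_workers(500, 1000)  # 800
mean_exposed_workers <- function(low, high) {
  if (any(c(low, high) < 0)) stop("worker counts must be nonnegative")
  if (any(low > high)) stop("low must be <= high")
  round_half_away((low + high) / 2, -2)
}

#' Excess cases from an exposed population and a risk
#'
#' @param n_exposed number of exposed workers (>= 0).
#' @param risk excess risk over the working life, percent.
#' @return expected number of excess cases, rounded half away from zero.
#' @export
#' @examples
#' excess_cases(6200, 1.5)  # 93
#' excess_cases(3100, 2.6)  # 81 (80.6 rounded)
excess_cases <- function(n_exposed, risk) {
  if (any(n_exposed < 0)) stop("n_exposed must be >= 0")
  if (any(risk < 0)) stop("risk must be >= 0")
  round_half_away(n_exposed * risk / 100)
}

#' Split a sector workforce across task-specific exposures
#'
#' When different diisocyanates are used in different tasks, attributing
#' the whole sector workforce to every species double-counts cases. This
#' scenario assigns fractions of the workforce to species-specific risks
#' and sums the per-task excess cases.
#'
#' @param n_total total workers in the sector.
#' @param splits data.frame with columns `fraction`, `analyte`,
#'   `risk_pct`; fractions must sum to at most 1.
#' @return list with `per_task` (data.frame `analyte`, `n_workers`,
#'   `cases`) and `combined` (total cases).
#' @export
#' @examples
#' task_split_scenario(9300, data.frame(
#'   fraction = c(2 / 3, 1 / 3), analyte = c("HDI", "MDI"),
#'   risk_pct = c(1.5, 2.6)))
task_split_scenario <- function(n_total, splits) {
  stop_if_not_scalar_number(n_total, "n_total", nonnegative = TRUE)
  if (!nrow(splits)) {
    return(list(per_task = data.frame(analyte = character(),
                                      n_workers = numeric(),
                                      cases = numeric()),
                combined = 0))
  }
  stopifnot(all(c("fraction", "analyte", "risk_pct") %in% names(splits)))
  if (any(splits$fraction < 0)) stop("fractions must be >= 0")
  if (sum(splits$fraction) > 1 + 1e-9) {
    stop("task fractions sum to more than 1")
  }
  n_workers <- n_total * splits$fraction
  cases <- excess_cases(n_workers, splits$risk_pct)
  list(per_task = data.frame(analyte = splits$analyte,
                             n_workers = n_workers, cases = cases),
       combined = sum(cases))
}

#' Project annual case counts over a working life
#'
#' @param cases_per_year average cases per year (>= 0).
#' @param years projection horizon in years (default 40, a working life).
#' @return total projected cases.
#' @export
#' @examples
#' project_annual_cases(4)  # 160
project_annual_cases <- function(cases_per_year, years = 40) {
  if (any(c(cases_per_year, years) < 0)) stop("inputs must be nonnegative")
  cases_per_year * years
}

#' Run the health impact assessment
#'
#' For every sector x species reconstruction, averages the capped
#' per-draw excess risks over the retained Monte Carlo exposures and
#' multiplies by the sector's mean exposed-worker count. Pairs listed in
#' `exclusions` (e.g. too few quantifiable measurements to reconstruct)
#' are logged and omitted from the results; case counts come from the
#' unrounded mean risk, the displayed risk is rounded to one decimal.
#'
#' @param reconstructions named list of `reconstruction_result` objects;
#'   names are `"sector/SPECIES"` pairs (e.g. `"construction/MDI"`).
#' @param workforce data.frame with `sector` and `mean_exposed` columns
#'   (default [hia_workforce()]).
#' @param curve a [rac_curve()].
#' @param exclusions optional data.frame with columns `sector`, `analyte`,
#'   `reason`.
#' @param interpolator optional exposure -> risk (%) function; defaults to
#'   the capped monotone spline of `curve` (use
#'   `function(e) lookup_rac_band(e, curve)` for plain band lookup).
#' @return data.frame with columns `sector`, `analyte`, `n_exposed`,
#'   `excess_risk_pct` (one decimal), `excess_cases`; the exclusion log is
#'   attached as attribute `"exclusions"`.
#' @export
run_hia <- function(reconstructions, workforce = hia_workforce(),
                    curve = rac_curve(), exclusions = NULL,
                    interpolator = NULL) {
  stopifnot(is.list(reconstructions), !is.null(names(reconstructions)))
  if (is.null(interpolator)) interpolator <- build_spline(curve)
  parts <- strsplit(names(reconstructions), "/", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("reconstruction names must be 'sector/SPECIES'")
  }
  rows <- lapply(seq_along(reconstructions), function(i) {
    sector <- parts[[i]][1]
    analyte <- parts[[i]][2]
    n_exposed <- workforce$mean_exposed[workforce$sector == sector]
    if (!length(n_exposed)) {
      stop("no workforce record for sector '", sector, "'")
    }
    risk <- mean_excess_risk(reconstructions[[i]]$draws, interpolator)
    data.frame(sector = sector, analyte = analyte, n_exposed = n_exposed,
               excess_risk_pct = round_half_away(risk, 1),
               excess_cases = excess_cases(n_exposed, risk))
  })
  out <- do.call(rbind, rows[order(names(reconstructions))])
  row.names(out) <- NULL
  if (is.null(exclusions)) {
    exclusions <- data.frame(sector = character(), analyte = character(),
                             reason = character())
  }
  attr(out, "exclusions") <- exclusions
  out
}
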