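# Excess-risk dose-response for bronchial hyperresponsiveness (BHR): the
# regulatory risk-assessment committee's band table relating working-life
# excess BHR risk to airborne NCO concentration, a capped monotone spline
# through it, and the averaging of per-draw risks over a reconstructed
# exposure distribution.

#' The packaged excess-risk band table
#'
#' Working-life excess BHR risk bands by air NCO concentration: 0.1% below
#' 0.025 ug NCO/m3 up to 5% above 0.67 ug NCO/m3. `knots` are the band
#' midpoints (lower bound for the open-ended top band) plus a (0, 0)
#' anchor, the support of the spline interpolant.
#'
#' @param cap maximum excess risk (%) the interpolant may return; the
#'   packaged default 7.5% limits extrapolation beyond the highest banded
#'   risk.
#' @return a `dose_response_curve` list with `bands` (data.frame
#'   `risk_pct`, `lower`, `upper`), `knots` (data.frame `exposure`,
#'   `risk_pct`) and `cap`.
#' @export
rac_curve <- function(cap = NULL) {
  bands <- utils::read.csv(pkg_extdata("rac_excess_risk.csv"))
  if (is.null(cap)) {
    cap <- yaml::read_yaml(pkg_extdata("defaults.yaml"))$risk_cap_pct
  }
  if (is.unsorted(bands$risk_pct, strictly = TRUE) ||
      is.unsorted(bands$lower)) {
    stop("excess-risk bands must be strictly increasing in risk and exposure")
  }
  mid <- ifelse(is.na(bands$upper), bands$lower,
                (bands$lower + bands$upper) / 2)
  knots <- data.frame(exposure = c(0, mid), risk_pct = c(0, bands$risk_pct))
  structure(list(bands = bands, knots = knots, cap = cap),
            class = "dose_response_curve")
}

#' Band lookup of excess BHR risk
#'
#' Returns the printed risk of the band containing the exposure: below the
#' first band boundary the lowest banded risk (0.1%) applies, gaps between
#' bands take the risk of the band below, and everything above the lower
#' bound of the open-ended top band (strictly above 0.67 ug NCO/m3) takes
#' the highest banded risk (5%).
#'
#' @param exposure air concentration(s), ug NCO/m3 (>= 0); vectorised.
#' @param curve a [rac_curve()].
#' @return excess risk in percent.
#' @export
#' @examples
#' lookup_rac_band(c(0.01, 0.3, 1.0))  # 0.1, 3, 5
lookup_rac_band <- function(exposure, curve = rac_curve()) {
  stopifnot(inherits(curve, "dose_response_curve"))
  if (any(exposure < 0, na.rm = TRUE)) stop("exposure must be >= 0")
  bands <- curve$bands
  k <- nrow(bands)
  # band i applies from its lower bound up to (but excluding) the next
  # band's lower bound; the top band only strictly above its lower bound
  idx <- findInterval(exposure, bands$lower[-1])  # 0 .. k-1
  risk <- bands$risk_pct[idx + 1]
  at_top_bound <- exposure == bands$lower[k]
  risk[at_top_bound] <- bands$risk_pct[k - 1]
  risk
}

#' Capped monotone spline through the excess-risk knots
#'
#' Shape-preserving (monotone) cubic interpolation through the band
#' midpoints with a (0, 0) anchor, so the whole distribution of exposure
#' levels maps smoothly onto risk. Above the last knot the curve rises
#' linearly at the final inter-knot slope until it reaches the cap, and is
#' flat thereafter; evaluation is clamped to \[0, cap\] everywhere.
#'
#' @param curve a [rac_curve()].
#' @return a function mapping exposure (ug NCO/m3) to excess risk (%).
#' @export
#' @examples
#' f <- build_spline()
#' f(0.275)  # 3 (a knot)
#' f(1000)   # 7.5 (the cap)
build_spline <- function(curve = rac_curve()) {
  stopifnot(inherits(curve, "dose_response_curve"))
  kn <- curve$knots
  if (is.unsorted(kn$exposure, strictly = TRUE) ||
      is.unsorted(kn$risk_pct, strictly = TRUE)) {
    stop("spline knots must be strictly increasing")
  }
  core <- stats::splinefun(kn$exposure, kn$risk_pct, method = "hyman")
  last_x <- kn$exposure[nrow(kn)]
  last_y <- kn$risk_pct[nrow(kn)]
  tail_slope <- (last_y - kn$risk_pct[nrow(kn) - 1]) /
    (last_x - kn$exposure[nrow(kn) - 1])
  cap <- curve$cap
  function(exposure) {
    if (any(exposure < 0, na.rm = TRUE)) stop("exposure must be >= 0")
    risk <- ifelse(exposure <= last_x, core(exposure),
                   last_y + tail_slope * (exposure - last_x))
    pmin(pmax(risk, 0), cap)
  }
}

#' Mean excess risk over a reconstructed exposure distribution
#'
#' Averages the capped per-draw risks of a Monte Carlo exposure sample —
#' the whole distribution contributes, not a single summary level.
#'
#' @param draws reconstructed exposures, ug NCO/m3 (nonempty).
#' @param interpolator risk function from [build_spline()] (or any
#'   exposure -> % mapping).
#' @return mean excess risk in percent.
#' @export
mean_excess_risk <- function(draws, interpolator = build_spline()) {
  if (!length(draws)) stop("draws must be nonempty")
  mean(interpolator(draws))
}
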