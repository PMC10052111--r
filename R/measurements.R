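# Measurement records: air (ug/m3) and urine (ug/L) observations with
# left-censoring at the limit of quantitation (LOQ).

MEASUREMENT_COLUMNS <- c("analyte", "matrix", "value", "unit", "loq",
                         "below_loq", "sector", "creatinine", "date")

expected_unit <- function(matrix) {
  switch(matrix, air = "ug/m3", urine = "ug/L",
         stop("matrix must be 'air' or 'urine', got '", matrix, "'"))
}

#' Build a measurement table
#'
#' Constructs the canonical measurement data.frame used throughout the
#' package: one row per air or urine observation, with explicit units and a
#' left-censoring flag. Units are never inferred: air records are ug/m3,
#' urine records ug/L.
#'
#' @param analyte analyte identifier (species like `"MDI"` or metabolite
#'   like `"MDA"`).
#' @param value observed concentration (>= 0).
#' @param loq limit of quantitation, same units as `value` (> 0).
#' @param below_loq logical; `TRUE` when the observation is censored below
#'   the LOQ (the raw `value` is then not used downstream — see
#'   [substitute_below_loq()]).
#' @param matrix `"air"` or `"urine"`.
#' @param sector sector identifier (optional).
#' @param creatinine urinary creatinine in g/L (urine only, optional).
#' @param date observation date as character (optional).
#' @return data.frame of class `di_measurements`.
#' @export
#' @examples
#' measurements(analyte = "MDA", value = c(0.4, 0.1), loq = 0.2,
#'              below_loq = c(FALSE, TRUE), matrix = "urine")
measurements <- function(analyte, value, loq, below_loq = FALSE,
                         matrix = "urine", sector = NA_character_,
                         creatinine = NA_real_, date = NA_character_) {
  df <- data.frame(analyte = analyte, matrix = matrix, value = value,
                   unit = vapply(as.character(matrix), expected_unit, ""),
                   loq = loq, below_loq = below_loq, sector = sector,
                   creatinine = creatinine, date = as.character(date),
                   stringsAsFactors = FALSE, row.names = NULL)
  validate_measurements(df)
}

#' Validate a measurement table
#'
#' @param df data.frame with the columns of [measurements()].
#' @return the validated data.frame, classed `di_measurements`.
#' @export
validate_measurements <- function(df) {
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("measurement table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_matrix <- !df$matrix %in% c("air", "urine")
  if (any(bad_matrix)) {
    stop("invalid matrix in row(s) ", paste(which(bad_matrix), collapse = ", "),
         " (must be 'air' or 'urine')")
  }
  wrong_unit <- df$unit != vapply(df$matrix, expected_unit, "")
  if (any(wrong_unit)) {
    stop("unit does not match matrix in row(s) ",
         paste(which(wrong_unit), collapse = ", "),
         " (air must be ug/m3, urine ug/L)")
  }
  bad_value <- !is.na(df$value) & df$value < 0
  if (any(bad_value)) {
    stop("negative concentration in row(s) ",
         paste(which(bad_value), collapse = ", "))
  }
  if (!is.logical(df$below_loq)) stop("below_loq must be logical")
  class(df) <- unique(c("di_measurements", class(df)))
  df
}

#' Substitute censored values with LOQ/2
#'
#' Standard handling of left-censored occupational-hygiene data: every
#' record flagged below the limit of quantitation is assigned the value
#' LOQ/2; uncensored records are unchanged and row order is preserved. The
#' operation is idempotent.
#'
#' @param df a measurement table (see [measurements()]).
#' @return the table with censored values replaced; the `below_loq` flag is
#'   retained so censoring information is not lost.
#' @export
#' @examples
#' m <- measurements("MDA", c(0.4, 0.08), loq = 0.1,
#'                   below_loq = c(FALSE, TRUE))
#' substitute_below_loq(m)$value  # 0.40 0.05
substitute_below_loq <- function(df) {
  df <- validate_measurements(df)
  cens <- which(df$below_loq)
  bad <- cens[is.na(df$loq[cens]) | df$loq[cens] <= 0]
  if (length(bad)) {
    stop("censored record(s) with missing or non-positive LOQ in row(s) ",
         paste(bad, collapse = ", "))
  }
  df$value[cens] <- df$loq[cens] / 2
  df
}

#' Convert between per-gram-creatinine and per-litre urinary units
#'
#' Creatinine correction normalises urinary analyte concentrations for
#' urine dilution. `creatinine_to_volume()` converts ug/g creatinine to
#' ug/L by multiplying with the creatinine concentration (g/L);
#' `volume_to_creatinine()` is its inverse.
#'
#' @param conc numeric vector: ug/g creatinine (forward) or ug/L (inverse).
#' @param creatinine urinary creatinine in g/L (> 0); the default 1.36 g/L
#'   is the packaged mean adult value.
#' @return numeric vector in the target units.
#' @export
#' @examples
#' creatinine_to_volume(21.5)   # ~29.2 ug/L
#' creatinine_to_volume(150.2)  # ~204 ug/L
creatinine_to_volume <- function(conc, creatinine = default_creatinine()) {
  if (any(creatinine <= 0, na.rm = TRUE) || anyNA(creatinine)) {
    stop("creatinine must be a positive value in g/L")
  }
  conc * creatinine
}

#' @rdname creatinine_to_volume
#' @export
volume_to_creatinine <- function(conc, creatinine = default_creatinine()) {
  if (any(creatinine <= 0, na.rm = TRUE) || anyNA(creatinine)) {
    stop("creatinine must be a positive value in g/L")
  }
  conc / creatinine
}

#' @rdname creatinine_to_volume
#' @export
default_creatinine <- function() {
  yaml::read_yaml(pkg_extdata("defaults.yaml"))$creatinine_mean_g_l
}

#' Count exceedances of an exposure limit
#'
#' Counts values strictly above a threshold (OEL-compliance language:
#' "exceeded the limit" means above it) and reports the percentage to one
#' decimal, ties rounded away from zero.
#'
#' @param values numeric vector of concentrations (e.g. ug NCO/m3).
#' @param threshold exposure limit (> 0), same units.
#' @return list with `count` and `percent`.
#' @export
#' @examples
#' exceedance_stats(c(5, 12, 40), 10)  # 2 of 3 -> 66.7%
exceedance_stats <- function(values, threshold) {
  stop_if_not_scalar_number(threshold, "threshold", positive = TRUE)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to assess for exceedance")
  count <- sum(values > threshold)
  list(count = count,
       percent = round_half_away(100 * count / length(values), 1))
}

#' Summary statistics for a measurement table
#'
#' Reports the standard biomonitoring summary: sample size, number and
#' share of records at or above the LOQ, geometric mean, median, 95th
#' percentile and maximum, computed on LOQ/2-substituted values. Quantiles
#' use linear interpolation between order statistics with inclusive
#' endpoints (plotting positions (k-1)/(n-1), `stats::quantile` type 7),
#' the same convention as [fit_empirical_distribution()].
#'
#' @param df a measurement table; censored records must already be
#'   substituted (see [substitute_below_loq()]).
#' @param quantile_type quantile estimator passed to [stats::quantile()].
#' @return list with `n`, `n_geq_loq`, `pct_geq_loq`, `gm`, `p50`, `p95`,
#'   `max`.
#' @export
summarize_levels <- function(df, quantile_type = 7) {
  df <- validate_measurements(df)
  if (!nrow(df)) stop("cannot summarize an empty measurement table")
  v <- df$value
  if (any(is.na(v) | v <= 0)) {
    stop("non-positive or missing values; substitute censored records first")
  }
  q <- stats::quantile(v, c(0.5, 0.95), type = quantile_type, names = FALSE)
  n_geq <- sum(!df$below_loq)
  list(n = nrow(df), n_geq_loq = n_geq,
       pct_geq_loq = round_half_away(100 * n_geq / nrow(df), 1),
       gm = geometric_mean(v), p50 = q[1], p95 = q[2], max = max(v))
}
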