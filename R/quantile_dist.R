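# Empirical-quantile exposure distributions: a piecewise-linear inverse
# CDF through the observed order statistics. Strongly skewed biomonitoring
# data are poorly captured by any single parametric (e.g. lognormal)
# family, so the Monte Carlo integration samples this nonparametric object
# instead.

#' Construct a quantile distribution
#'
#' @param probs nondecreasing probabilities in \[0, 1\].
#' @param values nondecreasing concentrations, same length as `probs`.
#' @return object of class `quantile_distribution`.
#' @export
quantile_distribution <- function(probs, values) {
  if (length(probs) != length(values) || length(probs) < 2) {
    stop("probs and values must have equal length >= 2")
  }
  if (is.unsorted(probs) || is.unsorted(values)) {
    stop("probs and values must both be nondecreasing")
  }
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]")
  structure(list(probs = probs, values = values),
            class = "quantile_distribution")
}

#' Fit an empirical quantile distribution
#'
#' Builds the piecewise-linear inverse CDF through the sorted sample with
#' inclusive-endpoint plotting positions (k-1)/(n-1), so the fitted
#' distribution spans exactly the observed range (the minimum is the 0th
#' and the maximum the 100th percentile). This is the `stats::quantile`
#' type-7 convention; `quantile_type` switches to any other type by
#' evaluating that estimator on a fine probability grid.
#'
#' @param values positive concentrations (ug/L), censored records already
#'   substituted; at least two values.
#' @param quantile_type quantile estimator convention (default 7).
#' @return a [quantile_distribution()].
#' @export
#' @examples
#' d <- fit_empirical_distribution(c(1, 2, 3, 4))
#' inverse_cdf(d, 0.5)  # 2.5
fit_empirical_distribution <- function(values, quantile_type = 7) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least two values to fit a distribution")
  if (any(values <= 0)) {
    stop("values must be positive after LOQ substitution")
  }
  if (quantile_type == 7) {
    v <- sort(values)
    n <- length(v)
    quantile_distribution(probs = (seq_len(n) - 1) / (n - 1), values = v)
  } else {
    p <- seq(0, 1, length.out = max(length(values), 201L))
    quantile_distribution(p, stats::quantile(values, p, type = quantile_type,
                                             names = FALSE))
  }
}

#' Evaluate the inverse CDF of a quantile distribution
#'
#' Linear interpolation between the stored quantiles; constant beyond the
#' endpoints.
#'
#' @param dist a [quantile_distribution()].
#' @param p probabilities in \[0, 1\].
#' @return concentrations at those quantiles.
#' @export
inverse_cdf <- function(dist, p) {
  stopifnot(inherits(dist, "quantile_distribution"))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  if (all(dist$values == dist$values[1])) {
    return(rep(dist$values[1], length(p)))
  }
  stats::approx(dist$probs, dist$values, xout = p, ties = "ordered",
                rule = 2)$y
}

#' Sample from a quantile distribution
#'
#' Inverse-CDF sampling: draws U ~ Uniform(0, 1) and maps them through
#' [inverse_cdf()]. Fully reproducible given `seed`.
#'
#' @param dist a [quantile_distribution()].
#' @param n number of draws (>= 1).
#' @param seed integer seed (optional; when `NULL` the current RNG stream
#'   is used).
#' @return numeric vector of `n` draws.
#' @export
sample_distribution <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "quantile_distribution"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive count")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  inverse_cdf(dist, stats::runif(n))
}

#' @export
print.quantile_distribution <- function(x, ...) {
  cat(sprintf("<quantile_distribution> %d knots over [%g, %g]\n",
              length(x$probs), min(x$values), max(x$values)))
  invisible(x)
}
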