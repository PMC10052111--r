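#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used throughout occupational-hygiene reporting (so 80.6 cases
#' round to 81, and 25.56% rounds to 25.6%). Base R's `round()` rounds ties
#' to even and cannot reproduce these figures.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places (may be negative, e.g. -2 rounds to
#'   the nearest hundred).
#' @return numeric vector of the same length.
#' @export
#' @examples
#' round_half_away(80.6)      # 81
#' round_half_away(750, -2)   # 800
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @param na.rm drop missing values first.
#' @return scalar geometric mean.
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) stop("geometric mean is undefined for non-positive values")
  exp(mean(log(x)))
}

# Shared argument checks ------------------------------------------------

stop_if_not_scalar_number <- function(x, name, positive = FALSE,
                                      nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  }
  if (nonnegative && x < 0) {
    stop(sprintf("`%s` must be >= 0 (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "dihia", mustWork = FALSE)
  if (!nzchar(path)) {
    # during development (pkgload) fall back to the source tree
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("packaged data file not found: ", file)
  path
}
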