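#' Min-max normalization onto the unit interval
#'
#' Maps a numeric vector affinely so its minimum becomes 0 and its maximum 1,
#' the scaling convention under which the error-asymmetry theory is stated
#' (both variables equally scaled on the unit interval).
#'
#' @param v Numeric vector, length at least 2, with `max(v) > min(v)`.
#' @return `(v - min(v)) / (max(v) - min(v))`.
#' @examples
#' normalize_minmax(c(0, 2, 4))
#' @export
normalize_minmax <- function(v) {
  v <- as.numeric(v)
  if (length(v) < 2) {
    stop("Need at least 2 values to normalize.", call. = FALSE)
  }
  r <- range(v)
  if (!all(is.finite(r)) || r[2] <= r[1]) {
    stop("Degenerate input: constant vector cannot be min-max normalized ",
         "(causal direction undecidable).", call. = FALSE)
  }
  (v - r[1]) / (r[2] - r[1])
}

#' Standardize to mean 0, variance 1
#'
#' Centers and scales to unit variance using the population convention
#' (divisor `n`), the alternative scaling used for unbounded variables.
#'
#' @param v Numeric vector, length at least 2, with positive variance.
#' @return Vector with sample mean 0 and population-convention variance 1.
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(v) {
  v <- as.numeric(v)
  if (length(v) < 2) {
    stop("Need at least 2 values to standardize.", call. = FALSE)
  }
  m <- mean(v)
  s2 <- mean((v - m)^2)
  if (!is.finite(s2) || s2 <= 0) {
    stop("Degenerate input: zero variance vector cannot be standardized.",
         call. = FALSE)
  }
  (v - m) / sqrt(s2)
}

#' Scale both variables of a pair
#'
#' @param pair An [observed_pair()] or two-column data frame.
#' @param mode `"minmax"` (onto `[0, 1]`, the default) or `"zscore"`
#'   (mean 0, population variance 1).
#' @return The scaled pair.
#' @export
scale_pair <- function(pair, mode = c("minmax", "zscore")) {
  pair <- as_observed_pair(pair)
  mode <- match.arg(mode)
  f <- if (mode == "minmax") normalize_minmax else standardize
  pair_like(pair, f(pair$x), f(pair$y))
}

scott_bandwidth <- function(v) {
  n <- length(v)
  s <- stats::sd(v)
  if (s <= 0) s <- max(abs(v), 1) * 1e-8  # collapse guard for constant axes
  s * n^(-1 / 6)  # Scott's rule, d = 2
}

#' Joint density score of each observation
#'
#' Evaluates a two-dimensional Gaussian product-kernel density estimate of the
#' joint sample at each observed point. The density is normalized to integrate
#' to one, so the low-density threshold (0.1 by default in
#' [remove_low_density()]) is on an absolute density scale.
#'
#' @param pair An [observed_pair()] or two-column data frame (n >= 5); scaling
#'   should already have been applied.
#' @param bandwidth Either `"scott"` (per-axis plug-in rule
#'   `sd * n^(-1/6)`) or a numeric vector of two positive per-axis bandwidths.
#' @return A nonnegative numeric vector, one density estimate per point.
#' @export
density_scores <- function(pair, bandwidth = "scott") {
  pair <- as_observed_pair(pair)
  n <- nrow(pair)
  if (n < 5) {
    stop("Insufficient data: density scores need at least 5 points.",
         call. = FALSE)
  }
  if (identical(bandwidth, "scott")) {
    hx <- scott_bandwidth(pair$x)
    hy <- scott_bandwidth(pair$y)
  } else {
    bandwidth <- as.numeric(bandwidth)
    if (length(bandwidth) != 2 || any(!is.finite(bandwidth)) ||
        any(bandwidth <= 0)) {
      stop("`bandwidth` must be \"scott\" or two positive numbers.",
           call. = FALSE)
    }
    hx <- bandwidth[1]
    hy <- bandwidth[2]
  }
  kx <- stats::dnorm(outer(pair$x, pair$x, "-") / hx) / hx
  ky <- stats::dnorm(outer(pair$y, pair$y, "-") / hy) / hy
  as.numeric(rowMeans(kx * ky))
}

#' Remove low-density points from a pair
#'
#' Drops observations whose joint kernel-density estimate falls below a
#' threshold, so isolated outliers have less impact on the regression errors.
#' Order of the surviving points is preserved and the pair's name, ground
#' truth and weight are carried over.
#'
#' @inheritParams density_scores
#' @param threshold Nonnegative density cutoff; points with estimated density
#'   `>= threshold` are kept. Default 0.1.
#' @return The filtered [observed_pair()].
#' @export
remove_low_density <- function(pair, threshold = 0.1, bandwidth = "scott") {
  pair <- as_observed_pair(pair)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop("`threshold` must be a single nonnegative number.", call. = FALSE)
  }
  keep <- density_scores(pair, bandwidth = bandwidth) >= threshold
  if (!any(keep)) {
    stop("All points fall below the density threshold; empty result.",
         call. = FALSE)
  }
  pair_like(pair, pair$x[keep], pair$y[keep])
}
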