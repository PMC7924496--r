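#' Construct an observed cause-effect pair
#'
#' An `observed_pair` is a tibble with numeric columns `x` and `y` (one row per
#' joint observation) carrying three attributes: a `name`, the ground-truth
#' causal direction `truth` (`"x_causes_y"`, `"y_causes_x"` or `"unknown"`),
#' and a nonnegative `weight` used when several datasets are too similar to
#' count as independent examples in a benchmark.
#'
#' @param x,y Equal-length finite numeric vectors, length at least 10.
#' @param name Label for the pair.
#' @param truth Ground-truth direction, one of `"x_causes_y"`, `"y_causes_x"`,
#'   `"unknown"`.
#' @param weight Nonnegative benchmark weight (default 1).
#' @return A tibble of class `observed_pair` with columns `x` and `y`.
#' @examples
#' observed_pair(rnorm(20), rnorm(20), name = "demo")
#' @export
observed_pair <- function(x, y, name = "pair", truth = "unknown", weight = 1) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have identical length.", call. = FALSE)
  }
  if (length(x) < 10) {
    stop("An observed pair needs at least 10 observations.", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("All entries of `x` and `y` must be finite.", call. = FALSE)
  }
  truth <- match.arg(truth, c("x_causes_y", "y_causes_x", "unknown"))
  if (!is.numeric(weight) || length(weight) != 1 || weight < 0) {
    stop("`weight` must be a single nonnegative number.", call. = FALSE)
  }
  out <- tibble::tibble(x = x, y = y)
  attr(out, "name") <- as.character(name)
  attr(out, "truth") <- truth
  attr(out, "weight") <- as.numeric(weight)
  class(out) <- c("observed_pair", class(out))
  out
}

#' Coerce a two-column data frame to an observed pair
#'
#' @param data A data frame whose first two columns are the observations of
#'   the two variables (or an `observed_pair`, returned unchanged).
#' @inheritParams observed_pair
#' @return An [observed_pair()].
#' @export
as_observed_pair <- function(data, name = "pair", truth = "unknown",
                             weight = 1) {
  if (inherits(data, "observed_pair")) {
    return(data)
  }
  if (!is.data.frame(data) || ncol(data) < 2) {
    stop("`data` must be a data frame with at least two columns.",
         call. = FALSE)
  }
  observed_pair(data[[1]], data[[2]], name = name, truth = truth,
                weight = weight)
}

pair_name <- function(pair) attr(pair, "name") %||% "pair"
pair_truth <- function(pair) attr(pair, "truth") %||% "unknown"
pair_weight <- function(pair) attr(pair, "weight") %||% 1

# Rebuild a pair from new columns, carrying name/truth/weight (and any
# generator record) over. No minimum-length check: derived pairs (splits,
# filtered subsets) may be smaller than the n >= 10 required of inputs.
pair_like <- function(pair, x, y) {
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y))
  attr(out, "name") <- pair_name(pair)
  attr(out, "truth") <- pair_truth(pair)
  attr(out, "weight") <- pair_weight(pair)
  gen <- attr(pair, "generator")
  if (!is.null(gen)) attr(out, "generator") <- gen
  class(out) <- c("observed_pair", class(out))
  out
}

#' Swap the two variables of a pair
#'
#' Exchanges `x` and `y` and flips the ground-truth label accordingly; used by
#' antisymmetry checks and mirror-suite benchmarks.
#'
#' @param pair An [observed_pair()].
#' @return The pair with roles of `x` and `y` exchanged.
#' @export
swap_pair <- function(pair) {
  pair <- as_observed_pair(pair)
  truth <- switch(pair_truth(pair),
                  x_causes_y = "y_causes_x",
                  y_causes_x = "x_causes_y",
                  "unknown")
  observed_pair(pair$y, pair$x, name = pair_name(pair), truth = truth,
                weight = pair_weight(pair))
}

#' @export
print.observed_pair <- function(x, ...) {
  cat(sprintf("<observed_pair> %s: n = %d, truth = %s, weight = %g\n",
              pair_name(x), nrow(x), pair_truth(x), pair_weight(x)))
  NextMethod()
}
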