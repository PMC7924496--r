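#' Run protocol for repeated split/fit/score runs
#'
#' @param n_runs Number of repeated random train/test splits (default 100).
#' @param train_fraction Fraction of observations used for training; the
#'   evaluation protocol uses 0.7, 0.5 or 0.3 (default 0.7).
#' @param subsample_cap If not `NULL`, each run first draws (without
#'   replacement) a uniform subsample of at most this many points. `NULL`
#'   (default) disables the cap for cheap families; 500 is used for the
#'   expensive ones (SVR_LIN, NN) by [reci_infer()].
#' @param seed Integer master seed; per-run randomness is derived
#'   deterministically from `(seed, run_index)`.
#' @return A `run_protocol` object.
#' @export
run_protocol <- function(n_runs = 100L, train_fraction = 0.7,
                         subsample_cap = NULL, seed = 1L) {
  if (n_runs < 1) stop("`n_runs` must be positive.", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie in (0, 1).", call. = FALSE)
  }
  if (!is.null(subsample_cap) && subsample_cap < 10) {
    stop("`subsample_cap` must be at least 10.", call. = FALSE)
  }
  structure(list(n_runs = as.integer(n_runs),
                 train_fraction = train_fraction,
                 subsample_cap = if (!is.null(subsample_cap))
                   as.integer(subsample_cap),
                 seed = as.integer(seed)),
            class = "run_protocol")
}

# Deterministic per-run seed below 2^31, a function of (seed, run_index) only
# so runs are order-independent and parallelizable.
run_seed <- function(seed, run_index) {
  m <- 2147483647
  as.integer((abs(as.double(seed)) %% m * 1000003 + as.double(run_index)) %% m)
}

#' Split a pair into train and test once
#'
#' Draws a disjoint exhaustive random partition with
#' `|train| = round(train_fraction * n)`, determined entirely by the
#' protocol seed and the run index.
#'
#' @param pair An [observed_pair()] (n >= 10).
#' @param protocol A [run_protocol()].
#' @param run_index Positive integer identifying the run.
#' @return A list with elements `train` and `test`, both observed pairs.
#' @export
split_pair <- function(pair, protocol, run_index = 1L) {
  pair <- as_observed_pair(pair)
  n <- nrow(pair)
  n_train <- round(protocol$train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  idx <- withr::with_seed(run_seed(protocol$seed, run_index),
                          sample.int(n, n_train))
  list(train = pair_like(pair, pair$x[idx], pair$y[idx]),
       test = pair_like(pair, pair$x[-idx], pair$y[-idx]))
}

#' Test MSE in both regression directions, averaged over runs
#'
#' For each run the pair is split at random, the family is fitted on the
#' training part in both directions (x predicting y and y predicting x), and
#' the test mean squared errors are recorded. Both fits within one run share
#' the run-derived seed and the same split, so swapping the variables exactly
#' mirrors the errors. Run-averaged test errors estimate the two expected
#' conditional variances whose comparison decides the causal direction.
#'
#' @param pair An [observed_pair()], already scaled.
#' @param spec A [family_spec()].
#' @param protocol A [run_protocol()]; if its `subsample_cap` is set and the
#'   pair is larger, each run first draws a uniform subsample of the cap size.
#' @return A `directional_errors` object: per-run tibble plus the two run
#'   means `mean_y_given_x` and `mean_x_given_y`.
#' @export
directional_errors <- function(pair, spec, protocol = run_protocol()) {
  pair <- as_observed_pair(pair)
  one_run <- function(r) {
    rs <- run_seed(protocol$seed, r)
    p <- pair
    cap <- protocol$subsample_cap
    if (!is.null(cap) && nrow(p) > cap) {
      idx <- withr::with_seed(rs + 1L, sample.int(nrow(p), cap))
      p <- pair_like(p, p$x[idx], p$y[idx])
    }
    sp <- split_pair(p, protocol, r)
    spec_r <- spec
    spec_r$seed <- rs
    fwd <- fit_family(spec_r, sp$train$x, sp$train$y)
    bwd <- fit_family(spec_r, sp$train$y, sp$train$x)
    c(mse_y_given_x = model_mse(fwd, sp$test$x, sp$test$y),
      mse_x_given_y = model_mse(bwd, sp$test$y, sp$test$x))
  }
  runs <- purrr::map(seq_len(protocol$n_runs), one_run)
  runs <- tibble::tibble(
    run = seq_len(protocol$n_runs),
    mse_y_given_x = purrr::map_dbl(runs, "mse_y_given_x"),
    mse_x_given_y = purrr::map_dbl(runs, "mse_x_given_y"))
  structure(list(runs = runs,
                 mean_y_given_x = mean(runs$mse_y_given_x),
                 mean_x_given_y = mean(runs$mse_x_given_y),
                 spec = spec, protocol = protocol),
            class = "directional_errors")
}

#' @export
print.directional_errors <- function(x, ...) {
  cat(sprintf(
    "<directional_errors> %s over %d run(s): MSE(y|x) = %.4g, MSE(x|y) = %.4g\n",
    format(x$spec), nrow(x$runs), x$mean_y_given_x, x$mean_x_given_y))
  invisible(x)
}

#' Select the best regression family for a pair
#'
#' Evaluates each candidate with [directional_errors()] and returns the one
#' minimizing the *sum* of the two direction-averaged test MSEs. The summed
#' criterion is direction-symmetric, so model selection cannot itself leak the
#' causal answer. Ties are broken by candidate-list order.
#'
#' @inheritParams directional_errors
#' @param candidates A list of [family_spec()] objects (or compact labels such
#'   as `"POLY:3"`).
#' @return A list with elements `spec` (the winner) and `errors` (its
#'   [directional_errors()]).
#' @export
select_family <- function(pair, candidates, protocol = run_protocol()) {
  if (length(candidates) < 1) {
    stop("Need at least one candidate family.", call. = FALSE)
  }
  candidates <- purrr::map(candidates, function(cand) {
    if (is.character(cand)) parse_family(cand) else cand
  })
  best <- NULL
  failures <- character(0)
  for (cand in candidates) {
    errs <- tryCatch(directional_errors(pair, cand, protocol),
                     error = function(e) e)
    if (inherits(errs, "error")) {
      failures <- c(failures, sprintf("%s: %s", format(cand),
                                      conditionMessage(errs)))
      next
    }
    total <- errs$mean_y_given_x + errs$mean_x_given_y
    if (is.null(best) || total < best$total) {
      best <- list(spec = cand, errors = errs, total = total)
    }
  }
  if (is.null(best)) {
    stop("All candidate families failed:\n",
         paste(failures, collapse = "\n"), call. = FALSE)
  }
  best[c("spec", "errors")]
}

#' Error-ratio confidence of a direction decision
#'
#' `1 - min(e1, e2) / max(e1, e2)`: 0 when the two direction-averaged errors
#' are equal, approaching 1 as one direction's error dominates.
#'
#' @param mean_y_given_x,mean_x_given_y Nonnegative run-averaged test MSEs,
#'   not both zero.
#' @return A confidence in `[0, 1]`.
#' @examples
#' reci_confidence(0.01, 0.02)
#' @export
reci_confidence <- function(mean_y_given_x, mean_x_given_y) {
  e <- c(mean_y_given_x, mean_x_given_y)
  if (any(e < 0)) stop("Errors must be nonnegative.", call. = FALSE)
  if (all(e == 0)) {
    stop("Confidence undefined: both direction errors are zero.",
         call. = FALSE)
  }
  1 - min(e) / max(e)
}

new_decision <- function(direction, confidence, threshold) {
  structure(list(direction = direction, confidence = confidence,
                 threshold = threshold),
            class = "causal_decision")
}

#' Decide the causal direction from directional errors
#'
#' `decide()` declares the direction with the strictly smaller run-averaged
#' test MSE and returns `"none"` on exact equality.
#' `decide_with_threshold()` additionally rejects the decision when the
#' error-ratio confidence falls below `t` (at `t = 0` the two procedures are
#' equivalent).
#'
#' @param errors A [directional_errors()] object.
#' @return A `causal_decision` with fields `direction` (`"x_causes_y"`,
#'   `"y_causes_x"` or `"none"`), `confidence` and `threshold`.
#' @export
decide <- function(errors) {
  decide_with_threshold(errors, t = 0)
}

#' @rdname decide
#' @param t Confidence threshold in `[0, 1]`; decisions with confidence
#'   `>= t` are kept (boundary inclusive).
#' @export
decide_with_threshold <- function(errors, t = 0) {
  stopifnot(inherits(errors, "directional_errors"))
  if (t < 0 || t > 1) stop("`t` must lie in [0, 1].", call. = FALSE)
  e1 <- errors$mean_y_given_x
  e2 <- errors$mean_x_given_y
  if (e1 == e2) {
    return(new_decision("none", 0, t))
  }
  conf <- reci_confidence(e1, e2)
  if (conf < t) {
    return(new_decision("none", conf, t))
  }
  new_decision(if (e1 < e2) "x_causes_y" else "y_causes_x", conf, t)
}

#' @export
print.causal_decision <- function(x, ...) {
  cat(sprintf("<causal_decision> %s (confidence %.4f, threshold %.2f)\n",
              x$direction, x$confidence, x$threshold))
  invisible(x)
}

#' Infer the causal direction of a two-variable dataset
#'
#' The end-to-end decision procedure: optionally remove low-density points
#' (scale, filter, rescale on the survivors), scale both variables, estimate
#' both directions' run-averaged test MSEs for every candidate family, select
#' the candidate with the smallest direction-summed error, and decide the
#' direction with the error-ratio confidence attached.
#'
#' @param data A two-column data frame or [observed_pair()]; first column is
#'   `x`, second `y`.
#' @param candidates Candidate families: a list of [family_spec()] objects or
#'   compact labels (default `"POLY:3"`).
#' @param protocol A [run_protocol()].
#' @param scale `"minmax"` (default) or `"zscore"`.
#' @param filter_low_density If `TRUE`, remove points whose joint kernel
#'   density (on the scaled pair) falls below `density_threshold` before
#'   rescaling and fitting.
#' @param density_threshold Density cutoff used when filtering (default 0.1).
#' @param threshold Confidence threshold `t` for rejecting a decision
#'   (default 0: always decide unless the errors tie exactly).
#' @return A `reci_fit` object; see [tidy.reci_fit()], [glance.reci_fit()]
#'   and [autoplot.reci_fit()].
#' @examples
#' pair <- simulate_dependent_pair(kind = "Invertible", alpha = 0.1,
#'                                 n_samples = 300, seed = 2)
#' fit <- reci_infer(pair, candidates = list("POLY:3"),
#'                   protocol = run_protocol(n_runs = 5, seed = 1))
#' glance(fit)
#' @export
reci_infer <- function(data, candidates = list("POLY:3"),
                       protocol = run_protocol(),
                       scale = c("minmax", "zscore"),
                       filter_low_density = FALSE, density_threshold = 0.1,
                       threshold = 0) {
  scale <- match.arg(scale)
  pair <- as_observed_pair(data)
  n_input <- nrow(pair)
  if (filter_low_density) {
    pair <- remove_low_density(scale_pair(pair, scale),
                               threshold = density_threshold)
  }
  pair <- scale_pair(pair, scale)
  candidates <- purrr::map(candidates, function(cand) {
    if (is.character(cand)) parse_family(cand) else cand
  })
  # expensive families default to the 500-point per-run cap
  protocols <- purrr::map(candidates, function(cand) {
    if (is.null(protocol$subsample_cap) &&
        cand$family %in% c("SVR_LIN", "NN")) {
      pr <- protocol
      pr$subsample_cap <- 500L
      pr
    } else {
      protocol
    }
  })
  best <- NULL
  failures <- character(0)
  for (i in seq_along(candidates)) {
    errs <- tryCatch(directional_errors(pair, candidates[[i]],
                                        protocols[[i]]),
                     error = function(e) e)
    if (inherits(errs, "error")) {
      failures <- c(failures, sprintf("%s: %s", format(candidates[[i]]),
                                      conditionMessage(errs)))
      next
    }
    total <- errs$mean_y_given_x + errs$mean_x_given_y
    if (is.null(best) || total < best$total) {
      best <- list(spec = candidates[[i]], errors = errs, total = total)
    }
  }
  if (is.null(best)) {
    stop("All candidate families failed:\n",
         paste(failures, collapse = "\n"), call. = FALSE)
  }
  decision <- decide_with_threshold(best$errors, threshold)
  structure(list(pair = pair, n_input = n_input, spec = best$spec,
                 errors = best$errors, decision = decision,
                 scale = scale, filtered = filter_low_density),
            class = "reci_fit")
}

#' @export
print.reci_fit <- function(x, ...) {
  cat(sprintf(
    "<reci_fit> %s: %s (xi = %.4f)\n  family %s, MSE(y|x) = %.4g, MSE(x|y) = %.4g over %d run(s)\n",
    pair_name(x$pair), x$decision$direction, x$decision$confidence,
    format(x$spec), x$errors$mean_y_given_x, x$errors$mean_x_given_y,
    nrow(x$errors$runs)))
  invisible(x)
}
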