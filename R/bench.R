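parse_numeric_fields <- function(lines, path, min_fields, max_fields = NULL) {
  lines <- lines[nzchar(trimws(lines))]
  purrr::imap(lines, function(line, i) {
    fields <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (!is.null(max_fields) && length(fields) > max_fields) {
      stop(sprintf(
        "%s line %d has %d columns; only two-variable pairs are supported ",
        path, i, length(fields)), "(multivariate pairs are out of scope).",
        call. = FALSE)
    }
    if (length(fields) < min_fields) {
      stop(sprintf("%s line %d has %d field(s); expected at least %d.",
                   path, i, length(fields), min_fields), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop(sprintf("%s line %d: cannot parse '%s' as a number.",
                   path, i, fields[which(is.na(vals))[1]]), call. = FALSE)
    }
    vals
  })
}

#' Read a two-column cause-effect pair file
#'
#' Reads one whitespace-delimited pair file in the Tuebingen cause-effect
#' pair layout: one observation per row, exactly two numeric fields
#' (scientific notation accepted). Files with more columns are rejected,
#' mirroring the exclusion of multivariate datasets from the benchmark.
#'
#' @param path File path.
#' @param name Pair label (defaults to the file name without extension).
#' @param truth Ground-truth direction if known.
#' @param weight Benchmark weight.
#' @return An [observed_pair()].
#' @export
read_pair_file <- function(path, name = NULL, truth = "unknown",
                           weight = 1) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  rows <- parse_numeric_fields(readLines(path), path,
                               min_fields = 2, max_fields = 2)
  if (length(rows) < 10) {
    stop(sprintf("%s has only %d rows; need at least 10.", path,
                 length(rows)), call. = FALSE)
  }
  m <- do.call(rbind, rows)
  observed_pair(m[, 1], m[, 2], name = name, truth = truth, weight = weight)
}

#' Read a pair metadata file
#'
#' Parses the pairmeta layout: one row per pair with six whitespace-delimited
#' fields — pair id, cause column start and end, effect column start and end,
#' weight. Pairs whose cause or effect spans more than one column are
#' multivariate and rejected.
#'
#' @param path File path.
#' @return A tibble with columns `pair`, `cause_column` (1 or 2), `truth`,
#'   `weight`.
#' @export
read_pairmeta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (length(fields) != 6) {
      stop(sprintf("%s line %d has %d field(s); expected 6.", path, i,
                   length(fields)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields[2:6]))
    if (any(is.na(vals))) {
      stop(sprintf("%s line %d: cannot parse metadata fields as numbers.",
                   path, i), call. = FALSE)
    }
    if (vals[1] != vals[2] || vals[3] != vals[4]) {
      stop(sprintf(
        "%s line %d: cause/effect spans more than one column; ", path, i),
        "multivariate pairs are out of scope.", call. = FALSE)
    }
    if (!vals[1] %in% c(1, 2) || !vals[3] %in% c(1, 2) ||
        vals[1] == vals[3]) {
      stop(sprintf("%s line %d: cause/effect columns must be 1 and 2.",
                   path, i), call. = FALSE)
    }
    tibble::tibble(pair = fields[1], cause_column = as.integer(vals[1]),
                   truth = if (vals[1] == 1) "x_causes_y" else "y_causes_x",
                   weight = vals[5])
  })
  dplyr::bind_rows(rows)
}

#' Weighted accuracy of direction decisions
#'
#' Computes `sum(w_m * delta(dhat_m, d_m)) / sum(w_m)` over the datasets of a
#' benchmark: the weight-normalized fraction of correctly inferred
#' directions.
#'
#' @param rows A data frame with columns `decision`, `truth` and `weight`
#'   (e.g. from [tidy.reci_benchmark()]).
#' @param forced If `TRUE` (default), rows with decision `"none"` count as
#'   incorrect (a decision was forced); if `FALSE` they are excluded from
#'   both numerator and denominator.
#' @return The weighted accuracy in `[0, 1]`.
#' @export
weighted_accuracy <- function(rows, forced = TRUE) {
  stopifnot(all(c("decision", "truth", "weight") %in% names(rows)))
  if (!forced) {
    rows <- dplyr::filter(rows, .data$decision != "none")
  }
  total <- sum(rows$weight)
  if (nrow(rows) == 0 || total <= 0) {
    stop("Undefined accuracy: total weight is zero.", call. = FALSE)
  }
  sum(rows$weight * (rows$decision == rows$truth)) / total
}

#' Accuracy as a function of forced decision rate
#'
#' For each decision rate `r`, keeps the `ceiling(r * M)` datasets with the
#' highest confidence (ties broken by dataset order) and computes the
#' weighted accuracy of the forced decisions on that subset. Plotting
#' accuracy against decision rate shows whether the error-ratio confidence
#' ranks correct decisions first.
#'
#' @param rows A data frame with columns `decision`, `truth`, `weight` and
#'   `confidence`.
#' @param rates Decision rates in `(0, 1]` (default `seq(0.1, 1, 0.1)`).
#' @return A tibble with columns `decision_rate`, `n_kept`, `accuracy`.
#' @export
decision_rate_curve <- function(rows, rates = seq(0.1, 1, by = 0.1)) {
  stopifnot("confidence" %in% names(rows))
  m <- nrow(rows)
  ord <- order(-rows$confidence)  # stable: ties keep dataset order
  purrr::map_dfr(rates, function(r) {
    k <- min(m, ceiling(r * m))
    kept <- rows[ord[seq_len(k)], ]
    tibble::tibble(decision_rate = r, n_kept = k,
                   accuracy = weighted_accuracy(kept, forced = TRUE))
  })
}

#' Benchmark the decision procedure over a suite of pairs
#'
#' Applies the full pipeline — optional low-density filtering, scaling,
#' candidate-family selection and the direction decision — to every pair of a
#' suite, then assembles the weighted accuracy and the decision-rate curve.
#' Per-pair failures are recorded as decision `"none"` with the error message
#' and never abort the suite.
#'
#' @param suite A list of [observed_pair()] objects (e.g. from
#'   [simulate_suite()] or [read_pair_file()]).
#' @param candidates Candidate families as in [reci_infer()].
#' @param protocol A [run_protocol()].
#' @param scale `"minmax"` or `"zscore"`.
#' @param filter_low_density,density_threshold Low-density filtering options.
#' @param threshold Confidence threshold for rejecting decisions.
#' @param rates Decision rates for the accuracy curve.
#' @return A `reci_benchmark` object; `tidy()` gives the per-dataset rows,
#'   `glance()` the weighted accuracy, `autoplot()` the decision-rate curve.
#' @export
run_benchmark <- function(suite, candidates = list("POLY:3"),
                          protocol = run_protocol(),
                          scale = c("minmax", "zscore"),
                          filter_low_density = FALSE,
                          density_threshold = 0.1, threshold = 0,
                          rates = seq(0.1, 1, by = 0.1)) {
  if (length(suite) == 0) stop("Empty suite.", call. = FALSE)
  if (length(candidates) == 0) {
    stop("Configuration error: empty candidate list.", call. = FALSE)
  }
  scale <- match.arg(scale)
  rows <- purrr::map_dfr(suite, function(pair) {
    pair <- as_observed_pair(pair)
    fit <- tryCatch(
      reci_infer(pair, candidates = candidates, protocol = protocol,
                 scale = scale, filter_low_density = filter_low_density,
                 density_threshold = density_threshold,
                 threshold = threshold),
      error = function(e) e)
    if (inherits(fit, "error")) {
      tibble::tibble(name = pair_name(pair), decision = "none",
                     confidence = 0, truth = pair_truth(pair),
                     weight = pair_weight(pair), family = NA_character_,
                     mse_y_given_x = NA_real_, mse_x_given_y = NA_real_,
                     note = conditionMessage(fit))
    } else {
      tibble::tibble(name = pair_name(pair),
                     decision = fit$decision$direction,
                     confidence = fit$decision$confidence,
                     truth = pair_truth(pair), weight = pair_weight(pair),
                     family = format(fit$spec),
                     mse_y_given_x = fit$errors$mean_y_given_x,
                     mse_x_given_y = fit$errors$mean_x_given_y,
                     note = NA_character_)
    }
  })
  structure(list(rows = rows,
                 weighted_accuracy = weighted_accuracy(rows, forced = TRUE),
                 curve = decision_rate_curve(rows, rates),
                 protocol = protocol, scale = scale,
                 threshold = threshold),
            class = "reci_benchmark")
}

#' @export
print.reci_benchmark <- function(x, ...) {
  cat(sprintf("<reci_benchmark> %d dataset(s), weighted accuracy %.3f\n",
              nrow(x$rows), x$weighted_accuracy))
  invisible(x)
}
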