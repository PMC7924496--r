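#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted direction inference
#'
#' @param x A `reci_fit` from [reci_infer()].
#' @param ... Unused.
#' @return One row per run and direction: columns `run`, `direction`
#'   (`"y_given_x"` / `"x_given_y"`) and `mse`.
#' @export
tidy.reci_fit <- function(x, ...) {
  tidyr::pivot_longer(x$errors$runs, -"run", names_to = "direction",
                      names_prefix = "mse_", values_to = "mse")
}

#' @rdname tidy.reci_fit
#' @return For `glance()`: a one-row tibble with the pair name, selected
#'   family, both run-averaged MSEs, the decision, confidence and threshold.
#' @export
glance.reci_fit <- function(x, ...) {
  tibble::tibble(name = pair_name(x$pair), family = format(x$spec),
                 n = x$n_input, n_used = nrow(x$pair),
                 n_runs = nrow(x$errors$runs),
                 mse_y_given_x = x$errors$mean_y_given_x,
                 mse_x_given_y = x$errors$mean_x_given_y,
                 direction = x$decision$direction,
                 confidence = x$decision$confidence,
                 threshold = x$decision$threshold)
}

#' Plot the per-run error distributions of a fitted inference
#'
#' Boxplots of the per-run test MSE in both regression directions; the
#' direction with the lower run-averaged error is the inferred causal
#' direction.
#'
#' @param object A `reci_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reci_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$direction, y = .data$mse)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(
      x = NULL, y = "test MSE per run",
      title = sprintf("%s: %s (confidence %.3f)", pair_name(object$pair),
                      object$decision$direction,
                      object$decision$confidence)) +
    ggplot2::theme_minimal()
}

#' Tidy a benchmark result
#'
#' @param x A `reci_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return The per-dataset rows: name, decision, confidence, truth, weight,
#'   selected family, both mean MSEs and a failure note when applicable.
#' @export
tidy.reci_benchmark <- function(x, ...) x$rows

#' @rdname tidy.reci_benchmark
#' @return For `glance()`: one row with the number of datasets, the forced
#'   weighted accuracy and the accuracy excluding no-decisions.
#' @export
glance.reci_benchmark <- function(x, ...) {
  nondeg <- x$rows$decision != "none"
  tibble::tibble(
    n_datasets = nrow(x$rows),
    n_decided = sum(nondeg),
    weighted_accuracy = x$weighted_accuracy,
    accuracy_decided = if (any(nondeg)) {
      weighted_accuracy(x$rows, forced = FALSE)
    } else {
      NA_real_
    })
}

#' Plot the decision-rate curve of a benchmark
#'
#' @param object A `reci_benchmark`.
#' @param ... Unused.
#' @return A ggplot of weighted accuracy against forced decision rate.
#' @export
autoplot.reci_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$decision_rate,
                               y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "decision rate", y = "weighted accuracy") +
    ggplot2::theme_minimal()
}

#' Tidy a theory verification report
#'
#' @param x A `theory_report` from [convergence_report()].
#' @param ... Unused.
#' @return One row per noise level: `alpha`, empirical `ratio`, its
#'   Monte-Carlo standard error and the quadrature limit value.
#' @export
tidy.theory_report <- function(x, ...) {
  dplyr::mutate(x$ratios, limit = x$lemma1_value)
}

#' @rdname tidy.theory_report
#' @return For `glance()`: one row with the quadrature limit, the postulate
#'   covariance and whether the theorem bound held at the smallest noise
#'   level.
#' @export
glance.theory_report <- function(x, ...) {
  tibble::tibble(lemma1_value = x$lemma1_value,
                 postulate_cov = x$postulate_cov,
                 bound_satisfied = x$bound_satisfied)
}

#' Plot empirical variance ratios against the quadrature limit
#'
#' @param object A `theory_report`.
#' @param ... Unused.
#' @return A ggplot of the empirical anticausal/causal variance ratio per
#'   noise level, with the quadrature limit and the bound of 1 as reference
#'   lines.
#' @export
autoplot.theory_report <- function(object, ...) {
  ggplot2::ggplot(object$ratios,
                  ggplot2::aes(x = .data$alpha, y = .data$ratio)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ratio - 2 * .data$se,
                                          ymax = .data$ratio + 2 * .data$se)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$lemma1_value,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "noise level alpha (decreasing)",
                  y = "anticausal / causal variance ratio") +
    ggplot2::theme_minimal()
}
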