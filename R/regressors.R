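#' Specify a regression family
#'
#' The candidate families used to estimate the conditional expectation in each
#' direction by least squares:
#' \describe{
#'   \item{LOG}{logistic curve `a + (b - a) / (1 + exp(c * (d - x)))`,}
#'   \item{MON}{shifted monomial `a * x^n + b` with exponent `n` in 2..9,}
#'   \item{POLY}{polynomial `sum_i a_i x^i` of degree `k` in 1..9,}
#'   \item{SVR_LIN}{support-vector regression with a linear kernel,}
#'   \item{NN}{a small dense feedforward network with hidden layout one of
#'     2, 5, 10, 20, 2-4 or 4-8.}
#' }
#'
#' @param family One of `"LOG"`, `"MON"`, `"POLY"`, `"SVR_LIN"`, `"NN"`.
#' @param order Integer exponent/degree for MON (2..9) or POLY (1..9).
#' @param hidden Integer vector of hidden-layer widths for NN; must be one of
#'   `2`, `5`, `10`, `20`, `c(2, 4)`, `c(4, 8)`.
#' @param seed Integer seed controlling random restarts / initialization.
#' @param cost,epsilon SVR_LIN hyperparameters (regularization and
#'   epsilon-tube half-width).
#' @return A `family_spec` object.
#' @examples
#' family_spec("POLY", order = 3)
#' parse_family("NN:4-8")
#' @export
family_spec <- function(family = c("LOG", "MON", "POLY", "SVR_LIN", "NN"),
                        order = NULL, hidden = NULL, seed = 1L,
                        cost = 1, epsilon = 0.1) {
  family <- match.arg(family)
  nn_menu <- list(2L, 5L, 10L, 20L, c(2L, 4L), c(4L, 8L))
  if (family == "MON") {
    if (is.null(order) || !(order %in% 2:9)) {
      stop("MON requires an exponent `order` in 2..9.", call. = FALSE)
    }
  } else if (family == "POLY") {
    if (is.null(order) || !(order %in% 1:9)) {
      stop("POLY requires a degree `order` in 1..9.", call. = FALSE)
    }
  } else if (family == "NN") {
    hidden <- as.integer(hidden)
    ok <- any(vapply(nn_menu, function(h) identical(h, hidden), logical(1)))
    if (!ok) {
      stop("NN requires `hidden` to be one of 2, 5, 10, 20, 2-4, 4-8.",
           call. = FALSE)
    }
  }
  structure(
    list(family = family,
         order = if (family %in% c("MON", "POLY")) as.integer(order),
         hidden = if (family == "NN") hidden,
         seed = as.integer(seed), cost = cost, epsilon = epsilon),
    class = "family_spec")
}

#' @rdname family_spec
#' @param label A compact family label such as `"POLY:3"`, `"MON:2"`,
#'   `"NN:4-8"`, `"LOG"` or `"SVR_LIN"` (as used in run configurations).
#' @export
parse_family <- function(label, seed = 1L) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  fam <- parts[1]
  arg <- if (length(parts) > 1) parts[2] else NULL
  if (fam == "NN") {
    family_spec("NN", hidden = as.integer(strsplit(arg, "-")[[1]]),
                seed = seed)
  } else if (fam %in% c("MON", "POLY")) {
    family_spec(fam, order = as.integer(arg), seed = seed)
  } else {
    family_spec(fam, seed = seed)
  }
}

#' @export
format.family_spec <- function(x, ...) {
  switch(x$family,
         MON = paste0("MON:", x$order),
         POLY = paste0("POLY:", x$order),
         NN = paste0("NN:", paste(x$hidden, collapse = "-")),
         x$family)
}

#' @export
print.family_spec <- function(x, ...) {
  cat("<family_spec>", format(x), "\n")
  invisible(x)
}

logistic_eval <- function(par, x) {
  par[1] + (par[2] - par[1]) / (1 + exp(par[3] * (par[4] - x)))
}

fit_logistic <- function(x, y, seed, restarts = 5L) {
  df <- data.frame(x = x, y = y)
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      start <- list(a = min(y) + stats::runif(1, -0.1, 0.1),
                    b = max(y) + stats::runif(1, -0.1, 0.1),
                    c = stats::runif(1, 0.5, 15),
                    d = stats::runif(1, min(x), max(x)))
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ a + (b - a) / (1 + exp(c * (d - x))),
          data = df, start = start,
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss) {
          best <- list(par = stats::coef(fit), rss = rss)
        }
      }
    }
  })
  if (is.null(best)) {
    stop("LOG fit failed to converge from any of the restart seeds.",
         call. = FALSE)
  }
  unname(best$par)
}

# Flatten/unflatten net weights; layout is input(1) -> hidden... -> output(1),
# tanh hidden activations, linear output.
nn_layout <- function(hidden) {
  sizes <- c(1L, hidden, 1L)
  purrr::map(seq_len(length(sizes) - 1), function(l) {
    c(inp = sizes[l], out = sizes[l + 1])
  })
}

nn_npar <- function(hidden) {
  sum(vapply(nn_layout(hidden), function(d) (d[["inp"]] + 1) * d[["out"]],
             numeric(1)))
}

nn_forward <- function(par, x, hidden, keep = FALSE) {
  a <- matrix(x, ncol = 1)
  acts <- list(a)
  pos <- 0L
  layers <- nn_layout(hidden)
  nl <- length(layers)
  for (l in seq_len(nl)) {
    d <- layers[[l]]
    np <- d[["inp"]] * d[["out"]]
    w <- matrix(par[pos + seq_len(np)], d[["inp"]], d[["out"]])
    b <- par[pos + np + seq_len(d[["out"]])]
    pos <- pos + np + d[["out"]]
    z <- sweep(a %*% w, 2, b, "+")
    a <- if (l < nl) tanh(z) else z
    if (keep) acts[[l + 1]] <- a
  }
  if (keep) acts else as.numeric(a)
}

nn_obj <- function(par, x, y, hidden) {
  mean((y - nn_forward(par, x, hidden))^2)
}

nn_grad <- function(par, x, y, hidden) {
  layers <- nn_layout(hidden)
  nl <- length(layers)
  acts <- nn_forward(par, x, hidden, keep = TRUE)
  n <- length(x)
  # backprop of mean squared error
  delta <- 2 * (acts[[nl + 1]] - matrix(y, ncol = 1)) / n
  grad <- numeric(length(par))
  offs <- c(0, cumsum(vapply(layers, function(d)
    (d[["inp"]] + 1) * d[["out"]], numeric(1))))
  for (l in rev(seq_len(nl))) {
    d <- layers[[l]]
    np <- d[["inp"]] * d[["out"]]
    gw <- t(acts[[l]]) %*% delta
    gb <- colSums(delta)
    grad[offs[l] + seq_len(np)] <- as.numeric(gw)
    grad[offs[l] + np + seq_len(d[["out"]])] <- gb
    if (l > 1) {
      w <- matrix(par[offs[l] + seq_len(np)], d[["inp"]], d[["out"]])
      delta <- (delta %*% t(w)) * (1 - acts[[l]]^2)
    }
  }
  grad
}

fit_nn <- function(x, y, hidden, seed, maxit = 2000L) {
  npar <- nn_npar(hidden)
  init <- withr::with_seed(seed, stats::runif(npar, -0.5, 0.5))
  opt <- stats::optim(init, nn_obj, nn_grad, x = x, y = y, hidden = hidden,
                      method = "BFGS", control = list(maxit = maxit))
  opt$par
}

#' Fit a regression family by least squares
#'
#' Estimates the family's parameters by (approximately, for the nonconvex
#' families) minimizing the mean squared error of its functional form. The fit
#' is deterministic given the spec's seed: LOG uses 5 seeded random restarts
#' of Levenberg-Marquardt nonlinear least squares, MON and POLY are exact
#' ordinary least squares, SVR_LIN is a linear-kernel support-vector fit with
#' fixed hyperparameters, and NN is a seeded full-batch gradient fit with a
#' 2000-iteration budget.
#'
#' @param spec A [family_spec()].
#' @param x,y Equal-length numeric vectors; `x` should already be scaled to a
#'   bounded range.
#' @return A `reci_model` with elements `spec`, `parameters`, `train_mse`.
#' @examples
#' m <- fit_family(family_spec("POLY", order = 1), 1:10 / 10, 2 * (1:10 / 10) + 1)
#' predict(m, c(0, 1))
#' @export
fit_family <- function(spec, x, y) {
  stopifnot(inherits(spec, "family_spec"))
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("Unequal lengths.", call. = FALSE)
  min_n <- switch(spec$family, MON = 4L, POLY = spec$order + 2L, 4L)
  if (length(x) < min_n) {
    stop("Too few observations to fit ", format(spec), ".", call. = FALSE)
  }
  fitobj <- NULL
  parameters <- switch(
    spec$family,
    POLY = {
      X <- outer(x, seq_len(spec$order), "^")
      co <- stats::coef(stats::lm.fit(cbind(1, X), y))
      co[is.na(co)] <- 0  # rank-deficient design: dropped terms contribute 0
      unname(co)
    },
    MON = {
      co <- stats::coef(stats::lm.fit(cbind(x^spec$order, 1), y))
      co[is.na(co)] <- 0
      unname(co)  # (a, b)
    },
    LOG = fit_logistic(x, y, spec$seed),
    SVR_LIN = {
      fitobj <- e1071::svm(matrix(x, ncol = 1), y, kernel = "linear",
                           cost = spec$cost, epsilon = spec$epsilon,
                           scale = FALSE, type = "eps-regression")
      # collapse to slope/intercept: w = sum(alpha_i * x_i), b = -rho
      w <- as.numeric(t(fitobj$coefs) %*% fitobj$SV)
      c(w, -fitobj$rho)
    },
    NN = fit_nn(x, y, spec$hidden, spec$seed)
  )
  if (any(!is.finite(parameters))) {
    stop("Fit produced non-finite parameters for ", format(spec), ".",
         call. = FALSE)
  }
  model <- structure(list(spec = spec, parameters = parameters,
                          fit = fitobj, train_mse = NA_real_),
                     class = "reci_model")
  model$train_mse <- model_mse(model, x, y)
  model
}

#' Predict from a fitted regression family
#'
#' @param object A `reci_model` from [fit_family()].
#' @param x Numeric vector of predictor values.
#' @param ... Unused.
#' @return Elementwise evaluation of the fitted functional form at `x`.
#' @export
predict.reci_model <- function(object, x, ...) {
  x <- as.numeric(x)
  p <- object$parameters
  switch(object$spec$family,
         POLY = drop(cbind(1, outer(x, seq_len(object$spec$order), "^")) %*% p),
         MON = p[1] * x^object$spec$order + p[2],
         LOG = logistic_eval(p, x),
         SVR_LIN = p[1] * x + p[2],
         NN = nn_forward(p, x, object$spec$hidden))
}

#' Mean squared prediction error
#'
#' @param model A `reci_model`.
#' @param x,y Equal-length numeric vectors.
#' @return `mean((y - predict(model, x))^2)`.
#' @export
model_mse <- function(model, x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 1) {
    stop("`x` and `y` must be nonempty and of equal length.", call. = FALSE)
  }
  mean((y - predict(model, x))^2)
}

#' @export
print.reci_model <- function(x, ...) {
  cat(sprintf("<reci_model> %s, train MSE %.4g\n", format(x$spec),
              x$train_mse))
  invisible(x)
}
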