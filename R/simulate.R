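#' Random monotone function as a mixture of Gaussian CDFs
#'
#' Builds `s(c) = sum_i beta_i * Psi(c | mu_i, sigma_i)` with `Psi` the
#' Gaussian CDF: a convex combination of sigmoidal steps, strictly increasing
#' with range inside `[0, 1]`. With random components this yields arbitrary
#' random monotone shapes; it is the invertible-mechanism generator and also a
#' menu entry for the source-mixing functions.
#'
#' @param n_components Number of mixture components (default 5).
#' @param betas Nonnegative weights summing to 1 (drawn uniform then
#'   normalized when `NULL`).
#' @param mus Component means in `[0, 1]` (drawn uniform when `NULL`).
#' @param sigmas Component standard deviations in `(0, 0.1]` (drawn uniform
#'   when `NULL`).
#' @param seed Integer seed used when any component is drawn.
#' @return A monotone function of one numeric argument, with the component
#'   parameters attached as attributes.
#' @examples
#' s <- cdf_mixture(seed = 1)
#' s(c(0, 0.5, 1))
#' @export
cdf_mixture <- function(n_components = 5L, betas = NULL, mus = NULL,
                        sigmas = NULL, seed = 1L) {
  if (n_components < 1) stop("Need at least one component.", call. = FALSE)
  if (is.null(betas) || is.null(mus) || is.null(sigmas)) {
    drawn <- withr::with_seed(seed, list(
      betas = stats::runif(n_components),
      mus = stats::runif(n_components),
      sigmas = stats::runif(n_components, 1e-3, 0.1)))
    if (is.null(betas)) betas <- drawn$betas / sum(drawn$betas)
    if (is.null(mus)) mus <- drawn$mus
    if (is.null(sigmas)) sigmas <- drawn$sigmas
  }
  if (length(betas) != n_components || length(mus) != n_components ||
      length(sigmas) != n_components) {
    stop("`betas`, `mus`, `sigmas` must all have length `n_components`.",
         call. = FALSE)
  }
  if (any(betas < 0) || abs(sum(betas) - 1) > 1e-12) {
    stop("`betas` must be nonnegative and sum to 1.", call. = FALSE)
  }
  if (any(mus < 0) || any(mus > 1)) {
    stop("`mus` must lie in [0, 1].", call. = FALSE)
  }
  if (any(sigmas <= 0) || any(sigmas > 0.1)) {
    stop("`sigmas` must lie in (0, 0.1].", call. = FALSE)
  }
  f <- function(c) {
    vapply(c, function(ci) sum(betas * stats::pnorm(ci, mus, sigmas)),
           numeric(1))
  }
  attr(f, "betas") <- betas
  attr(f, "mus") <- mus
  attr(f, "sigmas") <- sigmas
  f
}

#' Affine rescaling onto an interval
#'
#' @param v Non-constant numeric vector.
#' @param a,b Target interval endpoints, `a < b`.
#' @return `v` mapped affinely so its minimum is `a` and maximum `b`.
#' @export
rescale_interval <- function(v, a, b) {
  if (a >= b) stop("`a` must be smaller than `b`.", call. = FALSE)
  r <- range(v)
  if (r[2] <= r[1]) {
    stop("Degenerate input: constant vector cannot be rescaled.",
         call. = FALSE)
  }
  a + (v - r[1]) / (r[2] - r[1]) * (b - a)
}

# Source-distribution menu: uniform, three Gaussians (sigma drawn per
# dataset), and a fixed two-component Gaussian mixture. Choosing and sampling
# are separate so the structural draw does not depend on the sample size.
pick_source <- function(sigma) {
  which <- sample.int(5, 1)
  switch(which,
         list(id = 1L, mean = 0.5, label = "U(0,1)"),
         list(id = 2L, mean = 0, label = sprintf("N(0,%.2f^2)", sigma)),
         list(id = 3L, mean = 0.5, label = sprintf("N(0.5,%.2f^2)", sigma)),
         list(id = 4L, mean = 1, label = sprintf("N(1,%.2f^2)", sigma)),
         list(id = 5L, mean = 0.5, label = "GM(0.3/0.7, 0.1)"))
}

sample_source <- function(src, n, sigma) {
  switch(src$id,
         stats::runif(n),
         stats::rnorm(n, 0, sigma),
         stats::rnorm(n, 0.5, sigma),
         stats::rnorm(n, 1, sigma),
         stats::rnorm(n, c(0.3, 0.7)[sample.int(2, n, replace = TRUE)], 0.1))
}

# Mixing-function menu: identity, exp, fresh CDF mixture on the min-max
# mapped input (CDF mixtures need arguments in [0, 1]).
draw_mixing_fun <- function() {
  which <- sample.int(3, 1)
  switch(which,
         list(f = identity, label = "identity"),
         list(f = exp, label = "exp"),
         {
           s5 <- cdf_mixture(seed = sample.int(.Machine$integer.max, 1))
           list(f = function(v) s5(normalize_minmax(v)), label = "s5.minmax")
         })
}

draw_phi <- function(kind) {
  switch(kind,
    Linear = list(f = identity, label = "identity"),
    Invertible = {
      s5 <- cdf_mixture(seed = sample.int(.Machine$integer.max, 1))
      list(f = s5, label = "s5")
    },
    NonInvertible = {
      which <- sample.int(3, 1)
      switch(which,
             list(f = function(c) rescale_interval(c, -2, 2)^2,
                  label = "rescale(-2,2)^2"),
             list(f = function(c) rescale_interval(c, -2, 2)^4,
                  label = "rescale(-2,2)^4"),
             list(f = function(c) sin(rescale_interval(c, -2 * pi, 2 * pi)),
                  label = "sin(rescale(-2pi,2pi))"))
    })
}

#' Simulate a cause-effect pair with dependent noise
#'
#' Generates one pair from the shared-source construction: two hidden sources
#' `S1`, `S2` are drawn i.i.d. from (possibly different) menu distributions
#' and mean-centered; cause and noise are randomly weighted linear
#' combinations of menu functions of the sources,
#' `C' = w1 f1(S1) + (1 - w1) f2(S2)` and `N' = w2 f3(S1) + (1 - w2) f4(S2)`
#' with `w1, w2 ~ U(0, 1)`; then `C = minmax(C')`,
#' `N = alpha * standardize(N')` and `E = phi(C) + N`. Because `C` and `N`
#' share sources they are dependent, violating the independent-noise
#' assumption of additive noise models on purpose.
#'
#' @param kind Mechanism class: `"Linear"` (`phi = identity`),
#'   `"Invertible"` (a fresh random CDF mixture) or `"NonInvertible"` (one of
#'   `rescale(.,-2,2)^2`, `rescale(.,-2,2)^4`, `sin(rescale(.,-2pi,2pi))`).
#' @param alpha Noise level in `[0, 1]`.
#' @param n_samples Number of observations (default 1000).
#' @param seed Integer seed; the pair is reproducible from it.
#' @param name Pair label.
#' @return An [observed_pair()] with `x = C`, `y = E`,
#'   `truth = "x_causes_y"`, and a `generator` attribute recording the drawn
#'   weights, sources, functions and mechanism label.
#' @examples
#' simulate_dependent_pair("Invertible", alpha = 0.2, n_samples = 200, seed = 1)
#' @export
simulate_dependent_pair <- function(kind = c("Linear", "Invertible",
                                             "NonInvertible"),
                                    alpha = 0.2, n_samples = 1000L,
                                    seed = 1L, name = NULL) {
  kind <- match.arg(kind)
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1].",
                                   call. = FALSE)
  if (n_samples < 10) stop("`n_samples` must be at least 10.", call. = FALSE)
  if (is.null(name)) name <- sprintf("%s_a%g_s%d", kind, alpha, seed)

  for (attempt in 0:4) {
    out <- withr::with_seed(run_seed(seed, attempt), {
      # structural draws first, data draws after, so the same seed yields the
      # same mechanism regardless of n_samples
      w1 <- stats::runif(1)
      w2 <- stats::runif(1)
      sigma <- stats::runif(1, 0.5, 1.5)  # Gaussian-source sd, per dataset
      s1 <- pick_source(sigma)
      s2 <- pick_source(sigma)
      fs <- purrr::map(1:4, function(i) draw_mixing_fun())
      phi <- draw_phi(kind)
      S1 <- sample_source(s1, n_samples, sigma) - s1$mean
      S2 <- sample_source(s2, n_samples, sigma) - s2$mean
      Cp <- w1 * fs[[1]]$f(S1) + (1 - w1) * fs[[2]]$f(S2)
      Np <- w2 * fs[[3]]$f(S1) + (1 - w2) * fs[[4]]$f(S2)
      if (diff(range(Cp)) <= 0 || mean((Np - mean(Np))^2) <= 0) {
        NULL  # degenerate draw; retry with perturbed sub-seed
      } else {
        C <- normalize_minmax(Cp)
        N <- if (alpha == 0) rep(0, n_samples) else alpha * standardize(Np)
        E <- phi$f(C) + N
        record <- list(kind = kind, alpha = alpha, seed = seed,
                       w1 = w1, w2 = w2, sigma = sigma,
                       sources = c(s1$label, s2$label),
                       mixing = purrr::map_chr(fs, "label"),
                       phi_label = phi$label, phi = phi$f, C = C, N = N)
        pair <- observed_pair(C, E, name = name, truth = "x_causes_y")
        attr(pair, "generator") <- record
        pair
      }
    })
    if (!is.null(out)) return(out)
  }
  stop("Degenerate cause after 5 attempts; cannot generate pair.",
       call. = FALSE)
}

#' Simulate a pair in the small-noise theorem regime
#'
#' Generates `E = phi(C) + alpha * N` under the assumptions of the
#' error-asymmetry theorem: `phi` strictly increasing on `[0, 1]` with
#' `phi(0) = 0`, `phi(1) = 1`; `C` drawn from a compact-support density on
#' `[0, 1]`; `N | c` uniform on `[-sqrt(3) s(c), sqrt(3) s(c)]` (the simplest
#' compact-support law with controllable variance), with the conditional
#' standard-deviation profile `s(.)` renormalized so that the expected
#' conditional noise variance `E[Var[N|C]]` equals 1.
#'
#' @param phi Strictly increasing function on `[0, 1]` with `phi(0) = 0`,
#'   `phi(1) = 1` (default identity).
#' @param phi_prime Its derivative (used by the theory module; default
#'   constant 1 matching the identity).
#' @param cause_sampler Function `n -> n` draws of `C` in `[0, 1]`
#'   (default `runif`).
#' @param cause_density Density of `C` on `[0, 1]` (default uniform).
#' @param sd_profile Function `c -> sd(N | c)` up to normalization, positive
#'   (default constant 1).
#' @param alpha Positive noise level.
#' @param n_samples Number of observations.
#' @param seed Integer seed.
#' @param name Pair label.
#' @return An [observed_pair()] with `x = C`, `y = E` and a `generator`
#'   attribute recording `phi`, `phi_prime`, the renormalized profile
#'   `cond_sd`, `cause_density`, `alpha` and the noise support bounds
#'   `n_minus < 0 < n_plus`.
#' @examples
#' p <- simulate_theorem_pair(phi = function(c) (c + c^2) / 2,
#'                            phi_prime = function(c) (1 + 2 * c) / 2,
#'                            alpha = 0.05, n_samples = 500, seed = 1)
#' attr(p, "generator")$n_plus
#' @export
simulate_theorem_pair <- function(phi = identity,
                                  phi_prime = function(c) rep(1, length(c)),
                                  cause_sampler = stats::runif,
                                  cause_density = function(c)
                                    rep(1, length(c)),
                                  sd_profile = function(c)
                                    rep(1, length(c)),
                                  alpha = 0.05, n_samples = 1000L,
                                  seed = 1L, name = NULL) {
  if (alpha < 0) stop("`alpha` must be nonnegative.", call. = FALSE)
  if (is.null(name)) name <- sprintf("theorem_a%g_s%d", alpha, seed)
  # renormalize s(.) so E[s(C)^2] = 1 under the cause density (quadrature)
  grid <- seq(0, 1, length.out = 10001)
  w <- simpson_weights(length(grid)) / (length(grid) - 1)
  ev <- sum(w * sd_profile(grid)^2 * cause_density(grid))
  if (!is.finite(ev) || ev <= 0) {
    stop("Noise profile yields zero expected variance.", call. = FALSE)
  }
  s_norm <- function(c) sd_profile(c) / sqrt(ev)
  s_max <- max(s_norm(grid))
  n_plus <- sqrt(3) * s_max
  n_minus <- -n_plus
  pair <- withr::with_seed(seed, {
    C <- cause_sampler(n_samples)
    N <- stats::runif(n_samples, -1, 1) * sqrt(3) * s_norm(C)
    E <- phi(C) + alpha * N
    observed_pair(C, E, name = name, truth = "x_causes_y")
  })
  attr(pair, "generator") <- list(
    phi = phi, phi_prime = phi_prime, cond_sd = s_norm,
    cond_var = function(c) s_norm(c)^2, cause_density = cause_density,
    alpha = alpha, n_minus = n_minus, n_plus = n_plus, seed = seed)
  pair
}

#' Shift and rescale the effect onto the unit interval
#'
#' Maps the effect `e` of the small-noise family onto the same scale as the
#' cause: `(e - alpha * n_minus) / (1 + alpha * n_plus - alpha * n_minus)`,
#' which attains 0 and 1 as its extreme values over the support.
#'
#' @param e Numeric vector of effect values.
#' @param alpha Nonnegative noise level.
#' @param n_minus,n_plus Noise support bounds, `n_minus < n_plus`.
#' @return The rescaled vector.
#' @export
tilde_rescale <- function(e, alpha, n_minus, n_plus) {
  if (alpha < 0) stop("`alpha` must be nonnegative.", call. = FALSE)
  if (n_minus >= n_plus) stop("`n_minus` must be below `n_plus`.",
                              call. = FALSE)
  (e - alpha * n_minus) / (1 + alpha * n_plus - alpha * n_minus)
}

#' Simulate a suite of dependent-noise pairs
#'
#' @inheritParams simulate_dependent_pair
#' @param n_datasets Number of pairs (the evaluation suites use 100 per
#'   noise level).
#' @param seed Master seed; pair `i` uses seed `seed + i - 1`.
#' @return A list of [observed_pair()] objects.
#' @export
simulate_suite <- function(kind = c("Linear", "Invertible", "NonInvertible"),
                           alpha = 0.2, n_datasets = 100L, n_samples = 1000L,
                           seed = 1L) {
  kind <- match.arg(kind)
  purrr::map(seq_len(n_datasets), function(i) {
    simulate_dependent_pair(kind, alpha = alpha, n_samples = n_samples,
                            seed = seed + i - 1L)
  })
}
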