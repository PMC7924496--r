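test_that("CDF mixtures are monotone with range in [0, 1]", {
  s1 <- cdf_mixture(n_components = 1, betas = 1, mus = 0.5, sigmas = 0.1)
  expect_equal(s1(0.5), 0.5)

  # symmetric two-component mixture passes through (0.5, 0.5)
  s2 <- cdf_mixture(n_components = 2, betas = c(0.5, 0.5), mus = c(0.3, 0.7),
                    sigmas = c(0.05, 0.05))
  expect_equal(s2(0.5), 0.5, tolerance = 1e-12)

  grid <- seq(0, 1, length.out = 1000)
  for (seed in 1:5) {
    s <- cdf_mixture(seed = seed)
    v <- s(grid)
    expect_true(all(diff(v) > 0))
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_error(cdf_mixture(n_components = 2, betas = c(0.7, 0.7),
                           mus = c(0.2, 0.8), sigmas = c(0.1, 0.1)),
               "sum to 1")
  expect_error(cdf_mixture(n_components = 1, betas = 1, mus = 0.5,
                           sigmas = 0.5), "0.1")
})

test_that("interval rescaling hits its endpoints exactly", {
  expect_equal(rescale_interval(c(0, 1), -2, 2), c(-2, 2))
  expect_equal(rescale_interval(c(0, 0.5, 1), -2, 2), c(-2, 0, 2))
  withr::with_seed(1, v <- stats::rnorm(50))
  out <- rescale_interval(v, -3, 7)
  expect_equal(range(out), c(-3, 7))
  expect_error(rescale_interval(rep(1, 5), 0, 1), "Degenerate")
})

test_that("dependent pairs honor the printed generative equations", {
  # zero noise: effect is exactly the mechanism of the cause
  p0 <- simulate_dependent_pair("Invertible", alpha = 0, n_samples = 400,
                                seed = 2)
  g0 <- attr(p0, "generator")
  expect_equal(p0$y, g0$phi(p0$x), tolerance = 1e-15)

  # cause is min-max normalized
  for (seed in 1:5) {
    p <- simulate_dependent_pair("NonInvertible", alpha = 0.3,
                                 n_samples = 200, seed = seed)
    expect_equal(range(p$x), c(0, 1))
    expect_identical(pair_truth(p), "x_causes_y")
  }

  # residual variance is alpha^2 (noise is alpha times a standardized term)
  p4 <- simulate_dependent_pair("Invertible", alpha = 0.4, n_samples = 10000,
                                seed = 4)
  g4 <- attr(p4, "generator")
  resid <- p4$y - g4$phi(p4$x)
  expect_equal(mean((resid - mean(resid))^2), 0.16, tolerance = 0.016)
})

test_that("pairs are bit-identical under the same seed", {
  a <- simulate_dependent_pair("Linear", alpha = 0.5, n_samples = 300,
                               seed = 99)
  b <- simulate_dependent_pair("Linear", alpha = 0.5, n_samples = 300,
                               seed = 99)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  c1 <- simulate_theorem_pair(alpha = 0.1, n_samples = 300, seed = 7)
  c2 <- simulate_theorem_pair(alpha = 0.1, n_samples = 300, seed = 7)
  expect_identical(c1$y, c2$y)
})

test_that("shared sources create cause-noise dependence in the Linear suite", {
  frac <- mean(vapply(1:100, function(seed) {
    p <- simulate_dependent_pair("Linear", alpha = 1, n_samples = 10000,
                                 seed = seed)
    g <- attr(p, "generator")
    abs(stats::cor(g$C, g$N)) > 0.1
  }, logical(1)))
  expect_gte(frac, 0.3)
})

test_that("invertible pairs with noise are non-deterministic given the cause", {
  p <- simulate_dependent_pair("Invertible", alpha = 0.5, n_samples = 20000,
                               seed = 12)
  v <- reci:::binned_expected_conditional_variance(p$x, p$y, 50)$estimate
  expect_gt(v, 0.01)
})

test_that("theorem-regime noise has the assumed conditional structure", {
  # constant profile: Var[N|c] = 1 in every bin, E[Var[N|C]] = 1
  p <- simulate_theorem_pair(alpha = 0.2, n_samples = 1e5, seed = 1)
  g <- attr(p, "generator")
  N <- (p$y - g$phi(p$x)) / g$alpha
  b <- reci:::equal_count_bins(p$x, 50)
  binvars <- tapply(N, b, stats::var)
  expect_true(all(abs(binvars - 1) < 0.2))
  est <- reci:::binned_expected_conditional_variance(p$x, N, 50)$estimate
  expect_equal(est, 1, tolerance = 0.05)

  # centered conditional noise: binned means within 3 standard errors of 0
  binmeans <- tapply(N, b, mean)
  binse <- tapply(N, b, function(v) stats::sd(v) / sqrt(length(v)))
  expect_true(all(abs(binmeans) < 3 * binse))

  # support: all effects inside [alpha*n_minus, 1 + alpha*n_plus]
  expect_true(all(p$y >= g$alpha * g$n_minus - 1e-12))
  expect_true(all(p$y <= 1 + g$alpha * g$n_plus + 1e-12))
})

test_that("profile renormalization drives E[Var[N|C]] to one", {
  p <- simulate_theorem_pair(sd_profile = function(c) 0.2 + 2 * c^2,
                             alpha = 0.1, n_samples = 1e6, seed = 3)
  g <- attr(p, "generator")
  N <- (p$y - g$phi(p$x)) / g$alpha
  est <- reci:::binned_expected_conditional_variance(p$x, N, 100)$estimate
  expect_equal(est, 1, tolerance = 0.02)
  expect_error(simulate_theorem_pair(sd_profile = function(c) 0 * c),
               "zero expected variance")
})

test_that("tilde rescaling maps the effect support onto [0, 1]", {
  e <- c(0.3, 0.7)
  expect_equal(tilde_rescale(e, 0, -1, 1), e)
  expect_equal(tilde_rescale(0.1 * -1, 0.1, -1, 1), 0)
  expect_equal(tilde_rescale(1 + 0.1 * 1, 0.1, -1, 1), 1)
  expect_equal(tilde_rescale(c(-1, 0, 2), 1, -1, 1), c(0, 1, 3) / 3)
  expect_error(tilde_rescale(e, 0.1, 1, -1), "below")
})

test_that("suites carry sequential seeds and the declared size", {
  suite <- simulate_suite("Invertible", alpha = 0.1, n_datasets = 5,
                          n_samples = 50, seed = 10)
  expect_length(suite, 5)
  seeds <- vapply(suite, function(p) attr(p, "generator")$seed, numeric(1))
  expect_equal(seeds, 10:14)
})
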