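# Independent oracles used across the suite.

# O(n^2) double-loop Gaussian product-kernel density sum, evaluated at each
# sample point (the dedicated brute-force counterpart of density_scores).
brute_force_density <- function(x, y, hx, hy) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      s <- s + stats::dnorm((x[i] - x[j]) / hx) *
        stats::dnorm((y[i] - y[j]) / hy)
    }
    out[i] <- s / (n * hx * hy)
  }
  out
}

scott_h <- function(v) stats::sd(v) * length(v)^(-1 / 6)

# Build a directional_errors object directly from two mean errors (for
# decision-rule arithmetic tests that do not need real fits).
make_errors <- function(mean_y_given_x, mean_x_given_y) {
  runs <- tibble::tibble(run = 1L, mse_y_given_x = mean_y_given_x,
                         mse_x_given_y = mean_x_given_y)
  structure(list(runs = runs, mean_y_given_x = mean_y_given_x,
                 mean_x_given_y = mean_x_given_y,
                 spec = family_spec("POLY", order = 1),
                 protocol = run_protocol(n_runs = 1)),
            class = "directional_errors")
}

# A tight cluster plus one far outlier; the density oracle separates them.
cluster_with_outlier <- function(n_cluster = 200, seed = 42) {
  withr::with_seed(seed, {
    x <- c(stats::rnorm(n_cluster, 0.5, 0.03), 5)
    y <- c(stats::rnorm(n_cluster, 0.5, 0.03), 5)
  })
  observed_pair(x, y, name = "cluster+outlier")
}

# Quadratic-mix mechanism used throughout: phi(c) = (c + c^2)/2,
# phi(0) = 0, phi(1) = 1, slope in [1/2, 3/2].
quad_phi <- function(c) (c + c^2) / 2
quad_phi_prime <- function(c) (1 + 2 * c) / 2
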