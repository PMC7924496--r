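# Composite-Simpson weights on a uniform grid of m points (m odd): the
# pattern (1, 4, 2, ..., 4, 1) / 3. Multiplying by the step h integrates.
simpson_weights <- function(m) {
  if (m < 3 || m %% 2 == 0) stop("Simpson grid needs an odd m >= 3.",
                                 call. = FALSE)
  w <- rep(c(4, 2), length.out = m - 2)
  c(1, w[-(m - 2)], 4, 1) / 3
}

simpson_quad <- function(f, m = 10001L) {
  grid <- seq(0, 1, length.out = m)
  h <- 1 / (m - 1)
  sum(simpson_weights(m) * f(grid)) * h
}

# Quadrature with a Richardson-style refinement check: value on m points is
# accepted once the grid-doubled value agrees to rtol; a value that keeps
# growing under refinement is flagged as divergent.
refined_quad <- function(f, m = 10001L, rtol = 1e-6, max_refine = 4L) {
  v <- simpson_quad(f, m)
  for (i in seq_len(max_refine)) {
    m2 <- 2L * (m - 1L) + 1L
    v2 <- simpson_quad(f, m2)
    if (!is.finite(v2)) {
      stop("Nonintegrable mechanism: quadrature diverges.", call. = FALSE)
    }
    if (abs(v2 - v) <= rtol * max(1, abs(v2))) {
      return(v2)
    }
    if (abs(v2) > 10 * abs(v) && abs(v2) > 1e6) {
      stop("Nonintegrable mechanism: value grows without bound under ",
           "grid refinement.", call. = FALSE)
    }
    v <- v2
    m <- m2
  }
  v
}

#' Describe a mechanism for numerical verification
#'
#' Packages the four ingredients of the small-noise theory — the mechanism
#' `phi`, its derivative, the conditional noise variance profile
#' `c -> Var[N|c]`, and the cause density on `[0, 1]` — and checks the
#' normalization constraints by quadrature: the cause density integrates to 1
#' and the expected conditional noise variance is 1.
#'
#' @param phi Strictly increasing function on `[0, 1]` with `phi(0) = 0`,
#'   `phi(1) = 1`.
#' @param phi_prime Its derivative, positive on `(0, 1)`.
#' @param cond_var Function `c -> Var[N|c]`, nonnegative.
#' @param cause_density Density of the cause on `[0, 1]`.
#' @param check If `TRUE` (default), verify the two unit normalizations to
#'   `tol` and that `phi_prime` is positive on the interior.
#' @param tol Quadrature tolerance for the normalization checks.
#' @return A `mechanism_record`.
#' @examples
#' rec <- mechanism_record(function(c) (c + c^2) / 2,
#'                         function(c) (1 + 2 * c) / 2)
#' lemma1_integral(rec)
#' @export
mechanism_record <- function(phi, phi_prime,
                             cond_var = function(c) rep(1, length(c)),
                             cause_density = function(c) rep(1, length(c)),
                             check = TRUE, tol = 1e-6) {
  rec <- structure(list(phi = phi, phi_prime = phi_prime,
                        cond_var = cond_var, cause_density = cause_density),
                   class = "mechanism_record")
  if (check) {
    interior <- seq(1e-6, 1 - 1e-6, length.out = 2001)
    if (any(phi_prime(interior) <= 0)) {
      stop("`phi_prime` must be positive on (0, 1).", call. = FALSE)
    }
    mass <- refined_quad(cause_density, rtol = tol)
    if (abs(mass - 1) > 100 * tol) {
      stop(sprintf("Cause density integrates to %.6f, not 1.", mass),
           call. = FALSE)
    }
    ev <- refined_quad(function(c) cond_var(c) * cause_density(c),
                       rtol = tol)
    if (abs(ev - 1) > 100 * tol) {
      stop(sprintf("Expected conditional noise variance is %.6f, not 1.",
                   ev), call. = FALSE)
    }
  }
  rec
}

# A mechanism record from a theorem-regime pair's generator attribute.
record_from_pair <- function(pair) {
  gen <- attr(pair, "generator")
  if (is.null(gen) || is.null(gen$phi_prime)) {
    stop("Pair carries no theorem-regime generator record.", call. = FALSE)
  }
  mechanism_record(gen$phi, gen$phi_prime, gen$cond_var, gen$cause_density,
                   check = FALSE)
}

#' Limiting anticausal/causal variance ratio by quadrature
#'
#' Computes `int_0^1 Var[N|c] p_C(c) / phi'(c)^2 dc`, the small-noise limit
#' of the ratio of the expected conditional variance in the anticausal
#' direction to that in the causal direction. Under the independence
#' postulate this value is at least 1, with equality only for a linear
#' mechanism — the asymmetry that the decision procedure exploits.
#'
#' @param rec A [mechanism_record()].
#' @param m Uniform grid size for composite Simpson quadrature (odd,
#'   default 10001); the value is refinement-checked to relative `1e-6`.
#' @return The quadrature value.
#' @export
lemma1_integral <- function(rec, m = 10001L) {
  stopifnot(inherits(rec, "mechanism_record"))
  refined_quad(function(c) {
    rec$cond_var(c) * rec$cause_density(c) / rec$phi_prime(c)^2
  }, m = m)
}

#' Covariance of the mechanism slope with the weighted noise variance
#'
#' Computes `int phi' Var[N|c] p_C dc - int phi' dc * int Var[N|c] p_C dc`
#' on the unit interval: the covariance (under the uniform measure) between
#' the slope of the mechanism and the cause-density-weighted conditional
#' noise variance. The independence postulate asserts this is zero; a
#' nonzero value quantifies how strongly a mechanism violates it.
#'
#' @inheritParams lemma1_integral
#' @return The quadrature value of the covariance.
#' @export
postulate_covariance <- function(rec, m = 10001L) {
  stopifnot(inherits(rec, "mechanism_record"))
  joint <- refined_quad(function(c) {
    rec$phi_prime(c) * rec$cond_var(c) * rec$cause_density(c)
  }, m = m)
  slope <- refined_quad(rec$phi_prime, m = m)
  wvar <- refined_quad(function(c) rec$cond_var(c) * rec$cause_density(c),
                       m = m)
  joint - slope * wvar
}

# Equal-count bin assignment of v into `bins` bins (ties broken by order).
equal_count_bins <- function(v, bins) {
  n <- length(v)
  bins <- min(bins, n)
  as.integer(ceiling(rank(v, ties.method = "first") * bins / n))
}

# Within-bin variances of `target` conditioned on equal-count bins of `cond`,
# averaged with bin-probability weights. Returns the estimate and its
# Monte-Carlo standard error (spread of per-bin variances across bins).
binned_expected_conditional_variance <- function(cond, target, bins = 100L) {
  b <- equal_count_bins(cond, bins)
  df <- tibble::tibble(b = b, v = target)
  per <- dplyr::summarise(dplyr::group_by(df, b),
                          var = stats::var(.data$v), n = dplyr::n(),
                          .groups = "drop")
  per <- dplyr::filter(per, .data$n >= 2)
  if (nrow(per) == 0) stop("All bins empty or singletons.", call. = FALSE)
  wts <- per$n / sum(per$n)
  est <- sum(wts * per$var)
  se <- stats::sd(per$var) / sqrt(nrow(per))
  list(estimate = est, se = se)
}

#' Empirical anticausal/causal conditional-variance ratio
#'
#' Nonparametric finite-sample counterpart of [lemma1_integral()]: rescales
#' the effect with [tilde_rescale()], estimates `E[Var[C | E~]]` and
#' `E[Var[E~ | C]]` by equal-count binning (within-bin variance averaged with
#' bin-probability weights), and returns their anticausal/causal ratio.
#'
#' @param pair A theorem-regime [observed_pair()] (from
#'   [simulate_theorem_pair()], whose generator record supplies the noise
#'   support bounds).
#' @param bins Number of equal-count bins (default 100); reduced with a
#'   warning when the sample is too small for 50 points per bin.
#' @return The ratio, with the two estimates and their Monte-Carlo standard
#'   errors attached as attributes `causal`, `anticausal`, `se_ratio`.
#' @export
empirical_ratio <- function(pair, bins = 100L) {
  gen <- attr(pair, "generator")
  if (is.null(gen)) {
    stop("Pair carries no generator record (noise support unknown).",
         call. = FALSE)
  }
  alpha <- gen$alpha
  if (alpha == 0) {
    stop("Undefined ratio: the relation is deterministic (alpha = 0), so ",
         "the causal-direction error is zero.", call. = FALSE)
  }
  n <- nrow(pair)
  if (n < 50 * bins) {
    bins <- max(2L, n %/% 50L)
    warning(sprintf("Sample too small for requested bins; using %d bins.",
                    bins))
  }
  e_tilde <- tilde_rescale(pair$y, alpha, gen$n_minus, gen$n_plus)
  causal <- binned_expected_conditional_variance(pair$x, e_tilde, bins)
  anticausal <- binned_expected_conditional_variance(e_tilde, pair$x, bins)
  if (causal$estimate == 0) {
    stop("Undefined ratio: causal-direction conditional variance is zero.",
         call. = FALSE)
  }
  ratio <- anticausal$estimate / causal$estimate
  se <- ratio * sqrt((anticausal$se / anticausal$estimate)^2 +
                       (causal$se / causal$estimate)^2)
  structure(ratio, causal = causal$estimate,
            anticausal = anticausal$estimate, se_ratio = se)
}

#' Binned check of the causal-direction error scaling
#'
#' Estimates `E[Var[E_alpha | C]]` by equal-count binning on the cause. In
#' the small-noise family this quantity equals `alpha^2` exactly (the noise
#' has unit expected conditional variance), so the estimate divided by
#' `alpha^2` should be close to 1 up to sampling error and within-bin
#' curvature bias.
#'
#' @inheritParams empirical_ratio
#' @return The binned estimate of `E[Var[E_alpha | C]]`.
#' @export
causal_direction_mse_check <- function(pair, bins = 100L) {
  gen <- attr(pair, "generator")
  if (is.null(gen)) {
    stop("Pair carries no generator record.", call. = FALSE)
  }
  if (gen$alpha == 0) return(0)
  binned_expected_conditional_variance(pair$x, pair$y, bins)$estimate
}

#' Numerical verification report for a mechanism
#'
#' Assembles, for one mechanism, the quadrature value of the limiting
#' variance ratio, the independence-postulate covariance, and empirical
#' binned variance-ratio estimates over a grid of decreasing noise levels,
#' together with the check that the smallest-noise ratio respects the
#' theorem's lower bound of 1 within two Monte-Carlo standard errors.
#'
#' @param phi,phi_prime,cause_sampler,cause_density,sd_profile As in
#'   [simulate_theorem_pair()].
#' @param alpha_grid Positive noise levels, decreasing (default
#'   `c(0.2, 0.1, 0.05, 0.02, 0.01)`).
#' @param n Sample size per noise level (default `2e5`).
#' @param bins Equal-count bins for the empirical estimates.
#' @param seed Integer seed.
#' @return A `theory_report` with fields `lemma1_value`, `postulate_cov`,
#'   `ratios` (a tibble of `alpha`, `ratio`, `se`), and `bound_satisfied`.
#' @examples
#' rep <- convergence_report(alpha_grid = c(0.1, 0.05), n = 20000, seed = 1)
#' tidy(rep)
#' @export
convergence_report <- function(phi = identity,
                               phi_prime = function(c) rep(1, length(c)),
                               cause_sampler = stats::runif,
                               cause_density = function(c)
                                 rep(1, length(c)),
                               sd_profile = function(c) rep(1, length(c)),
                               alpha_grid = c(0.2, 0.1, 0.05, 0.02, 0.01),
                               n = 2e5, bins = 100L, seed = 1L) {
  if (any(alpha_grid <= 0) || is.unsorted(rev(alpha_grid), strictly = TRUE)) {
    stop("`alpha_grid` must be positive and strictly decreasing.",
         call. = FALSE)
  }
  # normalized record for the quadrature values
  grid <- seq(0, 1, length.out = 10001)
  w <- simpson_weights(length(grid)) / (length(grid) - 1)
  ev <- sum(w * sd_profile(grid)^2 * cause_density(grid))
  cond_var <- function(c) sd_profile(c)^2 / ev
  rec <- mechanism_record(phi, phi_prime, cond_var, cause_density,
                          check = FALSE)
  lemma1 <- lemma1_integral(rec)
  pcov <- postulate_covariance(rec)
  rows <- purrr::map(seq_along(alpha_grid), function(i) {
    pair <- simulate_theorem_pair(phi, phi_prime, cause_sampler,
                                  cause_density, sd_profile,
                                  alpha = alpha_grid[i], n_samples = n,
                                  seed = run_seed(seed, i))
    r <- empirical_ratio(pair, bins = bins)
    tibble::tibble(alpha = alpha_grid[i], ratio = as.numeric(r),
                   se = attr(r, "se_ratio"))
  })
  ratios <- dplyr::bind_rows(rows)
  last <- ratios[nrow(ratios), ]
  structure(list(lemma1_value = lemma1, postulate_cov = pcov,
                 ratios = ratios,
                 bound_satisfied = last$ratio >= 1 - 2 * last$se),
            class = "theory_report")
}

#' @export
print.theory_report <- function(x, ...) {
  cat(sprintf(
    "<theory_report> limit ratio (quadrature) = %.6f, postulate covariance = %.3g\n",
    x$lemma1_value, x$postulate_cov))
  cat(sprintf("  bound satisfied at smallest alpha: %s\n",
              x$bound_satisfied))
  print(x$ratios)
  invisible(x)
}
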