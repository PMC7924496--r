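test_that("splits are exhaustive, disjoint, sized and reproducible", {
  pair <- observed_pair(1:10, 11:20)
  pr <- run_protocol(n_runs = 3, train_fraction = 0.7, seed = 5)
  sp <- split_pair(pair, pr, 1)
  expect_equal(nrow(sp$train), 7)
  expect_equal(nrow(sp$test), 3)
  expect_length(intersect(sp$train$x, sp$test$x), 0)
  expect_setequal(c(sp$train$x, sp$test$x), pair$x)

  sp2 <- split_pair(pair, pr, 1)
  expect_identical(sp$train$x, sp2$train$x)
  sp3 <- split_pair(pair, pr, 2)
  expect_false(identical(sort(sp$train$x), sort(sp3$train$x)))
})

test_that("directional errors vanish for a realizable forward model", {
  withr::with_seed(1, x <- stats::runif(500))
  pair <- observed_pair(x, x^3)
  errs <- directional_errors(pair, family_spec("POLY", order = 3),
                             run_protocol(n_runs = 10, seed = 1))
  expect_lt(errs$mean_y_given_x, 1e-8)
  expect_gt(errs$mean_x_given_y, errs$mean_y_given_x)
  expect_equal(errs$mean_y_given_x, mean(errs$runs$mse_y_given_x))
})

test_that("a single run populates length-1 run vectors equal to the means", {
  withr::with_seed(2, pair <- observed_pair(stats::runif(60),
                                            stats::runif(60)))
  errs <- directional_errors(pair, family_spec("POLY", order = 1),
                             run_protocol(n_runs = 1, seed = 3))
  expect_equal(nrow(errs$runs), 1)
  expect_equal(errs$mean_y_given_x, errs$runs$mse_y_given_x)
  expect_equal(errs$mean_x_given_y, errs$runs$mse_x_given_y)
})

test_that("each run depends only on (seed, run_index)", {
  withr::with_seed(3, pair <- observed_pair(stats::runif(80),
                                            stats::runif(80)^2))
  pr5 <- run_protocol(n_runs = 5, seed = 9)
  pr3 <- run_protocol(n_runs = 3, seed = 9)
  e5 <- directional_errors(pair, family_spec("POLY", order = 2), pr5)
  e3 <- directional_errors(pair, family_spec("POLY", order = 2), pr3)
  expect_equal(e5$runs[1:3, ], e3$runs)
})

test_that("exchangeable linear pairs give statistically equal errors", {
  withr::with_seed(4, {
    u <- stats::runif(400)
    pair <- observed_pair(u + stats::rnorm(400, sd = 0.1),
                          u + stats::rnorm(400, sd = 0.1))
  })
  errs <- directional_errors(scale_pair(pair), family_spec("POLY", order = 1),
                             run_protocol(n_runs = 30, seed = 1))
  d <- errs$runs$mse_y_given_x - errs$runs$mse_x_given_y
  expect_lt(abs(mean(d)), 2 * stats::sd(d) / sqrt(length(d)))
})

test_that("family selection prefers the realizable candidate and keeps ties", {
  withr::with_seed(5, x <- stats::runif(200))
  pair <- observed_pair(x, x^3)
  pr <- run_protocol(n_runs = 5, seed = 2)
  sel <- select_family(pair, list("POLY:1", "POLY:3"), pr)
  expect_identical(format(sel$spec), "POLY:3")

  one <- select_family(pair, list(family_spec("POLY", order = 2)), pr)
  expect_identical(format(one$spec), "POLY:2")

  # identical candidates tie exactly; the first in the list wins
  a <- family_spec("POLY", order = 3, seed = 1)
  b <- family_spec("POLY", order = 3, seed = 2)
  tie <- select_family(pair, list(a, b), pr)
  expect_identical(tie$spec$seed, a$seed)

  expect_error(select_family(pair, list(), pr), "at least one")
})

test_that("the error-ratio confidence follows 1 - min/max", {
  expect_equal(reci_confidence(0.01, 0.02), 0.5)
  expect_equal(reci_confidence(0.3, 0.3), 0)
  expect_equal(reci_confidence(0, 0.3), 1)
  expect_error(reci_confidence(0, 0), "both direction errors are zero")
  withr::with_seed(6, {
    for (i in 1:20) {
      e <- stats::runif(2)
      conf <- reci_confidence(e[1], e[2])
      expect_gte(conf, 0)
      expect_lte(conf, 1)
      expect_equal(conf, reci_confidence(e[2], e[1]))
    }
  })
})

test_that("decisions follow the smaller averaged error", {
  d1 <- decide(make_errors(0.1, 0.4))
  expect_identical(d1$direction, "x_causes_y")
  expect_equal(d1$confidence, 0.75)

  d2 <- decide(make_errors(0.4, 0.1))
  expect_identical(d2$direction, "y_causes_x")

  d3 <- decide(make_errors(0.2, 0.2))
  expect_identical(d3$direction, "none")
  expect_equal(d3$confidence, 0)
})

test_that("thresholding rejects low-confidence decisions, boundary inclusive", {
  expect_identical(decide_with_threshold(make_errors(0.01, 0.02), 0.6)$direction,
                   "none")
  expect_identical(decide_with_threshold(make_errors(0.01, 0.02), 0.5)$direction,
                   "x_causes_y")
  # t = 0 is identical to the unthresholded rule
  withr::with_seed(7, {
    for (i in 1:25) {
      e <- make_errors(stats::runif(1), stats::runif(1))
      expect_identical(decide(e)$direction,
                       decide_with_threshold(e, 0)$direction)
    }
  })
})

test_that("swapping the variables flips the decision, not the confidence", {
  for (seed in 1:4) {
    pair <- simulate_dependent_pair("Invertible", alpha = 0.2,
                                    n_samples = 300, seed = seed)
    pr <- run_protocol(n_runs = 5, seed = 11)
    f1 <- reci_infer(pair, list("POLY:3"), pr)
    f2 <- reci_infer(swap_pair(pair), list("POLY:3"), pr)
    expect_equal(f1$decision$confidence, f2$decision$confidence)
    expect_equal(f1$errors$mean_y_given_x, f2$errors$mean_x_given_y)
    flipped <- c(x_causes_y = "y_causes_x", y_causes_x = "x_causes_y",
                 none = "none")[[f1$decision$direction]]
    expect_identical(f2$decision$direction, flipped)
  }
})

test_that("noise-free monotone nonlinear pairs are recovered almost surely", {
  hits <- 0L
  pr <- run_protocol(n_runs = 3, seed = 1)
  for (seed in 1:100) {
    x <- withr::with_seed(seed, stats::runif(100))
    pair <- observed_pair(x, x^3, truth = "x_causes_y")
    fit <- reci_infer(pair, list("POLY:3"), pr)
    hits <- hits + (fit$decision$direction == "x_causes_y")
  }
  expect_gte(hits, 95)
})

test_that("tidiers expose runs and the one-row summary", {
  pair <- simulate_dependent_pair("Invertible", alpha = 0.1,
                                  n_samples = 200, seed = 3)
  fit <- reci_infer(pair, list("POLY:2"), run_protocol(n_runs = 4, seed = 1))
  td <- tidy(fit)
  expect_equal(nrow(td), 8)
  expect_setequal(unique(td$direction), c("y_given_x", "x_given_y"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_identical(gl$direction, fit$decision$direction)
  expect_s3_class(autoplot(fit), "ggplot")
})
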