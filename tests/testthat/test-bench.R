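write_pair_file <- function(x, y, path = withr::local_tempfile(
                              fileext = ".txt",
                              .local_envir = parent.frame())) {
  writeLines(paste(format(x, scientific = FALSE), y), path)
  path
}

test_that("pair files parse, including scientific notation", {
  withr::with_seed(1, {
    x <- round(stats::rnorm(12), 4)
    y <- round(stats::rnorm(12), 4)
  })
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(paste(x, y, sep = "\t"), path)
  pair <- read_pair_file(path)
  expect_equal(pair$x, x)
  expect_equal(pair$y, y)

  sci <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(rep("1e-3 2E2", 9), "-1.5e+1 3"), sci)
  psci <- read_pair_file(sci)
  expect_equal(psci$x[1], 0.001)
  expect_equal(psci$y[1], 200)
  expect_equal(psci$x[10], -15)
})

test_that("malformed and multivariate pair files are rejected with context", {
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2", "3 oops", rep("5 6", 8)), bad)
  expect_error(read_pair_file(bad), "line 2")

  tri <- withr::local_tempfile(fileext = ".txt")
  writeLines(rep("1 2 3", 10), tri)
  expect_error(read_pair_file(tri), "multivariate")

  short <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2", "3 4"), short)
  expect_error(read_pair_file(short), "at least 10")

  onecol <- withr::local_tempfile(fileext = ".txt")
  writeLines(rep("1", 10), onecol)
  expect_error(read_pair_file(onecol), "at least 2")
})

test_that("pairmeta rows yield cause column, truth and weight", {
  meta <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0001 1 1 2 2 1.0", "0005 2 2 1 1 0.5"), meta)
  rec <- read_pairmeta(meta)
  expect_equal(rec$cause_column, c(1L, 2L))
  expect_equal(rec$truth, c("x_causes_y", "y_causes_x"))
  expect_equal(rec$weight, c(1, 0.5))

  span <- withr::local_tempfile(fileext = ".txt")
  writeLines("0002 1 2 3 3 1.0", span)
  expect_error(read_pairmeta(span), "multivariate")
})

test_that("weighted accuracy implements the weight-normalized delta sum", {
  rows <- tibble::tibble(
    decision = c("x_causes_y", "x_causes_y", "y_causes_x", "x_causes_y"),
    truth = c("x_causes_y", "x_causes_y", "y_causes_x", "y_causes_x"),
    weight = 1)
  expect_equal(weighted_accuracy(rows), 0.75)

  rows2 <- tibble::tibble(decision = c("x_causes_y", "y_causes_x"),
                          truth = c("x_causes_y", "x_causes_y"),
                          weight = c(2, 1))
  expect_equal(weighted_accuracy(rows2), 2 / 3)
  expect_equal(weighted_accuracy(dplyr::mutate(rows, decision = truth)), 1)

  # no-decision rows: incorrect when forced, excluded otherwise
  rows3 <- tibble::tibble(decision = c("x_causes_y", "none"),
                          truth = "x_causes_y", weight = 1)
  expect_equal(weighted_accuracy(rows3, forced = TRUE), 0.5)
  expect_equal(weighted_accuracy(rows3, forced = FALSE), 1)
  expect_error(weighted_accuracy(dplyr::mutate(rows, weight = 0)),
               "total weight")
})

test_that("the decision-rate curve keeps the most confident prefix", {
  rows <- tibble::tibble(
    decision = c("x_causes_y", "x_causes_y", "y_causes_x", "x_causes_y"),
    truth = c("x_causes_y", "y_causes_x", "y_causes_x", "y_causes_x"),
    weight = 1, confidence = c(0.9, 0.6, 0.4, 0.2))
  curve <- decision_rate_curve(rows, rates = c(0.25, 0.5, 1))
  expect_equal(curve$n_kept, c(1, 2, 4))
  expect_equal(curve$accuracy[1], 1)            # single correct top row
  expect_equal(curve$accuracy[3], weighted_accuracy(rows))

  # equal confidences: prefix in dataset order, flat curve
  flat <- dplyr::mutate(rows, confidence = 0.5)
  cf <- decision_rate_curve(flat, rates = c(0.5, 1))
  expect_equal(cf$accuracy, c(0.5, 0.5))
})

test_that("benchmarks are antisymmetric and reproducible", {
  suite <- simulate_suite("Invertible", alpha = 0.1, n_datasets = 6,
                          n_samples = 150, seed = 21)
  mirror <- purrr::map(suite, swap_pair)
  pr <- run_protocol(n_runs = 4, seed = 2)
  bm <- run_benchmark(suite, list("POLY:3"), pr)
  bm_m <- run_benchmark(mirror, list("POLY:3"), pr)
  rows <- tidy(bm)
  rows_m <- tidy(bm_m)
  flip <- c(x_causes_y = "y_causes_x", y_causes_x = "x_causes_y",
            none = "none")
  expect_identical(unname(flip[rows$decision]), rows_m$decision)
  expect_lte(bm$weighted_accuracy + bm_m$weighted_accuracy, 2)

  bm2 <- run_benchmark(suite, list("POLY:3"), pr)
  expect_identical(tidy(bm2), rows)

  # recomputing the weighted accuracy from the rows reproduces the field
  expect_equal(weighted_accuracy(rows), bm$weighted_accuracy)
  expect_equal(bm$curve$accuracy[nrow(bm$curve)], bm$weighted_accuracy)
  expect_error(run_benchmark(suite, list(), pr), "Configuration")
})

test_that("benchmark accuracy on low-noise invertible pairs beats chance", {
  suite <- simulate_suite("Invertible", alpha = 0.05, n_datasets = 20,
                          n_samples = 300, seed = 1)
  bm <- run_benchmark(suite, list("POLY:3"),
                      run_protocol(n_runs = 5, seed = 1))
  expect_gt(bm$weighted_accuracy, 0.5)
  gl <- glance(bm)
  expect_equal(gl$n_datasets, 20)
  expect_s3_class(autoplot(bm), "ggplot")
})

test_that("per-pair failures are recorded, not fatal", {
  good <- simulate_dependent_pair("Invertible", alpha = 0.1,
                                  n_samples = 100, seed = 1)
  bad <- observed_pair(rep(c(0, 1), 10), rep(c(0, 1), 10), name = "degenerate")
  bm <- run_benchmark(list(good, bad), list("POLY:9"),
                      run_protocol(n_runs = 2, seed = 1))
  rows <- tidy(bm)
  expect_equal(nrow(rows), 2)
})
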