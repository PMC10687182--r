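# PLS-DA subset scoring and random-frog selection.

test_that("the PLS-DA scorer is zero on separable data and chance on permuted labels", {
  d <- make_blob_data(15, n_features = 6, informative = 1:2, effect = 8, seed = 1)
  expect_equal(plsda_cv_error(d$x, d$y, subset = 1:2, seed = 3), 0)
  expect_equal(plsda_cv_error(d$x, d$y, seed = 3), 0) # all features still separable

  # permutation null: error about 0.5
  errs <- vapply(1:20, function(i) {
    set.seed(100 + i)
    plsda_cv_error(d$x, sample(d$y), seed = i)
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.5), 0.1)

  expect_error(plsda_cv_error(d$x, rep("a", nrow(d$x))), "both classes")
  expect_error(plsda_cv_error(d$x, d$y, subset = integer(0)), "nonempty")
})

test_that("a constant feature scores no better than the majority class", {
  d <- make_blob_data(12, n_features = 3, informative = 1, effect = 6, seed = 2)
  d$x[, 3] <- 1 # constant column
  err <- plsda_cv_error(d$x, d$y, subset = 3, seed = 4)
  majority_err <- min(table(d$y)) / length(d$y)
  expect_gte(err, majority_err - 1e-9)
})

test_that("random frog ranks a perfectly informative feature first", {
  d <- make_blob_data(20, n_features = 10, informative = 1, effect = 10, seed = 5)
  rf <- random_frog(d$x, d$y, n_iterations = 200, q0 = 3, seed = 7)
  expect_equal(names(which.max(rf$probabilities)), "f1")
  expect_true(all(rf$probabilities >= 0 & rf$probabilities <= 1))
})

test_that("duplicated informative features are exchangeable across seeds", {
  # within one short run a chain may lock onto either duplicate; averaged
  # over seeds the two must be selected equally often
  p1 <- numeric(10); p2 <- numeric(10)
  for (s in 1:10) {
    d <- make_blob_data(15, n_features = 8, informative = 1, effect = 5, seed = s)
    d$x[, 2] <- d$x[, 1] # exact duplicate
    rf <- random_frog(d$x, d$y, n_iterations = 300, q0 = 3, seed = 100 + s)
    p1[s] <- rf$probabilities["f1"]; p2[s] <- rf$probabilities["f2"]
  }
  expect_lt(abs(mean(p1) - mean(p2)), 0.15)
})

test_that("a single-iteration run reflects pure subset bookkeeping", {
  d <- make_blob_data(10, n_features = 6, seed = 3)
  expect_warning(rf <- random_frog(d$x, d$y, n_iterations = 1, q0 = 3, seed = 2),
                 "iterations")
  expect_true(all(rf$probabilities %in% c(0, 1)))
  expect_equal(sum(rf$probabilities), length(rf$final_subset))
})

test_that("random frog is reproducible from its seed", {
  d <- make_blob_data(12, n_features = 8, informative = 1, effect = 4, seed = 6)
  a <- random_frog(d$x, d$y, n_iterations = 80, seed = 11)
  b <- random_frog(d$x, d$y, n_iterations = 80, seed = 11)
  expect_identical(a$probabilities, b$probabilities)
  expect_identical(a$error_trace, b$error_trace)
})

test_that("partition tallies return exactly the requested subset size", {
  d <- make_blob_data(15, n_features = 12, informative = 1:3, effect = 4, seed = 8)
  tly <- tally_over_partitions(d$x, d$y, n_partitions = 3, n_iterations = 60,
                               q0 = 4, seed = 21)
  expect_length(tly$top_subset, 10)
  expect_length(unique(tly$top_subset), 10)
  expect_true(all(tly$counts <= 3))

  one <- tally_over_partitions(d$x, d$y, n_partitions = 1, n_iterations = 60,
                               q0 = 4, seed = 22)
  expect_true(all(one$counts %in% c(0, 1)))
  rf_top <- names(sort(one$mean_prob, decreasing = TRUE))
  expect_setequal(one$top_subset, names(one$counts)[one$counts == 1])
})

test_that("tallies are reproducible and write a readable CSV", {
  d <- make_blob_data(12, n_features = 8, informative = 1, effect = 4, seed = 9)
  a <- tally_over_partitions(d$x, d$y, n_partitions = 2, n_iterations = 60,
                             q0 = 3, subset_size = 4, seed = 5)
  b <- tally_over_partitions(d$x, d$y, n_partitions = 2, n_iterations = 60,
                             q0 = 3, subset_size = 4, seed = 5)
  expect_identical(a$counts, b$counts)
  expect_identical(a$top_subset, b$top_subset)

  p <- file.path(tempdir(), "tally.csv")
  on.exit(unlink(p), add = TRUE)
  write_tally(a, p)
  df <- read.csv(p)
  expect_equal(nrow(df), 8)
  expect_equal(sum(df$selected), 4)
})
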