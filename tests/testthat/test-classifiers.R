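# LS-SVM, PLS-DA and KNN classifiers.

test_that("LS-SVM separates distant blobs and satisfies its KKT system", {
  d <- make_blob_data(10, n_features = 2, informative = 1:2, effect = 6, seed = 1)
  fit <- lssvm(d$x, d$y, gamma = 10, sigma_k = 1)
  expect_equal(unname(mean(predict(fit, d$x) == d$y)), 1)
  expect_lt(fit$kkt_residual, 1e-8)
})

test_that("LS-SVM coefficients match a dense linear-solver oracle", {
  set.seed(2)
  x <- matrix(rnorm(12), 6, 2)
  y <- c(1, 1, 1, -1, -1, -1)
  gamma <- 5; sk <- 1.3
  fit <- lssvm(x, y, gamma = gamma, sigma_k = sk)
  # oracle: assemble the KKT system explicitly and solve it independently
  K <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6)
    K[i, j] <- exp(-sum((x[i, ] - x[j, ])^2) / sk^2)
  A <- rbind(c(0, rep(1, 6)), cbind(1, K + diag(6) / gamma))
  sol <- qr.solve(A, c(0, y))
  expect_lt(max(abs(c(fit$b, fit$alpha) - sol)), 1e-8)
  # decision values agree with the explicit expansion
  f1 <- sum(fit$alpha * exp(-colSums((t(x) - x[1, ])^2) / sk^2)) + fit$b
  expect_equal(unname(predict(fit, x[1, , drop = FALSE], type = "decision")), f1,
               tolerance = 1e-10)
})

test_that("LS-SVM grid tuning returns the CV-error argmin over the grid", {
  d <- make_blob_data(12, n_features = 2, informative = 1:2, effect = 3, seed = 4)
  gam <- c(0.1, 10); sig <- c(0.5, 5)
  tn <- tune_lssvm(d$x, d$y, gammas = gam, sigmas = sig, folds = 4, seed = 9)
  # exhaustive re-evaluation with the same folds
  errs <- matrix(NA_real_, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    tn_ij <- tune_lssvm(d$x, d$y, gammas = gam[i], sigmas = sig[j],
                        folds = 4, seed = 9)
    errs[i, j] <- tn_ij$error
  }
  expect_equal(tn$error, min(errs), tolerance = 1e-12)
  expect_error(lssvm(d$x, d$y, gamma = -1), "> 0")
})

test_that("univariate PLS-DA with one component equals thresholded least squares", {
  set.seed(6)
  x <- matrix(rnorm(30), 30, 1)
  y01 <- as.numeric(x[, 1] + rnorm(30, 0, 0.4) > 0)
  fit <- plsda(x, y01, max_lv = 1)
  beta <- cov(x[, 1], y01) / var(x[, 1])
  alpha <- mean(y01) - beta * mean(x[, 1])
  ols_pred <- as.numeric(alpha + beta * x[, 1] >= 0.5)
  got <- predict(fit, x)
  expect_equal(as.numeric(got == "1"), ols_pred)
  expect_equal(unname(predict(fit, x, type = "score")),
               unname(alpha + beta * x[, 1]), tolerance = 1e-10)
})

test_that("full-rank PLS equals multiple linear regression", {
  set.seed(7)
  x <- matrix(rnorm(25 * 4), 25, 4)
  y <- as.numeric(x %*% c(1, -2, 0.5, 0) + rnorm(25, 0, 0.1) > 0)
  fit <- siribruise:::pls1_fit(x, y, ncomp = 4)
  lm_fit <- lm(y ~ x)
  pred_pls <- siribruise:::pls1_predict(fit, x, 4)
  expect_equal(unname(pred_pls), unname(fitted(lm_fit)), tolerance = 1e-8)
})

test_that("PLS-DA LOO selection reaches zero error on separable blobs and caps LVs", {
  d <- make_blob_data(10, n_features = 3, informative = 1, effect = 8, seed = 8)
  fit <- plsda(d$x, d$y, max_lv = 3)
  expect_equal(min(fit$cv_error), 0)
  expect_warning(plsda(d$x, d$y, max_lv = 50), "capped")
})

test_that("KNN recalls the training set at K = 1 and rejects even K", {
  d <- make_blob_data(8, n_features = 2, informative = 1, effect = 3, seed = 9)
  expect_equal(unname(knn_classify(d$x, d$y, d$x, k = 1)), d$y)
  expect_error(knn_classify(d$x, d$y, d$x, k = 2), "odd")
  expect_error(knn_classify(d$x, d$y, d$x, k = 99), "exceeds")
})

test_that("KNN equals the brute-force neighbour oracle on random data", {
  set.seed(11)
  x_tr <- matrix(rnorm(60), 30, 2)
  y_tr <- sample(c("a", "b"), 30, replace = TRUE)
  x_te <- matrix(rnorm(20), 10, 2)
  expect_equal(unname(knn_classify(x_tr, y_tr, x_te, k = 3)),
               oracle_knn(x_tr, y_tr, x_te, 3))
  expect_equal(unname(knn_classify(x_tr, y_tr, x_te, k = 7)),
               oracle_knn(x_tr, y_tr, x_te, 7))
})

test_that("KNN tuning minimizes the fold-averaged error over the K grid", {
  d <- make_blob_data(15, n_features = 2, informative = 1:2, effect = 2, seed = 12)
  tn <- tune_knn(d$x, d$y, ks = c(1, 3, 5, 7), folds = 5, seed = 3)
  expect_equal(tn$error[match(tn$k, tn$ks)], min(tn$error))
})

test_that("the evaluation harness scores an oracle perfectly and adds up", {
  d <- make_blob_data(15, n_features = 4, informative = 1, effect = 6, seed = 13)
  ft <- cbind(data.frame(sample_id = sprintf("s%02d", 1:30),
                         degree = rep(c("S0", "S2"), each = 15),
                         label = d$y, source_image = "RT"),
              as.data.frame(d$x))
  ev <- evaluate(ft, model = "oracle", scope = "S2", n_reps = 5, seed = 1)
  expect_equal(ev$summary$mean, c(100, 100, 100))
  expect_equal(ev$summary$se, c(0, 0, 0))

  ev2 <- evaluate(ft, model = "plsda", scope = "S2", n_reps = 4, seed = 2)
  # balanced classes: ACC must equal the average of the TP and TN rates
  r <- ev2$reps
  expect_equal(r$acc, (r$tp + r$tn) / 2, tolerance = 1e-9)
})

test_that("evaluation is invariant to the row order of the feature table", {
  d <- make_blob_data(12, n_features = 4, informative = 1, effect = 5, seed = 14)
  ft <- cbind(data.frame(sample_id = sprintf("s%02d", 1:24),
                         degree = rep(c("S0", "S1"), each = 12),
                         label = d$y, source_image = "RT"),
              as.data.frame(d$x))
  set.seed(3)
  shuffled <- ft[sample(nrow(ft)), ]
  a <- evaluate(ft, model = "knn", scope = "S1", n_reps = 3, seed = 5)
  b <- evaluate(shuffled, model = "knn", scope = "S1", n_reps = 3, seed = 5)
  expect_equal(a$summary, b$summary)
  expect_equal(a$reps, b$reps)
})
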