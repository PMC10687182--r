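## Binary classifiers: LS-SVM (RBF), PLS-DA and KNN, written as classic
## fitting functions returning classed S3 objects with predict methods.

# squared Euclidean cross-distance matrix
.sqdist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

# map labels to the model's numeric coding; bruised/positive is the first of
# `levels` if given, else the alphabetically later level (so "bruised" < "sound"
# works out naturally when levels = c("bruised", "sound"))
.code_labels <- function(y, positive = NULL) {
  y <- as.character(y)
  lv <- sort(unique(y))
  if (length(lv) != 2L) stop("binary classification needs exactly two classes", call. = FALSE)
  if (is.null(positive)) positive <- if ("bruised" %in% lv) "bruised" else lv[2]
  list(pm1 = ifelse(y == positive, 1, -1), b01 = ifelse(y == positive, 1, 0),
       positive = positive, negative = setdiff(lv, positive))
}

#' Least-squares support vector machine with an RBF kernel
#'
#' Fits the LS-SVM dual problem, which replaces the SVM's inequality
#' constraints by equalities so training reduces to one symmetric linear
#' (KKT) system:
#' \deqn{\begin{pmatrix} 0 & \mathbf 1^\top \\ \mathbf 1 & K + I/\gamma
#' \end{pmatrix}\begin{pmatrix} b \\ \alpha \end{pmatrix} =
#' \begin{pmatrix} 0 \\ y \end{pmatrix}}
#' with \eqn{K_{ij} = \exp(-\lVert x_i - x_j\rVert^2/\sigma_k^2)} and
#' \eqn{y_i \in \{-1,+1\}}. The decision value for a new point is
#' \eqn{f(x) = \sum_i \alpha_i K(x, x_i) + b}, classified by its sign.
#'
#' @param x Numeric matrix of predictors (rows = samples).
#' @param y Two-class labels (character/factor), or numeric -1/+1.
#' @param gamma Regularization parameter (> 0); larger values fit the
#'   training data more tightly.
#' @param sigma_k RBF kernel width (> 0), on the scale of the predictor
#'   distances.
#' @param positive Label treated as +1 (default `"bruised"` if present).
#' @return Object of class `siri_lssvm` with `alpha`, `b`, the stored
#'   training inputs and the KKT residual of the solved system.
#' @examples
#' x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 3), 10))
#' fit <- lssvm(x, rep(c("sound", "bruised"), each = 10), gamma = 10, sigma_k = 1)
#' mean(predict(fit, x) == rep(c("sound", "bruised"), each = 10))
#' @export
lssvm <- function(x, y, gamma = 10, sigma_k = 1, positive = NULL) {
  x <- as.matrix(x)
  if (gamma <= 0 || sigma_k <= 0) stop("gamma and sigma_k must be > 0", call. = FALSE)
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    code <- list(pm1 = y, positive = "1", negative = "-1")
  } else code <- .code_labels(y, positive)
  n <- nrow(x)
  K <- exp(-.sqdist(x, x) / sigma_k^2)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / gamma))
  rhs <- c(0, code$pm1)
  sol <- tryCatch(solve(A, rhs),
                  error = function(e) stop("singular KKT system; increase the gamma regularization",
                                           call. = FALSE))
  res <- max(abs(A %*% sol - rhs))
  structure(list(alpha = sol[-1], b = sol[1], gamma = gamma, sigma_k = sigma_k,
                 x_train = x, kkt_residual = res,
                 positive = code$positive, negative = code$negative),
            class = "siri_lssvm")
}

#' @rdname lssvm
#' @param object A fitted `siri_lssvm`.
#' @param newdata Matrix of new observations.
#' @param type `"class"` (default) or `"decision"` for the raw decision value.
#' @param ... Unused.
#' @export
predict.siri_lssvm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  Kx <- exp(-.sqdist(newdata, object$x_train) / object$sigma_k^2)
  f <- drop(Kx %*% object$alpha) + object$b
  if (type == "decision") f else ifelse(f >= 0, object$positive, object$negative)
}

#' @export
print.siri_lssvm <- function(x, ...) {
  cat(sprintf("LS-SVM (RBF): n = %d, gamma = %g, sigma_k = %g, KKT residual = %.2e\n",
              length(x$alpha), x$gamma, x$sigma_k, x$kkt_residual))
  invisible(x)
}

#' @export
coef.siri_lssvm <- function(object, ...) c(b = object$b, alpha = object$alpha)

#' Tune LS-SVM hyperparameters by cross-validated grid search
#'
#' Evaluates a logarithmic `(gamma, sigma_k)` grid — by default 7 x 7 points
#' spanning gamma in 10^-1..10^4 and sigma_k in 10^-1..10^2 — by stratified
#' k-fold (default 10) cross-validation and returns the grid point with the
#' lowest CV misclassification error (ties to the first grid point in
#' row-major order, so the result is deterministic given the fold seed).
#'
#' @inheritParams lssvm
#' @param gammas,sigmas Candidate grids.
#' @param folds Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @return List with `gamma`, `sigma_k` and the CV `error`.
#' @export
tune_lssvm <- function(x, y, gammas = 10^seq(-1, 4, length.out = 7),
                       sigmas = 10^seq(-1, 2, length.out = 7),
                       folds = 10, seed = NULL, positive = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  fold <- stratified_folds(y, folds, seed)
  d2 <- .sqdist(x, x)
  best <- list(error = Inf, gamma = gammas[1], sigma_k = sigmas[1])
  for (g in gammas) for (s in sigmas) {
    errs <- 0; ntot <- 0
    for (f in sort(unique(fold))) {
      tr <- fold != f; te <- !tr
      if (length(unique(y[tr])) < 2L) next
      code <- .code_labels(y[tr], positive)
      n <- sum(tr)
      K <- exp(-d2[tr, tr, drop = FALSE] / s^2)
      A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / g))
      sol <- tryCatch(solve(A, c(0, code$pm1)), error = function(e) NULL)
      if (is.null(sol)) { errs <- errs + sum(te); ntot <- ntot + sum(te); next }
      Kx <- exp(-d2[te, tr, drop = FALSE] / s^2)
      pred <- ifelse(drop(Kx %*% sol[-1]) + sol[1] >= 0, code$positive, code$negative)
      errs <- errs + sum(pred != y[te]); ntot <- ntot + sum(te)
    }
    err <- errs / max(ntot, 1)
    if (err < best$error) best <- list(error = err, gamma = g, sigma_k = s)
  }
  best
}

## ---- PLS ----

# PLS1 (NIPALS) on centred data; returns coefficients for every number of
# components 1..ncomp, so prediction at any truncation is cheap.
pls1_fit <- function(x, y, ncomp) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  ncomp <- min(ncomp, p, n - 1L)
  mx <- colMeans(x); my <- mean(y)
  xc <- sweep(x, 2, mx); yc <- y - my
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); qv <- numeric(ncomp)
  used <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_sc <- drop(xc %*% w)
    tt <- sum(t_sc^2)
    if (tt < 1e-12) break
    p_l <- drop(crossprod(xc, t_sc)) / tt
    q_l <- sum(yc * t_sc) / tt
    xc <- xc - tcrossprod(t_sc, p_l)
    yc <- yc - q_l * t_sc
    W[, a] <- w; P[, a] <- p_l; qv[a] <- q_l
    used <- a
  }
  if (used == 0L) {
    return(list(coefs = matrix(0, p, 1), intercepts = my, ncomp = 1L,
                x_mean = mx, y_mean = my))
  }
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  qv <- qv[seq_len(used)]
  # regression coefficients for each truncation a: B_a = W_a (P_a' W_a)^-1 q_a
  coefs <- matrix(0, p, used)
  for (a in seq_len(used)) {
    Wa <- W[, 1:a, drop = FALSE]
    Ba <- Wa %*% solve(crossprod(P[, 1:a, drop = FALSE], Wa), qv[1:a])
    coefs[, a] <- Ba
  }
  intercepts <- my - drop(crossprod(coefs, mx))
  list(coefs = coefs, intercepts = intercepts, ncomp = used,
       x_mean = mx, y_mean = my)
}

pls1_predict <- function(fit, newx, ncomp = fit$ncomp) {
  ncomp <- min(ncomp, fit$ncomp)
  drop(as.matrix(newx) %*% fit$coefs[, ncomp]) + fit$intercepts[ncomp]
}

#' Partial least squares discriminant analysis
#'
#' PLS1 regression (NIPALS) on a 0/1 class coding, thresholded at 0.5. The
#' number of latent variables is chosen by leave-one-out cross-validation
#' (smallest misclassification error, ties to fewer components). Data are
#' centred internally; at full rank the fitted values coincide with ordinary
#' multiple linear regression.
#'
#' @param x Numeric predictor matrix.
#' @param y Two-class labels, or numeric 0/1.
#' @param max_lv Maximum number of latent variables considered (capped at the
#'   data rank bound `min(n-1, p)` with a warning when it exceeds it).
#' @param positive Label coded as 1 (default `"bruised"` if present).
#' @return Object of class `siri_plsda` with the chosen `n_lv`, the LOO error
#'   per candidate, and the underlying PLS fit.
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 2), 20))
#' fit <- plsda(x, rep(c(0, 1), each = 20), max_lv = 2)
#' fit$n_lv
#' @export
plsda <- function(x, y, max_lv = 10, positive = NULL) {
  x <- as.matrix(x)
  if (is.numeric(y) && all(y %in% c(0, 1))) {
    code <- list(b01 = y, positive = "1", negative = "0")
  } else code <- .code_labels(y, positive)
  n <- nrow(x)
  cap <- min(ncol(x), n - 1L)
  if (max_lv > cap) {
    warning(sprintf("max_lv capped at the rank bound %d", cap), call. = FALSE)
    max_lv <- cap
  }
  max_lv <- max(1L, max_lv)
  # LOO-CV over the number of components
  err <- matrix(0, n, max_lv)
  for (i in seq_len(n)) {
    fit_i <- pls1_fit(x[-i, , drop = FALSE], code$b01[-i], max_lv)
    for (a in seq_len(max_lv)) {
      pred <- pls1_predict(fit_i, x[i, , drop = FALSE], min(a, fit_i$ncomp))
      err[i, a] <- (pred >= 0.5) != (code$b01[i] == 1)
    }
  }
  cv_err <- colMeans(err)
  n_lv <- which.min(cv_err) # first minimum = fewest components
  fit <- pls1_fit(x, code$b01, n_lv)
  structure(list(fit = fit, n_lv = fit$ncomp, cv_error = cv_err,
                 threshold = 0.5, positive = code$positive,
                 negative = code$negative),
            class = "siri_plsda")
}

#' @rdname plsda
#' @param object A fitted `siri_plsda`.
#' @param newdata Matrix of new observations.
#' @param type `"class"` (default) or `"score"` for the continuous response.
#' @param ... Unused.
#' @export
predict.siri_plsda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  sc <- pls1_predict(object$fit, as.matrix(newdata))
  if (type == "score") sc
  else ifelse(sc >= object$threshold, object$positive, object$negative)
}

#' @export
print.siri_plsda <- function(x, ...) {
  cat(sprintf("PLS-DA: %d latent variable(s) chosen by LOO-CV (error %.3f)\n",
              x$n_lv, x$cv_error[x$n_lv]))
  invisible(x)
}

#' @export
coef.siri_plsda <- function(object, ...) {
  c(intercept = object$fit$intercepts[object$fit$ncomp],
    object$fit$coefs[, object$fit$ncomp])
}

## ---- KNN ----

#' K-nearest-neighbour classification
#'
#' Euclidean majority vote among the K nearest training samples. K must be
#' odd (binary vote ties are then impossible); distance ties are broken by
#' the smaller training index, so predictions are deterministic.
#'
#' @param x_train,y_train Training inputs and labels.
#' @param x_test Observations to classify.
#' @param k Odd neighbourhood size, at most `nrow(x_train)`.
#' @return Character vector of predicted labels.
#' @examples
#' knn_classify(matrix(c(0, 0, 1, 1), 2), c("a", "b"), matrix(c(0.1, 0), 1), k = 1)
#' @export
knn_classify <- function(x_train, y_train, x_test, k = 3) {
  if (k %% 2 == 0) stop("k must be odd to avoid vote ties", call. = FALSE)
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  if (k > nrow(x_train)) stop("k exceeds the number of training samples", call. = FALSE)
  y_train <- as.character(y_train)
  d2 <- .sqdist(x_test, x_train)
  apply(d2, 1, function(di) {
    nb <- order(di, seq_along(di))[seq_len(k)] # ties -> smaller index
    votes <- table(y_train[nb])
    names(votes)[which.max(votes)]
  })
}

#' Tune K for KNN by stratified cross-validation
#'
#' @param x,y Training data.
#' @param ks Candidate odd values of K (default 1, 3, ..., 15, truncated to
#'   the largest feasible size).
#' @param folds CV folds (default 10).
#' @param seed Fold-assignment seed.
#' @return List with the chosen `k` (smallest K among minimizers) and the CV
#'   `error` per candidate.
#' @export
tune_knn <- function(x, y, ks = seq(1, 15, by = 2), folds = 10, seed = NULL) {
  x <- as.matrix(x); y <- as.character(y)
  fold <- stratified_folds(y, folds, seed)
  min_train <- min(table(fold[fold %in% unique(fold)]))
  ks <- ks[ks <= nrow(x) - max(table(fold))]
  if (!length(ks)) ks <- 1
  errs <- vapply(ks, function(k) {
    bad <- 0; ntot <- 0
    for (f in sort(unique(fold))) {
      tr <- fold != f
      pred <- knn_classify(x[tr, , drop = FALSE], y[tr], x[!tr, , drop = FALSE],
                           k = min(k, sum(tr) - (1 - sum(tr) %% 2)))
      bad <- bad + sum(pred != y[!tr]); ntot <- ntot + sum(!tr)
    }
    bad / ntot
  }, numeric(1))
  list(k = ks[which.min(errs)], error = errs, ks = ks)
}
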