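## Random-frog feature selection scored by cross-validated PLS-DA.

#' Cross-validated PLS-DA misclassification rate of a feature subset
#'
#' Stratified k-fold cross-validation of a PLS-DA fit restricted to the given
#' feature columns. Within each fold, PLS components are computed once up to
#' `max_lv` and test predictions are evaluated at every truncation; the
#' reported error is the minimum over the number of latent variables of the
#' fold-averaged misclassification rate (i.e. the subset is scored at its
#' best LV count, capped at `min(10, subset size)`). Deterministic given
#' `seed`.
#'
#' @param x Feature matrix.
#' @param y Two-class labels.
#' @param subset Column indices (or names) of the candidate subset; default
#'   all columns. Must be nonempty.
#' @param folds Number of CV folds (default 5).
#' @param seed Fold-assignment seed.
#' @param max_lv Cap on latent variables (default 10, further capped by the
#'   subset size and fold training size).
#' @return Misclassification rate in \[0, 1\].
#' @export
plsda_cv_error <- function(x, y, subset = seq_len(ncol(x)), folds = 5,
                           seed = NULL, max_lv = 10) {
  x <- as.matrix(x)
  if (length(subset) < 1L) stop("feature subset must be nonempty", call. = FALSE)
  y <- as.character(y)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  code <- .code_labels(y)
  xs <- x[, subset, drop = FALSE]
  fold <- stratified_folds(y, folds, seed)
  lv_cap <- max(1L, min(max_lv, ncol(xs)))
  fold_ids <- sort(unique(fold))
  err <- matrix(NA_real_, length(fold_ids), lv_cap)
  wt <- numeric(length(fold_ids))
  for (fi in seq_along(fold_ids)) {
    tr <- fold != fold_ids[fi]; te <- !tr
    if (length(unique(y[tr])) < 2L) stop("a training fold lost a class; use fewer folds", call. = FALSE)
    sc <- standardize_train_test(xs[tr, , drop = FALSE], xs[te, , drop = FALSE])
    fit <- pls1_fit(sc$train, code$b01[tr], lv_cap)
    for (a in seq_len(lv_cap)) {
      pred <- pls1_predict(fit, sc$test, min(a, fit$ncomp)) >= 0.5
      err[fi, a] <- sum(pred != (code$b01[te] == 1))
    }
    wt[fi] <- sum(te)
  }
  min(colSums(err) / sum(wt))
}

#' Random-frog stochastic search over feature subsets
#'
#' A reversible-jump MCMC-like search: starting from a random subset of `q0`
#' features, each iteration proposes a candidate subset whose size is drawn
#' from `round(Normal(Q, theta*Q))` (floored at 1, capped at the feature
#' count) by adding or removing uniformly chosen features (a size-preserving
#' proposal swaps one member for one non-member), scores it with
#' [plsda_cv_error()], accepts it if its error is lower, and otherwise
#' accepts it with probability `eta * err_current / err_candidate` (capped at
#' 1). One cross-validation fold assignment is drawn per run and reused for
#' every score, so candidate errors are exactly comparable and repeat subsets
#' are memoized. The selection probability of a feature is the fraction of
#' iterations whose retained subset contains it. Fully reproducible from
#' `seed`.
#'
#' @param x Feature matrix (>= 2 columns).
#' @param y Two-class labels.
#' @param n_iterations Number of search iterations (default 1000). Values
#'   below 50 trigger a short-chain warning.
#' @param q0 Initial subset size (default 10, capped at the feature count).
#' @param theta Proposal spread factor (> 0, default 0.3).
#' @param eta Uphill acceptance factor in (0, 1\] (default 0.1).
#' @param folds CV folds of the PLS-DA scorer (default 5).
#' @param seed Integer seed.
#' @return Object of class `siri_frog`: named `probabilities` per feature,
#'   the final subset, and the accepted-error trace.
#' @examples
#' x <- cbind(sep = rep(c(0, 4), each = 10), matrix(rnorm(60), 20))
#' colnames(x) <- paste0("f", 1:4)
#' rf <- random_frog(x, rep(c("a", "b"), each = 10), n_iterations = 60, seed = 1)
#' names(which.max(rf$probabilities))
#' @export
random_frog <- function(x, y, n_iterations = 1000, q0 = 10, theta = 0.3,
                        eta = 0.1, folds = 5, seed = 1) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2L) stop("random frog needs at least two features", call. = FALSE)
  if (n_iterations < 1L) stop("n_iterations must be >= 1", call. = FALSE)
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  if (eta <= 0 || eta > 1) stop("eta must be in (0, 1]", call. = FALSE)
  if (n_iterations < 50L)
    warning("fewer than 50 iterations: selection probabilities will be noisy",
            call. = FALSE)
  q0 <- max(1L, min(p, q0))
  feat_names <- colnames(x)
  if (is.null(feat_names)) feat_names <- paste0("V", seq_len(p))

  with_seed(seed, {
    # one fold assignment for the whole run: candidate scores are exactly
    # comparable, and repeat subsets can be memoized
    fold_seed <- sample.int(2^30, 1)
    memo <- new.env(parent = emptyenv())
    score <- function(subset) {
      key <- paste(subset, collapse = ",")
      if (!is.null(memo[[key]])) return(memo[[key]])
      memo[[key]] <- plsda_cv_error(x, y, subset, folds = folds, seed = fold_seed)
      memo[[key]]
    }
    current <- sort(sample.int(p, q0))
    err_cur <- score(current)
    hits <- numeric(p)
    trace <- numeric(n_iterations)
    for (it in seq_len(n_iterations)) {
      q_star <- max(1L, min(p, round(stats::rnorm(1, length(current),
                                                  theta * length(current)))))
      cand <- current
      if (q_star < length(cand)) {
        cand <- sort(sample(cand, q_star))
      } else if (q_star > length(cand)) {
        pool <- setdiff(seq_len(p), cand)
        cand <- sort(c(cand, sample(pool, min(q_star - length(cand), length(pool)))))
      } else {
        # size-preserving move: swap one member for one non-member, so the
        # chain still mixes between exchangeable features
        pool <- setdiff(seq_len(p), cand)
        if (length(pool) > 0L && length(cand) > 0L)
          cand <- sort(c(cand[-sample.int(length(cand), 1)],
                         pool[sample.int(length(pool), 1)]))
      }
      err_cand <- score(cand)
      accept <- if (err_cand < err_cur) TRUE else {
        ratio <- if (err_cand == 0) 1 else err_cur / err_cand
        stats::runif(1) < min(1, eta * ratio)
      }
      if (accept) { current <- cand; err_cur <- err_cand }
      hits[current] <- hits[current] + 1
      trace[it] <- err_cur
    }
    probs <- hits / n_iterations
    names(probs) <- feat_names
    structure(list(probabilities = probs, final_subset = feat_names[current],
                   error_trace = trace, n_iterations = n_iterations,
                   config = list(q0 = q0, theta = theta, eta = eta,
                                 folds = folds, seed = seed)),
              class = "siri_frog")
  })
}

#' @export
print.siri_frog <- function(x, ...) {
  cat(sprintf("Random frog: %d iterations, final subset of %d features\n",
              x$n_iterations, length(x$final_subset)))
  top <- sort(x$probabilities, decreasing = TRUE)[seq_len(min(10, length(x$probabilities)))]
  cat("Top selection probabilities:\n")
  print(round(top, 3))
  invisible(x)
}

#' Tally random-frog selections over repeated dataset partitions
#'
#' Runs the random-frog search on the training portion of repeated stratified
#' 7:3 splits, takes the top `subset_size` features of each run (by
#' within-run selection probability), and counts how often each feature makes
#' a run's top set. The final subset is the `subset_size` features with the
#' highest counts; ties are broken by higher mean selection probability, then
#' by feature order.
#'
#' @param x Feature matrix with named columns.
#' @param y Two-class labels.
#' @param n_partitions Number of random splits (default 30).
#' @param split_ratio Training fraction (default 0.7).
#' @param subset_size Size of the per-run and final subsets (default 10).
#' @param n_iterations,q0,theta,eta,folds Passed to [random_frog()].
#' @param seed Master seed; partition seeds are derived from it.
#' @return Object of class `siri_tally`: per-feature `counts`, `mean_prob`,
#'   and the final `top_subset` (feature names).
#' @export
tally_over_partitions <- function(x, y, n_partitions = 30, split_ratio = 0.7,
                                  subset_size = 10, n_iterations = 1000,
                                  q0 = 10, theta = 0.3, eta = 0.1, folds = 5,
                                  seed = 1) {
  x <- as.matrix(x)
  if (n_partitions < 1L) stop("n_partitions must be >= 1", call. = FALSE)
  y <- as.character(y)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  feat_names <- colnames(x)
  if (is.null(feat_names)) feat_names <- paste0("V", seq_len(ncol(x)))
  counts <- stats::setNames(numeric(ncol(x)), feat_names)
  prob_sum <- counts
  for (b in seq_len(n_partitions)) {
    tr <- stratified_split(y, split_ratio, seed = derive_seed(seed, 7L * b))
    rf <- random_frog(x[tr, , drop = FALSE], y[tr], n_iterations = n_iterations,
                      q0 = q0, theta = theta, eta = eta, folds = folds,
                      seed = derive_seed(seed, 7L * b + 1L))
    top <- order(-rf$probabilities, seq_along(rf$probabilities))[seq_len(subset_size)]
    counts[top] <- counts[top] + 1
    prob_sum <- prob_sum + rf$probabilities
  }
  mean_prob <- prob_sum / n_partitions
  ord <- order(-counts, -mean_prob, seq_along(counts))
  top_subset <- feat_names[ord[seq_len(subset_size)]]
  structure(list(counts = counts, mean_prob = mean_prob,
                 top_subset = top_subset, n_partitions = n_partitions,
                 subset_size = subset_size),
            class = "siri_tally")
}

#' @export
print.siri_tally <- function(x, ...) {
  cat(sprintf("Selection tally over %d partitions (top %d features):\n",
              x$n_partitions, x$subset_size))
  df <- data.frame(feature = x$top_subset,
                   count = x$counts[x$top_subset],
                   mean_prob = round(x$mean_prob[x$top_subset], 3),
                   row.names = NULL)
  print(df)
  invisible(x)
}

#' Write a selection tally as a CSV table
#'
#' @param tally A `siri_tally`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_tally <- function(tally, path) {
  df <- data.frame(feature = names(tally$counts), count = as.integer(tally$counts),
                   mean_prob = tally$mean_prob,
                   selected = names(tally$counts) %in% tally$top_subset)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
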