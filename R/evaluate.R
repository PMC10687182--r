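## Repeated stratified-split evaluation: TP/TN/ACC with standard errors.

# fit + predict one model on standardized train/test matrices
.fit_predict <- function(model, x_tr, y_tr, x_te, tune_seed) {
  switch(model,
    lssvm = {
      tn <- tune_lssvm(x_tr, y_tr, seed = tune_seed)
      fit <- lssvm(x_tr, y_tr, gamma = tn$gamma, sigma_k = tn$sigma_k)
      predict(fit, x_te)
    },
    plsda = {
      fit <- plsda(x_tr, y_tr, max_lv = min(10, ncol(x_tr), nrow(x_tr) - 1L))
      predict(fit, x_te)
    },
    knn = {
      tn <- tune_knn(x_tr, y_tr, seed = tune_seed)
      knn_classify(x_tr, y_tr, x_te, k = tn$k)
    },
    oracle = stop("oracle handled by caller"),
    stop("unknown model: ", model, call. = FALSE)
  )
}

#' Repeated-split evaluation of a bruise classifier
#'
#' Evaluates one classifier on a Haralick feature table under the study's
#' protocol: the scope defines the positives (bruised samples of the stated
#' degree, or all bruised degrees for `"ALL"`) against the sound (S0)
#' negatives; each repetition draws a stratified 7:3 train/test split,
#' standardizes features on the training fold, optionally restricts to a
#' selected feature subset, tunes and fits the model, and scores the test
#' fold. Reported are the true-positive rate (bruised correctly flagged),
#' true-negative rate (sound correctly flagged) and overall accuracy, as
#' percentages, with means and standard errors over repetitions. The table
#' is sorted by `sample_id` before any seeded draw, so results are invariant
#' to row order.
#'
#' @param features Feature data.frame from [dataset_features()] (columns
#'   `sample_id`, `degree`, `label`, `source_image`, then features).
#' @param model `"lssvm"`, `"plsda"`, `"knn"`, or `"oracle"` (passes the true
#'   labels through; useful for harness checks).
#' @param scope `"S1"`, `"S2"`, `"S3"` or `"ALL"`.
#' @param n_reps Number of repetitions (default 30).
#' @param split Training fraction (default 0.7).
#' @param subset Optional character vector of feature names to restrict to
#'   (e.g. a [tally_over_partitions()] top subset).
#' @param seed Master seed; per-repetition seeds are derived from it.
#' @return Object of class `siri_eval`: a list with the per-repetition rates
#'   and a summary data.frame (`metric`, `mean`, `se`, in percent).
#' @export
evaluate <- function(features, model = c("lssvm", "plsda", "knn", "oracle"),
                     scope = c("ALL", "S1", "S2", "S3"), n_reps = 30,
                     split = 0.7, subset = NULL, seed = 1) {
  model <- match.arg(model)
  scope <- match.arg(scope)
  meta_cols <- c("sample_id", "degree", "label", "source_image")
  stopifnot(all(meta_cols %in% names(features)))
  keep_deg <- if (scope == "ALL") c("S0", "S1", "S2", "S3") else c("S0", scope)
  df <- features[features$degree %in% keep_deg, , drop = FALSE]
  df <- df[order(df$sample_id), , drop = FALSE] # canonical order before seeding
  y <- ifelse(df$degree == "S0", "sound", "bruised")
  if (!any(y == "sound") || !any(y == "bruised"))
    stop("scope needs both bruised and sound samples", call. = FALSE)
  feat_cols <- setdiff(names(df), meta_cols)
  if (!is.null(subset)) {
    missing <- setdiff(subset, feat_cols)
    if (length(missing))
      stop("subset names not in the feature table: ", paste(missing, collapse = ", "),
           call. = FALSE)
    feat_cols <- subset
  }
  x <- as.matrix(df[, feat_cols, drop = FALSE])

  tp <- tn <- acc <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- derive_seed(seed, 13L * r)
    # resample (with a derived seed) if a test fold is missing a class
    for (attempt in 0:10) {
      tr_idx <- stratified_split(y, split, seed = derive_seed(rep_seed, attempt))
      te_idx <- setdiff(seq_along(y), tr_idx)
      if (length(unique(y[te_idx])) == 2L && length(unique(y[tr_idx])) == 2L) break
      message("degenerate split (single-class fold); resampling")
    }
    if (model == "oracle") {
      pred <- y[te_idx]
    } else {
      sc <- standardize_train_test(x[tr_idx, , drop = FALSE],
                                   x[te_idx, , drop = FALSE])
      pred <- .fit_predict(model, sc$train, y[tr_idx], sc$test,
                           tune_seed = derive_seed(rep_seed, 999L))
    }
    truth <- y[te_idx]
    tp[r] <- 100 * sum(pred == "bruised" & truth == "bruised") / sum(truth == "bruised")
    tn[r] <- 100 * sum(pred == "sound" & truth == "sound") / sum(truth == "sound")
    acc[r] <- 100 * sum(pred == truth) / length(truth)
  }
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  summary <- data.frame(metric = c("TP", "TN", "ACC"),
                        mean = c(mean(tp), mean(tn), mean(acc)),
                        se = c(se(tp), se(tn), se(acc)))
  structure(list(model = model, scope = scope,
                 source = unique(df$source_image)[1], n_reps = n_reps,
                 reps = data.frame(tp = tp, tn = tn, acc = acc),
                 summary = summary),
            class = "siri_eval")
}

#' @export
print.siri_eval <- function(x, ...) {
  cat(sprintf("Evaluation: %s on %s features, scope %s, %d stratified 7:3 splits\n",
              toupper(x$model), x$source, x$scope, x$n_reps))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-3s %6.2f%% (se %.2f)\n", s$metric[i], s$mean[i], s$se[i]))
  invisible(x)
}

#' Evaluate a grid of models, sources and scopes
#'
#' Convenience wrapper producing one evaluation-report table across image
#' sources (feature tables), degrees and models, mirroring the usual
#' input x degree x model x (TP, TN, ACC) report layout.
#'
#' @param feature_tables Named list of feature data.frames, e.g.
#'   `list(AC = ..., RT = ...)`.
#' @param models Character vector of model names.
#' @param scopes Character vector of scopes.
#' @param subsets Optional named list (by source) of feature-name subsets.
#' @param ... Passed to [evaluate()].
#' @return data.frame with columns `source`, `scope`, `model`, `metric`,
#'   `mean`, `se`.
#' @export
evaluate_grid <- function(feature_tables, models = c("lssvm", "plsda", "knn"),
                          scopes = c("S1", "S2", "S3", "ALL"),
                          subsets = NULL, ...) {
  out <- list()
  for (src in names(feature_tables)) {
    for (scope in scopes) for (model in models) {
      ev <- evaluate(feature_tables[[src]], model = model, scope = scope,
                     subset = subsets[[src]], ...)
      out[[length(out) + 1L]] <-
        cbind(data.frame(source = src, scope = scope, model = model),
              ev$summary)
    }
  }
  do.call(rbind, out)
}
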