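#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Evaluate `expr` under a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so package functions never perturb the session stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministically derive a stream seed from a master seed and a stage index.
# Kept below 2^31 - 1 so the result is always a valid integer seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 9973) %% 2147483647)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}

# Stratified train indices at `ratio` (per-class rounding; every class keeps
# at least one sample on each side when it has >= 2 members).
stratified_split <- function(labels, ratio = 0.7, seed = NULL) {
  with_seed(seed, {
    idx_train <- integer(0)
    for (cl in unique(labels)) {
      members <- which(labels == cl)
      n_tr <- round(length(members) * ratio)
      n_tr <- max(1L, min(length(members) - 1L, n_tr))
      if (length(members) == 1L) n_tr <- 1L
      idx_train <- c(idx_train, sample(members, n_tr))
    }
    sort(idx_train)
  })
}

# Stratified k-fold assignment: a fold id per sample, each class spread as
# evenly as possible across folds.
stratified_folds <- function(labels, k, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      members <- which(labels == cl)
      fold[members] <- sample(rep_len(seq_len(k), length(members)))
    }
    fold
  })
}

# z-score using training-fold statistics; zero-variance columns pass through
# centred only (avoids 0/0 on constant features).
standardize_train_test <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sd <- apply(x_train, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(
    train = sweep(sweep(x_train, 2, mu), 2, sd, "/"),
    test  = sweep(sweep(x_test, 2, mu), 2, sd, "/")
  )
}
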