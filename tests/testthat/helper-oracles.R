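# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately use naive loops / closed forms, not the package's
# vectorized implementations.

# GLCM pair counting by explicit double loop over every pixel.
oracle_glcm <- function(q, valid, angle, levels, distance = 1L,
                        symmetric = TRUE, normalize = TRUE) {
  off <- switch(as.character(angle),
                "0" = c(0L, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0L), "135" = c(-distance, -distance))
  counts <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q) &&
        isTRUE(valid[i, j]) && isTRUE(valid[i2, j2])) {
      counts[q[i, j] + 1L, q[i2, j2] + 1L] <-
        counts[q[i, j] + 1L, q[i2, j2] + 1L] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  if (normalize && sum(counts) > 0) counts <- counts / sum(counts)
  counts
}

# Otsu by exhaustive scan over every interior bin edge, recomputing class
# statistics from scratch at each candidate.
oracle_otsu <- function(values, bins = 256) {
  lo <- min(values); hi <- max(values)
  edges <- lo + seq_len(bins - 1L) * (hi - lo) / bins
  best <- -Inf; best_t <- NA_real_
  for (t in edges) {
    a <- values[values <= t]; b <- values[values > t]
    if (length(a) == 0L || length(b) == 0L) next
    m <- mean(values)
    bcv <- length(a) * (mean(a) - m)^2 + length(b) * (mean(b) - m)^2
    if (bcv > best + 1e-12) { best <- bcv; best_t <- t }
  }
  best_t
}

# Contrast index by direct scalar evaluation of the defining ratio.
oracle_ci <- function(bruise_vals, sound_vals) {
  z <- c(bruise_vals, sound_vals)
  num <- length(bruise_vals) * (mean(bruise_vals) - mean(z))^2 +
    length(sound_vals) * (mean(sound_vals) - mean(z))^2
  den <- sum((z - mean(z))^2)
  num / den
}

# KNN by explicit distance loops with smaller-index tie-breaking.
oracle_knn <- function(x_train, y_train, x_test, k) {
  out <- character(nrow(x_test))
  for (t in seq_len(nrow(x_test))) {
    d <- numeric(nrow(x_train))
    for (i in seq_len(nrow(x_train)))
      d[i] <- sqrt(sum((x_test[t, ] - x_train[i, ])^2))
    nb <- order(d, seq_along(d))[seq_len(k)]
    tab <- table(y_train[nb])
    out[t] <- names(tab)[which.max(tab)]
  }
  out
}

# Haralick statistics recomputed term-by-term with scalar loops (a subset
# sufficient to cross-check the package implementation on toy matrices).
oracle_haralick <- function(p) {
  ng <- nrow(p)
  lg2 <- function(x) if (x > 0) log2(x) else 0
  asm <- 0; ent <- 0; con <- 0; idm <- 0; varr <- 0
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum((seq_len(ng) - 1) * px)
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    v <- p[i, j]
    asm <- asm + v^2
    ent <- ent - v * lg2(v)
    con <- con + (i - j)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    varr <- varr + ((i - 1) - mu_x)^2 * v
  }
  se <- 0
  for (k in 0:(2 * ng - 2)) {
    ps <- 0
    for (i in seq_len(ng)) for (j in seq_len(ng))
      if ((i - 1) + (j - 1) == k) ps <- ps + p[i, j]
    se <- se - ps * lg2(ps)
  }
  c(asm = asm, entropy = ent, contrast = con, idm = idm, variance = varr,
    sum_entropy = se)
}

# Two-class Gaussian feature data with a given set of informative columns.
make_blob_data <- function(n_per_class = 20, n_features = 10,
                           informative = 1, effect = 3, seed = 1,
                           feature_names = paste0("f", seq_len(n_features))) {
  set.seed(seed)
  y <- rep(c("sound", "bruised"), each = n_per_class)
  x <- matrix(rnorm(2 * n_per_class * n_features), 2 * n_per_class)
  x[y == "bruised", informative] <- x[y == "bruised", informative] + effect
  colnames(x) <- feature_names
  list(x = x, y = y)
}

# Small phantom settings used to keep image-based tests fast.
small_phantom <- function(degree, seed, ...) {
  make_phantom(degree, width = 96, height = 96, seed = seed,
               bruise_radius = if (degree == "S0") NULL else 9, ...)
}
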