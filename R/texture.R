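#' GLCM extraction settings
#'
#' @param levels Number of gray levels after quantization (default 32).
#' @param distance Pixel-pair offset distance (fixed at 1 in this analysis).
#' @param angles Offset directions in degrees; must be the four standard
#'   directions `c(0, 45, 90, 135)`.
#' @param symmetric Add the transpose so the matrix is symmetric (default).
#' @param normalize Normalize the matrix to unit sum (default).
#' @return Object of class `siri_glcm_spec`.
#' @export
glcm_spec <- function(levels = 32, distance = 1, angles = c(0, 45, 90, 135),
                      symmetric = TRUE, normalize = TRUE) {
  if (levels < 2) stop("need at least 2 gray levels", call. = FALSE)
  if (!identical(sort(angles), c(0, 45, 90, 135)))
    stop("angles must be exactly 0, 45, 90, 135 degrees", call. = FALSE)
  structure(list(levels = as.integer(levels), distance = as.integer(distance),
                 angles = angles, symmetric = isTRUE(symmetric),
                 normalize = isTRUE(normalize)),
            class = "siri_glcm_spec")
}

#' Quantize a masked image to discrete gray levels
#'
#' Linear min-max quantization of the masked pixels into `{0, ..., levels-1}`
#' (per-image normalization, which suits floating-point RT images whose
#' absolute scale varies with frequency). Out-of-mask pixels are marked
#' invalid and excluded from pair counting.
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix; must be nonempty.
#' @param levels Number of levels (>= 2).
#' @return List with `q` (integer matrix, NA outside the mask) and `valid`
#'   (logical matrix). A constant masked region maps entirely to level 0.
#' @export
quantize_masked <- function(image, mask, levels = 32) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (levels < 2) stop("need at least 2 gray levels", call. = FALSE)
  v <- image[mask]
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  rng <- range(v)
  if (diff(rng) == 0) {
    q[mask] <- 0L
  } else {
    q[mask] <- pmin(as.integer(levels) - 1L,
                    as.integer(floor((v - rng[1]) / diff(rng) * levels)))
  }
  list(q = q, valid = mask)
}

# (row, col) pixel offset of a GLCM direction at unit distance; angles are
# measured counterclockwise with 0 deg = horizontal neighbour to the right.
.glcm_offset <- function(angle, distance = 1L) {
  switch(as.character(angle),
         "0"   = c(0L, distance),
         "45"  = c(-distance, distance),
         "90"  = c(-distance, 0L),
         "135" = c(-distance, -distance),
         stop("angle must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Gray-level co-occurrence matrix for one direction
#'
#' Counts co-occurrences of quantized gray levels at a fixed pixel offset.
#' Both pixels of a pair must be valid (inside the mask). With
#' `symmetric = TRUE` the transpose is added (each pair counted in both
#' directions); with `normalize = TRUE` the matrix is scaled to unit sum.
#'
#' @param q Integer matrix of levels in `{0, ..., levels-1}` (NA allowed
#'   outside the valid map), as produced by [quantize_masked()].
#' @param valid Logical matrix of valid pixels.
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param levels Number of gray levels.
#' @param distance Offset distance in pixels (default 1).
#' @param symmetric,normalize See [glcm_spec()].
#' @return `levels x levels` numeric matrix.
#' @examples
#' qm <- matrix(c(0L, 1L, 0L, 1L), 2)
#' glcm(qm, matrix(TRUE, 2, 2), angle = 0, levels = 2)
#' @export
glcm <- function(q, valid, angle, levels, distance = 1L,
                 symmetric = TRUE, normalize = TRUE) {
  off <- .glcm_offset(angle, as.integer(distance))
  n <- nrow(q); m <- ncol(q)
  r1 <- max(1L, 1L - off[1]):min(n, n - off[1])
  c1 <- max(1L, 1L - off[2]):min(m, m - off[2])
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- valid[r1, c1, drop = FALSE] & valid[r1 + off[1], c1 + off[2], drop = FALSE]
  ok[is.na(ok)] <- FALSE
  if (!any(ok))
    stop(sprintf("no valid pixel pairs at angle %g degrees", angle), call. = FALSE)
  i <- a[ok]; j <- b[ok]
  counts <- matrix(tabulate(i * levels + j + 1L, nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  if (normalize) counts <- counts / sum(counts)
  counts
}

#' The 14 Haralick statistics of a normalized GLCM
#'
#' Computes Haralick's original 14 texture statistics from a symmetric,
#' normalized co-occurrence matrix, in a fixed order: angular second moment,
#' contrast, correlation, sum of squares variance, inverse difference moment,
#' sum average, sum variance, sum entropy, entropy, difference variance,
#' difference entropy, information measures of correlation 1 and 2, and the
#' maximal correlation coefficient. Entropies use base-2 logarithms with
#' \eqn{0 \log 0 \equiv 0}. Degenerate cases are mapped to finite fallbacks:
#' correlation and the maximal correlation coefficient are 0 when a marginal
#' variance vanishes, and the information measures are 0 when the relevant
#' entropies vanish.
#'
#' @param p Square numeric matrix summing to 1 (tolerance 1e-8), symmetric.
#' @return Named numeric vector of length 14.
#' @examples
#' haralick14(diag(2) / 2)[c("asm", "entropy", "contrast")]
#' @export
haralick14 <- function(p) {
  if (abs(sum(p) - 1) > 1e-8)
    stop("GLCM must be normalized to unit sum", call. = FALSE)
  ng <- nrow(p)
  lv <- seq_len(ng) - 1 # level values 0..ng-1
  log2z <- function(x) ifelse(x > 0, log2(x), 0)

  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(lv * px); mu_y <- sum(lv * py)
  var_x <- sum((lv - mu_x)^2 * px); var_y <- sum((lv - mu_y)^2 * py)

  ii <- matrix(lv, ng, ng); jj <- t(ii)
  # distributions of i+j (0..2ng-2) and |i-j| (0..ng-1)
  p_sum <- vapply(0:(2 * ng - 2), function(k) sum(p[ii + jj == k]), numeric(1))
  p_dif <- vapply(0:(ng - 1), function(k) sum(p[abs(ii - jj) == k]), numeric(1))
  ks <- 0:(2 * ng - 2); kd <- 0:(ng - 1)

  asm <- sum(p^2)
  contrast <- sum(kd^2 * p_dif)
  correlation <- if (var_x > 0 && var_y > 0)
    (sum(ii * jj * p) - mu_x * mu_y) / sqrt(var_x * var_y) else 0
  variance <- sum((ii - mu_x)^2 * p)
  idm <- sum(p / (1 + (ii - jj)^2))
  sum_avg <- sum(ks * p_sum)
  sum_var <- sum((ks - sum_avg)^2 * p_sum)
  sum_ent <- -sum(p_sum * log2z(p_sum))
  entropy <- -sum(p * log2z(p))
  dif_avg <- sum(kd * p_dif)
  dif_var <- sum((kd - dif_avg)^2 * p_dif)
  dif_ent <- -sum(p_dif * log2z(p_dif))

  hx <- -sum(px * log2z(px)); hy <- -sum(py * log2z(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(p * log2z(pxy))
  hxy2 <- -sum(pxy * log2z(pxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- if (hxy2 > 0 || entropy > 0)
    sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy)))) else 0

  # maximal correlation coefficient: sqrt of the second largest eigenvalue of
  # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)), over levels with px > 0
  nz <- which(px > 0)
  mcc <- 0
  if (length(nz) >= 2) {
    pk <- p[nz, nz, drop = FALSE]
    # Q = A %*% t(B) with A(i,k) = p(i,k)/px(i), B(j,k) = p(j,k)/py(k)
    a_m <- pk / px[nz]
    b_m <- sweep(pk, 2, py[nz], "/")
    qmat <- a_m %*% t(b_m)
    ev <- sort(Re(eigen(qmat, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) >= 2 && is.finite(ev[2]))
      mcc <- sqrt(min(1, max(0, ev[2])))
  }

  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_avg,
    sum_variance = sum_var, sum_entropy = sum_ent, entropy = entropy,
    difference_variance = dif_var, difference_entropy = dif_ent,
    imc1 = imc1, imc2 = imc2, mcc = mcc)
}

#' 56-dimensional Haralick feature vector of a masked image
#'
#' Quantizes the masked image, builds the symmetric normalized GLCM for each
#' of the four standard directions at distance 1, and concatenates the 14
#' Haralick statistics per direction in the fixed order 0, 45, 90, 135
#' degrees. Names are `"<stat>_a<angle>"` and are stable across runs so
#' selection tallies are comparable.
#'
#' @param image Numeric matrix (AC or RT image).
#' @param mask Logical matrix (the fruit mask).
#' @param spec A [glcm_spec()].
#' @return Named numeric vector of length 56; all entries finite.
#' @examples
#' img <- matrix(runif(64), 8)
#' length(feature_vector(img, matrix(TRUE, 8, 8)))
#' @export
feature_vector <- function(image, mask, spec = glcm_spec()) {
  qz <- quantize_masked(image, mask, spec$levels)
  out <- unlist(lapply(c(0, 45, 90, 135), function(a) {
    g <- glcm(qz$q, qz$valid, angle = a, levels = spec$levels,
              distance = spec$distance, symmetric = spec$symmetric,
              normalize = spec$normalize)
    f <- haralick14(g)
    names(f) <- paste0(names(f), "_a", a)
    f
  }))
  stopifnot(length(out) == 56L, all(is.finite(out)))
  out
}

#' Haralick feature table of a dataset
#'
#' Demodulates every triplet of a dataset, masks the fruit from its DC image
#' and extracts the 56 Haralick features from the chosen enhanced image.
#'
#' @param dataset A `siri_dataset`.
#' @param source `"RT"` (default) or `"AC"`.
#' @param sigma AC filter sigma (px) for [demodulate()].
#' @param mask_threshold_frac Fruit-mask threshold as a fraction of the DC
#'   dynamic range.
#' @param spec A [glcm_spec()].
#' @return A data.frame: `sample_id`, `degree`, `label`, `source_image`, then
#'   the 56 named feature columns.
#' @export
dataset_features <- function(dataset, source = c("RT", "AC"), sigma = 2,
                             mask_threshold_frac = 0.1, spec = glcm_spec()) {
  source <- match.arg(source)
  stopifnot(inherits(dataset, "siri_dataset"))
  rows <- lapply(dataset$manifest$sample_id, function(sid) {
    tr <- dataset$triplets[[sid]]
    dm <- demodulate(tr, sigma = sigma)
    thr <- min(dm$dc) + mask_threshold_frac * diff(range(dm$dc))
    fm <- erode_mask(fruit_mask_from_dc(dm$dc, thr), ceiling(3 * sigma))
    fv <- feature_vector(if (source == "RT") dm$rt else dm$ac, fm, spec)
    as.data.frame(as.list(fv))
  })
  feats <- do.call(rbind, rows)
  cbind(data.frame(sample_id = dataset$manifest$sample_id,
                   degree = dataset$manifest$degree,
                   label = ifelse(dataset$manifest$degree == "S0", "sound", "bruised"),
                   source_image = source, stringsAsFactors = FALSE),
        feats)
}
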