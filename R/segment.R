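## Fruit masking and bruise/sound partitioning.

# 4-connected component labelling of a logical matrix, by merging vertical
# runs column-by-column with a union-find. Returns an integer matrix
# (0 = background).
label_components4 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  labels <- matrix(0L, n, m)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  prev_runs <- NULL # data.frame(start, end, id) of the previous column
  for (j in seq_len(m)) {
    col <- mask[, j]
    if (!any(col)) { prev_runs <- NULL; next }
    r <- rle(col)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    runs <- data.frame(start = starts[keep], end = ends[keep], id = NA_integer_)
    for (k in seq_len(nrow(runs))) {
      parent[length(parent) + 1L] <- length(parent) + 1L
      runs$id[k] <- length(parent)
      if (!is.null(prev_runs)) {
        touching <- which(prev_runs$start <= runs$end[k] & prev_runs$end >= runs$start[k])
        for (t in touching) {
          a <- find(runs$id[k]); b <- find(prev_runs$id[t])
          if (a != b) parent[max(a, b)] <- min(a, b)
        }
      }
      labels[runs$start[k]:runs$end[k], j] <- runs$id[k]
    }
    prev_runs <- runs
  }
  if (length(parent)) {
    roots <- vapply(seq_along(parent), find, integer(1))
    ids <- match(roots, sort(unique(roots)))
    nz <- labels > 0L
    labels[nz] <- ids[labels[nz]]
  }
  labels
}

#' Fruit mask from a DC image
#'
#' Thresholds the DC image (the uniform-illumination equivalent) to separate
#' the fruit from the dark background, then cleans the mask with a
#' morphological closing and hole filling and keeps the largest 4-connected
#' foreground component. The detection geometry is assumed stable, so one
#' manually chosen threshold is reused for all samples of a study.
#'
#' @param dc_image Numeric matrix (DC image, counts).
#' @param threshold Intensity threshold in counts; pixels strictly above it
#'   are foreground. Must lie within the image's intensity range.
#' @param close_radius Disk radius (px) of the morphological closing
#'   (default 3); 0 disables morphology.
#' @return Logical matrix (the fruit mask).
#' @examples
#' dc <- matrix(0, 32, 32); dc[8:24, 8:24] <- 100
#' sum(fruit_mask_from_dc(dc, 10))
#' @export
fruit_mask_from_dc <- function(dc_image, threshold, close_radius = 3) {
  stopifnot_scalar(threshold, "threshold")
  if (threshold < min(dc_image) - 1e-12 || threshold > max(dc_image) + 1e-12)
    stop(sprintf("threshold %g lies outside the DC intensity range [%g, %g]",
                 threshold, min(dc_image), max(dc_image)), call. = FALSE)
  mask <- dc_image > threshold
  if (!any(mask))
    stop(sprintf("empty fruit mask: no pixel exceeds threshold %g", threshold),
         call. = FALSE)
  if (close_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L, shape = "disc")
    mask <- EBImage::closing(mask * 1, brush) > 0.5
  }
  mask <- EBImage::fillHull(mask * 1) > 0.5
  labs <- label_components4(mask)
  if (max(labs) > 1L) {
    sizes <- tabulate(labs[labs > 0L])
    mask <- labs == which.max(sizes)
  }
  mask
}

#' Erode a mask by a disk radius
#'
#' Shrinks a binary mask inward. Used to trim the fruit-mask boundary by the
#' AC filter support before segmentation and texture extraction: Gaussian
#' filtering mixes background zeros into AC near the fruit rim, producing an
#' artefactual dark ring in RT that would otherwise contaminate the
#' bruise/sound split.
#'
#' @param mask Logical matrix.
#' @param radius Disk radius in pixels; 0 returns the mask unchanged.
#' @return Logical matrix.
#' @export
erode_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  EBImage::erode(mask * 1, brush) > 0.5
}

#' Otsu's threshold on a masked intensity sample
#'
#' Histogram-based Otsu thresholding: the masked values are binned into
#' `bins` equal-width bins spanning their min-max range and the threshold
#' maximizing the between-class variance is returned. The candidate
#' thresholds are the interior bin edges; ties are broken toward the lowest
#' maximizing threshold, so the result is deterministic.
#'
#' @param values Numeric vector of intensities (e.g. RT values inside the
#'   fruit mask). Must contain at least two distinct values.
#' @param bins Number of histogram bins (default 256).
#' @return The threshold value; classify as "below" if `value <= threshold`.
#' @examples
#' otsu_threshold(c(rep(10, 50), rep(200, 50)))
#' @export
otsu_threshold <- function(values, bins = 256) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || diff(range(values)) == 0)
    stop("Otsu threshold undefined: input is constant (no valid split)", call. = FALSE)
  lo <- min(values); hi <- max(values)
  bin <- pmin(bins, pmax(1L, 1L + floor((values - lo) / (hi - lo) * bins)))
  h <- tabulate(bin, nbins = bins)
  # exact per-bin value sums, so each candidate split is scored on the true
  # class means (equivalent to an exhaustive scan over the bin edges)
  sums <- numeric(bins)
  rs <- rowsum(values, bin)
  sums[as.integer(rownames(rs))] <- rs[, 1]
  w <- cumsum(h)                  # class-0 weight at each interior edge
  mu <- cumsum(sums)
  n <- w[bins]; mu_t <- mu[bins]
  w0 <- w[-bins]; mu0 <- mu[-bins]
  valid <- w0 > 0 & w0 < n
  # between-class variance, up to a constant factor
  bcv <- rep(-Inf, bins - 1L)
  bcv[valid] <- (mu_t * w0[valid] - n * mu0[valid])^2 / (w0[valid] * (n - w0[valid]))
  k <- which.max(bcv)             # which.max takes the first (lowest) maximizer
  lo + k * (hi - lo) / bins
}

#' Partition the fruit into bruised and sound tissue from an RT image
#'
#' Applies Otsu's threshold to the RT values inside the fruit mask and labels
#' the darker class as bruised (subsurface bruises appear as darker regions
#' in the modulated component). The three masks form an exact partition:
#' bruise and sound are disjoint and their union is the fruit mask.
#'
#' @param rt_image Numeric matrix (RT image).
#' @param fruit_mask Logical matrix from [fruit_mask_from_dc()].
#' @param polarity `"dark"` (default; bruise is the class at or below the
#'   threshold) or `"bright"`.
#' @param separability_floor If the between-class to total variance ratio of
#'   the split falls below this value, a low-separability warning is issued
#'   (the Otsu split always exists, even on sound fruit).
#' @param bins Histogram bins passed to [otsu_threshold()].
#' @return Object of class `siri_segmentation` with logical `fruit_mask`,
#'   `bruise_mask`, `sound_mask`, the `threshold_used` and the achieved
#'   `separability` (between/total variance ratio).
#' @examples
#' rt <- matrix(0.8, 32, 32); rt[10:15, 10:15] <- 0.2
#' seg <- split_bruise_sound(rt, matrix(TRUE, 32, 32))
#' sum(seg$bruise_mask)
#' @export
split_bruise_sound <- function(rt_image, fruit_mask, polarity = c("dark", "bright"),
                               separability_floor = 0.05, bins = 256) {
  polarity <- match.arg(polarity)
  if (!any(fruit_mask)) stop("fruit mask is empty", call. = FALSE)
  vals <- rt_image[fruit_mask]
  thr <- otsu_threshold(vals, bins = bins)
  below <- rt_image <= thr & fruit_mask
  bruise <- if (polarity == "dark") below else (fruit_mask & !below)
  sound <- fruit_mask & !bruise
  # achieved separability of the split
  z <- vals; zb <- rt_image[bruise]; zs <- rt_image[sound]
  tot <- sum((z - mean(z))^2)
  btw <- length(zb) * (mean(zb) - mean(z))^2 + length(zs) * (mean(zs) - mean(z))^2
  sep <- if (tot > 0) btw / tot else 0
  if (sep < separability_floor)
    warning(sprintf("low-separability split (between/total variance = %.3f): the region may contain no bruise", sep),
            call. = FALSE)
  structure(list(fruit_mask = fruit_mask, bruise_mask = bruise,
                 sound_mask = sound, threshold_used = thr, separability = sep),
            class = "siri_segmentation")
}

#' @export
print.siri_segmentation <- function(x, ...) {
  cat(sprintf("SIRI segmentation: fruit %d px = bruise %d px + sound %d px (threshold %.4g, separability %.3f)\n",
              sum(x$fruit_mask), sum(x$bruise_mask), sum(x$sound_mask),
              x$threshold_used, x$separability))
  invisible(x)
}
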