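#' Three-phase demodulation of a pattern triplet
#'
#' Recovers the planar (DC) and modulated (AC) components from three pattern
#' images acquired with equally spaced phase offsets (-2*pi/3, 0, +2*pi/3):
#' \deqn{I_{DC} = (I_1 + I_2 + I_3)/3}
#' \deqn{I_{AC} = \frac{\sqrt 2}{3}\sqrt{(I_1-I_2)^2 + (I_1-I_3)^2 + (I_2-I_3)^2}}
#' Both are exact for ideal sinusoids at any carrier phase, involve only
#' pixel-wise algebra, and the pairwise differences cancel any common additive
#' offset shared by the three images.
#'
#' @param triplet A `siri_triplet`, or a plain list of three equally sized
#'   numeric matrices.
#' @return List with `dc` and `ac` matrices (doubles, regardless of input bit
#'   depth); `ac` is nonnegative by construction.
#' @examples
#' tpd_demodulate(list(matrix(100, 2, 2), matrix(150, 2, 2), matrix(120, 2, 2)))$dc[1, 1]
#' @export
tpd_demodulate <- function(triplet) {
  imgs <- if (inherits(triplet, "siri_triplet")) triplet$images else triplet
  if (!is.list(imgs) || length(imgs) != 3L)
    stop("three-phase demodulation needs exactly three images", call. = FALSE)
  d <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(m) identical(dim(m), d), logical(1))))
    stop("the three pattern images must have identical dimensions", call. = FALSE)
  i1 <- imgs[[1]] * 1.0; i2 <- imgs[[2]] * 1.0; i3 <- imgs[[3]] * 1.0
  dc <- (i1 + i2 + i3) / 3
  ac <- sqrt(2) / 3 * sqrt((i1 - i2)^2 + (i1 - i3)^2 + (i2 - i3)^2)
  list(dc = dc, ac = ac)
}

#' Ratio (RT) image: AC / DC with a guarded division
#'
#' The ratio image divides out shared multiplicative structure (surface
#' reflectance, curvature vignetting), flattening the background and
#' enhancing bruise contrast relative to the raw AC image. Pixels where DC is
#' at or below `eps` (e.g. the background off the fruit) are set to 0 rather
#' than dividing.
#'
#' @param dc,ac Equally sized numeric matrices; `dc` must be nonnegative.
#' @param eps Division guard (default 1e-9).
#' @return Matrix of the same size.
#' @export
ratio_image <- function(dc, ac, eps = 1e-9) {
  if (!identical(dim(dc), dim(ac)))
    stop("dc and ac must have identical dimensions", call. = FALSE)
  rt <- matrix(0, nrow(dc), ncol(dc))
  ok <- dc > eps
  rt[ok] <- ac[ok] / dc[ok]
  rt
}

# truncated, renormalized 1-D Gaussian kernel (radius ceil(4*sigma))
.gauss_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian low-pass filtering with reflective boundaries
#'
#' Separable 2-D Gaussian smoothing used to denoise AC images before ratio
#' formation. The kernel is truncated at 4 standard deviations and
#' renormalized to unit sum; boundaries are handled by edge reflection, so a
#' constant image passes through unchanged and the mean intensity of
#' interior-dominated images is preserved.
#'
#' @param image Numeric matrix.
#' @param sigma Kernel standard deviation in pixels; `sigma = 0` returns the
#'   input unchanged.
#' @return Filtered matrix.
#' @export
gaussian_lowpass <- function(image, sigma) {
  stopifnot_scalar(sigma, "sigma")
  if (sigma < 0) stop("filter sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(image)
  k <- .gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  # symmetric (edge-repeating) reflection of out-of-range indices
  reflect_idx <- function(i, n) {
    repeat {
      below <- i < 1L; above <- i > n
      if (!any(below) && !any(above)) return(i)
      i[below] <- 1L - i[below]
      i[above] <- 2L * n + 1L - i[above]
    }
  }
  conv1 <- function(m) {
    n <- nrow(m)
    mp <- m[reflect_idx(seq(1L - r, n + r), n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(k))
      out <- out + k[t] * mp[(t - 1) + seq_len(n), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(image))))
}

#' Demodulate a pattern triplet into DC, AC and RT images
#'
#' Runs [tpd_demodulate()], low-pass filters the AC image (default Gaussian
#' sigma 2 px; `sigma = 0` disables), then forms the ratio image RT = AC/DC
#' from the filtered AC — filtering precedes the ratio so the division does
#' not amplify AC noise.
#'
#' @param triplet A `siri_triplet`.
#' @param sigma Gaussian filter standard deviation in pixels (default 2).
#' @param eps Division guard for RT.
#' @return Object of class `siri_demod` with `dc`, `ac` (filtered), `rt`,
#'   `frequency` and `filter_sigma`.
#' @examples
#' tr <- render_triplet(make_phantom("S2", seed = 1), illumination_spec(150),
#'                      noise_spec(0, quantize = FALSE))
#' dm <- demodulate(tr)
#' range(dm$rt)
#' @export
demodulate <- function(triplet, sigma = 2, eps = 1e-9) {
  da <- tpd_demodulate(triplet)
  ac <- gaussian_lowpass(da$ac, sigma)
  freq <- if (inherits(triplet, "siri_triplet")) triplet$illumination$frequency else NA_real_
  structure(list(dc = da$dc, ac = ac, rt = ratio_image(da$dc, ac, eps),
                 frequency = freq, filter_sigma = sigma),
            class = "siri_demod")
}

#' @export
print.siri_demod <- function(x, ...) {
  cat(sprintf("SIRI demodulation (%dx%d px, f = %g cycles/m, AC filter sigma = %g px)\n",
              nrow(x$dc), ncol(x$dc), x$frequency, x$filter_sigma))
  cat(sprintf("  DC range [%.2f, %.2f]; AC range [%.2f, %.2f]; RT range [%.3f, %.3f]\n",
              min(x$dc), max(x$dc), min(x$ac), max(x$ac), min(x$rt), max(x$rt)))
  invisible(x)
}

#' Write demodulation results as float TIFFs plus 8-bit preview PNGs
#'
#' @param demod A `siri_demod`.
#' @param dir Output directory.
#' @param prefix File name prefix (typically the sample id).
#' @return Invisibly, the written file paths.
#' @export
write_demod <- function(demod, dir, prefix = "sample") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (what in c("dc", "ac", "rt")) {
    img <- demod[[what]]
    p_tif <- file.path(dir, sprintf("%s_%s.tif", prefix, what))
    tiff::writeTIFF(img / max(max(img), 1e-12), p_tif,
                    bits.per.sample = 32, reduce = FALSE)
    rng <- range(img)
    prev <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
    p_png <- file.path(dir, sprintf("%s_%s_preview.png", prefix, what))
    png::writePNG(prev, p_png)
    paths <- c(paths, p_tif, p_png)
  }
  invisible(paths)
}
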