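#' Contrast index of a bruise/sound partition
#'
#' Quantifies how distinguishable the bruised tissue is from the rest of the
#' fruit as the ratio of the between-class variance to the total variance of
#' the pixel intensities over the whole fruit region:
#' \deqn{CI = \frac{N_x(\bar x - \bar z)^2 + N_y(\bar y - \bar z)^2}
#'                 {\sum_{i=1}^{N_z} (z_i - \bar z)^2}}
#' with \eqn{x} the bruised pixels, \eqn{y} the sound pixels and \eqn{z}
#' their union (so \eqn{N_x + N_y = N_z}). CI lies in \[0, 1\]; higher values
#' mean a more visible bruise. CI is invariant to affine rescaling of the
#' intensities.
#'
#' @param image Numeric matrix (typically the RT image).
#' @param seg A `siri_segmentation` (or any list with logical `bruise_mask`
#'   and `sound_mask` matrices).
#' @return Object of class `siri_ci`: list with `ci` and `region_stats`
#'   (means `x_bar`, `y_bar`, `z_bar` and counts `n_x`, `n_y`, `n_z`).
#' @examples
#' seg <- list(bruise_mask = matrix(c(TRUE, TRUE, FALSE, FALSE), 2),
#'             sound_mask  = matrix(c(FALSE, FALSE, TRUE, TRUE), 2))
#' contrast_index(matrix(c(1, 2, 5, 6), 2), seg)$ci  # 16/17
#' @export
contrast_index <- function(image, seg) {
  x <- image[seg$bruise_mask]
  y <- image[seg$sound_mask]
  if (length(x) < 1L) stop("empty bruise region: CI undefined", call. = FALSE)
  if (length(y) < 1L) stop("empty sound region: CI undefined", call. = FALSE)
  z <- c(x, y)
  xb <- mean(x); yb <- mean(y); zb <- mean(z)
  num <- length(x) * (xb - zb)^2 + length(y) * (yb - zb)^2
  den <- sum((z - zb)^2)
  ci <- if (den == 0) {
    if (num > 1e-12) stop("internal error: between-class variance positive with zero total variance")
    0
  } else num / den
  stopifnot(num <= den * (1 + 1e-12)) # 2-class partition: between <= total
  structure(list(ci = min(ci, 1),
                 region_stats = list(x_bar = xb, y_bar = yb, z_bar = zb,
                                     n_x = length(x), n_y = length(y),
                                     n_z = length(z))),
            class = "siri_ci")
}

#' @export
print.siri_ci <- function(x, ...) {
  s <- x$region_stats
  cat(sprintf("Contrast index %.4f (bruise %d px mean %.4g; sound %d px mean %.4g)\n",
              x$ci, s$n_x, s$x_bar, s$n_y, s$y_bar))
  invisible(x)
}

#' Spatial-frequency sweep of the contrast index
#'
#' Emulates the operating-frequency calibration: for each bruise degree a few
#' replicate phantoms are generated, and each is rendered, demodulated,
#' segmented and scored with the contrast index on its RT image at every
#' candidate frequency (the same phantom is re-imaged at every frequency,
#' as when sweeping a physical sample). The cell value is the mean CI over
#' replicates, and the operating frequency is chosen by [select_frequency()].
#'
#' @param degrees Bruised degrees to sweep (default S1, S2, S3).
#' @param frequencies Candidate spatial frequencies, cycles/m; at least two
#'   unless a single fixed frequency is being confirmed.
#' @param replicates Phantoms per degree (default 3).
#' @param noise A [noise_spec()].
#' @param seed Master seed.
#' @param sigma AC filter sigma (px) passed to [demodulate()].
#' @param mask_threshold_frac Fruit-mask threshold as a fraction of the DC
#'   dynamic range (default 0.1).
#' @param source Image on which CI is computed: `"RT"` (default) or `"AC"`.
#' @param rule Selection rule passed to [select_frequency()].
#' @param ... Further arguments to [make_phantom()].
#' @return Object of class `siri_sweep`: `ci_table` (degrees x frequencies),
#'   `frequencies`, `selected_frequency`.
#' @examples
#' \donttest{
#' sw <- frequency_sweep(frequencies = c(100, 150, 200), replicates = 1,
#'                       noise = noise_spec(0, quantize = FALSE), seed = 1)
#' sw$selected_frequency
#' }
#' @export
frequency_sweep <- function(degrees = c("S1", "S2", "S3"),
                            frequencies = seq(50, 500, by = 50),
                            replicates = 3, noise = noise_spec(), seed = 1,
                            sigma = 2, mask_threshold_frac = 0.1,
                            source = c("RT", "AC"), rule = "mild-first", ...) {
  source <- match.arg(source)
  if (length(frequencies) < 1L) stop("no frequencies to sweep", call. = FALSE)
  ci_table <- matrix(NA_real_, length(degrees), length(frequencies),
                     dimnames = list(degrees, as.character(frequencies)))
  for (d in seq_along(degrees)) {
    for (r in seq_len(replicates)) {
      ph <- make_phantom(degrees[d], seed = derive_seed(seed, d * 100L + r), ...)
      cis <- vapply(seq_along(frequencies), function(fi) {
        tryCatch({
          illum <- illumination_spec(frequencies[fi])
          ns <- noise_spec(noise$sigma, noise$quantize,
                           seed = derive_seed(seed, d * 10000L + r * 100L + fi))
          tr <- render_triplet(ph, illum, ns)
          dm <- demodulate(tr, sigma = sigma)
          thr <- min(dm$dc) + mask_threshold_frac * diff(range(dm$dc))
          fm <- erode_mask(fruit_mask_from_dc(dm$dc, thr), ceiling(3 * sigma))
          seg <- suppressWarnings(split_bruise_sound(
            if (source == "RT") dm$rt else dm$ac, fm))
          contrast_index(if (source == "RT") dm$rt else dm$ac, seg)$ci
        }, error = function(e) NA_real_)
      }, numeric(1))
      ci_table[d, ] <- if (r == 1L) cis else ci_table[d, ] + cis
    }
    ci_table[d, ] <- ci_table[d, ] / replicates
  }
  sweep <- structure(list(ci_table = ci_table, frequencies = frequencies,
                          degrees = degrees, source = source,
                          selected_frequency = NA_real_),
                     class = "siri_sweep")
  sweep$selected_frequency <- select_frequency(sweep, rule = rule)
  sweep
}

#' @export
print.siri_sweep <- function(x, ...) {
  cat(sprintf("Contrast-index frequency sweep (%s images):\n", x$source))
  print(round(x$ci_table, 3))
  cat(sprintf("Selected operating frequency: %g cycles/m\n", x$selected_frequency))
  invisible(x)
}

#' Select the operating spatial frequency from a CI sweep
#'
#' Default `"mild-first"` rule: mild bruises are the hardest to detect, so
#' the frequency maximizing the CI of the mildest swept degree wins; ties are
#' broken by the CI of the next degree (and so on), and finally by preferring
#' the lower frequency. Frequencies with any missing cell are excluded.
#'
#' @param sweep A `siri_sweep`, or a degree-by-frequency CI matrix with
#'   frequencies as column names (rows ordered mildest first).
#' @param rule Only `"mild-first"` is implemented.
#' @return The selected frequency (cycles/m).
#' @export
select_frequency <- function(sweep, rule = "mild-first") {
  rule <- match.arg(rule, "mild-first")
  tab <- if (inherits(sweep, "siri_sweep")) sweep$ci_table else sweep
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1, dimnames = list(NULL, names(tab)))
  if (ncol(tab) == 0L || nrow(tab) == 0L) stop("empty CI table", call. = FALSE)
  freqs <- as.numeric(colnames(tab))
  complete <- colSums(is.na(tab)) == 0L
  if (!any(complete)) stop("no frequency has a complete CI column", call. = FALSE)
  tab <- tab[, complete, drop = FALSE]
  freqs <- freqs[complete]
  # lexicographic: CI of degree 1 desc, then degree 2 desc, ..., then freq asc
  ord <- do.call(order, c(lapply(seq_len(nrow(tab)), function(d) -tab[d, ]),
                          list(freqs)))
  freqs[ord[1]]
}
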