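#' Illumination specification for sinusoidal pattern projection
#'
#' Describes one structured-illumination setting: the fringe spatial frequency
#' along the column (x) axis, the three phase offsets and the DC/AC amplitudes
#' of the projected pattern in digital counts. The projected intensity at
#' column coordinate \eqn{x} (metres) for phase \eqn{\varphi_n} is
#' \deqn{I_n(x) = I_{DC} + I_{AC}\cos(2\pi f x + \varphi_n).}
#'
#' @param frequency Fringe spatial frequency in cycles per metre (\eqn{f_x});
#'   the orthogonal frequency \eqn{f_y} is fixed at 0 (fringes vary along
#'   columns only).
#' @param phases Numeric vector of three phase offsets in radians. Default
#'   `c(-2*pi/3, 0, 2*pi/3)`, the equally spaced offsets required by
#'   three-phase demodulation.
#' @param i_dc,i_ac DC offset and AC amplitude of the projected pattern in
#'   counts. Defaults 255/2 each, so the ideal pattern spans the full 8-bit
#'   range. Must satisfy `0 <= i_ac <= i_dc`.
#' @return An object of class `siri_illumination`.
#' @examples
#' illumination_spec(150)
#' @export
illumination_spec <- function(frequency, phases = c(-2 * pi / 3, 0, 2 * pi / 3),
                              i_dc = 255 / 2, i_ac = 255 / 2) {
  stopifnot_scalar(frequency, "frequency")
  if (frequency < 0) stop("spatial frequency must be >= 0", call. = FALSE)
  if (length(phases) != 3L) stop("exactly three phase offsets are required", call. = FALSE)
  ph <- sort(phases %% (2 * pi))
  if (any(abs(diff(ph)) < 1e-9))
    stop("phase offsets must be distinct modulo 2*pi", call. = FALSE)
  if (!(i_ac >= 0 && i_ac <= i_dc))
    stop("need 0 <= i_ac <= i_dc so the ideal pattern is nonnegative", call. = FALSE)
  structure(list(frequency = frequency, fy = 0, phases = phases,
                 i_dc = i_dc, i_ac = i_ac),
            class = "siri_illumination")
}

#' @export
print.siri_illumination <- function(x, ...) {
  cat(sprintf("SIRI illumination: f = %g cycles/m, phases = (%s) rad, I_DC = %g, I_AC = %g\n",
              x$frequency, paste(signif(x$phases, 4), collapse = ", "),
              x$i_dc, x$i_ac))
  invisible(x)
}

#' Sensor noise specification
#'
#' @param sigma Standard deviation of additive Gaussian read noise, in counts.
#' @param quantize If `TRUE`, clip to \[0, 255\] and round to integer counts
#'   (8-bit acquisition); if `FALSE`, return continuous nonnegative counts.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   renders.
#' @return An object of class `siri_noise`.
#' @export
noise_spec <- function(sigma = 1, quantize = TRUE, seed = NULL) {
  stopifnot_scalar(sigma, "sigma")
  if (sigma < 0) stop("noise sigma must be >= 0", call. = FALSE)
  structure(list(sigma = sigma, quantize = isTRUE(quantize), seed = seed),
            class = "siri_noise")
}

# Per-degree defaults for the bruise effect: AC attenuation depth at the
# curve's peak, and bruise radius in pixels. S0 is sound (no bruise).
.degree_defaults <- function() {
  list(
    S0 = list(delta = 0,    radius = 0),
    S1 = list(delta = 0.35, radius = 18),
    S2 = list(delta = 0.55, radius = 22),
    S3 = list(delta = 0.75, radius = 26)
  )
}

#' Generate a ground-truthed fruit phantom
#'
#' Builds a synthetic scene emulating a fruit imaged under structured
#' illumination: a bright elliptical fruit region whose diffuse reflectance
#' falls off toward the rim (surface-curvature vignetting), a
#' frequency-dependent modulation transfer for the AC component, and, for
#' bruised degrees, a subsurface bruise disk that attenuates only the AC
#' (modulated) component. The bruise attenuation follows a rise-then-fall
#' frequency profile
#' \deqn{c(f) = \delta \, (f/f_{peak}) \exp(1 - f/f_{peak}),}
#' peaking at `f_peak` with depth \eqn{\delta} increasing with bruise degree,
#' so detectability over a frequency sweep rises to a single interior maximum
#' and then decays.
#'
#' @param degree Bruise degree: `"S0"` (sound), `"S1"` (mild), `"S2"`
#'   (moderate) or `"S3"` (severe). The attenuation depth and bruise radius
#'   are strictly increasing S1 < S2 < S3.
#' @param width,height Image size in pixels.
#' @param pixel_pitch Metres per pixel (default 0.5 mm/px, so 150 cycles/m is
#'   about 0.075 cycles/px — several pixels per fringe, Nyquist-safe to
#'   500 cycles/m).
#' @param f_peak Peak frequency of the bruise-contrast curve, cycles/m.
#' @param delta Attenuation depth at the peak, in \[0, 1\]; default set by
#'   `degree`. Multiplied by `effect_scale`.
#' @param effect_scale Global scaling of the bruise attenuation depth; use
#'   values below 1 for weak-contrast studies.
#' @param bruise_radius Bruise disk radius in pixels; default set by `degree`.
#' @param base_reflectance Central diffuse reflectance of the fruit before
#'   jitter, in \[0, 1\].
#' @param vignette_depth Fractional reflectance drop at the fruit rim (radial
#'   cosine falloff): rim reflectance is `(1 - vignette_depth)` times the
#'   central value. 0 disables vignetting.
#' @param mtf_scale Exponential attenuation scale of the modulation transfer
#'   function, cycles/m: `modulation(f) = exp(-f / mtf_scale)`, emulating the
#'   loss of AC signal (hence darker AC/RT images) at high fringe density.
#' @param texture_sd Relative standard deviation of the smooth random tissue
#'   texture applied to the per-pixel modulation map (default 0.025). This is
#'   the within-tissue heterogeneity that survives in RT images: it sets the
#'   within-class variance floor of the contrast index and gives the GLCM
#'   features their texture content. 0 disables it.
#' @param reflectance_texture_sd Relative standard deviation of the smooth
#'   random texture on the diffuse reflectance map (default 0.05). It appears
#'   in DC and AC images but cancels in the RT ratio, emulating surface
#'   colour/albedo mottle.
#' @param texture_scale Correlation length (Gaussian smoothing sigma, px) of
#'   both texture fields (default 3).
#' @param jitter If `TRUE` (default), draw small per-sample perturbations of
#'   the fruit centre, axes, reflectance level and vignette depth from the
#'   seeded generator, emulating sample-to-sample variability.
#' @param seed Integer seed; the same seed and parameters give an identical
#'   scene field-by-field.
#' @return An object of class `siri_phantom` with the reflectance map, the
#'   ground-truth fruit and bruise masks, and the frequency-response
#'   functions used by [render_triplet()].
#' @seealso [render_triplet()], [simulate_dataset()]
#' @examples
#' ph <- make_phantom("S2", seed = 1)
#' ph
#' @export
make_phantom <- function(degree = c("S0", "S1", "S2", "S3"),
                         width = 256, height = 256, pixel_pitch = 5e-4,
                         f_peak = 150, delta = NULL, effect_scale = 1,
                         bruise_radius = NULL,
                         base_reflectance = 0.85, vignette_depth = 0.35,
                         mtf_scale = 600, texture_sd = 0.025,
                         reflectance_texture_sd = 0.025, texture_scale = 3,
                         jitter = TRUE, seed = NULL) {
  degree <- match.arg(degree)
  defs <- .degree_defaults()[[degree]]
  if (is.null(delta)) delta <- defs$delta
  if (is.null(bruise_radius)) bruise_radius <- defs$radius
  delta <- delta * effect_scale
  if (delta < 0 || delta > 1) stop("bruise attenuation depth must be in [0, 1]", call. = FALSE)

  with_seed(seed, {
    cx <- width / 2 + 0.5
    cy <- height / 2 + 0.5
    ax <- 0.40 * width
    ay <- 0.34 * height
    refl <- base_reflectance
    vig <- vignette_depth
    if (jitter) {
      cx <- cx + stats::runif(1, -6, 6)
      cy <- cy + stats::runif(1, -6, 6)
      ax <- ax * stats::runif(1, 0.92, 1.08)
      ay <- ay * stats::runif(1, 0.92, 1.08)
      refl <- min(1, max(0.05, refl * stats::runif(1, 0.88, 1.12)))
      vig <- min(0.9, max(0, vig * stats::runif(1, 0.8, 1.2)))
    }

    # 0-based pixel coordinates, x = column, origin top-left, row-major.
    xs <- matrix(rep(seq_len(width) - 1, each = height), nrow = height)
    ys <- matrix(rep(seq_len(height) - 1, times = width), nrow = height)
    # normalized elliptical radius (1 at the rim)
    r <- sqrt(((xs - (cx - 1)) / ax)^2 + ((ys - (cy - 1)) / ay)^2)
    fruit_mask <- r <= 1

    # smooth unit-mean random texture field: white noise, Gaussian-smoothed,
    # rescaled to the requested relative sd and clamped at +/- 3 sd
    texture_field <- function(rel_sd) {
      if (rel_sd <= 0) return(matrix(1, height, width))
      fld <- gaussian_lowpass(matrix(stats::rnorm(height * width), height),
                              texture_scale)
      fld <- (fld - mean(fld)) / stats::sd(fld) * rel_sd
      1 + pmin(pmax(fld, -3 * rel_sd), 3 * rel_sd)
    }
    refl_tex <- texture_field(reflectance_texture_sd)
    mod_tex <- texture_field(texture_sd)

    reflectance <- matrix(0, height, width)
    reflectance[fruit_mask] <-
      refl * (1 - vig * (1 - cos(pi * r[fruit_mask] / 2))) * refl_tex[fruit_mask]
    reflectance <- pmin(pmax(reflectance, 0), 1)

    # bruise disk placed near, but not at, the fruit centre
    if (degree == "S0" || bruise_radius <= 0) {
      bx <- cx; by <- cy; br <- 0
      bruise_mask <- matrix(FALSE, height, width)
    } else {
      off_r <- if (jitter) stats::runif(1, 0, 0.25) else 0.15
      off_a <- if (jitter) stats::runif(1, 0, 2 * pi) else 0
      bx <- cx + off_r * ax * cos(off_a)
      by <- cy + off_r * ay * sin(off_a)
      br <- bruise_radius * (if (jitter) stats::runif(1, 0.9, 1.1) else 1)
      bruise_mask <- sqrt((xs - (bx - 1))^2 + (ys - (by - 1))^2) <= br
      # the bruise must lie strictly inside the fruit ellipse
      edge <- sqrt(((xs - (cx - 1)) / ax)^2 + ((ys - (cy - 1)) / ay)^2)
      if (any(bruise_mask & edge >= 0.98))
        stop("bruise disk extends outside the fruit ellipse; shrink its radius or offset",
             call. = FALSE)
    }

    fp <- f_peak; dl <- delta; ms <- mtf_scale
    structure(list(
      width = width, height = height, pixel_pitch = pixel_pitch,
      fruit_center = c(x = cx, y = cy), fruit_axes = c(x = ax, y = ay),
      dc_reflectance_map = reflectance,
      fruit_mask = fruit_mask,
      modulation_fn = function(f) exp(-f / ms),
      modulation_texture = mod_tex,
      bruise_center = c(x = bx, y = by), bruise_radius = br,
      bruise_mask = bruise_mask,
      bruise_degree = degree,
      bruise_delta = dl, f_peak = fp,
      bruise_contrast_fn = function(f) {
        ifelse(f <= 0, 0, dl * (f / fp) * exp(1 - f / fp))
      }
    ), class = "siri_phantom")
  })
}

#' @export
print.siri_phantom <- function(x, ...) {
  cat(sprintf("SIRI phantom (%dx%d px, %.2g mm/px): degree %s", x$width,
              x$height, x$pixel_pitch * 1e3, x$bruise_degree))
  if (x$bruise_degree == "S0") cat(" (sound, no bruise)\n")
  else cat(sprintf(", bruise r = %.1f px, peak attenuation %.2f at %g cycles/m\n",
                   x$bruise_radius, x$bruise_delta, x$f_peak))
  invisible(x)
}
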