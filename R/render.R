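#' Render the three phase-shifted pattern images of a phantom
#'
#' Simulates acquisition of one sample under structured illumination: for each
#' phase offset \eqn{\varphi_n} the noiseless image is
#' \deqn{I_n = R\,I_{DC} + R\,M(f)\,(1 - c(f)\,B)\,I_{AC}
#'       \cos(2\pi f x + \varphi_n)}
#' where \eqn{R} is the per-pixel diffuse reflectance, \eqn{M(f)} the
#' modulation transfer at spatial frequency \eqn{f}, \eqn{c(f)} the bruise AC
#' attenuation, \eqn{B} the bruise-disk indicator and \eqn{x} the column
#' coordinate in metres. Additive Gaussian sensor noise is applied, then
#' (optionally) clipping to \[0, 255\] and rounding to 8-bit counts.
#'
#' @param scene A [make_phantom()] scene.
#' @param illum An [illumination_spec()].
#' @param noise A [noise_spec()]; `noise_spec(0, quantize = FALSE)` gives the
#'   ideal continuous render.
#' @param sample_id Optional identifier stored with the triplet.
#' @return An object of class `siri_triplet`: list with `images` (list of
#'   three matrices), `illumination`, `sample_id` and `degree`.
#' @examples
#' tr <- render_triplet(make_phantom("S1", seed = 1), illumination_spec(150),
#'                      noise_spec(0, quantize = FALSE))
#' range(tr$images[[2]])
#' @export
render_triplet <- function(scene, illum, noise = noise_spec(),
                           sample_id = "sample") {
  stopifnot(inherits(scene, "siri_phantom"), inherits(illum, "siri_illumination"))
  if (!inherits(noise, "siri_noise")) stop("'noise' must be a noise_spec()", call. = FALSE)
  f <- illum$frequency
  att <- scene$bruise_contrast_fn(f)
  # per-pixel modulation: MTF envelope times the tissue texture field
  mod <- scene$modulation_fn(f)
  if (!is.null(scene$modulation_texture))
    mod <- pmin(mod * scene$modulation_texture, 1)
  # AC amplitude map: reflectance * modulation * (1 - attenuation inside the bruise)
  amp <- scene$dc_reflectance_map * mod * illum$i_ac
  amp[scene$bruise_mask] <- amp[scene$bruise_mask] * (1 - att)
  dc <- scene$dc_reflectance_map * illum$i_dc
  # carrier phase along columns (x in metres)
  xm <- (seq_len(scene$width) - 1) * scene$pixel_pitch
  theta <- 2 * pi * f * xm

  images <- with_seed(noise$seed, {
    lapply(illum$phases, function(phi) {
      carrier <- matrix(cos(theta + phi), nrow = scene$height,
                        ncol = scene$width, byrow = TRUE)
      img <- dc + amp * carrier
      if (noise$sigma > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, noise$sigma),
                            nrow = scene$height)
      if (noise$quantize) img <- round(pmin(pmax(img, 0), 255))
      img
    })
  })
  structure(list(images = images, illumination = illum,
                 sample_id = sample_id, degree = scene$bruise_degree),
            class = "siri_triplet")
}

#' @export
print.siri_triplet <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("SIRI pattern triplet '%s' (%s): 3 x %dx%d images at %g cycles/m\n",
              x$sample_id, x$degree, d[1], d[2], x$illumination$frequency))
  invisible(x)
}

#' Simulate a labelled dataset of pattern triplets
#'
#' Generates `n_per_class` phantoms per bruise degree (each with its own
#' seeded geometry/reflectance jitter) and renders the three-phase pattern
#' triplet for each at one spatial frequency. The result carries a manifest
#' (sample id, degree, label, frequency, seed) and the per-sample ground
#' truth masks, which downstream validation (e.g. segmentation Dice scores)
#' can use.
#'
#' @param n_per_class Samples per degree (the emulated study used 100).
#' @param degrees Character vector of degrees to include.
#' @param frequency Spatial frequency in cycles/m (default 150).
#' @param noise A [noise_spec()]; its seed, if any, is ignored — per-sample
#'   noise seeds are derived from `seed`.
#' @param seed Master seed; the same seed reproduces the dataset
#'   bit-identically.
#' @param ... Further arguments passed to [make_phantom()] (e.g.
#'   `effect_scale`, `width`, `height`).
#' @return An object of class `siri_dataset`: list with `triplets` (list of
#'   `siri_triplet`), `manifest` (data.frame), `truth` (list of ground-truth
#'   fruit/bruise masks) and `frequency`.
#' @examples
#' ds <- simulate_dataset(2, degrees = c("S0", "S2"), seed = 1)
#' ds$manifest
#' @export
simulate_dataset <- function(n_per_class, degrees = c("S0", "S1", "S2", "S3"),
                             frequency = 150, noise = noise_spec(), seed = 1,
                             ...) {
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  known <- c("S0", "S1", "S2", "S3")
  if (!all(degrees %in% known))
    stop("unknown degree label(s): ", paste(setdiff(degrees, known), collapse = ", "),
         call. = FALSE)
  illum <- illumination_spec(frequency)
  triplets <- list()
  truth <- list()
  rows <- list()
  k <- 0L
  for (deg in degrees) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      sid <- sprintf("%s_%03d", deg, i)
      s_phantom <- derive_seed(seed, 2L * k)
      s_noise <- derive_seed(seed, 2L * k + 1L)
      ph <- make_phantom(deg, seed = s_phantom, ...)
      ns <- noise_spec(noise$sigma, noise$quantize, seed = s_noise)
      triplets[[sid]] <- render_triplet(ph, illum, ns, sample_id = sid)
      truth[[sid]] <- list(fruit_mask = ph$fruit_mask, bruise_mask = ph$bruise_mask)
      rows[[sid]] <- data.frame(sample_id = sid, degree = deg,
                                label = if (deg == "S0") "sound" else "bruised",
                                frequency_cpm = frequency, seed = s_phantom,
                                stringsAsFactors = FALSE)
    }
  }
  structure(list(triplets = triplets, manifest = do.call(rbind, rows),
                 truth = truth, frequency = frequency),
            class = "siri_dataset")
}

#' @export
print.siri_dataset <- function(x, ...) {
  cat(sprintf("SIRI dataset: %d triplets at %g cycles/m\n",
              length(x$triplets), x$frequency))
  print(table(x$manifest$degree))
  invisible(x)
}

#' Write a simulated dataset to disk as 8-bit PNGs plus a CSV manifest
#'
#' Files are named `<sample>_<phase>.png` with phase in 1..3; the manifest
#' gains `file1..file3` columns with the relative file names. Continuous
#' (unquantized) renders are clipped to \[0, 255\] on write, since PNG is an
#' 8/16-bit format; keep `quantize = TRUE` for round-trip fidelity.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "siri_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  files <- matrix("", nrow(man), 3)
  for (i in seq_len(nrow(man))) {
    sid <- man$sample_id[i]
    tr <- dataset$triplets[[sid]]
    for (p in 1:3) {
      fn <- sprintf("%s_%d.png", sid, p)
      png::writePNG(pmin(pmax(tr$images[[p]] / 255, 0), 1), file.path(dir, fn))
      files[i, p] <- fn
    }
  }
  man$file1 <- files[, 1]; man$file2 <- files[, 2]; man$file3 <- files[, 3]
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Read a pattern-triplet dataset from a manifest
#'
#' @param manifest_path Path to a `manifest.csv` written by [write_dataset()]
#'   (or assembled by hand with the same columns). Images are read as 8-bit
#'   grayscale PNGs and rescaled to counts in \[0, 255\].
#' @return A `siri_dataset` (without ground-truth masks).
#' @export
read_dataset <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "degree", "frequency_cpm", "file1", "file2", "file3")
  if (!all(need %in% names(man)))
    stop("manifest is missing columns: ", paste(setdiff(need, names(man)), collapse = ", "),
         call. = FALSE)
  dir <- dirname(manifest_path)
  triplets <- list()
  for (i in seq_len(nrow(man))) {
    imgs <- lapply(c(man$file1[i], man$file2[i], man$file3[i]), function(fn) {
      img <- png::readPNG(file.path(dir, fn))
      if (length(dim(img)) == 3L) img <- img[, , 1]
      img * 255
    })
    illum <- illumination_spec(man$frequency_cpm[i])
    triplets[[man$sample_id[i]]] <-
      structure(list(images = imgs, illumination = illum,
                     sample_id = man$sample_id[i], degree = man$degree[i]),
                class = "siri_triplet")
  }
  if (is.null(man$label)) man$label <- ifelse(man$degree == "S0", "sound", "bruised")
  structure(list(triplets = triplets, manifest = man, truth = NULL,
                 frequency = man$frequency_cpm[1]),
            class = "siri_dataset")
}
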