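# Pattern rendering and dataset simulation.

flat_scene <- function(width = 16, height = 4) {
  ph <- make_phantom("S0", width = width, height = height, jitter = FALSE,
                     vignette_depth = 0, base_reflectance = 1,
                     texture_sd = 0, reflectance_texture_sd = 0)
  ph$dc_reflectance_map[] <- 1
  ph$fruit_mask[] <- TRUE
  ph$modulation_fn <- function(f) 1
  ph$modulation_texture <- NULL
  ph
}

test_that("the renderer matches the scalar pattern equation", {
  # single pixel, reflectance 1, modulation 1: I_n = 100 + 50 cos(theta + phi)
  # with theta = pi/2 -> (143.3013, 100, 56.6987), computed by hand from the
  # cosine addition values cos(pi/2 -/+ 2pi/3) = +/- sqrt(3)/2.
  ph <- flat_scene()
  f <- 150
  # choose the pixel pitch so column 2 (x index 1) sits at theta = pi/2
  ph$pixel_pitch <- (pi / 2) / (2 * pi * f)
  tr <- render_triplet(ph, illumination_spec(f, i_dc = 100, i_ac = 50),
                       noise_spec(0, quantize = FALSE))
  got <- vapply(tr$images, function(m) m[1, 2], numeric(1))
  expect_equal(got, c(100 + 50 * sqrt(3) / 2, 100, 100 - 50 * sqrt(3) / 2),
               tolerance = 1e-12)
  expect_equal(round(got, 1), c(143.3, 100.0, 56.7))
})

test_that("a flat scene at I_DC = I_AC = 255/2 reaches 255 where the cosine is 1", {
  ph <- flat_scene()
  tr <- render_triplet(ph, illumination_spec(150), noise_spec(0, quantize = FALSE))
  # phase offset 0 (second image), column 1 has cosine argument 0
  expect_equal(tr$images[[2]][1, 1], 255, tolerance = 1e-12)
})

test_that("zero AC amplitude makes the three images identical", {
  ph <- flat_scene()
  tr <- render_triplet(ph, illumination_spec(150, i_dc = 120, i_ac = 0),
                       noise_spec(0, quantize = FALSE))
  expect_identical(tr$images[[1]], tr$images[[2]])
  expect_identical(tr$images[[2]], tr$images[[3]])
})

test_that("quantized renders are 8-bit and ideal renders never clip", {
  ph <- make_phantom("S2", seed = 4)
  trq <- render_triplet(ph, illumination_spec(150), noise_spec(1, TRUE, seed = 2))
  v <- unlist(trq$images)
  expect_true(all(v >= 0 & v <= 255))
  expect_true(all(v == round(v)))
  trc <- render_triplet(ph, illumination_spec(150), noise_spec(0, quantize = FALSE))
  expect_true(all(unlist(trc$images) >= 0))
  expect_true(max(unlist(trc$images)) <= 255 + 1e-9)
})

test_that("rendering is deterministic under a fixed noise seed", {
  ph <- make_phantom("S1", seed = 9)
  a <- render_triplet(ph, illumination_spec(150), noise_spec(1, TRUE, seed = 3))
  b <- render_triplet(ph, illumination_spec(150), noise_spec(1, TRUE, seed = 3))
  expect_identical(a$images, b$images)
})

test_that("invalid illumination settings are rejected", {
  expect_error(illumination_spec(-10), "frequency")
  expect_error(illumination_spec(150, i_dc = 100, i_ac = 120), "nonnegative")
  expect_error(illumination_spec(150, phases = c(0, 0, 1)), "distinct")
})

test_that("simulate_dataset builds balanced labelled sets and rejects bad degrees", {
  ds <- simulate_dataset(2, degrees = c("S0", "S1", "S2", "S3"), seed = 1,
                         width = 96, height = 96, bruise_radius = 9)
  expect_length(ds$triplets, 8)
  expect_equal(unname(table(ds$manifest$degree)), rep(2L, 4),
               ignore_attr = TRUE)
  expect_equal(ds$manifest$label[ds$manifest$degree == "S0"], rep("sound", 2))

  ds1 <- simulate_dataset(1, degrees = "S0", seed = 1, width = 64, height = 64)
  expect_length(ds1$triplets, 1)
  expect_error(simulate_dataset(2, degrees = c("S0", "SX"), seed = 1), "unknown degree")
})

test_that("written datasets are byte-identical across runs and round-trip", {
  d1 <- file.path(tempdir(), "ds_a"); d2 <- file.path(tempdir(), "ds_b")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  ds <- simulate_dataset(1, degrees = c("S0", "S2"), seed = 12,
                         width = 64, height = 64, bruise_radius = 6)
  write_dataset(ds, d1)
  write_dataset(simulate_dataset(1, degrees = c("S0", "S2"), seed = 12,
                                 width = 64, height = 64, bruise_radius = 6), d2)
  f1 <- list.files(d1, full.names = TRUE); f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  back <- read_dataset(file.path(d1, "manifest.csv"))
  expect_equal(back$triplets[["S2_001"]]$images,
               lapply(ds$triplets[["S2_001"]]$images, unname))
})
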