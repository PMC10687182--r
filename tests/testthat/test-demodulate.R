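# Three-phase demodulation, ratio image and Gaussian filtering.

test_that("TPD matches the scalar evaluation of the defining sums", {
  o <- tpd_demodulate(list(matrix(100, 1, 1), matrix(150, 1, 1), matrix(120, 1, 1)))
  expect_equal(o$dc[1, 1], (100 + 150 + 120) / 3, tolerance = 1e-12)
  expect_equal(o$ac[1, 1], sqrt(2) / 3 * sqrt(2500 + 400 + 900), tolerance = 1e-12)
  expect_equal(round(o$ac[1, 1], 4), 29.0593)
})

test_that("TPD is exact for ideal sinusoids at every carrier phase", {
  # one row whose columns cover carrier phases densely over [0, 2pi)
  theta <- seq(0, 2 * pi, length.out = 257)[-257]
  phases <- c(-2 * pi / 3, 0, 2 * pi / 3)
  for (amps in list(c(127.5, 127.5), c(100, 30))) {
    imgs <- lapply(phases, function(phi)
      matrix(amps[1] + amps[2] * cos(theta + phi), nrow = 1))
    o <- tpd_demodulate(imgs)
    expect_true(max(abs(o$dc - amps[1])) < 1e-6)
    expect_true(max(abs(o$ac - amps[2])) < 1e-6)
  }
})

test_that("constant triplets demodulate to zero AC and common offsets cancel", {
  c3 <- lapply(1:3, function(i) matrix(42, 5, 5))
  o <- tpd_demodulate(c3)
  expect_true(all(o$dc == 42))
  expect_true(all(o$ac == 0))

  set.seed(1)
  imgs <- lapply(1:3, function(i) matrix(runif(25, 0, 200), 5))
  offset <- matrix(rnorm(25, 50, 10), 5)
  a <- tpd_demodulate(imgs)
  b <- tpd_demodulate(lapply(imgs, function(m) m + offset))
  expect_equal(a$ac, b$ac, tolerance = 1e-9)
  expect_true(all(a$ac >= 0))
})

test_that("malformed triplets are rejected", {
  expect_error(tpd_demodulate(list(matrix(0, 2, 2), matrix(0, 2, 2))), "three")
  expect_error(tpd_demodulate(list(matrix(0, 2, 2), matrix(0, 2, 2),
                                   matrix(0, 3, 2))), "dimensions")
})

test_that("the ratio image divides out common multiplicative structure", {
  a <- matrix(runif(36, 10, 50), 6)
  expect_true(all(ratio_image(a, a) == 1))

  # a smooth positive vignette applied to all three patterns cancels in RT
  ph <- make_phantom("S2", seed = 6, width = 96, height = 96, bruise_radius = 9)
  tr <- render_triplet(ph, illumination_spec(150), noise_spec(0, quantize = FALSE))
  g <- outer(seq(0.6, 1, length.out = 96), seq(0.7, 1.1, length.out = 96))
  d0 <- tpd_demodulate(tr$images)
  d1 <- tpd_demodulate(lapply(tr$images, function(m) m * g))
  rt0 <- ratio_image(d0$dc, d0$ac)
  rt1 <- ratio_image(d1$dc, d1$ac)
  inside <- d0$dc > 1 # compare where the guard is inactive in both
  expect_lt(max(abs(rt0[inside] - rt1[inside])), 1e-9)

  # zero-DC background: guarded, not NaN
  dc <- matrix(0, 4, 4); ac <- matrix(1, 4, 4)
  expect_true(all(ratio_image(dc, ac) == 0))
})

test_that("Gaussian low-pass matches a directly evaluated kernel and preserves structure", {
  img <- matrix(rnorm(400), 20)
  expect_identical(gaussian_lowpass(img, 0), img)
  expect_error(gaussian_lowpass(img, -1), ">= 0")

  cst <- matrix(3.7, 33, 33)
  expect_equal(gaussian_lowpass(cst, 2.5), cst, tolerance = 1e-12)

  # impulse response equals the truncated, renormalized sampled kernel
  imp <- matrix(0, 65, 65); imp[33, 33] <- 1
  out <- gaussian_lowpass(imp, 2)
  r <- ceiling(4 * 2)
  k1 <- exp(-((-r:r)^2) / (2 * 2^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  expect_lt(max(abs(out[33 + (-r:r), 33 + (-r:r)] - k2)), 1e-6)
  expect_equal(sum(out), 1, tolerance = 1e-9)

  # interior-dominated mean preservation
  set.seed(2)
  big <- matrix(runif(128 * 128), 128)
  expect_equal(mean(gaussian_lowpass(big, 2)), mean(big), tolerance = 1e-6)
})

test_that("demodulate wires filtering before the ratio and keeps metadata", {
  ph <- make_phantom("S1", seed = 8, width = 96, height = 96, bruise_radius = 9)
  tr <- render_triplet(ph, illumination_spec(200), noise_spec(1, TRUE, seed = 1))
  dm <- demodulate(tr, sigma = 2)
  expect_s3_class(dm, "siri_demod")
  expect_equal(dm$frequency, 200)
  raw <- tpd_demodulate(tr)
  expect_equal(dm$ac, gaussian_lowpass(raw$ac, 2), tolerance = 1e-12)
  expect_equal(dm$rt, ratio_image(raw$dc, dm$ac), tolerance = 1e-12)
  expect_true(all(dm$ac >= 0) && all(dm$dc >= 0))
})
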