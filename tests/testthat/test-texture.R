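# GLCM construction and Haralick statistics.

test_that("masked quantization maps range endpoints and constants correctly", {
  img <- matrix(seq(0, 1, length.out = 16), 4)
  mask <- matrix(TRUE, 4, 4)
  qz <- quantize_masked(img, mask, 4)
  expect_equal(qz$q[1, 1], 0L)
  expect_equal(qz$q[4, 4], 3L)

  cst <- quantize_masked(matrix(5, 3, 3), matrix(TRUE, 3, 3), 8)
  expect_true(all(cst$q == 0L))

  # histogram equals a direct binning oracle
  set.seed(5)
  img2 <- matrix(runif(400), 20)
  qz2 <- quantize_masked(img2, matrix(TRUE, 20, 20), 8)
  rng <- range(img2)
  oracle_bins <- pmin(7L, floor((img2 - rng[1]) / diff(rng) * 8))
  expect_equal(tabulate(qz2$q + 1L, 8), tabulate(oracle_bins + 1L, 8))

  expect_error(quantize_masked(img, matrix(FALSE, 4, 4), 4), "empty")
})

test_that("the 2x2 worked example gives the hand-counted symmetric GLCM", {
  q <- matrix(c(0L, 1L, 0L, 1L), 2)  # [[0,0],[1,1]] row-wise
  g <- glcm(q, matrix(TRUE, 2, 2), angle = 0, levels = 2)
  expect_equal(g, matrix(c(0.5, 0, 0, 0.5), 2), tolerance = 1e-12)

  cst <- glcm(matrix(0L, 3, 3), matrix(TRUE, 3, 3), angle = 0, levels = 4)
  expect_equal(cst[1, 1], 1)
  expect_equal(sum(cst), 1)
})

test_that("GLCMs are symmetric, normalized, and fail without valid pairs", {
  set.seed(8)
  q <- matrix(sample(0:7, 100, replace = TRUE), 10)
  for (a in c(0, 45, 90, 135)) {
    g <- glcm(q, matrix(TRUE, 10, 10), angle = a, levels = 8)
    expect_equal(sum(g), 1, tolerance = 1e-12)
    expect_equal(g, t(g), tolerance = 1e-12)
  }
  lone <- matrix(FALSE, 5, 5); lone[3, 3] <- TRUE
  expect_error(glcm(matrix(0L, 5, 5), lone, angle = 0, levels = 2),
               "no valid pixel pairs")
})

test_that("GLCM pair counts equal the brute-force double loop on random images", {
  set.seed(123)
  for (i in 1:50) {
    levels <- sample(c(2, 4, 8), 1)
    q <- matrix(sample(0:(levels - 1), 64, replace = TRUE), 8)
    valid <- matrix(runif(64) > 0.2, 8)
    if (sum(valid) < 8) valid[] <- TRUE
    for (a in c(0, 45, 90, 135)) {
      got <- tryCatch(glcm(q, valid, angle = a, levels = levels),
                      error = function(e) NULL)
      want <- oracle_glcm(q, valid, a, levels)
      if (is.null(got)) { expect_equal(sum(want), 0); next }
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("Haralick statistics hit the degenerate and worked values", {
  single <- matrix(0, 4, 4); single[1, 1] <- 1
  h <- haralick14(single)
  expect_equal(unname(h["asm"]), 1)
  expect_equal(unname(h["entropy"]), 0)
  expect_equal(unname(h["contrast"]), 0)
  expect_equal(unname(h["correlation"]), 0) # zero marginal variance fallback
  expect_equal(unname(h["mcc"]), 0)
  expect_true(all(is.finite(h)))

  h2 <- haralick14(diag(2) / 2)
  expect_equal(unname(h2["asm"]), 0.5)
  expect_equal(unname(h2["entropy"]), 1) # one bit
  expect_equal(unname(h2["contrast"]), 0)

  expect_error(haralick14(diag(2)), "normalized")
})

test_that("Haralick statistics match scalar oracles on random toy GLCMs", {
  set.seed(21)
  for (i in 1:20) {
    m <- matrix(runif(9), 3); m <- m + t(m); p <- m / sum(m)
    h <- haralick14(p)
    o <- oracle_haralick(p)
    for (nm in names(o)) expect_equal(unname(h[nm]), unname(o[nm]),
                                      tolerance = 1e-10)
  }
})

test_that("feature vectors have 56 stable, finite entries", {
  set.seed(4)
  img <- matrix(runif(96 * 96), 96)
  mask <- matrix(TRUE, 96, 96)
  fv <- feature_vector(img, mask)
  expect_length(fv, 56)
  expect_true(all(is.finite(fv)))
  expect_identical(fv, feature_vector(img, mask))
  expect_equal(sum(grepl("_a0$", names(fv))), 14)
  expect_equal(names(fv)[1:2], c("asm_a0", "contrast_a0"))
})

test_that("rotating the image by 90 degrees swaps the 0/90 and 45/135 blocks", {
  set.seed(9)
  img <- matrix(runif(30 * 30), 30)
  mask <- matrix(runif(900) > 0.1, 30)
  rot <- function(m) t(m[nrow(m):1, , drop = FALSE]) # 90-degree rotation
  f0 <- feature_vector(img, mask)
  f1 <- feature_vector(rot(img), rot(mask))
  pick <- function(v, a) { out <- v[grepl(paste0("_a", a, "$"), names(v))]
                           names(out) <- sub("_a.*", "", names(out)); out }
  expect_equal(pick(f1, 90), pick(f0, 0), tolerance = 1e-8)
  expect_equal(pick(f1, 0), pick(f0, 90), tolerance = 1e-8)
  expect_equal(pick(f1, 45), pick(f0, 135), tolerance = 1e-8)
  expect_equal(pick(f1, 135), pick(f0, 45), tolerance = 1e-8)
})
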