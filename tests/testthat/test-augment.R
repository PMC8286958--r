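blob_image <- function(n = 96, sigma = 10, center = c(0, 0)) {
  ax <- seq_len(n) - (n + 1) / 2
  outer(ax, ax, function(x, y) exp(-((x - center[1])^2 + (y - center[2])^2) /
                                     (2 * sigma^2)))
}

test_that("resample_affine agrees with EBImage on rotation and translation", {
  skip_if_not_installed("EBImage")
  img <- blob_image(center = c(9, -6)) + 0.3 * blob_image(sigma = 30)
  n <- nrow(img)
  # pure translation
  sh <- resample_affine(img, diag(2), c(5, -3), n, pad = "zero")
  eb <- EBImage::translate(img, c(-5, 3), bg.col = 0)
  expect_lt(max(abs(sh - eb)), 1e-6)
  # pure rotation about the centre
  g <- 25
  A <- matrix(c(cos(g * pi / 180), sin(g * pi / 180),
                -sin(g * pi / 180), cos(g * pi / 180)), 2, 2)
  rot <- resample_affine(img, A, c(0, 0), n, pad = "zero")
  ebr <- EBImage::rotate(img, -g, output.dim = c(n, n), bg.col = 0)
  keep <- 20:(n - 20) # compare away from the border
  expect_lt(max(abs(rot[keep, keep] - ebr[keep, keep])), 0.02)
})

test_that("in-plane rotation crops to the inscribed region and inverts", {
  img <- blob_image(center = c(10, 4))
  out0 <- augment_inplane(img, 0)
  n <- nrow(img)
  m <- floor(n / sqrt(2))
  expect_equal(dim(out0), c(m, m))
  # gamma = 0 is a pure centre crop
  off <- (n - m) / 2
  direct <- resample_affine(img, diag(2), c(0, 0), m)
  expect_lt(max(abs(out0 - direct)), 1e-9)
  # full turn equals no turn
  expect_lt(max(abs(augment_inplane(img, 360) - out0)), 1e-3)
  # rotating by gamma then -gamma recovers the doubly-cropped original
  fwd <- augment_inplane(img, 35, crop = 1)
  back <- augment_inplane(fwd, -35, crop = 1)
  keep <- 30:(n - 30)
  expect_lt(max(abs(back[keep, keep] - img[keep, keep])), 0.02)
})

test_that("translation crop shifts by the converted pixel offset", {
  img <- blob_image()
  pitch <- 2.5
  out0 <- augment_translation(img, c(0, 0), pitch, 48)
  direct <- resample_affine(img, diag(2), c(0, 0), 48, pad = "edge")
  expect_lt(max(abs(out0 - direct)), 1e-9)
  # a shift of exactly k pixels
  k <- 4
  outk <- augment_translation(img, c(pitch * k, 0), pitch, 48)
  expect_lt(max(abs(outk[1:(48 - k), ] - out0[(1 + k):48, ])), 1e-9)
  # composing t then -t on a larger canvas recovers the centred crop
  # (integer-pixel shifts so bilinear resampling is exact)
  step1 <- augment_translation(img, c(10, -5), pitch, 80)
  step2 <- augment_translation(step1, c(-10, 5), pitch, 48)
  expect_lt(max(abs(step2 - out0)), 1e-9)
  # window leaving the image warns and pads with edge values
  expect_warning(augment_translation(img, c(200, 0), pitch, 48), "bounds")
})

test_that("contrast augmentation preserves the mean exactly", {
  set.seed(11)
  img <- matrix(runif(64^2), 64, 64)
  expect_identical(augment_contrast(img, 1), img)
  for (cc in c(0.75, 0.9, 1.25)) {
    out <- augment_contrast(img, cc)
    expect_equal(mean(out), mean(img), tolerance = 1e-9)
    expect_equal(stats::sd(out), cc * stats::sd(img), tolerance = 1e-9)
  }
  expect_equal(augment_contrast(img, 0), matrix(mean(img), 64, 64),
               tolerance = 1e-12)
})

test_that("scale augmentation shrinks content and rejects factors above 1", {
  img <- blob_image(sigma = 12)
  expect_equal(augment_scale(img, 1), img, tolerance = 1e-9)
  small <- augment_scale(img, 0.8)
  # effective blob width scales by s
  width <- function(m) sqrt(sum(m * (row(m) - (nrow(m) + 1) / 2)^2) / sum(m))
  expect_equal(width(small), 0.8 * width(img), tolerance = 0.02)
  expect_error(augment_scale(img, 1.1), "s <= 1")
})

test_that("preprocess maps intensities to [0, 1] line integrals", {
  # constant image degenerates to zeros
  expect_equal(preprocess(matrix(2, 8, 8)), matrix(0, 8, 8))
  # two-valued image {I0, I0/e} -> {0, 1}
  img <- matrix(c(1, exp(-1)), 8, 8)
  out <- preprocess(img)
  expect_equal(sort(unique(as.vector(out))), c(0, 1))
  expect_equal(out[img == 1], rep(0, sum(img == 1)))
  # monotone decreasing in intensity; full range attained
  set.seed(12)
  r <- matrix(runif(256, 0.1, 2), 16, 16)
  pr <- preprocess(r)
  expect_equal(min(pr), 0)
  expect_equal(max(pr), 1)
  o <- order(as.vector(r))
  expect_true(all(diff(as.vector(pr)[o]) <= 1e-12))
  expect_warning(preprocess(matrix(c(0, 1, 2, 3), 2, 2)), "clamped")
})

test_that("flip_image reverses the x axis and is an involution", {
  img <- matrix(1:12, 3, 4)
  expect_equal(flip_image(img), img[3:1, ])
  expect_equal(flip_image(flip_image(img)), img)
})
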