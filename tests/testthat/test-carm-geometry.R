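test_that("beam_direction follows the printed formula and ignores gamma, t", {
  expect_equal(as.vector(beam_direction(pose())), c(0, 0, 1))
  expect_equal(as.vector(beam_direction(pose(alpha = 90))), c(1, 0, 0))
  # direct evaluation of [sin a, -cos a sin b, cos a cos b] at (30, 45)
  expect_equal(as.vector(beam_direction(pose(alpha = 30, beta = 45))),
               c(0.5, -0.61237, 0.61237), tolerance = 1e-4)
  set.seed(1)
  p <- random_poses(200)
  v1 <- beam_direction(p)
  v2 <- beam_direction(pose(p$alpha, p$beta, 0, 0, 0))
  expect_equal(v1, v2)
  expect_equal(sqrt(rowSums(v1^2)), rep(1, nrow(p)), tolerance = 1e-9)
})

test_that("non-finite pose parameters are rejected", {
  expect_error(pose(alpha = NA), "finite")
  expect_error(pose(beta = Inf), "finite")
  expect_error(beam_direction(data.frame(alpha = 1, beta = 2)), "lacks column")
})

test_that("angular_error matches hand-derived ray angles and is symmetric", {
  # acos near 1 resolves angles only to ~1e-6 degrees
  expect_lt(angular_error(pose(12, -7, 40, 3, 9), pose(12, -7, 1, 2, 3)), 1e-5)
  expect_equal(angular_error(pose(alpha = 30), pose()), 30)
  expect_equal(angular_error(pose(beta = 20), pose(beta = -20)), 40)
  set.seed(2)
  a <- random_poses(100); b <- random_poses(100)
  expect_equal(angular_error(a, b), angular_error(b, a))
  expect_true(all(angular_error(a, b) >= 0 & angular_error(a, b) <= 180))
  expect_lt(max(angular_error(a, a)), 1e-5)
})

test_that("gamma_error wraps across +-180 and is periodic", {
  expect_equal(gamma_error(10, 10), 0)
  expect_equal(gamma_error(350, 10), 20)
  expect_equal(gamma_error(180, -180), 0)
  set.seed(3)
  a <- runif(50, -720, 720); b <- runif(50, -720, 720)
  k <- sample(-3:3, 50, TRUE); m <- sample(-3:3, 50, TRUE)
  expect_equal(gamma_error(a + 360 * k, b + 360 * m), gamma_error(a, b))
  expect_true(all(gamma_error(a, b) >= 0 & gamma_error(a, b) <= 180))
})

test_that("translation_error is the Euclidean detector-plane distance", {
  expect_equal(translation_error(pose(), pose()), 0)
  expect_equal(translation_error(pose(tx = 3, ty = 4), pose()), 5)
  expect_equal(translation_error(pose(), pose(tx = -50)), 50)
})

test_that("pose_errors bundles all five metrics rowwise", {
  p <- pose(alpha = c(0, 10), beta = c(0, 0), gamma = c(0, 170),
            tx = c(0, 0), ty = c(0, 0))
  ph <- pose(alpha = c(30, 10), beta = c(0, 0), gamma = c(0, -170),
             tx = c(3, 0), ty = c(4, 0))
  e <- pose_errors(p, ph)
  expect_equal(e$d_theta, c(30, 0), tolerance = 1e-6)
  expect_equal(e$d_alpha, c(30, 0))
  expect_equal(e$d_gamma, c(0, 20))
  expect_equal(e$dc, c(5, 0))
})

test_that("rotation_matrix is orthonormal and consistent with beam_direction", {
  expect_equal(rotation_matrix(pose()), diag(3))
  expect_equal(rotation_matrix(pose(30, 45, 123))[, 3],
               c(0.5, -0.61237, 0.61237), tolerance = 1e-4)
  set.seed(4)
  p <- random_poses(1000)
  for (i in seq_len(100)) {
    R <- rotation_matrix(p[i, ])
    expect_equal(R %*% t(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
  v <- beam_direction(p)
  third <- t(vapply(seq_len(nrow(p)),
                    function(i) rotation_matrix(p[i, ])[, 3], numeric(3)))
  expect_lt(max(abs(third - v)), 1e-9)
})

test_that("pose updates invert sampled offsets and respect laterality", {
  std <- pose(alpha = 5, beta = -3, gamma = 10, tx = 4, ty = -6)
  expect_equal(apply_pose_update(std, pose()), std)
  expect_equal(apply_pose_update(pose(alpha = 10), pose(alpha = 10))$alpha, 0)
  # composing an offset and applying it as update returns the standard pose
  set.seed(5)
  off <- random_poses(50)
  back <- apply_pose_update(compose_pose(std, off), off)
  for (col in c("alpha", "beta", "tx", "ty")) {
    expect_equal(back[[col]], rep(std[[col]], 50), tolerance = 1e-9)
  }
  expect_equal(gamma_error(back$gamma, rep(std$gamma, 50)), rep(0, 50),
               tolerance = 1e-9)
  # update invertibility: apply u then -u
  p <- random_poses(50)
  u <- random_poses(50)
  minus_u <- pose(-u$alpha, -u$beta, -u$gamma, -u$tx, -u$ty)
  round_trip <- apply_pose_update(apply_pose_update(p, u), minus_u)
  expect_equal(round_trip$alpha, p$alpha, tolerance = 1e-9)
  expect_equal(gamma_error(round_trip$gamma, p$gamma), rep(0, 50),
               tolerance = 1e-9)
  # mirrored laterality flips alpha, gamma, tx before application
  upd <- pose(alpha = 10, beta = 2, gamma = 20, tx = 5, ty = 7)
  right <- apply_pose_update(pose(), upd, laterality = "right")
  expect_equal(right$alpha, 10)
  expect_equal(right$beta, -2)
  expect_equal(right$gamma, 20)
  expect_equal(right$tx, 5)
  expect_equal(right$ty, -7)
  # mirror is self-inverse
  expect_equal(mirror_pose(mirror_pose(u)), u)
})

test_that("poses round-trip through JSON", {
  p <- random_poses(5)
  p$laterality <- c("left", "right", "left", "left", "right")
  path <- tempfile(fileext = ".json")
  pose_to_json(p, path)
  q <- pose_from_json(path)
  expect_equal(as.data.frame(q), as.data.frame(p), tolerance = 1e-12)
})

test_that("normalize_angle maps into (-180, 180]", {
  expect_equal(normalize_angle(c(190, -180, 360, 180)), c(-170, 180, 0, 180))
  x <- runif(100, -1000, 1000)
  y <- normalize_angle(x)
  expect_true(all(y > -180 & y <= 180))
  expect_equal(gamma_error(x, y), rep(0, 100), tolerance = 1e-9)
})
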