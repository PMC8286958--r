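test_that("label encoding applies the stated scalings and inverts exactly", {
  # zero pose: out-of-plane and translations zero, sin/cos at (1, 0)
  expect_equal(as.vector(encode_labels(pose(), "coarse")),
               c(0, 0, 1, 0, 0, 0))
  # stated scalings at the domain corners
  expect_equal(as.vector(encode_labels(pose(30, -30, 90, 50, -50), "coarse")),
               c(1, -1, 0, 1, 1, -1), tolerance = 1e-12)
  # round trip on random in-domain poses, both stages
  set.seed(41)
  p <- random_poses(1000, range = 30, t_range = 50)
  back <- decode_labels(encode_labels(p, "coarse"), "coarse")
  expect_equal(as.data.frame(back), as.data.frame(p), tolerance = 1e-9)
  cfg <- sampling_config()
  fs <- 3 * cfg$fine_sigma
  pf <- pose(runif(500, -fs, fs), runif(500, -fs, fs), runif(500, -fs, fs),
             runif(500, -50, 50), runif(500, -50, 50))
  backf <- decode_labels(encode_labels(pf, "fine"), "fine")
  expect_equal(as.data.frame(backf), as.data.frame(pf), tolerance = 1e-9)
  # out-of-domain coarse poses are rejected
  expect_error(encode_labels(pose(alpha = 31), "coarse"), "coarse domain")
  expect_error(encode_labels(pose(tx = 60), "coarse"), "translation")
})

test_that("recover_gamma is the scale-invariant atan2 decoding", {
  expect_equal(recover_gamma(sin(pi / 6), cos(pi / 6)), 30)
  expect_equal(recover_gamma(0, -1), 180)
  set.seed(42)
  theta <- runif(200, -179.999, 180)
  s <- sin(theta * pi / 180); c <- cos(theta * pi / 180)
  expect_equal(recover_gamma(s, c), theta, tolerance = 1e-9)
  lambda <- runif(200, 0.1, 10)
  expect_equal(recover_gamma(lambda * s, lambda * c), theta, tolerance = 1e-9)
  expect_error(recover_gamma(0, 0), "undefined")
})

test_that("the coarse L2 loss reproduces the printed weights", {
  tgt <- encode_output(pose(5, -3, 100, 10, -20), "coarse")
  expect_equal(coarse_loss(tgt, tgt), 0)
  off_alpha <- tgt; off_alpha$alpha <- off_alpha$alpha + 1
  expect_equal(coarse_loss(off_alpha, tgt), 1)
  off_t <- tgt; off_t$tx <- off_t$tx + 1
  expect_equal(coarse_loss(off_t, tgt), (pi / 180)^2)
  # equal-penalty property: 1 degree ~ (180 / pi) mm
  off_eq <- tgt; off_eq$tx <- off_eq$tx + 180 / pi
  expect_equal(coarse_loss(off_eq, tgt), coarse_loss(off_alpha, tgt),
               tolerance = 1e-12)
  # strictly positive away from the target
  set.seed(43)
  for (i in 1:20) {
    pert <- tgt + rnorm(6, sd = 0.1)
    expect_gt(coarse_loss(pert, tgt), 0)
  }
})

test_that("the fine L1 loss penalizes linearly with weight pi/180 on t", {
  tgt <- encode_output(pose(2, 1, -5, 10, 4), "fine")
  expect_equal(fine_loss(tgt, tgt), 0)
  off <- tgt; off$alpha <- off$alpha + 2
  expect_equal(fine_loss(off, tgt), 2)
  off_t <- tgt; off_t$ty <- off_t$ty + 1
  expect_equal(fine_loss(off_t, tgt), pi / 180)
})

test_that("models have the stated head sizes and are seed-deterministic", {
  cfg <- model_config(input_size = 32, channels = c(4, 8, 8, 16),
                      convs_per_block = 1, fc_width = c(32, 16))
  mc <- build_model(cfg, "coarse", seed = 7)
  mf <- build_model(cfg, "fine", seed = 7)
  expect_equal(nrow(mc$params$fc3_W), 6) # extra sin/cos neuron
  expect_equal(nrow(mf$params$fc3_W), 5)
  # raw forward on a zero image is finite (all-zero activations are the
  # degenerate fixed point); decoding needs a non-degenerate image
  Y0 <- carmpose:::.cnn_forward_cpp(mc$params, mc$desc,
                                    matrix(0, 32 * 32, 1))
  expect_true(all(is.finite(Y0)))
  set.seed(99)
  expect_true(all(is.finite(as.matrix(
    predict(mc, matrix(runif(32 * 32), 32, 32))))))
  mc2 <- build_model(cfg, "coarse", seed = 7)
  set.seed(1); x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(predict(mc, x), predict(mc2, x))
  # four blocks, three FC layers in the parameter list
  expect_equal(sum(grepl("^conv\\d_W$", names(mc$params))), 4)
  expect_equal(sum(grepl("^fc\\d_W$", names(mc$params))), 3)
})

test_that("the training loss matches the R reference loss", {
  cfg <- model_config(input_size = 32, channels = c(4, 8, 8, 16),
                      convs_per_block = 1, fc_width = c(32, 16))
  m <- build_model(cfg, "coarse", seed = 8)
  set.seed(2)
  n <- 32
  imgs <- array(runif(32 * 32 * n), c(32, 32, n))
  truth <- random_poses(n, range = 30, t_range = 50)
  pred_raw <- predict(m, imgs) # decoded pose predictions
  # R-side loss in label units from decoded predictions
  X <- imgs; dim(X) <- c(32 * 32, n)
  Y <- t(encode_labels(truth, "coarse", m$sampling))
  w <- carmpose:::loss_weights_normalized("coarse", m$sampling)
  cpp_loss <- carmpose:::.cnn_loss_cpp(m$params, m$desc, X, Y, w, 2L)
  out <- carmpose:::.cnn_forward_cpp(m$params, m$desc, X)
  ref <- mean(vapply(seq_len(n), function(i) {
    o <- tibble::tibble(alpha = out[1, i] * 30, beta = out[2, i] * 30,
                        c_gamma = out[3, i], s_gamma = out[4, i],
                        tx = out[5, i] * 50, ty = out[6, i] * 50)
    coarse_loss(o, encode_output(truth[i, ], "coarse"))
  }, numeric(1)))
  expect_equal(cpp_loss, ref, tolerance = 1e-9)
})

test_that("a one-sample dataset can be driven to near-zero loss", {
  cfg <- model_config(input_size = 32, channels = c(4, 8, 8, 16),
                      convs_per_block = 1, fc_width = c(32, 16))
  m <- build_model(cfg, "coarse", seed = 9)
  img <- array(blob_or_noise <- matrix(runif(32 * 32), 32, 32), c(32, 32, 1))
  lab <- tibble::tibble(subject_id = "S1", split = "train",
                        alpha = 12, beta = -6, gamma = 45, tx = 10, ty = -20)
  ds <- structure(list(images = img, labels = lab, stage = "coarse",
                       sampling = sampling_config(),
                       config = dataset_config(), carm = carm_config(),
                       seed = 1),
                  class = "carm_dataset")
  fit <- train_regressor(m, ds, training_config(learning_rate = 1e-2,
                                                batch_size = 1,
                                                epochs = 30,
                                                batches_per_epoch = 20),
                         seed = 10)
  expect_lt(regressor_loss(fit, ds, split = "train"), 1e-3)
})

test_that("training reduces validation loss on a learnable mapping", {
  # images whose mean brightness encodes alpha: trivially learnable
  set.seed(44)
  n <- 400
  alpha <- runif(n, -30, 30)
  imgs <- array(0, c(32, 32, n))
  for (i in seq_len(n)) {
    imgs[, , i] <- matrix(0.5 + alpha[i] / 90 + rnorm(1024, sd = 0.02), 32, 32)
  }
  lab <- tibble::tibble(
    subject_id = rep(c("A", "B"), each = n / 2),
    split = rep(c("train", "val"), each = n / 2),
    alpha = alpha, beta = 0, gamma = 0, tx = 0, ty = 0
  )
  ds <- structure(list(images = imgs, labels = lab, stage = "fine",
                       sampling = sampling_config(),
                       config = dataset_config(), carm = carm_config(),
                       seed = 1),
                  class = "carm_dataset")
  cfg <- model_config(input_size = 32, channels = c(4, 8, 8, 16),
                      convs_per_block = 1, fc_width = c(32, 16))
  m <- build_model(cfg, "fine", seed = 11)
  before <- regressor_loss(m, ds, split = "val")
  fit <- train_regressor(m, ds, training_config(learning_rate = 1e-3,
                                                epochs = 10,
                                                batches_per_epoch = 20),
                         seed = 12)
  after <- regressor_loss(fit, ds, split = "val")
  expect_lt(after, before)
  expect_equal(nrow(fit$history), 10)
  expect_true(all(is.finite(fit$history$train_loss)))
})

test_that("training aborts cleanly when the loss turns non-finite", {
  cfg <- model_config(input_size = 32, channels = c(4, 8, 8, 16),
                      convs_per_block = 1, fc_width = c(32, 16))
  m <- build_model(cfg, "fine", seed = 13)
  sess <- carmpose:::.cnn_session_new(m$params, m$desc)
  X <- matrix(runif(32 * 32 * 4), 32 * 32, 4)
  Y <- matrix(NaN, 5, 4)
  w <- carmpose:::loss_weights_normalized("fine", sampling_config())
  expect_error(carmpose:::.cnn_session_step(sess, X, Y, w, 1L, 1e-4),
               "diverged")
})

test_that("regressors round-trip through JSON checkpoints", {
  cfg <- model_config(input_size = 32, channels = c(4, 8, 8, 16),
                      convs_per_block = 1, fc_width = c(32, 16))
  m <- build_model(cfg, "fine", seed = 15)
  path <- tempfile(fileext = ".json")
  write_regressor(m, path)
  back <- read_regressor(path)
  set.seed(3); x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  expect_equal(predict(back, x), predict(m, x), tolerance = 1e-12)
})

test_that("tidy and glance summarize regressors", {
  cfg <- model_config(input_size = 32, channels = c(4, 8, 8, 16),
                      convs_per_block = 1, fc_width = c(32, 16))
  m <- build_model(cfg, "coarse", seed = 16)
  td <- tidy(m)
  expect_true(all(c("term", "n") %in% names(td)))
  expect_equal(sum(td$n), sum(vapply(m$params, length, 0)))
  gl <- glance(m)
  expect_equal(gl$stage, "coarse")
  expect_false(gl$trained)
})
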