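#' CNN architecture configuration
#'
#' The pose regressors share one architecture: four convolutional blocks
#' followed by three fully connected layers. Every 3x3 convolution is
#' followed by batch normalization; a ReLU follows the last convolution of
#' each block (i.e. after every `convs_per_block`-th convolutional layer),
#' and each block halves the spatial resolution with a stride-2 convolution.
#' The block/layer structure is fixed; channel and FC widths are free.
#'
#' @param input_size Input image side, pixels (must be divisible by 16).
#' @param channels Output channels of the four blocks.
#' @param convs_per_block Convolutions per block (the last one strides).
#' @param fc_width Widths of the two hidden fully connected layers; the
#'   third FC layer is the output head (6 outputs coarse, 5 fine).
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_size = 256, channels = c(32, 64, 128, 256),
                         convs_per_block = 2, fc_width = c(1024, 256)) {
  stopifnot(length(channels) == 4, length(fc_width) == 2,
            convs_per_block >= 1, input_size %% 16 == 0, input_size >= 16)
  structure(
    list(input_size = as.integer(input_size), channels = as.integer(channels),
         convs_per_block = as.integer(convs_per_block),
         fc_width = as.integer(fc_width)),
    class = "model_config"
  )
}

#' Desk-scale architecture
#'
#' A small instance of the same block structure for 48 x 48 inputs, sized
#' so that the full two-stage experiment trains in minutes on one CPU.
#'
#' @return A [model_config()].
#' @export
desk_model_config <- function() {
  model_config(input_size = 48, channels = c(16, 32, 64, 128),
               convs_per_block = 1, fc_width = c(256, 128))
}

#' Training hyperparameters
#'
#' Adam with learning rate 1e-4 and batch size 64; an epoch is
#' `batches_per_epoch` randomly drawn batches, and the weights with the
#' best validation loss across epochs are kept. When `lr_final` differs
#' from `learning_rate` the rate decays exponentially from one to the
#' other across the epochs (short schedules benefit from a coarse-to-fine
#' step size; the default is a constant rate).
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Samples per batch.
#' @param epochs Training epochs (full-scale reference: 1500).
#' @param batches_per_epoch Batches per epoch (reference: 50).
#' @param lr_final Learning rate in the last epoch.
#' @param verbose Print per-epoch losses.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, batch_size = 64,
                            epochs = 50, batches_per_epoch = 50,
                            lr_final = learning_rate,
                            verbose = FALSE) {
  stopifnot(learning_rate > 0, lr_final > 0, batch_size >= 1, epochs >= 1,
            batches_per_epoch >= 1)
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs),
         batches_per_epoch = as.integer(batches_per_epoch),
         lr_final = lr_final,
         verbose = isTRUE(verbose)),
    class = "training_config"
  )
}

lr_schedule <- function(config) {
  e <- config$epochs
  if (e == 1) return(config$learning_rate)
  config$learning_rate *
    (config$lr_final / config$learning_rate)^((seq_len(e) - 1) / (e - 1))
}

#' Translation loss weight
#'
#' `w = pi / 180`: with this factor a millimetre of detector translation is
#' penalized like a degree of rotation expressed in radians, balancing the
#' orientation (degrees) and translation (mm) terms of the losses.
#'
#' @return The scalar weight.
#' @export
loss_weight <- function() pi / 180

fine_scale <- function(sampling) 3 * sampling$fine_sigma

#' Encode poses as normalized regression targets
#'
#' Coarse stage: `alpha`, `beta` are scaled by `1/coarse_range` and the
#' translations by `1/translation_range` into \[-1, 1\]; the in-plane
#' rotation is mapped to its sin/cos pair `(c_gamma, s_gamma)` so the
#' target is continuous across the +-180 wrap (6 outputs). Fine stage:
#' `alpha`, `beta`, `gamma` are scaled by the 3-sigma bound of the fine
#' Gaussian law and translations by `1/translation_range` (5 outputs); the
#' fine Gaussian is untruncated, so fine targets may rarely exceed 1 in
#' magnitude. The encoding is exactly invertible by [decode_labels()].
#'
#' @param p A pose table.
#' @param stage `"coarse"` or `"fine"`.
#' @param sampling A [sampling_config()] carrying the normalization ranges.
#' @return A numeric matrix, one row per pose; 6 columns
#'   (`alpha, beta, c_gamma, s_gamma, tx, ty`) for coarse, 5
#'   (`alpha, beta, gamma, tx, ty`) for fine.
#' @export
encode_labels <- function(p, stage = c("coarse", "fine"),
                          sampling = sampling_config()) {
  stage <- match.arg(stage)
  p <- as_pose(p)
  r <- sampling$coarse_range
  tr <- sampling$translation_range
  if (stage == "coarse") {
    if (any(abs(p$alpha) > r + 1e-9) || any(abs(p$beta) > r + 1e-9)) {
      stop("pose outside the coarse domain |alpha|, |beta| <= ", r, call. = FALSE)
    }
    if (any(abs(p$tx) > tr + 1e-9) || any(abs(p$ty) > tr + 1e-9)) {
      stop("translation outside the sampling range", call. = FALSE)
    }
    g <- deg2rad(p$gamma)
    cbind(alpha = p$alpha / r, beta = p$beta / r,
          c_gamma = cos(g), s_gamma = sin(g),
          tx = p$tx / tr, ty = p$ty / tr)
  } else {
    fs <- fine_scale(sampling)
    cbind(alpha = p$alpha / fs, beta = p$beta / fs, gamma = p$gamma / fs,
          tx = p$tx / tr, ty = p$ty / tr)
  }
}

#' Decode network outputs back to poses
#'
#' Inverse of [encode_labels()]; the coarse in-plane rotation is recovered
#' from its sin/cos channels with [recover_gamma()].
#'
#' @param y Numeric matrix of (predicted) targets, columns as produced by
#'   [encode_labels()].
#' @param stage `"coarse"` or `"fine"`.
#' @param sampling A [sampling_config()].
#' @return A pose tibble.
#' @export
decode_labels <- function(y, stage = c("coarse", "fine"),
                          sampling = sampling_config()) {
  stage <- match.arg(stage)
  y <- rbind(y)
  r <- sampling$coarse_range
  tr <- sampling$translation_range
  if (stage == "coarse") {
    stopifnot(ncol(y) == 6)
    pose(alpha = y[, 1] * r, beta = y[, 2] * r,
         gamma = recover_gamma(y[, 4], y[, 3]),
         tx = y[, 5] * tr, ty = y[, 6] * tr)
  } else {
    stopifnot(ncol(y) == 5)
    fs <- fine_scale(sampling)
    pose(alpha = y[, 1] * fs, beta = y[, 2] * fs, gamma = y[, 3] * fs,
         tx = y[, 4] * tr, ty = y[, 5] * tr)
  }
}

#' Recover an angle from predicted sin/cos channels
#'
#' \eqn{\hat\gamma = \mathrm{atan2}(\hat s / \lVert(\hat s,\hat c)\rVert,
#' \ \hat c / \lVert(\hat s,\hat c)\rVert)} in degrees: the prediction pair
#' is projected onto the unit circle, so any positive rescaling of
#' `(s, c)` gives the same angle.
#'
#' @param s_gamma,c_gamma Predicted sine and cosine channels.
#' @return Angles in (-180, 180] degrees.
#' @export
recover_gamma <- function(s_gamma, c_gamma) {
  n <- sqrt(s_gamma^2 + c_gamma^2)
  if (any(n == 0)) stop("undefined angle: (s, c) = (0, 0)", call. = FALSE)
  normalize_angle(rad2deg(atan2(s_gamma / n, c_gamma / n)))
}

output_cols <- function(stage) {
  if (stage == "coarse") c("alpha", "beta", "c_gamma", "s_gamma", "tx", "ty")
  else c("alpha", "beta", "gamma", "tx", "ty")
}

#' Regression output in label units from a pose
#'
#' Helper turning a pose table into the output representation the losses
#' operate on (degrees, millimetres, and raw sin/cos channels for the
#' coarse stage).
#'
#' @param p A pose table.
#' @param stage `"coarse"` or `"fine"`.
#' @return A tibble with the stage's output columns.
#' @export
encode_output <- function(p, stage = c("coarse", "fine")) {
  stage <- match.arg(stage)
  p <- as_pose(p)
  if (stage == "coarse") {
    g <- deg2rad(p$gamma)
    tibble::tibble(alpha = p$alpha, beta = p$beta,
                   c_gamma = cos(g), s_gamma = sin(g),
                   tx = p$tx, ty = p$ty)
  } else {
    tibble::tibble(alpha = p$alpha, beta = p$beta, gamma = p$gamma,
                   tx = p$tx, ty = p$ty)
  }
}

#' Coarse-stage weighted L2 loss
#'
#' Sum of squared errors on the out-of-plane rotations (degrees) and on the
#' sin/cos channels of the in-plane rotation, plus `loss_weight()^2` times
#' the squared detector-translation errors (mm), averaged over rows. Zero
#' exactly at the target and strictly positive elsewhere.
#'
#' @param output,target Tibbles with columns `alpha, beta, c_gamma,
#'   s_gamma, tx, ty` (see [encode_output()]).
#' @return Scalar loss.
#' @export
coarse_loss <- function(output, target) {
  w2 <- loss_weight()^2
  d <- as.matrix(output[output_cols("coarse")]) -
    as.matrix(target[output_cols("coarse")])
  mean(d[, 1]^2 + d[, 2]^2 + d[, 3]^2 + d[, 4]^2 + w2 * (d[, 5]^2 + d[, 6]^2))
}

#' Fine-stage weighted L1 loss
#'
#' Sum of absolute rotation errors (degrees) plus `loss_weight()` times the
#' absolute translation errors (mm), averaged over rows; penalizes pose
#' errors linearly.
#'
#' @param output,target Tibbles with columns `alpha, beta, gamma, tx, ty`.
#' @return Scalar loss.
#' @export
fine_loss <- function(output, target) {
  w <- loss_weight()
  d <- as.matrix(output[output_cols("fine")]) -
    as.matrix(target[output_cols("fine")])
  mean(abs(d[, 1]) + abs(d[, 2]) + abs(d[, 3]) + w * (abs(d[, 4]) + abs(d[, 5])))
}

# per-output weights that make the C++ loss (on normalized targets) equal
# the label-unit losses above
loss_weights_normalized <- function(stage, sampling) {
  tr <- sampling$translation_range
  w <- loss_weight()
  if (stage == "coarse") {
    r <- sampling$coarse_range
    c(r^2, r^2, 1, 1, (w * tr)^2, (w * tr)^2)
  } else {
    fs <- fine_scale(sampling)
    c(fs, fs, fs, w * tr, w * tr)
  }
}

#' Build an untrained pose regressor
#'
#' Instantiates the CNN with He-initialized weights. The coarse head has
#' six outputs (the extra neuron carries the second in-plane channel), the
#' fine head five.
#'
#' @param config A [model_config()].
#' @param stage `"coarse"` or `"fine"`.
#' @param sampling The [sampling_config()] fixing the label normalization.
#' @param seed Optional integer seed for the weight initialization.
#' @return An object of class `carm_regressor`.
#' @export
build_model <- function(config = desk_model_config(),
                        stage = c("coarse", "fine"),
                        sampling = sampling_config(), seed = NULL) {
  stage <- match.arg(stage)
  if (!is.null(seed)) set.seed(seed)
  out_dim <- if (stage == "coarse") 6L else 5L
  cpb <- config$convs_per_block
  conv_channels <- rep(config$channels, each = cpb)
  conv_stride <- rep(c(rep(1L, cpb - 1L), 2L), 4L)
  conv_relu <- rep(c(rep(0L, cpb - 1L), 1L), 4L)
  hw_out <- config$input_size / 16L
  flat <- hw_out^2 * config$channels[4]
  fc_sizes <- c(config$fc_width, out_dim)
  fc_in <- c(flat, config$fc_width)

  params <- list()
  cin <- 1L
  for (l in seq_along(conv_channels)) {
    cout <- conv_channels[l]
    params[[paste0("conv", l, "_W")]] <-
      matrix(stats::rnorm(cout * cin * 9, sd = sqrt(2 / (cin * 9))), cout, cin * 9)
    params[[paste0("conv", l, "_gamma")]] <- rep(1, cout)
    params[[paste0("conv", l, "_beta")]] <- rep(0, cout)
    params[[paste0("conv", l, "_rmean")]] <- rep(0, cout)
    params[[paste0("conv", l, "_rvar")]] <- rep(1, cout)
    cin <- cout
  }
  for (l in seq_along(fc_sizes)) {
    params[[paste0("fc", l, "_W")]] <-
      matrix(stats::rnorm(fc_sizes[l] * fc_in[l], sd = sqrt(2 / fc_in[l])),
             fc_sizes[l], fc_in[l])
    params[[paste0("fc", l, "_b")]] <- rep(0, fc_sizes[l])
  }
  structure(
    list(stage = stage, config = config, sampling = sampling,
         desc = list(input_size = config$input_size,
                     conv_channels = as.integer(conv_channels),
                     conv_stride = as.integer(conv_stride),
                     conv_relu = as.integer(conv_relu),
                     fc_sizes = as.integer(fc_sizes)),
         params = params, trained = FALSE, history = NULL),
    class = "carm_regressor"
  )
}

#' @export
print.carm_regressor <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0))
  cat(sprintf("<carm_regressor> %s stage, input %d px, %d parameters, %s\n",
              x$stage, x$config$input_size, np,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

images_as_matrix <- function(images, input_size) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  d <- dim(images)
  stopifnot(length(d) == 3, d[1] == input_size, d[2] == input_size)
  dim(images) <- c(d[1] * d[2], d[3])
  images
}

#' Train a pose regressor on a labeled dataset
#'
#' Runs seeded minibatch Adam on the weighted stage loss (L2 with sin/cos
#' in-plane channels for coarse, L1 for fine), computing the loss in label
#' units (degrees / mm). Training and validation subjects come from the
#' dataset's `split` column and are disjoint by construction of the
#' cohort. The returned model carries the weights of the epoch with the
#' lowest validation loss and a per-epoch loss history.
#'
#' @param model A `carm_regressor` from [build_model()].
#' @param dataset A `carm_dataset` of the same stage.
#' @param config A [training_config()].
#' @param seed Optional seed for batch sampling.
#' @return The trained `carm_regressor`; `$history` holds a tibble of
#'   per-epoch train/validation losses.
#' @export
train_regressor <- function(model, dataset, config = training_config(),
                            seed = NULL) {
  stopifnot(inherits(model, "carm_regressor"), inherits(dataset, "carm_dataset"))
  if (!identical(model$stage, dataset$stage)) {
    stop("model and dataset stages differ", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  lab <- dataset$labels
  is_train <- lab$split == "train"
  is_val <- lab$split == "val"
  if (!any(is_train)) stop("dataset holds no training split", call. = FALSE)
  train_subj <- unique(lab$subject_id[is_train])
  val_subj <- unique(lab$subject_id[is_val])
  if (length(intersect(train_subj, val_subj))) {
    stop("train and validation subjects overlap", call. = FALSE)
  }
  w <- loss_weights_normalized(model$stage, model$sampling)
  loss_type <- if (model$stage == "coarse") 2L else 1L

  if (identical(dataset$store, "projection")) {
    fit <- train_online(model, dataset, config, w, loss_type)
  } else {
    X <- images_as_matrix(dataset$images, model$config$input_size)
    Y <- t(encode_labels(lab, model$stage, model$sampling))
    fit <- .cnn_train_cpp(
      model$params, model$desc,
      X[, is_train, drop = FALSE], Y[, is_train, drop = FALSE],
      X[, is_val, drop = FALSE], Y[, is_val, drop = FALSE],
      w, loss_type, lr_schedule(config), config$batch_size,
      config$epochs, config$batches_per_epoch, config$verbose
    )
    # re-estimate the batch-norm statistics over the training set so that
    # inference reproduces training-time normalization
    fit$params <- .cnn_calibrate_bn_cpp(fit$params, model$desc,
                                        X[, is_train, drop = FALSE])
  }
  model$params <- fit$params
  model$trained <- TRUE
  model$history <- tibble::tibble(
    epoch = seq_len(config$epochs),
    train_loss = as.double(fit$train_loss),
    val_loss = as.double(fit$val_loss)
  )
  model$best_val <- fit$best_val
  model$training <- config
  model
}

# minibatch loop with online augmentation: every batch samples projections
# and draws fresh in-plane rotation / translation / scale / contrast
# augmentations, exactly the laws the dataset builder uses.
train_online <- function(model, dataset, config, w, loss_type) {
  lab <- dataset$labels
  cfg <- dataset$config
  pitch <- cfg$sim_fov / cfg$sim_resolution
  sampling <- dataset$sampling
  stage <- dataset$stage
  sr <- dataset$scale_range %||% c(0.8, 1)
  cr <- dataset$contrast_range %||% c(0.75, 1.25)
  fs <- cfg$final_size
  stopifnot(fs == model$config$input_size)

  draw_batch <- function(idx) {
    n <- length(idx)
    gam <- sample_gamma(n, stage, sampling)
    tr <- sample_translation(n, sampling)
    s_draw <- stats::runif(n, sr[1], sr[2])
    c_draw <- stats::runif(n, cr[1], cr[2])
    X <- matrix(0, fs * fs, n)
    for (b in seq_len(n)) {
      X[, b] <- augment_projection(dataset$images[, , idx[b]], gam[b],
                                   tr[b, ], s_draw[b], c_draw[b], pitch, fs)
    }
    p <- pose(alpha = lab$alpha[idx], beta = lab$beta[idx],
              gamma = gam, tx = tr[, 1], ty = tr[, 2])
    list(X = X, Y = t(encode_labels(p, stage, sampling)))
  }

  tr_idx <- which(lab$split == "train")
  va_idx <- which(lab$split == "val")
  # fixed augmented validation set for stable model selection
  val <- if (length(va_idx)) {
    vb <- draw_batch(rep(va_idx, length.out = min(1024, 4 * length(va_idx))))
  } else NULL

  sess <- .cnn_session_new(model$params, model$desc)
  lr <- lr_schedule(config)
  tr_hist <- va_hist <- rep(NA_real_, config$epochs)
  best_val <- Inf
  best_params <- NULL
  for (ep in seq_len(config$epochs)) {
    ep_loss <- 0
    for (it in seq_len(config$batches_per_epoch)) {
      idx <- sample(tr_idx, min(config$batch_size, length(tr_idx)))
      batch <- draw_batch(idx)
      ep_loss <- ep_loss + .cnn_session_step(sess, batch$X, batch$Y, w,
                                             loss_type, lr[ep])
    }
    tr_hist[ep] <- ep_loss / config$batches_per_epoch
    if (!is.null(val)) {
      params <- .cnn_session_params(sess)
      cb <- draw_batch(sample(tr_idx, min(256, length(tr_idx))))
      params <- .cnn_calibrate_bn_cpp(params, model$desc, cb$X)
      va_hist[ep] <- .cnn_loss_cpp(params, model$desc, val$X, val$Y, w,
                                   loss_type)
      if (va_hist[ep] < best_val) {
        best_val <- va_hist[ep]
        best_params <- params
      }
    }
    if (config$verbose) {
      message(sprintf("epoch %3d  train %.4f  val %s", ep, tr_hist[ep],
                      if (is.null(val)) "-" else sprintf("%.4f", va_hist[ep])))
    }
  }
  # recalibrate the selected weights on a large augmented training sample
  chosen <- if (is.null(best_params)) .cnn_session_params(sess) else best_params
  if (is.null(best_params)) best_val <- NA_real_
  calib <- draw_batch(sample(tr_idx, min(2048, length(tr_idx)), replace = TRUE))
  params <- .cnn_calibrate_bn_cpp(chosen, model$desc, calib$X)
  list(params = params, train_loss = tr_hist, val_loss = va_hist,
       best_val = best_val)
}

#' Predict pose updates from images
#'
#' Runs the network forward (inference-mode batch normalization) and
#' decodes the outputs back to pose space.
#'
#' @param object A trained `carm_regressor`.
#' @param images A single image matrix or an array `size x size x n`,
#'   preprocessed as by [make_input_image()].
#' @param ... Unused.
#' @return A pose tibble of predicted updates, one row per image.
#' @export
predict.carm_regressor <- function(object, images, ...) {
  X <- images_as_matrix(images, object$config$input_size)
  Y <- .cnn_forward_cpp(object$params, object$desc, X)
  decode_labels(t(Y), object$stage, object$sampling)
}

#' Evaluate the stage loss of a model on a dataset
#'
#' @param model A `carm_regressor`.
#' @param dataset A `carm_dataset` of the same stage.
#' @param split Which split(s) to evaluate.
#' @return Scalar loss in label units.
#' @export
regressor_loss <- function(model, dataset, split = "val") {
  keep <- dataset$labels$split %in% split
  stopifnot(any(keep))
  X <- images_as_matrix(dataset$images, model$config$input_size)[, keep, drop = FALSE]
  Y <- t(encode_labels(dataset$labels[keep, ], model$stage, model$sampling))
  .cnn_loss_cpp(model$params, model$desc, X, Y,
                loss_weights_normalized(model$stage, model$sampling),
                if (model$stage == "coarse") 2L else 1L)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pose regressor: one row per parameter tensor
#'
#' @param x A `carm_regressor`.
#' @param ... Unused.
#' @return A tibble with `term`, `rows`, `cols`, `n`.
#' @export
tidy.carm_regressor <- function(x, ...) {
  tibble::tibble(
    term = names(x$params),
    rows = vapply(x$params, NROW, 0),
    cols = vapply(x$params, NCOL, 0),
    n = vapply(x$params, length, 0)
  )
}

#' One-row model summary
#'
#' @param x A `carm_regressor`.
#' @param ... Unused.
#' @return A one-row tibble: stage, input size, parameter count, epochs
#'   trained and best validation loss.
#' @export
glance.carm_regressor <- function(x, ...) {
  tibble::tibble(
    stage = x$stage,
    input_size = x$config$input_size,
    n_parameters = sum(vapply(x$params, length, 0)),
    trained = x$trained,
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    best_val_loss = if (is.null(x$best_val)) NA_real_ else x$best_val
  )
}

#' Save / load a regressor checkpoint
#'
#' Checkpoints are plain JSON (weights flattened), so they are portable
#' and diffable.
#'
#' @param model A `carm_regressor`.
#' @param path File path (`.json`).
#' @return `write_regressor`: `path` invisibly; `read_regressor`: the model.
#' @export
write_regressor <- function(model, path) {
  obj <- list(
    stage = model$stage,
    config = unclass(model$config),
    sampling = unclass(model$sampling),
    desc = model$desc,
    trained = model$trained,
    params = lapply(model$params, function(p) {
      list(dim = dim(p) %||% length(p), data = as.double(p))
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_regressor
#' @export
read_regressor <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, obj$config)
  samp <- do.call(sampling_config, obj$sampling)
  model <- build_model(cfg, obj$stage, samp)
  stopifnot(identical(names(model$params), names(obj$params)))
  model$params <- purrr::map2(obj$params, model$params, function(saved, proto) {
    v <- as.double(saved$data)
    if (is.matrix(proto)) matrix(v, nrow(proto), ncol(proto)) else v
  })
  model$trained <- isTRUE(obj$trained)
  model
}
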