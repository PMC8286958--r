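#' Simulation-in-the-loop imaging device
#'
#' Wraps a phantom volume and the imaging configuration into a function
#' `device(abs_pose)` returning the preprocessed network input image for an
#' absolute C-arm pose — the role a real C-arm plays at deployment. All
#' evaluation in this package runs against this simulated device; a
#' hardware adapter only needs to honour the same one-argument contract.
#'
#' @param volume A [volume_grid()].
#' @param carm A [carm_config()].
#' @param config A [dataset_config()].
#' @return A function mapping a one-row pose table to an input image.
#' @export
carm_simulator <- function(volume, carm = carm_config(),
                           config = dataset_config()) {
  force(volume); force(carm); force(config)
  function(abs_pose) make_input_image(volume, abs_pose, carm, config)
}

#' Perfect-oracle stand-in for a trained regressor
#'
#' Returns the true pose offset of the current pose from the standard pose
#' instead of predicting it from the image. Useful for plumbing checks of
#' the inference pipeline and the evaluation harness: with oracle models
#' every repositioning step lands exactly on the standard pose, so every
#' reported error must be zero.
#'
#' @param stage `"coarse"` or `"fine"`.
#' @param sampling A [sampling_config()].
#' @return An object of class `carm_oracle` usable wherever a trained
#'   `carm_regressor` is expected by [two_stage_predict()] and
#'   [evaluate_regressors()].
#' @export
oracle_regressor <- function(stage = c("coarse", "fine"),
                             sampling = sampling_config()) {
  stage <- match.arg(stage)
  structure(list(stage = stage, sampling = sampling, trained = TRUE),
            class = "carm_oracle")
}

# one prediction step: trained models see only the image; the oracle is
# handed the true poses instead
predict_update <- function(model, image, current, standard) {
  if (inherits(model, "carm_oracle")) {
    if (is.null(standard)) stop("oracle prediction requires the standard pose")
    apply_pose_update(current, standard) # current - standard
  } else {
    predict(model, image)
  }
}

#' Two-stage sequential pose prediction
#'
#' From an initial absolute pose, acquires an image from the device, lets
#' the coarse regressor predict the 5-DoF update, repositions with
#' [apply_pose_update()], re-acquires, and refines once with the fine
#' regressor. Returns the pose trajectory (initial, post-coarse,
#' post-fine). If the initial offset from `standard` exceeds the coarse
#' capture range, a warning flag is set in the output but the prediction is
#' still returned.
#'
#' @param initial_pose Absolute initial [pose()] (one row).
#' @param coarse_model,fine_model Trained `carm_regressor`s.
#' @param device A device function from [carm_simulator()].
#' @param standard The subject's standard pose (used only for the
#'   capture-range flag; pass `NULL` to skip the check).
#' @param laterality `"left"` or `"right"`; a right-side image is flipped
#'   before prediction and the update is un-mirrored on application.
#' @return A tibble with rows `initial`, `coarse`, `fine`: the stage, the
#'   absolute pose columns and `outside_capture_range`.
#' @export
two_stage_predict <- function(initial_pose, coarse_model, fine_model, device,
                              standard = NULL,
                              laterality = c("left", "right")) {
  laterality <- match.arg(laterality)
  p0 <- as_pose(initial_pose)
  stopifnot(nrow(p0) == 1L)
  outside <- FALSE
  if (!is.null(standard)) {
    off <- apply_pose_update(p0, standard) # offset = initial - standard
    r <- coarse_model$sampling$coarse_range + 1e-9
    outside <- abs(off$alpha) > r || abs(off$beta) > r
    if (outside) warning("initial pose outside the coarse capture range")
  }
  acquire <- function(p) {
    img <- device(p)
    if (laterality == "right") flip_image(img) else img
  }
  u1 <- predict_update(coarse_model, acquire(p0), p0, standard)
  p1 <- apply_pose_update(p0, u1, laterality)
  u2 <- predict_update(fine_model, acquire(p1), p1, standard)
  p2 <- apply_pose_update(p1, u2, laterality)
  out <- dplyr::bind_rows(p0, p1, p2)
  tibble::tibble(stage = c("initial", "coarse", "fine"), out,
                 outside_capture_range = outside)
}

#' Evaluate regressors on the test split of a phantom cohort
#'
#' The parameter-recovery harness: for every test subject, `n_initial`
#' initial poses are drawn around the subject's standard pose from the
#' coarse sampling law (a random grid vertex for `alpha`, `beta`, uniform
#' in-plane rotation, uniform detector translation), and three repositioning
#' strategies are run against the simulated device:
#' \describe{
#'   \item{`two_stage`}{coarse prediction, reposition, fine prediction
#'     (the proposed pipeline; its `coarse` row doubles as the
#'     single-prediction baseline).}
#'   \item{`iterated_coarse`}{the coarse network applied twice with one
#'     re-projection in between.}
#' }
#' All five error metrics are computed against the subject's standard pose
#' after every stage.
#'
#' @param coarse_model,fine_model Trained `carm_regressor`s.
#' @param cohort A cohort tibble from [make_cohort()].
#' @param carm,config,sampling Imaging and sampling configuration (must
#'   match the training datasets).
#' @param n_initial Initial poses per test subject.
#' @param seed Seed for the initial-pose draws.
#' @param split Cohort split to evaluate (default `"test"`).
#' @return A `carm_eval` object: `$samples` has one row per (subject,
#'   draw, method, stage) with the error metrics; `$aggregates` the
#'   mean/sd/median per method, stage and metric; `$meta` seeds and sizes.
#' @export
evaluate_regressors <- function(coarse_model, fine_model, cohort,
                                carm = carm_config(),
                                config = dataset_config(),
                                sampling = sampling_config(),
                                n_initial = 25, seed = 1L, split = "test") {
  rows <- which(cohort$split %in% split)
  if (!length(rows)) stop("cohort has no subjects in split ", split, call. = FALSE)
  set.seed(seed)
  grid <- sample_coarse_poses(sampling)
  samples <- list()
  for (r in rows) {
    std <- pose(cohort$alpha[r], cohort$beta[r], cohort$gamma[r],
                cohort$tx[r], cohort$ty[r])
    device <- carm_simulator(cohort$volume[[r]], carm, config)
    pick <- base::sample(nrow(grid), n_initial, replace = TRUE)
    gam <- sample_gamma(n_initial, "coarse", sampling)
    tr <- sample_translation(n_initial, sampling)
    for (i in seq_len(n_initial)) {
      off <- pose(grid$alpha[pick[i]], grid$beta[pick[i]], gam[i],
                  tr[i, 1], tr[i, 2])
      p0 <- compose_pose(std, off)
      traj <- two_stage_predict(p0, coarse_model, fine_model, device,
                                standard = std)
      # iterated coarse: apply the coarse network twice
      u1 <- predict_update(coarse_model, device(p0), p0, std)
      q1 <- apply_pose_update(p0, u1)
      u2 <- predict_update(coarse_model, device(q1), q1, std)
      q2 <- apply_pose_update(q1, u2)
      it <- tibble::tibble(stage = c("initial", "stage1", "stage2"),
                           dplyr::bind_rows(p0, q1, q2))
      traj$stage <- c("initial", "stage1", "stage2")
      for (m in list(list(name = "two_stage", tr = traj),
                     list(name = "iterated_coarse", tr = it))) {
        err <- pose_errors(std, m$tr[c("alpha", "beta", "gamma", "tx", "ty")])
        samples[[length(samples) + 1L]] <- tibble::tibble(
          subject_id = cohort$subject_id[r], draw = i, method = m$name,
          stage = m$tr$stage, err
        )
      }
    }
  }
  samples <- dplyr::bind_rows(samples)
  long <- tidyr::pivot_longer(samples, dplyr::all_of(metric_names()),
                              names_to = "metric", values_to = "value")
  aggregates <- dplyr::summarise(
    dplyr::group_by(long, .data$method, .data$stage, .data$metric),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    median = stats::median(.data$value), .groups = "drop"
  )
  structure(
    list(samples = samples, aggregates = aggregates,
         meta = list(seed = seed, n_initial = n_initial,
                     subjects = cohort$subject_id[rows],
                     n_samples = nrow(samples))),
    class = "carm_eval"
  )
}

metric_names <- function() c("d_theta", "d_alpha", "d_beta", "d_gamma", "dc")

#' @export
print.carm_eval <- function(x, ...) {
  cat("<carm_eval>", length(x$meta$subjects), "test subjects x",
      x$meta$n_initial, "initial poses\n")
  agg <- dplyr::filter(x$aggregates, .data$metric == "d_theta")
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-16s %-8s mean d_theta %6.2f deg\n",
                agg$method[i], agg$stage[i], agg$mean[i]))
  }
  invisible(x)
}

#' Tidy an evaluation report: one row per sample and metric
#'
#' @param x A `carm_eval`.
#' @param ... Unused.
#' @return A long tibble: subject, draw, method, stage, metric, value.
#' @export
tidy.carm_eval <- function(x, ...) {
  tidyr::pivot_longer(x$samples, dplyr::all_of(metric_names()),
                      names_to = "metric", values_to = "value")
}

#' One-row summary of an evaluation report
#'
#' @param x A `carm_eval`.
#' @param ... Unused.
#' @return A one-row tibble with the mean `d_theta`, `d_gamma` and `dc` of
#'   the two-stage trajectory (initial / post-coarse / post-fine) and the
#'   iterated-coarse endpoint.
#' @export
glance.carm_eval <- function(x, ...) {
  g <- function(method, stage, metric) {
    v <- dplyr::filter(x$aggregates, .data$method == !!method,
                       .data$stage == !!stage, .data$metric == !!metric)
    v$mean
  }
  tibble::tibble(
    n = x$meta$n_samples,
    d_theta_initial = g("two_stage", "initial", "d_theta"),
    d_theta_coarse = g("two_stage", "stage1", "d_theta"),
    d_theta_fine = g("two_stage", "stage2", "d_theta"),
    d_theta_iterated = g("iterated_coarse", "stage2", "d_theta"),
    d_gamma_coarse = g("two_stage", "stage1", "d_gamma"),
    d_gamma_fine = g("two_stage", "stage2", "d_gamma"),
    dc_coarse = g("two_stage", "stage1", "dc"),
    dc_fine = g("two_stage", "stage2", "dc")
  )
}

#' Write an evaluation report to disk
#'
#' Per-sample metrics as CSV, aggregates as JSON.
#'
#' @param eval_report A `carm_eval`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(eval_report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(eval_report$samples, file.path(dir, "samples.csv"))
  jsonlite::write_json(
    list(aggregates = eval_report$aggregates, meta = eval_report$meta),
    file.path(dir, "aggregates.json"), digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}

#' Desk-scale parameter-recovery benchmark
#'
#' The package's end-to-end experiment: generate a randomized femur-phantom
#' cohort, build coarse and fine training sets, train both regressors, and
#' evaluate the two-stage pipeline and the iterated-coarse baseline on the
#' held-out test subjects. Everything is a deterministic function of
#' `seed`. Problem sizes default to the desk scale documented in the
#' methods vignette (30 subjects, 64 x 64 inputs).
#'
#' @param seed Integer master seed.
#' @param n_subjects Cohort size.
#' @param model_cfg A [model_config()].
#' @param train_cfg Coarse-stage [training_config()]; the desk default runs
#'   3000 Adam steps with an exponentially decaying rate.
#' @param fine_train_cfg Fine-stage [training_config()] (the narrow fine
#'   pose law converges in fewer steps).
#' @param config A [dataset_config()].
#' @param sampling A [sampling_config()].
#' @param carm A [carm_config()]; the desk default marches rays at the
#'   voxel spacing.
#' @param n_initial Initial poses per test subject during evaluation.
#' @param verbose Print progress.
#' @return A list: `eval` (a `carm_eval`), `coarse_model`, `fine_model`,
#'   `cohort`, and `timings` (seconds per phase).
#' @export
run_recovery_benchmark <- function(seed = 1L, n_subjects = 30,
                                   model_cfg = desk_model_config(),
                                   train_cfg = training_config(
                                     learning_rate = 1e-3, lr_final = 1e-4,
                                     epochs = 85, batches_per_epoch = 50),
                                   fine_train_cfg = training_config(
                                     learning_rate = 1e-3, lr_final = 1e-4,
                                     epochs = 34, batches_per_epoch = 50),
                                   config = dataset_config(),
                                   sampling = sampling_config(),
                                   carm = carm_config(step_size = 2),
                                   n_initial = 25, verbose = FALSE) {
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  say <- function(...) if (verbose) message(sprintf(...))

  say("building %d-subject cohort ...", n_subjects)
  cohort <- make_cohort(n_subjects, phantom_spec(), seed = seed)
  t1 <- tic()

  say("rendering coarse training set ...")
  ds_coarse <- build_dataset(cohort, "coarse", sampling, config, carm,
                             seed = seed + 1L, store = "projection")
  t2 <- tic()
  say("training coarse regressor (online augmentation) ...")
  coarse <- build_model(model_cfg, "coarse", sampling, seed = seed + 3L)
  coarse <- train_regressor(coarse, ds_coarse, train_cfg, seed = seed + 4L)
  rm(ds_coarse)

  say("rendering fine training set ...")
  ds_fine <- build_dataset(cohort, "fine", sampling, config, carm,
                           seed = seed + 2L, store = "projection")
  say("training fine regressor (online augmentation) ...")
  fine <- build_model(model_cfg, "fine", sampling, seed = seed + 5L)
  fine <- train_regressor(fine, ds_fine, fine_train_cfg, seed = seed + 6L)
  rm(ds_fine)
  t3 <- tic()

  say("evaluating on held-out subjects ...")
  ev <- evaluate_regressors(coarse, fine, cohort, carm, config, sampling,
                            n_initial = n_initial, seed = seed + 7L)
  t4 <- tic()

  list(
    eval = ev, coarse_model = coarse, fine_model = fine, cohort = cohort,
    timings = c(cohort = t1 - t0, coarse_render = t2 - t1,
                training = t3 - t2, evaluation = t4 - t3)
  )
}
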