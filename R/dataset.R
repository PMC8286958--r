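#' Dataset rendering configuration
#'
#' Controls how labeled training images are rendered and assembled.
#' `sim_fov` is the detector region rendered by the projector, in detector
#' millimetres (default: the full 300 mm panel at 72 px). The in-plane
#' rotation augmentation centre-crops to the inscribed `1/sqrt(2)` region,
#' and the translation crop then shifts a window inside what remains; the
#' final network input covers [final_fov()] detector millimetres at
#' `final_size` pixels.
#'
#' Two ways of realizing the translation label are supported. `"crop"`
#' (default) shifts the crop window on a single rendered projection, so one
#' ray cast serves all `augmentations_per_pose` samples of a pose —
#' rotation, translation, scale and contrast augmentation are then nearly
#' free, which is what makes dense augmentation affordable. `"projector"`
#' applies `(tx, ty)` as a physical detector offset during ray casting
#' (exact cone-beam parallax, one cast per sample).
#'
#' @param final_size Network input side, pixels.
#' @param sim_resolution Rendered image side, pixels.
#' @param sim_fov Rendered detector region, mm.
#' @param augmentations_per_pose Augmented samples emitted per sampled pose.
#' @param n_fine_per_subject Fine-stage poses drawn per subject.
#' @param translation_mode `"projector"` or `"crop"`.
#' @param I0 Unattenuated flux used for the Beer-Lambert conversion.
#' @return An object of class `dataset_config`.
#' @export
dataset_config <- function(final_size = 48, sim_resolution = 72,
                           sim_fov = 300, augmentations_per_pose = 4,
                           n_fine_per_subject = 200,
                           translation_mode = c("crop", "projector"),
                           I0 = 1) {
  translation_mode <- match.arg(translation_mode)
  stopifnot(final_size >= 16, sim_resolution >= 32, sim_fov > 0,
            augmentations_per_pose >= 1, n_fine_per_subject >= 1, I0 > 0)
  structure(
    list(final_size = as.integer(final_size),
         sim_resolution = as.integer(sim_resolution),
         sim_fov = sim_fov,
         augmentations_per_pose = as.integer(augmentations_per_pose),
         n_fine_per_subject = as.integer(n_fine_per_subject),
         translation_mode = translation_mode, I0 = I0),
    class = "dataset_config"
  )
}

#' Field of view of the final network input, mm at the detector
#'
#' The network input is a `final_size`-pixel window cropped from the
#' rendered projection at its native pixel pitch, so the field of view is
#' simply `final_size * sim_fov / sim_resolution` (112.5 mm at the
#' defaults). The rendered region must be large enough that a window
#' rotated by any angle and shifted by any translation within the sampling
#' law stays (almost) inside it; border samples repeat edge values.
#'
#' @param config A [dataset_config()].
#' @return Millimetres of detector covered by the network input.
#' @export
final_fov <- function(config) {
  config$final_size * config$sim_fov / config$sim_resolution
}

sim_carm <- function(carm, config) {
  carm_config(
    source_detector_distance = carm$source_detector_distance,
    source_isocenter_distance = carm$source_isocenter_distance,
    detector_size = config$sim_fov,
    sim_resolution = config$sim_resolution,
    step_size = carm$step_size
  )
}

#' Render the network input image for an absolute C-arm pose
#'
#' The deployment-time image path: project the volume at `abs_pose`
#' (all five parameters physical, including the detector rotation and
#' offset), convert to intensities, centre-crop to the training field of
#' view, resize to the network input size, and preprocess. Training images
#' built by [build_dataset()] cover the identical field of view, so a
#' trained regressor can be applied directly to these images.
#'
#' @param volume A [volume_grid()].
#' @param abs_pose A single absolute [pose()].
#' @param carm A [carm_config()] (its `detector_size` is ignored in favour
#'   of the rendered `sim_fov`).
#' @param config A [dataset_config()].
#' @return A `final_size` x `final_size` matrix in \[0, 1\].
#' @export
make_input_image <- function(volume, abs_pose, carm = carm_config(),
                             config = dataset_config()) {
  sc <- sim_carm(carm, config)
  img <- to_intensity(project(volume, abs_pose, sc), config$I0)
  img <- resample_affine(img, diag(2), c(0, 0), config$final_size,
                         pad = "edge")
  preprocess(img)
}

#' Build a labeled coarse- or fine-stage dataset from a phantom cohort
#'
#' For every subject in the requested splits, pose offsets are sampled
#' relative to that subject's standard pose (the coarse grid or the fine
#' Gaussian law), each offset is rendered by the projector, augmented
#' (in-plane rotation, translation crop, scale, contrast) and preprocessed,
#' and the offset itself becomes the label. All randomness is funnelled
#' through one seeded generator, so a rebuild with the same seed reproduces
#' the label table bit for bit.
#'
#' With `store = "projection"` the dataset keeps the rendered projections
#' themselves (one per pose, intensity domain) instead of augmented network
#' inputs; [train_regressor()] then draws the augmentations fresh for every
#' batch (online augmentation). This is the preferred mode for training:
#' the network never sees the same augmented sample twice. `store =
#' "final"` bakes `augmentations_per_pose` samples per pose into the
#' dataset, which is what the serialization round trip and fixed-dataset
#' workflows use.
#'
#' @param cohort A cohort tibble from [make_cohort()].
#' @param stage `"coarse"` or `"fine"`.
#' @param sampling A [sampling_config()].
#' @param config A [dataset_config()].
#' @param carm A [carm_config()].
#' @param splits Which cohort splits to include.
#' @param seed Integer seed for the sampling and augmentation draws.
#' @param scale_range,contrast_range Online augmentation laws.
#' @param store `"final"` (augmented network inputs) or `"projection"`
#'   (raw projections for online augmentation during training).
#' @return A `carm_dataset`: list with `images` (array, one slice per
#'   sample), `labels` (tibble: subject_id, split, stage, the pose-offset
#'   label columns `alpha`...`ty`, and for `store = "final"` the
#'   augmentation draws `gamma`, `tx`, `ty`, `s`, `c`), and the
#'   configurations used.
#' @export
build_dataset <- function(cohort, stage = c("coarse", "fine"),
                          sampling = sampling_config(),
                          config = dataset_config(),
                          carm = carm_config(),
                          splits = c("train", "val"),
                          seed = 1L,
                          scale_range = c(0.8, 1),
                          contrast_range = c(0.75, 1.25),
                          store = c("final", "projection")) {
  stage <- match.arg(stage)
  store <- match.arg(store)
  stopifnot(nrow(cohort) > 0)
  if (scale_range[2] > 1) stop("scale augmentation must not exceed 1", call. = FALSE)
  if (contrast_range[1] > 1 || contrast_range[2] < 1) {
    stop("contrast range must contain 1", call. = FALSE)
  }
  rows <- which(cohort$split %in% splits)
  if (!length(rows)) stop("no cohort subjects in requested splits", call. = FALSE)
  set.seed(seed)
  sc <- sim_carm(carm, config)
  pitch <- pixel_pitch(sc)
  n_aug <- if (store == "projection") 1L else config$augmentations_per_pose
  out_px <- if (store == "projection") config$sim_resolution else config$final_size

  all_imgs <- list()
  all_labels <- list()
  for (r in rows) {
    vol <- cohort$volume[[r]]
    std <- cohort[r, c("alpha", "beta", "gamma", "tx", "ty")]
    offsets <- if (stage == "coarse") {
      sample_coarse_poses(sampling)
    } else {
      sample_fine_poses(config$n_fine_per_subject, sampling)
    }
    n_pose <- nrow(offsets)
    n_samp <- n_pose * n_aug
    gam <- sample_gamma(n_samp, stage, sampling)
    tr <- sample_translation(n_samp, sampling)
    s_draw <- stats::runif(n_samp, scale_range[1], scale_range[2])
    c_draw <- stats::runif(n_samp, contrast_range[1], contrast_range[2])

    imgs <- array(0, c(out_px, out_px, n_samp))
    k <- 0L
    for (i in seq_len(n_pose)) {
      base_proj <- NULL
      for (a in seq_len(n_aug)) {
        k <- k + 1L
        off <- offsets[i, ]
        if (store == "final" && config$translation_mode == "projector") {
          # the label (tx, ty) lives in the final image frame; the physical
          # detector offset is applied before the in-plane rotation
          # augmentation, so rotate it forward by the drawn gamma
          g <- deg2rad(gam[k])
          off$tx <- cos(g) * tr[k, 1] - sin(g) * tr[k, 2]
          off$ty <- sin(g) * tr[k, 1] + cos(g) * tr[k, 2]
          abs_pose <- compose_pose(std, off)
          img <- to_intensity(project(vol, abs_pose, sc), config$I0)
          imgs[, , k] <- augment_projection(img, gam[k], c(0, 0), s_draw[k],
                                            c_draw[k], pitch,
                                            config$final_size)
        } else {
          # one projection per pose; all augmentations act on the image
          if (is.null(base_proj)) {
            base_proj <- to_intensity(project(vol, compose_pose(std, off), sc),
                                      config$I0)
          }
          imgs[, , k] <- if (store == "projection") base_proj else
            augment_projection(base_proj, gam[k], tr[k, ], s_draw[k],
                               c_draw[k], pitch, config$final_size)
        }
      }
    }
    idx <- rep(seq_len(n_pose), each = n_aug)
    lab <- tibble::tibble(
      subject_id = cohort$subject_id[r],
      split = cohort$split[r],
      stage = stage,
      alpha = offsets$alpha[idx],
      beta = offsets$beta[idx],
      gamma = normalize_angle(gam),
      tx = tr[, 1],
      ty = tr[, 2],
      s = s_draw,
      c = c_draw
    )
    if (store == "projection") {
      # augmentation parameters are drawn at training time instead
      lab$gamma <- 0; lab$tx <- 0; lab$ty <- 0; lab$s <- 1; lab$c <- 1
    }
    all_imgs[[length(all_imgs) + 1L]] <- imgs
    all_labels[[length(all_labels) + 1L]] <- lab
  }
  images <- array(unlist(all_imgs, use.names = FALSE),
                  c(out_px, out_px,
                    sum(vapply(all_imgs, function(x) dim(x)[3], 0))))
  structure(
    list(images = images,
         labels = dplyr::bind_rows(all_labels),
         stage = stage, sampling = sampling, config = config, carm = carm,
         seed = seed, store = store,
         scale_range = scale_range, contrast_range = contrast_range),
    class = "carm_dataset"
  )
}

#' @export
print.carm_dataset <- function(x, ...) {
  cat(sprintf("<carm_dataset> %s stage: %d samples of %d x %d px, %d subjects\n",
              x$stage, dim(x$images)[3], dim(x$images)[1], dim(x$images)[2],
              dplyr::n_distinct(x$labels$subject_id)))
  invisible(x)
}

#' Serialize / load a labeled dataset
#'
#' Images go to a NIfTI stack, labels to CSV, and the configurations and
#' seed to a YAML manifest, so a dataset directory fully documents how to
#' reproduce itself.
#'
#' @param dataset A `carm_dataset`.
#' @param dir Directory (created if needed).
#' @return `write_dataset`: `dir` invisibly; `read_dataset`: the restored
#'   `carm_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(dataset$images),
                     file.path(dir, "images.nii.gz"))
  readr::write_csv(dataset$labels, file.path(dir, "labels.csv"))
  manifest <- list(
    stage = dataset$stage, seed = dataset$seed,
    store = dataset$store %||% "final",
    scale_range = dataset$scale_range, contrast_range = dataset$contrast_range,
    sampling = unclass(dataset$sampling),
    config = unclass(dataset$config),
    carm = unclass(dataset$carm)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  img <- RNifti::readNifti(file.path(dir, "images.nii.gz"))
  labels <- readr::read_csv(file.path(dir, "labels.csv"),
                            show_col_types = FALSE)
  structure(
    list(images = array(as.double(img), dim = dim(img)),
         labels = labels,
         stage = man$stage,
         sampling = do.call(sampling_config, man$sampling[
           c("coarse_range", "coarse_step", "fine_sigma", "translation_range")]),
         config = do.call(dataset_config, man$config),
         carm = do.call(carm_config, man$carm),
         seed = man$seed, store = man$store %||% "final",
         scale_range = unlist(man$scale_range),
         contrast_range = unlist(man$contrast_range)),
    class = "carm_dataset"
  )
}
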