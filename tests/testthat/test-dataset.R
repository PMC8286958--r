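test_that("dataset assembly yields poses x augmentations samples per subject", {
  cohort <- tiny_cohort()
  ds <- build_dataset(cohort, "coarse", fast_sampling(), fast_dataset_config(),
                      splits = c("train", "val"), seed = 3)
  n_subj <- sum(cohort$split %in% c("train", "val"))
  expect_equal(dim(ds$images)[3], 25 * n_subj) # 5x5 grid, 1 augmentation
  expect_equal(nrow(ds$labels), 25 * n_subj)
  # labels inside the stage domain; augmentation draws recorded
  expect_true(all(abs(ds$labels$alpha) <= 30 & abs(ds$labels$beta) <= 30))
  expect_true(all(ds$labels$gamma > -180 & ds$labels$gamma <= 180))
  expect_true(all(abs(ds$labels$tx) <= 50))
  expect_true(all(ds$labels$s <= 1)) # scale augmentation never zooms in
  expect_true(all(ds$images >= 0 & ds$images <= 1))
})

test_that("two subjects at the default coarse grid give 882 samples", {
  cohort <- tiny_cohort()
  two <- cohort[cohort$split %in% c("train", "val"), ][1:2, ]
  ds <- build_dataset(two, "coarse", sampling_config(),
                      fast_dataset_config(), splits = c("train", "val"),
                      seed = 2)
  expect_equal(dim(ds$images)[3], 882) # 2 x 441 poses, one augmentation each
})

test_that("rebuilding with the same seed is bit-identical", {
  cohort <- tiny_cohort()
  ds1 <- build_dataset(cohort, "fine", fast_sampling(), fast_dataset_config(),
                       seed = 9)
  ds2 <- build_dataset(cohort, "fine", fast_sampling(), fast_dataset_config(),
                       seed = 9)
  expect_identical(ds1$labels, ds2$labels)
  expect_identical(ds1$images, ds2$images)
  ds3 <- build_dataset(cohort, "fine", fast_sampling(), fast_dataset_config(),
                       seed = 10)
  expect_false(identical(ds3$labels$alpha, ds1$labels$alpha))
})

test_that("fine-stage labels follow the Gaussian law and both modes work", {
  cohort <- tiny_cohort()
  for (mode in c("crop", "projector")) {
    ds <- build_dataset(cohort, "fine", fast_sampling(),
                        fast_dataset_config(translation_mode = mode),
                        splits = "train", seed = 4)
    expect_equal(unique(ds$labels$stage), "fine")
    expect_true(all(abs(ds$labels$gamma) < 90)) # fine gamma law is narrow
    expect_true(all(abs(ds$labels$tx) <= 50 & abs(ds$labels$ty) <= 50))
  }
})

test_that("training images match the deployment image path", {
  cohort <- tiny_cohort()
  r <- which(cohort$split == "train")[1]
  cfg <- dataset_config(final_size = 48, sim_resolution = 128,
                        augmentations_per_pose = 1, n_fine_per_subject = 4)
  one <- cohort[r, ]
  one$split <- "train"
  ds <- build_dataset(one, "fine", sampling_config(), cfg, seed = 6)
  std <- pose(one$alpha, one$beta, one$gamma, one$tx, one$ty)
  for (i in seq_len(4)) {
    lab <- ds$labels[i, ]
    abs_pose <- compose_pose(std, pose(lab$alpha, lab$beta, lab$gamma,
                                       lab$tx, lab$ty))
    dep <- make_input_image(one$volume[[1]], abs_pose, config = cfg)
    # apply the recorded photometric augmentations to the deployment image
    train_img <- ds$images[, , i]
    dep_aug <- pmin(1, pmax(0, augment_contrast(augment_scale(dep, lab$s),
                                                lab$c)))
    expect_lt(mean(abs(dep_aug - train_img)), 0.04)
    expect_gt(stats::cor(as.vector(dep_aug), as.vector(train_img)), 0.97)
  }
})

test_that("datasets serialize to NIfTI + CSV + YAML and load back", {
  cohort <- tiny_cohort()
  ds <- build_dataset(cohort, "coarse", fast_sampling(), fast_dataset_config(),
                      splits = "train", seed = 5)
  dir <- file.path(tempdir(), "ds-roundtrip")
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "images.nii.gz")))
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  back <- read_dataset(dir)
  expect_equal(back$images, ds$images, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(as.data.frame(back$labels)[, c("alpha", "beta", "gamma")],
               as.data.frame(ds$labels)[, c("alpha", "beta", "gamma")],
               tolerance = 1e-9)
  expect_equal(back$stage, "coarse")
  expect_equal(back$sampling$coarse_step, 15)
})

test_that("degenerate augmentation configs are rejected", {
  cohort <- tiny_cohort()
  expect_error(build_dataset(cohort, "coarse", scale_range = c(0.9, 1.2)),
               "scale")
  expect_error(build_dataset(cohort, "coarse", contrast_range = c(1.1, 1.3)),
               "contrast")
  expect_error(build_dataset(cohort, "coarse", splits = "nonexistent"),
               "splits")
})
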