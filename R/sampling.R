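#' Pose-sampling configuration for training-set generation
#'
#' The coarse stage samples a uniform grid over the out-of-plane rotations,
#' `alpha, beta` in `[-coarse_range, coarse_range]` degrees in steps of
#' `coarse_step` (defaults 30 and 3: a 21 x 21 grid). The fine stage samples
#' `alpha, beta` from a centred Gaussian whose standard deviation
#' `fine_sigma = coarse_range / 2.576` is chosen so that the coarse region
#' is covered with 99% confidence (2.576 is the two-sided 99% normal
#' quantile; the value is computed, so changing `coarse_range` propagates).
#' Detector translations are drawn uniformly from
#' `[-translation_range, translation_range]^2` mm.
#'
#' @param coarse_range Half-width of the coarse grid, degrees.
#' @param coarse_step Grid step, degrees; must divide `2 * coarse_range`.
#' @param fine_sigma Fine-stage Gaussian SD, degrees.
#' @param translation_range Half-width of the translation law, mm.
#' @return An object of class `sampling_config`.
#' @export
sampling_config <- function(coarse_range = 30, coarse_step = 3,
                            fine_sigma = coarse_range / 2.576,
                            translation_range = 50) {
  stopifnot(coarse_range > 0, coarse_step > 0, fine_sigma > 0,
            translation_range >= 0)
  if (abs((2 * coarse_range / coarse_step) %% 1) > 1e-9) {
    stop("coarse_step must divide 2 * coarse_range", call. = FALSE)
  }
  structure(
    list(coarse_range = coarse_range, coarse_step = coarse_step,
         fine_sigma = fine_sigma, translation_range = translation_range),
    class = "sampling_config"
  )
}

#' Coarse pose grid around the standard beam direction
#'
#' Returns the full uniform grid over the `alpha`-`beta` plane (relative to
#' the subject's standard pose); `gamma` and the translations are zero at
#' simulation time and applied later as augmentations or detector offsets.
#'
#' @param config A [sampling_config()].
#' @return A pose tibble with `(2 * coarse_range / coarse_step + 1)^2` rows.
#' @examples
#' nrow(sample_coarse_poses()) # 441
#' @export
sample_coarse_poses <- function(config = sampling_config()) {
  g <- seq(-config$coarse_range, config$coarse_range, by = config$coarse_step)
  grid <- expand.grid(alpha = g, beta = g)
  pose(alpha = grid$alpha, beta = grid$beta)
}

#' Gaussian fine-stage pose sample
#'
#' Draws `alpha, beta` i.i.d. from `N(0, fine_sigma^2)` (untruncated; about
#' 99% of draws fall inside the coarse range by construction).
#'
#' @param n Number of poses.
#' @param config A [sampling_config()].
#' @return A pose tibble with `n` rows; `gamma`, `tx`, `ty` are zero.
#' @export
sample_fine_poses <- function(n, config = sampling_config()) {
  stopifnot(n >= 1)
  pose(alpha = stats::rnorm(n, 0, config$fine_sigma),
       beta = stats::rnorm(n, 0, config$fine_sigma))
}

#' In-plane rotation and translation augmentation laws
#'
#' The in-plane rotation is uniform on (-180, 180] for the coarse stage and
#' `N(0, (coarse_range/2.576)^2)` for the fine stage; translations are
#' uniform on the square `[-translation_range, translation_range]^2` mm for
#' both stages.
#'
#' @param n Number of draws.
#' @param stage `"coarse"` or `"fine"`.
#' @param config A [sampling_config()].
#' @return `sample_gamma`: numeric vector of angles, degrees;
#'   `sample_translation`: an `n` x 2 matrix of mm offsets.
#' @export
sample_gamma <- function(n, stage = c("coarse", "fine"),
                         config = sampling_config()) {
  stage <- match.arg(stage)
  if (stage == "coarse") {
    stats::runif(n, -180, 180)
  } else {
    stats::rnorm(n, 0, config$fine_sigma)
  }
}

#' @rdname sample_gamma
#' @export
sample_translation <- function(n, config = sampling_config()) {
  r <- config$translation_range
  cbind(tx = stats::runif(n, -r, r), ty = stats::runif(n, -r, r))
}
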