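#' Project a volume into a DRR-like line-integral image
#'
#' Casts one ray per detector pixel from the X-ray source through the volume
#' and integrates attenuation along it (monoenergetic line integrals,
#' trilinear interpolation, fixed step, zero attenuation outside the grid).
#' The source and detector are positioned by the pose: the principal ray is
#' `rotation_matrix(pose) %*% c(0, 0, 1)`, the source sits at
#' `-source_isocenter_distance` along it, and `tx`, `ty` shift the detector
#' within its own (gamma-rotated) plane. The result is in the line-integral
#' domain (dimensionless, values of \eqn{\int \mu\, dl}).
#'
#' @param volume A [volume_grid()].
#' @param pose A single [pose()] row.
#' @param config A [carm_config()].
#' @return A `projection_image`: a `sim_resolution` x `sim_resolution`
#'   matrix (first index x, second y) with attributes `pixel_pitch` (mm) and
#'   `pose`.
#' @examples
#' vol <- volume_grid(array(0.02, c(16, 16, 16)), spacing = 4)
#' img <- project(vol, pose(), carm_config(sim_resolution = 32))
#' range(img)
#' @export
project <- function(volume, pose, config = carm_config()) {
  stopifnot(inherits(volume, "volume_grid"))
  pose <- as_pose(pose)
  if (nrow(pose) != 1L) stop("project() takes a single pose; see project_many()", call. = FALSE)
  step <- config$step_size %||% (min(volume$spacing) / 2)
  if (step > min(volume$spacing)) {
    stop("step_size must not exceed the smallest voxel spacing", call. = FALSE)
  }
  R <- rotation_matrix(pose)
  support <- volume$support %||% support_box(volume$voxels, volume$spacing,
                                             volume$origin)
  px <- .project_cpp(
    as.double(volume$voxels), dim(volume$voxels),
    volume$spacing, volume$origin, support$lo, support$hi,
    R, pose$tx, pose$ty,
    config$source_detector_distance, config$source_isocenter_distance,
    config$detector_size, config$sim_resolution, step
  )
  projection_image(px, pixel_pitch(config), pose)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
projection_image <- function(pixels, pixel_pitch, pose = NULL) {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels), all(pixels >= 0))
  structure(pixels, pixel_pitch = pixel_pitch, pose = pose,
            class = c("projection_image", "matrix", "array"))
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image> %d x %d px @ %.3f mm, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "pixel_pitch"), min(x), max(x)))
  invisible(x)
}

#' Convert between line-integral and intensity domain
#'
#' `to_intensity()` applies the Beer-Lambert law
#' \eqn{I = I_0 e^{-\int \mu\, dl}} to a line-integral image;
#' `neg_log()` inverts it, recovering \eqn{\int \mu\, dl} from a strictly
#' positive intensity image. `neg_log(to_intensity(x, I0), I0)` is the
#' identity.
#'
#' @param img Numeric matrix: line integrals (`to_intensity`) or positive
#'   intensities (`neg_log`).
#' @param I0 Unattenuated detector flux (arbitrary units, default 1).
#' @return A matrix in the other domain, attributes preserved.
#' @export
to_intensity <- function(img, I0 = 1) {
  stopifnot(I0 > 0)
  out <- I0 * exp(-unclass_matrix(img))
  restore_attrs(out, img)
}

#' @rdname to_intensity
#' @export
neg_log <- function(img, I0 = 1) {
  m <- unclass_matrix(img)
  if (any(m <= 0)) {
    warning("non-positive intensities clamped to smallest positive value")
    m[m <= 0] <- min(m[m > 0], .Machine$double.xmin)
  }
  restore_attrs(-log(m / I0), img)
}

unclass_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

restore_attrs <- function(out, src) {
  for (a in c("pixel_pitch", "pose", "class")) {
    at <- attr(src, a, exact = TRUE)
    if (!is.null(at) && !identical(a, "class")) attr(out, a) <- at
  }
  out
}

#' Project a volume at many poses
#'
#' Convenience wrapper looping [project()] over the rows of a pose table.
#'
#' @param volume A [volume_grid()].
#' @param poses A pose table.
#' @param config A [carm_config()].
#' @return A list of `projection_image`s, one per pose row.
#' @export
project_many <- function(volume, poses, config = carm_config()) {
  poses <- as_pose(poses)
  lapply(seq_len(nrow(poses)), function(i) project(volume, poses[i, ], config))
}
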