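#' C-arm imaging geometry
#'
#' Bundles the geometric constants of the simulated C-arm. Defaults follow a
#' Siemens Cios Spin-class device: a 300 x 300 mm flat-panel detector and a
#' source-detector distance of 1164 mm, with the anatomy of interest assumed
#' to sit midway between source and detector (source-isocenter distance
#' 582 mm). `sim_resolution` is the square pixel grid the projector renders
#' (the physical panel is 1952 x 1952; simulations use a reduced grid).
#'
#' @param source_detector_distance Source to detector distance, mm.
#' @param source_isocenter_distance Source to isocenter distance, mm; must be
#'   strictly between 0 and `source_detector_distance`.
#' @param detector_size Side length of the square detector, mm.
#' @param sim_resolution Rendered image side length, pixels (>= 32).
#' @param step_size Ray-marching step, mm, or `NULL` to use half the smallest
#'   voxel spacing of the projected volume.
#' @return An object of class `carm_config`.
#' @examples
#' carm_config()
#' @export
carm_config <- function(source_detector_distance = 1164,
                        source_isocenter_distance = 582,
                        detector_size = 300,
                        sim_resolution = 128,
                        step_size = NULL) {
  stopifnot(
    source_isocenter_distance > 0,
    source_isocenter_distance < source_detector_distance,
    detector_size > 0,
    sim_resolution >= 32
  )
  if (!is.null(step_size)) stopifnot(step_size > 0)
  structure(
    list(
      source_detector_distance = source_detector_distance,
      source_isocenter_distance = source_isocenter_distance,
      detector_size = detector_size,
      sim_resolution = as.integer(sim_resolution),
      step_size = step_size
    ),
    class = "carm_config"
  )
}

#' @export
print.carm_config <- function(x, ...) {
  cat("<carm_config>\n")
  cat(sprintf("  source-detector %g mm, source-isocenter %g mm\n",
              x$source_detector_distance, x$source_isocenter_distance))
  cat(sprintf("  detector %g mm @ %d px (pitch %.3f mm), step %s\n",
              x$detector_size, x$sim_resolution,
              x$detector_size / x$sim_resolution,
              if (is.null(x$step_size)) "auto" else paste0(x$step_size, " mm")))
  invisible(x)
}

#' Detector pixel pitch of a configuration
#'
#' @param config A [carm_config()].
#' @return Millimetres per rendered pixel.
#' @export
pixel_pitch <- function(config) config$detector_size / config$sim_resolution

#' 3D attenuation volume on a regular grid
#'
#' A `volume_grid` holds linear attenuation values (1/mm) on a regular voxel
#' grid positioned relative to the C-arm isocenter. `origin` is the world
#' position (mm) of the centre of voxel (1,1,1); voxel index `i` along axis
#' `k` sits at `origin[k] + (i-1) * spacing[k]`.
#'
#' @param voxels 3D numeric array of attenuation coefficients, all >= 0,
#'   each dimension >= 8.
#' @param spacing Voxel spacing per axis, mm (length 1 or 3).
#' @param origin World offset of the first voxel centre, mm (default centres
#'   the grid on the isocenter).
#' @param standard_pose Optional reference standard [pose()] attached to the
#'   volume (one row).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(voxels, spacing = 1, origin = NULL, standard_pose = NULL) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (any(dim(voxels) < 8L)) stop("all volume dimensions must be >= 8", call. = FALSE)
  if (any(voxels < 0)) stop("attenuation values must be non-negative", call. = FALSE)
  spacing <- rep_len(as.double(spacing), 3L)
  stopifnot(all(spacing > 0))
  extent <- (dim(voxels) - 1) * spacing
  if (is.null(origin)) origin <- -extent / 2
  origin <- rep_len(as.double(origin), 3L)
  if (any(origin > 0) || any(origin + extent < 0)) {
    stop("isocenter must lie inside the volume bounding box", call. = FALSE)
  }
  if (!is.null(standard_pose)) standard_pose <- as_pose(standard_pose)
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         standard_pose = standard_pose,
         support = support_box(voxels, spacing, origin)),
    class = "volume_grid"
  )
}

# world-space box enclosing the nonzero voxels plus one voxel of
# interpolation margin; lets the projector skip empty space
support_box <- function(voxels, spacing, origin) {
  nz <- voxels != 0
  d <- dim(voxels)
  ax <- rowSums(nz, dims = 1) > 0
  m23 <- colSums(nz, dims = 1) # (d2 x d3) counts
  ay <- rowSums(m23) > 0
  az <- colSums(m23) > 0
  if (!any(ax)) {
    return(list(lo = rep(Inf, 3), hi = rep(-Inf, 3)))
  }
  idx_lo <- c(which(ax)[1], which(ay)[1], which(az)[1])
  idx_hi <- c(max(which(ax)), max(which(ay)), max(which(az)))
  list(lo = origin + (idx_lo - 2) * spacing,
       hi = origin + idx_hi * spacing)
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_grid> %d x %d x %d voxels @ %s mm, mu in [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = " x "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Read and write volumes as NIfTI
#'
#' Volumes are exchanged in NIfTI format; voxel spacing is carried in the
#' header and the isocenter offset in the sform translation.
#'
#' @param volume A [volume_grid()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume`: `path`, invisibly. `read_volume`: a
#'   [volume_grid()] (without a standard pose; store poses alongside, e.g.
#'   with [pose_to_json()]).
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_grid"))
  img <- RNifti::asNifti(volume$voxels)
  xf <- diag(c(volume$spacing, 1))
  xf[1:3, 4] <- volume$origin
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  volume_grid(
    voxels = array(as.double(img), dim = dim(img)),
    spacing = abs(diag(xf)[1:3]),
    origin = xf[1:3, 4]
  )
}
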