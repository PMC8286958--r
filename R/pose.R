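#' Construct a table of C-arm poses
#'
#' A pose describes the 5 degrees of freedom of a mobile C-arm relative to a
#' reference: the orbital rotation `alpha` (LAO, rotation within the gantry
#' plane), the angular rotation `beta` (CRA, rotation perpendicular to the
#' gantry plane), the in-plane detector rotation `gamma`, and the detector
#' translation `tx`, `ty` in the detector plane. Angles are degrees,
#' translations millimetres; translation along the beam is deliberately not
#' modelled (it only changes image scale).
#'
#' All arguments are recycled to a common length, so `pose()` builds a whole
#' table of poses at once. `gamma` is normalised to the interval (-180, 180].
#'
#' @param alpha Orbital rotation (LAO), degrees.
#' @param beta Angular rotation (CRA), degrees.
#' @param gamma In-plane detector rotation, degrees.
#' @param tx,ty Detector-plane translation, millimetres.
#' @return A tibble with columns `alpha`, `beta`, `gamma`, `tx`, `ty`, one
#'   row per pose.
#' @examples
#' pose()                      # the reference pose
#' pose(alpha = c(-30, 0, 30)) # three poses along the orbital axis
#' @export
pose <- function(alpha = 0, beta = 0, gamma = 0, tx = 0, ty = 0) {
  out <- tibble::tibble(
    alpha = as.double(alpha), beta = as.double(beta),
    gamma = as.double(gamma), tx = as.double(tx), ty = as.double(ty)
  )
  if (!all(vapply(out, function(x) all(is.finite(x)), logical(1)))) {
    stop("pose parameters must be finite", call. = FALSE)
  }
  out$gamma <- normalize_angle(out$gamma)
  out
}

#' @keywords internal
#' @noRd
as_pose <- function(p) {
  cols <- c("alpha", "beta", "gamma", "tx", "ty")
  if (is.data.frame(p)) {
    missing <- setdiff(cols, names(p))
    if (length(missing)) {
      stop("pose table lacks column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    p <- tibble::as_tibble(p)[cols]
  } else if (is.numeric(p) && length(p) == 5L) {
    p <- tibble::as_tibble(as.list(stats::setNames(p, cols)))
  } else {
    stop("cannot interpret object as pose(s)", call. = FALSE)
  }
  if (!all(vapply(p, function(x) all(is.finite(x)), logical(1)))) {
    stop("pose parameters must be finite", call. = FALSE)
  }
  p
}

#' Wrap angles into (-180, 180]
#'
#' @param x Angles in degrees, any range.
#' @return Angles wrapped into the half-open interval (-180, 180].
#' @examples
#' normalize_angle(c(190, -180, 360))
#' @export
normalize_angle <- function(x) {
  y <- x - 360 * floor((x + 180) / 360)
  y[y == -180] <- 180
  y
}

#' Principal-ray direction of a pose
#'
#' Maps the out-of-plane rotations (`alpha`, `beta`) of each pose to the unit
#' direction of the central source-to-detector ray,
#' \eqn{\nu = [\sin\alpha,\ -\cos\alpha \sin\beta,\ \cos\alpha \cos\beta]^T}.
#' The in-plane rotation `gamma` and the detector translation have no effect
#' on the principal ray.
#'
#' @param p A pose table (see [pose()]).
#' @return A numeric matrix with one row per pose and columns `vx`, `vy`,
#'   `vz`; every row has unit norm.
#' @examples
#' beam_direction(pose(alpha = 90))
#' @export
beam_direction <- function(p) {
  p <- as_pose(p)
  a <- deg2rad(p$alpha)
  b <- deg2rad(p$beta)
  v <- cbind(vx = sin(a), vy = -cos(a) * sin(b), vz = cos(a) * cos(b))
  v
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle between the principal rays of two poses
#'
#' The headline angular accuracy metric: the angle
#' \eqn{d\theta = \arccos(\nu \cdot \hat\nu)} between the ground-truth and
#' estimated principal rays, in degrees. It depends only on (`alpha`,
#' `beta`). The dot product is clamped to \[-1, 1\] before `acos` so rounding
#' can never produce `NaN`.
#'
#' @param p,p_hat Pose tables of equal length (rows recycled if one has a
#'   single row).
#' @return Numeric vector of angles in \[0, 180\] degrees.
#' @examples
#' angular_error(pose(alpha = 30), pose())
#' @export
angular_error <- function(p, p_hat) {
  v <- beam_direction(p)
  v_hat <- beam_direction(p_hat)
  if (nrow(v) == 1L && nrow(v_hat) > 1L) v <- v[rep(1L, nrow(v_hat)), , drop = FALSE]
  if (nrow(v_hat) == 1L && nrow(v) > 1L) v_hat <- v_hat[rep(1L, nrow(v)), , drop = FALSE]
  d <- rowSums(v * v_hat)
  rad2deg(acos(pmin(1, pmax(-1, d))))
}

#' Circular error of the in-plane rotation
#'
#' \eqn{d\gamma = \min(|\hat\gamma-\gamma|,\ 360-|\hat\gamma-\gamma|)}:
#' the shortest arc between two detector rotations, insensitive to full
#' turns of either argument.
#'
#' @param gamma_hat,gamma Angles in degrees, any range.
#' @return Numeric vector in \[0, 180\] degrees.
#' @examples
#' gamma_error(350, 10) # 20, across the wrap
#' @export
gamma_error <- function(gamma_hat, gamma) {
  d <- abs(gamma_hat - gamma) %% 360
  pmin(d, 360 - d)
}

#' Euclidean error of the detector translation
#'
#' \eqn{dc = \lVert [dt_x, dt_y] \rVert} in millimetres.
#'
#' @param p,p_hat Pose tables of equal length.
#' @return Numeric vector of distances in mm.
#' @export
translation_error <- function(p, p_hat) {
  p <- as_pose(p); p_hat <- as_pose(p_hat)
  sqrt((p_hat$tx - p$tx)^2 + (p_hat$ty - p$ty)^2)
}

#' All five pose-error metrics at once
#'
#' Computes, row by row, the principal-ray angle `d_theta`, the absolute
#' rotation errors `d_alpha`, `d_beta`, the circular in-plane error
#' `d_gamma`, and the detector-plane distance `dc` between a ground-truth
#' pose table and an estimate.
#'
#' @param p Ground-truth poses.
#' @param p_hat Estimated poses.
#' @return A tibble with columns `d_theta`, `d_alpha`, `d_beta`, `d_gamma`
#'   (degrees) and `dc` (mm).
#' @export
pose_errors <- function(p, p_hat) {
  p <- as_pose(p); p_hat <- as_pose(p_hat)
  tibble::tibble(
    d_theta = angular_error(p, p_hat),
    d_alpha = abs(p_hat$alpha - p$alpha),
    d_beta  = abs(p_hat$beta - p$beta),
    d_gamma = gamma_error(p_hat$gamma, p$gamma),
    dc      = translation_error(p, p_hat)
  )
}

#' Rotation matrix of a pose
#'
#' Returns the 3x3 rotation carrying the reference C-arm frame to the posed
#' frame, composed as `Rx(beta) %*% Ry(alpha) %*% Rz(gamma)`. With this
#' order the third column (the rotated z axis, i.e. the principal ray)
#' reproduces [beam_direction()] for every `gamma`.
#'
#' @param p A single pose (one-row table or length-5 numeric vector).
#' @return A 3x3 orthonormal matrix with determinant +1.
#' @export
rotation_matrix <- function(p) {
  p <- as_pose(p)
  if (nrow(p) != 1L) stop("rotation_matrix() expects a single pose", call. = FALSE)
  a <- deg2rad(p$alpha); b <- deg2rad(p$beta); g <- deg2rad(p$gamma)
  Ry <- matrix(c( cos(a), 0, sin(a),
                  0,      1, 0,
                 -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0,       0,
                 0, cos(b), -sin(b),
                 0, sin(b),  cos(b)), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(g), -sin(g), 0,
                 sin(g),  cos(g), 0,
                 0,       0,      1), 3, 3, byrow = TRUE)
  Rx %*% Ry %*% Rz
}

#' Mirror a pose across the detector x-axis (laterality flip)
#'
#' Paired anatomies (left vs right femur) are handled by mirroring: the
#' image is flipped horizontally and the pose parameters that change sign
#' under that reflection — `alpha`, `gamma` and `tx` — are negated while
#' `beta` and `ty` are kept. The map is its own inverse.
#'
#' @param p A pose table.
#' @return The mirrored pose table.
#' @export
mirror_pose <- function(p) {
  p <- as_pose(p)
  p$alpha <- -p$alpha
  p$gamma <- normalize_angle(-p$gamma)
  p$tx <- -p$tx
  p
}

#' Apply a predicted pose update to the current C-arm pose
#'
#' The regressors predict the offset of the current pose from the standard
#' pose. Repositioning subtracts that update: the angular parameters of
#' `update` are removed from `current` (inverse application), and the
#' predicted detector translation is removed in the current detector frame.
#' For a mirrored laterality the update was predicted on a horizontally
#' flipped image, so its `alpha`, `gamma` and `tx` components are
#' sign-flipped before application.
#'
#' @param current Current pose table.
#' @param update Predicted pose update(s), same number of rows (or one row).
#' @param laterality `"left"` (reference laterality, default) or `"right"`
#'   (mirrored).
#' @return The repositioned pose table.
#' @examples
#' p <- pose(alpha = 10)
#' apply_pose_update(p, pose(alpha = 10)) # back at the standard
#' @export
apply_pose_update <- function(current, update, laterality = c("left", "right")) {
  laterality <- match.arg(laterality)
  current <- as_pose(current)
  update <- as_pose(update)
  if (laterality == "right") update <- mirror_pose(update)
  if (nrow(update) == 1L && nrow(current) > 1L) {
    update <- update[rep(1L, nrow(current)), ]
  }
  pose(
    alpha = current$alpha - update$alpha,
    beta  = current$beta - update$beta,
    gamma = current$gamma - update$gamma,
    tx    = current$tx - update$tx,
    ty    = current$ty - update$ty
  )
}

#' Compose a standard pose with a sampled offset
#'
#' Inverse of [apply_pose_update()] with the reference laterality: the pose
#' a C-arm is actually at when it deviates from `standard` by `offset`
#' (parameters add). Labels in the training sets are exactly these offsets.
#'
#' @param standard Standard (reference) pose table.
#' @param offset Offset pose table (recycled if one row).
#' @return The absolute pose table.
#' @export
compose_pose <- function(standard, offset) {
  standard <- as_pose(standard)
  offset <- as_pose(offset)
  if (nrow(standard) == 1L && nrow(offset) > 1L) {
    standard <- standard[rep(1L, nrow(offset)), ]
  }
  pose(
    alpha = standard$alpha + offset$alpha,
    beta  = standard$beta + offset$beta,
    gamma = standard$gamma + offset$gamma,
    tx    = standard$tx + offset$tx,
    ty    = standard$ty + offset$ty
  )
}

#' Serialize / deserialize poses as JSON records
#'
#' Poses travel between tools as JSON arrays of records with fields
#' `alpha`, `beta`, `gamma` (degrees), `tx`, `ty` (mm) and optionally
#' `laterality`.
#'
#' @param p A pose table; extra columns (e.g. `laterality`) are preserved.
#' @param path File path; for `pose_to_json` with `path = NULL` the JSON
#'   string is returned.
#' @return `pose_to_json`: the path (or JSON string) invisibly;
#'   `pose_from_json`: a pose tibble.
#' @export
pose_to_json <- function(p, path = NULL) {
  stopifnot(is.data.frame(p))
  as_pose(p) # validates pose columns
  json <- jsonlite::toJSON(p, dataframe = "rows", digits = NA, auto_unbox = FALSE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname pose_to_json
#' @export
pose_from_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  keep <- intersect(c("alpha", "beta", "gamma", "tx", "ty", "laterality"), names(df))
  tibble::as_tibble(df)[keep]
}
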