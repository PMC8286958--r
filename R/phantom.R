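#' Specification of a parametric bone phantom
#'
#' Describes one synthetic subject: a femur-like phantom (cylindrical shaft,
#' angled neck and spherical head inside a soft-tissue ellipsoid) or a
#' vertebra-like phantom (elliptic-cylinder body with posterior spinous and
#' transverse processes). The phantoms stand in for a clinical CT cohort:
#' they are parametric solids, because what is under test is geometric pose
#' recovery, not anatomical realism. Each subject also carries a small rigid
#' perturbation of its reference standard pose (`pert_*`), emulating the
#' inter-subject variability of expert-defined standard planes; the
#' generated volume contains the anatomy *posed* by that perturbation, and
#' `make_phantom()` returns the matching reference standard pose.
#'
#' Default attenuation coefficients approximate soft tissue (0.02/mm) and
#' cortical bone (0.055/mm) at fluoroscopic energies.
#'
#' @param anatomy `"femur"` or `"vertebra"`.
#' @param size_factor Overall anatomical scale multiplier.
#' @param shaft_radius Femur shaft (or vertebral-body minor) radius, mm.
#' @param shaft_length Femur shaft length, mm.
#' @param head_radius Femoral head radius, mm.
#' @param neck_angle Femoral neck-shaft angle, degrees.
#' @param neck_anteversion Femoral neck anteversion, degrees: the anterior
#'   (out-of-plane) tilt of the neck axis. Besides being anatomically
#'   expected (10-20 degrees in adults), it breaks the front-back mirror
#'   symmetry a planar neck would have, which would otherwise make opposite
#'   oblique views nearly indistinguishable in projection.
#' @param neck_radius,neck_length Femoral neck dimensions, mm.
#' @param bone_mu,tissue_mu Linear attenuation of bone and soft tissue, 1/mm.
#' @param pert_alpha,pert_beta,pert_gamma Standard-pose perturbation
#'   rotations, degrees (each |value| <= 10).
#' @param pert_tx,pert_ty Standard-pose perturbation offsets, mm.
#' @param grid_dim Voxels per axis of the generated volume.
#' @param spacing Voxel spacing, mm.
#' @param seed Provenance seed recorded with the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(anatomy = c("femur", "vertebra"),
                         size_factor = 1,
                         shaft_radius = 13, shaft_length = 50,
                         head_radius = 22, neck_angle = 127,
                         neck_anteversion = 15,
                         neck_radius = 9, neck_length = 50,
                         bone_mu = 0.055, tissue_mu = 0.02,
                         pert_alpha = 0, pert_beta = 0, pert_gamma = 0,
                         pert_tx = 0, pert_ty = 0,
                         grid_dim = 96, spacing = 2, seed = 0L) {
  anatomy <- match.arg(anatomy)
  geom <- c(size_factor, shaft_radius, shaft_length, head_radius,
            neck_angle, neck_radius, neck_length, bone_mu, tissue_mu,
            grid_dim, spacing)
  if (any(geom <= 0)) stop("geometric and attenuation parameters must be positive", call. = FALSE)
  if (max(abs(c(pert_alpha, pert_beta, pert_gamma))) > 10) {
    stop("standard-pose perturbation rotations must be <= 10 degrees", call. = FALSE)
  }
  structure(
    list(anatomy = anatomy, size_factor = size_factor,
         shaft_radius = shaft_radius, shaft_length = shaft_length,
         head_radius = head_radius, neck_angle = neck_angle,
         neck_anteversion = neck_anteversion,
         neck_radius = neck_radius, neck_length = neck_length,
         bone_mu = bone_mu, tissue_mu = tissue_mu,
         pert_alpha = pert_alpha, pert_beta = pert_beta,
         pert_gamma = pert_gamma, pert_tx = pert_tx, pert_ty = pert_ty,
         grid_dim = as.integer(grid_dim), spacing = spacing,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Build a phantom volume with its reference standard pose
#'
#' Voxelizes the parametric anatomy of `spec` on a grid centred on the
#' isocenter. The anatomy is rigidly displaced by the subject's standard-pose
#' perturbation so that projecting the volume *at* the returned standard pose
#' reproduces the canonical standard view; a zero perturbation gives the
#' canonical pose (all parameters 0). Deterministic: the same spec always
#' yields the identical volume.
#'
#' @param spec A [phantom_spec()].
#' @param magnification Geometric magnification used to map the detector-
#'   plane offset of the standard pose to an object-plane shift (detector
#'   distance over isocenter distance; 2 for the default C-arm geometry).
#' @return A [volume_grid()] whose `standard_pose` field holds the one-row
#'   reference pose table.
#' @export
make_phantom <- function(spec, magnification = 2) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_dim
  sp <- spec$spacing
  extent <- (n - 1) * sp
  origin <- rep(-extent / 2, 3)
  ax <- origin[1] + (seq_len(n) - 1) * sp

  std <- pose(alpha = spec$pert_alpha, beta = spec$pert_beta,
              gamma = spec$pert_gamma, tx = spec$pert_tx, ty = spec$pert_ty)
  R <- rotation_matrix(std)
  # object-plane shift that compensates the detector offset of the standard pose
  shift <- R %*% c(std$tx / magnification, std$ty / magnification, 0)

  # canonical coordinates of every voxel: c = R^T (w - shift)
  w <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  cc <- sweep(w, 2, as.double(shift)) %*% R # (w - shift) %*% R == t(R^T t(w-shift))
  x <- cc[, 1]; y <- cc[, 2]; z <- cc[, 3]
  s <- spec$size_factor

  inside_cyl <- function(p0, d, len, r) {
    # finite cylinder from p0 along unit d with given length and radius
    px <- x - p0[1]; py <- y - p0[2]; pz <- z - p0[3]
    t <- px * d[1] + py * d[2] + pz * d[3]
    r2 <- (px - t * d[1])^2 + (py - t * d[2])^2 + (pz - t * d[3])^2
    t >= 0 & t <= len & r2 <= r^2
  }
  inside_ellipsoid <- function(c0, semi) {
    ((x - c0[1]) / semi[1])^2 + ((y - c0[2]) / semi[2])^2 +
      ((z - c0[3]) / semi[3])^2 <= 1
  }

  # attenuation tiers derived from the cortical value: trabecular bone and
  # fatty marrow (the shaft is a cortical tube, not a solid rod — the bright
  # tangent edges of the tube are what make its projection read like an
  # X-ray)
  # tiers interpolate between tissue and cortical so that bone_mu ==
  # tissue_mu collapses the whole skeleton to zero contrast
  mu_cort <- spec$bone_mu
  mu_trab <- spec$tissue_mu + 0.55 * (spec$bone_mu - spec$tissue_mu)
  mu_marrow <- max(0, spec$tissue_mu - 0.3 * (spec$bone_mu - spec$tissue_mu))

  if (spec$anatomy == "femur") {
    psi <- deg2rad(180 - spec$neck_angle) # neck direction from +y toward +x
    av <- deg2rad(spec$neck_anteversion)   # anterior tilt out of the shaft plane
    nd <- c(sin(psi) * cos(av), cos(psi), sin(psi) * sin(av))
    base <- c(-15, -20, 0) * s
    head_c <- base + spec$neck_length * s * nd
    shaft_p0 <- c(-15 * s, (-20 - spec$shaft_length) * s, 0)
    shaft <- inside_cyl(shaft_p0, c(0, 1, 0), spec$shaft_length * s,
                        spec$shaft_radius * s)
    medulla <- inside_cyl(shaft_p0, c(0, 1, 0), spec$shaft_length * s,
                          0.6 * spec$shaft_radius * s)
    neck <- inside_cyl(base, nd, spec$neck_length * s, spec$neck_radius * s)
    head <- (x - head_c[1])^2 + (y - head_c[2])^2 + (z - head_c[3])^2 <=
      (spec$head_radius * s)^2
    head_core <- (x - head_c[1])^2 + (y - head_c[2])^2 + (z - head_c[3])^2 <=
      ((spec$head_radius - 3) * s)^2
    # greater trochanter (lateral, opposite the head) and lesser trochanter
    # (medial-posterior): the bony landmarks surgeons read rotation from
    troch <- inside_ellipsoid(c(-28, -16, 2) * s, c(9, 15, 8) * s) |
      inside_ellipsoid(c(-6, -42, -9) * s, c(7, 10, 6) * s)
    # linea aspera: dense posterior ridge along the shaft; its offset from
    # the shaft midline is the classic cue for rotation about the shaft
    ridge <- inside_cyl(shaft_p0 + c(0, 0, -spec$shaft_radius * s), c(0, 1, 0),
                        spec$shaft_length * s, 4 * s)
    tissue <- inside_ellipsoid(c(0, -15, 0) * s, c(60, 85, 45) * s)

    mu <- numeric(length(x))
    mu[tissue] <- spec$tissue_mu
    mu[shaft | neck | head | ridge] <- mu_cort
    mu[head_core] <- mu_trab
    mu[troch] <- mu_trab
    mu[medulla] <- mu_marrow
    bone <- shaft | neck | head | troch | ridge
  } else {
    body <- ((x / (20 * s))^2 + ((z + 5 * s) / (15 * s))^2 <= 1) &
      abs(y) <= 16 * s
    spinous <- inside_cyl(c(0, 0, 8 * s), c(0, 0, 1), 30 * s, 5 * s)
    transverse <- inside_cyl(c(-33 * s, 0, 6 * s), c(1, 0, 0), 66 * s, 4 * s)
    core <- ((x / (17 * s))^2 + ((z + 5 * s) / (12 * s))^2 <= 1) &
      abs(y) <= 13 * s
    bone <- body | spinous | transverse
    tissue <- inside_ellipsoid(c(0, 0, 0), c(55, 42, 50) * s)
    mu <- numeric(length(x))
    mu[tissue] <- spec$tissue_mu
    mu[bone] <- mu_cort
    mu[core] <- mu_trab # cancellous centre of the vertebral body
  }

  vox <- array(mu, dim = c(n, n, n))

  # anatomy must not be clipped by the grid
  edge <- c(vox[1, , ], vox[n, , ], vox[, 1, ], vox[, n, ], vox[, , 1], vox[, , n])
  if (any(edge >= spec$bone_mu & spec$bone_mu > spec$tissue_mu)) {
    stop("phantom anatomy extends outside the volume grid", call. = FALSE)
  }
  volume_grid(vox, spacing = sp, origin = origin, standard_pose = std)
}

#' Mirror a phantom across the sagittal (x = 0) plane
#'
#' Produces the opposite laterality of a phantom. Mirroring the volume and
#' mirroring its standard pose with [mirror_pose()] commute with projection:
#' the image of the mirrored phantom equals the horizontally flipped image
#' of the original.
#'
#' @param volume A [volume_grid()].
#' @return The mirrored [volume_grid()].
#' @export
mirror_phantom <- function(volume) {
  stopifnot(inherits(volume, "volume_grid"))
  d <- dim(volume$voxels)
  vox <- volume$voxels[d[1]:1, , , drop = FALSE]
  origin <- volume$origin
  origin[1] <- -(volume$origin[1] + (d[1] - 1) * volume$spacing[1])
  sp <- volume$standard_pose
  volume_grid(vox, spacing = volume$spacing, origin = origin,
              standard_pose = if (is.null(sp)) NULL else mirror_pose(sp))
}

#' Generate a randomized phantom cohort with train/val/test split
#'
#' Samples `n` subject specs around `base_spec` — anatomical size, neck
#' angle, bone and tissue density, and the standard-pose perturbation all
#' vary independently per subject — builds every phantom, and assigns a
#' reproducible 60/20/20 train/validation/test split. The standard-pose
#' perturbation rotations are drawn from N(0, `pert_sd`^2) per axis
#' (clamped to +-10 deg) and the offsets from N(0, `offset_sd`^2) mm.
#'
#' @param n Number of subjects (>= 1).
#' @param base_spec The [phantom_spec()] around which subjects vary.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   it.
#' @param pert_sd Standard deviation of the standard-pose perturbation
#'   rotations, degrees.
#' @param offset_sd Standard deviation of the standard-pose offsets, mm.
#' @return A tibble with one row per subject: `subject_id`, `anatomy`,
#'   `split` (`"train"`, `"val"`, `"test"`), `laterality`, the standard-pose
#'   columns `alpha`...`ty`, and list columns `spec` and `volume`.
#' @export
make_cohort <- function(n, base_spec = phantom_spec(), seed = 1L,
                        pert_sd = 3, offset_sd = 3) {
  stopifnot(n >= 1)
  set.seed(seed)
  clamp <- function(v, lim) pmin(lim, pmax(-lim, v))
  specs <- lapply(seq_len(n), function(i) {
    sp <- base_spec
    sp$size_factor <- base_spec$size_factor * stats::runif(1, 0.85, 1.15)
    sp$neck_angle <- base_spec$neck_angle + stats::runif(1, -7, 7)
    sp$neck_anteversion <- base_spec$neck_anteversion + stats::runif(1, -7, 7)
    sp$bone_mu <- base_spec$bone_mu * stats::runif(1, 0.85, 1.15)
    sp$tissue_mu <- base_spec$tissue_mu * stats::runif(1, 0.9, 1.1)
    sp$pert_alpha <- clamp(stats::rnorm(1, 0, pert_sd), 10)
    sp$pert_beta <- clamp(stats::rnorm(1, 0, pert_sd), 10)
    sp$pert_gamma <- clamp(stats::rnorm(1, 0, pert_sd), 10)
    sp$pert_tx <- stats::rnorm(1, 0, offset_sd)
    sp$pert_ty <- stats::rnorm(1, 0, offset_sd)
    sp$seed <- as.integer(seed + i)
    sp
  })
  n_train <- round(0.6 * n)
  n_val <- round(0.2 * n)
  n_test <- n - n_train - n_val
  if (n_val == 0 || n_test == 0) {
    warning("cohort too small for a full 60/20/20 split; some splits are empty")
  }
  split <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))[
    order(stats::runif(n))]
  volumes <- lapply(specs, make_phantom)
  std <- dplyr::bind_rows(lapply(volumes, function(v) v$standard_pose))
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    anatomy = base_spec$anatomy,
    split = split,
    laterality = "left",
    std,
    spec = specs,
    volume = volumes
  )
}

#' Write a cohort manifest as CSV
#'
#' Records subject id, split, laterality, provenance seed and standard pose
#' (the volumes themselves are written separately with [write_volume()]).
#'
#' @param cohort A cohort tibble from [make_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  man <- dplyr::mutate(
    dplyr::select(cohort, "subject_id", "anatomy", "split", "laterality",
                  "alpha", "beta", "gamma", "tx", "ty"),
    seed = vapply(cohort$spec, function(s) s$seed, integer(1))
  )
  readr::write_csv(man, path)
  invisible(path)
}
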