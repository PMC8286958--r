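# Shared fixtures and the independent projector oracle.

random_poses <- function(n, range = 30, t_range = 50) {
  pose(
    alpha = runif(n, -range, range), beta = runif(n, -range, range),
    gamma = runif(n, -180, 180),
    tx = runif(n, -t_range, t_range), ty = runif(n, -t_range, t_range)
  )
}

# small homogeneous box volume
box_volume <- function(mu = 0.02, n = 16, spacing = 4) {
  volume_grid(array(mu, c(n, n, n)), spacing = spacing)
}

# centred solid sphere
sphere_volume <- function(mu = 0.03, n = 24, spacing = 3, radius = 25) {
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  g <- expand.grid(x = ax, y = ax, z = ax)
  vox <- array(as.double(g$x^2 + g$y^2 + g$z^2 <= radius^2) * mu, c(n, n, n))
  volume_grid(vox, spacing = spacing)
}

# smooth blob, optionally offset from the isocenter
blob_volume <- function(n = 24, spacing = 3, sigma = 15, center = c(0, 0, 0)) {
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  g <- expand.grid(x = ax, y = ax, z = ax)
  r2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  volume_grid(array(0.05 * exp(-r2 / (2 * sigma^2)), c(n, n, n)),
              spacing = spacing)
}

# plain-R trilinear interpolation with zero padding, vectorized over samples;
# idx is an m x 3 matrix of 0-based continuous voxel indices
trilinear_r <- function(vox, idx) {
  d <- dim(vox)
  i0 <- floor(idx)
  f <- idx - i0
  val <- numeric(nrow(idx))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    xi <- i0[, 1] + dx
    yi <- i0[, 2] + dy
    zi <- i0[, 3] + dz
    ok <- xi >= 0 & xi < d[1] & yi >= 0 & yi < d[2] & zi >= 0 & zi < d[3]
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    lin <- xi[ok] + d[1] * (yi[ok] + d[2] * zi[ok]) + 1
    val[ok] <- val[ok] + w[ok] * vox[lin]
  }
  val
}

# independent dense-quadrature projector: same geometry as project(), but
# implemented in plain R with a much finer fixed step (midpoint rule along
# the ray clipped to the grid bounding box)
oracle_project <- function(volume, p, config, oversample = 10) {
  stopifnot(nrow(p) == 1L)
  R <- rotation_matrix(p)
  u <- R[, 1]; v <- R[, 2]; w <- R[, 3]
  S <- -config$source_isocenter_distance * w
  C <- (config$source_detector_distance - config$source_isocenter_distance) * w +
    p$tx * u + p$ty * v
  nres <- config$sim_resolution
  pitch <- config$detector_size / nres
  step <- (config$step_size %||% (min(volume$spacing) / 2)) / oversample
  lo <- volume$origin - volume$spacing
  hi <- volume$origin + dim(volume$voxels) * volume$spacing
  img <- matrix(0, nres, nres)
  half <- (nres - 1) / 2
  for (j in seq_len(nres)) {
    for (i in seq_len(nres)) {
      P <- C + (i - 1 - half) * pitch * u + (j - 1 - half) * pitch * v
      d <- P - S
      len <- sqrt(sum(d^2))
      d <- d / len
      t0 <- 0; t1 <- len; miss <- FALSE
      for (k in 1:3) {
        if (abs(d[k]) < 1e-12) {
          if (S[k] <= lo[k] || S[k] >= hi[k]) miss <- TRUE
        } else {
          tt <- sort(c((lo[k] - S[k]) / d[k], (hi[k] - S[k]) / d[k]))
          t0 <- max(t0, tt[1]); t1 <- min(t1, tt[2])
        }
      }
      if (miss || t0 >= t1) next
      nstep <- ceiling((t1 - t0) / step)
      dt <- (t1 - t0) / nstep
      tt <- t0 + (seq_len(nstep) - 0.5) * dt
      pts <- cbind(S[1] + tt * d[1], S[2] + tt * d[2], S[3] + tt * d[3])
      idx <- sweep(sweep(pts, 2, volume$origin), 2, volume$spacing, "/")
      img[i, j] <- sum(trilinear_r(volume$voxels, idx)) * dt
    }
  }
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny cohort cached across tests within a file run
tiny_cohort <- local({
  cache <- NULL
  function(n = 4, seed = 42) {
    if (is.null(cache)) {
      cache <<- suppressWarnings(make_cohort(n, phantom_spec(), seed = seed))
    }
    cache
  }
})

# quick dataset settings: coarse 5x5 grid, low render resolution
fast_sampling <- function() sampling_config(coarse_range = 30, coarse_step = 15)
fast_dataset_config <- function(...) {
  dataset_config(final_size = 32, sim_resolution = 64, sim_fov = 300,
                 augmentations_per_pose = 1, n_fine_per_subject = 10, ...)
}
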