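# Small phantom used throughout the suite: same physics as the full-size
# default but on reduced grids so each test runs in seconds.
small_phantom_spec <- function(compression = 0.5, noise_snr = Inf, seed = 7L,
                               ...) {
  phantom_spec(compression = compression, noise_snr = noise_snr, seed = seed,
               slab_extent = c(24, 24),
               low_res_shape = c(48L, 16L, 12L),
               low_res_spacing = c(0.33, 1.5, 2.0),
               high_res_shape = c(72L, 64L, 64L),
               high_res_spacing = c(0.17, 0.38, 0.38),
               graft_radius = 6,
               supersample = c(2L, 4L, 4L),
               ...)
}

# analytic-geometry ball mask for meshing tests
ball_mask_grid <- function(radius = 5, h = 0.4, n = 36L) {
  co <- (seq_len(n) - (n + 1) / 2) * h
  X1 <- array(rep(co, times = n * n), c(n, n, n))
  X2 <- array(rep(rep(co, each = n), times = n), c(n, n, n))
  X3 <- array(rep(co, each = n * n), c(n, n, n))
  ball <- X1^2 + X2^2 + X3^2 <= radius^2
  volume_grid(array(ball, dim(ball)), rep(h, 3), rep(co[1], 3))
}

# 12-triangle unit cube surface
unit_cube_surface <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tri <- rbind(
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
    c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
    c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  surface_mesh(v, tri)
}

# regular simple grid with an affine vector field, for interpolation tests
affine_field_grid <- function(shape = c(12L, 10L, 8L),
                              spacing = c(0.5, 0.8, 1.1),
                              origin = c(-1, 0, 2),
                              A = matrix(c(0.1, 0, 0, 0.02, -0.05, 0,
                                           0, 0.03, 0.07), 3, 3, byrow = TRUE),
                              b = c(0.5, -0.2, 0.1)) {
  cx <- lapply(1:3, function(k) origin[k] + (seq_len(shape[k]) - 1) * spacing[k])
  pts <- cbind(
    rep(cx[[1]], times = prod(shape[2:3])),
    rep(rep(cx[[2]], each = shape[1]), times = shape[3]),
    rep(cx[[3]], each = prod(shape[1:2])))
  vals <- pts %*% t(A) + matrix(b, nrow(pts), 3, byrow = TRUE)
  volume_grid(array(vals, c(shape, 3L)), spacing, origin)
}

# A tiny constructed label volume: slab with bone below, cartilage above,
# donor cylinder with a uniform bone-boundary shift of `shift_vox` voxels.
toy_stepoff_labels <- function(shift_vox = 0L, n = c(20L, 21L, 15L),
                       spacing = c(0.17, 0.38, 0.38)) {
  lab <- array(0L, n)
  bone_top <- 8L
  surf_top <- 18L
  lab[1:bone_top, , ] <- 2L
  lab[(bone_top + 1):surf_top, , ] <- 1L
  jc <- 11L; kc <- 8L; r <- 6L
  for (j in seq_len(n[2])) for (k in seq_len(n[3])) {
    if ((j - jc)^2 + ((k - kc) * spacing[3] / spacing[2])^2 <= r^2 + 1e-6) {
      top <- bone_top + shift_vox
      lab[, j, k] <- 0L
      lab[1:top, j, k] <- 4L
      lab[(top + 1):surf_top, j, k] <- 3L
    }
  }
  volume_grid(lab, spacing)
}

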