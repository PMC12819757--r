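#' Wrap phase into (-pi, pi]
#'
#' @param phi phase in radians (any finite value, vectorized).
#' @return Phase congruent to `phi` modulo 2*pi, in (-pi, pi].
#' @export
wrap_phase <- function(phi) {
  if (any(!is.finite(phi))) stop("wrap_phase: input must be finite")
  out <- phi - 2 * pi * floor(phi / (2 * pi) + 0.5)
  # floor(x + 0.5) rounds half up, mapping -pi -> +pi as required
  out[out <= -pi] <- pi
  out
}

#' Smooth a complex acquisition with a 3-D Gaussian kernel
#'
#' Real and imaginary parts are filtered independently (equivalently, the
#' complex signal is convolved), which averages phasors rather than phases
#' and is therefore insensitive to wrapping. `sigma_vox = c(0,0,0)` returns
#' the input unchanged. The output magnitude never exceeds the input maximum.
#'
#' @param vol a [complex_volume()].
#' @param sigma_vox per-axis Gaussian sigma in voxels (>= 0).
#' @return A smoothed [complex_volume()].
#' @export
smooth_complex <- function(vol, sigma_vox = c(1, 1, 1)) {
  stopifnot(inherits(vol, "complex_volume"))
  if (any(sigma_vox < 0))
    stop("smooth_complex: sigma must be >= 0, got: ",
         paste(sigma_vox, collapse = ", "))
  if (all(sigma_vox == 0)) return(vol)
  sm <- gauss_smooth_3d(vol$grid$values, sigma_vox)
  complex_volume(grid_with_values(vol$grid, sm), vol$direction, vol$lambda)
}

# Unwrapping quality: negative local variance (3^3 box window) of the
# wrapped phase gradients along the three axes. High quality = locally
# smooth wrapped phase.
phase_quality <- function(phi) {
  box3 <- function(a) {
    for (axis in 1:3)
      a <- (shift_array(a, axis, -1L) + a + shift_array(a, axis, 1L)) / 3
    a
  }
  q <- array(0, dim(phi))
  for (axis in 1:3) {
    g <- wrap_phase(shift_array(phi, axis, -1L) - phi)
    v <- box3(g^2) - box3(g)^2
    q <- q - pmax(v, 0)
  }
  q
}

#' Unwrap a complex acquisition by quality-guided region growing
#'
#' Masked voxels are unwrapped by region growing in descending order of a
#' local quality measure (negative variance of wrapped phase gradients in a
#' 3x3x3 window), 6-connected, ties broken by lexicographic voxel index so
#' the result is deterministic. Disconnected mask components are unwrapped
#' independently. The remaining global 2*pi ambiguity is resolved, per
#' component intersecting `ref_region`, by subtracting the component's median
#' phase over the zero-displacement reference region (recorded in
#' `reference_offset`).
#'
#' @param vol a [complex_volume()] (typically after [smooth_complex()]).
#' @param mask logical array or logical-valued [volume_grid()]: voxels to
#'   unwrap. Must be nonempty.
#' @param ref_region optional logical array/[volume_grid()] of
#'   zero-displacement voxels (must intersect the mask).
#' @param seed_point optional length-3 1-based voxel index inside the mask to
#'   seed the first component.
#' @return An object of class `phase_volume`: `grid` (unwrapped phase,
#'   radians), `mask`, `component` (integer ids), `reference_offset`.
#' @export
unwrap_phase <- function(vol, mask, ref_region = NULL, seed_point = NULL) {
  stopifnot(inherits(vol, "complex_volume"))
  m <- as_mask_array(mask, vol$grid)
  if (!any(m)) stop("unwrap_phase: mask is empty")
  phi <- Arg(vol$grid$values)
  q <- phase_quality(phi)
  seed0 <- -1L
  if (!is.null(seed_point)) {
    seed_point <- as.integer(seed_point)
    stopifnot(length(seed_point) == 3L)
    if (any(seed_point < 1L) || any(seed_point > dim(m)) ||
        !m[seed_point[1], seed_point[2], seed_point[3]])
      stop("seed_point is outside the mask")
    d <- dim(m)
    seed0 <- (seed_point[1] - 1L) + d[1] * (seed_point[2] - 1L) +
      d[1] * d[2] * (seed_point[3] - 1L)
  }
  res <- .unwrap_region_grow(as.numeric(phi), as.integer(m),
                             as.integer(dim(m)), as.numeric(q), seed0)
  up <- array(res$phase, dim(m))
  comp <- array(res$component, dim(m))
  offsets <- numeric(0)
  if (!is.null(ref_region)) {
    rr <- as_mask_array(ref_region, vol$grid) & m
    if (!any(rr)) stop("unwrap_phase: reference region does not intersect the mask")
    for (cid in sort(unique(comp[rr]))) {
      med <- stats::median(up[rr & comp == cid])
      up[comp == cid] <- up[comp == cid] - med
      offsets[as.character(cid)] <- med
    }
  }
  up[!m] <- 0
  structure(list(grid = grid_with_values(vol$grid, up), mask = m,
                 component = comp, reference_offset = offsets,
                 lambda = vol$lambda, direction = vol$direction),
            class = "phase_volume")
}

as_mask_array <- function(mask, grid = NULL) {
  if (inherits(mask, "volume_grid")) {
    if (!is.null(grid) && !grid_same_geometry(mask, grid))
      stop_geometry_mismatch(mask, grid, "mask and volume")
    mask <- mask$values
  }
  if (!is.null(grid) && !identical(dim(mask)[1:3], grid_shape(grid)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match volume shape ", paste(grid_shape(grid), collapse = "x"))
  array(as.logical(mask), dim(mask)[1:3])
}

#' Convert unwrapped phase to a displacement component
#'
#' `u = lambda * phi / (2*pi)` on masked voxels (0 elsewhere); linear in phi.
#'
#' @param phase a `phase_volume` from [unwrap_phase()], or a numeric
#'   [volume_grid()] of unwrapped phase plus an explicit `mask`.
#' @param lambda encoding wavelength in mm; defaults to the wavelength
#'   carried by the phase volume.
#' @param mask optional logical array when `phase` is a bare grid.
#' @return A [volume_grid()] holding the displacement component in mm.
#' @export
phase_to_displacement <- function(phase, lambda = NULL, mask = NULL) {
  if (inherits(phase, "phase_volume")) {
    lambda <- lambda %||% phase$lambda
    mask <- phase$mask
    g <- phase$grid
  } else {
    stopifnot(inherits(phase, "volume_grid"))
    if (is.null(lambda)) stop("lambda (mm) is required for a bare phase grid")
    g <- phase
    if (is.null(mask)) mask <- array(TRUE, grid_shape(g))
  }
  u <- g$values * lambda / (2 * pi)
  u[!mask] <- 0
  grid_with_values(g, u)
}

#' Assemble three displacement components into a vector field
#'
#' Stacks the (U1, U2, U3) component volumes and applies per-component masked
#' Gaussian smoothing (normalized by the smoothed mask, so values outside the
#' mask never bleed in). `sigma_vox = c(0,0,0)` gives plain concatenation.
#'
#' @param components list of three scalar [volume_grid()]s on one grid,
#'   ordered by encoding direction (1, 2, 3).
#' @param mask logical array/[volume_grid()] for the field.
#' @param sigma_vox per-axis smoothing sigma in voxels; default
#'   `c(1, 0.5, 0.5)` (finer in-plane because those voxels are coarser).
#' @return An object of class `displacement_field`: `grid` (4-D, component
#'   last, mm) and `mask`.
#' @export
assemble_displacement_field <- function(components, mask,
                                        sigma_vox = c(1, 0.5, 0.5)) {
  stopifnot(length(components) == 3L)
  g1 <- components[[1]]
  for (k in 2:3) {
    if (!grid_same_geometry(g1, components[[k]]))
      stop_geometry_mismatch(g1, components[[k]],
                             sprintf("displacement components 1 and %d", k))
  }
  m <- as_mask_array(mask, g1)
  vals <- array(0, c(grid_shape(g1), 3L))
  for (k in 1:3) {
    v <- components[[k]]$values
    if (all(sigma_vox == 0)) {
      v[!m] <- 0
      vals[, , , k] <- v
    } else {
      vals[, , , k] <- gauss_smooth_masked(v, m, sigma_vox) * m
    }
  }
  structure(list(grid = volume_grid(vals, g1$spacing, g1$origin), mask = m),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat("<displacement_field> ", sum(x$mask), " masked voxels\n", sep = "")
  print(x$grid)
  invisible(x)
}

#' Recover a displacement field from encoded acquisitions
#'
#' Convenience wrapper for the standard chain: complex smoothing ->
#' quality-guided unwrapping (per direction) -> phase-to-displacement ->
#' assembly with masked smoothing.
#'
#' @param encoded list of three [complex_volume()]s (directions 1-3).
#' @param mask unwrapping mask (already dilated if desired).
#' @param ref_region zero-displacement reference region.
#' @param sigma_complex Gaussian sigma (voxels) for the complex stage.
#' @param sigma_displacement Gaussian sigma (voxels) for the assembled field.
#' @return A `displacement_field`.
#' @export
recover_displacement <- function(encoded, mask, ref_region,
                                 sigma_complex = c(1, 1, 1),
                                 sigma_displacement = c(1, 0.5, 0.5)) {
  comps <- lapply(encoded, function(cv) {
    sm <- smooth_complex(cv, sigma_complex)
    ph <- unwrap_phase(sm, mask, ref_region = ref_region)
    phase_to_displacement(ph)
  })
  assemble_displacement_field(comps, mask, sigma_displacement)
}
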