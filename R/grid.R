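#' Volume grid container
#'
#' A `volume_grid` holds a 3-D (or 4-D, component-last) numeric lattice with
#' explicit geometry: per-axis voxel spacing in mm and the world position (mm)
#' of the centre of voxel `(1,1,1)` (voxel-centre convention; the world
#' coordinate of 1-based voxel index `i` is `origin + (i - 1) * spacing`).
#' Axes follow the project-wide anatomical convention: axis 1 =
#' through-thickness, axis 2 = longitudinal (proximal-distal, proximal =
#' larger coordinate), axis 3 = transverse (medial-lateral).
#'
#' @param values numeric, complex or logical array, 3-D, or 4-D with the
#'   last axis holding vector/tensor components.
#' @param spacing numeric length-3, voxel size in mm (strictly positive).
#' @param origin numeric length-3, world position (mm) of the centre of the
#'   first voxel. Default `c(0, 0, 0)`.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || !(length(dim(values)) %in% c(3L, 4L)))
    stop("`values` must be a 3-D or 4-D array, got dimensions: ",
         paste(dim(values), collapse = " x "))
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive voxel sizes in mm, got: ",
         paste(spacing, collapse = ", "))
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite length-3 world position in mm")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat("<volume_grid> ", paste(d, collapse = " x "),
      if (length(d) == 4L) " (component-last)" else "", "\n", sep = "")
  cat("  spacing (mm): ", paste(format(x$spacing), collapse = " x "), "\n", sep = "")
  cat("  origin  (mm): ", paste(format(x$origin), collapse = ", "), "\n", sep = "")
  cat("  storage: ", typeof(x$values), "\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

grid_shape <- function(grid) dim(grid$values)[1:3]

#' World coordinates of voxel centres
#'
#' @param grid a [volume_grid()].
#' @param axis axis index 1-3.
#' @return Numeric vector of voxel-centre world coordinates (mm) along `axis`.
#' @export
grid_axis_coords <- function(grid, axis) {
  stopifnot(inherits(grid, "volume_grid"), axis %in% 1:3)
  n <- grid_shape(grid)[axis]
  grid$origin[axis] + (seq_len(n) - 1) * grid$spacing[axis]
}

#' Convert 1-based voxel indices to world coordinates (mm)
#'
#' @param grid a [volume_grid()].
#' @param idx integer matrix (n x 3) or length-3 vector of 1-based indices.
#' @return n x 3 matrix of world coordinates.
#' @export
grid_index_to_world <- function(grid, idx) {
  idx <- rbind_to_matrix(idx)
  sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' Convert world coordinates (mm) to fractional 1-based voxel indices
#'
#' @param grid a [volume_grid()].
#' @param xyz numeric matrix (n x 3) or length-3 vector of world positions.
#' @return n x 3 matrix of fractional voxel indices (1-based).
#' @export
grid_world_to_index <- function(grid, xyz) {
  xyz <- rbind_to_matrix(xyz)
  sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
}

rbind_to_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 3L)
}

#' Do two grids share the same geometry?
#'
#' Shapes must match exactly; spacing and origin to `tol` mm.
#' @param a,b [volume_grid()] objects.
#' @param tol tolerance in mm.
#' @return Logical scalar.
#' @export
grid_same_geometry <- function(a, b, tol = 1e-6) {
  identical(grid_shape(a), grid_shape(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_geometry_mismatch <- function(a, b, what = "volumes") {
  stop(sprintf(
    "%s have mismatched grids: shape %s vs %s, spacing (%s) vs (%s)",
    what,
    paste(grid_shape(a), collapse = "x"), paste(grid_shape(b), collapse = "x"),
    paste(format(a$spacing), collapse = ", "),
    paste(format(b$spacing), collapse = ", ")))
}

#' Replace the values of a grid, keeping geometry
#' @param grid a [volume_grid()].
#' @param values replacement array; first three dimensions must match.
#' @return A new [volume_grid()].
#' @export
grid_with_values <- function(grid, values) {
  if (!identical(dim(values)[1:3], grid_shape(grid)))
    stop("replacement values have shape ",
         paste(dim(values)[1:3], collapse = "x"), ", grid is ",
         paste(grid_shape(grid), collapse = "x"))
  volume_grid(values, grid$spacing, grid$origin)
}

#' Complex-valued displacement-encoded acquisition
#'
#' One acquisition of a stimulated-echo displacement-encoded sequence: the
#' voxel phase is `2*pi * u_d / lambda` where `u_d` is the displacement
#' component (mm) along the encoding direction and `lambda` the encoding
#' wavelength (mm).
#'
#' @param grid a [volume_grid()] of complex values.
#' @param direction encoding axis, 1, 2 or 3.
#' @param lambda encoding wavelength in mm (> 0).
#' @return An object of class `complex_volume`.
#' @export
complex_volume <- function(grid, direction, lambda) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!is.complex(grid$values)) stop("`grid` must hold complex values")
  if (!(direction %in% 1:3)) stop("`direction` must be 1, 2 or 3")
  if (!is.finite(lambda) || lambda <= 0)
    stop("`lambda` (encoding wavelength, mm) must be > 0, got ", lambda)
  structure(list(grid = grid, direction = as.integer(direction),
                 lambda = as.numeric(lambda)),
            class = "complex_volume")
}

#' @export
print.complex_volume <- function(x, ...) {
  cat("<complex_volume> direction ", x$direction,
      ", lambda = ", x$lambda, " mm\n", sep = "")
  print(x$grid)
  invisible(x)
}
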