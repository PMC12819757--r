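#' Morphological dilation / erosion with a Euclidean ball
#'
#' Dilation ORs the mask over all integer offsets with
#' `i^2 + j^2 + k^2 <= radius^2` (radius 3 gives the 123-voxel ball);
#' radius 0 is the identity. Erosion is dilation of the complement.
#'
#' @param mask logical array or logical-valued [volume_grid()].
#' @param radius_vox integer ball radius in voxels (>= 0).
#' @return Mask of the same type as the input.
#' @export
dilate_mask <- function(mask, radius_vox = 3L) {
  if (radius_vox < 0) stop("radius_vox must be >= 0")
  apply_ball_morph(mask, radius_vox, erode = FALSE)
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, radius_vox = 1L) {
  if (radius_vox < 0) stop("radius_vox must be >= 0")
  apply_ball_morph(mask, radius_vox, erode = TRUE)
}

#' @rdname dilate_mask
#' @param radius_mm ball radius in millimetres (anisotropic voxel sizes are
#'   honoured); requires a [volume_grid()] mask or explicit `spacing`.
#' @param spacing voxel spacing (mm) when the mask is a bare array.
#' @export
erode_mask_mm <- function(mask, radius_mm, spacing = NULL) {
  if (inherits(mask, "volume_grid")) spacing <- mask$spacing
  if (is.null(spacing)) stop("erode_mask_mm needs a volume_grid or spacing")
  apply_ball_morph(mask, radius_mm, erode = TRUE, spacing = spacing)
}

apply_ball_morph <- function(mask, radius, erode, spacing = c(1, 1, 1)) {
  was_grid <- inherits(mask, "volume_grid")
  g <- if (was_grid) mask else NULL
  m <- as_mask_array(mask)
  if (radius > 0) {
    if (erode) m <- !m
    rv <- floor(radius / spacing + 1e-9)
    offs <- expand.grid(i = -rv[1]:rv[1], j = -rv[2]:rv[2], k = -rv[3]:rv[3])
    offs <- offs[(offs$i * spacing[1])^2 + (offs$j * spacing[2])^2 +
                   (offs$k * spacing[3])^2 <= radius^2 + 1e-9, ]
    acc <- array(FALSE, dim(m))
    mn <- array(as.numeric(m), dim(m))
    for (row in seq_len(nrow(offs))) {
      s <- mn
      if (offs$i[row] != 0) s <- shift_array(s, 1L, offs$i[row])
      if (offs$j[row] != 0) s <- shift_array(s, 2L, offs$j[row])
      if (offs$k[row] != 0) s <- shift_array(s, 3L, offs$k[row])
      acc <- acc | (s > 0.5)
    }
    m <- if (erode) !acc else acc
  }
  if (was_grid) grid_with_values(g, array(m, dim(m))) else m
}

#' Resample a mask onto another grid geometry
#'
#' The mask is treated as an indicator, trilinearly interpolated at the
#' target voxel centres, and thresholded at 0.5 (clamped at the source
#' border).
#'
#' @param mask logical array on `source_grid`, or logical [volume_grid()].
#' @param target a [volume_grid()] (geometry template) or a list with
#'   `shape`, `spacing`, `origin`.
#' @param source_grid geometry of `mask` when it is a bare array.
#' @return Logical array on the target geometry (as a [volume_grid()]).
#' @export
resample_mask <- function(mask, target, source_grid = NULL) {
  if (inherits(mask, "volume_grid")) {
    source_grid <- mask
    mask <- as_mask_array(mask)
  }
  stopifnot(!is.null(source_grid))
  src <- grid_with_values(source_grid, array(as.numeric(mask), dim(mask)))
  out <- upsample_trilinear(src, target, extrapolate = "clamp")
  grid_with_values(out, array(out$values > 0.5, dim(out$values)))
}

target_geometry <- function(target) {
  if (inherits(target, "volume_grid"))
    list(shape = grid_shape(target), spacing = target$spacing,
         origin = target$origin)
  else list(shape = as.integer(target$shape), spacing = as.numeric(target$spacing),
            origin = as.numeric(target$origin))
}

#' Trilinear resampling onto a target grid
#'
#' Component-wise trilinear interpolation of a 3-D or 4-D (component-last)
#' volume at the target voxel centres; exact for fields affine in world
#' coordinates. The target extent must lie within the source extent
#' (voxel-centre hull) unless `extrapolate = "clamp"`, which extends the
#' source by nearest-edge values. With `fill_mask`, source voxels outside
#' the mask are first replaced by their nearest masked value so background
#' never bleeds into the interpolation.
#'
#' @param field a [volume_grid()] (3-D or 4-D) or `displacement_field`.
#' @param target target geometry ([volume_grid()] or list shape/spacing/origin).
#' @param extrapolate `"error"` (default) or `"clamp"`.
#' @param fill_mask optional logical array on the source grid.
#' @param fill_iter cap on nearest-fill sweeps (voxels); queries further than
#'   this outside the mask see zeros, which only matters outside the dilated
#'   region of interest.
#' @return A [volume_grid()] on the target geometry.
#' @export
upsample_trilinear <- function(field, target, extrapolate = c("error", "clamp"),
                               fill_mask = NULL, fill_iter = 6L) {
  extrapolate <- match.arg(extrapolate)
  if (inherits(field, "displacement_field")) {
    if (is.null(fill_mask)) fill_mask <- field$mask
    field <- field$grid
  }
  stopifnot(inherits(field, "volume_grid"))
  tg <- target_geometry(target)
  src_lo <- field$origin
  src_hi <- field$origin + (grid_shape(field) - 1) * field$spacing
  tgt_lo <- tg$origin
  tgt_hi <- tg$origin + (tg$shape - 1) * tg$spacing
  if (extrapolate == "error") {
    for (k in 1:3) {
      if (tgt_lo[k] < src_lo[k] - 1e-9 || tgt_hi[k] > src_hi[k] + 1e-9)
        stop(sprintf(
          "target extent [%.4g, %.4g] mm on axis %d lies outside the source extent [%.4g, %.4g] mm",
          tgt_lo[k], tgt_hi[k], k, src_lo[k], src_hi[k]))
    }
  }
  cx <- lapply(1:3, function(k) tg$origin[k] + (seq_len(tg$shape[k]) - 1) * tg$spacing[k])
  pts <- cbind(
    rep(cx[[1]], times = prod(tg$shape[2:3])),
    rep(rep(cx[[2]], each = tg$shape[1]), times = tg$shape[3]),
    rep(cx[[3]], each = prod(tg$shape[1:2])))
  idx <- grid_world_to_index(field, pts)
  d <- dim(field$values)
  ncomp <- if (length(d) == 4L) d[4] else 1L
  out <- array(0, c(tg$shape, ncomp))
  for (c_i in seq_len(ncomp)) {
    a <- if (length(d) == 4L) array(field$values[, , , c_i], d[1:3]) else field$values
    if (!is.null(fill_mask))
      a <- nearest_fill(a, fill_mask, field$spacing, max_iter = fill_iter)
    out[, , , c_i] <- trilinear_at(a, idx, clamp = extrapolate == "clamp")
  }
  if (ncomp == 1L) dim(out) <- tg$shape
  volume_grid(out, tg$spacing, tg$origin)
}

# ---- strain field containers ----------------------------------------------

new_strain_field <- function(kind, provenance, ...) {
  structure(c(list(kind = kind, provenance = provenance), list(...)),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  n <- if (x$kind == "nodal") nrow(x$tensors) else sum(x$mask)
  cat("<strain_field> ", x$kind, " (", x$provenance, "), ", n,
      if (x$kind == "nodal") " nodes\n" else " masked voxels\n", sep = "")
  invisible(x)
}

#' Grid-differencing strain oracle
#'
#' Computes the displacement gradient with central finite differences on the
#' voxel grid (one-sided at mask boundaries, in world mm), then the
#' Green-Lagrange tensor `E = (H + t(H) + t(H) H) / 2`. This path is
#' independent of the mesh pipeline and serves as its cross-validation
#' oracle.
#'
#' @param field a `displacement_field`, or a 4-D (3-component)
#'   [volume_grid()] plus `mask`.
#' @param mask logical array when `field` is a bare grid.
#' @return A `strain_field` (kind `"grid"`, provenance `"grid-differenced"`)
#'   with a 4-D 6-component tensor grid (order 11,22,33,12,13,23).
#' @export
grid_strain_oracle <- function(field, mask = NULL) {
  if (inherits(field, "displacement_field")) {
    mask <- field$mask
    field <- field$grid
  }
  stopifnot(inherits(field, "volume_grid"), length(dim(field$values)) == 4L)
  m <- as_mask_array(mask)
  d <- grid_shape(field)
  H <- array(0, c(d, 3, 3))
  mn <- array(as.numeric(m), d)
  for (comp in 1:3) {
    u <- array(field$values[, , , comp], d)
    for (axis in 1:3) {
      h <- field$spacing[axis]
      up <- shift_array(u, axis, -1L)   # value at i+1
      dn <- shift_array(u, axis, 1L)    # value at i-1
      mup <- shift_array(mn, axis, -1L) > 0.5
      mdn <- shift_array(mn, axis, 1L) > 0.5
      fwd <- (up - u) / h
      bwd <- (u - dn) / h
      g <- array(0, d)
      both <- m & mup & mdn
      g[both] <- (up[both] - dn[both]) / (2 * h)
      fo <- m & mup & !mdn
      g[fo] <- fwd[fo]
      bo <- m & !mup & mdn
      g[bo] <- bwd[bo]
      H[, , , comp, axis] <- g
    }
  }
  nvox <- prod(d)
  Hm <- array(H, c(nvox, 3, 3))
  S <- tensor_to_sym6(green_lagrange_from_gradient(Hm))
  S[!as.vector(m), ] <- 0
  new_strain_field("grid", "grid-differenced",
                   grid = volume_grid(array(S, c(d, 6L)),
                                      field$spacing, field$origin),
                   mask = m)
}

# ---- mesh strain path ------------------------------------------------------

#' Interpolate a grid field to mesh nodes
#'
#' Trilinear sampling of a (masked) grid field at the node coordinates.
#' Source voxels outside the mask are first replaced by their nearest masked
#' value (the mesh is guaranteed to stay within the dilated mask, so the
#' substitution distance is bounded by the dilation radius). Nodes whose
#' world position falls outside the grid hull take the clamped edge value.
#'
#' @param field a `displacement_field` or (3-D/4-D) [volume_grid()].
#' @param mesh a `tet_mesh` or `surface_mesh`.
#' @param mask optional logical array when `field` is a bare grid.
#' @return n_nodes x n_components matrix of sampled values.
#' @export
interpolate_to_nodes <- function(field, mesh, mask = NULL, fill_iter = 6L) {
  if (inherits(field, "displacement_field")) {
    mask <- mask %||% field$mask
    field <- field$grid
  }
  stopifnot(inherits(field, "volume_grid"))
  coords <- if (inherits(mesh, "tet_mesh")) mesh$nodes else mesh$vertices
  idx <- grid_world_to_index(field, coords)
  d <- dim(field$values)
  ncomp <- if (length(d) == 4L) d[4] else 1L
  out <- matrix(0, nrow(coords), ncomp)
  for (c_i in seq_len(ncomp)) {
    a <- if (length(d) == 4L) array(field$values[, , , c_i], d[1:3]) else field$values
    if (!is.null(mask))
      a <- nearest_fill(a, as_mask_array(mask), field$spacing,
                        max_iter = fill_iter)
    out[, c_i] <- trilinear_at(a, idx, clamp = TRUE)
  }
  out
}

#' Per-element Green-Lagrange strain on a tetrahedral mesh
#'
#' For each linear tetrahedron the displacement gradient is constant and is
#' evaluated from the shape-function derivatives:
#' `H = dU %*% solve(D)` with edge matrices `D` (coordinates) and `dU`
#' (displacements); then `E = (H + t(H) + t(H) H) / 2`. Exact for globally
#' affine displacement; identically zero for rigid-body motion.
#'
#' @param mesh a `tet_mesh` with nodal `displacement` set (n_nodes x 3 mm),
#'   or supply `displacement` explicitly.
#' @param displacement optional n_nodes x 3 matrix overriding
#'   `mesh$displacement`.
#' @return List with `tensors` (n_elem x 6, order 11,22,33,12,13,23) and
#'   `volumes` (n_elem, mm^3).
#' @export
element_green_lagrange <- function(mesh, displacement = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  U <- displacement %||% mesh$displacement
  if (is.null(U)) stop("mesh has no nodal displacement")
  U <- as.matrix(U)
  stopifnot(nrow(U) == nrow(mesh$nodes), ncol(U) == 3L)
  X <- mesh$nodes; T4 <- mesh$tets
  # edge matrices, columns = edges from node 1
  e <- lapply(2:4, function(j) X[T4[, j], , drop = FALSE] - X[T4[, 1], , drop = FALSE])
  du <- lapply(2:4, function(j) U[T4[, j], , drop = FALSE] - U[T4[, 1], , drop = FALSE])
  # D[, i, j]: j-th edge, i-th coordinate
  a11 <- e[[1]][, 1]; a21 <- e[[1]][, 2]; a31 <- e[[1]][, 3]
  a12 <- e[[2]][, 1]; a22 <- e[[2]][, 2]; a32 <- e[[2]][, 3]
  a13 <- e[[3]][, 1]; a23 <- e[[3]][, 2]; a33 <- e[[3]][, 3]
  det <- a11 * (a22 * a33 - a23 * a32) -
         a12 * (a21 * a33 - a23 * a31) +
         a13 * (a21 * a32 - a22 * a31)
  vol <- det / 6
  bad <- vol <= 0
  if (any(bad))
    stop("inverted or degenerate tetrahedron at element ", which(bad)[1])
  # inverse of D via adjugate: inv[i, j] = C[j, i] / det
  i11 <- (a22 * a33 - a23 * a32) / det
  i12 <- (a13 * a32 - a12 * a33) / det
  i13 <- (a12 * a23 - a13 * a22) / det
  i21 <- (a23 * a31 - a21 * a33) / det
  i22 <- (a11 * a33 - a13 * a31) / det
  i23 <- (a13 * a21 - a11 * a23) / det
  i31 <- (a21 * a32 - a22 * a31) / det
  i32 <- (a12 * a31 - a11 * a32) / det
  i33 <- (a11 * a22 - a12 * a21) / det
  n <- nrow(T4)
  H <- array(0, c(n, 3, 3))
  # dU is 3x3 per element with columns the edge displacement deltas;
  # H = dU %*% inv(D)
  dUc <- list(
    rbind_cols(du, 1),  # rows: edges, for displacement component 1
    rbind_cols(du, 2),
    rbind_cols(du, 3))
  inv <- list(c1 = cbind(i11, i21, i31), c2 = cbind(i12, i22, i32),
              c3 = cbind(i13, i23, i33))
  for (i in 1:3) for (j in 1:3) {
    H[, i, j] <- rowSums(dUc[[i]] * inv[[j]])
  }
  list(tensors = tensor_to_sym6(green_lagrange_from_gradient(H)),
       volumes = vol)
}

rbind_cols <- function(du, comp) {
  cbind(du[[1]][, comp], du[[2]][, comp], du[[3]][, comp])
}

#' Lumped-mass L2 projection of element tensors to mesh nodes
#'
#' Each nodal value is the volume-weighted mean of the tensors of adjacent
#' elements (componentwise). A constant element field projects to the same
#' constant at every node, and the volume integral of each component is
#' conserved (each element's volume is split equally over its four nodes).
#'
#' @param element_field list with `tensors` (n_elem x 6) and `volumes`, as
#'   returned by [element_green_lagrange()].
#' @param mesh the `tet_mesh` the tensors live on.
#' @return A `strain_field` (kind `"nodal"`, provenance
#'   `"element-projected"`) with `tensors` (n_nodes x 6) and the mesh.
#' @export
l2_project_to_nodes <- function(element_field, mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  Et <- element_field$tensors
  vol <- element_field$volumes
  T4 <- mesh$tets
  nn <- nrow(mesh$nodes)
  node_ids <- as.vector(T4)                     # 4 * n_elem incidences
  wts <- rep(vol, times = 4L)
  den <- as.vector(rowsum(wts, node_ids, reorder = TRUE))
  present <- sort(unique(node_ids))
  S <- matrix(0, nn, 6)
  for (c_i in 1:6) {
    num <- as.vector(rowsum(rep(Et[, c_i], times = 4L) * wts, node_ids,
                            reorder = TRUE))
    S[present, c_i] <- num / den
  }
  new_strain_field("nodal", "element-projected", tensors = S, mesh = mesh)
}

#' Mesh-path strain: interpolate, differentiate, project
#'
#' The production strain path: nodal displacements are interpolated from the
#' grid field, per-element Green-Lagrange tensors evaluated from the linear
#' shape functions, and projected back to nodes with the lumped-mass L2
#' projection.
#'
#' @param field `displacement_field` (typically upsampled to the anatomical
#'   grid).
#' @param mesh a `tet_mesh` of the cartilage.
#' @return A nodal `strain_field`; the mesh inside it carries the nodal
#'   displacements.
#' @export
mesh_strain <- function(field, mesh) {
  mesh$displacement <- interpolate_to_nodes(field, mesh)
  ef <- element_green_lagrange(mesh)
  l2_project_to_nodes(ef, mesh)
}

# ---- principal strains -----------------------------------------------------

# Vectorized closed-form eigenvalues of symmetric 3x3 tensors (rows of S,
# order 11,22,33,12,13,23), returned descending. Trigonometric method.
sym6_eigenvalues <- function(S) {
  a11 <- S[, 1]; a22 <- S[, 2]; a33 <- S[, 3]
  a12 <- S[, 4]; a13 <- S[, 5]; a23 <- S[, 6]
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  e1 <- e2 <- e3 <- q
  nz <- p > 0
  if (any(nz)) {
    b11 <- (a11 - q) / p; b22 <- (a22 - q) / p; b33 <- (a33 - q) / p
    b12 <- a12 / p; b13 <- a13 / p; b23 <- a23 / p
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1 <- q + 2 * p * cos(phi)
    l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
    l2 <- 3 * q - l1 - l3
    e1[nz] <- l1[nz]; e2[nz] <- l2[nz]; e3[nz] <- l3[nz]
  }
  out <- cbind(e1, e2, e3)
  dimnames(out) <- NULL
  out
}

#' Principal strains and eigen outcomes
#'
#' Eigen-decomposes each symmetric strain tensor. Eigenvalues are sorted
#' descending (`E1 >= E2 >= E3`); the minimum principal strain `E_min` is the
#' most negative eigenvalue (`E3`) and the maximum shear strain `E_maxshear`
#' is half the difference between the first and third eigenvalues.
#' Eigenvectors (optional; computed with `eigen(symmetric = TRUE)` per
#' tensor) are unit-norm with the sign fixed so the largest-magnitude
#' component is positive.
#'
#' @param E a `strain_field` (grid or nodal), or an n x 6 matrix of symmetric
#'   tensors (order 11,22,33,12,13,23).
#' @param vectors compute eigenvector triads as well (slower; per-tensor
#'   `eigen` calls).
#' @return An object of class `principal_strain_field` with `values`
#'   (n x 3 eigenvalues, descending), `E_min`, `E_maxshear`, optional
#'   `vectors` (n x 3 x 3, columns = eigenvectors), and the originating
#'   geometry (`kind`, plus `mask`/`grid` or `mesh`).
#' @export
principal_strains <- function(E, vectors = FALSE) {
  geom <- list(kind = "matrix")
  if (inherits(E, "strain_field")) {
    if (E$kind == "nodal") {
      geom <- list(kind = "nodal", mesh = E$mesh)
      S <- E$tensors
    } else {
      d <- grid_shape(E$grid)
      geom <- list(kind = "grid", mask = E$mask,
                   geometry = list(shape = d, spacing = E$grid$spacing,
                                   origin = E$grid$origin))
      S <- matrix(E$grid$values, prod(d), 6)
    }
  } else {
    S <- as.matrix(E)
    stopifnot(ncol(S) == 6L)
  }
  ev <- sym6_eigenvalues(S)
  vecs <- NULL
  if (vectors) {
    n <- nrow(S)
    vecs <- array(0, c(n, 3, 3))
    for (i in seq_len(n)) {
      A <- matrix(c(S[i, 1], S[i, 4], S[i, 5],
                    S[i, 4], S[i, 2], S[i, 6],
                    S[i, 5], S[i, 6], S[i, 3]), 3, 3)
      eg <- eigen(A, symmetric = TRUE)   # already descending
      V <- eg$vectors
      for (j in 1:3) {
        big <- which.max(abs(V[, j]))
        if (V[big, j] < 0) V[, j] <- -V[, j]
      }
      vecs[i, , ] <- V
      ev[i, ] <- eg$values
    }
  }
  structure(c(list(values = ev, E_min = ev[, 3],
                   E_maxshear = (ev[, 1] - ev[, 3]) / 2,
                   vectors = vecs), geom),
            class = "principal_strain_field")
}

#' @export
print.principal_strain_field <- function(x, ...) {
  cat("<principal_strain_field> ", nrow(x$values), " tensors (", x$kind, ")\n",
      sep = "")
  cat(sprintf("  E_min in [%.4g, %.4g]; E_maxshear max %.4g\n",
              min(x$E_min), max(x$E_min), max(x$E_maxshear)))
  invisible(x)
}

#' Rebuild a scalar outcome volume from a grid-based principal strain field
#'
#' @param ps a `principal_strain_field` with `kind == "grid"`.
#' @param outcome `"E_min"` or `"E_maxshear"`.
#' @return A scalar [volume_grid()] (0 outside the mask).
#' @export
principal_outcome_volume <- function(ps, outcome = c("E_min", "E_maxshear")) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(ps, "principal_strain_field"), ps$kind == "grid")
  g <- ps$geometry
  v <- array(ps[[outcome]], g$shape)
  v[!ps$mask] <- 0
  volume_grid(v, g$spacing, g$origin)
}
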