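test_that("ball dilation produces the exact Euclidean lattice ball", {
  n <- c(9, 9, 9)
  m <- array(FALSE, n); m[5, 5, 5] <- TRUE
  d3 <- dilate_mask(m, 3L)
  # brute-force count of lattice offsets with i^2 + j^2 + k^2 <= 9
  offs <- expand.grid(i = -3:3, j = -3:3, k = -3:3)
  expect_equal(sum(d3), sum(offs$i^2 + offs$j^2 + offs$k^2 <= 9))
  expect_equal(sum(d3), 123L)
  expect_identical(dilate_mask(m, 0L), m)
  full <- array(TRUE, n)
  expect_identical(dilate_mask(full, 3L), full)
  expect_true(all(d3[m]))   # superset of the input
  expect_error(dilate_mask(m, -1), ">= 0")
})

test_that("erosion is dual to dilation and mm-metric erosion honours anisotropy", {
  n <- c(12, 12, 12)
  set.seed(20)
  m <- array(runif(prod(n)) > 0.6, n)
  expect_identical(erode_mask(m, 2L), !dilate_mask(!m, 2L))
  g <- volume_grid(array(TRUE, c(9, 9, 9)), c(0.17, 0.38, 0.38))
  g$values[5, 5, 5] <- FALSE
  er <- erode_mask_mm(g, 0.4)
  # 0.4 mm reaches 2 voxels along axis 1 (0.17) but only 1 along axes 2-3
  expect_false(er$values[3, 5, 5])
  expect_true(er$values[2, 5, 5])
  expect_false(er$values[5, 4, 5])
  expect_true(er$values[5, 3, 5])
})

test_that("trilinear resampling reproduces constants and affine fields exactly", {
  src <- affine_field_grid()
  tgt <- list(shape = c(23L, 19L, 15L), spacing = c(0.22, 0.35, 0.5),
              origin = c(-0.8, 0.3, 2.2))
  out <- upsample_trilinear(src, tgt)
  ref <- affine_field_grid(shape = tgt$shape, spacing = tgt$spacing,
                           origin = tgt$origin)
  expect_lt(max(abs(out$values - ref$values)), 1e-10)
  cst <- volume_grid(array(4.2, c(5, 5, 5)), c(1, 1, 1))
  out2 <- upsample_trilinear(cst, list(shape = c(9L, 9L, 9L),
                                       spacing = c(0.5, 0.5, 0.5),
                                       origin = c(0, 0, 0)))
  expect_equal(out2$values, array(4.2, c(9, 9, 9)))
  expect_error(upsample_trilinear(cst, list(shape = c(9L, 9L, 9L),
                                            spacing = c(1, 1, 1),
                                            origin = c(-2, 0, 0))),
               "outside the source extent")
})

test_that("resampled phantom displacement converges as the source grid refines", {
  sp <- phantom_spec()   # full-width slab so the probe grid stays inside
  # sample the analytic field on two low-res grids, one at half the spacing,
  # interpolate both onto the same fine probe grid, compare to direct analytic
  probe <- list(shape = c(9L, 21L, 21L), spacing = c(0.4, 1.0, 1.0),
                origin = c(0.2, -10, -10))
  rms <- sapply(c(1, 0.5), function(f) {
    spc <- c(0.33, 1.5, 2.0) * f
    shp <- as.integer(ceiling(c(4.6, 44, 44) / spc))
    org <- c(-0.3, -spc[2] * floor(shp[2] / 2), -spc[3] * floor(shp[3] / 2))
    cx <- lapply(1:3, function(k) org[k] + (seq_len(shp[k]) - 1) * spc[k])
    pts <- cbind(rep(cx[[1]], times = prod(shp[2:3])),
                 rep(rep(cx[[2]], each = shp[1]), times = shp[3]),
                 rep(cx[[3]], each = prod(shp[1:2])))
    pts[, 1] <- pmin(pmax(pts[, 1], 0), 3.9)
    U <- analytic_displacement(sp, pts)
    src <- volume_grid(array(U, c(shp, 3L)), spc, org)
    out <- upsample_trilinear(src, probe, extrapolate = "clamp")
    cxp <- lapply(1:3, function(k) probe$origin[k] +
                    (seq_len(probe$shape[k]) - 1) * probe$spacing[k])
    pp <- cbind(rep(cxp[[1]], times = prod(probe$shape[2:3])),
                rep(rep(cxp[[2]], each = probe$shape[1]), times = probe$shape[3]),
                rep(cxp[[3]], each = prod(probe$shape[1:2])))
    Uref <- analytic_displacement(sp, pp)
    sqrt(mean((out$values - array(Uref, c(probe$shape, 3L)))^2))
  })
  expect_lt(rms[2], rms[1])
})

test_that("the grid strain oracle is exact for affine fields and rigid rotations", {
  g <- affine_field_grid(A = matrix(c(0.1, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3,
                                    byrow = TRUE), b = c(0, 0, 0))
  m <- array(TRUE, dim(g$values)[1:3])
  sf <- grid_strain_oracle(g, m)
  E11 <- sf$grid$values[, , , 1]
  expect_lt(max(abs(E11 - 0.105)), 1e-12)
  expect_lt(max(abs(sf$grid$values[, , , 2:6])), 1e-12)
  # 20-degree rigid rotation about axis 3: identically zero Green-Lagrange
  th <- 20 * pi / 180
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  grot <- affine_field_grid(A = Q - diag(3), b = c(0, 0, 0))
  sfr <- grid_strain_oracle(grot, m)
  expect_lt(max(abs(sfr$grid$values)), 1e-10)
  # simple shear u1 = 0.2 x2
  gsh <- affine_field_grid(A = matrix(c(0, 0.2, 0, 0, 0, 0, 0, 0, 0), 3, 3,
                                      byrow = TRUE), b = c(0, 0, 0))
  sfs <- grid_strain_oracle(gsh, m)
  expect_lt(max(abs(sfs$grid$values[, , , 4] - 0.1)), 1e-12)   # E12
  expect_lt(max(abs(sfs$grid$values[, , , 2] - 0.02)), 1e-12)  # E22
  expect_lt(max(abs(sfs$grid$values[, , , 1])), 1e-12)         # E11
})

test_that("grid-differenced phantom strain converges at second order in spacing", {
  sp <- small_phantom_spec()
  err_at <- function(f) {
    spc <- c(0.3, 0.8, 0.8) * f
    shp <- as.integer(round(c(3.9 / spc[1], 20 / spc[2], 20 / spc[3]))) + 1L
    org <- c(0, -spc[2] * floor(shp[2] / 2), -spc[3] * floor(shp[3] / 2))
    cx <- lapply(1:3, function(k) org[k] + (seq_len(shp[k]) - 1) * spc[k])
    pts <- cbind(rep(cx[[1]], times = prod(shp[2:3])),
                 rep(rep(cx[[2]], each = shp[1]), times = shp[3]),
                 rep(cx[[3]], each = prod(shp[1:2])))
    U <- analytic_displacement(sp, pts)
    g <- volume_grid(array(U, c(shp, 3L)), spc, org)
    m <- array(TRUE, shp)
    sf <- grid_strain_oracle(g, m)
    E <- analytic_strain(sp, pts)
    Ean <- cbind(E[, 1, 1], E[, 2, 2], E[, 3, 3],
                 E[, 1, 2], E[, 1, 3], E[, 2, 3])
    # interior only: one-sided boundary stencils are first order by design
    interior <- array(FALSE, shp)
    interior[2:(shp[1] - 1), 2:(shp[2] - 1), 2:(shp[3] - 1)] <- TRUE
    S <- matrix(sf$grid$values, prod(shp), 6)
    max(abs(S[interior, ] - Ean[interior, ]))
  }
  e1 <- err_at(1); e2 <- err_at(0.5)
  expect_lt(e2, e1 / 3)   # ~4x reduction expected at halved spacing
})

test_that("element Green-Lagrange tensors match closed forms on a cube mesh", {
  mesh <- build_tet_mesh(unit_cube_surface(), cell_mm = 0.5)
  X <- mesh$nodes
  # uniaxial stretch u1 = 0.1 x1
  U <- cbind(0.1 * X[, 1], 0, 0)
  ef <- element_green_lagrange(mesh, U)
  expect_lt(max(abs(ef$tensors[, 1] - 0.105)), 1e-12)
  expect_lt(max(abs(ef$tensors[, 2:6])), 1e-12)
  # rigid rotation: zero strain
  th <- 20 * pi / 180
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Urot <- X %*% t(Q) - X
  efr <- element_green_lagrange(mesh, Urot)
  expect_lt(max(abs(efr$tensors)), 1e-12)
  # simple shear u1 = 0.2 x2
  Ush <- cbind(0.2 * X[, 2], 0, 0)
  efs <- element_green_lagrange(mesh, Ush)
  expect_lt(max(abs(efs$tensors[, 4] - 0.1)), 1e-12)
  expect_lt(max(abs(efs$tensors[, 2] - 0.02)), 1e-12)
  expect_lt(max(abs(efs$tensors[, 1])), 1e-12)
  # inverted element rejected
  bad <- mesh
  bad$tets[1, ] <- bad$tets[1, c(1, 2, 4, 3)]
  expect_error(element_green_lagrange(bad, U), "element 1")
})

test_that("lumped L2 projection preserves constants, means and volume integrals", {
  mesh <- build_tet_mesh(unit_cube_surface(), cell_mm = 0.5)
  ne <- nrow(mesh$tets)
  const <- list(tensors = matrix(rep(c(0.1, -0.2, 0.3, 0, 0.05, 0), each = ne),
                                 ne, 6),
                volumes = tet_volumes(mesh))
  sf <- l2_project_to_nodes(const, mesh)
  for (c_i in 1:6)
    expect_lt(max(abs(sf$tensors[, c_i] - const$tensors[1, c_i])), 1e-12)
  # volume integral conservation: sum_e V_e E_e == sum_n (sum_adj V/4) E_n
  set.seed(30)
  rnd <- list(tensors = matrix(rnorm(ne * 6), ne, 6),
              volumes = tet_volumes(mesh))
  sfr <- l2_project_to_nodes(rnd, mesh)
  nodal_w <- rep(0, nrow(mesh$nodes))
  wts <- rep(rnd$volumes / 4, 4)   # each element splits equally over 4 nodes
  agg <- rowsum(wts, as.vector(mesh$tets))
  nodal_w[as.integer(rownames(agg))] <- agg
  for (c_i in 1:6) {
    int_elem <- sum(rnd$volumes * rnd$tensors[, c_i])
    int_node <- sum(nodal_w * sfr$tensors[, c_i])
    expect_equal(int_node, int_elem, tolerance = 1e-9)
  }
  # two equal-volume tets sharing a face: shared nodes average the values
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  two <- tet_mesh(nodes, rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))
  v2 <- tet_volumes(two)
  expect_true(all(v2 > 0))
  ef2 <- list(tensors = rbind(rep(1, 6), rep(3, 6)), volumes = c(1, 1))
  sf2 <- l2_project_to_nodes(ef2, two)
  expect_equal(unname(sf2$tensors[2, 1]), 2)   # shared node
  expect_equal(unname(sf2$tensors[1, 1]), 1)   # exclusive to element 1
  expect_equal(unname(sf2$tensors[5, 1]), 3)   # exclusive to element 2
})

test_that("principal strains order eigenvalues and derive the two outcomes", {
  S <- rbind(c(0.1, 0, -0.2, 0, 0, 0),       # diag(0.1, 0, -0.2)
             c(0.05, 0.05, 0.05, 0, 0, 0),   # hydrostatic
             c(0, 0, 0, 0.1, 0, 0))          # pure shear E12
  ps <- principal_strains(S, vectors = TRUE)
  expect_equal(ps$values[1, ], c(0.1, 0, -0.2), ignore_attr = TRUE)
  expect_equal(ps$E_min[1], -0.2)
  expect_equal(ps$E_maxshear[1], 0.15)
  expect_equal(ps$E_maxshear[2], 0)
  expect_equal(ps$values[3, ], c(0.1, 0, -0.1), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(ps$E_maxshear[3], 0.1, tolerance = 1e-12)
  # eigenvectors orthonormal, deterministic sign
  for (i in 1:3) {
    V <- ps$vectors[i, , ]
    expect_lt(max(abs(t(V) %*% V - diag(3))), 1e-8)
    for (j in 1:3) expect_gt(V[which.max(abs(V[, j])), j], 0)
  }
})

test_that("eigen outcomes are invariant under frame rotation", {
  set.seed(31)
  for (rep in 1:5) {
    A <- matrix(rnorm(9, sd = 0.1), 3, 3)
    E <- (A + t(A)) / 2
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    Er <- Q %*% E %*% t(Q)
    to6 <- function(M) cbind(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
    p1 <- principal_strains(to6(E))
    p2 <- principal_strains(to6(Er))
    expect_equal(p1$values, p2$values, tolerance = 1e-10)
    expect_equal(p1$E_min, p2$E_min, tolerance = 1e-10)
    expect_equal(p1$E_maxshear, p2$E_maxshear, tolerance = 1e-10)
  }
})

test_that("rigid-body nodal motion produces |E| below 1e-10 on the mesh path", {
  mesh <- build_tet_mesh(unit_cube_surface(), cell_mm = 0.34)
  set.seed(32)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  tr <- c(0.3, -1, 2)
  U <- mesh$nodes %*% t(Q) - mesh$nodes +
    matrix(tr, nrow(mesh$nodes), 3, byrow = TRUE)
  ef <- element_green_lagrange(mesh, U)
  sf <- l2_project_to_nodes(ef, mesh)
  expect_lt(max(abs(sf$tensors)), 1e-10)
})

test_that("node interpolation is exact for affine fields and voxel centres", {
  g <- affine_field_grid()
  nodes <- rbind(c(0.3, 1.1, 3.3), c(-0.5, 2, 4), c(2, 5, 8))
  mesh <- tet_mesh(nodes, matrix(1:4, 1)[, c(1, 2, 3, 1), drop = FALSE])
  mesh$nodes <- nodes
  vals <- interpolate_to_nodes(g, mesh)
  A <- matrix(c(0.1, 0, 0, 0.02, -0.05, 0, 0, 0.03, 0.07), 3, 3, byrow = TRUE)
  ref <- nodes %*% t(A) + matrix(c(0.5, -0.2, 0.1), 3, 3, byrow = TRUE)
  expect_lt(max(abs(vals - ref)), 1e-10)
  # node exactly at a voxel centre returns that voxel's value
  centre <- grid_index_to_world(g, c(3, 4, 5))
  mesh$nodes <- rbind(centre, centre, centre)
  v <- interpolate_to_nodes(g, mesh)
  expect_equal(unname(v[1, ]), g$values[3, 4, 5, ], tolerance = 1e-12)
})
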