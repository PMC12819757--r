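test_that("phantom displacement matches its closed form at anchor points", {
  sp <- phantom_spec(compression = 0.5)   # rho = sqrt(12.7 * 0.5)
  rho <- sqrt(12.7 * 0.5)
  # peak of the bump: straight-down compression by delta
  expect_equal(analytic_displacement(sp, c(3.9, 0, 0))[1, ],
               c(u1 = -0.5, u2 = 0, u3 = 0))
  # fixed base: zero everywhere on the bone interface plane
  expect_equal(max(abs(analytic_displacement(
    sp, cbind(0, seq(-20, 20, 5), seq(-20, 20, 5))))), 0)
  # one contact-width out on the surface
  u <- analytic_displacement(sp, c(3.9, rho, 0))[1, ]
  expect_equal(unname(u[1]), -0.5 * exp(-0.5), tolerance = 1e-12)
  expect_equal(unname(u[2]), 0.3 * 0.5 * exp(-0.5), tolerance = 1e-12)
  expect_equal(unname(u[3]), 0)
  # bound |u| <= delta (1 + beta)
  set.seed(11)
  pts <- cbind(runif(200, 0, 3.9), runif(200, -20, 20), runif(200, -20, 20))
  expect_true(all(sqrt(rowSums(analytic_displacement(sp, pts)^2)) <=
                    0.5 * 1.3 + 1e-12))
})

test_that("positions outside the slab raise errors naming the coordinate", {
  sp <- phantom_spec()
  expect_error(analytic_displacement(sp, c(2, 30, 0)), "x2 = 30")
  expect_error(analytic_displacement(sp, c(5, 0, 0)), "x1 = 5")
  expect_error(analytic_strain(sp, c(2, 0, -40)), "x3 = -40")
})

test_that("analytic strain matches the closed form and a finite-difference oracle", {
  sp <- phantom_spec(compression = 0.5)
  # centre column: E11 = -d/t + (d/t)^2/2, E off-diagonals vanish
  E <- analytic_strain(sp, c(3.9, 0, 0))[1, , ]
  dt <- 0.5 / 3.9
  expect_equal(E[1, 1], -dt + dt^2 / 2, tolerance = 1e-12)
  expect_equal(E[1, 2], 0); expect_equal(E[1, 3], 0)
  # zero strain on the interface plane
  expect_equal(max(abs(analytic_strain(sp, cbind(0, -10:10, 5)))), 0)
  # central finite differences of the displacement at random interior points
  set.seed(42)
  pts <- cbind(runif(10, 0.5, 3.5), runif(10, -15, 15), runif(10, -15, 15))
  h <- 1e-5
  for (q in seq_len(nrow(pts))) {
    x <- pts[q, ]
    Hfd <- matrix(0, 3, 3)
    for (j in 1:3) {
      e <- rep(0, 3); e[j] <- h
      Hfd[, j] <- (analytic_displacement(sp, x + e) -
                     analytic_displacement(sp, x - e)) / (2 * h)
    }
    Efd <- (Hfd + t(Hfd) + t(Hfd) %*% Hfd) / 2
    Ean <- analytic_strain(sp, x)[1, , ]
    expect_lt(max(abs(Efd - Ean)) / max(abs(Efd)), 1e-6)
  }
})

test_that("phantom_spec enforces its invariants", {
  expect_error(phantom_spec(compression = 4.0), "below the cartilage thickness")
  expect_error(phantom_spec(graft_radius = 30), "half-extent")
  expect_error(phantom_spec(stepoff_mean = 2, stepoff_amplitude = 2),
               "stepoff")
  expect_error(phantom_spec(lambda = -1), "> 0")
})

test_that("identical spec and seed give bit-identical datasets", {
  sp <- small_phantom_spec(noise_snr = 20, seed = 7L)
  a <- generate_phantom(sp, truth_highres = FALSE)
  b <- generate_phantom(sp, truth_highres = FALSE)
  expect_identical(a$magnitude$values, b$magnitude$values)
  for (d in 1:3)
    expect_identical(a$encoded[[d]]$grid$values, b$encoded[[d]]$grid$values)
  expect_identical(a$labels$values, b$labels$values)
})

test_that("noiseless zero-compression phantom encodes zero phase in tissue", {
  sp <- small_phantom_spec(compression = 0, noise_snr = Inf)
  ds <- generate_phantom(sp, truth_highres = FALSE)
  for (d in 1:3) {
    ph <- Arg(ds$encoded[[d]]$grid$values)
    expect_lt(max(abs(ph)), 1e-12)
  }
})

test_that("flush donor plug (s0 = s1 = 0) gives zero step-off at every crossing", {
  sp <- small_phantom_spec(stepoff_mean = 0, stepoff_amplitude = 0)
  ds <- generate_phantom(sp, truth_highres = FALSE)
  tab <- stepoff_table(ds$labels)
  expect_gt(nrow(tab), 10)
  expect_true(all(tab$stepoff_mm == 0))
})

test_that("phantom truth fields agree with the analytic closed forms", {
  sp <- small_phantom_spec()
  ds <- generate_phantom(sp, truth_highres = TRUE)
  lab <- ds$labels$values
  cart <- which(lab == 1L | lab == 3L)
  # sample a few cartilage voxels and compare against direct evaluation
  set.seed(5)
  pick <- sample(cart, 50)
  ijk <- arrayInd(pick, dim(lab))
  xyz <- grid_index_to_world(ds$labels, ijk)
  U <- analytic_displacement(sp, xyz)
  d <- dim(lab)
  for (c_i in 1:3) {
    stored <- ds$truth_displacement$values[cbind(ijk, c_i)]
    expect_equal(stored, unname(U[, c_i]), tolerance = 1e-12)
  }
  E <- analytic_strain(sp, xyz)
  expect_equal(ds$truth_strain$values[cbind(ijk, 1L)], E[, 1, 1],
               tolerance = 1e-12)
  expect_equal(ds$truth_strain$values[cbind(ijk, 4L)], E[, 1, 2],
               tolerance = 1e-12)
})

test_that("compression percentage reproduces the thickness-normalized value", {
  expect_equal(compression_percent(0.25, 3.9), 100 * 0.25 / 3.9)
  expect_equal(compression_percent(0.5, 3.9), 100 * 0.5 / 3.9)
  expect_error(compression_percent(0.25, 0), "> 0")
})
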