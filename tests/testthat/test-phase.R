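test_that("wrap_phase maps into (-pi, pi] and is 2*pi-periodic", {
  expect_equal(wrap_phase(0), 0)
  expect_equal(wrap_phase(3 * pi / 2), -pi / 2)
  expect_equal(wrap_phase(2 * pi * 1.25), pi / 2)  # u = 1.25 mm at lambda = 1
  expect_equal(wrap_phase(pi), pi)
  expect_equal(wrap_phase(-pi), pi)
  x <- seq(-20, 20, by = 0.37)
  expect_equal(wrap_phase(x + 6 * pi), wrap_phase(x), tolerance = 1e-12)
  expect_true(all(wrap_phase(x) > -pi & wrap_phase(x) <= pi))
  expect_error(wrap_phase(c(1, NA)), "finite")
})

make_cv <- function(phase, mag = 1, spacing = c(1, 1, 1)) {
  vals <- array(mag * exp(1i * phase), dim(phase))
  complex_volume(volume_grid(vals, spacing), 1, 1.0)
}

test_that("complex smoothing is identity at sigma 0 and preserves constants", {
  set.seed(4)
  ph <- array(runif(5 * 6 * 7, -pi, pi), c(5, 6, 7))
  cv <- make_cv(ph)
  expect_identical(smooth_complex(cv, c(0, 0, 0))$grid$values, cv$grid$values)
  const <- make_cv(array(0.3, c(6, 6, 6)))
  sm <- smooth_complex(const, c(1.5, 1, 2))
  expect_lt(max(abs(Arg(sm$grid$values) - 0.3)), 1e-12)
  # magnitude never exceeds the input maximum
  expect_lte(max(Mod(sm$grid$values)), max(Mod(const$grid$values)) + 1e-12)
  expect_error(smooth_complex(cv, c(-1, 0, 0)), ">= 0")
})

test_that("complex smoothing reduces phase noise (Monte-Carlo over seeds)", {
  # constant-phase tissue at SNR 10: the voxelwise phase error sd after a
  # (1,1,1)-voxel Gaussian must be below the unsmoothed sd for every seed
  worse <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    n <- c(10, 10, 10)
    true_phase <- 0.7
    sig <- array(exp(1i * true_phase), n) +
      array(complex(real = rnorm(prod(n), 0, 0.1),
                    imaginary = rnorm(prod(n), 0, 0.1)), n)
    cv <- complex_volume(volume_grid(sig, c(1, 1, 1)), 1, 1.0)
    sm <- smooth_complex(cv, c(1, 1, 1))
    err0 <- stats::sd(wrap_phase(Arg(cv$grid$values) - true_phase))
    err1 <- stats::sd(wrap_phase(Arg(sm$grid$values) - true_phase))
    if (err1 >= err0) worse <- worse + 1L
  }
  expect_equal(worse, 0L)
})

test_that("unwrapping recovers a noiseless ramp spanning several wraps", {
  n <- c(24, 10, 8)
  x <- array(rep(seq_len(n[1]), times = prod(n[2:3])), n)
  true_phase <- 0.9 * x        # ~3.4 wraps across the box
  cv <- make_cv(true_phase)
  mask <- array(TRUE, n)
  ref <- array(FALSE, n); ref[1, , ] <- TRUE
  pv <- unwrap_phase(cv, mask, ref_region = ref)
  # after referencing, recovered = truth + (truth median in ref region)
  expected <- true_phase - stats::median(true_phase[ref])
  expect_lt(max(abs(pv$grid$values - expected)), 1e-9)
  # smoothness certificate: 6-neighbour jumps below pi along the ramp axis
  v <- pv$grid$values
  expect_lt(max(abs(v[-1, , ] - v[-n[1], , ])), pi)
})

test_that("unwrapping leaves a constant phase untouched and honours seeds/masks", {
  n <- c(6, 6, 6)
  cv <- make_cv(array(0.3, n))
  pv <- unwrap_phase(cv, array(TRUE, n), seed_point = c(3, 3, 3))
  expect_equal(pv$grid$values, array(0.3, n), tolerance = 1e-12)
  expect_error(unwrap_phase(cv, array(FALSE, n)), "empty")
  expect_error(unwrap_phase(cv, array(TRUE, n), seed_point = c(7, 1, 1)),
               "outside")
  m <- array(TRUE, n); m[1, 1, 1] <- FALSE
  expect_error(unwrap_phase(cv, m, ref_region = array(FALSE, n)),
               "reference region")
})

test_that("disconnected mask components are unwrapped and referenced independently", {
  n <- c(12, 5, 5)
  x <- array(rep(seq_len(n[1]), times = prod(n[2:3])), n)
  true_phase <- 1.1 * x
  cv <- make_cv(true_phase)
  mask <- array(TRUE, n)
  mask[6:7, , ] <- FALSE       # split into two slabs
  ref <- array(FALSE, n); ref[c(1, 8), , ] <- TRUE
  pv <- unwrap_phase(cv, mask, ref_region = ref)
  expect_equal(length(unique(pv$component[mask])), 2L)
  for (cid in unique(pv$component[mask])) {
    sel <- mask & pv$component == cid
    resid <- pv$grid$values[sel] - true_phase[sel]
    # constant offset per component, median zero over its reference voxels
    expect_lt(diff(range(resid)), 1e-9)
    expect_lt(abs(stats::median(pv$grid$values[sel & ref])), 1e-9)
  }
})

test_that("unwrapping is invariant to global 2*pi shifts of the input phase", {
  set.seed(9)
  n <- c(10, 8, 6)
  ph <- array(0.4 * seq_len(n[1]), n)
  cv1 <- make_cv(ph)
  cv2 <- make_cv(ph + 4 * pi)   # same complex values up to numeric noise
  ref <- array(FALSE, n); ref[1, , ] <- TRUE
  p1 <- unwrap_phase(cv1, array(TRUE, n), ref_region = ref)
  p2 <- unwrap_phase(cv2, array(TRUE, n), ref_region = ref)
  expect_equal(p1$grid$values, p2$grid$values, tolerance = 1e-9)
})

test_that("phase-to-displacement is linear with slope lambda / 2 pi", {
  n <- c(4, 4, 4)
  g <- volume_grid(array(pi, n), c(1, 1, 1))
  u <- phase_to_displacement(g, lambda = 1)
  expect_equal(u$values, array(0.5, n))
  expect_equal(phase_to_displacement(
    volume_grid(array(2 * pi, n), c(1, 1, 1)), lambda = 1)$values,
    array(1.0, n))
  expect_equal(phase_to_displacement(
    volume_grid(array(0, n), c(1, 1, 1)), lambda = 1)$values, array(0, n))
  # homogeneity: u(alpha * phi) = alpha * u(phi)
  phi <- array(rnorm(prod(n)), n)
  u1 <- phase_to_displacement(volume_grid(3 * phi, c(1, 1, 1)), lambda = 2)
  u2 <- phase_to_displacement(volume_grid(phi, c(1, 1, 1)), lambda = 2)
  expect_equal(u1$values, 3 * u2$values, tolerance = 1e-12)
})

test_that("displacement assembly stacks components and respects sigma 0", {
  n <- c(6, 5, 4)
  mk <- function(v) volume_grid(array(v, n), c(0.33, 1.5, 2))
  zero <- assemble_displacement_field(list(mk(0), mk(0), mk(0)),
                                      array(TRUE, n), sigma_vox = c(1, 1, 1))
  expect_equal(max(abs(zero$grid$values)), 0)
  set.seed(10)
  comps <- lapply(1:3, function(i) mk(rnorm(prod(n))))
  df <- assemble_displacement_field(comps, array(TRUE, n),
                                    sigma_vox = c(0, 0, 0))
  for (i in 1:3) expect_equal(df$grid$values[, , , i], comps[[i]]$values)
  bad <- volume_grid(array(0, n + 1L), c(0.33, 1.5, 2))
  expect_error(assemble_displacement_field(list(comps[[1]], comps[[2]], bad),
                                           array(TRUE, n)), "mismatched grids")
})

test_that("the noiseless phantom round trip is the identity to lambda/100", {
  sp <- small_phantom_spec(compression = 0.5, noise_snr = Inf)
  ds <- generate_phantom(sp, truth_highres = FALSE)
  mask_d <- dilate_mask(ds$mask_lowres, 3L)
  disp <- recover_displacement(ds$encoded, mask_d, ds$ref_region_lowres$values,
                               sigma_complex = c(0, 0, 0),
                               sigma_displacement = c(0, 0, 0))
  er <- erode_mask(ds$mask_lowres$values, 1L)
  diffs <- disp$grid$values - ds$truth_displacement_lowres$values
  rms <- sqrt(mean(diffs[rep(er, 3)]^2))
  expect_lt(rms, 0.01)   # lambda / 100 at lambda = 1 mm
  # the U1 minimum sits at the indentation centre column
  u1 <- disp$grid$values[, , , 1]
  ijk <- arrayInd(which.min(u1), dim(u1))
  world <- grid_index_to_world(disp$grid, ijk)
  expect_lt(max(abs(world[1, 2:3])), max(sp$low_res_spacing[2:3]))
})
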