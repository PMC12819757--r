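#' Specification of the synthetic indentation phantom
#'
#' Defines a synthetic patellar-cartilage dataset: a flat cartilage slab of
#' thickness `cartilage_thickness` bonded to rigid subchondral bone (interface
#' plane at world `x1 = 0`, articular surface at `x1 = t`), indented at the
#' slab centre by a spherical indenter. The through-thickness displacement is
#' a smooth Gaussian bump scaled linearly through the thickness, with a
#' radial bulge; the closed form has exact derivatives so the Green-Lagrange
#' strain is known analytically everywhere. A circular osteochondral graft
#' (donor plug) of radius `graft_radius` is centred on the indentation axis,
#' its bone-cartilage boundary tilted so the rim step-off follows
#' `s(theta) = stepoff_mean + stepoff_amplitude * cos(theta)` with
#' `theta = 0` at the distal rim (smaller axis-2 coordinate); distal rim
#' elevated, proximal rim recessed for positive `stepoff_amplitude`.
#'
#' Displacement-encoded acquisitions are simulated on the low-resolution
#' grid by evaluating the complex signal `m * exp(2i*pi*u_d/lambda)` on a
#' supersampled lattice and block-averaging the complex values (intravoxel
#' dephasing), then adding independent complex Gaussian noise with standard
#' deviation `mean tissue magnitude / noise_snr` per component.
#'
#' @param cartilage_thickness cartilage thickness t, mm.
#' @param slab_extent lateral slab extents (axes 2, 3), mm.
#' @param indenter_radius spherical indenter radius R, mm (25.4 mm diameter).
#' @param compression effective surface compression delta, mm (0.25 or 0.50).
#' @param bulge_coefficient dimensionless radial bulge amplitude beta.
#' @param contact_width Gaussian contact half-width rho, mm; default the
#'   Hertz-like contact radius `sqrt(R * delta)`.
#' @param graft_radius donor plug radius, mm.
#' @param stepoff_mean,stepoff_amplitude mean s0 and amplitude s1 of the rim
#'   step-off profile, mm.
#' @param noise_snr magnitude signal-to-noise ratio; `Inf` for noiseless.
#' @param lambda displacement-encoding wavelength, mm.
#' @param low_res_shape,low_res_spacing displacement-encoded grid (voxels, mm).
#' @param high_res_shape,high_res_spacing anatomical grid (voxels, mm).
#' @param bone_depth modelled subchondral bone depth below the interface, mm.
#' @param supersample per-axis supersampling factors used when synthesizing
#'   the low-resolution complex signal.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   datasets.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(cartilage_thickness = 3.9,
                         slab_extent = c(46, 46),
                         indenter_radius = 12.7,
                         compression = 0.5,
                         bulge_coefficient = 0.3,
                         contact_width = NULL,
                         graft_radius = 9.5,
                         stepoff_mean = 0.0,
                         stepoff_amplitude = 0.5,
                         noise_snr = 30,
                         lambda = 1.0,
                         low_res_shape = c(96L, 32L, 24L),
                         low_res_spacing = c(0.33, 1.5, 2.0),
                         high_res_shape = c(196L, 128L, 128L),
                         high_res_spacing = c(0.17, 0.38, 0.38),
                         bone_depth = 6,
                         supersample = c(2L, 4L, 4L),
                         seed = 1L) {
  if (is.null(contact_width)) {
    # Hertz-like contact radius; an uncompressed phantom (delta = 0) has no
    # contact scale, so fall back to the 0.25 mm-compression width
    contact_width <- sqrt(indenter_radius * max(compression, 0.25))
  }
  spec <- structure(list(
    cartilage_thickness = cartilage_thickness,
    slab_extent = as.numeric(slab_extent),
    indenter_radius = indenter_radius,
    compression = compression,
    bulge_coefficient = bulge_coefficient,
    contact_width = contact_width,
    graft_radius = graft_radius,
    stepoff_mean = stepoff_mean,
    stepoff_amplitude = stepoff_amplitude,
    noise_snr = noise_snr,
    lambda = lambda,
    low_res_shape = as.integer(low_res_shape),
    low_res_spacing = as.numeric(low_res_spacing),
    high_res_shape = as.integer(high_res_shape),
    high_res_spacing = as.numeric(high_res_spacing),
    bone_depth = bone_depth,
    supersample = as.integer(supersample),
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  lens <- c(cartilage_thickness = spec$cartilage_thickness,
            indenter_radius = spec$indenter_radius,
            contact_width = spec$contact_width,
            graft_radius = spec$graft_radius,
            lambda = spec$lambda,
            bone_depth = spec$bone_depth,
            spec$slab_extent, spec$low_res_spacing, spec$high_res_spacing)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("phantom_spec: all lengths must be finite and > 0")
  if (spec$compression < 0 || spec$compression >= spec$cartilage_thickness)
    stop("phantom_spec: compression (", spec$compression,
         " mm) must be >= 0 and below the cartilage thickness (",
         spec$cartilage_thickness, " mm)")
  if (spec$graft_radius >= min(spec$slab_extent) / 2)
    stop("phantom_spec: graft_radius (", spec$graft_radius,
         " mm) must be smaller than the lateral half-extent (",
         min(spec$slab_extent) / 2, " mm)")
  if (abs(spec$stepoff_mean) + abs(spec$stepoff_amplitude) >=
        spec$cartilage_thickness)
    stop("phantom_spec: |stepoff_mean| + |stepoff_amplitude| must be below ",
         "the cartilage thickness")
  if (spec$noise_snr <= 0) stop("phantom_spec: noise_snr must be > 0")
  if (any(spec$low_res_shape < 2L) || any(spec$high_res_shape < 2L))
    stop("phantom_spec: grids need at least 2 voxels per axis")
  if (any(spec$supersample < 1L))
    stop("phantom_spec: supersample factors must be >= 1")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  cat(sprintf("  cartilage t = %.3g mm, compression = %.3g mm, bulge = %.3g\n",
              x$cartilage_thickness, x$compression, x$bulge_coefficient))
  cat(sprintf("  contact width rho = %.3g mm, indenter R = %.3g mm\n",
              x$contact_width, x$indenter_radius))
  cat(sprintf("  graft r = %.3g mm, step-off s0 = %.3g mm, s1 = %.3g mm\n",
              x$graft_radius, x$stepoff_mean, x$stepoff_amplitude))
  cat(sprintf("  lambda = %.3g mm, SNR = %.3g, seed = %d\n",
              x$lambda, x$noise_snr, x$seed))
  cat("  low-res grid:  ", paste(x$low_res_shape, collapse = "x"), " @ ",
      paste(x$low_res_spacing, collapse = " x "), " mm\n", sep = "")
  cat("  high-res grid: ", paste(x$high_res_shape, collapse = "x"), " @ ",
      paste(x$high_res_spacing, collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

# World geometry conventions: interface plane x1 = 0 (cartilage occupies
# [0, t], bone [-bone_depth, 0)); axes 2 and 3 centred so a voxel centre
# falls exactly on the indentation axis (x2 = x3 = 0).
phantom_grid_origin <- function(shape, spacing, x1_min = NULL) {
  o23 <- -spacing[2:3] * floor(shape[2:3] / 2)
  if (is.null(x1_min)) x1_min <- -8
  c(x1_min + spacing[1] / 2, o23)
}

phantom_highres_geometry <- function(spec) {
  list(shape = spec$high_res_shape, spacing = spec$high_res_spacing,
       origin = phantom_grid_origin(spec$high_res_shape, spec$high_res_spacing))
}

phantom_lowres_geometry <- function(spec) {
  list(shape = spec$low_res_shape, spacing = spec$low_res_spacing,
       origin = phantom_grid_origin(spec$low_res_shape, spec$low_res_spacing))
}

check_inside_slab <- function(spec, x) {
  he <- spec$slab_extent / 2
  tol <- 1e-9
  for (k in 2:3) {
    bad <- abs(x[, k]) > he[k - 1] + tol
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("position outside slab: x%d = %.4g mm exceeds half-extent %.4g mm",
                   k, x[i, k], he[k - 1]))
    }
  }
  bad <- x[, 1] > spec$cartilage_thickness + tol |
    x[, 1] < -spec$bone_depth - tol
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("position outside slab: x1 = %.4g mm not in [%.4g, %.4g] mm",
                 x[i, 1], -spec$bone_depth, spec$cartilage_thickness))
  }
  invisible(TRUE)
}

#' Closed-form phantom displacement field
#'
#' Smooth separable indentation bump: with `r` the in-plane distance from the
#' indentation axis, `g = exp(-r^2 / (2 rho^2))` and `f = max(x1, 0) / t`,
#' the displacement is `u1 = -delta * g * f` (through-thickness) and
#' `u_radial = beta * delta * (r / rho) * g * f` directed outward, i.e.
#' `u2 = (beta delta / rho) g f x2`, `u3 = (beta delta / rho) g f x3`.
#' The field vanishes identically at and below the bone interface (`x1 <= 0`)
#' and satisfies `|u| <= delta * (1 + beta)`.
#'
#' @param spec a [phantom_spec()].
#' @param x world positions, n x 3 matrix or length-3 vector (mm). Positions
#'   outside the slab raise an error naming the offending coordinate.
#' @return n x 3 matrix of displacements (mm), columns (u1, u2, u3).
#' @export
analytic_displacement <- function(spec, x) {
  x <- rbind_to_matrix(x)
  check_inside_slab(spec, x)
  d <- spec$compression; t <- spec$cartilage_thickness
  rho <- spec$contact_width; beta <- spec$bulge_coefficient
  r2 <- x[, 2]^2 + x[, 3]^2
  g <- exp(-r2 / (2 * rho^2))
  f <- pmax(x[, 1], 0) / t
  cbind(u1 = -d * g * f,
        u2 = (beta * d / rho) * g * f * x[, 2],
        u3 = (beta * d / rho) * g * f * x[, 3])
}

# Closed-form displacement gradient H[i, j] = d u_i / d x_j, returned as an
# n x 3 x 3 array. Zero for x1 <= 0 (rigid bone side).
analytic_displacement_gradient <- function(spec, x) {
  x <- rbind_to_matrix(x)
  check_inside_slab(spec, x)
  d <- spec$compression; t <- spec$cartilage_thickness
  rho <- spec$contact_width; beta <- spec$bulge_coefficient
  x1 <- x[, 1]; x2 <- x[, 2]; x3 <- x[, 3]
  inside <- x1 > 0
  g <- exp(-(x2^2 + x3^2) / (2 * rho^2))
  f <- pmax(x1, 0) / t
  cc <- beta * d / rho
  H <- array(0, c(nrow(x), 3, 3))
  H[, 1, 1] <- -d * g / t
  H[, 1, 2] <- d * f * g * x2 / rho^2
  H[, 1, 3] <- d * f * g * x3 / rho^2
  H[, 2, 1] <- cc * g * x2 / t
  H[, 2, 2] <- cc * f * g * (1 - x2^2 / rho^2)
  H[, 2, 3] <- -cc * f * g * x2 * x3 / rho^2
  H[, 3, 1] <- cc * g * x3 / t
  H[, 3, 2] <- -cc * f * g * x2 * x3 / rho^2
  H[, 3, 3] <- cc * f * g * (1 - x3^2 / rho^2)
  H[!inside, , ] <- 0
  H
}

#' Closed-form phantom Green-Lagrange strain
#'
#' Evaluates `E = (H + t(H) + t(H) %*% H) / 2` from the exact displacement
#' gradient of [analytic_displacement()].
#'
#' @inheritParams analytic_displacement
#' @return n x 3 x 3 array of symmetric strain tensors.
#' @export
analytic_strain <- function(spec, x) {
  H <- analytic_displacement_gradient(spec, x)
  green_lagrange_from_gradient(H)
}

# E = (H + H^T + H^T H)/2, vectorized over the first array dimension.
green_lagrange_from_gradient <- function(H) {
  n <- dim(H)[1]
  E <- array(0, c(n, 3, 3))
  for (i in 1:3) for (j in 1:3) {
    hthij <- H[, 1, i] * H[, 1, j] + H[, 2, i] * H[, 2, j] + H[, 3, i] * H[, 3, j]
    E[, i, j] <- (H[, i, j] + H[, j, i] + hthij) / 2
  }
  E
}

# Symmetric tensor array (n x 3 x 3) -> n x 6 matrix (11,22,33,12,13,23).
tensor_to_sym6 <- function(E) {
  cbind(E11 = E[, 1, 1], E22 = E[, 2, 2], E33 = E[, 3, 3],
        E12 = E[, 1, 2], E13 = E[, 1, 3], E23 = E[, 2, 3])
}

sym6_to_tensor <- function(S) {
  n <- nrow(S)
  E <- array(0, c(n, 3, 3))
  E[, 1, 1] <- S[, 1]; E[, 2, 2] <- S[, 2]; E[, 3, 3] <- S[, 3]
  E[, 1, 2] <- E[, 2, 1] <- S[, 4]
  E[, 1, 3] <- E[, 3, 1] <- S[, 5]
  E[, 2, 3] <- E[, 3, 2] <- S[, 6]
  E
}

# Donor-plug bone boundary height s(x) inside the graft: a linear tilt whose
# rim trace is s0 + s1*cos(theta), theta = 0 at the distal rim (x2 < 0).
stepoff_height <- function(spec, x2, x3) {
  spec$stepoff_mean - spec$stepoff_amplitude * x2 / spec$graft_radius
}

# Vectorized tissue classification at world points. Labels: 0 background,
# 1 recipient cartilage, 2 recipient bone, 3 donor cartilage, 4 donor bone.
phantom_classify <- function(spec, x1, x2, x3) {
  he <- spec$slab_extent / 2
  t <- spec$cartilage_thickness
  lab <- integer(length(x1))
  in_slab <- abs(x2) <= he[1] & abs(x3) <= he[2] &
    x1 >= -spec$bone_depth & x1 <= t
  in_graft <- in_slab & (x2^2 + x3^2 <= spec$graft_radius^2)
  s <- stepoff_height(spec, x2, x3)
  lab[in_slab & !in_graft & x1 >= 0] <- 1L
  lab[in_slab & !in_graft & x1 < 0] <- 2L
  lab[in_graft & x1 >= s] <- 3L
  lab[in_graft & x1 < s] <- 4L
  lab
}

phantom_magnitude_for_label <- function(lab) {
  c(0.05, 1.0, 0.6, 0.85, 0.6)[lab + 1L]
}

#' Generate a synthetic indentation dataset
#'
#' Builds the full phantom: high-resolution label and magnitude volumes,
#' optional ground-truth displacement and strain volumes, and the three
#' displacement-encoded complex acquisitions on the low-resolution grid.
#' All randomness (magnitude Rician-style noise, complex acquisition noise)
#' is driven by `spec$seed`; the same spec yields bit-identical datasets.
#'
#' @param spec a [phantom_spec()].
#' @param truth_highres if `TRUE` (default) include `truth_displacement` and
#'   `truth_strain` volumes on the high-resolution grid (memory-heavy for the
#'   full-size grid; disable when only labels/encodings are needed).
#' @return An object of class `phantom_dataset` with elements:
#'   `labels` (high-res integer label [volume_grid()]), `magnitude`
#'   (high-res), `truth_displacement` (4-D, component-last, mm),
#'   `truth_strain` (4-D, 6 components 11,22,33,12,13,23), `encoded`
#'   (list of three [complex_volume()]s, directions 1-3),
#'   `mask_lowres` / `ref_region_lowres` (logical low-res grids: cartilage
#'   mask and zero-displacement bone reference), `truth_displacement_lowres`
#'   (block-averaged analytic displacement on the low-res grid), and `spec`.
#' @export
generate_phantom <- function(spec, truth_highres = TRUE) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)

  hg <- phantom_highres_geometry(spec)
  hx <- lapply(1:3, function(k) hg$origin[k] + (seq_len(hg$shape[k]) - 1) * hg$spacing[k])
  n_h <- prod(hg$shape)
  X1 <- array(rep(hx[[1]], times = prod(hg$shape[2:3])), hg$shape)
  X2 <- array(rep(rep(hx[[2]], each = hg$shape[1]), times = hg$shape[3]), hg$shape)
  X3 <- array(rep(hx[[3]], each = prod(hg$shape[1:2])), hg$shape)

  lab <- phantom_classify(spec, as.vector(X1), as.vector(X2), as.vector(X3))
  labels <- volume_grid(array(lab, hg$shape), hg$spacing, hg$origin)

  mag_clean <- phantom_magnitude_for_label(lab)
  mean_tissue <- mean(mag_clean[lab > 0L])
  if (is.finite(spec$noise_snr)) {
    sd_n <- mean_tissue / spec$noise_snr
    mag <- sqrt((mag_clean + rnorm(n_h, 0, sd_n))^2 + rnorm(n_h, 0, sd_n)^2)
  } else mag <- mag_clean
  magnitude <- volume_grid(array(mag, hg$shape), hg$spacing, hg$origin)

  truth_displacement <- truth_strain <- NULL
  if (truth_highres) {
    cart <- lab == 1L | lab == 3L
    U <- matrix(0, n_h, 3)
    Ssym <- matrix(0, n_h, 6)
    if (any(cart)) {
      pts <- cbind(as.vector(X1)[cart], as.vector(X2)[cart], as.vector(X3)[cart])
      U[cart, ] <- analytic_displacement(spec, pts)
      Ssym[cart, ] <- tensor_to_sym6(analytic_strain(spec, pts))
    }
    truth_displacement <- volume_grid(array(U, c(hg$shape, 3L)),
                                      hg$spacing, hg$origin)
    truth_strain <- volume_grid(array(Ssym, c(hg$shape, 6L)),
                                hg$spacing, hg$origin)
  }

  enc <- phantom_encoded_volumes(spec)

  structure(list(labels = labels, magnitude = magnitude,
                 truth_displacement = truth_displacement,
                 truth_strain = truth_strain,
                 encoded = enc$encoded,
                 mask_lowres = enc$mask_lowres,
                 ref_region_lowres = enc$ref_region_lowres,
                 truth_displacement_lowres = enc$truth_displacement_lowres,
                 spec = spec), class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat("<phantom_dataset>\n")
  print(x$spec)
  cat("  high-res labels: ", paste(grid_shape(x$labels), collapse = "x"),
      "; encoded directions: ", length(x$encoded), "\n", sep = "")
  invisible(x)
}

# Synthesize the three encoded low-res complex volumes plus the low-res
# cartilage mask, bone reference region and block-averaged truth displacement.
phantom_encoded_volumes <- function(spec) {
  lg <- phantom_lowres_geometry(spec)
  fs <- spec$supersample
  sub_shape <- lg$shape * fs
  sub_spacing <- lg$spacing / fs
  sub_origin <- lg$origin - lg$spacing / 2 + sub_spacing / 2

  sx <- lapply(1:3, function(k) sub_origin[k] + (seq_len(sub_shape[k]) - 1) * sub_spacing[k])
  X1 <- array(rep(sx[[1]], times = prod(sub_shape[2:3])), sub_shape)
  X2 <- array(rep(rep(sx[[2]], each = sub_shape[1]), times = sub_shape[3]), sub_shape)
  X3 <- array(rep(sx[[3]], each = prod(sub_shape[1:2])), sub_shape)

  lab <- phantom_classify(spec, as.vector(X1), as.vector(X2), as.vector(X3))
  mag <- phantom_magnitude_for_label(lab)
  mean_tissue <- mean(mag[lab > 0L])

  cart <- lab == 1L | lab == 3L
  U <- matrix(0, length(lab), 3)
  if (any(cart)) {
    pts <- cbind(as.vector(X1)[cart], as.vector(X2)[cart], as.vector(X3)[cart])
    U[cart, ] <- analytic_displacement(spec, pts)
  }

  block_mean <- function(v) {
    a <- array(v, c(fs[1], lg$shape[1], fs[2], lg$shape[2], fs[3], lg$shape[3]))
    a <- aperm(a, c(1, 3, 5, 2, 4, 6))
    dim(a) <- c(prod(fs), prod(lg$shape))
    array(colMeans(a), lg$shape)
  }

  encoded <- vector("list", 3L)
  for (d in 1:3) {
    phase <- 2 * pi * U[, d] / spec$lambda
    sig <- block_mean(mag * exp(1i * phase))
    if (is.finite(spec$noise_snr)) {
      sd_n <- mean_tissue / spec$noise_snr
      sig <- sig + array(complex(real = rnorm(length(sig), 0, sd_n),
                                 imaginary = rnorm(length(sig), 0, sd_n)),
                         dim(sig))
    }
    encoded[[d]] <- complex_volume(
      volume_grid(sig, lg$spacing, lg$origin), d, spec$lambda)
  }

  cart_frac <- block_mean(as.numeric(cart))
  bone_frac <- block_mean(as.numeric(lab == 2L | lab == 4L))
  mask_lowres <- volume_grid(array(cart_frac > 0.5, lg$shape),
                             lg$spacing, lg$origin)
  # zero-displacement reference: predominantly-bone voxels just below the
  # interface (within two low-res voxels of x1 = 0)
  lx1 <- lg$origin[1] + (seq_len(lg$shape[1]) - 1) * lg$spacing[1]
  near_if <- array(rep(lx1 > -2 * lg$spacing[1] & lx1 < 0,
                       times = prod(lg$shape[2:3])), lg$shape)
  ref_region <- volume_grid(array(bone_frac > 0.99, lg$shape) & near_if,
                            lg$spacing, lg$origin)

  truth_lr <- array(0, c(lg$shape, 3L))
  for (d in 1:3) truth_lr[, , , d] <- block_mean(U[, d] * cart) /
    pmax(cart_frac, .Machine$double.eps)
  truth_lr[!is.finite(truth_lr)] <- 0
  truth_displacement_lowres <- volume_grid(truth_lr, lg$spacing, lg$origin)

  list(encoded = encoded, mask_lowres = mask_lowres,
       ref_region_lowres = ref_region,
       truth_displacement_lowres = truth_displacement_lowres)
}

#' Compression as a percentage of cartilage thickness
#'
#' @param compression effective surface displacement, mm.
#' @param thickness cartilage thickness, mm.
#' @return Compression percentage (e.g. 6.4 for 0.25 mm over 3.9 mm).
#' @export
compression_percent <- function(compression, thickness) {
  if (thickness <= 0) stop("thickness must be > 0")
  100 * compression / thickness
}
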