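#' @useDynLib cartistrain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile median coef lm qnorm rnorm runif
#' @importFrom utils write.csv read.csv
NULL

# 1-D Gaussian kernel, truncated at 4 sigma (matches the usual image-filter
# convention); sigma in voxels. sigma = 0 -> identity kernel.
gauss_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Shift a 3-D array by `by` voxels along `axis`, zero-filling.
shift_array <- function(a, axis, by) {
  if (by == 0) return(a)
  d <- dim(a)
  out <- array(if (is.complex(a)) 0 + 0i else 0, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  idx_src <- idx_dst <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out <- do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(a), idx_src)))))
  out
}

# Separable 3-D Gaussian filter with zero padding, per-axis sigma in voxels.
# Constant fields are *not* preserved near the border under zero padding;
# callers that need that use gauss_smooth_3d_normalized().
gauss_smooth_3d <- function(a, sigma_vox) {
  stopifnot(length(sigma_vox) == 3L)
  if (any(sigma_vox < 0)) stop("Gaussian sigma must be >= 0, got: ",
                               paste(sigma_vox, collapse = ", "))
  out <- a
  for (axis in 1:3) {
    k <- gauss_kernel_1d(sigma_vox[axis])
    if (length(k) == 1L) next
    r <- (length(k) - 1L) / 2L
    acc <- array(if (is.complex(out)) 0 + 0i else 0, dim(out))
    for (j in seq_along(k))
      acc <- acc + k[j] * shift_array(out, axis, j - 1L - r)
    out <- acc
  }
  out
}

# Gaussian filter renormalized by the smoothed all-ones volume so that
# constants are preserved exactly everywhere, including the border.
gauss_smooth_3d_normalized <- function(a, sigma_vox) {
  num <- gauss_smooth_3d(a, sigma_vox)
  den <- gauss_smooth_3d(array(1, dim(a)), sigma_vox)
  num / den
}

# Masked Gaussian smoothing: smooth(field * mask) / smooth(mask), so values
# outside the mask never bleed in. Voxels where smooth(mask) ~ 0 return 0.
gauss_smooth_masked <- function(a, mask, sigma_vox, eps = 1e-12) {
  m <- array(as.numeric(mask), dim(a))
  num <- gauss_smooth_3d(a * m, sigma_vox)
  den <- gauss_smooth_3d(m, sigma_vox)
  out <- array(0, dim(a))
  ok <- den > eps
  out[ok] <- num[ok] / den[ok]
  out
}

# Trilinear interpolation of a 3-D array at fractional 1-based voxel indices
# (n x 3 matrix). Queries outside [1, dim] are an error unless clamp = TRUE.
trilinear_at <- function(a, idx, clamp = FALSE) {
  d <- dim(a)
  if (clamp) {
    for (k in 1:3) idx[, k] <- pmin(pmax(idx[, k], 1), d[k])
  } else {
    bad <- idx[, 1] < 1 - 1e-9 | idx[, 1] > d[1] + 1e-9 |
           idx[, 2] < 1 - 1e-9 | idx[, 2] > d[2] + 1e-9 |
           idx[, 3] < 1 - 1e-9 | idx[, 3] > d[3] + 1e-9
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf(
        "query point %d at fractional index (%.3f, %.3f, %.3f) lies outside the source grid %s",
        i, idx[i, 1], idx[i, 2], idx[i, 3], paste(d, collapse = "x")))
    }
    for (k in 1:3) idx[, k] <- pmin(pmax(idx[, k], 1), d[k])
  }
  i0 <- pmin(floor(idx), matrix(rep(d - 1L, each = nrow(idx)), ncol = 3))
  i0 <- pmax(i0, 1)
  f <- idx - i0
  g <- function(di, dj, dk) {
    a[cbind(i0[, 1] + di, i0[, 2] + dj, i0[, 3] + dk)]
  }
  w <- function(fi, di) if (di == 1) fi else 1 - fi
  out <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    out <- out + w(f[, 1], di) * w(f[, 2], dj) * w(f[, 3], dk) * g(di, dj, dk)
  }
  out
}

# Nearest-voxel fill: replace values outside `mask` by the value of the
# nearest masked voxel (Euclidean distance in mm). Used to extend masked
# fields before interpolation so that queries near the mask border do not mix
# in meaningless background values. Iterative 6-neighbour dilation fill.
nearest_fill <- function(a, mask, spacing, max_iter = NULL) {
  d <- dim(a)
  filled <- mask
  out <- a
  out[!mask] <- 0
  if (is.null(max_iter)) max_iter <- sum(d)
  it <- 0L
  while (!all(filled) && it < max_iter) {
    it <- it + 1L
    num <- array(0, d); den <- array(0, d)
    fm <- array(as.numeric(filled), d)
    for (axis in 1:3) for (s in c(-1L, 1L)) {
      num <- num + shift_array(out * fm, axis, s)
      den <- den + shift_array(fm, axis, s)
    }
    new <- !filled & den > 0
    if (!any(new)) break
    out[new] <- num[new] / den[new]
    filled <- filled | new
  }
  out
}

# Percentile with linear interpolation between order statistics (quantile
# type 7, the common convention) or nearest-rank (type 1).
percentile_value <- function(x, p, method = c("linear", "nearest")) {
  method <- match.arg(method)
  stats::quantile(x, probs = p / 100, type = if (method == "linear") 7 else 1,
                  names = FALSE, na.rm = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
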