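#' Column-wise percentile projection (top view)
#'
#' Reduces each through-thickness column of masked voxels to a single
#' percentile value (default the 95th), producing a 2-D map over the plane
#' of the remaining two axes. Columns with no masked voxels are missing
#' (`NA`), never zero. Percentiles use linear interpolation between order
#' statistics by default; `method = "nearest"` selects nearest-rank.
#'
#' @param field scalar [volume_grid()] (e.g. an `E_min` magnitude volume).
#' @param mask logical array / [volume_grid()] congruent with `field`.
#' @param axis reduction axis (default 1, through-thickness).
#' @param p percentile in [0, 100].
#' @param method `"linear"` (interpolated order statistics) or `"nearest"`.
#' @return An object of class `projection_map`: `values` (2-D matrix, `NA`
#'   for empty columns), `coords` (world mm along the two kept axes),
#'   `axes` (kept axis ids), `p`.
#' @export
percentile_projection <- function(field, mask, axis = 1L, p = 95,
                                  method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(field, "volume_grid"), axis %in% 1:3,
            p >= 0, p <= 100)
  m <- as_mask_array(mask, field)
  keep <- setdiff(1:3, axis)
  a <- aperm(field$values, c(axis, keep))
  mm <- aperm(m, c(axis, keep))
  d <- dim(a)
  a <- matrix(a, d[1], d[2] * d[3])
  mm <- matrix(mm, d[1], d[2] * d[3])
  vals <- vapply(seq_len(ncol(a)), function(j) {
    x <- a[mm[, j], j]
    if (!length(x)) NA_real_ else percentile_value(x, p, method)
  }, numeric(1))
  structure(list(values = matrix(vals, d[2], d[3]),
                 coords = list(grid_axis_coords(field, keep[1]),
                               grid_axis_coords(field, keep[2])),
                 axes = keep, p = p),
            class = "projection_map")
}

#' @export
print.projection_map <- function(x, ...) {
  cat("<projection_map> ", paste(dim(x$values), collapse = " x "),
      " over axes (", paste(x$axes, collapse = ", "), "), p = ", x$p, "\n",
      sep = "")
  cat("  missing columns: ", sum(is.na(x$values)), "\n", sep = "")
  invisible(x)
}

#' Tidy a projection map into a tibble
#' @param x a `projection_map`.
#' @param ... unused.
#' @return Tibble with world coordinates of the two kept axes and `value`.
#' @export
tidy.projection_map <- function(x, ...) {
  nm <- paste0("x", x$axes)
  out <- tibble::tibble(
    a = rep(x$coords[[1]], times = length(x$coords[[2]])),
    b = rep(x$coords[[2]], each = length(x$coords[[1]])),
    value = as.vector(x$values))
  names(out)[1:2] <- nm
  out
}

#' @rdname tidy.projection_map
#' @param object a `projection_map`.
#' @method autoplot projection_map
#' @export
autoplot.projection_map <- function(object, ...) {
  df <- tidy.projection_map(object)
  nm <- names(df)[1:2]
  ggplot2::ggplot(df[!is.na(df$value), ],
                  ggplot2::aes(.data[[nm[1]]], .data[[nm[2]]],
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0("axis ", object$axes[1], " (mm)"),
                  y = paste0("axis ", object$axes[2], " (mm)"),
                  fill = sprintf("p%g", object$p)) +
    ggplot2::theme_minimal()
}

# generics re-exported so tidy()/autoplot() work without attaching ggplot2
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy <- function(x, ...) UseMethod("tidy")

donor_labels <- c(3L, 4L)
recipient_labels <- c(1L, 2L)
bone_labels <- c(2L, 4L)

#' Locate the donor-recipient interface in one slice
#'
#' Within the 1-2 plane slice at index `slice_index` (axis 3), finds the
#' first and last axis-2 columns containing donor tissue. The crossing at
#' the larger axis-2 coordinate is the proximal one. A slice without donor
#' tissue returns `NULL` (skip signal); a slice tangent to the rim returns
#' proximal and distal crossings in the same column.
#'
#' @param labels integer label [volume_grid()] (0 background, 1 recipient
#'   cartilage, 2 recipient bone, 3 donor cartilage, 4 donor bone).
#' @param slice_index 1-based index along axis 3.
#' @return `NULL`, or a list of two crossing records (side `"distal"`,
#'   `"proximal"`), each with `slice_index`, `col_donor`, `col_recipient`,
#'   `outward` (axis-2 step toward the recipient) and world coordinates.
#' @export
find_interface <- function(labels, slice_index) {
  stopifnot(inherits(labels, "volume_grid"))
  d <- grid_shape(labels)
  stopifnot(slice_index >= 1, slice_index <= d[3])
  sl <- labels$values[, , slice_index]
  donor_cols <- which(apply(sl, 2, function(col) any(col %in% donor_labels)))
  if (!length(donor_cols)) return(NULL)
  jmin <- min(donor_cols); jmax <- max(donor_cols)
  x2 <- grid_axis_coords(labels, 2)
  x3 <- grid_axis_coords(labels, 3)
  crossing <- function(side, j_donor, outward) {
    j_rec <- j_donor + outward
    if (j_rec < 1 || j_rec > d[2])
      stop("interface column ", j_donor, " touches the volume border; ",
           "no recipient column on the ", side, " side")
    list(side = side, slice_index = slice_index,
         col_donor = j_donor, col_recipient = j_rec, outward = outward,
         x2_donor = x2[j_donor], x2_recipient = x2[j_rec],
         x3 = x3[slice_index])
  }
  list(distal = crossing("distal", jmin, -1L),
       proximal = crossing("proximal", jmax, +1L))
}

# topmost bone voxel (largest axis-1 index, scanning from the articular side
# downward) in the (j, slice) column; error when the column holds no bone
bone_start_index <- function(labels, j, slice_index) {
  col <- labels$values[, j, slice_index]
  idx <- which(col %in% bone_labels)
  if (!length(idx))
    stop("no subchondral bone found in column (axis2 = ", j,
         ", slice = ", slice_index, ")")
  max(idx)
}

#' Step-off distance at an interface crossing
#'
#' In the recipient column adjacent to the interface and the donor column on
#' the other side, the start of the subchondral bone is the first
#' bone-labelled voxel scanning from the articular surface downward. The
#' step-off is the difference of those start depths in mm: positive when the
#' donor bone sits nearer the articular surface (elevated), negative when it
#' is recessed. Values are quantized to the axis-1 voxel size.
#'
#' @param labels label [volume_grid()] (see [find_interface()]).
#' @param crossing one crossing record from [find_interface()].
#' @return Signed step-off in mm.
#' @export
measure_stepoff <- function(labels, crossing) {
  i_rec <- bone_start_index(labels, crossing$col_recipient, crossing$slice_index)
  i_don <- bone_start_index(labels, crossing$col_donor, crossing$slice_index)
  (i_don - i_rec) * labels$spacing[1]
}

# mid-thickness axis-1 index of the recipient cartilage in a column;
# falls back to the donor column when the recipient column has no cartilage
mid_thickness_index <- function(labels, crossing) {
  for (j in c(crossing$col_recipient, crossing$col_donor)) {
    col <- labels$values[, j, crossing$slice_index]
    idx <- which(col %in% c(1L, 3L))
    if (length(idx)) return(as.integer(round(mean(range(idx)))))
  }
  stop("no cartilage in the interface columns of slice ", crossing$slice_index)
}

#' Matched strain sample on both sides of the graft interface
#'
#' Means of the outcome magnitude over a 3x3x3-voxel neighbourhood centred
#' `offset_mm` outside the interface (recipient side) and `offset_mm` inside
#' (donor side), at matched mid-thickness depth.
#'
#' @param field scalar outcome [volume_grid()] on the label grid (e.g.
#'   `E_min` or `E_maxshear`).
#' @param labels label [volume_grid()].
#' @param crossing a crossing record from [find_interface()].
#' @param offset_mm lateral query offset; must be at least one in-plane
#'   (axis 2) voxel.
#' @return Named numeric: `recipient`, `donor`.
#' @export
sample_strain_pair <- function(field, labels, crossing, offset_mm = NULL) {
  stopifnot(inherits(field, "volume_grid"))
  if (!grid_same_geometry(field, labels))
    stop_geometry_mismatch(field, labels, "outcome field and labels")
  sp2 <- field$spacing[2]
  if (is.null(offset_mm)) offset_mm <- 2 * sp2
  if (offset_mm < sp2 - 1e-9)
    stop("offset_mm = ", offset_mm, " mm is below one in-plane voxel (",
         sp2, " mm)")
  off_vox <- as.integer(round(offset_mm / sp2))
  i_mid <- mid_thickness_index(labels, crossing)
  d <- grid_shape(field)
  nb_mean <- function(j_centre, allowed) {
    ii <- pmin(pmax(i_mid + (-1:1), 1L), d[1])
    jj <- pmin(pmax(j_centre + (-1:1), 1L), d[2])
    kk <- pmin(pmax(crossing$slice_index + (-1:1), 1L), d[3])
    # a clean sample lies entirely on its own side of the interface;
    # neighbourhoods straddling tissues (e.g. near tangent slices) are
    # undefined rather than contaminated
    if (!all(labels$values[ii, jj, kk] %in% allowed)) return(NA_real_)
    mean(abs(field$values[ii, jj, kk]))
  }
  c(recipient = nb_mean(crossing$col_donor + crossing$outward * off_vox,
                        recipient_labels),
    donor = nb_mean(crossing$col_donor - crossing$outward * off_vox,
                    donor_labels))
}

#' Percent change in strain from recipient to donor
#'
#' `100 * (donor - recipient) / recipient`. Undefined (returns `NA`) when
#' the recipient magnitude is below `epsilon`. Note the formula is not
#' antisymmetric: `percent_change(r, d) != -percent_change(d, r)` in general.
#'
#' @param strain_recipient,strain_donor strain magnitudes (vectorized).
#' @param epsilon denominators below this are undefined.
#' @return Percent change(s); `NA` where undefined.
#' @export
percent_change <- function(strain_recipient, strain_donor, epsilon = 1e-6) {
  out <- 100 * (strain_donor - strain_recipient) / strain_recipient
  out[is.na(strain_recipient) | abs(strain_recipient) <= epsilon] <- NA_real_
  out
}

#' Step-off table around the graft rim
#'
#' For every 1-2 plane slice intersecting the donor plug: the proximal and
#' distal interface crossings, signed step-off, matched recipient/donor
#' samples of the two strain outcomes and their percent changes.
#'
#' @param labels label [volume_grid()].
#' @param e_min,e_maxshear scalar outcome [volume_grid()]s on the label grid
#'   (magnitudes are taken internally); `NULL` outcomes give `NA` columns.
#' @param offset_mm lateral strain query offset (default two axis-2 voxels).
#' @param epsilon percent-change denominator floor.
#' @return Tibble with columns `slice_index`, `side`, `stepoff_mm`,
#'   `E_min_recipient`, `E_min_donor`, `pct_change_Emin`,
#'   `E_maxshear_recipient`, `E_maxshear_donor`, `pct_change_Emaxshear`.
#' @export
stepoff_table <- function(labels, e_min = NULL, e_maxshear = NULL,
                          offset_mm = NULL, epsilon = 1e-6) {
  d <- grid_shape(labels)
  rows <- list()
  for (k in seq_len(d[3])) {
    cr <- find_interface(labels, k)
    if (is.null(cr)) next
    for (side in c("distal", "proximal")) {
      x <- cr[[side]]
      so <- measure_stepoff(labels, x)
      samp <- function(f) {
        if (is.null(f)) return(c(recipient = NA_real_, donor = NA_real_))
        sample_strain_pair(f, labels, x, offset_mm)
      }
      se <- samp(e_min); ss <- samp(e_maxshear)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        slice_index = k, side = side, stepoff_mm = so,
        E_min_recipient = se[["recipient"]], E_min_donor = se[["donor"]],
        pct_change_Emin = percent_change(se[["recipient"]], se[["donor"]],
                                         epsilon),
        E_maxshear_recipient = ss[["recipient"]],
        E_maxshear_donor = ss[["donor"]],
        pct_change_Emaxshear = percent_change(ss[["recipient"]],
                                              ss[["donor"]], epsilon))
    }
  }
  if (!length(rows))
    return(tibble::tibble(
      slice_index = integer(), side = character(), stepoff_mm = numeric(),
      E_min_recipient = numeric(), E_min_donor = numeric(),
      pct_change_Emin = numeric(), E_maxshear_recipient = numeric(),
      E_maxshear_donor = numeric(), pct_change_Emaxshear = numeric()))
  dplyr::bind_rows(rows)
}

#' Descriptive linear fits of percent strain change against step-off
#'
#' Ordinary least-squares fits (one per outcome) with step-off distance as
#' the independent variable, plus a scatter plot with proximal and distal
#' arcs as separate series. Purely descriptive: no inference is attached.
#' Outcomes with fewer than two finite points get `NA` fit coefficients
#' (the scatter is still drawn).
#'
#' @param table a [stepoff_table()] tibble.
#' @return List with `fits` (tibble: `outcome`, `slope`, `intercept`,
#'   `n_points`) and `plot` (ggplot).
#' @export
stepoff_scatter <- function(table) {
  fit_one <- function(ycol, label) {
    ok <- is.finite(table$stepoff_mm) & is.finite(table[[ycol]])
    n <- sum(ok)
    if (n < 2L || length(unique(table$stepoff_mm[ok])) < 2L)
      return(tibble::tibble(outcome = label, slope = NA_real_,
                            intercept = NA_real_, n_points = n))
    f <- stats::lm(table[[ycol]][ok] ~ table$stepoff_mm[ok])
    tibble::tibble(outcome = label, slope = unname(coef(f)[2]),
                   intercept = unname(coef(f)[1]), n_points = n)
  }
  fits <- dplyr::bind_rows(fit_one("pct_change_Emin", "E_min"),
                           fit_one("pct_change_Emaxshear", "E_maxshear"))
  long <- dplyr::bind_rows(
    tibble::tibble(stepoff_mm = table$stepoff_mm, side = table$side,
                   outcome = "E_min", pct_change = table$pct_change_Emin),
    tibble::tibble(stepoff_mm = table$stepoff_mm, side = table$side,
                   outcome = "E_maxshear",
                   pct_change = table$pct_change_Emaxshear))
  plt <- ggplot2::ggplot(long[is.finite(long$pct_change), ],
                         ggplot2::aes(.data$stepoff_mm, .data$pct_change,
                                      colour = .data$side)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                         formula = y ~ x, se = FALSE, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = "step-off distance (mm)",
                  y = "% change in strain (recipient to donor)") +
    ggplot2::theme_minimal()
  list(fits = fits, plot = plt)
}
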