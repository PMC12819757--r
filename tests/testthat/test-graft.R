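make_scalar_grid <- function(vals, spacing = c(0.17, 0.38, 0.38)) {
  volume_grid(vals, spacing)
}

test_that("column percentiles interpolate order statistics and flag empty columns", {
  a <- array(0, c(5, 2, 2))
  a[, 1, 1] <- c(0.0, 0.1, 0.2, 0.3, 0.4)
  a[, 2, 1] <- 7
  m <- array(TRUE, dim(a))
  m[, 1, 2] <- FALSE          # fully unmasked column
  pm <- percentile_projection(make_scalar_grid(a), m, p = 95)
  expect_equal(pm$values[1, 1], 0.38)      # between 4th and 5th order stats
  expect_equal(pm$values[2, 1], 7)         # constant column is that constant
  expect_true(is.na(pm$values[1, 2]))      # missing, not zero
  # nearest-rank alternative
  pm1 <- percentile_projection(make_scalar_grid(a), m, p = 95,
                               method = "nearest")
  expect_equal(pm1$values[1, 1], 0.4)
  # monotone in p and permutation-invariant within columns
  p50 <- percentile_projection(make_scalar_grid(a), m, p = 50)
  expect_true(all(p50$values <= pm$values, na.rm = TRUE))
  aperm_col <- a; aperm_col[, 1, 1] <- rev(a[, 1, 1])
  pmp <- percentile_projection(make_scalar_grid(aperm_col), m, p = 95)
  expect_equal(pmp$values[1, 1], pm$values[1, 1])
})

test_that("projection maps tidy into tibbles and plot", {
  a <- array(runif(4 * 3 * 2), c(4, 3, 2))
  pm <- percentile_projection(make_scalar_grid(a), array(TRUE, dim(a)))
  td <- tidy(pm)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("x2", "x3", "value"))
  expect_equal(nrow(td), 6)
  expect_s3_class(autoplot(pm), "ggplot")
})

test_that("interface finding returns proximal/distal crossings and skip signals", {
  labels <- toy_stepoff_labels()
  cr <- find_interface(labels, 5L)
  expect_named(cr, c("distal", "proximal"))
  expect_lt(cr$distal$x2_donor, cr$proximal$x2_donor)
  # centred graft: crossings symmetric about the centre within one voxel
  jc <- 11L
  expect_lte(abs((jc - cr$distal$col_donor) - (cr$proximal$col_donor - jc)), 1)
  expect_null(find_interface(labels, 1L))   # slice outside the graft
})

test_that("a slice tangent to the rim collapses to a single donor column", {
  labels <- toy_stepoff_labels()
  # find the last slice that still intersects the donor cylinder
  ks <- which(vapply(seq_len(dim(labels$values)[3]),
                     function(k) !is.null(find_interface(labels, k)),
                     logical(1)))
  cr <- find_interface(labels, max(ks))
  width <- cr$proximal$col_donor - cr$distal$col_donor
  expect_lte(width, 2L)
})

test_that("step-off is exactly equivariant in the boundary shift", {
  for (shift in c(-3L, -1L, 0L, 2L)) {
    labels <- toy_stepoff_labels(shift_vox = shift)
    cr <- find_interface(labels, 5L)
    expect_equal(measure_stepoff(labels, cr$distal), shift * 0.17,
                 tolerance = 1e-12)
    expect_equal(measure_stepoff(labels, cr$proximal), shift * 0.17,
                 tolerance = 1e-12)
  }
  # recessed by 3 voxels: -0.51 mm
  labels <- toy_stepoff_labels(shift_vox = -3L)
  cr <- find_interface(labels, 5L)
  expect_equal(measure_stepoff(labels, cr$distal), -0.51)
  # column with no bone at all errors with the column named
  nob <- toy_stepoff_labels()
  nob$values[nob$values == 2L] <- 0L
  crn <- find_interface(nob, 5L)
  expect_error(measure_stepoff(nob, crn$distal), "no subchondral bone")
})

test_that("matched strain sampling recovers constructed donor/recipient contrast", {
  labels <- toy_stepoff_labels()
  f <- labels$values * 0
  f[labels$values %in% c(1L, 2L)] <- 0.10      # recipient side magnitude
  f[labels$values %in% c(3L, 4L)] <- 0.13      # donor scaled x1.3
  fld <- grid_with_values(labels, array(f, dim(f)))
  cr <- find_interface(labels, 5L)
  for (side in c("distal", "proximal")) {
    pair <- sample_strain_pair(fld, labels, cr[[side]], offset_mm = 0.76)
    pc <- percent_change(pair[["recipient"]], pair[["donor"]])
    expect_gt(pc, 20); expect_lt(pc, 40)       # +30% up to sampling tolerance
  }
  # uniform field: identical samples, zero percent change
  uni <- grid_with_values(labels, array(0.2, dim(f)))
  pair <- sample_strain_pair(uni, labels, cr$distal, offset_mm = 0.76)
  expect_equal(unname(pair[["recipient"]]), unname(pair[["donor"]]))
  expect_equal(percent_change(pair[["recipient"]], pair[["donor"]]), 0)
  expect_error(sample_strain_pair(fld, labels, cr$distal, offset_mm = 0.1),
               "below one in-plane voxel")
})

test_that("percent change follows the recipient-normalized formula", {
  expect_equal(percent_change(0.10, 0.13), 30, tolerance = 1e-12)
  expect_equal(percent_change(0.10, 0.10), 0)
  expect_equal(percent_change(0.10, 0.08), -20, tolerance = 1e-12)
  expect_true(is.na(percent_change(1e-9, 0.1)))
  # not antisymmetric in general
  expect_false(isTRUE(all.equal(percent_change(0.10, 0.13),
                                -percent_change(0.13, 0.10))))
})

test_that("step-off scatter fits are descriptive least squares", {
  tab <- tibble::tibble(
    slice_index = 1:3, side = c("distal", "proximal", "distal"),
    stepoff_mm = c(0, 1, 2),
    E_min_recipient = 0.1, E_min_donor = 0.1,
    pct_change_Emin = c(0, 2, 4),
    E_maxshear_recipient = 0.1, E_maxshear_donor = 0.1,
    pct_change_Emaxshear = c(1, 1, 1))
  sc <- stepoff_scatter(tab)
  f <- sc$fits
  expect_equal(f$slope[f$outcome == "E_min"], 2, tolerance = 1e-12)
  expect_equal(f$intercept[f$outcome == "E_min"], 0, tolerance = 1e-12)
  expect_s3_class(sc$plot, "ggplot")
  # residuals of an intercept fit sum to zero
  fit <- stats::lm(pct_change_Emin ~ stepoff_mm, data = tab)
  expect_lt(abs(sum(stats::residuals(fit))), 1e-9)
  # single point: fit refused, scatter still produced
  sc1 <- stepoff_scatter(tab[1, ])
  expect_true(all(is.na(sc1$fits$slope)))
  expect_s3_class(sc1$plot, "ggplot")
})

test_that("the phantom step-off profile is recovered around the rim", {
  sp <- small_phantom_spec(stepoff_mean = 0, stepoff_amplitude = 0.5)
  ds <- generate_phantom(sp, truth_highres = FALSE)
  labels <- ds$labels
  n_cross <- 0L
  for (k in seq_len(dim(labels$values)[3])) {
    cr <- find_interface(labels, k)
    if (is.null(cr)) next
    for (side in c("distal", "proximal")) {
      x <- cr[[side]]
      measured <- measure_stepoff(labels, x)
      # the donor plug is tilted linearly: truth at the queried column
      s_true <- sp$stepoff_mean -
        sp$stepoff_amplitude * x$x2_donor / sp$graft_radius
      expect_lt(abs(measured - s_true), labels$spacing[1] + 1e-9)
      # arc directionality where the truth exceeds the one-voxel quantum
      if (s_true > labels$spacing[1]) expect_gt(measured, 0)
      if (s_true < -labels$spacing[1]) expect_lt(measured, 0)
      n_cross <- n_cross + 1L
    }
  }
  expect_gt(n_cross, 10)
})
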