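test_that("measure_cells averages normalized GFP over eroded labels", {
  g <- normalized_green(40, 40, fill = 0)
  g[10:25, 10:25] <- 0.5
  m <- matrix(0L, 40, 40)
  m[10:25, 10:25] <- 1L
  field <- field_image(list(red = matrix(0, 40, 40), green = g),
                       px_per_um = 4)
  cells <- measure_cells(field, label_mask(m),
                         quant_config(erosion_radius_px = 3))
  expect_equal(cells$mean_norm_gfp, 0.5)
  expect_true(cells$valid)
  expect_lt(cells$eroded_area_px, cells$area_px)

  # arithmetic mean over a 2x2 remnant
  g2 <- normalized_green(8, 8)
  g2[3:4, 3:4] <- c(0.1, 0.2, 0.3, 0.4)
  m2 <- matrix(0L, 8, 8)
  m2[3:4, 3:4] <- 1L
  f2 <- field_image(list(red = matrix(0, 8, 8), green = g2), 4)
  cells2 <- measure_cells(f2, label_mask(m2),
                          quant_config(erosion_radius_px = 0))
  expect_equal(cells2$mean_norm_gfp, 0.25)
})

test_that("measure_cells refuses unnormalized green input", {
  sf <- generate_field(tiny_mosaic_spec())
  mask <- sf$truth$label_mask
  expect_error(measure_cells(sf$field, mask), "not normalized")
})

test_that("per-cell means equal a brute-force loop oracle", {
  set.seed(13)
  m <- random_disk_mask(48, 48, 5, 6, 13)
  g <- matrix(runif(48 * 48), 48, 48)
  g[1] <- 0; g[48 * 48] <- 1
  attr(g, "normalized") <- TRUE
  field <- field_image(list(red = matrix(0, 48, 48), green = g), 4)
  r <- 2
  cells <- measure_cells(field, label_mask(m),
                         quant_config(erosion_radius_px = r))
  eroded <- brute_erode_labels(m, r)
  for (i in seq_len(nrow(cells))) {
    lab <- cells$cell_id[i]
    px <- which(eroded == lab)
    if (length(px) == 0) {
      expect_false(cells$valid[i])
    } else {
      vals <- numeric(0)
      for (p in px) vals <- c(vals, g[p])
      expect_equal(cells$mean_norm_gfp[i], mean(vals))
      expect_identical(cells$eroded_area_px[i], length(px))
    }
  }
})

test_that("cells eroded to nothing are invalid and excluded", {
  g <- normalized_green(20, 20, fill = 0.9)
  m <- matrix(0L, 20, 20)
  m[5, 5] <- 1L                 # vanishes under erosion
  m[10:18, 10:18] <- 2L         # survives
  field <- field_image(list(red = matrix(0, 20, 20), green = g), 4)
  cells <- measure_cells(field, label_mask(m),
                         quant_config(erosion_radius_px = 2))
  expect_identical(cells$valid, c(FALSE, TRUE))
  expect_true(is.na(cells$mean_norm_gfp[1]))
  cls <- classify_double_positive(cells, fixed_threshold(0.5))
  expect_identical(cls$n_valid, 1L)
  expect_equal(cls$fraction, 1)
})

test_that("calibrate_threshold implements the nearest-rank quantile", {
  vals <- (1:100) / 100
  cal <- calibrate_threshold(vals, alpha = 0.05)
  expect_equal(cal$threshold, 0.95)
  expect_equal(cal$observed_exceedance, 0.05)
  expect_identical(cal$source, "calibrated")

  cal2 <- calibrate_threshold(rep(0.3, 25), alpha = 0.05)
  expect_equal(cal2$threshold, 0.3)
  expect_equal(cal2$observed_exceedance, 0)

  # sort-and-count oracle on seeded uniforms
  set.seed(99)
  v <- runif(1000)
  cal3 <- calibrate_threshold(v, alpha = 0.05)
  expect_equal(cal3$threshold, sort(v)[950])
  expect_lte(cal3$observed_exceedance, 0.05)

  expect_error(calibrate_threshold(runif(10)), ">= 20")
  expect_error(calibrate_threshold(c(rep(0.5, 24), 1.2)), "\\[0, 1\\]")
})

test_that("classification respects strictness and matches hand counts", {
  cells <- structure(data.frame(
    field_id = "f", cell_id = 1:8, marker = "L", area_px = 10L,
    eroded_area_px = 5L, centroid_row = 1, centroid_col = 1,
    mean_norm_gfp = c(0, 0.1, 0.195, 0.21, 0.5, 0.9, 0.15, 0.12),
    valid = TRUE), class = c("cell_measurements", "data.frame"))
  cal <- fixed_threshold(0.195, "L")
  cls <- classify_double_positive(cells, cal, strict_greater = TRUE)
  expect_identical(cls$n_positive, 3L)       # hand count: 0.21, 0.5, 0.9
  expect_equal(cls$fraction, 0.375)
  expect_false(unname(cls$positive["3"]))    # tie goes negative
  cls2 <- classify_double_positive(cells, cal, strict_greater = FALSE)
  expect_identical(cls2$n_positive, 4L)      # tie now positive
  expect_error(classify_double_positive(cells[0, ], cal), "no cells")
})

test_that("classification is monotone in the threshold", {
  set.seed(21)
  cells <- structure(data.frame(
    field_id = "f", cell_id = 1:50, marker = "L", area_px = 10L,
    eroded_area_px = 5L, centroid_row = 1, centroid_col = 1,
    mean_norm_gfp = runif(50), valid = TRUE),
    class = c("cell_measurements", "data.frame"))
  fracs <- vapply(seq(0, 1, by = 0.05), function(t)
    classify_double_positive(cells, fixed_threshold(t))$fraction,
    numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("calibration is self-consistent on its own control set", {
  set.seed(31)
  for (alpha in c(0.05, 0.1)) {
    v <- round(runif(200), 3)  # ties included
    cal <- calibrate_threshold(v, alpha = alpha)
    expect_lte(mean(v > cal$threshold), alpha)
    smaller <- max(v[v < cal$threshold])
    expect_gt(mean(v > smaller), alpha)
  }
})

test_that("count_gfp_only applies the overlap-exclusion rule", {
  green <- matrix(0L, 30, 30)
  green[2:6, 2:6] <- 1L          # no red overlap -> counted
  green[10:14, 10:14] <- 2L      # fully inside red -> excluded
  green[20:24, 20:29] <- 3L      # 40% overlap -> counted at 0.5
  red <- matrix(0L, 30, 30)
  red[9:15, 9:15] <- 1L
  red[20:24, 26:29] <- 2L        # 20 of 50 green px
  gm <- label_mask(green); rm <- label_mask(red)
  n <- count_gfp_only(gm, rm, overlap_fraction = 0.5)
  expect_identical(as.integer(n), 2L)
  per <- attr(n, "per_label")
  # explicit pixel-intersection oracle
  for (i in seq_len(nrow(per))) {
    px <- which(green == per$label[i])
    ov <- 0
    for (p in px) if (red[p] > 0) ov <- ov + 1
    expect_equal(per$overlap[i], ov / length(px))
  }
  expect_identical(as.integer(count_gfp_only(gm,
    label_mask(matrix(0L, 30, 30)))), 3L)
  expect_error(count_gfp_only(gm, label_mask(matrix(0L, 5, 5))),
               "different shapes")
})

test_that("summarize_field converts counts to densities and keeps NA", {
  cells <- structure(data.frame(
    field_id = "f", cell_id = 1:100, marker = "L", area_px = 10L,
    eroded_area_px = 5L, centroid_row = 1, centroid_col = 1,
    mean_norm_gfp = 0.1, valid = TRUE),
    class = c("cell_measurements", "data.frame"))
  qc <- quant_config(field_area_um2 = 64 * 64)
  s <- summarize_field(cells, classify_double_positive(cells,
                                                       fixed_threshold(0.5)),
                       qc, field_id = "f", group = "wt")
  expect_equal(s$count_per_field, 100)
  expect_equal(s$density_per_mm2, 24414.0625)
  expect_equal(s$double_positive_fraction, 0)
  empty <- summarize_field(conemosaiq:::empty_measurements(), NULL, qc)
  expect_equal(empty$density_per_mm2, 0)
  expect_true(is.na(empty$double_positive_fraction))
})

test_that("classification is invariant to raw green rescaling", {
  sf <- generate_field(tiny_mosaic_spec(psf_sigma_px = 1, noise_sd = 5,
                                        seed = 17L))
  raw_green <- sf$field$channels$green
  mask <- sf$truth$label_mask
  qc <- quant_config(erosion_radius_px = 2)
  base <- NULL
  for (a in c(1, 0.1, 3, 100)) {
    f <- sf$field
    f$channels$green <- normalize_channel(a * raw_green)
    cells <- measure_cells(f, mask, qc)
    cls <- classify_double_positive(cells, fixed_threshold(0.3))
    if (is.null(base)) base <- cls$positive
    expect_identical(cls$positive, base)
  }
})

test_that("erosion reduces blur-induced misclassification of red cells", {
  # a red-only cell (radius 20 px at 16 px/um) ringed by four bright
  # green-only neighbours with a 1 px gap, psf sigma 10 px: blur bleeds
  # green across the whole border, pushing the uneroded mean above the
  # 0.195 threshold while the eroded core stays below it
  n <- 220
  red <- matrix(0, n, n); green <- matrix(0, n, n)
  mask <- matrix(0L, n, n)
  d <- 20 + 32 + 1
  red <- test_disk(red, 110, 110, 20, 2000)
  green <- test_disk(green, 110, 110, 20, 100)  # baseline only
  for (off in list(c(d, 0), c(-d, 0), c(0, d), c(0, -d)))
    green <- test_disk(green, 110 + off[1], 110 + off[2], 32, 2000)
  mask <- test_disk(mask, 110, 110, 20, 1L, add = FALSE)
  green <- gaussian_blur(green, 10) + 80
  field <- field_image(list(red = red,
                            green = normalize_channel(green)), 16)
  lm <- label_mask(mask, "red")
  errs <- vapply(c(0L, 10L), function(r) {
    cells <- measure_cells(field, lm, quant_config(erosion_radius_px = r))
    classify_double_positive(cells, fixed_threshold(0.195))$n_positive
  }, integer(1))
  expect_lt(errs[2], errs[1])  # erosion strictly reduces false positives
  expect_identical(errs, c(1L, 0L))
})

test_that("scale_erosion_radius maps the reference 10 px across resolutions", {
  expect_identical(scale_erosion_radius(10, 16), 10L)
  expect_identical(scale_erosion_radius(10, 4), 2L)
  expect_identical(scale_erosion_radius(10, 1), 1L)  # floored at 1
  expect_identical(scale_erosion_radius(0, 4), 0L)
})
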