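test_that("empty mosaic yields a background-only field and empty truth", {
  sf <- generate_field(tiny_mosaic_spec(n_red_cells = 0L,
                                        n_green_only_cells = 0L))
  expect_true(all(sf$field$channels$red == 80))
  expect_true(all(sf$field$channels$green == 80))
  expect_identical(nrow(sf$truth$cell_table), 0L)
  expect_identical(max(sf$truth$label_mask$labels), 0L)
})

test_that("exact_counts forces exactly round(f * n_red) double positives", {
  sf <- generate_field(mosaic_spec(field_size_um = 64, px_per_um = 2,
                                   n_red_cells = 50L,
                                   n_green_only_cells = 0L,
                                   double_positive_fraction = 0.2,
                                   exact_counts = TRUE, seed = 3L))
  tab <- table(sf$truth$cell_table$class)
  expect_identical(unname(tab[["double_positive"]]), 10L)
  expect_identical(sum(sf$truth$cell_table$class != "green_only"), 50L)
})

test_that("noise-free rendering matches a brute-force disk rasterizer", {
  spec <- tiny_mosaic_spec(psf_sigma_px = 0, noise_sd = 0)
  sf <- generate_field(spec)
  ct <- sf$truth$cell_table
  npx <- 64
  exp_red <- matrix(0, npx, npx)
  exp_green <- matrix(0, npx, npx)
  for (i in seq_len(nrow(ct))) {
    cx <- ct$x_um[i] * spec$px_per_um + 0.5
    cy <- ct$y_um[i] * spec$px_per_um + 0.5
    r <- ct$radius_um[i] * spec$px_per_um
    if (ct$class[i] != "green_only")
      exp_red <- test_disk(exp_red, cx, cy, r, ct$red_intensity[i])
    exp_green <- test_disk(exp_green, cx, cy, r, ct$green_intensity[i])
  }
  expect_equal(sf$field$channels$red,
               matrix(as.integer(round(exp_red + 80)), npx, npx))
  expect_equal(sf$field$channels$green,
               matrix(as.integer(round(exp_green + 80)), npx, npx))
})

test_that("identical spec + seed gives bit-identical output", {
  a <- generate_field(tiny_mosaic_spec(noise_sd = 15, psf_sigma_px = 1))
  b <- generate_field(tiny_mosaic_spec(noise_sd = 15, psf_sigma_px = 1))
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth, b$truth)
})

test_that("ground truth conserves counts and classes partition cells", {
  for (seed in 1:5) {
    spec <- tiny_mosaic_spec(field_size_um = 24,
                             n_red_cells = 5L + seed,
                             n_green_only_cells = seed,
                             double_positive_fraction = 0.4,
                             seed = seed)
    sf <- generate_field(spec)
    ct <- sf$truth$cell_table
    n <- spec$n_red_cells + spec$n_green_only_cells
    expect_identical(nrow(ct), n)
    labs <- mask_labels(sf$truth$label_mask)
    expect_identical(labs, seq_len(n))
    expect_setequal(unique(ct$class),
                    intersect(c("red_only", "double_positive",
                                "green_only"), ct$class))
    expect_identical(sum(ct$class == "double_positive"),
                     as.integer(round(0.4 * spec$n_red_cells)))
  }
})

test_that("overcrowded specs fail with an explicit error", {
  expect_error(mosaic_spec(field_size_um = 10, px_per_um = 4,
                           n_red_cells = 200L, n_green_only_cells = 0L),
               "too crowded")
  # passes the coarse area check but not placeable: dense + unlucky margin
  expect_error(generate_field(mosaic_spec(field_size_um = 12,
                                          px_per_um = 4,
                                          n_red_cells = 11L,
                                          n_green_only_cells = 0L,
                                          cell_radius_um = 1.5,
                                          min_spacing_um = 4.4,
                                          seed = 1L)),
               "too crowded")
})

test_that("hex layout places the requested number of cells", {
  sf <- generate_field(tiny_mosaic_spec(layout = "hex",
                                        hex_jitter_um = 0.1))
  expect_identical(nrow(sf$truth$cell_table), 10L)
  expect_identical(length(mask_labels(sf$truth$label_mask)), 10L)
})

test_that("cohorts are deterministic and propagate field identity", {
  cs <- cohort_spec(list(control = list(n_fields = 2),
                         mutant = list(n_fields = 2,
                                       double_positive_fraction = 0.4)),
                    base = tiny_mosaic_spec(), base_seed = 11L)
  a <- generate_cohort(cs)
  b <- generate_cohort(cs)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$fields$mutant_2$field$channels,
                   b$fields$mutant_2$field$channels)
  expect_setequal(a$manifest$group, c("control", "mutant"))
  expect_identical(nrow(a$manifest), 4L)
  # per-field seeds all distinct
  expect_identical(anyDuplicated(a$manifest$seed), 0L)
  # error annotated with group and field
  bad <- cohort_spec(list(g1 = list(n_fields = 1, min_spacing_um = 4.4,
                                    field_size_um = 12,
                                    n_red_cells = 11L,
                                    n_green_only_cells = 0L)),
                     base = tiny_mosaic_spec(), base_seed = 1L)
  expect_error(generate_cohort(bad), "group 'g1', field 1")
})

test_that("null cohorts differ only by sampling noise", {
  cs <- cohort_spec(list(a = list(n_fields = 10), b = list(n_fields = 10)),
                    base = tiny_mosaic_spec(n_red_cells = 8L,
                                            double_positive_fraction = 0.3,
                                            exact_counts = FALSE),
                    base_seed = 5L)
  co <- generate_cohort(cs)
  pooled <- tapply(co$manifest$true_dp_count, co$manifest$group, sum) /
    tapply(co$manifest$n_red_cells, co$manifest$group, sum)
  n <- sum(co$manifest$n_red_cells) / 2
  se <- sqrt(2 * 0.3 * 0.7 / n)
  expect_lt(abs(pooled[["a"]] - pooled[["b"]]), 4 * se)
})

test_that("unknown cohort overrides are rejected", {
  expect_error(cohort_spec(list(g = list(n_fields = 1, typo_key = 2)),
                           base = tiny_mosaic_spec()),
               "unknown mosaic_spec override")
})

test_that("synthetic expression: exclusive genes are silent without contamination", {
  spec <- synth_expression_spec(n_genes = 80L, seed = 2L)
  se <- generate_expression(spec)
  em <- se$matrix
  rod_excl <- se$truth$gene[se$truth$subtype == "rod"]
  cone_samples <- names(em$subtype)[em$subtype != "rod"]
  expect_true(all(em$counts[rod_excl, cone_samples] == 0))
  # and with contamination the same genes light up in cones
  se2 <- generate_expression(synth_expression_spec(
    n_genes = 80L, contamination_fraction = 0.2, seed = 2L))
  expect_gt(sum(se2$matrix$counts[rod_excl, cone_samples]), 0)
})

test_that("synthetic expression is deterministic and respects the design", {
  spec <- synth_expression_spec(n_genes = 60L, seed = 9L)
  a <- generate_expression(spec)
  b <- generate_expression(spec)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(as.integer(table(a$matrix$subtype)[c("rod", "UV", "S",
                                                        "M", "L")]),
                   c(6L, 5L, 6L, 7L, 6L))
})

test_that("expression column sums track the library size", {
  spec <- synth_expression_spec(n_genes = 300L, library_size = 5e5,
                                seed = 4L)
  se <- generate_expression(spec)
  mu <- se$mean_profile
  mu_scaled <- sweep(mu, 2, colSums(mu), "/") * 5e5
  for (j in seq_len(ncol(se$matrix$counts))) {
    s <- se$matrix$subtype[j]
    sd_j <- sqrt(sum(mu_scaled[, s] + 0.2 * mu_scaled[, s]^2))
    expect_lt(abs(sum(se$matrix$counts[, j]) - 5e5), 3.5 * sd_j)
  }
})

test_that("overlapping enriched sets are a validation error", {
  sets <- default_enriched_sets()
  sets$UV$genes <- c(sets$UV$genes, "rho")
  expect_error(synth_expression_spec(enriched_sets = sets), "overlap")
})
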