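# Synthetic plates, fields and stacks with planted ground truth.

test_that("plate layout honours the screen design and its capacity bound", {
  lay <- build_plate_layout(114, 42, 3, seed = 1)
  expect_equal(nrow(lay), 384L)
  expect_equal(sum(lay$role == "control"), 42L)
  expect_equal(sum(lay$role == "gene"), 342L)
  expect_equal(length(unique(lay$gene_id[lay$role == "gene"])), 114L)
  expect_true(all(table(lay$gene_id[lay$role == "gene"]) == 3L))
  expect_false(anyDuplicated(lay$well) > 0)

  only_controls <- build_plate_layout(0, 42, 3, seed = 1)
  expect_equal(nrow(only_controls), 42L)
  expect_true(all(only_controls$role == "control"))

  expect_error(build_plate_layout(120, 42, 3), "18 wells over capacity")
})

test_that("layout placement is randomized but reproducible by seed", {
  a <- build_plate_layout(20, 12, 3, seed = 5)
  b <- build_plate_layout(20, 12, 3, seed = 5)
  c <- build_plate_layout(20, 12, 3, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$gene_id, c$gene_id))
})

test_that("generated fields record their ground truth exactly", {
  f <- generate_field(small_spec(positive_fraction = 0.85), seed = 7)
  expect_equal(nrow(f$truth$cells), 60L)
  expect_equal(f$truth$n_positive, sum(f$truth$cells$positive))
  # positives ~ Binomial(60, 0.85): stay within 5 sd of the mean
  expect_gt(f$truth$n_positive, 60 * 0.85 - 5 * sqrt(60 * 0.85 * 0.15))
  # every positive cell has 1-3 recorded puncta, negatives none
  per_cell <- table(factor(f$truth$puncta$cell,
                           levels = f$truth$cells$cell))
  expect_true(all(per_cell[f$truth$cells$positive] >= 1))
  expect_true(all(per_cell[f$truth$cells$positive] <= 3))
  expect_true(all(per_cell[!f$truth$cells$positive] == 0))
  # puncta lie within one cell radius of their cell centre
  d <- sqrt((f$truth$puncta$row -
               f$truth$cells$row[f$truth$puncta$cell])^2 +
              (f$truth$puncta$col -
                 f$truth$cells$col[f$truth$puncta$cell])^2)
  expect_true(all(d <= small_spec()$nucleus_radius_px + 1))
})

test_that("an empty field is blank and a lone punctum is the only signal", {
  f0 <- generate_field(clean_spec(n_cells = 0L), seed = 1)
  expect_true(all(f0$nuclei == 0))
  expect_true(all(f0$gfp == 0))
  expect_equal(nrow(f0$truth$cells), 0L)
  expect_equal(nrow(f0$truth$puncta), 0L)

  f1 <- generate_field(clean_spec(n_cells = 1L, positive_fraction = 1),
                       seed = 2)
  expect_equal(nrow(f1$truth$puncta) >= 1, TRUE)
  nz <- which(f1$gfp > 0, arr.ind = TRUE)
  d <- outer(seq_len(nrow(nz)), seq_len(nrow(f1$truth$puncta)),
             Vectorize(function(i, j)
               sqrt((nz[i, 1] - f1$truth$puncta$row[j])^2 +
                      (nz[i, 2] - f1$truth$puncta$col[j])^2)))
  # every nonzero GFP pixel belongs to some punctum footprint (+soft edge)
  expect_true(all(apply(d, 1, min) <=
                    max(f1$truth$puncta$diameter) / 2 + 1.5))
})

test_that("nuclei never overlap and field generation is deterministic", {
  f <- generate_field(small_spec(), seed = 3)
  ce <- f$truth$cells
  dd <- as.matrix(dist(ce[, c("row", "col")]))
  diag(dd) <- Inf
  expect_gte(min(dd), 2 * small_spec()$nucleus_radius_px)

  g <- generate_field(small_spec(), seed = 3)
  expect_identical(f$nuclei, g$nuclei)
  expect_identical(f$gfp, g$gfp)
  expect_identical(f$truth, g$truth)
  h <- generate_field(small_spec(), seed = 4)
  expect_false(identical(f$nuclei, h$nuclei))
})

test_that("positivity is monotone in positive_fraction at a fixed seed", {
  ns <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(p)
    generate_field(small_spec(positive_fraction = p), seed = 11)$truth$n_positive,
    numeric(1))
  expect_true(all(diff(ns) >= 0))
  # and cell placement is shared across fractions
  a <- generate_field(small_spec(positive_fraction = 0.1), seed = 11)
  b <- generate_field(small_spec(positive_fraction = 0.9), seed = 11)
  expect_identical(a$truth$cells[, c("row", "col")],
                   b$truth$cells[, c("row", "col")])
})

test_that("field specs reject impossible geometries and fractions", {
  expect_error(field_spec(positive_fraction = 1.2), "positive_fraction")
  expect_error(field_spec(n_cells = 400, image_shape = c(256L, 256L)),
               "too small")
  expect_error(field_spec(n_cells = -1))
})

test_that("dose/time model is linear, clipped and monotone", {
  m <- dose_time_model(slope_conc = 0.001, slope_time = 0.005,
                       baseline = 0.23)
  conc <- c(100, 200, 300, 400)
  f <- positive_fraction_at(m, conc, 24)
  # exact linearity in the unclipped regime
  expect_equal(diff(f), rep(0.001 * 100, 3))
  expect_equal(positive_fraction_at(m, 500, 24), 0.85)
  expect_equal(positive_fraction_at(m, 1e5, 24), 1)
  expect_equal(positive_fraction_at(dose_time_model(baseline = -2), 0, 0), 0)
  expect_true(all(diff(positive_fraction_at(m, seq(0, 2000, 100), 24)) >= 0))
})

test_that("screen simulation plants effects where the truth says", {
  lay <- build_plate_layout(12, 8, 3, seed = 2)
  eff <- effect_table(sprintf("g%03d", 1:3), fraction_effect = 0.25)
  sim <- generate_screen(lay, dose_time_model(), eff,
                         n_fields_per_well = 1L, seed = 2,
                         base_spec = clean_spec(n_cells = 10L))
  wt <- sim$well_truth
  supp <- wt$gene_id[!is.na(wt$gene_id) & wt$fraction_effect < 1]
  expect_equal(sort(unique(supp)), sprintf("g%03d", 1:3))
  p0 <- positive_fraction_at(dose_time_model(), 500, 24)
  expect_equal(unique(wt$true_positive_fraction[wt$role == "control"]), p0)
  expect_equal(unique(wt$true_positive_fraction[wt$gene_id %in% supp]),
               min(1, p0 * 0.25))

  expect_error(generate_screen(lay, dose_time_model(),
                               effect_table("not_on_plate", 0.5),
                               base_spec = clean_spec(n_cells = 10L)),
               "absent from the layout")
})

test_that("brain stacks plant the requested aggregates and record density", {
  st <- generate_brain_stack(25, seed = 5)
  tr <- st$truth
  expect_equal(nrow(tr$objects), 25L)
  expect_true(all(tr$objects$n_voxels >= 10 & tr$objects$n_voxels <= 1000))
  expect_equal(tr$n_in_rois, sum(tr$objects$roi > 0))
  expect_equal(tr$density, tr$n_in_rois / tr$roi_volume_um3)

  st0 <- generate_brain_stack(0, seed = 5, noise_sd = 0, background = 0)
  expect_true(all(st0$stack == 0))
  expect_equal(st0$truth$density, 0)

  expect_error(generate_brain_stack(5, punctum_voxels = c(100, 2000)),
               "\\[10, 1000\\]")
})
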