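# Formats, configuration and pipeline orchestration.

test_that("field TIFFs round-trip within 16-bit quantization", {
  f <- generate_field(small_spec(), seed = 41)
  path <- file.path(withr::local_tempdir(), "P1_A01_f01.tif")
  write_field_tiff(f, path)
  g <- read_field_tiff(path)
  expect_lt(max(abs(g$nuclei - f$nuclei)), 1.01)
  expect_lt(max(abs(g$gfp - f$gfp)), 1.01)
})

test_that("stacks carry voxel sizes in a sidecar and refuse to guess", {
  st <- generate_brain_stack(10, seed = 2)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "animal1.tif")
  write_stack_tiff(st, path)
  rt <- read_stack_tiff(path)
  expect_equal(rt$voxel_size_um, st$voxel_size_um)
  expect_lt(max(abs(rt$stack - st$stack)), 1.01)

  file.remove(paste0(path, ".yaml"))
  expect_error(read_stack_tiff(path), "never assumed")
})

test_that("run configurations round-trip losslessly through YAML", {
  cfg <- run_config(seed = 9, out_dir = "somewhere",
                    screen = list(alpha = 0.01, n_sim = 250L),
                    brain = list(min_vox = 12L))
  path <- file.path(withr::local_tempdir(), "config.yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back$seed, 9L)
  expect_equal(back$screen$alpha, 0.01)
  expect_equal(back$screen$n_sim, 250L)
  expect_equal(back$brain$min_vox, 12L)
  expect_equal(back$segmentation, cfg$segmentation)
})

small_sim_config <- function(seed, out_dir) {
  run_config(seed = seed, out_dir = out_dir,
             screen = list(n_sim = 300L, alpha = 0.01),
             simulate = list(n_genes = 10L, n_controls = 10L,
                             n_replicates = 3L, n_fields_per_well = 1L,
                             field = list(n_cells = 40L,
                                          nucleus_radius_px = 6,
                                          image_shape = c(160L, 160L))))
}

test_that("the screen pipeline writes its products and is deterministic", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  r1 <- run_screen_pipeline(small_sim_config(3, dir1))
  r2 <- run_screen_pipeline(small_sim_config(3, dir2))
  for (f in c("cells.tsv", "wells.tsv", "hits.tsv", "thresholds.json",
              "qc_report.md"))
    expect_true(file.exists(file.path(dir1, f)))
  expect_identical(readLines(file.path(dir1, "hits.tsv")),
                   readLines(file.path(dir2, "hits.tsv")))
  expect_identical(readLines(file.path(dir1, "cells.tsv")),
                   readLines(file.path(dir2, "cells.tsv")))
  expect_identical(readLines(file.path(dir1, "thresholds.json")),
                   readLines(file.path(dir2, "thresholds.json")))

  dir3 <- withr::local_tempdir()
  r3 <- run_screen_pipeline(small_sim_config(4, dir3))
  expect_false(identical(readLines(file.path(dir1, "cells.tsv")),
                         readLines(file.path(dir3, "cells.tsv"))))
})

test_that("the screen pipeline consumes image directories with plate maps", {
  img_dir <- withr::local_tempdir()
  lay <- build_plate_layout(4, 8, 3, seed = 6)
  generate_screen(lay, dose_time_model(), effect_table(),
                  n_fields_per_well = 1L, seed = 6,
                  base_spec = small_spec(n_cells = 40L,
                                         image_shape = c(160L, 160L)),
                  dir = img_dir)
  out_dir <- withr::local_tempdir()
  cfg <- run_config(seed = 6, out_dir = out_dir,
                    screen = list(n_sim = 200L),
                    paths = list(images = img_dir,
                                 plate_map = file.path(img_dir,
                                                       "plate_map.csv")))
  run <- run_screen_pipeline(cfg)
  expect_equal(sort(unique(run$cells$well)), sort(lay$well))
  expect_true(file.exists(file.path(out_dir, "hits.tsv")))
})

test_that("unreadable images are skipped with a warning, runs continue", {
  img_dir <- withr::local_tempdir()
  lay <- build_plate_layout(4, 8, 3, seed = 8)
  generate_screen(lay, dose_time_model(), effect_table(),
                  n_fields_per_well = 1L, seed = 8,
                  base_spec = small_spec(n_cells = 40L,
                                         image_shape = c(160L, 160L)),
                  dir = img_dir)
  writeLines("not a tiff", file.path(img_dir, "P1_Z99_f01.tif"))
  cfg <- run_config(seed = 8, out_dir = withr::local_tempdir(),
                    screen = list(n_sim = 200L),
                    paths = list(images = img_dir,
                                 plate_map = file.path(img_dir,
                                                       "plate_map.csv")))
  expect_warning(run <- run_screen_pipeline(cfg), "unreadable")
  expect_gte(run$n_warnings, 1L)
  expect_equal(sort(unique(run$cells$well)), sort(lay$well))
})

test_that("an empty image directory is a clean error", {
  cfg <- run_config(out_dir = withr::local_tempdir(),
                    paths = list(images = withr::local_tempdir(),
                                 plate_map = "missing.csv"))
  expect_error(run_screen_pipeline(cfg), "no TIFF fields")
})

test_that("the brain pipeline runs from simulation and from disk", {
  out1 <- withr::local_tempdir()
  cfg <- run_config(seed = 2, out_dir = out1,
                    brain = list(control_group = "control"),
                    simulate = list(groups = list(control = 40,
                                                  suppressor = 13),
                                    n_per_group = 5L))
  run <- run_brain_pipeline(cfg)
  expect_true(file.exists(file.path(out1, "density.tsv")))
  expect_true(file.exists(file.path(out1, "stats.tsv")))
  ctrl <- run$records$normalized[run$records$group == "control"]
  expect_equal(mean(ctrl), 1)
  expect_lt(mean(run$records$normalized[run$records$group == "suppressor"]),
            0.7)
  expect_true(any(run$comparison$comparisons$method == "t_test"))

  # from disk
  stack_dir <- withr::local_tempdir()
  rows <- list()
  for (i in 1:2) {
    st <- generate_brain_stack(30, seed = 50 + i)
    write_stack_tiff(st, file.path(stack_dir, sprintf("an%d.tif", i)))
    rows[[i]] <- data.frame(animal_id = sprintf("an%d", i),
                            group = "control",
                            file = sprintf("an%d.tif", i))
  }
  groups_csv <- file.path(stack_dir, "groups.csv")
  write.csv(do.call(rbind, rows), groups_csv, row.names = FALSE)
  out2 <- withr::local_tempdir()
  cfg2 <- run_config(seed = 2, out_dir = out2,
                     brain = list(control_group = "control"),
                     paths = list(stacks = stack_dir, groups = groups_csv))
  run2 <- run_brain_pipeline(cfg2)
  expect_equal(nrow(run2$records), 2L)
  expect_equal(mean(run2$records$normalized), 1)
})
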