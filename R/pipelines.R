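#' Extract per-cell features from one field
#'
#' Runs the screen's per-field chain: illumination correction and contrast
#' stretch on the nuclei channel, global-threshold segmentation with the
#' size cutoff, centroid dilation into disjoint cell ROIs, local background
#' correction of the GFP channel, and per-ROI average/total intensities.
#'
#' @param field An `agg_field` (from [generate_field()] or
#'   [read_field_tiff()]).
#' @param seg_params A [segmentation_params()].
#' @param background_disk_px Disk radius for [subtract_local_background()].
#' @return Data frame with columns `plate`, `well`, `field`, `cell_id`,
#'   `area`, `avg_intensity`, `total_intensity`.
#' @export
analyze_field <- function(field, seg_params = segmentation_params(),
                          background_disk_px = 3) {
  pre <- preprocess_nuclei_image(field$nuclei)
  labels <- segment_nuclei(pre, seg_params)
  rois <- make_cell_rois(labels, field$gfp, seg_params)
  corrected <- subtract_local_background(field$gfp, background_disk_px)
  feats <- cell_intensity_features(rois, corrected)
  if (nrow(feats)) {
    feats <- cbind(data.frame(plate = field$plate %||% "P1",
                              well = field$well %||% NA_character_,
                              field = field$field %||% 1L),
                   feats)
  } else {
    feats <- data.frame(plate = character(0), well = character(0),
                        field = integer(0), cell_id = integer(0),
                        area = integer(0), avg_intensity = numeric(0),
                        total_intensity = numeric(0))
  }
  feats
}

#' Hit calling on a table of per-cell features
#'
#' For each intensity parameter, computes per-well signed KS statistics
#' against the pooled plate controls, robust plate Z-scores, the
#' Monte-Carlo calibrated |z| threshold for the two-of-three rule, and the
#' per-gene hit calls.
#'
#' @param cells Per-cell feature table (as emitted by [analyze_field()]).
#' @param platemap Plate map data frame (`well`, `role`, `gene_id`,
#'   `replicate`) for one plate.
#' @param parameters Per-cell value columns to analyze.
#' @param alpha Per-gene false-positive target of the threshold.
#' @param n_sim Monte-Carlo pseudo-genes.
#' @param min_hits Replicates required above threshold.
#' @param seed Integer seed (Monte-Carlo substream).
#' @return A list of class `screen_results`, one element per parameter, each
#'   with `well_stats`, `threshold`, `hits`.
#' @export
screen_hit_analysis <- function(cells, platemap,
                                parameters = c("avg_intensity",
                                               "total_intensity"),
                                alpha = 0.001, n_sim = 5000L,
                                min_hits = 2L, seed = 1L) {
  ctrl_wells <- platemap$well[platemap$role == "control"]
  res <- lapply(parameters, function(par) {
    ws <- well_ks_table(cells, platemap, par)
    ws <- zscore_plate(ws)
    ctrl_cells <- split(cells[[par]], cells$well)
    ctrl_cells <- ctrl_cells[intersect(ctrl_wells, names(ctrl_cells))]
    thr <- monte_carlo_threshold(ctrl_cells, n_sim = n_sim, alpha = alpha,
                                 seed = derive_seed(seed, paste0("mc_", par)))
    gene_z <- ws[ws$role == "gene" & !is.na(ws$ks), ]
    hits <- call_hits(gene_z, thr, min_hits = min_hits)
    list(parameter = par, well_stats = ws, threshold = thr, hits = hits)
  })
  names(res) <- parameters
  class(res) <- c("screen_results", "list")
  res
}

#' Genes called as hits in a screen analysis
#'
#' @param results A [screen_hit_analysis()] result.
#' @param parameter Parameter name, or `"any"` (union over parameters) /
#'   `"all"` (intersection, the two-parameter overlap set).
#' @return Character vector of gene identifiers.
#' @export
hit_genes <- function(results, parameter = "any") {
  sets <- lapply(results, function(r) r$hits$gene_id[r$hits$is_hit])
  if (parameter == "any") return(sort(unique(unlist(sets))))
  if (parameter == "all") return(sort(Reduce(intersect, sets)))
  sort(sets[[parameter]])
}

#' Run the screen pipeline end to end
#'
#' Consumes either a directory of field TIFFs plus a plate-map CSV
#' (`config$paths`), or a simulation block (`config$simulate`, a list with
#' `n_genes`, `n_controls`, `n_replicates`, `n_fields_per_well`,
#' `effects`, and field-spec overrides `field`), in which case the plate is
#' generated on the fly and fields are analyzed as they are produced, never
#' holding the whole plate in memory. Writes `cells.tsv`, `wells.tsv`,
#' `thresholds.json`, `hits.tsv` and `qc_report.md` under `config$out_dir`.
#'
#' @param config A [run_config()] (or path to its YAML).
#' @return A list of class `screen_pipeline_run`: `results`
#'   (per-parameter analyses), `cells`, `platemap`, `well_truth` (when
#'   simulated), `n_warnings`, `out_dir`.
#' @export
run_screen_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seg <- do.call(segmentation_params, config$segmentation)
  n_warn <- 0L

  cells_acc <- list()
  well_truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    layout <- build_plate_layout(sim$n_genes %||% 114L,
                                 sim$n_controls %||% 42L,
                                 sim$n_replicates %||% 3L,
                                 seed = config$seed)
    eff <- sim$effects %||% effect_table()
    if (!inherits(eff, "effect_table") && is.list(eff))
      eff <- do.call(effect_table, eff)
    spec <- do.call(field_spec, sim$field %||% list())
    dt <- if (is.null(sim$dose_time)) dose_time_model() else
      do.call(dose_time_model, sim$dose_time)
    collect <- function(fld, wrow, fno) {
      cells_acc[[length(cells_acc) + 1L]] <<-
        analyze_field(fld, seg, config$features$background_disk_px)
    }
    sim_out <- generate_screen(layout, dt, eff,
                               n_fields_per_well = sim$n_fields_per_well %||% 10L,
                               seed = config$seed,
                               conc_um = sim$conc_um %||% 500,
                               hours = sim$hours %||% 24,
                               base_spec = spec,
                               field_callback = collect)
    platemap <- layout
    well_truth <- sim_out$well_truth
  } else {
    if (is.null(config$paths$plate_map) || is.null(config$paths$images))
      stop("config must provide either a `simulate` block or ",
           "`paths$plate_map` and `paths$images`")
    files <- list.files(config$paths$images, pattern = "\\.tif{1,2}$",
                        full.names = TRUE)
    if (!length(files))
      stop("no TIFF fields found in ", config$paths$images)
    if (!file.exists(config$paths$plate_map))
      stop("plate map not found: ", config$paths$plate_map)
    platemap <- utils::read.csv(config$paths$plate_map,
                                stringsAsFactors = FALSE)
    for (f in files) {
      fld <- tryCatch(read_field_tiff(f), error = function(e) {
        warning("skipping unreadable image ", f, ": ", conditionMessage(e))
        NULL
      })
      if (is.null(fld)) {
        n_warn <- n_warn + 1L
        next
      }
      base <- sub("\\.tif{1,2}$", "", basename(f))
      parts <- strsplit(base, "_")[[1]]
      fld$plate <- parts[1]
      fld$well <- parts[2]
      fld$field <- as.integer(sub("^f", "", parts[3]))
      cells_acc[[length(cells_acc) + 1L]] <-
        analyze_field(fld, seg, config$features$background_disk_px)
    }
  }
  cells <- do.call(rbind, cells_acc)
  if (is.null(cells) || !nrow(cells)) stop("no cells extracted from any field")

  missing_wells <- setdiff(platemap$well, unique(cells$well))
  if (length(missing_wells)) {
    warning(length(missing_wells), " wells have no cells and are excluded: ",
            paste(utils::head(missing_wells, 10), collapse = ", "))
    n_warn <- n_warn + length(missing_wells)
    platemap <- platemap[!platemap$well %in% missing_wells, ]
  }

  results <- screen_hit_analysis(cells, platemap,
                                 parameters = config$screen$parameters,
                                 alpha = config$screen$alpha,
                                 n_sim = config$screen$n_sim,
                                 min_hits = config$screen$min_hits,
                                 seed = config$seed)

  # Outputs.
  write_tsv(cells, file.path(out_dir, "cells.tsv"))
  wells_tab <- do.call(rbind, lapply(results, function(r) {
    ws <- r$well_stats
    ws$parameter <- r$parameter
    ws
  }))
  rownames(wells_tab) <- NULL
  write_tsv(wells_tab, file.path(out_dir, "wells.tsv"))
  hits_tab <- do.call(rbind, lapply(results, function(r) {
    h <- as.data.frame(r$hits)
    if (nrow(h)) {
      h$parameter <- r$parameter
      h$timepoint <- config$screen$timepoint
    }
    h
  }))
  rownames(hits_tab) <- NULL
  write_tsv(hits_tab[hits_tab$is_hit, , drop = FALSE],
            file.path(out_dir, "hits.tsv"))
  thr_json <- lapply(results, function(r)
    list(parameter = r$parameter, z_threshold = r$threshold$z_threshold,
         alpha = r$threshold$alpha, n_sim = r$threshold$n_sim,
         null_location = r$threshold$null$location,
         null_scale = r$threshold$null$scale))
  jsonlite::write_json(thr_json, file.path(out_dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  qc_report(results, cells, platemap, config,
            file.path(out_dir, "qc_report.md"))

  structure(list(results = results, cells = cells, platemap = platemap,
                 well_truth = well_truth, n_warnings = n_warn,
                 out_dir = out_dir),
            class = "screen_pipeline_run")
}

qc_report <- function(results, cells, platemap, config, path) {
  per_field <- stats::aggregate(cell_id ~ well + field, data = cells,
                                FUN = length)
  lines <- c(
    "# Screen pipeline QC report", "",
    sprintf("- seed: %d", config$seed),
    sprintf("- wells analyzed: %d (%d control)", nrow(platemap),
            sum(platemap$role == "control")),
    sprintf("- fields analyzed: %d", nrow(per_field)),
    sprintf("- cells per field: median %.0f (range %d-%d)",
            stats::median(per_field$cell_id), min(per_field$cell_id),
            max(per_field$cell_id)),
    "")
  for (r in results) {
    ws <- r$well_stats
    cz <- ws$z[ws$role == "control"]
    lines <- c(lines,
               sprintf("## %s", r$parameter),
               sprintf("- control z: median %.3f, MAD %.3f",
                       stats::median(cz, na.rm = TRUE),
                       stats::mad(cz, na.rm = TRUE)),
               sprintf("- |z| threshold: %.3f (alpha %g, %d simulations)",
                       r$threshold$z_threshold, r$threshold$alpha,
                       r$threshold$n_sim),
               sprintf("- hits: %d of %d genes", sum(r$hits$is_hit),
                       nrow(r$hits)),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run the brain aggregation-density pipeline
#'
#' Consumes a directory of 3D stacks (TIFF + voxel-size sidecars) with a
#' group-label CSV (`animal_id`, `group`, `file`), or a simulation block
#' (`config$simulate`: `groups` = named list of per-group expected puncta
#' counts, `n_per_group`), detects aggregates, forms per-animal densities
#' over the ROI boxes, normalizes to the control group, and runs the group
#' comparison. Writes `density.tsv` and `stats.tsv` under `config$out_dir`.
#'
#' @param config A [run_config()] with a `brain` block; the control group is
#'   `config$brain$control_group` (defaults to the first group).
#' @return A list of class `brain_pipeline_run`: `records`, `comparison`,
#'   `out_dir`.
#' @export
run_brain_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bcfg <- config$brain
  recs <- list()
  if (!is.null(config$simulate) && !is.null(config$simulate$groups)) {
    sim <- config$simulate
    n_per <- sim$n_per_group %||% 8L
    roi_boxes <- sim$roi_boxes %||% default_roi_boxes()
    vox_um <- sim$voxel_size_um %||% c(0.5, 0.25, 0.25)
    for (g in names(sim$groups)) {
      for (i in seq_len(n_per)) {
        st <- generate_brain_stack(
          n_puncta = stats::rpois(1, sim$groups[[g]]),
          roi_boxes = roi_boxes, voxel_size_um = vox_um,
          seed = derive_seed(config$seed, paste0("brain_", g, "_", i)))
        obj <- detect_aggregates_3d(st$stack, threshold = bcfg$threshold,
                                    min_vox = bcfg$min_vox,
                                    max_vox = bcfg$max_vox,
                                    auto_percentile = bcfg$auto_percentile)
        dr <- aggregation_density(obj, roi_boxes, vox_um, dim(st$stack),
                                  animal_id = sprintf("%s_%02d", g, i))
        recs[[length(recs) + 1L]] <-
          data.frame(animal_id = dr$animal_id, group = g,
                     n_aggregates = dr$n_aggregates,
                     volume_um3 = dr$roi_volume_um3, density = dr$density)
      }
    }
  } else {
    if (is.null(config$paths$stacks) || is.null(config$paths$groups))
      stop("config must provide either a `simulate$groups` block or ",
           "`paths$stacks` and `paths$groups`")
    groups <- utils::read.csv(config$paths$groups, stringsAsFactors = FALSE)
    if (!nrow(groups)) stop("empty group table: ", config$paths$groups)
    roi_boxes <- bcfg$roi_boxes %||% default_roi_boxes()
    for (i in seq_len(nrow(groups))) {
      st <- read_stack_tiff(file.path(config$paths$stacks, groups$file[i]))
      obj <- detect_aggregates_3d(st$stack, threshold = bcfg$threshold,
                                  min_vox = bcfg$min_vox,
                                  max_vox = bcfg$max_vox,
                                  auto_percentile = bcfg$auto_percentile)
      dr <- aggregation_density(obj, roi_boxes, st$voxel_size_um,
                                dim(st$stack),
                                animal_id = groups$animal_id[i])
      recs[[length(recs) + 1L]] <-
        data.frame(animal_id = dr$animal_id, group = groups$group[i],
                   n_aggregates = dr$n_aggregates,
                   volume_um3 = dr$roi_volume_um3, density = dr$density)
    }
  }
  records <- do.call(rbind, recs)
  control <- bcfg$control_group %||% records$group[1]
  comparison <- if (length(unique(records$group)) >= 2) {
    normalize_and_compare(records, control)
  } else {
    records$normalized <- records$density / mean(records$density)
    structure(list(records = records, anova = NULL,
                   comparisons = data.frame(), control_group = control,
                   note = "single group; no tests run"),
              class = "density_comparison")
  }
  write_tsv(comparison$records, file.path(out_dir, "density.tsv"))
  stats_tab <- comparison$comparisons
  if (!is.null(comparison$anova)) {
    stats_tab <- rbind(
      data.frame(group1 = "ANOVA", group2 = "",
                 diff_normalized = NA_real_,
                 statistic = comparison$anova$f_value[1],
                 df = comparison$anova$df[1],
                 p_value = comparison$anova$p_value[1],
                 method = "anova_f", stringsAsFactors = FALSE),
      stats_tab)
  }
  write_tsv(stats_tab, file.path(out_dir, "stats.tsv"))
  structure(list(records = comparison$records, comparison = comparison,
                 out_dir = out_dir),
            class = "brain_pipeline_run")
}
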