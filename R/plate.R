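#' Build a randomized 384-well plate layout
#'
#' Assigns gene knockdown wells (in `n_replicates` replicate wells each) and
#' negative-control wells to random positions of a 384-well plate (16 rows x
#' 24 columns), emulating the screen's design of 114 unique genes in
#' triplicate plus 42 negative-control wells per plate. Placement is
#' randomized by `seed`; the same seed yields an identical layout.
#'
#' Control wells are treated as exchangeable draws from a single null
#' condition (the composition of the original seven negative controls is not
#' modelled).
#'
#' @param n_genes_per_plate Number of unique genes on the plate.
#' @param n_control_wells Number of negative-control wells.
#' @param n_replicates Replicate wells per gene.
#' @param seed Integer seed.
#' @param gene_ids Optional character vector of gene identifiers (length
#'   `n_genes_per_plate`); defaults to `g001`, `g002`, ...
#' @param plate Plate identifier.
#' @return A data frame of class `plate_layout` with columns
#'   `plate`, `well`, `role` (`"gene"` or `"control"`), `gene_id`,
#'   `replicate`, one row per occupied well.
#' @export
build_plate_layout <- function(n_genes_per_plate, n_control_wells,
                               n_replicates = 3L, seed = 1L,
                               gene_ids = NULL, plate = "P1") {
  stopifnot(is_count(n_genes_per_plate), is_count(n_control_wells),
            is_count(n_replicates), n_replicates >= 1)
  need <- n_genes_per_plate * n_replicates + n_control_wells
  if (need > 384L)
    stop("layout needs ", need, " wells (", n_genes_per_plate, " genes x ",
         n_replicates, " replicates + ", n_control_wells,
         " controls) but a 384-well plate has only 384; ",
         need - 384L, " wells over capacity")
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("g%03d", seq_len(n_genes_per_plate))
  } else {
    stopifnot(length(gene_ids) == n_genes_per_plate,
              !anyDuplicated(gene_ids))
  }
  wells <- as.vector(outer(LETTERS[1:16], sprintf("%02d", 1:24), paste0))
  set.seed(derive_seed(seed, "layout"))
  use <- sample(wells, need)
  role <- c(rep("gene", n_genes_per_plate * n_replicates),
            rep("control", n_control_wells))
  gene <- c(rep(gene_ids, each = n_replicates),
            rep(NA_character_, n_control_wells))
  repl <- c(rep(seq_len(n_replicates), times = n_genes_per_plate),
            seq_len(n_control_wells))
  out <- data.frame(plate = plate, well = use, role = role,
                    gene_id = gene, replicate = repl,
                    stringsAsFactors = FALSE)
  out <- out[order(out$well), ]
  rownames(out) <- NULL
  class(out) <- c("plate_layout", "data.frame")
  out
}

#' Linear dose/time model of the aggregate-positive fraction
#'
#' The fraction of cells with aggregates rises linearly with inducer
#' (CuSO4) concentration and with time post-induction, clipped to `[0, 1]`.
#' Defaults are set so that the screen's working point of 500 uM at 24 h
#' gives a true positive fraction of 0.85 (the mutant-like ">80%" regime),
#' with a further increase by 36 h.
#'
#' @param slope_conc Fraction per uM.
#' @param slope_time Fraction per hour.
#' @param baseline Fraction at zero concentration and time.
#' @return An object of class `dose_time_model`.
#' @export
dose_time_model <- function(slope_conc = 0.001, slope_time = 0.005,
                            baseline = 0.23) {
  stopifnot(is_number(slope_conc), is_number(slope_time), is_number(baseline))
  structure(list(slope_conc = slope_conc, slope_time = slope_time,
                 baseline = baseline),
            class = "dose_time_model")
}

#' Evaluate a dose/time model
#'
#' @param model A [dose_time_model()].
#' @param conc_um Inducer concentration(s), uM.
#' @param hours Hours post-induction.
#' @return True aggregate-positive fraction(s), clipped to `[0, 1]`.
#' @export
positive_fraction_at <- function(model, conc_um, hours) {
  stopifnot(inherits(model, "dose_time_model"))
  clip01(model$baseline + model$slope_conc * conc_um + model$slope_time * hours)
}

#' Per-gene effect table for a simulated screen
#'
#' Multiplicative shifts applied by each gene knockdown: `fraction_effect`
#' scales the aggregate-positive fraction (suppressors < 1, enhancers > 1)
#' and `intensity_effect` scales per-cell punctum intensity. Genes not listed
#' default to 1 (no effect); shifted fractions are clipped to `[0, 1]`.
#'
#' @param gene_id Character vector of gene identifiers.
#' @param fraction_effect Numeric vector of multiplicative shifts on the
#'   positive fraction (recycled).
#' @param intensity_effect Numeric vector of multiplicative shifts on punctum
#'   intensity (recycled).
#' @return A data frame of class `effect_table`.
#' @export
effect_table <- function(gene_id = character(0), fraction_effect = 1,
                         intensity_effect = 1) {
  stopifnot(!anyDuplicated(gene_id), all(fraction_effect >= 0),
            all(intensity_effect >= 0))
  out <- data.frame(gene_id = as.character(gene_id),
                    fraction_effect = rep_len(fraction_effect,
                                              length(gene_id)),
                    intensity_effect = rep_len(intensity_effect,
                                               length(gene_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("effect_table", "data.frame")
  out
}

effect_for <- function(effects, gene) {
  i <- match(gene, effects$gene_id)
  list(fraction = ifelse(is.na(i), 1, effects$fraction_effect[i]),
       intensity = ifelse(is.na(i), 1, effects$intensity_effect[i]))
}

#' Simulate a whole screening plate
#'
#' For every well of `layout`, derives the well's true aggregate-positive
#' fraction as `clip01(dose_time(conc, hours) * fraction_effect(gene))`
#' (control wells use effect 1) and generates `n_fields_per_well` fields with
#' [generate_field()]. Fully reproducible for a given `seed`.
#'
#' Generated fields can be returned in memory, written to disk as multi-page
#' TIFFs (page 1 nuclei, page 2 GFP) with a plate-map CSV and a ground-truth
#' TSV, or streamed to a callback (used by [run_screen_pipeline()] to avoid
#' holding a whole plate of pixels in memory).
#'
#' @param layout A [build_plate_layout()] result.
#' @param dose_time A [dose_time_model()].
#' @param effects An [effect_table()]. Every gene listed must occur in the
#'   layout.
#' @param n_fields_per_well Fields imaged per well.
#' @param seed Integer seed.
#' @param conc_um,hours Screening working point (defaults 500 uM, 24 h).
#' @param base_spec Template [field_spec()] shared by all wells; its
#'   `positive_fraction` and `punctum_intensity` are overridden per well.
#' @param dir If non-`NULL`, write images and tables under this directory.
#' @param field_callback If non-`NULL`, a `function(field, well_row, field_no)`
#'   invoked for each generated field, which is then discarded.
#' @return A list of class `screen_sim` with `layout`, `well_truth` (data
#'   frame: well, gene, role, true positive fraction, per-well planted
#'   effect), `fields` (list of `agg_field`, only when neither `dir` nor
#'   `field_callback` is given and the plate is small enough to hold),
#'   `seed`, and the paths written (if any).
#' @export
generate_screen <- function(layout, dose_time = dose_time_model(),
                            effects = effect_table(),
                            n_fields_per_well = 10L, seed = 1L,
                            conc_um = 500, hours = 24,
                            base_spec = field_spec(),
                            dir = NULL, field_callback = NULL) {
  stopifnot(inherits(layout, "plate_layout") || is.data.frame(layout),
            inherits(dose_time, "dose_time_model"),
            is.data.frame(effects),
            is_count(n_fields_per_well), n_fields_per_well >= 1,
            inherits(base_spec, "field_spec"))
  unknown <- setdiff(effects$gene_id, layout$gene_id)
  if (length(unknown))
    stop("effect table lists genes absent from the layout: ",
         paste(unknown, collapse = ", "))
  p0 <- positive_fraction_at(dose_time, conc_um, hours)
  eff <- effect_for(effects, layout$gene_id)
  eff$fraction[layout$role == "control"] <- 1
  eff$intensity[layout$role == "control"] <- 1
  well_truth <- data.frame(plate = layout$plate, well = layout$well,
                           role = layout$role, gene_id = layout$gene_id,
                           replicate = layout$replicate,
                           fraction_effect = eff$fraction,
                           intensity_effect = eff$intensity,
                           true_positive_fraction = clip01(p0 * eff$fraction),
                           stringsAsFactors = FALSE)

  keep <- is.null(dir) && is.null(field_callback)
  max_keep_px <- 2^26  # ~64 M pixel-pairs; beyond this, require dir/callback
  if (keep &&
      nrow(layout) * n_fields_per_well * prod(base_spec$image_shape) > max_keep_px)
    stop("this plate is too large to return in memory; supply `dir` or ",
         "`field_callback`")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(layout, file.path(dir, "plate_map.csv"),
                     row.names = FALSE)
    utils::write.table(well_truth, file.path(dir, "well_truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  fields <- if (keep) vector("list", nrow(layout) * n_fields_per_well)
  fi <- 0L
  for (w in seq_len(nrow(layout))) {
    sp <- base_spec
    sp$positive_fraction <- well_truth$true_positive_fraction[w]
    sp$punctum_intensity <- base_spec$punctum_intensity * eff$intensity[w]
    for (f in seq_len(n_fields_per_well)) {
      fseed <- derive_seed(seed, paste0(layout$plate[w], "_", layout$well[w],
                                        "_f", f))
      fld <- generate_field(sp, fseed)
      fld$plate <- layout$plate[w]
      fld$well <- layout$well[w]
      fld$field <- f
      fi <- fi + 1L
      if (!is.null(field_callback)) {
        field_callback(fld, layout[w, ], f)
      } else if (!is.null(dir)) {
        write_field_tiff(fld, file.path(dir, sprintf("%s_%s_f%02d.tif",
                                                     layout$plate[w],
                                                     layout$well[w], f)))
      } else {
        fields[[fi]] <- fld
      }
    }
  }
  structure(list(layout = layout, well_truth = well_truth,
                 fields = if (keep) fields, seed = seed,
                 dir = dir),
            class = "screen_sim")
}
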