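# File formats. Images travel as TIFF with intensities stored as
# AFU / 65535 in 16-bit pages (AFU are restored on read); tables as TSV/CSV;
# configuration as YAML; thresholds as JSON.

AFU_SCALE <- 65535

#' Write a two-channel field as a multi-page TIFF
#'
#' Page 1 is the nuclei channel, page 2 the GFP channel. Intensities (AFU)
#' are stored as 16-bit samples scaled by 1/65535 and restored on read.
#'
#' @param field An `agg_field` (or a list with `nuclei` and `gfp` matrices).
#' @param path Output path (`<plate>_<well>_f<field>.tif` by convention).
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(is.matrix(field$nuclei), is.matrix(field$gfp))
  tiff::writeTIFF(list(pmin(field$nuclei / AFU_SCALE, 1),
                       pmin(field$gfp / AFU_SCALE, 1)),
                  path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a two-channel field TIFF
#'
#' @param path Path written by [write_field_tiff()].
#' @return A list of class `agg_field` with `nuclei` and `gfp` matrices (AFU).
#' @export
read_field_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L)
    stop("expected a 2-page TIFF (nuclei, GFP) at ", path)
  structure(list(nuclei = pages[[1]] * AFU_SCALE,
                 gfp = pages[[2]] * AFU_SCALE, truth = NULL),
            class = "agg_field")
}

#' Write / read a 3D stack as a multi-page TIFF with a voxel-size sidecar
#'
#' One page per z-slice; the voxel size (micrometres, z/y/x) is stored in a
#' YAML sidecar `<path>.yaml`. Reading fails if the voxel size is missing
#' and not supplied explicitly — units are never assumed.
#'
#' @param stack A `brain_stack` or 3D array.
#' @param path Output path.
#' @param voxel_size_um Voxel size written to the sidecar (taken from the
#'   `brain_stack` when omitted).
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, voxel_size_um = NULL) {
  arr <- if (inherits(stack, "brain_stack")) stack$stack else stack
  if (is.null(voxel_size_um) && inherits(stack, "brain_stack"))
    voxel_size_um <- stack$voxel_size_um
  stopifnot(length(dim(arr)) == 3L, !is.null(voxel_size_um))
  pages <- lapply(seq_len(dim(arr)[1]),
                  function(z) pmin(arr[z, , ] / AFU_SCALE, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  yaml::write_yaml(list(voxel_size_um = as.numeric(voxel_size_um)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, voxel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]] * AFU_SCALE
  if (is.null(voxel_size_um)) {
    side <- paste0(path, ".yaml")
    if (!file.exists(side))
      stop("voxel size for ", path, " is unknown: no sidecar ", side,
           " and no `voxel_size_um` given; units are never assumed")
    voxel_size_um <- as.numeric(yaml::read_yaml(side)$voxel_size_um)
  }
  stopifnot(length(voxel_size_um) == 3L, all(voxel_size_um > 0))
  structure(list(stack = arr, voxel_size_um = voxel_size_um),
            class = "brain_stack")
}

#' Default run configuration
#'
#' Assembles the fully resolved configuration used by the pipelines:
#' segmentation and macro parameters, screen statistics settings, brain assay
#' settings, and the single global seed from which all named random
#' substreams are derived. Round-trips losslessly through YAML.
#'
#' @param seed Global seed.
#' @param out_dir Output directory for pipeline products.
#' @param ... Named overrides merged into the defaults (nested lists are
#'   merged recursively).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = "aggscreen_out", ...) {
  base <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    paths = list(images = NULL, plate_map = NULL, stacks = NULL,
                 groups = NULL),
    segmentation = list(size_cutoff = c(20, 2000), roi_radius_px = 10,
                        clump_solidity_min = 0.8, focus_variance_min = 0,
                        threshold_method = "otsu"),
    features = list(background_disk_px = 3),
    screen = list(alpha = 0.001, n_sim = 5000L, min_hits = 2L,
                  parameters = c("avg_intensity", "total_intensity"),
                  timepoint = "24h"),
    brain = list(threshold = "auto", auto_percentile = 0.995,
                 min_vox = 10L, max_vox = 1000L),
    simulate = NULL)
  over <- list(...)
  cfg <- modify_list_deep(base, over)
  class(cfg) <- c("run_config", "list")
  cfg
}

modify_list_deep <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(over[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `run_config`.
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, c(list(seed = raw$seed %||% 1L,
                             out_dir = raw$out_dir %||% "aggscreen_out"),
                        raw[setdiff(names(raw), c("seed", "out_dir"))]))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
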