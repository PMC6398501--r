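#' Parameters of the macro-equivalent counting pipeline
#'
#' Mirrors the recorded imaging macro: particles of size 10-500 px are
#' counted in both channels; "circularity 1" is read as the non-excluding
#' range `[0, 1]` (a strict equality filter would reject nearly every real
#' particle); the rolling-ball radius of 0.3 px is honoured as given (at that
#' scale it is a near-no-op background estimate), with the punctum-merging
#' intent implemented explicitly by a morphological closing so that puncta
#' closer than one cell radius are integrated into a single object.
#'
#' @param particle_size_range Area range (pixels) counted in the GFP channel.
#' @param circularity_range Allowed circularity `4*pi*A/P^2` range for DAPI
#'   particles.
#' @param rolling_radius_px Rolling-ball background radius, pixels.
#' @param dapi_particle_size_range Area range (pixels) for DAPI particles.
#' @param cell_radius_px Cellular radius used to merge same-cell puncta.
#' @param dapi_threshold_method,gfp_threshold_method Automatic threshold used
#'   to binarize each channel. The GFP channel defaults to the intermeans
#'   (IsoData) iteration seeded at the range midpoint, which places the cut
#'   between the diffuse reticular signal and the bright puncta so that only
#'   high-intensity puncta survive.
#' @return An object of class `macro_params`.
#' @export
macro_params <- function(particle_size_range = c(10, 500),
                         circularity_range = c(0, 1),
                         rolling_radius_px = 0.3,
                         dapi_particle_size_range = c(10, 500),
                         cell_radius_px = 10,
                         dapi_threshold_method = "otsu",
                         gfp_threshold_method = "isodata") {
  stopifnot(length(particle_size_range) == 2L,
            particle_size_range[1] <= particle_size_range[2],
            length(circularity_range) == 2L,
            circularity_range[1] <= circularity_range[2],
            is_number(rolling_radius_px), rolling_radius_px >= 0,
            length(dapi_particle_size_range) == 2L,
            dapi_particle_size_range[1] <= dapi_particle_size_range[2],
            is_number(cell_radius_px), cell_radius_px >= 1)
  structure(list(particle_size_range = particle_size_range,
                 circularity_range = circularity_range,
                 rolling_radius_px = rolling_radius_px,
                 dapi_particle_size_range = dapi_particle_size_range,
                 cell_radius_px = cell_radius_px,
                 dapi_threshold_method =
                   match.arg(dapi_threshold_method,
                             c("otsu", "isodata", "triangle")),
                 gfp_threshold_method =
                   match.arg(gfp_threshold_method,
                             c("isodata", "otsu", "triangle"))),
            class = "macro_params")
}

#' Local background correction by morphological opening
#'
#' Estimates the local background as the grayscale opening of the image with
#' a disk structuring element and subtracts it, flooring at zero. Structures
#' narrower than about twice the disk radius (the puncta) survive; wider
#' structures (the diffuse per-cell signal) and any constant pedestal are
#' removed, which makes downstream per-cell features invariant to additive
#' pedestals.
#'
#' @param gfp Non-negative numeric matrix.
#' @param disk_radius_px Disk radius in pixels (the screen used 3).
#' @return Numeric matrix, same shape, `>= 0`.
#' @export
subtract_local_background <- function(gfp, disk_radius_px = 3) {
  stopifnot(is.matrix(gfp), all(gfp >= 0), is_number(disk_radius_px),
            disk_radius_px >= 0)
  k <- disc_kernel(disk_radius_px)
  # A sub-pixel disk gives a background estimate that hugs the image; the
  # subtraction is then treated as a no-op rather than as signal removal.
  if (all(dim(k) == 1L)) return(gfp)
  bg <- gray_opening(gfp, k)
  pmax(gfp - bg, 0)
}

#' Per-cell intensity features over an ROI map
#'
#' @param rois A [make_cell_rois()] result (or a bare integer ROI matrix).
#' @param corrected_gfp Background-corrected GFP matrix, same shape.
#' @return Data frame with one row per ROI: `cell_id`, `area`,
#'   `avg_intensity`, `total_intensity`.
#' @export
cell_intensity_features <- function(rois, corrected_gfp) {
  roi <- if (inherits(rois, "roi_map")) rois$roi else rois
  stopifnot(is.matrix(roi), all(dim(roi) == dim(corrected_gfp)))
  idx <- which(roi > 0L)
  if (!length(idx))
    return(data.frame(cell_id = integer(0), area = integer(0),
                      avg_intensity = numeric(0), total_intensity = numeric(0)))
  lab <- roi[idx]
  vals <- corrected_gfp[idx]
  tot <- tapply(vals, lab, sum)
  n <- tapply(vals, lab, length)
  data.frame(cell_id = as.integer(names(tot)),
             area = as.integer(n),
             avg_intensity = as.numeric(tot / n),
             total_intensity = as.numeric(tot))
}

# Shared particle-analysis step: label a binary mask (8-connectivity) and
# count components passing an area range and, optionally, a circularity
# range computed as 4*pi*A/P^2 from the component perimeter.
count_particles <- function(mask, size_range, circularity_range = NULL) {
  labels <- label_8conn(mask)
  k <- max(labels)
  if (k == 0L) return(0L)
  areas <- label_areas(labels)
  ok <- areas >= size_range[1] & areas <= size_range[2]
  if (!is.null(circularity_range) &&
      (circularity_range[1] > 0 || circularity_range[2] < 1)) {
    fts <- EBImage::computeFeatures.shape(labels)
    per <- fts[, "s.perimeter"]
    circ <- pmin(4 * pi * areas / pmax(per, 1)^2, 1)
    ok <- ok & circ >= circularity_range[1] & circ <= circularity_range[2]
  }
  sum(ok)
}

#' Count cells from the DAPI channel (macro equivalent)
#'
#' Converts to 8-bit (linear min-max rescale), subtracts the image mean
#' (floored at zero), binarizes with an automatic threshold, splits touching
#' objects by a distance-transform watershed, and counts particles with area
#' in the configured size range and circularity in the configured range.
#'
#' @param dapi Single-channel numeric matrix.
#' @param params A [macro_params()].
#' @return Integer cell count.
#' @export
count_cells_binary <- function(dapi, params = macro_params()) {
  stopifnot(is.matrix(dapi), inherits(params, "macro_params"))
  img <- rescale_8bit(dapi)
  img <- pmax(img - mean(img), 0)
  if (all(img == 0)) return(0L)
  thr <- auto_threshold(img, params$dapi_threshold_method)
  mask <- img > thr
  if (!any(mask)) return(0L)
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::imageData(EBImage::watershed(dm))
  k <- max(ws)
  if (k == 0L) return(0L)
  areas <- label_areas(ws)
  ok <- areas >= params$dapi_particle_size_range[1] &
    areas <= params$dapi_particle_size_range[2]
  if (params$circularity_range[1] > 0 || params$circularity_range[2] < 1) {
    fts <- EBImage::computeFeatures.shape(ws)
    circ <- pmin(4 * pi * areas / pmax(fts[, "s.perimeter"], 1)^2, 1)
    ok <- ok & circ >= params$circularity_range[1] &
      circ <= params$circularity_range[2]
  }
  as.integer(sum(ok))
}

#' Count aggregate-positive cells from the GFP channel (macro equivalent)
#'
#' Converts to 8-bit, applies the rolling-ball background subtraction at the
#' configured radius, binarizes (midpoint-seeded intermeans threshold by
#' default, which places the cut above the diffuse reticular signal), merges
#' puncta closer than one cell radius into a single object by closing, and counts
#' objects with area in the configured size range. The resulting count is the
#' number of aggregate-positive cells.
#'
#' @param gfp Single-channel numeric matrix.
#' @param params A [macro_params()].
#' @return Integer count of aggregate-positive cells.
#' @export
count_aggregate_positive_cells <- function(gfp, params = macro_params()) {
  stopifnot(is.matrix(gfp), inherits(params, "macro_params"))
  img <- rescale_8bit(gfp)
  if (params$rolling_radius_px >= 0.5) {
    k <- disc_kernel(params$rolling_radius_px)
    if (!all(dim(k) == 1L)) {
      img <- pmax(img - gray_opening(img, k), 0)
    }
  }
  if (max(img) <= 0) return(0L)
  thr <- auto_threshold(img, params$gfp_threshold_method)
  mask <- img > thr
  if (!any(mask)) return(0L)
  # Integrate same-cell puncta (closer than one cell radius) into one object.
  ck <- disc_kernel(params$cell_radius_px / 2)
  if (!all(dim(ck) == 1L))
    mask <- EBImage::imageData(EBImage::closing(EBImage::Image(mask * 1),
                                                ck)) > 0.5
  as.integer(count_particles(mask, params$particle_size_range))
}

#' Fraction of cells that are aggregate-positive
#'
#' @param dapi_count Total cell count (from [count_cells_binary()]).
#' @param positive_count Aggregate-positive cell count (from
#'   [count_aggregate_positive_cells()]). The two counts come from different
#'   channels, so `positive_count <= dapi_count` is not required; the ratio
#'   is clipped to `[0, 1]`.
#' @return Fraction in `[0, 1]`.
#' @export
aggregate_fraction <- function(dapi_count, positive_count) {
  stopifnot(is_count(dapi_count), is_count(positive_count))
  if (dapi_count == 0)
    stop("cannot form an aggregate-positive fraction with zero cells ",
         "(dapi_count = 0)")
  clip01(positive_count / dapi_count)
}

#' Ordinary least-squares dose-response line
#'
#' Fits `y ~ x` by OLS, for the linear relation between inducer
#' concentration (or relative protein level) and the fraction of cells
#' showing aggregates.
#'
#' @param x Numeric dose or protein-level values (at least 2 distinct).
#' @param y Numeric fractions, same length.
#' @return A list of class `dose_response_fit`: `slope`, `intercept`,
#'   `r_squared`, `n_points`.
#' @export
fit_dose_response <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 2)
  if (length(unique(x)) < 2)
    stop("need at least 2 distinct x values to fit a dose-response line")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = max(0, min(1, r2)),
                 n_points = length(x)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("dose-response OLS fit: slope %.4g, intercept %.4g, R^2 %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}
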