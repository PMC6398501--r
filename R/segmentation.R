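#' Segmentation parameters for the screen pipeline
#'
#' @param size_cutoff Two-sided nucleus area cutoff (min, max) in pixels;
#'   connected components outside this range are discarded as outliers.
#' @param roi_radius_px Radius (pixels) by which nucleus centroids are
#'   dilated into cellular ROIs; 10 px corresponds to the estimated cellular
#'   radius of 5 um at 20x.
#' @param clump_solidity_min Nuclei with solidity (area / convex hull area)
#'   below this value are rejected as clumps.
#' @param focus_variance_min ROIs whose GFP intensity variance falls below
#'   this floor are rejected as out of focus (0 disables the filter).
#' @param threshold_method Automatic global threshold for the preprocessed
#'   nuclei image (`"otsu"`, `"isodata"` or `"triangle"`).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(size_cutoff = c(20, 2000),
                                roi_radius_px = 10,
                                clump_solidity_min = 0.8,
                                focus_variance_min = 0,
                                threshold_method = "otsu") {
  stopifnot(length(size_cutoff) == 2L, size_cutoff[1] < size_cutoff[2],
            is_number(roi_radius_px), roi_radius_px >= 1,
            is_number(clump_solidity_min), clump_solidity_min > 0,
            clump_solidity_min <= 1,
            is_number(focus_variance_min), focus_variance_min >= 0)
  structure(list(size_cutoff = size_cutoff,
                 roi_radius_px = roi_radius_px,
                 clump_solidity_min = clump_solidity_min,
                 focus_variance_min = focus_variance_min,
                 threshold_method = match.arg(threshold_method,
                                              c("otsu", "isodata",
                                                "triangle"))),
            class = "segmentation_params")
}

# Illumination estimate for a field of point-like sources (nuclei over a
# dark background). A smoothed copy of such an image tracks local cell
# density, not illumination, so the multiplicative gain field is estimated
# from the sources themselves: local intensity maxima (one per nucleus,
# height = gain x nucleus amplitude) are detected with a 7x7 max filter,
# and a quadratic surface is fitted through the peak heights. Per-nucleus
# amplitude variation averages out over the peaks, leaving the smooth gain
# surface.
smooth_illumination <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  mx <- gray_dilate(img, EBImage::makeBrush(7L, "box"))
  idx <- which(img >= mx & img > 0.25 * max(img))
  quad_basis <- function(y, x) {
    yy <- (y - 1) / max(ny - 1, 1) - 0.5
    xx <- (x - 1) / max(nx - 1, 1) - 0.5
    cbind(1, yy, xx, yy * xx, yy^2, xx^2)
  }
  if (length(idx) < 12L) {
    # Too few sources to constrain a surface; fall back to a flat estimate.
    return(matrix(mean(img[img > 0]), ny, nx))
  }
  py <- (idx - 1L) %% ny + 1L
  px <- (idx - 1L) %/% ny + 1L
  fit <- stats::lm.fit(quad_basis(py, px), img[idx])
  g <- expand.grid(y = seq_len(ny), x = seq_len(nx))
  surf <- matrix(quad_basis(g$y, g$x) %*% fit$coefficients, ny, nx)
  pmax(surf, 0.05 * max(surf))
}

#' Correct illumination and contrast-stretch a nuclei image
#'
#' Divides out the estimated smooth illumination field (a quadratic gain
#' surface fitted through the field's local intensity maxima) and linearly
#' rescales the result to the fixed display range `[0, 1]`. A flat image
#' maps to a flat image at mid-range; an all-zero image is returned
#' unchanged.
#'
#' @param nuclei_channel Single-channel non-negative numeric matrix.
#' @return Numeric matrix in `[0, 1]`.
#' @export
preprocess_nuclei_image <- function(nuclei_channel) {
  stopifnot(is.matrix(nuclei_channel), all(nuclei_channel >= 0))
  if (all(nuclei_channel == 0)) return(nuclei_channel)
  illum <- smooth_illumination(nuclei_channel)
  floor_val <- max(mean(illum) * 1e-3, .Machine$double.eps)
  corrected <- nuclei_channel / pmax(illum, floor_val)
  rng <- range(corrected)
  if (rng[2] <= rng[1])
    return(matrix(0.5, nrow(corrected), ncol(corrected)))
  (corrected - rng[1]) / (rng[2] - rng[1])
}

#' Segment nuclei by global threshold and 8-connected labelling
#'
#' Thresholds the preprocessed nuclei image globally (Otsu by default),
#' labels 8-connected foreground components, and discards components whose
#' pixel area falls outside the two-sided size cutoff.
#'
#' @param preprocessed Output of [preprocess_nuclei_image()].
#' @param params A [segmentation_params()].
#' @return Integer label matrix (`0` background, labels `1..K`), with the
#'   per-label pixel areas attached as attribute `areas`.
#' @export
segment_nuclei <- function(preprocessed, params = segmentation_params()) {
  stopifnot(is.matrix(preprocessed), inherits(params, "segmentation_params"))
  if (all(preprocessed == 0))
    return(structure(matrix(0L, nrow(preprocessed), ncol(preprocessed)),
                     areas = integer(0)))
  thr <- auto_threshold(preprocessed * 255, params$threshold_method) / 255
  mask <- preprocessed > thr
  labels <- label_8conn(mask)
  areas <- label_areas(labels)
  bad <- which(areas < params$size_cutoff[1] | areas > params$size_cutoff[2])
  if (length(bad)) {
    labels[labels %in% bad] <- 0L
    keep <- setdiff(which(areas > 0), bad)
    labels[labels > 0L] <- match(labels[labels > 0L], keep)
    areas <- areas[keep]
  }
  structure(labels, areas = as.integer(areas))
}

# Solidity (area / convex hull area) of one labelled component given its
# pixel coordinates. Treats pixels as unit squares for a stable hull area.
component_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n <= 3) return(1)
  pts <- rbind(cbind(rows + 0.5, cols + 0.5), cbind(rows + 0.5, cols - 0.5),
               cbind(rows - 0.5, cols + 0.5), cbind(rows - 0.5, cols - 0.5))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  m <- nrow(hp)
  a <- abs(sum(hp[, 1] * hp[c(2:m, 1), 2] - hp[c(2:m, 1), 1] * hp[, 2])) / 2
  min(n / a, 1)
}

#' Build per-cell ROIs by dilating nucleus centroids
#'
#' Each retained nucleus contributes a disk ROI of radius `roi_radius_px`
#' about its (unweighted) pixel centroid. Pixels claimed by several disks go
#' to the nearest centroid (ties to the lower label). Nuclei failing the
#' clump filter (solidity below `clump_solidity_min`) or whose ROI GFP
#' variance falls below `focus_variance_min` contribute no ROI.
#'
#' @param labels Label matrix from [segment_nuclei()].
#' @param gfp_channel GFP channel matrix of the same shape (used by the
#'   out-of-focus filter).
#' @param params A [segmentation_params()].
#' @return A list of class `roi_map`: `roi` (integer matrix assigning each
#'   pixel to at most one cell), `centroids` (data frame `cell`, `row`,
#'   `col`, `kept`, `reject_reason`).
#' @export
make_cell_rois <- function(labels, gfp_channel,
                           params = segmentation_params()) {
  stopifnot(is.matrix(labels), is.matrix(gfp_channel),
            all(dim(labels) == dim(gfp_channel)),
            inherits(params, "segmentation_params"))
  ny <- nrow(labels); nx <- ncol(labels)
  k <- max(labels, 0L)
  cen <- data.frame(cell = integer(0), row = numeric(0), col = numeric(0),
                    kept = logical(0), reject_reason = character(0))
  roi <- matrix(0L, ny, nx)
  if (k == 0L)
    return(structure(list(roi = roi, centroids = cen), class = "roi_map"))

  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- (idx - 1L) %% ny + 1L
  cols <- (idx - 1L) %/% ny + 1L
  cy <- tapply(rows, lab, mean)
  cx <- tapply(cols, lab, mean)
  sol <- vapply(seq_len(k), function(l) {
    sel <- lab == l
    component_solidity(rows[sel], cols[sel])
  }, numeric(1))

  reason <- rep("", k)
  reason[sol < params$clump_solidity_min] <- "clump"

  r <- params$roi_radius_px
  ir <- as.integer(ceiling(r))
  best <- matrix(Inf, ny, nx)
  order_keep <- which(reason == "")
  for (l in order_keep) {
    y0 <- as.integer(round(cy[[l]])); x0 <- as.integer(round(cx[[l]]))
    ys <- max(1L, y0 - ir):min(ny, y0 + ir)
    xs <- max(1L, x0 - ir):min(nx, x0 + ir)
    dy <- matrix(ys - cy[[l]], length(ys), length(xs))
    dx <- matrix(xs - cx[[l]], length(ys), length(xs), byrow = TRUE)
    d2 <- dy^2 + dx^2
    sub_b <- best[ys, xs]
    claim <- d2 <= r^2 & d2 < sub_b  # strict: ties stay with the lower label
    if (any(claim)) {
      sub_r <- roi[ys, xs]
      sub_r[claim] <- l
      sub_b[claim] <- d2[claim]
      roi[ys, xs] <- sub_r
      best[ys, xs] <- sub_b
    }
  }

  # Out-of-focus filter: ROI-level GFP intensity variance below the floor.
  if (params$focus_variance_min > 0) {
    ridx <- which(roi > 0L)
    rl <- roi[ridx]
    vs <- tapply(gfp_channel[ridx], rl, stats::var)
    low <- as.integer(names(vs))[!is.na(vs) & vs < params$focus_variance_min]
    if (length(low)) {
      roi[roi %in% low] <- 0L
      reason[low] <- "out_of_focus"
    }
  }

  cen <- data.frame(cell = seq_len(k), row = as.numeric(cy),
                    col = as.numeric(cx), kept = reason == "",
                    reject_reason = reason, stringsAsFactors = FALSE)
  structure(list(roi = roi, centroids = cen), class = "roi_map")
}
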