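#' Default ventral nerve cord ROI boxes for synthetic stacks
#'
#' Three congruent axis-aligned 3D boxes laid side by side along x, emulating
#' fixed-size regions of interest drawn along the tip of the ventral nerve
#' cord. Boxes are half-open voxel intervals `[lo, hi)` in (z, y, x) order,
#' 1-based.
#'
#' @param stack_dim Integer (nz, ny, nx) dimensions of the stack.
#' @return A list of three boxes, each `list(lo =, hi =)`.
#' @export
default_roi_boxes <- function(stack_dim = c(32L, 96L, 192L)) {
  nz <- stack_dim[1]; ny <- stack_dim[2]; nx <- stack_dim[3]
  w <- floor((nx - 8) / 3)
  lapply(0:2, function(k) {
    list(lo = c(1, 9, 5 + k * w), hi = c(nz + 1, ny - 7, 5 + (k + 1) * w))
  })
}

#' Generate a synthetic 3D brain stack with planted aggregates
#'
#' Places `n_puncta` bright, non-overlapping, roughly spherical objects over
#' a dim noisy background, records each object's centroid, voxel count and
#' ROI membership, and returns the true aggregation density over the ROI
#' boxes. Deterministic per seed.
#'
#' @param n_puncta Number of aggregates to plant.
#' @param roi_boxes List of half-open boxes as in [default_roi_boxes()].
#' @param voxel_size_um Numeric (z, y, x) voxel size in micrometres.
#' @param punctum_voxels Integer range (lo, hi) of target voxel counts per
#'   aggregate; must lie within the detectable range `[10, 1000]`.
#' @param seed Integer seed.
#' @param stack_dim Integer (nz, ny, nx) stack dimensions.
#' @param punctum_intensity,background,noise_sd Intensity model, AFU.
#' @return A list of class `brain_stack` with `stack` (3D array), the voxel
#'   size, ROI boxes, and `truth`: data frame of objects (`id`, `z`, `y`,
#'   `x`, `n_voxels`, `roi` — 0 when outside every box), plus `n_in_rois`,
#'   `roi_volume_um3` (total over the three boxes) and `density`
#'   (aggregates per cubic micrometre over the ROIs).
#' @export
generate_brain_stack <- function(n_puncta, roi_boxes = default_roi_boxes(),
                                 voxel_size_um = c(0.5, 0.25, 0.25),
                                 punctum_voxels = c(30L, 200L), seed = 1L,
                                 stack_dim = c(32L, 96L, 192L),
                                 punctum_intensity = 100,
                                 background = 10, noise_sd = 2) {
  stopifnot(is_count(n_puncta), length(stack_dim) == 3L,
            length(voxel_size_um) == 3L, all(voxel_size_um > 0),
            length(punctum_voxels) == 2L,
            punctum_voxels[1] <= punctum_voxels[2])
  if (punctum_voxels[1] < 10 || punctum_voxels[2] > 1000)
    stop("punctum_voxels must lie within the detectable object-size range ",
         "[10, 1000] voxels, got [", punctum_voxels[1], ", ",
         punctum_voxels[2], "]")
  nz <- stack_dim[1]; ny <- stack_dim[2]; nx <- stack_dim[3]
  set.seed(derive_seed(seed, "brain"))
  stack <- array(background, dim = stack_dim)

  # Place sphere centres with pairwise separation >= r_a + r_b + 2.
  vox <- if (n_puncta > 0)
    sample(seq(punctum_voxels[1], punctum_voxels[2]), n_puncta,
           replace = TRUE) else integer(0)
  rads <- (3 * vox / (4 * pi))^(1 / 3)
  centers <- matrix(NA_real_, n_puncta, 3L)
  placed <- 0L
  tries <- 0L
  max_tries <- 500L * max(n_puncta, 1L)
  while (placed < n_puncta && tries < max_tries) {
    tries <- tries + 1L
    i <- placed + 1L
    m <- ceiling(rads[i]) + 1
    cand <- c(runif(1, m + 1, nz - m), runif(1, m + 1, ny - m),
              runif(1, m + 1, nx - m))
    ok <- TRUE
    if (placed > 0L) {
      dd <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                            cand)^2))
      if (any(dd < rads[seq_len(placed)] + rads[i] + 2)) ok <- FALSE
    }
    if (ok) {
      placed <- i
      centers[i, ] <- round(cand)
    }
  }
  if (placed < n_puncta)
    stop("could not place ", n_puncta, " non-overlapping aggregates in a ",
         paste(stack_dim, collapse = "x"), " stack")

  # Render each aggregate with exactly its target voxel count: grow a
  # rasterized ball until it holds >= v voxels, then keep the v nearest to
  # the centre (deterministic tie-break), so every object stays inside the
  # detectable [10, 1000] voxel range.
  n_actual <- integer(n_puncta)
  for (i in seq_len(n_puncta)) {
    v <- vox[i]
    r <- max(rads[i], 1)
    for (grow in 1:100) {
      ir <- ceiling(r)
      zs <- (centers[i, 1] - ir):(centers[i, 1] + ir)
      ys <- (centers[i, 2] - ir):(centers[i, 2] + ir)
      xs <- (centers[i, 3] - ir):(centers[i, 3] + ir)
      g <- expand.grid(z = zs, y = ys, x = xs)
      d2 <- (g$z - centers[i, 1])^2 + (g$y - centers[i, 2])^2 +
        (g$x - centers[i, 3])^2
      if (sum(d2 <= r^2) >= v) break
      r <- r + 0.15
    }
    keep <- order(d2)[seq_len(v)]
    n_actual[i] <- v
    idx <- cbind(g$z, g$y, g$x)[keep, , drop = FALSE]
    stack[idx] <- punctum_intensity
    # truth describes the emitted voxels: record the rasterized centroid
    centers[i, ] <- colMeans(idx)
  }
  if (noise_sd > 0)
    stack <- pmax(stack + array(rnorm(length(stack), 0, noise_sd),
                                dim = stack_dim), 0)

  roi <- integer(n_puncta)
  for (b in seq_along(roi_boxes)) {
    bx <- roi_boxes[[b]]
    inb <- rep(TRUE, n_puncta)
    for (a in 1:3)
      inb <- inb & centers[, a] >= bx$lo[a] & centers[, a] < bx$hi[a]
    roi[inb & roi == 0L] <- b
  }
  vol <- sum(vapply(roi_boxes, function(b)
    prod(b$hi - b$lo) * prod(voxel_size_um), numeric(1)))
  truth <- data.frame(id = seq_len(n_puncta),
                      z = centers[, 1], y = centers[, 2], x = centers[, 3],
                      n_voxels = n_actual, roi = roi)
  structure(list(stack = stack, voxel_size_um = voxel_size_um,
                 roi_boxes = roi_boxes,
                 truth = list(objects = truth,
                              n_in_rois = sum(roi > 0),
                              roi_volume_um3 = vol,
                              density = sum(roi > 0) / vol),
                 seed = seed),
            class = "brain_stack")
}
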