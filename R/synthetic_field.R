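#' Specification of a synthetic two-channel imaging field
#'
#' Describes one field of view of the screening microscope: a nuclei (DAPI)
#' channel and a GFP channel over the same pixel grid. Defaults emulate the
#' screen's acquisition conditions: roughly 400 cells per field imaged at 20x,
#' a cellular radius of about 10 pixels (5 um), a mutant-like
#' aggregate-positive fraction of 0.85, a dim diffuse (reticular, ER-like)
#' GFP component in every cell, bright compact puncta in positive cells, a
#' smooth multiplicative illumination gradient and additive Gaussian noise.
#' Intensities are in arbitrary fluorescence units (AFU).
#'
#' @param n_cells Target number of cells in the field.
#' @param positive_fraction Probability that a cell is aggregate-positive.
#' @param nucleus_radius_px Nucleus/cell radius in pixels (maximum semi-axis
#'   of the rendered nucleus ellipse; also the scale used to place puncta).
#' @param puncta_lambda Mean of the truncated Poisson governing puncta per
#'   positive cell (support restricted to `puncta_range`).
#' @param puncta_range Integer range (lo, hi) of puncta per positive cell.
#' @param punctum_diameter_px Integer range of punctum diameters, pixels.
#' @param punctum_intensity Peak punctum intensity, AFU.
#' @param diffuse_intensity Diffuse per-cell GFP intensity, AFU. Applied to
#'   every cell (the reticular wild-type-like signal).
#' @param nucleus_intensity Peak nucleus intensity in the DAPI channel, AFU.
#' @param illumination_gradient_amplitude Peak fractional deviation of the
#'   smooth illumination surface from its mean (applied to both channels).
#' @param noise_sd Standard deviation of additive Gaussian noise, AFU.
#' @param image_shape Integer vector (rows, cols) of the field in pixels.
#' @return An object of class `field_spec` (a validated list).
#' @seealso [generate_field()]
#' @export
field_spec <- function(n_cells = 400,
                       positive_fraction = 0.85,
                       nucleus_radius_px = 10,
                       puncta_lambda = 1.5,
                       puncta_range = c(1L, 3L),
                       punctum_diameter_px = c(3L, 7L),
                       punctum_intensity = 200,
                       diffuse_intensity = 20,
                       nucleus_intensity = 150,
                       illumination_gradient_amplitude = 0.15,
                       noise_sd = 4,
                       image_shape = c(1024L, 1024L)) {
  stopifnot(is_count(n_cells),
            is_number(positive_fraction),
            is_number(nucleus_radius_px), nucleus_radius_px >= 2,
            is_number(puncta_lambda), puncta_lambda > 0,
            length(puncta_range) == 2L, puncta_range[1] >= 1,
            puncta_range[1] <= puncta_range[2],
            length(punctum_diameter_px) == 2L, punctum_diameter_px[1] >= 2,
            punctum_diameter_px[1] <= punctum_diameter_px[2],
            is_number(punctum_intensity), punctum_intensity >= 0,
            is_number(diffuse_intensity), diffuse_intensity >= 0,
            is_number(nucleus_intensity), nucleus_intensity > 0,
            is_number(illumination_gradient_amplitude),
            illumination_gradient_amplitude >= 0,
            is_number(noise_sd), noise_sd >= 0,
            length(image_shape) == 2L, all(image_shape >= 16))
  if (positive_fraction < 0 || positive_fraction > 1)
    stop("`positive_fraction` must lie in [0, 1], got ", positive_fraction)
  # Random sequential placement of non-overlapping nuclei jams at ~55% disc
  # coverage; refuse specs that would exceed a safe fraction of that.
  r <- nucleus_radius_px
  if (n_cells * pi * r^2 > 0.45 * prod(image_shape))
    stop("image_shape ", paste(image_shape, collapse = "x"),
         " is too small to place ", n_cells,
         " non-overlapping nuclei of radius ", r,
         "; increase image_shape or reduce n_cells")
  structure(list(n_cells = as.integer(n_cells),
                 positive_fraction = positive_fraction,
                 nucleus_radius_px = nucleus_radius_px,
                 puncta_lambda = puncta_lambda,
                 puncta_range = as.integer(puncta_range),
                 punctum_diameter_px = as.integer(punctum_diameter_px),
                 punctum_intensity = punctum_intensity,
                 diffuse_intensity = diffuse_intensity,
                 nucleus_intensity = nucleus_intensity,
                 illumination_gradient_amplitude = illumination_gradient_amplitude,
                 noise_sd = noise_sd,
                 image_shape = as.integer(image_shape)),
            class = "field_spec")
}

# Dart-throwing placement of n points with pairwise distance >= min_dist,
# at least `margin` pixels from the border, using a bucket grid.
place_centers <- function(n, min_dist, ny, nx, margin) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  if (ny - 2 * margin < 1 || nx - 2 * margin < 1)
    stop("image too small for the requested margin")
  bucket <- max(min_dist, 1)
  nby <- ceiling(ny / bucket)
  nbx <- ceiling(nx / bucket)
  buckets <- vector("list", nby * nbx)
  pts <- matrix(NA_real_, n, 2L)
  placed <- 0L
  tries <- 0L
  max_tries <- 400L * n + 2000L
  d2 <- min_dist^2
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    y <- runif(1, margin + 1, ny - margin)
    x <- runif(1, margin + 1, nx - margin)
    by <- floor((y - 1) / bucket) + 1
    bx <- floor((x - 1) / bucket) + 1
    ok <- TRUE
    for (dby in -1:1) {
      b2y <- by + dby
      if (b2y < 1 || b2y > nby) next
      for (dbx in -1:1) {
        b2x <- bx + dbx
        if (b2x < 1 || b2x > nbx) next
        for (j in buckets[[(b2x - 1) * nby + b2y]]) {
          if ((pts[j, 1] - y)^2 + (pts[j, 2] - x)^2 < d2) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (!ok) break
    }
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- c(y, x)
      bi <- (bx - 1) * nby + by
      buckets[[bi]] <- c(buckets[[bi]], placed)
    }
  }
  if (placed < n)
    stop("could not place ", n, " non-overlapping nuclei (placed ", placed,
         "); a larger image_shape is needed")
  round(pts)
}

# Patch for a Gaussian-profile ellipse (truncated at its boundary).
# `r` is the maximum semi-axis, `q` >= 1 the axis ratio, `theta` orientation.
# Returns list(ys, xs, val); the caller adds the patch in place (this avoids
# copying the full field raster on every cell).
ellipse_patch <- function(ny, nx, cy, cx, r, q, theta, amp,
                          profile = c("gauss", "disk")) {
  profile <- match.arg(profile)
  ir <- ceiling(r)
  ys <- max(1L, cy - ir):min(ny, cy + ir)
  xs <- max(1L, cx - ir):min(nx, cx + ir)
  dy <- matrix(ys - cy, length(ys), length(xs))
  dx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  m <- (u / r)^2 + (v / (r / q))^2
  val <- if (profile == "gauss") amp * exp(-2 * m) else amp + 0 * m
  val[m > 1] <- 0
  list(ys = ys, xs = xs, val = val)
}

# Patch for a punctum: a flat disk of the given diameter with a ~1 px soft
# shoulder (a minimal stand-in for diffraction blur; profiles are flat-topped).
punctum_patch <- function(ny, nx, cy, cx, diameter, amp) {
  r <- diameter / 2
  ir <- ceiling(r + 1.5)
  ys <- max(1L, cy - ir):min(ny, cy + ir)
  xs <- max(1L, cx - ir):min(nx, cx + ir)
  dy <- matrix(ys - cy, length(ys), length(xs))
  dx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  d <- sqrt(dy^2 + dx^2)
  val <- amp * pmin(1, pmax(0, (r + 1.2 - d) / 1.2))
  list(ys = ys, xs = xs, val = val)
}

# Smooth low-order polynomial illumination surface with mean ~1 and peak
# fractional deviation `amp`; coefficients drawn from the current RNG stream.
illumination_surface <- function(ny, nx, amp) {
  if (amp <= 0) return(matrix(1, ny, nx))
  cf <- runif(5, -1, 1)
  yy <- matrix(seq_len(ny) / ny - 0.5, ny, nx)
  xx <- matrix(seq_len(nx) / nx - 0.5, ny, nx, byrow = TRUE)
  g <- cf[1] * yy + cf[2] * xx + cf[3] * yy * xx + cf[4] * yy^2 + cf[5] * xx^2
  g <- g - mean(g)
  mx <- max(abs(g))
  if (mx > 0) g <- g / mx * amp
  1 + g
}

#' Generate one synthetic two-channel field with ground truth
#'
#' Renders a nuclei channel (Gaussian-profile ellipses, axis ratio at most
#' 1.5) and a GFP channel (diffuse per-cell signal plus, in aggregate-positive
#' cells, 1-3 bright compact puncta) over a smooth multiplicative
#' illumination gradient with additive Gaussian noise. Every cell and punctum
#' is recorded in the returned ground truth. Output is deterministic for a
#' given `(spec, seed)`.
#'
#' Cells are placed with centres at least `2 * nucleus_radius_px + 2` pixels
#' apart, so nuclei never overlap. Whether a cell is positive is decided by
#' comparing a per-cell uniform draw with `positive_fraction`; the draw stream
#' is independent of the placement stream, so increasing `positive_fraction`
#' at a fixed seed only ever adds positive cells (monotone coupling).
#'
#' @param spec A [field_spec()].
#' @param seed Integer seed.
#' @return A list of class `agg_field` with elements `nuclei` and `gfp`
#'   (numeric matrices, AFU), and `truth`, itself a list with `cells` (data
#'   frame: `cell`, `row`, `col`, `positive`), `puncta` (data frame: `cell`,
#'   `row`, `col`, `diameter`), `n_positive` and `positive_fraction`.
#' @export
generate_field <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "field_spec"))
  ny <- spec$image_shape[1]
  nx <- spec$image_shape[2]
  nuc <- matrix(0, ny, nx)
  gfp <- matrix(0, ny, nx)
  r <- spec$nucleus_radius_px
  n <- spec$n_cells

  set.seed(derive_seed(seed, "placement"))
  centers <- place_centers(n, 2 * r + 2, ny, nx, margin = r + 1)
  grad_coef_seed <- derive_seed(seed, "illumination")

  set.seed(derive_seed(seed, "positivity"))
  upos <- if (n > 0) runif(n) else numeric(0)
  positive <- upos < spec$positive_fraction

  set.seed(derive_seed(seed, "render"))
  puncta <- list()
  if (n > 0) {
    qs <- runif(n, 1, 1.5)
    ths <- runif(n, 0, pi)
    amps <- spec$nucleus_intensity * runif(n, 0.8, 1.2)
    for (i in seq_len(n)) {
      p <- ellipse_patch(ny, nx, centers[i, 1], centers[i, 2], r, qs[i],
                         ths[i], amps[i])
      nuc[p$ys, p$xs] <- nuc[p$ys, p$xs] + p$val
      if (spec$diffuse_intensity > 0) {
        p <- ellipse_patch(ny, nx, centers[i, 1], centers[i, 2], r, 1, 0,
                           spec$diffuse_intensity, profile = "disk")
        gfp[p$ys, p$xs] <- gfp[p$ys, p$xs] + p$val
      }
    }
    for (i in which(positive)) {
      k <- rpois_truncated(1, spec$puncta_lambda, spec$puncta_range)
      pp <- place_puncta(k, centers[i, 1], centers[i, 2], r,
                         spec$punctum_diameter_px)
      for (j in seq_len(nrow(pp))) {
        p <- punctum_patch(ny, nx, pp[j, 1], pp[j, 2], pp[j, 3],
                           spec$punctum_intensity)
        gfp[p$ys, p$xs] <- gfp[p$ys, p$xs] + p$val
      }
      puncta[[length(puncta) + 1L]] <-
        data.frame(cell = i, row = pp[, 1], col = pp[, 2], diameter = pp[, 3])
    }
  }

  set.seed(grad_coef_seed)
  grad <- illumination_surface(ny, nx, spec$illumination_gradient_amplitude)
  nuc <- nuc * grad
  gfp <- gfp * grad
  if (spec$noise_sd > 0) {
    set.seed(derive_seed(seed, "noise"))
    nuc <- pmax(nuc + matrix(rnorm(ny * nx, 0, spec$noise_sd), ny, nx), 0)
    gfp <- pmax(gfp + matrix(rnorm(ny * nx, 0, spec$noise_sd), ny, nx), 0)
  }

  cells <- data.frame(cell = seq_len(n),
                      row = if (n) centers[, 1] else numeric(0),
                      col = if (n) centers[, 2] else numeric(0),
                      positive = positive,
                      nucleus_amp = if (n > 0) amps else numeric(0))
  puncta <- if (length(puncta)) do.call(rbind, puncta) else
    data.frame(cell = integer(0), row = numeric(0), col = numeric(0),
               diameter = numeric(0))
  structure(list(nuclei = nuc, gfp = gfp,
                 truth = list(cells = cells, puncta = puncta,
                              n_positive = sum(positive),
                              positive_fraction = spec$positive_fraction),
                 spec = spec, seed = seed),
            class = "agg_field")
}

# Truncated Poisson draw(s) on the integer interval [range[1], range[2]].
rpois_truncated <- function(n, lambda, range) {
  ks <- range[1]:range[2]
  p <- stats::dpois(ks, lambda)
  ks[sample.int(length(ks), n, replace = TRUE, prob = p)]
}

# Place k non-touching puncta (centres within 0.6 * cell radius of the cell
# centre; aggregates cluster near the nucleus/ER). Retries with shrunken
# diameters if a non-overlapping arrangement is not found.
place_puncta <- function(k, cy, cx, cell_radius, diam_range) {
  if (k == 0L) return(matrix(numeric(0), 0L, 3L))
  rmax <- 0.6 * cell_radius
  for (attempt in 1:40) {
    d <- sample(seq(diam_range[1], diam_range[2]), k, replace = TRUE)
    if (attempt > 20) d <- rep(diam_range[1], k)
    ang <- runif(k, 0, 2 * pi)
    rad <- sqrt(runif(k)) * rmax
    py <- round(cy + rad * sin(ang))
    px <- round(cx + rad * cos(ang))
    ok <- TRUE
    if (k > 1) {
      for (a in 1:(k - 1)) for (b in (a + 1):k) {
        if ((py[a] - py[b])^2 + (px[a] - px[b])^2 <
            (d[a] / 2 + d[b] / 2 + 2)^2) ok <- FALSE
      }
    }
    if (ok) return(cbind(py, px, d))
  }
  # Fall back to a single punctum at the cell centre.
  cbind(cy, cx, diam_range[1])
}

#' @export
print.agg_field <- function(x, ...) {
  cat("<agg_field> ", paste(dim(x$nuclei), collapse = "x"),
      " px, ", nrow(x$truth$cells), " cells (",
      x$truth$n_positive, " aggregate-positive)\n", sep = "")
  invisible(x)
}
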