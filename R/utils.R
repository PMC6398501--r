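# Internal helpers shared across modules.

#' Derive a reproducible sub-seed for a named random stream
#'
#' All randomness in the package flows from a single user seed; independent
#' stages (layout, field rendering, Monte-Carlo resampling, ...) draw from
#' sub-seeds derived deterministically from that seed and a stream name, so
#' that regenerating one stage never perturbs another.
#'
#' @param seed Integer seed.
#' @param stream Character stream name.
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @keywords internal
derive_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 65521 * 32361 + h * 17 + 1) %% 2147483647)
}

#' @keywords internal
clip01 <- function(x) pmin(pmax(x, 0), 1)

#' @keywords internal
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == round(x)

#' @keywords internal
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Odd-sized disc structuring element of a given pixel radius. Radii below 0.5
# give a single-pixel (no-op) element.
#' @keywords internal
disc_kernel <- function(radius_px) {
  size <- 2L * as.integer(round(radius_px)) + 1L
  if (size < 3L) return(matrix(1, 1L, 1L))
  EBImage::makeBrush(size, shape = "disc")
}

# Linear min-max rescale of a matrix onto [0, 255] (8-bit convention).
# A flat image maps to mid-range, by convention.
#' @keywords internal
rescale_8bit <- function(img) {
  rng <- range(img)
  if (rng[2] <= rng[1]) return(matrix(127.5, nrow(img), ncol(img)))
  (img - rng[1]) / (rng[2] - rng[1]) * 255
}

# Histogram-based automatic thresholds on a [0, 255] image. All return the
# threshold on the same scale as the input.
#' @keywords internal
auto_threshold <- function(img, method = c("triangle", "otsu", "isodata")) {
  method <- match.arg(method)
  v <- as.numeric(img)
  if (method == "otsu") {
    return(EBImage::otsu(EBImage::Image(v / 255), range = c(0, 1), levels = 256) * 255)
  }
  if (method == "isodata") {
    # Intermeans iteration seeded at the range midpoint (the ImageJ-style
    # default). With a bright sparse class present (puncta), the midpoint
    # seed converges to the fixed point between the dim mass (background +
    # diffuse signal) and the bright class, not to the background/diffuse
    # split that a mean-seeded iteration or Otsu finds.
    rng <- range(v)
    if (rng[2] <= rng[1]) return(rng[1])
    t_old <- -Inf
    t_new <- mean(rng)
    for (i in 1:100) {
      lo <- v[v <= t_new]
      hi <- v[v > t_new]
      if (!length(lo) || !length(hi)) break
      t_old <- t_new
      t_new <- (mean(lo) + mean(hi)) / 2
      if (abs(t_new - t_old) < 0.5) break
    }
    return(t_new)
  }
  # Triangle method: designed for a dominant background peak with a long
  # bright tail (puncta over diffuse signal). Works on a 256-bin histogram.
  h <- tabulate(pmin(pmax(floor(v) + 1L, 1L), 256L), nbins = 256L)
  peak <- which.max(h)
  last <- max(which(h > 0))
  if (last <= peak) return(peak - 1)
  bx <- peak:last
  # Distance from histogram points to the line joining the peak and the tail end.
  dx <- last - peak
  dy <- h[last] - h[peak]
  d <- abs(dy * (bx - peak) - dx * (h[bx] - h[peak])) / sqrt(dx^2 + dy^2)
  bx[which.max(d)] - 1
}

# Grayscale morphology on arbitrary intensity scales. EBImage's grayscale
# erode/dilate operate on [0, 1]; these wrappers rescale by the image maximum
# around the call.
#' @keywords internal
gray_erode <- function(img, kernel) {
  mx <- max(img)
  if (mx <= 0) return(img)
  EBImage::imageData(EBImage::erode(EBImage::Image(img / mx), kernel)) * mx
}

#' @keywords internal
gray_dilate <- function(img, kernel) {
  mx <- max(img)
  if (mx <= 0) return(img)
  EBImage::imageData(EBImage::dilate(EBImage::Image(img / mx), kernel)) * mx
}

#' @keywords internal
gray_opening <- function(img, kernel) {
  gray_dilate(gray_erode(img, kernel), kernel)
}

# Connected-component labelling over foreground linear indices of an array of
# dimension `dims`, using the full Moore neighbourhood (8-connectivity in 2D,
# 26-connectivity in 3D). Returns integer labels 1..K aligned with `fg_idx`.
# Implemented as vectorized minimum-label propagation with path halving.
#' @keywords internal
label_components_idx <- function(fg_idx, dims) {
  n <- length(fg_idx)
  if (n == 0L) return(integer(0))
  ord <- order(fg_idx)
  fg <- as.numeric(fg_idx[ord])
  co <- arrayInd(fg, dims)
  nd <- length(dims)
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  mult <- cumprod(c(1, dims[-nd]))
  nb <- matrix(NA_integer_, n, nrow(offs))
  dmat <- matrix(dims, n, nd, byrow = TRUE)
  for (k in seq_len(nrow(offs))) {
    nc <- sweep(co, 2, offs[k, ], "+")
    ok <- rowSums(nc >= 1L & nc <= dmat) == nd
    lin <- as.numeric((nc - 1) %*% mult) + 1
    lin[!ok] <- NA
    nb[, k] <- match(lin, fg)
  }
  lab <- seq_len(n)
  repeat {
    new <- lab
    for (k in seq_len(ncol(nb))) {
      m <- nb[, k]
      has <- which(!is.na(m))
      if (length(has)) new[has] <- pmin(new[has], new[m[has]])
    }
    new <- pmin(new, new[new])
    if (identical(new, lab)) break
    lab <- new
  }
  lab <- match(lab, sort(unique(lab)))
  out <- integer(n)
  out[ord] <- lab
  out
}

# Connected-component labelling of a binary matrix (8-connectivity), returned
# as an integer matrix with labels 1..K (0 = background).
#' @keywords internal
label_8conn <- function(mask) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask > 0)
  out[fg] <- label_components_idx(fg, dim(mask))
  out
}

# Pixel areas of each label in a label matrix (named integer vector).
#' @keywords internal
label_areas <- function(labels) {
  lab <- labels[labels > 0]
  if (!length(lab)) return(integer(0))
  tabulate(lab, nbins = max(lab))
}
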