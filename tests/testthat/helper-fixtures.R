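# Shared fixtures: everything is generated in code at test time.

# Down-scaled field: ~60 cells in a 192 px field, nucleus radius 6. The
# statistical structure (binomial positives, puncta, gradient, noise) matches
# the full-scale defaults; only the problem size is smaller.
small_spec <- function(...) {
  args <- modifyList(list(n_cells = 60L, nucleus_radius_px = 6,
                          image_shape = c(192L, 192L)), list(...))
  do.call(field_spec, args)
}

# Noise-free, gradient-free, diffuse-free variant for exact-recovery checks.
clean_spec <- function(...) {
  small_spec(noise_sd = 0, illumination_gradient_amplitude = 0,
             diffuse_intensity = 0, ...)
}

# Per-cell intensity sample of one synthetic control-like well: a mixture of
# punctate (bright) and diffuse-only (dim) cells, mirroring the screen's
# per-cell average intensities without rendering images.
sim_well_cells <- function(n = 150, positive_fraction = 0.85) {
  pos <- runif(n) < positive_fraction
  ifelse(pos, rnorm(n, 25, 8), abs(rnorm(n, 8, 1.5)))
}

sim_control_wells <- function(n_wells = 42, n_cells = 150) {
  out <- replicate(n_wells, sim_well_cells(n_cells), simplify = FALSE)
  names(out) <- sprintf("C%02d", seq_len(n_wells))
  out
}

# Brute-force two-sample KS oracle: |F_a - F_b| evaluated at every pooled
# data point (independent of the package implementation).
ks_oracle <- function(a, b) {
  t <- sort(unique(c(a, b)))
  fa <- ecdf(a)(t)
  fb <- ecdf(b)(t)
  max(abs(fa - fb))
}

# Grid of constant-amplitude Gaussian blobs under a known multiplicative
# quadratic gradient; used to measure illumination-correction residuals
# without per-cell amplitude noise.
gradient_test_field <- function(n_side = 12, spacing = 24, r = 6,
                                coef = c(0.5, -0.3, 0.2, 0.25, -0.2)) {
  n_px <- spacing * (n_side + 1)
  img <- matrix(0, n_px, n_px)
  centers <- as.matrix(expand.grid(row = spacing * seq_len(n_side),
                                   col = spacing * seq_len(n_side)))
  for (i in seq_len(nrow(centers))) {
    ys <- (centers[i, 1] - r):(centers[i, 1] + r)
    xs <- (centers[i, 2] - r):(centers[i, 2] + r)
    dy <- matrix(ys - centers[i, 1], length(ys), length(xs))
    dx <- matrix(xs - centers[i, 2], length(ys), length(xs), byrow = TRUE)
    m <- (dy^2 + dx^2) / r^2
    v <- 150 * exp(-2 * m)
    v[m > 1] <- 0
    img[ys, xs] <- img[ys, xs] + v
  }
  yy <- (row(img) - 1) / (n_px - 1) - 0.5
  xx <- (col(img) - 1) / (n_px - 1) - 0.5
  g <- coef[1] * yy + coef[2] * xx + coef[3] * yy * xx +
    coef[4] * yy^2 + coef[5] * xx^2
  g <- 1 + (g - mean(g))
  list(img = img * g, gradient = g, centers = centers)
}

# Relative fitted-plane range of blob peak heights across the field: the
# measured gradient amplitude seen by the downstream threshold.
peak_gradient_amplitude <- function(img, centers) {
  p <- vapply(seq_len(nrow(centers)), function(i) {
    max(img[(centers[i, 1] - 3):(centers[i, 1] + 3),
            (centers[i, 2] - 3):(centers[i, 2] + 3)])
  }, numeric(1))
  fv <- fitted(lm(p ~ centers[, 1] + centers[, 2]))
  (max(fv) - min(fv)) / mean(p)
}

# 3D array with one rectangular object of exactly `n_vox` voxels (a straight
# 1-voxel-thick rod, bent into layers if needed), at the given corner.
plant_block <- function(stack, n_vox, at = c(2L, 2L, 2L), value = 100) {
  d <- dim(stack)
  nx <- min(n_vox, d[3] - at[3])
  full <- n_vox %/% nx
  rem <- n_vox %% nx
  for (layer in seq_len(full))
    stack[at[1], at[2] + layer - 1L, at[3]:(at[3] + nx - 1L)] <- value
  if (rem > 0)
    stack[at[1], at[2] + full, at[3]:(at[3] + rem - 1L)] <- value
  stack
}
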