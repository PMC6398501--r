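#' Detect aggregates in a 3D confocal stack
#'
#' Thresholds the stack (by default at a high percentile of the stack's own
#' intensities, an explicit stand-in for the per-image manual threshold that
#' removes low-intensity tissue background), groups suprathreshold voxels by
#' 26-connectivity, and keeps components with voxel counts inside the
#' inclusive range `[min_vox, max_vox]` (objects over 1000 voxels and
#' "garbage" under 10 voxels are excluded).
#'
#' @param stack 3D numeric array `(z, y, x)`, or a `brain_stack` from
#'   [generate_brain_stack()].
#' @param threshold Numeric intensity threshold, or `"auto"` to use the
#'   `auto_percentile` quantile of the stack.
#' @param min_vox,max_vox Inclusive component size bounds, voxels.
#' @param auto_percentile Quantile used when `threshold = "auto"`.
#' @return Data frame of class `aggregate_objects`: `label`, `n_voxels`,
#'   `z`, `y`, `x` (voxel centroids), with the threshold used as attribute
#'   `threshold`. A threshold above the stack maximum yields zero objects.
#' @export
detect_aggregates_3d <- function(stack, threshold = "auto",
                                 min_vox = 10L, max_vox = 1000L,
                                 auto_percentile = 0.995) {
  if (inherits(stack, "brain_stack")) stack <- stack$stack
  stopifnot(is.array(stack), length(dim(stack)) == 3L,
            is_count(min_vox), is_count(max_vox), min_vox < max_vox)
  thr <- if (identical(threshold, "auto")) {
    as.numeric(stats::quantile(stack, auto_percentile))
  } else {
    stopifnot(is_number(threshold))
    threshold
  }
  fg <- which(stack > thr)
  empty <- data.frame(label = integer(0), n_voxels = integer(0),
                      z = numeric(0), y = numeric(0), x = numeric(0))
  if (!length(fg))
    return(structure(empty, threshold = thr, class = c("aggregate_objects",
                                                       "data.frame")))
  lab <- label_components_idx(fg, dim(stack))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_vox & sizes <= max_vox)
  if (!length(keep))
    return(structure(empty, threshold = thr, class = c("aggregate_objects",
                                                       "data.frame")))
  co <- arrayInd(fg, dim(stack))
  sel <- lab %in% keep
  lab2 <- match(lab[sel], keep)
  out <- data.frame(label = seq_along(keep),
                    n_voxels = as.integer(sizes[keep]),
                    z = as.numeric(tapply(co[sel, 1], lab2, mean)),
                    y = as.numeric(tapply(co[sel, 2], lab2, mean)),
                    x = as.numeric(tapply(co[sel, 3], lab2, mean)))
  structure(out, threshold = thr, class = c("aggregate_objects",
                                            "data.frame"))
}

#' Aggregation density over fixed ventral nerve cord ROIs
#'
#' Counts detected objects whose centroid falls inside each of the (congruent)
#' half-open ROI boxes `[lo, hi)`, and forms the per-animal density as the
#' mean per-ROI count divided by the single-ROI volume in cubic micrometres
#' (equivalently, total in-ROI objects over total ROI volume).
#'
#' @param objects A [detect_aggregates_3d()] result.
#' @param roi_boxes List of boxes as in [default_roi_boxes()]; all boxes must
#'   lie inside the stack that produced `objects`.
#' @param voxel_size_um Numeric (z, y, x) voxel size in micrometres.
#' @param stack_dim Optional stack dimensions for bounds checking.
#' @param animal_id Optional identifier carried into the record.
#' @return A list of class `density_record`: `animal_id`, `n_aggregates`
#'   (total in ROIs), `per_roi_counts`, `roi_volume_um3` (total over ROIs),
#'   `density` (aggregates per um^3).
#' @export
aggregation_density <- function(objects, roi_boxes,
                                voxel_size_um, stack_dim = NULL,
                                animal_id = NA_character_) {
  stopifnot(is.data.frame(objects), length(voxel_size_um) == 3L,
            all(voxel_size_um > 0), length(roi_boxes) >= 1)
  vols <- vapply(roi_boxes, function(b) prod(b$hi - b$lo), numeric(1))
  if (max(vols) - min(vols) > 1e-9 * max(vols))
    warning("ROI boxes are not congruent; using their mean volume")
  if (!is.null(stack_dim)) {
    for (b in roi_boxes) {
      if (any(b$lo < 1) || any(b$hi > stack_dim + 1))
        stop("ROI box [", paste(b$lo, collapse = ","), ") - [",
             paste(b$hi, collapse = ","), ") lies outside the stack")
    }
  }
  counts <- vapply(roi_boxes, function(b) {
    inb <- objects$z >= b$lo[1] & objects$z < b$hi[1] &
      objects$y >= b$lo[2] & objects$y < b$hi[2] &
      objects$x >= b$lo[3] & objects$x < b$hi[3]
    sum(inb)
  }, numeric(1))
  vol_um3 <- mean(vols) * prod(voxel_size_um)
  structure(list(animal_id = animal_id,
                 n_aggregates = as.integer(sum(counts)),
                 per_roi_counts = as.integer(counts),
                 roi_volume_um3 = vol_um3 * length(roi_boxes),
                 density = mean(counts) / vol_um3),
            class = "density_record")
}

#' Normalize aggregation densities to a control group and compare groups
#'
#' Normalizes each animal's density to the mean of the control group (so the
#' control group's mean normalized density is exactly 1) and runs the group
#' comparison: a two-sided Student's t-test for two groups, or a one-way
#' ANOVA followed by Fisher's LSD — unadjusted pairwise t-tests using the
#' pooled within-group variance — for more than two. LSD p-values are
#' reported unadjusted by construction; the output flags this.
#'
#' @param records Data frame with columns `animal_id`, `group`, `density`.
#' @param control_group Label of the control group.
#' @param test `"t_test"` or `"anova_lsd"` (default chooses by group count).
#' @return A list of class `density_comparison`: `records` (with
#'   `normalized` column), `anova` (data frame, or `NULL` for two groups),
#'   `comparisons` (pairwise table: `group1`, `group2`, `diff_normalized`,
#'   `statistic`, `df`, `p_value`, `method`), `control_group`, `note`.
#' @export
normalize_and_compare <- function(records, control_group,
                                  test = c("auto", "t_test", "anova_lsd")) {
  test <- match.arg(test)
  stopifnot(all(c("animal_id", "group", "density") %in% names(records)))
  if (!control_group %in% records$group)
    stop("control group '", control_group, "' not present in records")
  ctrl_mean <- mean(records$density[records$group == control_group])
  if (ctrl_mean <= 0)
    stop("control group mean density must be positive to normalize")
  records$normalized <- records$density / ctrl_mean

  sizes <- table(records$group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("groups with fewer than 2 animals excluded from tests: ",
            paste(small, collapse = ", "))
    test_rec <- records[!records$group %in% small, ]
  } else test_rec <- records
  groups <- unique(test_rec$group)
  k <- length(groups)
  if (test == "auto") test <- if (k <= 2) "t_test" else "anova_lsd"

  anova_tab <- NULL
  comparisons <- data.frame(group1 = character(0), group2 = character(0),
                            diff_normalized = numeric(0),
                            statistic = numeric(0), df = numeric(0),
                            p_value = numeric(0), method = character(0))
  if (k >= 2) {
    if (test == "t_test") {
      others <- setdiff(groups, control_group)
      comparisons <- do.call(rbind, lapply(others, function(g) {
        a <- test_rec$normalized[test_rec$group == g]
        b <- test_rec$normalized[test_rec$group == control_group]
        if (stats::sd(c(a, b)) == 0) {
          data.frame(group1 = g, group2 = control_group,
                     diff_normalized = mean(a) - mean(b), statistic = 0,
                     df = length(a) + length(b) - 2, p_value = 1,
                     method = "t_test", stringsAsFactors = FALSE)
        } else {
          tt <- stats::t.test(a, b, var.equal = TRUE)
          data.frame(group1 = g, group2 = control_group,
                     diff_normalized = mean(a) - mean(b),
                     statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p_value = tt$p.value,
                     method = "t_test", stringsAsFactors = FALSE)
        }
      }))
    } else {
      test_rec$group <- factor(test_rec$group)
      fit <- stats::aov(normalized ~ group, data = test_rec)
      sm <- summary(fit)[[1]]
      anova_tab <- data.frame(term = trimws(rownames(sm)),
                              df = sm$Df, sum_sq = sm$`Sum Sq`,
                              mean_sq = sm$`Mean Sq`,
                              f_value = sm$`F value`[1:nrow(sm)],
                              p_value = sm$`Pr(>F)`[1:nrow(sm)])
      mse <- sm$`Mean Sq`[2]
      dfr <- sm$Df[2]
      gl <- levels(test_rec$group)
      pairs <- utils::combn(gl, 2)
      comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
        g1 <- pairs[1, i]; g2 <- pairs[2, i]
        a <- test_rec$normalized[test_rec$group == g1]
        b <- test_rec$normalized[test_rec$group == g2]
        se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
        tv <- if (se > 0) (mean(a) - mean(b)) / se else 0
        data.frame(group1 = g1, group2 = g2,
                   diff_normalized = mean(a) - mean(b), statistic = tv,
                   df = dfr,
                   p_value = if (se > 0) 2 * stats::pt(-abs(tv), dfr) else 1,
                   method = "fisher_lsd", stringsAsFactors = FALSE)
      }))
    }
  }
  structure(list(records = records, anova = anova_tab,
                 comparisons = comparisons, control_group = control_group,
                 note = paste("Fisher's LSD p-values are unadjusted",
                              "pairwise t-tests on the pooled",
                              "within-group variance")),
            class = "density_comparison")
}

#' @export
print.density_comparison <- function(x, ...) {
  cat("Aggregation density, normalized to group '", x$control_group,
      "'\n", sep = "")
  means <- tapply(x$records$normalized, x$records$group, mean)
  for (g in names(means))
    cat(sprintf("  %-24s mean normalized density %.3f (n = %d)\n", g,
                means[[g]], sum(x$records$group == g)))
  if (!is.null(x$anova))
    cat(sprintf("  one-way ANOVA: F = %.3f, p = %.3g\n",
                x$anova$f_value[1], x$anova$p_value[1]))
  if (nrow(x$comparisons)) {
    cat("  comparisons (", x$comparisons$method[1], "):\n", sep = "")
    for (i in seq_len(nrow(x$comparisons)))
      cat(sprintf("    %s vs %s: diff %.3f, p = %.3g\n",
                  x$comparisons$group1[i], x$comparisons$group2[i],
                  x$comparisons$diff_normalized[i],
                  x$comparisons$p_value[i]))
  }
  invisible(x)
}
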