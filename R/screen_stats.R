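#' Signed two-sample Kolmogorov-Smirnov statistic
#'
#' `D = F_sample(t*) - F_reference(t*)` evaluated at the point `t*` of the
#' pooled support that maximizes `|F_sample - F_reference|`. A positive value
#' means the sample is stochastically smaller than the reference (lower
#' intensities: the suppressor direction); `|D|` equals the classical
#' two-sample KS statistic.
#'
#' @param sample,reference Non-empty numeric vectors of per-cell values.
#' @return Signed statistic in `[-1, 1]`.
#' @export
ks_statistic <- function(sample, reference) {
  if (!length(sample) || !length(reference))
    stop("ks_statistic needs non-empty sample and reference")
  ks_signed_sorted(sort(sample), sort(reference))
}

# Core of ks_statistic over pre-sorted inputs (hot path for the Monte-Carlo
# resampling loop).
ks_signed_sorted <- function(s, r) {
  t <- c(s, r)
  fs <- findInterval(t, s) / length(s)
  fr <- findInterval(t, r) / length(r)
  d <- fs - fr
  d[which.max(abs(d))]
}

#' Per-well KS statistics against the pooled plate controls
#'
#' For every well of one plate, computes the signed KS statistic between the
#' well's per-cell values and the pool of all control-well cells on the same
#' plate. Control wells are compared leave-one-out (their own cells are
#' excluded from the pool), so control and gene wells are measured against
#' statistically equivalent references.
#'
#' @param cells Data frame of per-cell features with at least columns `well`
#'   and the value column named by `parameter` (e.g. `avg_intensity`,
#'   `total_intensity`).
#' @param platemap Data frame with columns `well`, `role`, `gene_id`,
#'   `replicate` for one plate.
#' @param parameter Name of the per-cell value column.
#' @return Data frame of class `well_stats` with columns `well`, `role`,
#'   `gene_id`, `replicate`, `n_cells`, `ks` (and attribute `parameter`).
#' @export
well_ks_table <- function(cells, platemap, parameter = "avg_intensity") {
  stopifnot(parameter %in% names(cells), "well" %in% names(cells))
  ctrl_wells <- platemap$well[platemap$role == "control"]
  if (!length(ctrl_wells)) stop("platemap has no control wells")
  vals <- split(cells[[parameter]], cells$well)
  ctrl_list <- vals[intersect(ctrl_wells, names(vals))]
  if (!length(ctrl_list)) stop("no cells found in any control well")
  out <- platemap[, c("well", "role", "gene_id", "replicate")]
  out$n_cells <- vapply(out$well,
                        function(w) length(vals[[w]]), integer(1))
  out$ks <- NA_real_
  pool_all <- sort(unlist(ctrl_list, use.names = FALSE))
  for (i in seq_len(nrow(out))) {
    w <- out$well[i]
    v <- vals[[w]]
    if (is.null(v) || !length(v)) next
    ref <- if (out$role[i] == "control" && w %in% names(ctrl_list)) {
      sort(unlist(ctrl_list[names(ctrl_list) != w], use.names = FALSE))
    } else pool_all
    out$ks[i] <- ks_signed_sorted(sort(v), ref)
  }
  attr(out, "parameter") <- parameter
  class(out) <- c("well_stats", "data.frame")
  out
}

# Robust null location/scale from control-well KS statistics.
control_null_stats <- function(ks_controls) {
  m <- stats::median(ks_controls)
  s <- stats::mad(ks_controls)  # already scaled by 1.4826
  if (s <= 0)
    stop("degenerate control null: all control KS statistics are identical ",
         "(zero scale)")
  list(location = m, scale = s)
}

#' Plate Z-scores from robust control normalization
#'
#' Estimates the null location and scale of the per-well KS statistic from
#' the same plate's control wells (median and MAD of their leave-one-out
#' statistics) and standardizes every well:
#' `z = (D - median_null) / (1.4826 * MAD_null)`.
#'
#' @param well_stats A [well_ks_table()] result.
#' @param min_controls Minimum number of control wells required (default 8).
#' @return The input with a `z` column filled in.
#' @export
zscore_plate <- function(well_stats, min_controls = 8L) {
  stopifnot(inherits(well_stats, "well_stats") || is.data.frame(well_stats))
  ctrl <- well_stats$ks[well_stats$role == "control" &
                          !is.na(well_stats$ks)]
  if (length(ctrl) < min_controls)
    stop("plate Z-scores need at least ", min_controls,
         " control wells with cells; found ", length(ctrl))
  null <- control_null_stats(ctrl)
  well_stats$z <- (well_stats$ks - null$location) / null$scale
  attr(well_stats, "null") <- null
  well_stats
}

#' Monte-Carlo threshold for the two-of-three hit rule
#'
#' Simulates null pseudo-genes from the plate's control wells and returns the
#' `(1 - alpha)` quantile of the pseudo-gene statistic as the Z-score
#' threshold. Each pseudo-gene is a triplicate of distinct control wells
#' (wells drawn without replacement within a pseudo-triplicate); each chosen
#' well contributes a bootstrap resample of its own cells, whose KS statistic
#' against the pooled remaining controls is standardized with the plate's
#' null location/scale. The pseudo-gene statistic is the second-largest
#' `|z|` of the triplicate — the order statistic the two-of-three decision
#' rule actually thresholds. Cell-level bootstrap smoothing is essential:
#' with well-level resampling alone the simulated null would be capped at
#' the second-largest observed control `|z|`, and the threshold could not be
#' calibrated to small `alpha`.
#'
#' @param control_cells Named list of numeric vectors: per-cell values of
#'   each control well of one plate.
#' @param n_sim Number of simulated pseudo-genes (>= 1000 recommended).
#' @param alpha Target per-gene false-positive probability.
#' @param seed Integer seed.
#' @return A list of class `threshold_result`: `z_threshold`, `alpha`,
#'   `n_sim`, `seed`, `null` (location/scale used), and `sim` (the simulated
#'   pseudo-gene statistics).
#' @export
monte_carlo_threshold <- function(control_cells, n_sim = 5000L,
                                  alpha = 0.001, seed = 1L) {
  stopifnot(is.list(control_cells), is_count(n_sim), n_sim >= 1,
            is_number(alpha), alpha > 0, alpha <= 1)
  nw <- length(control_cells)
  if (nw < 4L)
    stop("Monte-Carlo threshold needs at least 4 control wells, got ", nw)
  sizes <- lengths(control_cells)
  if (any(sizes == 0)) stop("every control well must contain cells")
  sorted <- lapply(control_cells, sort)
  # Leave-one-out references and observed control statistics.
  loo_ref <- vector("list", nw)
  d_obs <- numeric(nw)
  for (w in seq_len(nw)) {
    loo_ref[[w]] <- sort(unlist(sorted[-w], use.names = FALSE))
    d_obs[w] <- ks_signed_sorted(sorted[[w]], loo_ref[[w]])
  }
  null <- control_null_stats(d_obs)

  set.seed(derive_seed(seed, "monte_carlo"))
  stat <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    wells <- sample.int(nw, 3L)
    zs <- numeric(3L)
    for (j in 1:3) {
      w <- wells[j]
      boot <- sort(sample(control_cells[[w]], sizes[w], replace = TRUE))
      d <- ks_signed_sorted(boot, loo_ref[[w]])
      zs[j] <- (d - null$location) / null$scale
    }
    stat[i] <- sort(abs(zs), partial = 2)[2]
  }
  structure(list(z_threshold = as.numeric(stats::quantile(stat, 1 - alpha)),
                 alpha = alpha, n_sim = as.integer(n_sim),
                 seed = as.integer(seed), null = null, sim = stat),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo |z| threshold %.3f (alpha = %g, %d simulations)\n",
              x$z_threshold, x$alpha, x$n_sim))
  invisible(x)
}

#' Call hits under the two-of-three replicate rule
#'
#' A gene is a hit when at least `min_hits` of its replicate wells have
#' `|z|` above the threshold. Direction comes from the signs of the
#' qualifying replicates: all positive (stochastically smaller intensities)
#' is a suppressor, all negative an enhancer, disagreement is mixed.
#'
#' @param well_z Data frame with columns `gene_id`, `replicate`, `z` (gene
#'   wells of one plate/parameter; e.g. a [zscore_plate()] result filtered to
#'   `role == "gene"`).
#' @param z_threshold Numeric threshold on `|z|` (or a `threshold_result`).
#' @param min_hits Minimum qualifying replicates (default 2).
#' @return Data frame of class `hit_calls`: `gene_id`, `n_replicates`,
#'   `n_above`, `is_hit`, `direction`, and the replicate z-values `z1..zK`.
#' @export
call_hits <- function(well_z, z_threshold, min_hits = 2L) {
  if (inherits(z_threshold, "threshold_result"))
    z_threshold <- z_threshold$z_threshold
  stopifnot(is_number(z_threshold), is_count(min_hits), min_hits >= 1,
            all(c("gene_id", "z") %in% names(well_z)))
  genes <- split(well_z, well_z$gene_id)
  short <- names(genes)[vapply(genes, nrow, integer(1)) < min_hits |
                          vapply(genes, function(g) any(is.na(g$z)),
                                 logical(1))]
  if (length(short)) {
    warning("skipping genes with missing replicate z-values: ",
            paste(short, collapse = ", "))
    genes <- genes[setdiff(names(genes), short)]
  }
  kmax <- if (length(genes)) max(vapply(genes, nrow, integer(1))) else 0L
  rows <- lapply(genes, function(g) {
    z <- g$z[order(g$replicate)]
    above <- abs(z) > z_threshold
    n_above <- sum(above)
    dir <- if (n_above == 0) NA_character_
    else if (all(z[above] > 0)) "suppressor"
    else if (all(z[above] < 0)) "enhancer"
    else "mixed"
    zp <- c(z, rep(NA_real_, kmax - length(z)))
    out <- data.frame(gene_id = g$gene_id[1],
                      n_replicates = length(z),
                      n_above = n_above,
                      is_hit = n_above >= min_hits,
                      direction = dir, stringsAsFactors = FALSE)
    for (j in seq_len(kmax)) out[[paste0("z", j)]] <- zp[j]
    out
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), n_replicates = integer(0),
               n_above = integer(0), is_hit = logical(0),
               direction = character(0))
  rownames(out) <- NULL
  attr(out, "z_threshold") <- z_threshold
  attr(out, "min_hits") <- as.integer(min_hits)
  class(out) <- c("hit_calls", "data.frame")
  out
}

#' False-positive and false-negative rates against planted truth
#'
#' @param hits A [call_hits()] result (or data frame with `gene_id`,
#'   `is_hit`).
#' @param true_modifiers Character vector of genes planted as modifiers.
#' @return A list of class `error_rates`: `fp_rate` (called-hit nulls over
#'   nulls), `fn_rate` (missed modifiers over modifiers; `NA` when no
#'   modifiers were planted), `n_null`, `n_modifier`.
#' @export
estimate_error_rates <- function(hits, true_modifiers = character(0)) {
  stopifnot(all(c("gene_id", "is_hit") %in% names(hits)))
  is_mod <- hits$gene_id %in% true_modifiers
  n_null <- sum(!is_mod)
  n_mod <- sum(is_mod)
  fp <- if (n_null > 0) sum(hits$is_hit[!is_mod]) / n_null else NA_real_
  fn <- if (n_mod > 0) sum(!hits$is_hit[is_mod]) / n_mod else NA_real_
  structure(list(fp_rate = fp, fn_rate = fn,
                 n_null = n_null, n_modifier = n_mod),
            class = "error_rates")
}

#' Per-category percentage of screened genes called as targets
#'
#' @param hit_genes Character vector of genes called as hits.
#' @param categories Data frame with columns `gene_id`, `category` listing
#'   every screened gene and its category.
#' @return Data frame `category`, `n_screened`, `n_hits`, `percent`.
#' @export
category_summary <- function(hit_genes, categories) {
  stopifnot(all(c("gene_id", "category") %in% names(categories)))
  missing <- setdiff(hit_genes, categories$gene_id)
  if (length(missing))
    stop("hit genes without a category: ", paste(missing, collapse = ", "))
  cats <- sort(unique(categories$category))
  n_scr <- vapply(cats, function(cc)
    sum(categories$category == cc), integer(1))
  n_hit <- vapply(cats, function(cc)
    sum(categories$gene_id[categories$category == cc] %in% hit_genes),
    integer(1))
  data.frame(category = cats, n_screened = n_scr, n_hits = n_hit,
             percent = 100 * n_hit / n_scr, row.names = NULL)
}
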