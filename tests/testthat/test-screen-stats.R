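# KS statistic, plate Z-scores, Monte-Carlo thresholds and hit calls.

test_that("the signed KS statistic matches its definition on small cases", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(1:5, 6:10), 1)      # sample entirely below
  expect_equal(ks_statistic(6:10, 1:5), -1)
  expect_equal(abs(ks_statistic(c(1, 2, 3), c(2, 3, 4))), 1 / 3,
               tolerance = 1e-12)
  expect_error(ks_statistic(numeric(0), 1:3), "non-empty")
})

test_that("|KS| equals the brute-force oracle on 200 random instances", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    m <- sample(2:50, 1)
    if (i %% 2 == 0) {              # integer draws force ties
      a <- sample(1:8, n, replace = TRUE)
      b <- sample(1:8, m, replace = TRUE)
    } else {
      a <- rnorm(n)
      b <- rnorm(m, 0.5)
    }
    expect_equal(abs(ks_statistic(a, b)), ks_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("KS is invariant under strictly increasing transforms", {
  set.seed(7)
  for (i in 1:25) {
    a <- rnorm(30)
    b <- rnorm(40, 0.3)
    d0 <- ks_statistic(a, b)
    expect_identical(d0, ks_statistic(exp(a), exp(b)))
    expect_identical(d0, ks_statistic(2 * a + 7, 2 * b + 7))
  }
})

test_that("plate z-scores are calibrated under the null", {
  set.seed(1)
  meds <- numeric(10)
  spreads <- numeric(10)
  for (p in 1:10) {
    wells <- c(sim_control_wells(42, 150),
               setNames(replicate(60, sim_well_cells(150), simplify = FALSE),
                        sprintf("G%02d", 1:60)))
    cells <- data.frame(well = rep(names(wells), lengths(wells)),
                        avg_intensity = unlist(wells))
    platemap <- data.frame(well = names(wells),
                           role = rep(c("control", "gene"), c(42, 60)),
                           gene_id = c(rep(NA, 42), sprintf("g%02d", 1:60)),
                           replicate = 1L)
    ws <- zscore_plate(well_ks_table(cells, platemap))
    gz <- ws$z[ws$role == "gene"]
    meds[p] <- median(gz)
    spreads[p] <- mad(gz)
  }
  expect_lt(abs(mean(meds)), 0.15)
  expect_lt(abs(mean(spreads) - 1), 0.15)
})

test_that("z-score edge cases behave as defined", {
  ws <- data.frame(well = sprintf("W%02d", 1:10),
                   role = c(rep("control", 9), "gene"),
                   gene_id = c(rep(NA, 9), "g1"), replicate = 1L,
                   n_cells = 100L,
                   ks = c(0.10, 0.12, 0.08, 0.11, 0.09, 0.13, 0.07,
                          0.115, 0.105, 0.105))
  # control null median is the 5th of the 9 sorted control values: 0.105
  class(ws) <- c("well_stats", "data.frame")
  out <- zscore_plate(ws)
  expect_equal(out$z[10], 0)                  # gene at the null median

  few <- ws[c(1:5, 10), ]
  expect_error(zscore_plate(few), "at least 8")

  degen <- ws
  degen$ks <- 0.1
  expect_error(zscore_plate(degen), "zero scale")
})

test_that("hit calls implement the two-of-three rule with direction", {
  t0 <- 2.5
  zdf <- function(z) data.frame(gene_id = "g1", replicate = 1:3, z = z)
  h <- call_hits(zdf(c(t0 + 1, t0 + 1, t0 - 1)), t0)
  expect_true(h$is_hit)
  expect_equal(h$n_above, 2L)
  expect_equal(h$direction, "suppressor")

  expect_false(call_hits(zdf(c(t0 + 1, t0 - 1, t0 - 1)), t0)$is_hit)

  enh <- call_hits(zdf(c(-t0 - 1, -t0 - 1, 0)), t0)
  expect_true(enh$is_hit)
  expect_equal(enh$direction, "enhancer")

  mix <- call_hits(zdf(c(t0 + 1, -t0 - 1, t0 + 2)), t0)
  expect_equal(mix$direction, "mixed")
})

test_that("hit calls ignore replicate order and warn on missing z-values", {
  z <- c(3.1, -0.2, 2.9)
  a <- call_hits(data.frame(gene_id = "g", replicate = 1:3, z = z), 2.5)
  b <- call_hits(data.frame(gene_id = "g", replicate = c(3, 1, 2),
                            z = z[c(3, 1, 2)]), 2.5)
  expect_equal(a$is_hit, b$is_hit)
  expect_equal(a$n_above, b$n_above)
  expect_equal(a[, c("z1", "z2", "z3")], b[, c("z1", "z2", "z3")])

  expect_warning(
    out <- call_hits(data.frame(gene_id = c("g1", "g1", "g1", "g2"),
                                replicate = c(1:3, 1),
                                z = c(3, 3, 3, 9)), 2.5),
    "missing replicate")
  expect_equal(out$gene_id, "g1")
})

test_that("Monte-Carlo thresholds respect quantile semantics", {
  set.seed(3)
  ctrl <- sim_control_wells(12, 80)
  t_all <- monte_carlo_threshold(ctrl, n_sim = 400, alpha = 1, seed = 5)
  expect_equal(t_all$z_threshold, min(t_all$sim))

  t_strict <- monte_carlo_threshold(ctrl, n_sim = 400, alpha = 0.01, seed = 5)
  t_loose <- monte_carlo_threshold(ctrl, n_sim = 400, alpha = 0.1, seed = 5)
  expect_gte(t_strict$z_threshold, t_loose$z_threshold)

  expect_error(monte_carlo_threshold(ctrl[1:3], 100, 0.05, 1), "at least 4")

  # determinism
  t2 <- monte_carlo_threshold(ctrl, n_sim = 400, alpha = 0.01, seed = 5)
  expect_identical(t_strict$z_threshold, t2$z_threshold)
})

test_that("the threshold is calibrated against held-out null pseudo-genes", {
  set.seed(11)
  ctrl <- sim_control_wells(42, 150)
  thr <- monte_carlo_threshold(ctrl, n_sim = 5000, alpha = 0.001, seed = 7)
  pool <- sort(unlist(ctrl, use.names = FALSE))
  null <- thr$null
  fresh <- replicate(2000, {
    zs <- vapply(1:3, function(j) {
      d <- ks_statistic(sim_well_cells(150), pool)
      (d - null$location) / null$scale
    }, numeric(1))
    sort(abs(zs))[2]
  })
  expect_lte(mean(fresh > thr$z_threshold), 0.002)
})

test_that("error rates are computed against the planted truth", {
  hits <- data.frame(gene_id = sprintf("g%02d", 1:20),
                     is_hit = c(rep(TRUE, 8), rep(FALSE, 12)))
  er <- estimate_error_rates(hits, true_modifiers = sprintf("g%02d", 1:10))
  expect_equal(er$fp_rate, 0)
  expect_equal(er$fn_rate, 2 / 10)

  none <- estimate_error_rates(transform(hits, is_hit = FALSE),
                               sprintf("g%02d", 1:10))
  expect_equal(none$fp_rate, 0)
  expect_equal(none$fn_rate, 1)

  no_truth <- estimate_error_rates(hits)
  expect_true(is.na(no_truth$fn_rate))
})

test_that("category summaries are percentages of screened genes", {
  cats <- data.frame(gene_id = sprintf("g%02d", 1:30),
                     category = rep(c("ALS", "UPS", "lipid"), each = 10))
  cs <- category_summary(sprintf("g%02d", 1:5), cats)
  expect_equal(cs$percent[cs$category == "ALS"], 50)
  expect_equal(cs$percent[cs$category == "UPS"], 0)

  empty <- category_summary(character(0), cats)
  expect_true(all(empty$percent == 0))

  expect_error(category_summary("unknown_gene", cats), "without a category")
})

test_that("two-parameter hit sets combine by union and intersection", {
  fake <- list(
    avg = list(hits = data.frame(gene_id = c("a", "b", "c"),
                                 is_hit = c(TRUE, TRUE, FALSE))),
    tot = list(hits = data.frame(gene_id = c("a", "b", "c"),
                                 is_hit = c(TRUE, FALSE, TRUE))))
  expect_equal(hit_genes(fake, "any"), c("a", "b", "c"))
  expect_equal(hit_genes(fake, "all"), "a")
  expect_equal(hit_genes(fake, "avg"), c("a", "b"))
})
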