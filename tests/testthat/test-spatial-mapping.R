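test_that("structure-cluster cross-tabulation is exact and keeps empty structures", {
  st <- toy_structures(c("s1", "s2"))
  cells <- data.frame(cell_id = c("m1", "m2", "m3"),
                      cluster_id = c("c1", "c1", "c2"),
                      structure_id = "s1", stringsAsFactors = FALSE)
  comp <- structure_cluster_counts(cells, st)
  expect_equal(comp$counts["s1", "c1"], 2L)
  expect_equal(comp$counts["s1", "c2"], 1L)
  expect_equal(sum(comp$counts["s2", ]), 0L)   # empty structure retained

  # unknown-cluster cells are excluded with a logged count
  tax <- data.frame(cluster_id = c("c1", "c2"))
  cells2 <- rbind(cells, data.frame(cell_id = "m4", cluster_id = "cX",
                                    structure_id = "s2"))
  expect_message(comp2 <- structure_cluster_counts(cells2, st, tax), "1 spatial")
  expect_equal(sum(comp2$counts), 3L)
  expect_error(structure_cluster_counts(cells, st[0, ]), "empty")
})

test_that("cross-tabulation equals a brute-force nested loop on simulated data", {
  cfg <- sim_config(n_clusters = 8, seed = 31, whole_brain_density = 300)
  tax <- simulate_taxonomy(cfg)
  sp <- simulate_spatial_dataset(cfg, tax)
  comp <- structure_cluster_counts(sp$cells, sp$structures, tax)
  for (s in sp$structures$structure_id) {
    for (cl in tax$cluster_id) {
      manual <- 0
      for (i in seq_len(nrow(sp$cells))) {
        if (sp$cells$structure_id[i] == s && sp$cells$cluster_id[i] == cl) {
          manual <- manual + 1
        }
      }
      expect_identical(comp$counts[s, cl], as.integer(manual))
    }
  }
})

test_that("apportionment floors each per-cluster contribution before summing", {
  st <- toy_structures("s1")
  comp <- structure_cluster_counts(
    data.frame(cell_id = sprintf("m%02d", 1:14),
               cluster_id = rep(c("c1", "c2"), c(10, 4)),
               structure_id = "s1"), st)
  stats <- data.frame(cluster_id = c("c1", "c2"),
                      p_a = c(0.25, 0.5), p_b = c(0.25, 0.5),
                      p_ab = c(0.25, 0.5))
  # 10 x 0.25 -> floor(2.5) = 2;  plus 4 x 0.5 -> floor(2.0) = 2;  total 4
  est <- apportion(comp, stats)
  expect_equal(est$est_ab, 4L)
  # one-cluster case: floor(2.5) = 2
  stats1 <- stats[1, ]
  expect_message(est1 <- apportion(comp, stats1), "contribute zero")
  expect_equal(est1$est_ab, 2L)
  # the alternative reading floors once after summing: floor(2.5 + 2.0) = 4
  # distinguishable with fractions 0.25 and 0.35 on 10 + 10 cells
  comp2 <- structure_cluster_counts(
    data.frame(cell_id = sprintf("m%02d", 1:20),
               cluster_id = rep(c("c1", "c2"), each = 10),
               structure_id = "s1"), st)
  stats2 <- data.frame(cluster_id = c("c1", "c2"), p_a = c(0.25, 0.35),
                       p_b = c(0.25, 0.35), p_ab = c(0.25, 0.35))
  expect_equal(apportion(comp2, stats2)$est_ab, 5L)                  # 2 + 3
  expect_equal(apportion(comp2, stats2, round = "after_sum")$est_ab, 6L)  # floor(6.0)
  expect_error(apportion(comp2, transform(stats2, p_a = -0.1)), "negative")
})

test_that("apportionment is monotone in the fractions with floor bias bounded by cluster count", {
  set.seed(41)
  st <- toy_structures(c("s1", "s2", "s3"))
  cells <- data.frame(cell_id = sprintf("m%03d", 1:600),
                      cluster_id = sample(paste0("c", 1:12), 600, TRUE),
                      structure_id = sample(st$structure_id, 600, TRUE))
  comp <- structure_cluster_counts(cells, st)
  for (rep in 1:20) {
    p <- runif(12)
    stats <- data.frame(cluster_id = paste0("c", 1:12), p_a = p, p_b = p,
                        p_ab = p)
    est <- apportion(comp, stats)
    p_aligned <- p[match(colnames(comp$counts), stats$cluster_id)]
    exact <- as.numeric(comp$counts %*% p_aligned)
    n_contrib <- rowSums(comp$counts > 0)
    expect_true(all(exact - est$est_ab >= -1e-6))          # floor never overshoots
    expect_true(all(exact - est$est_ab < n_contrib + 1e-6)) # bias < cluster count
    # raising one cluster's fraction never lowers any estimate
    p2 <- p; j <- sample(12, 1); p2[j] <- min(1, p2[j] + runif(1))
    est2 <- apportion(comp, transform(stats, p_ab = p2))
    expect_true(all(est2$est_ab >= est$est_ab))
  }
})

test_that("partial-volume correction divides by the covered fraction", {
  st <- toy_structures(c("s1", "s2"), covered = c(0.5, 1))
  cells <- data.frame(cell_id = sprintf("m%03d", 1:200),
                      cluster_id = "c1",
                      structure_id = rep(c("s1", "s2"), each = 100))
  comp <- structure_cluster_counts(cells, st)
  stats <- data.frame(cluster_id = "c1", p_a = 0.5, p_b = 0.5, p_ab = 0.5)
  corr <- partial_volume_correct(apportion(comp, stats), comp)
  expect_equal(corr$corr_ab[corr$structure_id == "s1"], 100)  # 50 / 0.5
  expect_equal(corr$corr_ab[corr$structure_id == "s2"], 50)   # fraction 1 identity
})

test_that("a structure sampled at fraction 0.25 recovers its full count after correction", {
  st <- toy_structures(c("part", "full"), volume = 5, covered = c(0.25, 1))
  w <- matrix(0.5, 2, 2)
  cfg <- sim_config(n_clusters = 2, seed = 33, structures = st, mixtures = w,
                    whole_brain_density = 2e5,
                    gene_rates = data.frame(cluster_id = c("c001", "c002"),
                                            p_a = c(0.4, 0.2),
                                            p_b = c(0.8, 0.6), odds = 1),
                    cells_per_cluster_mu = 5000, cells_per_cluster_size = 1e9)
  study <- simulate_paired(cfg)
  res <- run_pipeline(study)
  corr <- res$corrected
  part <- corr$corr_ab[corr$structure_id == "part"]
  full <- corr$corr_ab[corr$structure_id == "full"]
  # identical structures: corrected counts agree within sampling error
  se <- sqrt(full) * sqrt(1 + 1 / 0.25)
  expect_lt(abs(part - full), 4 * se)
})

test_that("through-origin calibration matches the closed form and a brute-force minimizer", {
  one <- calibrate(data.frame(estimated_count = 100, literature_count = 200))
  expect_equal(one$k, 2)
  two <- calibrate(data.frame(estimated_count = c(100, 50),
                              literature_count = c(200, 100)))
  expect_equal(two$k, 2)
  set.seed(51)
  est <- runif(7, 50, 5000)
  lit <- 20 * est * exp(rnorm(7, 0, 0.2))
  fit <- calibrate(data.frame(estimated_count = est, literature_count = lit))
  # independent 1-D minimization of the squared error
  oracle <- optimize(function(k) sum((lit - k * est)^2),
                     interval = c(0, 1000), tol = 1e-10)$minimum
  expect_equal(fit$k, oracle, tolerance = 1e-6)
  expect_error(calibrate(data.frame(estimated_count = c(0, 0),
                                    literature_count = c(1, 2))), "zero")
})

test_that("whole-brain scaling multiplies and rounds half away from zero", {
  corr <- data.frame(structure_id = c("s1", "s2"), region_id = "R1",
                     n_cells = c(10L, 10L), est_a = c(1L, 3L),
                     est_b = c(2L, 4L), est_ab = c(1L, 2L),
                     covered_fraction = 1,
                     corr_a = c(100, 3), corr_b = c(2, 4),
                     corr_ab = c(100.25, 2.5))
  m2 <- calibrate(data.frame(estimated_count = 100, literature_count = 200))
  wb <- whole_brain_estimate(corr, m2)
  expect_equal(wb$wb_a, c(200L, 6L))
  expect_equal(wb$wb_ab, c(201L, 5L))   # 200.5 -> 201 (half away from zero)
  m1 <- calibrate(data.frame(estimated_count = 1, literature_count = 1))
  expect_equal(whole_brain_estimate(corr, m1)$wb_a, c(100L, 3L))  # k = 1 identity
})
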