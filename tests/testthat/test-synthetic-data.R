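test_that("taxonomy generation is seeded, labelled and validated", {
  cfg1 <- sim_config(n_clusters = 1, seed = 0)
  tax1 <- simulate_taxonomy(cfg1)
  expect_equal(nrow(tax1), 1)
  expect_true(tax1$class_label %in% c("neuron", "non-neuron"))
  expect_true(tax1$neurotransmitter %in% nt_categories())

  cfg <- sim_config(n_clusters = 50, seed = 1)
  tax_a <- simulate_taxonomy(cfg)
  tax_b <- simulate_taxonomy(cfg)
  expect_identical(tax_a, tax_b)                       # determinism
  expect_equal(anyDuplicated(tax_a$cluster_id), 0L)    # 50 unique ids
  expect_true(all(tax_a$neurotransmitter[tax_a$class_label == "non-neuron"]
                  == "none"))
  expect_true(all(tax_a$p_ab <= pmin(tax_a$p_a, tax_a$p_b) + 1e-12))
  expect_error(sim_config(n_clusters = 0), "n_clusters")
})

test_that("odds multiplier maps marginals to a consistent joint probability", {
  expect_equal(joint_positive_prob(0.3, 0.6, 1), 0.18)    # independence
  expect_equal(joint_positive_prob(0.3, 0.6, 0), 0)       # exclusion
  expect_equal(joint_positive_prob(0, 0.6, 5), 0)         # degenerate marginal
  # enrichment: recompute the odds ratio from the implied 2x2 table
  p11 <- joint_positive_prob(0.3, 0.6, 4)
  p10 <- 0.3 - p11; p01 <- 0.6 - p11; p00 <- 1 - 0.3 - 0.6 + p11
  expect_equal(p11 * p00 / (p10 * p01), 4, tolerance = 1e-10)
  expect_lte(p11, 0.3)
  expect_error(joint_positive_prob(0.3, 0.6, -1), "odds")
})

test_that("deep generator honours degenerate and independent rates", {
  n <- 5000
  rates <- data.frame(cluster_id = c("z", "ind"),
                      p_a = c(0, 0.3), p_b = c(0.5, 0.6), odds = c(1, 1))
  cfg <- sim_config(n_clusters = 2, seed = 3, gene_rates = rates,
                    cells_per_cluster_mu = n, cells_per_cluster_size = 1e9)
  tax <- simulate_taxonomy(cfg)
  deep <- simulate_deep_dataset(cfg, tax)
  calls <- call_positivity(deep$dataset, cfg$rule)
  byc <- split(calls, calls$cluster_id)
  # p_a = 0 -> no A-positive cells at all in that cluster
  expect_equal(sum(byc[["z"]]$pos_a), 0)
  # odds 1 -> empirical double fraction ~ product of single fractions,
  # within 3 binomial standard errors at n = 5000
  f <- byc[["ind"]]
  p_ab_hat <- mean(f$pos_ab)
  prod_hat <- mean(f$pos_a) * mean(f$pos_b)
  se <- sqrt(0.18 * 0.82 / nrow(f))
  expect_lt(abs(p_ab_hat - prod_hat), 3 * se)
})

test_that("a 100-fold marginal rate imbalance yields a ~100-fold positive-count imbalance", {
  n_cl <- 20
  rates <- data.frame(cluster_id = sprintf("c%02d", 1:n_cl),
                      p_a = 0.005, p_b = 0.5, odds = 1)
  cfg <- sim_config(n_clusters = n_cl, seed = 5, gene_rates = rates,
                    cells_per_cluster_mu = 2000, cells_per_cluster_size = 1e9)
  tax <- simulate_taxonomy(cfg)
  deep <- simulate_deep_dataset(cfg, tax)
  calls <- call_positivity(deep$dataset, cfg$rule)
  n_tot <- nrow(calls)
  n_a <- sum(calls$pos_a); n_b <- sum(calls$pos_b)
  # A+ count within 3 SE of its small expectation; ratio ~ 100
  expect_lt(abs(n_a - n_tot * 0.005), 3 * sqrt(n_tot * 0.005 * 0.995))
  expect_gt(n_b / n_a, 50)
  expect_lt(n_b / n_a, 200)
})

test_that("counts realize exactly the drawn positivity indicators", {
  # the generator's ground-truth realized fractions must be recovered
  # perfectly by the positivity rule in force
  cfg <- sim_config(n_clusters = 10, seed = 9, cells_per_cluster_mu = 300)
  tax <- simulate_taxonomy(cfg)
  deep <- simulate_deep_dataset(cfg, tax)
  calls <- call_positivity(deep$dataset, cfg$rule)
  stats <- cluster_fractions(calls)
  m <- merge(stats, deep$truth, by = "cluster_id")
  expect_equal(m$p_a, m$p_a_real)
  expect_equal(m$p_b, m$p_b_real)
  expect_equal(m$p_ab, m$p_ab_real)
  # and realized fractions approach configured rates at n = 1e4
  cfg2 <- sim_config(n_clusters = 2, seed = 10,
                     gene_rates = data.frame(cluster_id = c("u", "v"),
                                             p_a = c(0.3, 0.1),
                                             p_b = c(0.6, 0.4),
                                             odds = 2),
                     cells_per_cluster_mu = 1e4, cells_per_cluster_size = 1e9)
  deep2 <- simulate_deep_dataset(cfg2, simulate_taxonomy(cfg2))
  tr <- deep2$truth
  for (i in 1:2) {
    se_a <- sqrt(tr$p_a_config[i] * (1 - tr$p_a_config[i]) / tr$n_cells[i])
    se_b <- sqrt(tr$p_b_config[i] * (1 - tr$p_b_config[i]) / tr$n_cells[i])
    expect_lt(abs(tr$p_a_real[i] - tr$p_a_config[i]), 3 * se_a)
    expect_lt(abs(tr$p_b_real[i] - tr$p_b_config[i]), 3 * se_b)
  }
})

test_that("spatial sampling follows volume, coverage and cluster mixtures", {
  st <- toy_structures(c("full", "half"), volume = 10, covered = c(1, 0.5))
  n_cl <- 4
  w <- matrix(1 / n_cl, nrow = 2, ncol = n_cl)
  cfg <- sim_config(n_clusters = n_cl, seed = 2, structures = st,
                    mixtures = w, whole_brain_density = 1e5)
  tax <- simulate_taxonomy(cfg)
  sp <- simulate_spatial_dataset(cfg, tax)
  n_obs <- table(factor(sp$cells$structure_id, levels = st$structure_id))
  expect_full <- 10 * 1e5 * cfg$sampling_rate  # 50000 cells
  expect_lt(abs(n_obs[["full"]] - expect_full), 4 * sqrt(expect_full))
  # identical structures at coverage 1.0 vs 0.5 observed in ~2:1 ratio
  expect_lt(abs(n_obs[["full"]] / n_obs[["half"]] - 2), 0.1)
  # truth records the fully covered counts, so observed <= truth overall
  expect_lte(sum(n_obs), sum(sp$truth$structures$n_section_full) * 1.02)

  # degenerate single-cluster mixture
  w1 <- matrix(0, nrow = 2, ncol = n_cl); w1[, 3] <- 1
  cfg1 <- sim_config(n_clusters = n_cl, seed = 2, structures = st,
                     mixtures = w1)
  sp1 <- simulate_spatial_dataset(cfg1, tax)
  expect_true(all(sp1$cells$cluster_id == tax$cluster_id[3]))
})

test_that("reference populations carry exact or noisy literature counts, reproducibly", {
  cfg0 <- sim_config(seed = 4, ref_noise_sd = 0)
  st <- simulate_paired(cfg0)
  expect_equal(nrow(st$references), 7)   # the seven configured populations
  expect_equal(st$references$literature_count, st$references$true_count)
  cfgN <- sim_config(seed = 4, ref_noise_sd = 0.1)
  r1 <- simulate_paired(cfgN)$references
  r2 <- simulate_paired(cfgN)$references
  expect_identical(r1, r2)               # deterministic under seed
  expect_false(all(r1$literature_count == r1$true_count))
  bad <- sim_config(seed = 4)
  bad$reference_populations$structure_id[1] <- "NOPE"
  tax <- simulate_taxonomy(bad)
  sp <- simulate_spatial_dataset(bad, tax)
  expect_error(simulate_reference_populations(bad, sp), "NOPE")
})

test_that("the full paired study is byte-identical under one seed", {
  cfg <- sim_config(n_clusters = 15, seed = 123, cells_per_cluster_mu = 50)
  s1 <- simulate_paired(cfg)
  s2 <- simulate_paired(cfg)
  expect_identical(s1$taxonomy, s2$taxonomy)
  expect_identical(s1$deep$truth, s2$deep$truth)
  expect_identical(as.matrix(s1$deep$dataset$counts),
                   as.matrix(s2$deep$dataset$counts))
  expect_identical(s1$spatial$cells, s2$spatial$cells)
  expect_identical(s1$references, s2$references)
})
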