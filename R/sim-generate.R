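#' Joint positive probability from marginals and an odds multiplier
#'
#' Solves the 2x2 cell-level table with marginals \code{p_a}, \code{p_b} and
#' odds ratio \code{odds} for the double-positive probability p11. An odds
#' multiplier of 1 gives independence (p11 = p_a * p_b); larger values give
#' co-expression enrichment, values below 1 depletion, 0 mutual exclusion.
#'
#' @param p_a,p_b marginal positive probabilities in [0, 1] (vectorized).
#' @param odds odds multiplier >= 0.
#' @return p11, satisfying max(0, p_a + p_b - 1) <= p11 <= min(p_a, p_b).
#' @export
joint_positive_prob <- function(p_a, p_b, odds) {
  n <- max(length(p_a), length(p_b), length(odds))
  p_a <- rep_len(p_a, n); p_b <- rep_len(p_b, n); odds <- rep_len(odds, n)
  if (any(p_a < 0 | p_a > 1 | p_b < 0 | p_b > 1)) {
    stop("marginal probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(odds < 0)) stop("odds multiplier must be >= 0", call. = FALSE)
  p11 <- numeric(n)
  ind <- abs(odds - 1) < 1e-12
  p11[ind] <- p_a[ind] * p_b[ind]
  if (any(!ind)) {
    th <- odds[!ind]; pa <- p_a[!ind]; pb <- p_b[!ind]
    s <- 1 + (pa + pb) * (th - 1)
    disc <- s^2 - 4 * th * (th - 1) * pa * pb
    p11[!ind] <- (s - sqrt(pmax(disc, 0))) / (2 * (th - 1))
  }
  pmin(pmax(p11, pmax(0, p_a + p_b - 1)), pmin(p_a, p_b))
}

#' Generate the shared cluster taxonomy with per-cluster expression rates
#'
#' Draws, deterministically given the config seed, each cluster's class
#' (neuron / non-neuron), neurotransmitter annotation (non-neuronal clusters
#' are always \code{"none"}), and the per-cluster marginal positive rates for
#' the two genes together with the co-expression odds multiplier. With
#' default \code{rate_params} gene A is rare (most clusters near zero, a
#' minority elevated) and gene B broadly expressed, reproducing a ~100-fold
#' prevalence imbalance.
#'
#' @param config a \code{\link{sim_config}}.
#' @return data.frame with \code{cluster_id}, \code{class_label},
#'   \code{neurotransmitter}, \code{p_a}, \code{p_b}, \code{odds},
#'   \code{p_ab} (the implied true double-positive rate).
#' @export
simulate_taxonomy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_clusters
  cluster_id <- sprintf("c%03d", seq_len(n))
  class_label <- ifelse(stats::runif(n) < config$neuron_prob,
                        "neuron", "non-neuron")
  nt <- rep("none", n)
  is_n <- class_label == "neuron"
  cats <- names(config$nt_weights)
  nt[is_n] <- sample(cats, sum(is_n), replace = TRUE,
                     prob = config$nt_weights)
  if (is.null(config$gene_rates)) {
    rp <- config$rate_params
    hi <- stats::runif(n) < rp$p_a_high_prob
    p_a <- ifelse(hi,
                  stats::rbeta(n, rp$p_a_high[1], rp$p_a_high[2]),
                  stats::rbeta(n, rp$p_a_low[1], rp$p_a_low[2]))
    p_b <- stats::rbeta(n, rp$p_b[1], rp$p_b[2])
    odds <- rep(rp$odds, n)
  } else {
    gr <- config$gene_rates
    if (nrow(gr) != n) stop("gene_rates must have one row per cluster",
                            call. = FALSE)
    cluster_id <- as.character(gr$cluster_id)
    p_a <- gr$p_a; p_b <- gr$p_b; odds <- gr$odds
  }
  if (anyDuplicated(cluster_id)) .stop_listing("duplicated cluster_id",
    cluster_id[duplicated(cluster_id)])
  data.frame(cluster_id = cluster_id, class_label = class_label,
             neurotransmitter = nt, p_a = p_a, p_b = p_b, odds = odds,
             p_ab = joint_positive_prob(p_a, p_b, odds),
             stringsAsFactors = FALSE)
}

# minimum count making a cell positive under the rule, given library size
.min_positive_count <- function(rule, lib) {
  if (rule$mode == "log2cpm") floor(lib * 2^rule$threshold / 1e6) + 1
  else rep(rule$min_count, length(lib))
}

#' Generate the deep single-cell dataset
#'
#' Draws per-cluster cell numbers, per-cell positivity indicators for the two
#' genes from the cluster's joint 2x2 law, log-normal library sizes, and
#' counts placed so that the positivity rule in force recovers exactly the
#' drawn indicators (positive cells receive at least the minimum count that
#' clears the rule for their library size; negative cells receive zero).
#' Ground truth records both the configured and the realized per-cluster
#' fractions.
#'
#' @param config a \code{\link{sim_config}}.
#' @param taxonomy output of \code{\link{simulate_taxonomy}}.
#' @return list with \code{dataset} (an \code{\link{expression_dataset}}) and
#'   \code{truth} (data.frame of per-cluster configured and realized
#'   fractions).
#' @export
simulate_deep_dataset <- function(config, taxonomy) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_cl <- nrow(taxonomy)
  # infinite dispersion size = fixed cluster sizes (exactly mu cells each)
  n_cells <- if (is.infinite(config$cells_per_cluster_size)) {
    rep(as.integer(round(config$cells_per_cluster_mu)), n_cl)
  } else {
    pmax(1L, stats::rnbinom(n_cl, mu = config$cells_per_cluster_mu,
                            size = config$cells_per_cluster_size))
  }
  total <- sum(n_cells)
  cluster <- rep(taxonomy$cluster_id, n_cells)
  p11 <- rep(taxonomy$p_ab, n_cells)
  p10 <- rep(taxonomy$p_a, n_cells) - p11
  p01 <- rep(taxonomy$p_b, n_cells) - p11
  u <- stats::runif(total)
  pos_a <- u < p11 + p10
  pos_b <- u < p11 | (u >= p11 + p10 & u < p11 + p10 + p01)
  lib <- pmax(1000, round(stats::rlnorm(total, config$library_meanlog,
                                        config$library_sdlog)))
  m <- .min_positive_count(config$rule, lib)
  draw_counts <- function(pos) {
    cnt <- integer(total)
    k <- sum(pos)
    if (k) cnt[pos] <- m[pos] + stats::rpois(k, lambda = pmax(1, m[pos]))
    cnt
  }
  cnt_a <- draw_counts(pos_a)
  cnt_b <- draw_counts(pos_b)
  counts <- Matrix::sparseMatrix(
    i = c(rep(1L, total), rep(2L, total)),
    j = rep(seq_len(total), 2L),
    x = c(cnt_a, cnt_b), dims = c(2L, total),
    dimnames = list(c(config$gene_a, config$gene_b), NULL))
  cells <- data.frame(
    cell_id = sprintf("d%06d", seq_len(total)),
    cluster_id = cluster,
    class_label = rep(taxonomy$class_label, n_cells),
    neurotransmitter = rep(taxonomy$neurotransmitter, n_cells),
    library_size = lib,
    stringsAsFactors = FALSE)
  ds <- expression_dataset(counts, cells)
  cl <- factor(cluster, levels = taxonomy$cluster_id)
  truth <- data.frame(
    cluster_id = taxonomy$cluster_id,
    n_cells = as.integer(table(cl)),
    p_a_config = taxonomy$p_a, p_b_config = taxonomy$p_b,
    p_ab_config = taxonomy$p_ab,
    p_a_real = as.numeric(tapply(pos_a, cl, mean)),
    p_b_real = as.numeric(tapply(pos_b, cl, mean)),
    p_ab_real = as.numeric(tapply(pos_a & pos_b, cl, mean)),
    stringsAsFactors = FALSE)
  list(dataset = ds, truth = truth)
}

#' Generate the spatial dataset
#'
#' Emulates a sectioned, spatially resolved dataset over the configured
#' structures. Each structure's whole-brain cell number is volume times the
#' whole-brain density; a fully covered section series captures the fraction
#' thickness/interval of those cells, and partial coverage further thins the
#' observed count (Poisson). Cell cluster labels are drawn from the
#' structure's mixture. Ground truth records the fully covered expected
#' counts, the expected whole-brain positive counts per structure (from the
#' configured rates), and the true proportionality factor
#' interval/thickness.
#'
#' @param config a \code{\link{sim_config}}.
#' @param taxonomy output of \code{\link{simulate_taxonomy}}.
#' @return list with \code{cells} (data.frame: cell_id, structure_id,
#'   cluster_id), \code{structures} (the structure table), \code{mixtures}
#'   (structures x clusters weight matrix) and \code{truth} (list with
#'   per-structure data.frame and \code{k_true}).
#' @export
simulate_spatial_dataset <- function(config, taxonomy) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(config$structures) == 0) stop("structure list is empty", call. = FALSE)
  set.seed(config$seed + 2L)
  st <- config$structures
  n_s <- nrow(st); n_cl <- nrow(taxonomy)
  w <- config$mixtures
  if (is.null(w)) {
    g <- matrix(stats::rgamma(n_s * n_cl, shape = config$mixture_concentration),
                nrow = n_s)
    w <- g / rowSums(g)
  }
  if (ncol(w) != n_cl) stop("mixture matrix must have one column per cluster",
                            call. = FALSE)
  dimnames(w) <- list(st$structure_id, taxonomy$cluster_id)
  n_whole <- round(st$volume_mm3 * config$whole_brain_density)
  n_sect <- n_whole * config$sampling_rate
  n_obs <- stats::rpois(n_s, n_sect * st$covered_fraction)
  cells <- do.call(rbind, lapply(seq_len(n_s), function(i) {
    if (n_obs[i] == 0) return(NULL)
    data.frame(structure_id = st$structure_id[i],
               cluster_id = sample(taxonomy$cluster_id, n_obs[i],
                                   replace = TRUE, prob = w[i, ]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(cells)) cells <- data.frame(structure_id = character(0),
                                          cluster_id = character(0))
  cells <- cbind(cell_id = sprintf("m%06d", seq_len(nrow(cells))), cells)
  truth_s <- data.frame(
    structure_id = st$structure_id,
    n_whole = n_whole,
    n_section_full = n_sect,
    true_a = n_whole * as.numeric(w %*% taxonomy$p_a),
    true_b = n_whole * as.numeric(w %*% taxonomy$p_b),
    true_ab = n_whole * as.numeric(w %*% taxonomy$p_ab),
    stringsAsFactors = FALSE)
  list(cells = cells, structures = st, mixtures = w,
       truth = list(structures = truth_s,
                    k_true = 1 / config$sampling_rate))
}

#' Generate literature reference counts for calibration
#'
#' Each configured reference population is pinned to a marker cluster in its
#' structure (the highest-weight clusters, assigned in order for populations
#' sharing a structure) and given a literature count equal to its true
#' whole-brain cell number times multiplicative log-normal noise
#' (\code{ref_noise_sd = 0} gives exact literature counts).
#'
#' @param config a \code{\link{sim_config}}.
#' @param spatial output of \code{\link{simulate_spatial_dataset}}.
#' @return data.frame with \code{population}, \code{structure_id},
#'   \code{cluster_id}, \code{true_count}, \code{literature_count}.
#' @export
simulate_reference_populations <- function(config, spatial) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  refs <- config$reference_populations
  bad <- setdiff(refs$structure_id, spatial$structures$structure_id)
  if (length(bad)) .stop_listing(
    "reference structure(s) absent from the structure list", bad)
  w <- spatial$mixtures
  truth <- spatial$truth$structures
  out <- do.call(rbind, lapply(split(refs, refs$structure_id), function(r) {
    s <- r$structure_id[1]
    ord <- order(w[s, ], decreasing = TRUE)
    # recycle marker clusters if a structure hosts more reference
    # populations than there are clusters
    idx <- ord[(seq_len(nrow(r)) - 1L) %% length(ord) + 1L]
    r$cluster_id <- colnames(w)[idx]
    n_whole <- truth$n_whole[truth$structure_id == s]
    r$true_count <- n_whole * w[s, r$cluster_id]
    r
  }))
  rownames(out) <- NULL
  out <- out[match(refs$population, out$population), ]
  noise <- if (config$ref_noise_sd > 0) {
    exp(stats::rnorm(nrow(out), 0, config$ref_noise_sd))
  } else 1
  out$literature_count <- out$true_count * noise
  rownames(out) <- NULL
  out
}

#' Generate a complete paired synthetic study
#'
#' Runs all generator stages from one config: taxonomy, deep dataset,
#' spatial dataset and calibration references. Deterministic given the
#' config seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{config}, \code{taxonomy}, \code{deep},
#'   \code{spatial}, \code{references}.
#' @export
simulate_paired <- function(config = sim_config()) {
  taxonomy <- simulate_taxonomy(config)
  deep <- simulate_deep_dataset(config, taxonomy)
  spatial <- simulate_spatial_dataset(config, taxonomy)
  references <- simulate_reference_populations(config, spatial)
  list(config = config, taxonomy = taxonomy, deep = deep,
       spatial = spatial, references = references)
}
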