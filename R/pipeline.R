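#' Run the full co-expression estimation pipeline
#'
#' Executes the whole chain on a paired study (typically from
#' \code{\link{simulate_paired}}): positivity calls on the deep dataset,
#' per-cluster fractions, spatial cross-tabulation, apportionment onto
#' structures, partial-volume correction, calibration against the reference
#' populations, whole-brain scaling, neurotransmitter phenotype of the
#' apportioned double-positives, the per-structure summary table and region
#' roll-ups.
#'
#' @param study list with \code{config}, \code{taxonomy}, \code{deep},
#'   \code{spatial}, \code{references} as produced by
#'   \code{\link{simulate_paired}} (or assembled from files).
#' @param rule positivity rule; default the rule in the study config.
#' @param min_cells,min_density structure selection thresholds (strict;
#'   defaults 350 and 50).
#' @param round apportionment rounding, see \code{\link{apportion}}.
#' @return list with every intermediate: \code{calls}, \code{stats},
#'   \code{totals}, \code{composition}, \code{apportioned},
#'   \code{corrected}, \code{references}, \code{model}, \code{estimates},
#'   \code{phenotype}, \code{summary}, \code{rollup}, \code{headline}.
#' @export
run_pipeline <- function(study, rule = NULL, min_cells = 350,
                         min_density = 50, round = "per_cluster") {
  config <- study$config
  if (is.null(rule)) rule <- config$rule
  calls <- call_positivity(study$deep$dataset, rule,
                           gene_a = config$gene_a, gene_b = config$gene_b)
  stats <- cluster_fractions(calls, study$deep$dataset)
  totals <- dataset_summary(calls, study$deep$dataset)
  composition <- structure_cluster_counts(study$spatial$cells,
                                          study$spatial$structures,
                                          taxonomy = study$taxonomy)
  apportioned <- apportion(composition, stats, round = round)
  corrected <- partial_volume_correct(apportioned, composition)
  refs <- reference_estimates(composition, study$references)
  model <- calibrate(refs)
  estimates <- whole_brain_estimate(corrected, model)
  phenotype <- structure_phenotype(composition, stats)
  summary <- summarize_structures(estimates, structures = study$spatial$structures,
                                  nt = phenotype, min_cells = min_cells,
                                  min_density = min_density)
  rollup <- region_rollup(summary)
  headline <- headline_shares(totals)
  list(calls = calls, stats = stats, totals = totals,
       composition = composition, apportioned = apportioned,
       corrected = corrected, references = refs, model = model,
       estimates = estimates, phenotype = phenotype, summary = summary,
       rollup = rollup, headline = headline)
}
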