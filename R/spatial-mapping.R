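#' Cross-tabulate spatial cells by structure and cluster
#'
#' The spatial side of the label transfer: an exact count of cells per
#' (structure, cluster) in the spatially resolved dataset. Structures present
#' in the structure table but containing no cells are retained as zero rows.
#' Cells whose cluster is absent from the taxonomy are excluded and their
#' number reported via a message.
#'
#' @param spatial_cells data.frame with \code{cell_id}, \code{cluster_id},
#'   \code{structure_id}.
#' @param structures data.frame with \code{structure_id}, \code{region_id},
#'   \code{volume_mm3}, \code{covered_fraction}.
#' @param taxonomy optional data.frame with \code{cluster_id}; when given,
#'   cells with clusters outside it are dropped (logged).
#' @return object of class \code{structure_composition}: list with
#'   \code{counts} (integer matrix, structures x clusters) and
#'   \code{structures} (the structure table, one row per matrix row).
#' @export
structure_cluster_counts <- function(spatial_cells, structures,
                                     taxonomy = NULL) {
  if (nrow(structures) == 0) stop("structure table is empty", call. = FALSE)
  need <- c("structure_id", "region_id", "volume_mm3", "covered_fraction")
  if (!all(need %in% names(structures))) {
    stop("structure table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(structures$volume_mm3 <= 0)) stop("volume_mm3 must be > 0", call. = FALSE)
  if (any(structures$covered_fraction <= 0 | structures$covered_fraction > 1)) {
    stop("covered_fraction must be in (0, 1]", call. = FALSE)
  }
  cells <- spatial_cells
  if (!is.null(taxonomy)) {
    bad <- !(cells$cluster_id %in% taxonomy$cluster_id)
    if (any(bad)) {
      message(sum(bad), " spatial cell(s) with cluster absent from the ",
              "taxonomy excluded")
      cells <- cells[!bad, , drop = FALSE]
    }
  }
  unk <- setdiff(unique(cells$structure_id), structures$structure_id)
  if (length(unk)) .stop_listing("spatial cells in structure(s) missing from the structure table", unk)
  s_lev <- as.character(structures$structure_id)
  c_lev <- sort(unique(as.character(cells$cluster_id)))
  if (!is.null(taxonomy)) c_lev <- sort(unique(as.character(taxonomy$cluster_id)))
  tab <- table(factor(cells$structure_id, levels = s_lev),
               factor(cells$cluster_id, levels = c_lev))
  counts <- matrix(as.integer(tab), nrow = length(s_lev),
                   dimnames = list(s_lev, c_lev))
  structure(list(counts = counts, structures = structures),
            class = "structure_composition")
}

#' @export
print.structure_composition <- function(x, ...) {
  cat("<structure_composition> ", nrow(x$counts), " structures x ",
      ncol(x$counts), " clusters; ", sum(x$counts), " cells\n", sep = "")
  invisible(x)
}

#' Apportion per-cluster positive fractions onto structures
#'
#' For each structure s and marker X, the estimated positive count is the sum
#' over clusters of the cluster's cell count in s times its positive fraction
#' in the deep dataset, each contribution truncated to its integer part
#' before summing (the default), or truncated once after summing
#' (\code{round = "after_sum"}). Clusters observed in the spatial composition
#' but absent from the deep-set statistics contribute zero and are logged.
#'
#' @param composition a \code{\link{structure_cluster_counts}} result.
#' @param stats a \code{\link{cluster_fractions}} result.
#' @param round \code{"per_cluster"} (floor each (cluster, structure)
#'   contribution) or \code{"after_sum"}.
#' @return data.frame with \code{structure_id}, \code{region_id},
#'   \code{n_cells} (spatial cells in the structure), \code{est_a},
#'   \code{est_b}, \code{est_ab} (non-negative integers).
#' @export
apportion <- function(composition, stats,
                      round = c("per_cluster", "after_sum")) {
  round <- match.arg(round)
  stopifnot(inherits(composition, "structure_composition"))
  if (any(stats$p_a < 0 | stats$p_b < 0 | stats$p_ab < 0, na.rm = TRUE)) {
    stop("negative positive fraction in cluster stats", call. = FALSE)
  }
  cl <- colnames(composition$counts)
  idx <- match(cl, stats$cluster_id)
  absent <- cl[is.na(idx) & colSums(composition$counts) > 0]
  if (length(absent)) {
    message(length(absent), " cluster(s) in the spatial set without ",
            "deep-set statistics contribute zero positives: ",
            paste(utils::head(absent, 5), collapse = ", "))
  }
  p <- function(col) {
    v <- stats[[col]][idx]
    v[is.na(v)] <- 0
    v
  }
  # eps absorbs double-rounding in n * (m/n) products so that exact-ratio
  # contributions like 10 * 0.3 floor to 3, not 2
  eps <- 1e-9
  est <- function(pv) {
    contrib <- sweep(composition$counts, 2, pv, `*`)
    if (round == "per_cluster") as.integer(rowSums(floor(contrib + eps)))
    else as.integer(floor(rowSums(contrib) + eps))
  }
  data.frame(structure_id = rownames(composition$counts),
             region_id = composition$structures$region_id,
             n_cells = as.integer(rowSums(composition$counts)),
             est_a = est(p("p_a")), est_b = est(p("p_b")),
             est_ab = est(p("p_ab")),
             stringsAsFactors = FALSE)
}

#' Correct apportioned counts for partial section coverage
#'
#' Structures only partly covered by the sampled sections have their counts
#' scaled up by the reciprocal of the covered-volume fraction (a ratio
#' estimator); fully covered structures are unchanged.
#'
#' @param apportioned output of \code{\link{apportion}}.
#' @param composition the matching \code{structure_composition} (supplies
#'   \code{covered_fraction}).
#' @return the apportioned table with added real-valued columns
#'   \code{corr_a}, \code{corr_b}, \code{corr_ab} and the
#'   \code{covered_fraction} used.
#' @export
partial_volume_correct <- function(apportioned, composition) {
  st <- composition$structures
  f <- st$covered_fraction[match(apportioned$structure_id, st$structure_id)]
  if (anyNA(f)) .stop_listing("structure(s) missing from composition",
    apportioned$structure_id[is.na(f)])
  if (any(f <= 0)) stop("covered_fraction must be > 0", call. = FALSE)
  apportioned$covered_fraction <- f
  apportioned$corr_a <- apportioned$est_a / f
  apportioned$corr_b <- apportioned$est_b / f
  apportioned$corr_ab <- apportioned$est_ab / f
  apportioned
}

#' Coverage-corrected counts for calibration reference populations
#'
#' Each reference population is a marker-defined cell population: one cluster
#' within one structure. Its atlas-side estimate is the spatial cell count of
#' that (cluster, structure), corrected for partial coverage — the quantity
#' regressed against the literature-reported whole-brain count.
#'
#' @param composition a \code{structure_composition}.
#' @param references data.frame with \code{population}, \code{structure_id},
#'   \code{cluster_id}, \code{literature_count}.
#' @return the reference table with an added \code{estimated_count} column.
#' @export
reference_estimates <- function(composition, references) {
  st <- composition$structures
  bad <- !(references$structure_id %in% st$structure_id)
  if (any(bad)) .stop_listing("reference structure(s) not in structure table",
    references$structure_id[bad])
  f <- st$covered_fraction[match(references$structure_id, st$structure_id)]
  n <- mapply(function(s, c) {
    if (!c %in% colnames(composition$counts)) 0L
    else composition$counts[s, c]
  }, as.character(references$structure_id), as.character(references$cluster_id))
  references$estimated_count <- as.numeric(n) / f
  references
}

#' Fit the whole-brain proportionality factor
#'
#' Least-squares regression through the origin of literature-reported
#' whole-brain counts on atlas-derived estimated counts:
#' k = sum(lit * est) / sum(est^2). A single multiplicative factor, no
#' intercept, unweighted.
#'
#' @param references data.frame with \code{estimated_count} and
#'   \code{literature_count} (see \code{\link{reference_estimates}}).
#' @return object of class \code{calibration_model}: list with \code{k},
#'   \code{references}, and the residuals \code{literature - k * estimated}.
#' @export
calibrate <- function(references) {
  est <- references$estimated_count
  lit <- references$literature_count
  if (length(est) < 1) stop("need at least one reference", call. = FALSE)
  if (all(est == 0)) stop("all estimated counts are zero; cannot calibrate",
                          call. = FALSE)
  k <- sum(lit * est) / sum(est^2)
  structure(list(k = k, references = references,
                 residuals = lit - k * est),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> k =", format(x$k, digits = 6), "from",
      nrow(x$references), "reference population(s)\n")
  invisible(x)
}

#' Scale corrected counts to whole-brain estimates
#'
#' Multiplies the coverage-corrected counts by the proportionality factor and
#' rounds half away from zero to integers.
#'
#' @param corrected output of \code{\link{partial_volume_correct}}.
#' @param model a \code{\link{calibrate}} fit.
#' @return the input table with integer columns \code{wb_a}, \code{wb_b},
#'   \code{wb_ab} (whole-brain estimates) and attribute \code{k}.
#' @export
whole_brain_estimate <- function(corrected, model) {
  stopifnot(inherits(model, "calibration_model"))
  k <- model$k
  corrected$wb_a <- as.integer(round_half_away(k * corrected$corr_a))
  corrected$wb_b <- as.integer(round_half_away(k * corrected$corr_b))
  corrected$wb_ab <- as.integer(round_half_away(k * corrected$corr_ab))
  attr(corrected, "k") <- k
  corrected
}
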