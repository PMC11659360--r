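#' Per-cluster positive fractions
#'
#' The statistic transferred from the deep dataset to the spatial dataset:
#' for every cluster, the exact fraction of its cells called positive for
#' gene A, gene B, and both. Clusters with zero cells do not appear.
#'
#' @param calls output of \code{\link{call_positivity}}.
#' @param dataset the \code{\link{expression_dataset}} the calls came from
#'   (supplies class and neurotransmitter labels if present).
#' @return data.frame with columns \code{cluster_id}, \code{n_cells},
#'   \code{p_a}, \code{p_b}, \code{p_ab} and, when available,
#'   \code{class_label}, \code{neurotransmitter}.
#' @export
cluster_fractions <- function(calls, dataset = NULL) {
  miss <- which(is.na(calls$cluster_id) | calls$cluster_id == "")
  if (length(miss)) .stop_listing("cluster label missing for cell(s)",
    calls$cell_id[miss])
  cl <- factor(calls$cluster_id)
  n <- as.integer(table(cl))
  out <- data.frame(
    cluster_id = levels(cl),
    n_cells = n,
    p_a = as.numeric(tapply(calls$pos_a, cl, sum)) / n,
    p_b = as.numeric(tapply(calls$pos_b, cl, sum)) / n,
    p_ab = as.numeric(tapply(calls$pos_ab, cl, sum)) / n,
    stringsAsFactors = FALSE)
  if (!is.null(dataset)) {
    keep <- intersect(c("class_label", "neurotransmitter"),
                      names(dataset$cells))
    if (length(keep)) {
      lab <- unique(dataset$cells[, c("cluster_id", keep), drop = FALSE])
      if (anyDuplicated(lab$cluster_id)) {
        .stop_listing("inconsistent cluster annotations for cluster(s)",
                      lab$cluster_id[duplicated(lab$cluster_id)])
      }
      out <- merge(out, lab, by = "cluster_id", sort = FALSE)
      out <- out[order(out$cluster_id), ]
      rownames(out) <- NULL
    }
  }
  out
}

#' Neurotransmitter composition of double-positive cells
#'
#' For each group (cluster or structure), the percentage of its
#' double-positive cells in each neurotransmitter category. Each cell
#' contributes through its cluster's annotation, as in atlas taxonomies where
#' neurotransmitter identity is a cluster-level attribute. Groups with no
#' double-positive cells are omitted entirely (composition undefined), not
#' reported as zeros.
#'
#' @param calls output of \code{\link{call_positivity}}.
#' @param dataset the source \code{\link{expression_dataset}}; its cell
#'   metadata must carry \code{neurotransmitter} (and \code{structure_id}
#'   when grouping by structure).
#' @param group_by \code{"cluster"} or \code{"structure"}.
#' @return data.frame with the group id, \code{n_double}, one count column
#'   per category (\code{n_<cat>}) and one percentage column per category
#'   (\code{pct_<cat>}); counts sum to \code{n_double} exactly and raw
#'   percentages sum to 100.
#' @export
phenotype_composition <- function(calls, dataset,
                                  group_by = c("cluster", "structure")) {
  group_by <- match.arg(group_by)
  key <- if (group_by == "cluster") "cluster_id" else "structure_id"
  if (!key %in% names(dataset$cells)) {
    stop("cell metadata lacks '", key, "'", call. = FALSE)
  }
  if (!"neurotransmitter" %in% names(dataset$cells)) {
    stop("cell metadata lacks 'neurotransmitter'", call. = FALSE)
  }
  m <- dataset$cells[match(calls$cell_id, dataset$cells$cell_id), ]
  dp <- calls$pos_ab
  if (!any(dp)) {
    return(data.frame(group = character(0), n_double = integer(0)))
  }
  cats <- nt_categories()
  grp <- factor(m[[key]][dp])
  nt <- factor(m$neurotransmitter[dp], levels = cats)
  if (anyNA(nt)) .stop_listing("unknown neurotransmitter label(s)",
    unique(m$neurotransmitter[dp][is.na(nt)]))
  tab <- table(grp, nt)
  n_double <- rowSums(tab)
  out <- data.frame(group = rownames(tab), n_double = as.integer(n_double),
                    stringsAsFactors = FALSE)
  names(out)[1] <- key
  for (cc in cats) out[[paste0("n_", cc)]] <- as.integer(tab[, cc])
  for (cc in cats) out[[paste0("pct_", cc)]] <- 100 * tab[, cc] / n_double
  rownames(out) <- NULL
  out
}

#' Whole-dataset positive-cell summary
#'
#' Headline totals over all cells: the number of A+, B+ and double-positive
#' cells, the share of double-positives relative to each single-positive
#' total, and the fraction of double-positives that are neurons (when the
#' metadata carries \code{class_label}).
#'
#' @param calls output of \code{\link{call_positivity}}.
#' @param dataset optional source dataset, for the neuron share.
#' @return a list with \code{n_cells}, \code{n_a}, \code{n_b}, \code{n_ab},
#'   \code{pct_ab_vs_a}, \code{pct_ab_vs_b} (percent, NA when the denominator
#'   is zero) and \code{pct_ab_neuron} (NA when unavailable or undefined).
#' @export
dataset_summary <- function(calls, dataset = NULL) {
  n_a <- sum(calls$pos_a); n_b <- sum(calls$pos_b); n_ab <- sum(calls$pos_ab)
  pct_neuron <- NA_real_
  if (!is.null(dataset) && "class_label" %in% names(dataset$cells) && n_ab > 0) {
    m <- dataset$cells[match(calls$cell_id, dataset$cells$cell_id), ]
    pct_neuron <- 100 * sum(m$class_label[calls$pos_ab] == "neuron") / n_ab
  }
  list(n_cells = nrow(calls), n_a = n_a, n_b = n_b, n_ab = n_ab,
       pct_ab_vs_a = if (n_a > 0) 100 * n_ab / n_a else NA_real_,
       pct_ab_vs_b = if (n_b > 0) 100 * n_ab / n_b else NA_real_,
       pct_ab_neuron = pct_neuron)
}
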