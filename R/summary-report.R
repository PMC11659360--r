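#' Neurotransmitter composition of apportioned double-positive counts
#'
#' Structure-level analogue of \code{\link{phenotype_composition}} for
#' estimated (apportioned) counts: each cluster's floored double-positive
#' contribution to a structure is attributed to the cluster's
#' neurotransmitter category, and percentages are taken over the structure's
#' total apportioned double-positive count. Structures with no apportioned
#' double-positives are omitted.
#'
#' @param composition a \code{\link{structure_cluster_counts}} result.
#' @param stats a \code{\link{cluster_fractions}} result carrying a
#'   \code{neurotransmitter} column.
#' @return data.frame with \code{structure_id}, \code{n_double_est} and one
#'   \code{pct_<category>} column per neurotransmitter category (raw
#'   percentages, not yet rounded).
#' @export
structure_phenotype <- function(composition, stats) {
  if (!"neurotransmitter" %in% names(stats)) {
    stop("cluster stats lack a 'neurotransmitter' column", call. = FALSE)
  }
  cl <- colnames(composition$counts)
  idx <- match(cl, stats$cluster_id)
  p_ab <- stats$p_ab[idx]; p_ab[is.na(p_ab)] <- 0
  nt <- as.character(stats$neurotransmitter[idx]); nt[is.na(nt)] <- "none"
  contrib <- floor(sweep(composition$counts, 2, p_ab, `*`) + 1e-9)
  cats <- nt_categories()
  agg <- sapply(cats, function(cc) {
    cols <- which(nt == cc)
    if (!length(cols)) return(rep(0, nrow(contrib)))
    rowSums(contrib[, cols, drop = FALSE])
  })
  agg <- matrix(agg, nrow = nrow(contrib), dimnames = list(rownames(contrib), cats))
  tot <- rowSums(agg)
  keep <- tot > 0
  out <- data.frame(structure_id = rownames(agg)[keep],
                    n_double_est = as.integer(tot[keep]),
                    stringsAsFactors = FALSE)
  for (cc in cats) out[[paste0("pct_", cc)]] <- 100 * agg[keep, cc] / tot[keep]
  rownames(out) <- NULL
  out
}

#' Build the per-structure region summary table
#'
#' Assembles the Table-1-shaped summary: whole-brain positive counts per
#' structure, double-positive percentages relative to each single-positive
#' count (one decimal, half away from zero), integer neurotransmitter
#' percentages, double-positive density per mm3, and the selection flag.
#'
#' @param estimates data.frame with \code{structure_id}, \code{region_id}
#'   and the count columns named by \code{cols}.
#' @param cols named character vector mapping markers to columns of
#'   \code{estimates}; default the whole-brain columns of
#'   \code{\link{whole_brain_estimate}}.
#' @param structures optional structure table supplying \code{volume_mm3};
#'   without it densities (and hence selection flags) are \code{NA}.
#' @param nt optional \code{\link{structure_phenotype}} output; its
#'   percentages are rounded to integers here.
#' @param min_cells,min_density selection thresholds, both strict
#'   (\code{>}): more than \code{min_cells} double-positive cells and more
#'   than \code{min_density} cells per mm3. Defaults 350 and 50.
#' @return data.frame with columns \code{region_id}, \code{structure_id},
#'   \code{est_a}, \code{est_b}, \code{est_ab}, \code{pct_ab_vs_a},
#'   \code{pct_ab_vs_b}, \code{nt_<category>} (integer percentages, NA when
#'   no double-positives), \code{density_per_mm3}, \code{selected}.
#' @export
summarize_structures <- function(estimates,
                                 cols = c(a = "wb_a", b = "wb_b", ab = "wb_ab"),
                                 structures = NULL, nt = NULL,
                                 min_cells = 350, min_density = 50) {
  for (col in cols) {
    if (!col %in% names(estimates)) {
      stop("estimates lack column '", col, "'", call. = FALSE)
    }
  }
  a <- estimates[[cols[["a"]]]]; b <- estimates[[cols[["b"]]]]
  ab <- estimates[[cols[["ab"]]]]
  bad <- which(a == 0 & ab > 0)
  if (length(bad)) .stop_listing(
    "inconsistent counts (double-positives but no A-positives) in structure(s)",
    estimates$structure_id[bad])
  bad_b <- which(b == 0 & ab > 0)
  if (length(bad_b)) .stop_listing(
    "inconsistent counts (double-positives but no B-positives) in structure(s)",
    estimates$structure_id[bad_b])
  out <- data.frame(region_id = estimates$region_id,
                    structure_id = estimates$structure_id,
                    est_a = a, est_b = b, est_ab = ab,
                    stringsAsFactors = FALSE)
  out$pct_ab_vs_a <- ifelse(a > 0, round_half_away(100 * ab / a, 1), NA_real_)
  out$pct_ab_vs_b <- ifelse(b > 0, round_half_away(100 * ab / b, 1), NA_real_)
  cats <- nt_categories()
  for (cc in cats) out[[paste0("nt_", cc)]] <- NA_integer_
  if (!is.null(nt)) {
    m <- match(out$structure_id, nt$structure_id)
    for (cc in cats) {
      v <- nt[[paste0("pct_", cc)]][m]
      out[[paste0("nt_", cc)]] <- as.integer(round_half_away(v))
    }
  }
  if (!is.null(structures)) {
    vol <- structures$volume_mm3[match(out$structure_id,
                                       structures$structure_id)]
    out$volume_mm3 <- vol
    out$density_per_mm3 <- ab / vol
  } else {
    out$volume_mm3 <- NA_real_
    out$density_per_mm3 <- NA_real_
  }
  select_structures(out, min_cells = min_cells, min_density = min_density)
}

#' Flag structures passing the double-positive selection filter
#'
#' A structure is selected iff it has more than \code{min_cells}
#' double-positive cells and a double-positive density of more than
#' \code{min_density} cells per mm3; both comparisons are strict, so a
#' structure sitting exactly on either threshold is not selected.
#'
#' @param summary a \code{\link{summarize_structures}} table (needs
#'   \code{est_ab} and \code{density_per_mm3}).
#' @param min_cells,min_density the thresholds (defaults 350, 50).
#' @return the table with a logical \code{selected} column (NA where the
#'   density is unknown).
#' @export
select_structures <- function(summary, min_cells = 350, min_density = 50) {
  summary$selected <- summary$est_ab > min_cells &
    summary$density_per_mm3 > min_density
  summary
}

#' Roll structure counts up to brain regions
#'
#' For each parent region: the double-positive total over structures passing
#' the selection filter ("listed") and over all structures ("total"),
#' mirroring the bracketed [listed/total] headers of the summary table.
#'
#' @param summary a \code{\link{summarize_structures}} table with a logical
#'   \code{selected} column (NA selection flags are an error; decide
#'   selection first or supply \code{selected}).
#' @param selected optional logical vector overriding the table's column.
#' @return data.frame with \code{region_id}, \code{listed_double},
#'   \code{total_double}, one row per region in order of first appearance.
#' @export
region_rollup <- function(summary, selected = NULL) {
  if (is.null(selected)) selected <- summary$selected
  if (is.null(selected) || anyNA(selected)) {
    stop("selection flags are missing; supply 'selected' or compute densities",
         call. = FALSE)
  }
  if (anyNA(summary$region_id) || any(summary$region_id == "")) {
    .stop_listing("structure(s) without a region",
      summary$structure_id[is.na(summary$region_id) | summary$region_id == ""])
  }
  reg <- factor(summary$region_id, levels = unique(summary$region_id))
  listed <- tapply(summary$est_ab * selected, reg, sum)
  total <- tapply(summary$est_ab, reg, sum)
  data.frame(region_id = levels(reg),
             listed_double = as.integer(listed),
             total_double = as.integer(total),
             stringsAsFactors = FALSE)
}

#' Headline double-positive shares
#'
#' The whole-dataset shares of double-positive cells relative to each
#' single-positive total, as one-decimal percentages (half away from zero).
#'
#' @param n_a,n_b,n_ab positive-cell totals; alternatively pass a
#'   \code{\link{dataset_summary}} list as \code{n_a}.
#' @return list with \code{pct_ab_vs_a} and \code{pct_ab_vs_b}; a zero
#'   denominator yields NA with a warning.
#' @export
headline_shares <- function(n_a, n_b = NULL, n_ab = NULL) {
  if (is.list(n_a)) {
    tot <- n_a
    n_b <- tot$n_b; n_ab <- tot$n_ab; n_a <- tot$n_a
  }
  share <- function(num, den, label) {
    if (den <= 0) {
      warning("zero ", label, " total; share undefined", call. = FALSE)
      return(NA_real_)
    }
    round_half_away(100 * num / den, 1)
  }
  list(pct_ab_vs_a = share(n_ab, n_a, "A-positive"),
       pct_ab_vs_b = share(n_ab, n_b, "B-positive"))
}
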