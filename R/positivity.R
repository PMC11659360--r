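#' Expression dataset container
#'
#' Bundles a sparse two-gene (or more) count matrix with per-cell metadata.
#' Counts are genes x cells. \code{library_size} is the per-cell total
#' transcript count used as the CPM denominator; when the metadata does not
#' supply one (a matrix restricted to the genes of interest cannot imply
#' transcriptome totals) it is computed as the column sum of \code{counts}.
#'
#' @param counts matrix or \link[Matrix]{sparseMatrix} of non-negative integer
#'   counts, genes in rows (rownames = gene ids), cells in columns.
#' @param cells data.frame of per-cell metadata with at least \code{cell_id}
#'   and \code{cluster_id}; optional \code{class_label}, \code{neurotransmitter},
#'   \code{structure_id}, \code{library_size}.
#' @return an object of class \code{expression_dataset}: a list with elements
#'   \code{counts} (dgCMatrix), \code{cells} (data.frame, one row per column
#'   of \code{counts}, with a \code{library_size} column).
#' @export
expression_dataset <- function(counts, cells) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames", call. = FALSE)
  if (!is.data.frame(cells)) stop("cells must be a data.frame", call. = FALSE)
  if (!all(c("cell_id", "cluster_id") %in% names(cells))) {
    stop("cells must contain 'cell_id' and 'cluster_id'", call. = FALSE)
  }
  if (nrow(cells) != ncol(counts)) {
    stop("cells has ", nrow(cells), " rows but counts has ", ncol(counts),
         " columns", call. = FALSE)
  }
  if (anyDuplicated(cells$cell_id)) .stop_listing("duplicated cell_id",
    cells$cell_id[duplicated(cells$cell_id)])
  if (any(counts@x < 0)) stop("counts must be non-negative", call. = FALSE)
  colnames(counts) <- cells$cell_id
  if (is.null(cells$library_size)) {
    cells$library_size <- Matrix::colSums(counts)
  } else {
    over <- which(apply(counts, 2, max) > cells$library_size)
    if (length(over)) .stop_listing("gene count exceeds library_size for cell(s)",
      cells$cell_id[over])
  }
  structure(list(counts = counts, cells = cells), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells; ", length(unique(x$cells$cluster_id)), " clusters\n", sep = "")
  invisible(x)
}

#' Positivity rule
#'
#' Two ways of declaring a cell positive for a gene, matching the conventions
#' of large-scale atlas analyses: a threshold on log2(CPM) (used for deep
#' whole-transcriptome datasets), or a minimum raw count without any
#' normalization (used for targeted-panel data where CPM is not meaningful).
#'
#' @param mode \code{"log2cpm"} or \code{"count"}.
#' @param threshold log2(CPM) threshold for \code{mode = "log2cpm"};
#'   positivity requires log2(CPM) strictly greater than this, i.e.
#'   CPM > 2^threshold. Default 3.
#' @param min_count minimum raw count for \code{mode = "count"}; positivity
#'   requires count >= min_count. Default 1.
#' @return object of class \code{positivity_rule}.
#' @export
positivity_rule <- function(mode = c("log2cpm", "count"), threshold = 3,
                            min_count = 1L) {
  mode <- match.arg(mode)
  .assert_scalar_number(threshold, "threshold")
  .assert_scalar_number(min_count, "min_count", lower = 1)
  structure(list(mode = mode, threshold = threshold,
                 min_count = as.integer(min_count)),
            class = "positivity_rule")
}

#' @export
print.positivity_rule <- function(x, ...) {
  if (x$mode == "log2cpm") {
    cat("<positivity_rule> log2(CPM) >", x$threshold, "\n")
  } else {
    cat("<positivity_rule> raw count >=", x$min_count, "\n")
  }
  invisible(x)
}

#' Counts per million for one gene
#'
#' CPM = count / library_size * 1e6. A zero count gives CPM 0; positivity
#' under a log2 threshold never evaluates log2 of zero because the comparison
#' log2(CPM) > t is carried out as CPM > 2^t.
#'
#' @param dataset an \code{\link{expression_dataset}}.
#' @param gene gene id (must be a rowname of the count matrix).
#' @return named numeric vector of per-cell CPM values.
#' @export
compute_cpm <- function(dataset, gene) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!gene %in% rownames(dataset$counts)) {
    stop("gene '", gene, "' not present in dataset", call. = FALSE)
  }
  lib <- dataset$cells$library_size
  zero <- which(lib <= 0)
  if (length(zero)) .stop_listing("library_size is zero for cell(s)",
    dataset$cells$cell_id[zero])
  cnt <- as.numeric(dataset$counts[gene, ])
  stats::setNames(cnt / lib * 1e6, dataset$cells$cell_id)
}

#' Call per-cell single and double positivity for two genes
#'
#' Under the log2cpm rule a cell is positive iff its CPM exceeds 2^threshold
#' (strict); under the count rule iff its raw count is at least
#' \code{min_count}, with no normalization. The double-positive flag is the
#' conjunction of the two single calls.
#'
#' @param dataset an \code{\link{expression_dataset}}.
#' @param rule a \code{\link{positivity_rule}}.
#' @param gene_a,gene_b the two genes of interest (default \code{"Ghsr"},
#'   \code{"Cnr1"}).
#' @return data.frame with columns \code{cell_id}, \code{cluster_id},
#'   \code{pos_a}, \code{pos_b}, \code{pos_ab} (logical), carrying the rule
#'   and gene names as attributes.
#' @export
call_positivity <- function(dataset, rule = positivity_rule(),
                            gene_a = "Ghsr", gene_b = "Cnr1") {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(rule, "positivity_rule"))
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(dataset$counts)) {
      stop("gene of interest '", g, "' absent from dataset", call. = FALSE)
    }
  }
  if (rule$mode == "log2cpm") {
    cut <- 2^rule$threshold
    pos_a <- compute_cpm(dataset, gene_a) > cut
    pos_b <- compute_cpm(dataset, gene_b) > cut
  } else {
    pos_a <- as.numeric(dataset$counts[gene_a, ]) >= rule$min_count
    pos_b <- as.numeric(dataset$counts[gene_b, ]) >= rule$min_count
  }
  out <- data.frame(cell_id = dataset$cells$cell_id,
                    cluster_id = dataset$cells$cluster_id,
                    pos_a = unname(pos_a), pos_b = unname(pos_b),
                    pos_ab = unname(pos_a & pos_b),
                    stringsAsFactors = FALSE)
  attr(out, "rule") <- rule
  attr(out, "genes") <- c(a = gene_a, b = gene_b)
  out
}
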