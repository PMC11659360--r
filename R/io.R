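#' Write an expression dataset to a directory
#'
#' Counts go to MatrixMarket (\code{counts.mtx}, genes x cells), gene ids to
#' \code{genes.tsv}, cell metadata to \code{cells.tsv} (tab-delimited with a
#' header row).
#'
#' @param dataset an \code{\link{expression_dataset}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_expression_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "expression_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(dataset$counts, file.path(dir, "counts.mtx"))
  utils::write.table(data.frame(gene_id = rownames(dataset$counts)),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an expression dataset written by \code{write_expression_dataset}
#'
#' @param dir directory containing \code{counts.mtx}, \code{genes.tsv},
#'   \code{cells.tsv}.
#' @return an \code{\link{expression_dataset}}.
#' @export
read_expression_dataset <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "counts.mtx"))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  rownames(counts) <- genes$gene_id
  expression_dataset(counts, cells)
}

#' Write / read a plain tab-delimited table
#'
#' Thin wrappers fixing the dialect (tab separator, header row, no quoting,
#' no row names) used for all the pipeline's delimited outputs: cell
#' metadata, structure tables, cluster statistics, reference tables and the
#' region summary. \code{read_tsv} restores these tables field-for-field.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return \code{write_tsv}: \code{path} invisibly; \code{read_tsv}: a
#'   data.frame.
#' @export
write_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a simulation config as a flat key/value text file
#'
#' Scalar fields are written as \code{key = value} lines; table-valued
#' fields (structures, gene rates, references, mixtures) are written as
#' sibling TSV files next to \code{path}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param path path of the key/value file; sibling tables use its stem.
#' @return \code{path}, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  stem <- sub("\\.[^.]*$", "", path)
  scalars <- c("n_clusters", "seed", "neuron_prob", "cells_per_cluster_mu",
               "cells_per_cluster_size", "library_meanlog", "library_sdlog",
               "gene_a", "gene_b", "mixture_concentration",
               "whole_brain_density", "section_thickness_um",
               "section_interval_um", "ref_noise_sd")
  lines <- vapply(scalars, function(k) paste(k, "=", config[[k]]), "")
  lines <- c(lines,
             paste("rule_mode =", config$rule$mode),
             paste("rule_threshold =", config$rule$threshold),
             paste("rule_min_count =", config$rule$min_count),
             paste("nt_weights =", paste(names(config$nt_weights),
                                         config$nt_weights, sep = ":",
                                         collapse = ",")))
  writeLines(lines, path)
  write_tsv(config$structures, paste0(stem, "_structures.tsv"))
  write_tsv(config$reference_populations, paste0(stem, "_references.tsv"))
  if (!is.null(config$gene_rates)) {
    write_tsv(config$gene_rates, paste0(stem, "_gene_rates.tsv"))
  }
  invisible(path)
}

#' Write a simulated study to a directory
#'
#' Lays out the full paired study as plain-text files: the deep dataset
#' (MatrixMarket + TSVs), spatial cell metadata, the structure table, the
#' reference table, the taxonomy with its true rates, per-structure truth,
#' and the config.
#'
#' @param study output of \code{\link{simulate_paired}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_dataset(study$deep$dataset, file.path(dir, "deep"))
  write_tsv(study$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_tsv(study$deep$truth, file.path(dir, "truth_clusters.tsv"))
  write_tsv(study$spatial$cells, file.path(dir, "spatial_cells.tsv"))
  write_tsv(study$spatial$structures, file.path(dir, "structures.tsv"))
  write_tsv(study$spatial$truth$structures,
            file.path(dir, "truth_structures.tsv"))
  write_tsv(study$references, file.path(dir, "references.tsv"))
  write_sim_config(study$config, file.path(dir, "config.txt"))
  invisible(dir)
}
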