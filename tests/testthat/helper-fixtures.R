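# Small in-code fixtures shared across test files.

# dataset from a plain count matrix (genes x cells); library sizes default to
# the supplied totals so CPM values are fully controlled by the test
toy_dataset <- function(counts, cluster = NULL, lib = NULL, nt = NULL,
                        class_label = NULL, structure = NULL) {
  n <- ncol(counts)
  cells <- data.frame(cell_id = sprintf("cell%03d", seq_len(n)),
                      cluster_id = if (is.null(cluster)) rep("c1", n) else cluster,
                      stringsAsFactors = FALSE)
  if (!is.null(lib)) cells$library_size <- lib
  if (!is.null(nt)) cells$neurotransmitter <- nt
  if (!is.null(class_label)) cells$class_label <- class_label
  if (!is.null(structure)) cells$structure_id <- structure
  expression_dataset(counts, cells)
}

# independent per-cell oracle for positivity: a literal loop over cells
# applying the definitions, no vectorization shared with the implementation
oracle_calls <- function(dataset, rule, gene_a = "A", gene_b = "B") {
  n <- ncol(dataset$counts)
  pos <- function(gene, i) {
    cnt <- as.numeric(dataset$counts[gene, i])
    if (rule$mode == "count") return(cnt >= rule$min_count)
    if (cnt == 0) return(FALSE)
    cpm <- cnt / dataset$cells$library_size[i] * 1e6
    log2(cpm) > rule$threshold
  }
  a <- vapply(seq_len(n), function(i) pos(gene_a, i), TRUE)
  b <- vapply(seq_len(n), function(i) pos(gene_b, i), TRUE)
  data.frame(cell_id = dataset$cells$cell_id, pos_a = a, pos_b = b,
             pos_ab = a & b, stringsAsFactors = FALSE)
}

# random two-gene dataset for oracle-equivalence checks
random_dataset <- function(n = 200, seed = 42, genes = c("A", "B")) {
  set.seed(seed)
  counts <- rbind(rpois(n, 1), rpois(n, 5))
  rownames(counts) <- genes
  lib <- sample(500:5e5, n, replace = TRUE)
  lib <- pmax(lib, counts[1, ] + counts[2, ])
  toy_dataset(counts, cluster = sample(paste0("c", 1:5), n, replace = TRUE),
              lib = lib)
}

# hand-made positivity calls table (for downstream modules)
toy_calls <- function(cluster, pos_a, pos_b) {
  data.frame(cell_id = sprintf("cell%03d", seq_along(cluster)),
             cluster_id = cluster, pos_a = as.logical(pos_a),
             pos_b = as.logical(pos_b),
             pos_ab = as.logical(pos_a) & as.logical(pos_b),
             stringsAsFactors = FALSE)
}

# structure table builder
toy_structures <- function(ids, regions = "R1", volume = 1,
                           covered = 1) {
  data.frame(structure_id = ids,
             region_id = rep_len(regions, length(ids)),
             volume_mm3 = rep_len(volume, length(ids)),
             covered_fraction = rep_len(covered, length(ids)),
             stringsAsFactors = FALSE)
}
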