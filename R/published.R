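#' Published whole-brain Ghsr/Cnr1 mapping results
#'
#' Per-structure whole-brain estimates reported by a published quantitative
#' mapping of Ghsr- and Cnr1-expressing cells across the mouse brain, built
#' on the Allen whole-mouse-brain transcriptomic atlas (release 20240831).
#' The printed counts and percentages serve as worked-example inputs: feeding
#' the counts through \code{\link{summarize_structures}},
#' \code{\link{region_rollup}} and \code{\link{headline_shares}} should
#' reproduce the printed percentages and bracketed region sums (up to the
#' source table's own rounding, which deviates from half-away-from-zero by
#' 0.1-0.2 in a handful of cells).
#'
#' @return \code{published_structure_summary}: data.frame of the 33 listed
#'   structures with region, Ghsr+/Cnr1+/double counts, printed percentages
#'   and integer neurotransmitter percentages.
#' @export
published_structure_summary <- function() {
  read_tsv(system.file("extdata", "published_structure_summary.tsv",
                       package = "coexatlas", mustWork = TRUE))
}

#' @rdname published_structure_summary
#' @return \code{published_region_totals}: data.frame of per-region listed
#'   (selected structures only) and total double-positive sums, including the
#'   unlisted-remainder "Other" row.
#' @export
published_region_totals <- function() {
  read_tsv(system.file("extdata", "published_region_totals.tsv",
                       package = "coexatlas", mustWork = TRUE))
}

#' @rdname published_structure_summary
#' @return \code{published_dataset_totals}: named numeric vector of the deep
#'   dataset's headline totals (Ghsr+, Cnr1+ and double-positive cell
#'   numbers, and the neuronal share of double-positives).
#' @export
published_dataset_totals <- function() {
  x <- read_tsv(system.file("extdata", "published_dataset_totals.tsv",
                            package = "coexatlas", mustWork = TRUE))
  stats::setNames(x$value, x$quantity)
}
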