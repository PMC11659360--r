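#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; the printed tables this package
#' reproduces round halves away from zero (2.5 -> 3, -2.5 -> -3).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded to \code{digits} decimals.
#' @examples
#' round_half_away(2.5)    # 3
#' round_half_away(96.25, 1)  # 96.3
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stop() with the offending values listed, capped for readability
.stop_listing <- function(msg, ids) {
  ids <- as.character(ids)
  shown <- paste(utils::head(ids, 5), collapse = ", ")
  if (length(ids) > 5) shown <- paste0(shown, ", ... (", length(ids), " total)")
  stop(msg, ": ", shown, call. = FALSE)
}

.assert_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("'", name, "' must be a single number", call. = FALSE)
  }
  if (strict && x <= lower) stop("'", name, "' must be > ", lower, call. = FALSE)
  if (!strict && x < lower) stop("'", name, "' must be >= ", lower, call. = FALSE)
  invisible(x)
}

#' Neurotransmitter categories used throughout
#'
#' The six annotated neurotransmitter classes of the shared cluster taxonomy,
#' in the column order of the region summary table, plus \code{"none"} for
#' non-neuronal clusters.
#'
#' @return character vector of category names.
#' @export
nt_categories <- function() {
  c("GABA", "GABA-Glyc", "Glut-GABA", "Glut", "Chol", "Dopa", "none")
}
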