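# Internal helpers shared across modules.

# Classed conditions so callers can distinguish bad input kinds programmatically.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("refstab_", class), "refstab_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric mean
#'
#' @param x numeric vector, all values > 0.
#' @param na.rm drop missing values before averaging.
#' @return the geometric mean of `x`.
#' @export
geomean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) abort("geometric mean requires strictly positive values", "domain_error")
  exp(mean(log(x)))
}

# Stable ordering used for all rank vectors: primary key ascending, then
# explicit tie-break columns, finally lexicographic id so results are
# permutation-invariant in the input order.
rank_with_ties <- function(primary, ..., ids) {
  ord <- order(primary, ..., ids)
  rnk <- integer(length(primary))
  rnk[ord] <- seq_along(primary)
  rnk
}

assert_gene_sample_matrix <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    abort(sprintf("%s must be a numeric gene x sample matrix", what), "format_error")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    abort(sprintf("%s must carry gene row names and sample column names", what), "format_error")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    abort(sprintf("%s has duplicated gene or sample names", what), "integrity_error")
  invisible(m)
}
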