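#' Relative quantities from Ct values
#'
#' Converts a merged gene x sample Ct matrix to relative quantities
#' q = B^(anchor_Ct - Ct) per gene, where B is the per-cycle amplification
#' factor: B = 2 by default (perfect doubling), or B = 1 + E/100 when
#' per-gene efficiencies are supplied. With the default min-Ct anchor, every
#' gene's quantities lie in (0, 1] with q = 1 at its lowest Ct (the qBase
#' convention); a per-gene mean anchor is available instead.
#'
#' @param ct a [ct_table] (merged; pivoted internally) or a gene x sample
#'   Ct matrix.
#' @param efficiencies optional named numeric vector of efficiencies in
#'   percent, one per gene (E = 100 means B = 2). All genes must be covered.
#' @param anchor `"min"` (default) or `"mean"`: the per-gene Ct used as the
#'   q = 1 reference point.
#' @return a gene x sample matrix of quantities (> 0) with attributes
#'   `anchor` and `groups` (when derived from a `ct_table`).
#' @export
relative_quantities <- function(ct, efficiencies = NULL,
                                anchor = c("min", "mean")) {
  anchor <- match.arg(anchor)
  m <- if (inherits(ct, "ct_table")) ct_matrix(ct) else ct
  assert_gene_sample_matrix(m, "Ct matrix")
  if (is.null(efficiencies)) {
    base <- rep(2, nrow(m))
  } else {
    missing_e <- setdiff(rownames(m), names(efficiencies))
    if (length(missing_e))
      abort(paste0("no efficiency supplied for gene(s): ",
                   paste(missing_e, collapse = ", ")), "config_error")
    base <- 1 + efficiencies[rownames(m)] / 100
    if (any(base <= 1)) abort("efficiencies must be > 0%", "domain_error")
  }
  anchor_ct <- if (anchor == "min") apply(m, 1, min) else rowMeans(m)
  # base and anchor_ct are per gene; column-major recycling applies them row-wise
  q <- base ^ (anchor_ct - m)
  dimnames(q) <- dimnames(m)
  attr(q, "anchor") <- anchor
  attr(q, "groups") <- attr(m, "groups")
  q
}
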