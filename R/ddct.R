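#' Multi-reference 2^-ddCt relative quantification
#'
#' Classic comparative-Ct fold changes of target genes against a reference
#' gene set. Per sample, delta-Ct = Ct(target) - mean Ct(references); the
#' arithmetic mean of reference Ct values equals (minus) the log2 of the
#' geometric mean of the reference quantities, so a multi-gene reference
#' behaves exactly like one pseudo-gene whose Ct is the per-sample mean.
#' ddCt subtracts the control group's mean delta-Ct and the per-sample fold
#' is 2^-ddCt. Group summaries are the arithmetic mean and SD of per-sample
#' folds, normalised so the control group's mean fold is exactly 1
#' (geometric-mean summarisation is available instead).
#'
#' @param ct a merged [ct_table] (one measurement per sample x gene;
#'   technical replicates are merged first if present).
#' @param targets character vector of target genes.
#' @param references non-empty character vector of reference genes,
#'   disjoint from `targets`.
#' @param control_group group label folds are expressed against.
#' @param summary `"arithmetic"` (default) or `"geometric"` group
#'   summarisation of per-sample folds.
#' @return a data.frame of class `fold_change_result`: `target`, `group`,
#'   `fold_change`, `sd`, `n`, `control_group`, with attribute
#'   `per_sample`, a data.frame of per-sample `fold` values (raw
#'   2^-ddCt, not renormalised).
#' @examples
#' ct <- ct_table(data.frame(
#'   sample_id = rep(c("c1", "t1"), each = 2),
#'   group = rep(c("Control", "T3"), each = 2),
#'   gene = rep(c("dio3", "ube2m.S"), 2), replicate = 1L,
#'   ct = c(25, 20, 23, 20)))
#' ddct_fold_change(ct, "dio3", "ube2m.S", "Control")
#' @export
ddct_fold_change <- function(ct, targets, references, control_group,
                             summary = c("arithmetic", "geometric")) {
  summary <- match.arg(summary)
  stopifnot(inherits(ct, "ct_table"))
  if (!length(references)) abort("references must be non-empty", "config_error")
  if (length(intersect(targets, references)))
    abort("targets and references must be disjoint", "config_error")
  if (!control_group %in% ct$group)
    abort(paste0("control group not present: ", control_group), "config_error")
  if (anyDuplicated(paste(ct$sample_id, ct$gene, sep = "\r")))
    ct <- merge_technical_replicates(ct)$ct
  missing_g <- setdiff(c(targets, references), ct$gene)
  if (length(missing_g))
    abort(paste0("gene(s) absent from Ct table: ", paste(missing_g, collapse = ", ")),
          "config_error")

  m <- suppressWarnings(ct_matrix(ct))
  have_refs <- colSums(is.na(m[references, , drop = FALSE])) == 0
  groups <- attr(m, "groups")
  ref_ct <- colMeans(m[references, , drop = FALSE])

  per_sample <- list(); rows <- list()
  for (tg in targets) {
    ok <- !is.na(m[tg, ]) & have_refs
    if (!all(ok))
      warning(sprintf("dropping %d sample(s) incomplete for %s", sum(!ok), tg),
              call. = FALSE)
    dct <- m[tg, ok] - ref_ct[ok]
    grp <- groups[ok]
    if (!any(grp == control_group))
      abort(paste0("no usable control-group sample for target ", tg), "config_error")
    ddct <- dct - mean(dct[grp == control_group])
    fold <- 2^(-ddct)
    per_sample[[tg]] <- data.frame(target = tg, sample_id = names(fold),
                                   group = unname(grp), fold = unname(fold),
                                   stringsAsFactors = FALSE)
    ctrl_center <- if (summary == "arithmetic") mean(fold[grp == control_group]) else
      geomean(fold[grp == control_group])
    for (g in unique(grp)) {
      f <- fold[grp == g]
      center <- if (summary == "arithmetic") mean(f) else geomean(f)
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg, group = g,
        fold_change = center / ctrl_center,
        sd = if (length(f) > 1) stats::sd(f) / ctrl_center else NA_real_,
        n = length(f), control_group = control_group,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, per_sample = do.call(rbind, per_sample),
            summary = summary,
            class = c("fold_change_result", "data.frame"))
}
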