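#' Technical-replicate concordance filtering
#'
#' Technical replicates of the same (sample, gene) well group are checked
#' for concordance: groups whose Ct spread (max - min) exceeds `max_spread`
#' cycles are discordant. Under the default policy the whole group is
#' removed from the analysis (the conservative reading of the usual
#' "duplicates differing by more than 0.5 cycles are discarded" rule);
#' under `policy = "keep_nearest"` the single replicate closest to the
#' gene's median Ct across the plate is retained instead. Surviving groups
#' are collapsed to their arithmetic mean Ct.
#'
#' @param ct a [ct_table] with technical replicates.
#' @param max_spread maximum tolerated Ct spread within a replicate group,
#'   in cycles (default 0.5; the rule is strict: spread > `max_spread`
#'   rejects).
#' @param policy `"drop_group"` (default) or `"keep_nearest"`.
#' @return a list with elements
#'   \describe{
#'     \item{ct}{a merged [ct_table], one row per surviving (sample, gene),
#'       `replicate = 1`.}
#'     \item{rejected}{data.frame of discordant groups: `sample_id`, `gene`,
#'       `n_replicates`, `spread`.}
#'   }
#' @export
merge_technical_replicates <- function(ct, max_spread = 0.5,
                                       policy = c("drop_group", "keep_nearest")) {
  policy <- match.arg(policy)
  stopifnot(inherits(ct, "ct_table"))
  key <- paste(ct$sample_id, ct$gene, sep = "\r")
  groups <- split(seq_len(nrow(ct)), key)
  gene_median <- tapply(ct$ct, ct$gene, stats::median)

  keep_rows <- list(); rej <- list()
  for (idx in groups) {
    cts <- ct$ct[idx]
    spread <- max(cts) - min(cts)
    if (spread > max_spread) {
      rej[[length(rej) + 1L]] <- data.frame(
        sample_id = ct$sample_id[idx[1]], gene = ct$gene[idx[1]],
        n_replicates = length(idx), spread = spread, stringsAsFactors = FALSE)
      if (policy == "keep_nearest") {
        nearest <- idx[which.min(abs(cts - gene_median[[ct$gene[idx[1]]]]))]
        keep_rows[[length(keep_rows) + 1L]] <- data.frame(
          sample_id = ct$sample_id[nearest], group = ct$group[nearest],
          gene = ct$gene[nearest], replicate = 1L, ct = ct$ct[nearest],
          stringsAsFactors = FALSE)
      }
    } else {
      keep_rows[[length(keep_rows) + 1L]] <- data.frame(
        sample_id = ct$sample_id[idx[1]], group = ct$group[idx[1]],
        gene = ct$gene[idx[1]], replicate = 1L, ct = mean(cts),
        stringsAsFactors = FALSE)
    }
  }
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(sample_id = character(), gene = character(),
               n_replicates = integer(), spread = numeric())
  if (!length(keep_rows)) {
    message("all replicate groups rejected; merged table is empty")
    merged_df <- data.frame(sample_id = character(), group = character(),
                            gene = character(), replicate = integer(), ct = numeric())
    merged <- structure(merged_df, metadata = attr(ct, "metadata") %||% list(),
                        class = c("ct_table", "data.frame"))
  } else {
    merged_df <- do.call(rbind, keep_rows)
    # restore the input's (sample, gene) encounter order
    merged_df <- merged_df[order(match(paste(merged_df$sample_id, merged_df$gene, sep = "\r"), key)), ]
    merged <- ct_table(merged_df, metadata = attr(ct, "metadata") %||% list())
  }
  list(ct = merged, rejected = rejected)
}
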