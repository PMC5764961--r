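#' Per-gene mean and variation of a TPM matrix
#'
#' The screening statistics behind RNA-seq candidate selection: the
#' arithmetic mean and the sample standard deviation (n - 1 denominator) of
#' each gene's abundance across samples (developmental stages).
#'
#' @param tpm a [tpm_matrix] with at least 2 samples.
#' @return a data.frame with columns `gene`, `mean_tpm`, `sd_tpm`,
#'   `n_samples`, one row per gene in input order.
#' @export
gene_variation_stats <- function(tpm) {
  assert_gene_sample_matrix(unclass(tpm), "TPM matrix")
  if (ncol(tpm) < 2) abort("need >= 2 samples to compute variation", "insufficient_data")
  m <- unclass(tpm)
  data.frame(gene = rownames(m),
             mean_tpm = rowMeans(m),
             sd_tpm = apply(m, 1, stats::sd),
             n_samples = ncol(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank candidate reference genes by least variation
#'
#' Keeps genes whose mean abundance is strictly above `min_mean_tpm` (the
#' screening floor, default 50 TPM) and ranks them by ascending SD; ties are
#' broken by ascending mean, then gene id. An empty ranking (no gene passes
#' the floor) is returned as a 0-row ranking, not an error.
#'
#' @param stats output of [gene_variation_stats()] (or a [tpm_matrix], which
#'   is converted).
#' @param min_mean_tpm expression floor in TPM; comparison is strict (`>`).
#' @return a data.frame of class `candidate_ranking` with columns `gene`,
#'   `mean_tpm`, `sd_tpm`, `rank` (1..K, ascending SD), ordered by rank, and
#'   attribute `min_mean_tpm`.
#' @export
rank_candidates <- function(stats, min_mean_tpm = 50) {
  if (inherits(stats, "tpm_matrix")) stats <- gene_variation_stats(stats)
  if (!nrow(stats)) abort("no gene statistics supplied", "insufficient_data")
  keep <- stats$mean_tpm > min_mean_tpm
  if (!any(keep))
    message("no gene passes the mean TPM floor of ", min_mean_tpm)
  kept <- stats[keep, , drop = FALSE]
  ord <- order(kept$sd_tpm, kept$mean_tpm, kept$gene)
  out <- kept[ord, c("gene", "mean_tpm", "sd_tpm"), drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, min_mean_tpm = min_mean_tpm,
            class = c("candidate_ranking", "data.frame"))
}

#' Candidate rankings with and without excluded samples
#'
#' Screens the full matrix and, in parallel, the matrix with the given
#' samples (e.g. the oocyte stage) removed, under one shared expression
#' floor. Genes that are quiet everywhere but strongly shifted in the
#' excluded stage rank far better in the "without" ranking; comparing the
#' two rankings exposes them.
#'
#' @param tpm a [tpm_matrix].
#' @param excluded_samples character vector of sample ids to drop for the
#'   second ranking (may be empty, giving identical rankings).
#' @param min_mean_tpm shared expression floor (strict `>`).
#' @return a list with elements `with_all` and `without_excluded`, each a
#'   `candidate_ranking`.
#' @export
dual_ranking <- function(tpm, excluded_samples = character(), min_mean_tpm = 50) {
  if (!all(excluded_samples %in% colnames(tpm)))
    abort("excluded_samples must be a subset of the matrix sample ids", "config_error")
  remaining <- setdiff(colnames(tpm), excluded_samples)
  if (length(remaining) < 2)
    abort("exclusion leaves fewer than 2 samples", "insufficient_data")
  list(with_all = rank_candidates(tpm, min_mean_tpm),
       without_excluded = rank_candidates(
         tpm_matrix(unclass(tpm)[, remaining, drop = FALSE]), min_mean_tpm))
}

#' Genes in the top n of two rankings
#'
#' @param rank_a,rank_b `candidate_ranking` objects.
#' @param n number of top-ranked genes to intersect (truncated, with a
#'   message, if either ranking is shorter).
#' @return a data.frame with columns `gene`, `rank_a`, `rank_b`, ordered by
#'   `rank_a`.
#' @export
overlap_top <- function(rank_a, rank_b, n) {
  if (n < 1) abort("n must be >= 1", "config_error")
  n_eff <- min(n, nrow(rank_a), nrow(rank_b))
  if (n_eff < n)
    message("top-n truncated to ", n_eff, " (shorter ranking)")
  top_a <- rank_a[rank_a$rank <= n_eff, ]
  top_b <- rank_b[rank_b$rank <= n_eff, ]
  genes <- intersect(top_a$gene, top_b$gene)
  out <- data.frame(gene = genes,
                    rank_a = top_a$rank[match(genes, top_a$gene)],
                    rank_b = top_b$rank[match(genes, top_b$gene)],
                    stringsAsFactors = FALSE)
  out[order(out$rank_a), , drop = FALSE]
}

#' Keep the better-ranked homeolog of each duplicated gene
#'
#' Allotetraploid genomes carry two homeologous copies of many genes,
#' conventionally suffixed `.L` and `.S`. When both copies of a base name
#' appear in a ranking, only the better-ranked copy is retained; genes
#' without a homeolog partner (or without a suffix) pass through. Ranks are
#' renumbered 1..K after selection.
#'
#' @param ranking a `candidate_ranking`.
#' @return a `candidate_ranking` with at most one copy per base gene name.
#' @export
select_homeolog <- function(ranking) {
  base <- sub("\\.(L|S)$", "", ranking$gene)
  suffixed <- grepl("\\.(L|S)$", ranking$gene)
  keep <- rep(TRUE, nrow(ranking))
  for (b in unique(base[suffixed])) {
    idx <- which(base == b & suffixed)
    if (length(idx) > 1) {
      best <- idx[which.min(ranking$rank[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  out <- ranking[keep, , drop = FALSE]
  out <- out[order(out$rank), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, min_mean_tpm = attr(ranking, "min_mean_tpm"),
            class = class(ranking))
}
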