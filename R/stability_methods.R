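# The four reference-gene stability statistics. All operate on complete
# gene x sample matrices; logs are base 2 throughout (one PCR cycle is one
# doubling, so Ct differences are log2 abundance ratios).

stability_result <- function(gene, value, rank, method,
                             orientation = "lower_is_stable", extra = NULL) {
  out <- data.frame(gene = gene, value = value, rank = rank,
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, method = method, orientation = orientation,
            class = c("stability_result", "data.frame"))
}

#' Comparative delta-Ct stability
#'
#' For every pair of candidate genes, the per-sample Ct difference
#' (delta-Ct) is computed and its standard deviation (n - 1) taken across
#' samples; a gene's stability value is the arithmetic mean of these SDs
#' over all its pairings. Genes whose delta-Ct to every other candidate is
#' nearly constant are stable; rank 1 is the lowest mean SD.
#'
#' @param ct_matrix gene x sample Ct matrix (>= 3 genes, >= 3 samples), as
#'   produced by [ct_matrix()].
#' @return a `stability_result` data.frame (`gene`, `value`, `rank`).
#' @export
delta_ct_stability <- function(ct_matrix) {
  assert_gene_sample_matrix(ct_matrix, "Ct matrix")
  g <- nrow(ct_matrix)
  if (g < 3) abort("delta-Ct stability needs >= 3 genes", "insufficient_data")
  if (ncol(ct_matrix) < 3) abort("delta-Ct stability needs >= 3 samples", "insufficient_data")
  pair_sd <- pairwise_ct_sd(ct_matrix)
  vals <- rowMeans(pair_sd) * g / (g - 1)  # exclude the zero self-pair
  rk <- rank_with_ties(vals, ids = rownames(ct_matrix))
  stability_result(rownames(ct_matrix), unname(vals), rk, "delta_ct")
}

# SD over samples of Ct_j - Ct_k for all gene pairs (diagonal 0).
pairwise_ct_sd <- function(m) {
  g <- nrow(m)
  out <- matrix(0, g, g, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(g - 1)) {
    for (k in (j + 1):g) {
      s <- stats::sd(m[j, ] - m[k, ])
      out[j, k] <- s; out[k, j] <- s
    }
  }
  out
}

#' geNorm expression stability (M) with iterative exclusion
#'
#' The pairwise variation of genes j and k is V_jk, the standard deviation
#' over samples of log2(q_j / q_k); a gene's M value is the mean of V_jk
#' over all other candidates. The least stable gene (highest M) is removed
#' and M recomputed, repeating until two genes remain; those two share the
#' final M and cannot be ranked apart by the method itself.
#'
#' @param quantities gene x sample matrix of relative quantities, all > 0
#'   (see [relative_quantities()]); >= 3 genes and >= 3 samples.
#' @return a list with elements
#'   \describe{
#'     \item{result}{a `stability_result` whose `value` is each gene's M at
#'       its exclusion step (the final pair share the 2-gene M); ranks follow
#'       the reverse exclusion order, the final pair ordered by their M at
#'       the penultimate iteration.}
#'     \item{trace}{a `genorm_trace`: `exclusion_order` (first = least
#'       stable), `m_at_exclusion`, `final_pair`, and `iterations`, a list of
#'       per-iteration M vectors.}
#'   }
#' @export
genorm <- function(quantities) {
  assert_gene_sample_matrix(quantities, "quantity matrix")
  if (any(quantities <= 0)) abort("quantities must be > 0", "domain_error")
  if (nrow(quantities) < 3) abort("geNorm needs >= 3 genes", "insufficient_data")
  if (ncol(quantities) < 3) abort("geNorm needs >= 3 samples", "insufficient_data")
  lq <- log2(quantities)
  remaining <- rownames(quantities)
  excluded <- character(); m_at_exclusion <- numeric()
  iterations <- list()
  penultimate_m <- NULL
  while (length(remaining) > 2) {
    m <- genorm_m(lq[remaining, , drop = FALSE])
    iterations[[length(iterations) + 1L]] <- m
    worst <- pick_worst_genorm(m, lq[remaining, , drop = FALSE])
    excluded <- c(excluded, worst)
    m_at_exclusion <- c(m_at_exclusion, m[[worst]])
    remaining <- setdiff(remaining, worst)
    if (length(remaining) == 2) penultimate_m <- m[remaining]
  }
  final_m <- genorm_m(lq[remaining, , drop = FALSE])
  iterations[[length(iterations) + 1L]] <- final_m
  # final pair ordered by M in the last 3-gene iteration; ties lexicographic
  pair_ord <- remaining[order(penultimate_m[remaining], remaining)]
  genes <- c(pair_ord, rev(excluded))  # rank 1 first; last excluded = rank 3
  values <- c(final_m[pair_ord], rev(m_at_exclusion))
  rk <- seq_along(genes)
  trace <- structure(list(exclusion_order = excluded,
                          m_at_exclusion = m_at_exclusion,
                          final_pair = sort(remaining),
                          iterations = iterations),
                     class = "genorm_trace")
  list(result = stability_result(genes, unname(values), rk, "genorm"),
       trace = trace)
}

# Mean over partners of SD(log2 ratio): M_j for every gene of a log2 matrix.
genorm_m <- function(lq) {
  g <- nrow(lq)
  v <- matrix(0, g, g, dimnames = list(rownames(lq), rownames(lq)))
  for (j in seq_len(g - 1)) {
    for (k in (j + 1):g) {
      s <- stats::sd(lq[j, ] - lq[k, ])
      v[j, k] <- s; v[k, j] <- s
    }
  }
  rowSums(v) / (g - 1)
}

# Exclusion tie rule: highest M; among (numerical) ties, the gene with the
# larger pairwise variation to the current best (lowest-M) gene; then
# lexicographically last.
pick_worst_genorm <- function(m, lq, tol = 1e-12) {
  worst_val <- max(m)
  tied <- names(m)[m >= worst_val - tol]
  if (length(tied) == 1) return(tied)
  best <- names(m)[which.min(m)]
  v_to_best <- vapply(tied, function(g) {
    if (g == best) -Inf else stats::sd(lq[g, ] - lq[best, ])
  }, numeric(1))
  # larger variation to the best gene goes first; residual ties lexicographic
  tied[order(-v_to_best, tied)][1]
}

#' geNorm pairwise variation (V) and the optimal number of references
#'
#' The normalisation factor NF_n of a sample is the geometric mean of the n
#' best-ranked genes' quantities. V_n/n+1 is the standard deviation over
#' samples of log2(NF_n / NF_{n+1}); a small V means adding the (n+1)-th
#' gene hardly changes normalisation, so n genes suffice. The recommended n
#' is the smallest with V below `threshold` (conventionally 0.15); when no
#' n satisfies it, all genes are recommended and `threshold_met` is FALSE.
#'
#' @param quantities the quantity matrix given to [genorm()].
#' @param genorm_fit the list returned by [genorm()] on those quantities
#'   (or its `result` component).
#' @param threshold V cut-off below which n references are deemed enough.
#' @return a list: `v` (data.frame `n`, `v` for n = 2..G-1),
#'   `recommended_n`, `threshold`, `threshold_met`.
#' @export
genorm_v <- function(quantities, genorm_fit, threshold = 0.15) {
  res <- if (is.list(genorm_fit) && !is.data.frame(genorm_fit)) genorm_fit$result else genorm_fit
  if (!setequal(res$gene, rownames(quantities)))
    abort("genorm result and quantity matrix cover different genes", "integrity_error")
  g <- nrow(quantities)
  if (g < 4) abort("V series needs >= 4 genes", "insufficient_data")
  ranked <- res$gene[order(res$rank)]
  lq <- log2(quantities)
  nf_log <- function(n) colMeans(lq[ranked[seq_len(n)], , drop = FALSE])  # log2 geometric mean
  v <- vapply(2:(g - 1), function(n) stats::sd(nf_log(n) - nf_log(n + 1)), numeric(1))
  vdf <- data.frame(n = 2:(g - 1), v = v)
  ok <- which(v < threshold)
  list(v = vdf,
       recommended_n = if (length(ok)) vdf$n[ok[1]] else g,
       threshold = threshold,
       threshold_met = length(ok) > 0)
}

#' BestKeeper descriptive statistics and index correlation
#'
#' Works on raw Ct values. Per gene it reports the arithmetic and geometric
#' mean Ct, range, "SD" (the mean absolute deviation from the arithmetic
#' mean, in cycles — the convention of the original BestKeeper tool; the
#' classical n-1 SD is included as `sd_classic`) and CV% = SD/AM x 100. The
#' BestKeeper index is the per-sample geometric mean Ct over all candidate
#' genes; each gene's Pearson correlation with the index (with two-sided
#' p-value) is reported alongside. The primary stability ordering is by
#' ascending SD; genes with SD > 1 cycle are flagged inconsistent.
#'
#' @param ct_matrix gene x sample Ct matrix (>= 2 genes, >= 3 samples, all
#'   Ct > 0).
#' @return a list of class `bestkeeper_result`:
#'   \describe{
#'     \item{result}{`stability_result` ordered by SD (`value` = SD).}
#'     \item{gene_stats}{per-gene descriptives: `gene`, `arith_mean`,
#'       `geo_mean`, `min`, `max`, `sd` (MAD), `sd_classic`, `cv_pct`,
#'       `r_index`, `p_value`, `inconsistent`.}
#'     \item{index}{per-sample geometric mean Ct.}
#'   }
#' @export
bestkeeper <- function(ct_matrix) {
  assert_gene_sample_matrix(ct_matrix, "Ct matrix")
  if (any(ct_matrix <= 0)) abort("Ct values must be > 0", "domain_error")
  if (nrow(ct_matrix) < 2) abort("BestKeeper needs >= 2 genes", "insufficient_data")
  if (ncol(ct_matrix) < 3) abort("BestKeeper needs >= 3 samples", "insufficient_data")
  am <- rowMeans(ct_matrix)
  mad_ <- rowMeans(abs(ct_matrix - am))
  index <- apply(ct_matrix, 2, geomean)
  cor_stats <- t(apply(ct_matrix, 1, function(ct_row) {
    if (stats::sd(index) == 0 || stats::sd(ct_row) == 0)
      return(c(r = NA_real_, p = NA_real_))
    ht <- stats::cor.test(ct_row, index)
    c(r = unname(ht$estimate), p = ht$p.value)
  }))
  gene_stats <- data.frame(
    gene = rownames(ct_matrix),
    arith_mean = unname(am),
    geo_mean = apply(ct_matrix, 1, geomean),
    min = apply(ct_matrix, 1, min),
    max = apply(ct_matrix, 1, max),
    sd = unname(mad_),
    sd_classic = apply(ct_matrix, 1, stats::sd),
    cv_pct = unname(mad_ / am * 100),
    r_index = cor_stats[, "r"],
    p_value = cor_stats[, "p"],
    inconsistent = unname(mad_ > 1),
    row.names = NULL, stringsAsFactors = FALSE)
  rk <- rank_with_ties(gene_stats$sd, ids = gene_stats$gene)
  structure(list(result = stability_result(gene_stats$gene, gene_stats$sd, rk,
                                           "bestkeeper",
                                           extra = data.frame(r_index = gene_stats$r_index)),
                 gene_stats = gene_stats,
                 index = index),
            class = "bestkeeper_result")
}

#' NormFinder model-based stability
#'
#' Decomposes log2-scale expression into gene, sample, group-specific gene
#' effects and noise. Samples are first centred (the per-sample mean over
#' genes is removed, absorbing loading differences); per group the sample
#' variance of the residuals is decontaminated for the contribution of the
#' other genes' noise, giving an intragroup variance estimate per gene and
#' group. With one group the stability value is the intragroup SD. With
#' several groups the intergroup difference d of each gene (its group mean
#' residual minus its overall mean) is shrunk toward zero in proportion to
#' its sampling noise, and the stability value combines |d| with the
#' intragroup uncertainty. Lower is more stable; rank 1 is best.
#'
#' @param log_quantities gene x sample matrix of log2 relative quantities
#'   (e.g. `log2(relative_quantities(ct))`); >= 3 genes (the
#'   decontamination divides by 1 - 2/k) and every group with >= 2 samples.
#' @param groups optional character vector (or named sample->group vector)
#'   of group labels, one per column; `NULL` treats all samples as one group.
#' @return a list of class `normfinder_result`:
#'   \describe{
#'     \item{result}{`stability_result` (`value` = stability rho).}
#'     \item{intragroup_var}{gene x group matrix of decontaminated variance
#'       estimates (negative estimates truncated to 0; truncations counted
#'       in `n_truncated`).}
#'     \item{intergroup_d}{gene x group matrix of (unshrunk) intergroup
#'       differences, log2 units; columns sum to ~0. `NULL` for one group.}
#'     \item{group_sizes}{named vector of samples per group.}
#'   }
#' @export
normfinder <- function(log_quantities, groups = NULL) {
  assert_gene_sample_matrix(log_quantities, "log-quantity matrix")
  k <- nrow(log_quantities)
  if (k < 3)
    abort("NormFinder needs >= 3 genes (variance decontamination divides by 1 - 2/k)",
          "insufficient_data")
  n <- ncol(log_quantities)
  if (is.null(groups)) groups <- rep("all", n)
  if (!is.null(names(groups))) groups <- groups[colnames(log_quantities)]
  groups <- as.character(groups)
  if (length(groups) != n) abort("one group label per sample required", "config_error")
  sizes <- table(groups)
  if (any(sizes < 2)) abort("every group needs >= 2 samples", "insufficient_data")
  glev <- names(sizes)

  # sample centering removes per-sample global shifts
  r <- sweep(log_quantities, 2, colMeans(log_quantities))

  n_trunc <- 0L
  sig2 <- matrix(NA_real_, k, length(glev), dimnames = list(rownames(log_quantities), glev))
  for (g in glev) {
    rg <- r[, groups == g, drop = FALSE]
    v <- apply(rg, 1, stats::var)
    s_g <- (k / (k - 1)) * sum(v)
    est <- (v - s_g / k^2) / (1 - 2 / k)
    n_trunc <- n_trunc + sum(est < 0)
    sig2[, g] <- pmax(0, est)
  }

  if (length(glev) == 1) {
    rho <- sqrt(sig2[, 1])
    d <- NULL
  } else {
    overall <- rowMeans(r)
    d <- vapply(glev, function(g) rowMeans(r[, groups == g, drop = FALSE]) - overall,
                numeric(k))
    dimnames(d) <- list(rownames(log_quantities), glev)
    ng <- as.numeric(sizes[glev])
    rho <- numeric(k)
    for (i in seq_len(k)) {
      noise <- sig2[i, ] / ng
      gamma2 <- max(0, stats::var(d[i, ]) - mean(noise))
      shrink <- gamma2 / (gamma2 + noise)
      d_tilde <- d[i, ] * shrink
      rho[i] <- mean(abs(d_tilde) + sqrt(noise * shrink))
    }
  }
  rk <- rank_with_ties(rho, ids = rownames(log_quantities))
  structure(list(result = stability_result(rownames(log_quantities), unname(rho),
                                           rk, "normfinder"),
                 intragroup_var = sig2,
                 intergroup_d = d,
                 group_sizes = stats::setNames(as.integer(sizes), names(sizes)),
                 n_truncated = n_trunc),
            class = "normfinder_result")
}

#' Consensus ranking across stability methods
#'
#' Aggregates several `stability_result` rankings by the geometric mean of
#' each gene's ranks (the RefFinder-style comprehensive ranking). Ties are
#' broken by the gene's best single-method rank, then gene id.
#'
#' @param results list of `stability_result` objects covering the same
#'   gene set.
#' @return a data.frame: `gene`, `geomean_rank`, one rank column per
#'   method, and `rank` (the consensus rank).
#' @export
consensus_rank <- function(results) {
  if (!length(results)) abort("no stability results supplied", "config_error")
  genes <- sort(results[[1]]$gene)
  for (r in results) {
    if (!setequal(r$gene, genes))
      abort("stability results cover different gene sets", "integrity_error")
  }
  rank_mat <- vapply(results, function(r) r$rank[match(genes, r$gene)],
                     numeric(length(genes)))
  rank_mat <- matrix(rank_mat, nrow = length(genes),
                     dimnames = list(genes, vapply(results, attr, "", "method")))
  gm <- exp(rowMeans(log(rank_mat)))
  best <- apply(rank_mat, 1, min)
  ord <- order(gm, best, genes)
  out <- data.frame(gene = genes, geomean_rank = unname(gm),
                    rank_mat, row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
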