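#' Fit a reference-gene stability analysis
#'
#' The central model-fitting entry point: given RT-qPCR measurements of a
#' panel of candidate reference genes across samples, it runs the four
#' independent stability statistics — comparative delta-Ct, geNorm (M and
#' pairwise variation V), BestKeeper and NormFinder — and aggregates them
#' into a consensus ranking by geometric mean of ranks.
#'
#' delta-Ct and BestKeeper operate on the raw Ct matrix; geNorm and
#' NormFinder operate on relative quantities q = B^(min Ct - Ct) per gene
#' (B = 2 unless per-gene efficiencies are supplied), NormFinder on their
#' log2. Logs are base 2 throughout: a Ct difference of one cycle is one
#' doubling.
#'
#' @param ct a [ct_table] (technical replicates are merged first if
#'   present, using `max_spread`), or a gene x sample Ct matrix.
#' @param groups optional sample-to-group labelling for NormFinder's
#'   intergroup component: a character vector named by sample id, or `NULL`
#'   to take groups from the `ct_table`. Grouped NormFinder is only used
#'   when every group has at least `min_group_size` samples; below that the
#'   intergroup variance component is estimated too poorly to be useful
#'   (the original method's guidance), so the analysis falls back to
#'   single-group mode with a message. [normfinder()] itself accepts any
#'   grouping with >= 2 samples per group.
#' @param min_group_size smallest per-group sample count for which grouped
#'   NormFinder is attempted (default 8).
#' @param methods which statistics to run (default all four).
#' @param efficiencies optional named per-gene amplification efficiencies
#'   (percent) used when converting Ct to quantities.
#' @param v_threshold geNorm V cut-off for the recommended number of
#'   reference genes (conventionally 0.15).
#' @param max_spread technical-replicate concordance limit, cycles.
#' @return an object of class `ref_stability` with components
#'   `ct_matrix`, `quantities`, `results` (named list of
#'   `stability_result`), `bestkeeper`, `normfinder` (full method objects),
#'   `genorm_trace`, `v` (V series list or `NULL` when < 4 genes),
#'   `consensus`, `groups`, `call`. Methods: [print.ref_stability()],
#'   [summary.ref_stability()], [plot.ref_stability()],
#'   [stability_ranks()], [recommended_references()].
#' @examples
#' sim <- simulate_ct_dataset(ct_sim_design(seed = 7))
#' fit <- ref_stability(sim$ct)
#' fit
#' head(stability_ranks(fit))
#' recommended_references(fit)
#' @export
ref_stability <- function(ct, groups = NULL,
                          methods = c("delta_ct", "genorm", "bestkeeper", "normfinder"),
                          efficiencies = NULL, v_threshold = 0.15,
                          max_spread = 0.5, min_group_size = 8) {
  methods <- match.arg(methods, several.ok = TRUE)
  cl <- match.call()
  if (inherits(ct, "ct_table")) {
    if (anyDuplicated(paste(ct$sample_id, ct$gene, sep = "\r"))) {
      ct <- merge_technical_replicates(ct, max_spread = max_spread)$ct
    }
    m <- ct_matrix(ct)
  } else {
    m <- ct
    assert_gene_sample_matrix(m, "Ct matrix")
  }
  if (is.null(groups)) groups <- attr(m, "groups")
  q <- relative_quantities(m, efficiencies = efficiencies)

  results <- list()
  bk <- nf <- trace <- vres <- NULL
  if ("delta_ct" %in% methods) results$delta_ct <- delta_ct_stability(m)
  if ("genorm" %in% methods) {
    gn <- genorm(q)
    results$genorm <- gn$result
    trace <- gn$trace
    if (nrow(q) >= 4) vres <- genorm_v(q, gn, threshold = v_threshold)
  }
  if ("bestkeeper" %in% methods) {
    bk <- bestkeeper(m)
    results$bestkeeper <- bk$result
  }
  if ("normfinder" %in% methods) {
    nf_groups <- groups
    if (!is.null(nf_groups)) {
      sizes <- table(nf_groups[colnames(m)])
      if (any(sizes < min_group_size) || length(sizes) < 2) {
        if (length(sizes) >= 2)
          message("groups smaller than ", min_group_size,
                  " samples; NormFinder run in single-group mode")
        nf_groups <- NULL
      }
    }
    nf <- normfinder(log2(q), groups = nf_groups)
    results$normfinder <- nf$result
  }
  consensus <- if (length(results) > 1) consensus_rank(results) else {
    r <- results[[1]]
    data.frame(gene = r$gene, geomean_rank = r$rank, rank = r$rank,
               stringsAsFactors = FALSE)
  }
  structure(list(ct_matrix = m, quantities = q, results = results,
                 bestkeeper = bk, normfinder = nf, genorm_trace = trace,
                 v = vres, consensus = consensus, groups = groups, call = cl),
            class = "ref_stability")
}

#' @export
print.ref_stability <- function(x, ...) {
  cat("Reference-gene stability analysis\n")
  cat(sprintf("  %d genes x %d samples; methods: %s\n",
              nrow(x$ct_matrix), ncol(x$ct_matrix),
              paste(names(x$results), collapse = ", ")))
  top <- utils::head(x$consensus$gene, 3)
  cat("  consensus top genes:", paste(top, collapse = ", "), "\n")
  if (!is.null(x$v))
    cat(sprintf("  geNorm V: %d reference gene(s) recommended (V threshold %.2f%s)\n",
                x$v$recommended_n, x$v$threshold,
                if (x$v$threshold_met) "" else ", threshold never met"))
  invisible(x)
}

#' Summarise a stability fit
#'
#' @param object a `ref_stability` fit.
#' @param ... unused.
#' @return a list of class `summary.ref_stability` with the per-method
#'   value/rank table, the V series and the consensus.
#' @export
summary.ref_stability <- function(object, ...) {
  structure(list(table = stability_ranks(object),
                 v = object$v, consensus = object$consensus,
                 n_genes = nrow(object$ct_matrix),
                 n_samples = ncol(object$ct_matrix)),
            class = "summary.ref_stability")
}

#' @export
print.summary.ref_stability <- function(x, ...) {
  cat(sprintf("Stability of %d candidate reference genes over %d samples\n\n",
              x$n_genes, x$n_samples))
  print(x$table, digits = 4)
  if (!is.null(x$v)) {
    cat("\ngeNorm pairwise variation:\n")
    print(x$v$v, digits = 4)
    cat(sprintf("recommended number of reference genes: %d\n", x$v$recommended_n))
  }
  invisible(x)
}

#' Combined value/rank table of a stability fit
#'
#' @param fit a `ref_stability` object.
#' @return a data.frame with one row per gene, per-method `<method>_value`
#'   and `<method>_rank` columns, and the consensus `geomean_rank` and
#'   `rank`, ordered by consensus rank.
#' @export
stability_ranks <- function(fit) {
  stopifnot(inherits(fit, "ref_stability"))
  out <- fit$consensus[, c("gene", "geomean_rank")]
  for (mth in names(fit$results)) {
    r <- fit$results[[mth]]
    out[[paste0(mth, "_value")]] <- r$value[match(out$gene, r$gene)]
    out[[paste0(mth, "_rank")]] <- r$rank[match(out$gene, r$gene)]
  }
  out$rank <- fit$consensus$rank[match(out$gene, fit$consensus$gene)]
  out[order(out$rank), , drop = FALSE]
}

#' Recommended reference-gene set
#'
#' The geNorm-V-recommended number of genes, taken in consensus-rank order
#' (or geNorm order when `by = "genorm"`).
#'
#' @param fit a `ref_stability` object.
#' @param by ranking to draw genes from.
#' @return character vector of gene names.
#' @export
recommended_references <- function(fit, by = c("consensus", "genorm")) {
  by <- match.arg(by)
  n <- if (!is.null(fit$v)) fit$v$recommended_n else 2L
  ranking <- if (by == "consensus") fit$consensus$gene else
    fit$results$genorm$gene[order(fit$results$genorm$rank)]
  ranking[seq_len(min(n, length(ranking)))]
}

#' Plot a stability fit
#'
#' Two base-graphics panels: per-gene geNorm M (or the first available
#' method's values) in rank order, and the geNorm V series with the
#' decision threshold.
#'
#' @param x a `ref_stability` object.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.ref_stability <- function(x, ...) {
  has_v <- !is.null(x$v)
  old <- graphics::par(mfrow = c(1, if (has_v) 2 else 1),
                       mar = c(7, 4, 3, 1))
  on.exit(graphics::par(old))
  r <- x$results$genorm %||% x$results[[1]]
  r <- r[order(r$rank), ]
  graphics::barplot(r$value, names.arg = r$gene, las = 2,
                    ylab = paste(attr(r, "method"), "stability value"),
                    main = "Candidate stability (lower = more stable)", ...)
  if (has_v) {
    graphics::plot(x$v$v$n, x$v$v$v, type = "b", pch = 19,
                   xlab = "n reference genes", ylab = expression(V[n/n + 1]),
                   main = "geNorm pairwise variation")
    graphics::abline(h = x$v$threshold, lty = 2)
  }
  invisible(x)
}
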