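# Synthetic-data generators with fully specified ground truth. The point is
# that every downstream stage can be validated by parameter recovery:
# designed noise SDs, group effects, stable-gene identity and fold changes
# are returned alongside the data, never re-derived from it.

#' Design for a synthetic Ct experiment
#'
#' Encodes the generative model for an RT-qPCR experiment:
#' Ct(sample s in group g, gene i, replicate r) =
#'   baseline_i + offset_ig + shift_s + bio_noise(0, sigma_i) +
#'   rep_noise(0, rep_noise_sd),
#' with biological noise drawn once per (sample, gene) and replicate noise
#' per well. A fraction `discordant_rate` of wells additionally has one
#' replicate displaced by > 0.5 cycles, emulating pipetting failures that
#' the replicate-concordance filter must catch.
#'
#' The default design mirrors a typical staged developmental study: 16
#' candidate genes over 8 stages with 3 biological replicates each and
#' duplicate wells, per-gene biological SDs spanning 0.05-1.0 cycles with
#' one uniquely stable pair (the two lowest SDs well separated from the
#' rest), no group-specific expression shifts, and a modest per-sample
#' loading shift.
#'
#' @param genes character vector of gene names.
#' @param baseline_ct per-gene baseline Ct, cycles.
#' @param sigma per-gene biological noise SD, cycles (>= 0).
#' @param groups character vector of group (stage/treatment) labels.
#' @param n_per_group biological replicates (samples) per group.
#' @param group_offsets optional gene x group matrix of expression offsets
#'   in cycles (negative = higher expression); default all zero.
#' @param shift_sd SD of the per-sample global Ct shift, cycles.
#' @param tech_reps technical replicates per well group (>= 1).
#' @param rep_noise_sd technical replicate noise SD, cycles.
#' @param discordant_rate probability a (sample, gene) well group is made
#'   discordant (spread forced > 0.5 cycles).
#' @param target_genes genes whose `group_offsets` encode true biological
#'   effects (reported as fold changes in the ground truth rather than as
#'   instability).
#' @param control_group group that fold changes are expressed against.
#' @param seed integer seed; the generator is a pure function of
#'   (design, seed).
#' @return a list of class `ct_sim_design`.
#' @seealso [simulate_ct_dataset()]
#' @export
ct_sim_design <- function(genes = sprintf("g%02d", 1:16),
                          baseline_ct = seq(18, 30, length.out = length(genes)),
                          sigma = c(0.05, 0.07,
                                    seq(0.25, 1.0, length.out = length(genes) - 2)),
                          groups = c("NF0", "NF1", "NF10", "NF21",
                                     "NF37", "NF41", "NF48", "NF50"),
                          n_per_group = 3,
                          group_offsets = NULL,
                          shift_sd = 0.2,
                          tech_reps = 2,
                          rep_noise_sd = 0.05,
                          discordant_rate = 0.02,
                          target_genes = character(),
                          control_group = groups[1],
                          seed = 1L) {
  if (is.null(group_offsets))
    group_offsets <- matrix(0, length(genes), length(groups),
                            dimnames = list(genes, groups))
  if (length(baseline_ct) != length(genes) || length(sigma) != length(genes))
    abort("baseline_ct and sigma must have one value per gene", "config_error")
  if (any(sigma < 0) || shift_sd < 0 || rep_noise_sd < 0)
    abort("all noise SDs must be >= 0", "config_error")
  if (discordant_rate < 0 || discordant_rate > 1)
    abort("discordant_rate must be a probability", "config_error")
  if (n_per_group < 1 || tech_reps < 1)
    abort("group sizes and replicate counts must be >= 1", "config_error")
  if (!all(dim(group_offsets) == c(length(genes), length(groups))))
    abort("group_offsets must be genes x groups", "config_error")
  if (!all(target_genes %in% genes))
    abort("target_genes must be a subset of genes", "config_error")
  structure(list(genes = genes, baseline_ct = stats::setNames(baseline_ct, genes),
                 sigma = stats::setNames(sigma, genes), groups = groups,
                 n_per_group = n_per_group, group_offsets = group_offsets,
                 shift_sd = shift_sd, tech_reps = tech_reps,
                 rep_noise_sd = rep_noise_sd, discordant_rate = discordant_rate,
                 target_genes = target_genes, control_group = control_group,
                 seed = as.integer(seed)),
            class = "ct_sim_design")
}

#' Simulate an RT-qPCR Ct dataset with known ground truth
#'
#' @param design a [ct_sim_design()].
#' @return a list with elements
#'   \describe{
#'     \item{ct}{a [ct_table] of simulated wells.}
#'     \item{truth}{a `synthetic_ground_truth` list: `stability_order`
#'       (most stable first, by effective per-sample SD = sqrt(sigma^2 +
#'       population variance of the gene's group offsets), candidate genes
#'       only), `stable_pair`, `sigma`, `effective_sd`, `group_offsets`,
#'       `true_fold_changes` (target x group matrix of 2^-(offset -
#'       control offset)), `control_group`, `discordant_wells` (data.frame
#'       of injected failures), and the `design` itself.}
#'   }
#' @export
simulate_ct_dataset <- function(design) {
  if (!inherits(design, "ct_sim_design")) abort("design must be a ct_sim_design", "config_error")
  set.seed(design$seed)
  genes <- design$genes
  samples <- data.frame(
    sample_id = as.vector(t(outer(design$groups, seq_len(design$n_per_group),
                                  function(g, b) paste0(g, "_b", b)))),
    group = rep(design$groups, each = design$n_per_group),
    stringsAsFactors = FALSE)
  n_s <- nrow(samples)
  shift <- stats::rnorm(n_s, 0, design$shift_sd)

  rows <- vector("list", n_s * length(genes))
  disc <- list()
  idx <- 0L
  for (s in seq_len(n_s)) {
    g_lab <- samples$group[s]
    for (i in seq_along(genes)) {
      mu <- design$baseline_ct[i] + design$group_offsets[i, g_lab] + shift[s] +
        stats::rnorm(1, 0, design$sigma[i])
      cts <- mu + stats::rnorm(design$tech_reps, 0, design$rep_noise_sd)
      discordant <- design$tech_reps >= 2 &&
        stats::runif(1) < design$discordant_rate
      if (discordant) {
        # displaced off the first replicate so the group spread is
        # guaranteed to exceed the 0.5-cycle concordance limit
        cts[design$tech_reps] <- cts[1] + 0.6 + abs(stats::rnorm(1, 0, 0.3))
        disc[[length(disc) + 1L]] <- data.frame(
          sample_id = samples$sample_id[s], gene = genes[i],
          stringsAsFactors = FALSE)
      }
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        sample_id = samples$sample_id[s], group = g_lab, gene = genes[i],
        replicate = seq_len(design$tech_reps), ct = cts,
        stringsAsFactors = FALSE)
    }
  }
  ct <- ct_table(do.call(rbind, rows))

  # effective per-sample SD combines biological noise with between-group
  # expression shifts (population variance over samples)
  off_var <- apply(design$group_offsets, 1, function(o) {
    o_s <- rep(o, each = design$n_per_group)
    mean((o_s - mean(o_s))^2)
  })
  eff_sd <- sqrt(design$sigma^2 + off_var)
  candidates <- setdiff(genes, design$target_genes)
  stab_order <- candidates[order(eff_sd[candidates], candidates)]
  fold <- NULL
  if (length(design$target_genes)) {
    off <- design$group_offsets[design$target_genes, , drop = FALSE]
    fold <- 2^-(off - off[, design$control_group])
  }
  truth <- structure(list(
    stability_order = stab_order,
    stable_pair = stab_order[1:2],
    sigma = design$sigma, effective_sd = eff_sd,
    group_offsets = design$group_offsets,
    true_fold_changes = fold, control_group = design$control_group,
    discordant_wells = if (length(disc)) do.call(rbind, disc) else
      data.frame(sample_id = character(), gene = character()),
    design = design), class = "synthetic_ground_truth")
  list(ct = ct, truth = truth)
}

#' Simulate a TPM matrix with designed mean/SD structure
#'
#' Gene i's abundance across samples is mean_i + sd_i * z, where z is one
#' shared standardised profile (sample mean 0, sample SD exactly 1, values
#' bounded within about 2.6 SDs), plus optional extra Gaussian noise. With
#' `noise_sd = 0` every gene's sample SD is therefore exactly its designed
#' SD, so the designed least-variation ranking is recovered exactly.
#' Designated genes additionally receive a large offset in one sample (an
#' "oocyte-like" stage), reproducing the situation where a gene looks
#' stable only once that stage is excluded.
#'
#' @param n_genes,n_samples matrix dimensions (>= 2 each).
#' @param mean_range range the designed per-gene means are drawn from
#'   (uniformly).
#' @param sd_profile per-gene designed SDs; default assigns each gene a
#'   coefficient of variation from 1% to 30% of its mean (in gene order),
#'   which also guarantees non-negative values.
#' @param offset_genes genes (names or indices) given the offset in
#'   `offset_sample`.
#' @param offset size of that offset, TPM.
#' @param offset_sample column receiving the offset (default the first).
#' @param noise_sd extra i.i.d. Gaussian noise SD (values truncated at 0).
#' @param seed integer seed.
#' @return a list with elements `tpm` (a [tpm_matrix]) and `truth`, a
#'   `synthetic_ground_truth` list with `mean`, `sd` (designed values),
#'   `ranking_with_all` and `ranking_without_offset_sample` (intended
#'   least-variation orders over genes with designed mean > 50, computed
#'   from the designed noise-free matrix), `offset_genes`, `offset_sample`.
#' @export
simulate_tpm_matrix <- function(n_genes = 200, n_samples = 14,
                                mean_range = c(5, 500), sd_profile = NULL,
                                offset_genes = character(), offset = 500,
                                offset_sample = 1, noise_sd = 0, seed = 1L) {
  if (n_genes < 2 || n_samples < 2) abort("need at least a 2 x 2 design", "config_error")
  set.seed(as.integer(seed))
  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- sprintf("stage%02d", seq_len(n_samples))
  mu <- stats::runif(n_genes, mean_range[1], mean_range[2])
  if (is.null(sd_profile)) {
    cv <- seq(0.01, 0.30, length.out = n_genes)
    sd_profile <- cv * mu
  }
  if (length(sd_profile) != n_genes)
    abort("sd_profile must have one value per gene", "config_error")
  z <- stats::rnorm(n_samples)
  z <- pmin(pmax(z, -2), 2)
  z <- as.numeric(scale(z))  # mean 0, sample SD exactly 1
  m0 <- outer(mu, rep(1, n_samples)) + outer(sd_profile, z)
  dimnames(m0) <- list(genes, samples)
  if (is.numeric(offset_sample)) offset_sample <- samples[offset_sample]
  if (is.numeric(offset_genes)) offset_genes <- genes[offset_genes]
  m0[offset_genes, offset_sample] <- m0[offset_genes, offset_sample] + offset

  designed_order <- function(m) {
    sds <- apply(m, 1, stats::sd)
    means <- rowMeans(m)
    keep <- means > 50
    rownames(m)[keep][order(sds[keep], means[keep], rownames(m)[keep])]
  }
  truth <- structure(list(
    mean = stats::setNames(mu, genes),
    sd = stats::setNames(sd_profile, genes),
    ranking_with_all = designed_order(m0),
    ranking_without_offset_sample =
      designed_order(m0[, setdiff(samples, offset_sample), drop = FALSE]),
    offset_genes = offset_genes, offset_sample = offset_sample),
    class = "synthetic_ground_truth")

  m <- m0
  if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
  m <- pmax(m, 0)
  list(tpm = tpm_matrix(m), truth = truth)
}

#' Simulate a dilution-series standard curve
#'
#' Ct = intercept - log10(concentration) / log10(1 + E/100) + noise, so a
#' noiseless series inverts [amplification_efficiency()] exactly.
#'
#' @param efficiency_pct true amplification efficiency E, percent (> 0).
#' @param intercept_ct Ct at relative concentration 1.
#' @param steps relative concentrations, positive and descending (default
#'   the common 1:10 ... 1:10,000 series).
#' @param noise_sd Gaussian Ct noise SD, cycles.
#' @param gene label carried into the table.
#' @param seed integer seed.
#' @return a data.frame with columns `gene`, `concentration`, `ct`.
#' @export
simulate_dilution_series <- function(efficiency_pct, intercept_ct = 20,
                                     steps = c(1, 0.1, 0.01, 0.001),
                                     noise_sd = 0, gene = "primer", seed = 1L) {
  if (efficiency_pct <= 0) abort("efficiency must be > 0%", "config_error")
  if (any(steps <= 0) || is.unsorted(rev(steps)))
    abort("dilution steps must be positive and descending", "config_error")
  set.seed(as.integer(seed))
  ct <- intercept_ct - log10(steps) / log10(1 + efficiency_pct / 100) +
    stats::rnorm(length(steps), 0, noise_sd)
  data.frame(gene = gene, concentration = steps, ct = ct,
             stringsAsFactors = FALSE)
}
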