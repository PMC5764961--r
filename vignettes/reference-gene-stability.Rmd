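---
title: "Selecting and validating RT-qPCR reference genes with refstab"
author: "refstab authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and validating RT-qPCR reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative quantification by RT-qPCR stands or falls with its reference
(housekeeping) genes: every fold change is measured against them, so a
"reference" whose expression drifts across developmental stages or
treatments injects that drift into every result. refstab implements the
standard two-phase workflow for choosing references:

1. **Screening**: candidate genes are short-listed from an RNA-seq
   abundance matrix (TPM) by requiring a minimum mean expression and
   ranking by least variation across conditions.
2. **Validation**: the short-listed candidates are measured by RT-qPCR and
   ranked by four independent stability statistics — comparative delta-Ct,
   geNorm, BestKeeper and NormFinder — plus a geometric-mean consensus,
   and geNorm's pairwise variation V decides how many references are
   enough.

The package also covers the supporting steps (technical-replicate
concordance QC, amplification-efficiency estimation from dilution
standard curves, multi-reference 2^-ddCt quantification of target genes)
and ships simulators whose ground truth makes the whole pipeline testable
without laboratory data.

## Screening from RNA-seq

For each gene the arithmetic mean and sample standard deviation (n − 1
denominator) of TPM across stages are computed; genes with mean strictly
above a floor (default 50 TPM) are ranked by ascending SD, ties broken by
mean and then gene id. The floor excludes genes too quiet to be practical
qPCR references; the SD ranking favours flat profiles. Raw SD rather than
the coefficient of variation is used, matching the screening convention of
ranking "least deviation" with a separate expression floor; because SD
scales with expression level this slightly favours lower-expressed genes
among those passing the floor, which is why the floor matters.

Two refinements mirror the realities of staged designs and allotetraploid
genomes:

- `dual_ranking()` ranks with and without designated samples (typically
  the unfertilised-egg/oocyte stage, whose maternal transcriptome is
  atypical). A gene that is flat everywhere except that stage moves from
  the bottom of one ranking to the top of the other; `overlap_top()`
  intersects the two top lists so that selected candidates are robust to
  the choice.
- `select_homeolog()` keeps the better-ranked of the `.L`/`.S` homeolog
  pair so a duplicated genome contributes each gene once.

## From Ct to the stability statistics

**Replicate QC.** Technical replicates of one well group must agree;
groups whose Ct spread (max − min) exceeds 0.5 cycles are discarded
entirely (the conservative reading of the usual duplicate rule — the pair,
not just the outlier, is unreliable), the rest collapse to their mean Ct.
An alternative policy keeps the replicate nearest the gene's plate-median
Ct. The spread rule generalises to >2 replicates via max − min, the most
conservative choice.

**Relative quantities.** geNorm and NormFinder work on linear-scale
relative quantities `q = B^(Ct_min − Ct)` per gene, with B = 2 by default
(one cycle = one doubling) or `B = 1 + E/100` with per-gene efficiencies.
Anchoring at the per-gene minimum Ct bounds quantities in (0, 1] (the
qBase convention); since every statistic below is invariant to per-gene
rescaling, the anchor is cosmetic, and a mean-Ct anchor is available.

**delta-Ct** averages, per gene, the SDs of its pairwise per-sample Ct
differences. **geNorm** computes the same pairwise dispersions on
log2-quantity ratios (with base-2 quantities the two coincide exactly —
asserted in the test suite), averages them into M, then iteratively
removes the highest-M gene; the last two genes share the final M and
cannot be separated by the method. Ranks for the final pair follow their
M at the penultimate (three-gene) iteration, ties lexicographic; when
several genes tie for the worst M at an iteration the one with the larger
pairwise variation to the current best gene is removed first. **geNorm V**
compares normalisation factors built from the n and n+1 best genes; the
smallest n with V below 0.15 (the conventional cut-off, exposed as a
parameter because it is a community default, not a law) is the
recommended number of references. **BestKeeper** works on raw Ct: its
"SD" is the mean absolute deviation from the mean (the original tool's
definition; the classical SD is reported alongside), genes with MAD > 1
cycle are flagged inconsistent, and each gene's Pearson correlation with
the per-sample geometric-mean-Ct index is reported with its p-value.
**NormFinder** is model-based: after centring each sample (removing
loading artefacts), per-group residual variances are decontaminated for
the other genes' noise — `sigma_i^2 = (v_i − S/k^2)/(1 − 2/k)` with
`S = k/(k−1) · sum(v)` — negative estimates truncated to zero (and
counted); with multiple groups, intergroup differences are shrunk toward
zero in proportion to their sampling noise and combined with the
intragroup uncertainty into the stability value.

The **consensus** is the geometric mean of each gene's four ranks (the
RefFinder-style aggregate), ties broken by best single-method rank.

All four statistics are deliberately validated two ways: against naive
loop-based reimplementations (agreement to 1e-9 on random matrices) and
by parameter recovery on simulated data.

### Numerical and degenerate-input choices

- Logs are base 2 everywhere; Ct is a base-2 scale.
- Matrices must be complete; samples missing any gene are dropped with a
  warning before analysis (all four statistics assume complete panels).
- geNorm requires strictly positive quantities and at least 3 genes and
  3 samples; NormFinder requires at least 3 genes because the
  decontamination divides by 1 − 2/k, and at least 2 samples per group.
- A constant BestKeeper index makes the correlation undefined; it is
  reported as missing rather than guessed.
- Within-method ties are ordered deterministically (value, then gene id),
  so gene and sample permutations of the input never change any output —
  a property the test suite asserts directly.

## Group handling in NormFinder

NormFinder's intergroup component needs group sizes large enough to
estimate a per-group variance. With very small groups (e.g. triplicate
stages) the intergroup variance estimate truncates to zero for many genes
and the stability value degenerates, which is why the method's authors
recommend ungrouped analysis below roughly eight samples per group.
`ref_stability()` follows that guidance: it only runs grouped NormFinder
when every group has at least `min_group_size` (default 8) samples and
otherwise falls back to single-group mode with a message. Calling
`normfinder()` directly bypasses the guard (any grouping with >= 2
samples per group), which the grouped-formula tests use.

## Multi-reference 2^-ddCt

`ddct_fold_change()` normalises targets against the arithmetic mean Ct of
the reference set — algebraically identical to the log2 geometric mean of
the reference quantities, so two references behave exactly like one
pseudo-gene at their mean Ct (asserted as an identity in the tests).
Group summaries are the mean ± SD of per-sample folds, rescaled so the
control group's mean fold is exactly 1; a geometric-mean summary is
available. Efficiency-corrected (Pfaffl-type) ratios are deliberately out
of scope; the estimator is the plain 2^-ddCt.

## What the simulators emulate — and what they do not

`simulate_ct_dataset()` generates
`Ct = baseline_i + offset_ig + shift_s + N(0, sigma_i) + N(0, sigma_rep)`
with optional discordant-well injection (one replicate displaced by more
than 0.5 cycles). The default design mirrors a staged developmental
study: 16 candidate genes, 8 stages × 3 biological replicates, duplicate
wells, biological SDs spanning 0.05–1.0 cycles with one uniquely stable
pair, a 0.2-cycle per-sample loading shift, 0.05-cycle replicate noise,
and a 2% discordance rate — sizes chosen to be representative of a real
plate layout while keeping simulation-heavy tests fast. Noise is Gaussian
on the Ct (log-abundance) scale. The ground truth orders genes by
effective SD, `sqrt(sigma_i^2 + var_g(offset_ig))`, so designed group
effects count as instability for a would-be reference.

`simulate_tpm_matrix()` uses one shared standardised profile across
samples so each gene's sample SD equals its designed SD *exactly* at zero
extra noise — that is what makes "the designed ranking is recovered
exactly" a testable statement rather than a probabilistic one. Designed
"oocyte-like" offsets reproduce the dual-ranking divergence. Default
per-gene SDs are assigned as 1–30% CVs, which also keeps values positive
(the generator truncates at zero otherwise).

`simulate_dilution_series()` inverts the efficiency estimator exactly at
zero noise: `Ct = intercept − log10(conc)/log10(1 + E/100)`.

What passing these tests shows is that the statistics, their rankings and
the pipeline plumbing are correct under the generative model. Real
RT-qPCR data violate that model in ways the simulators intentionally do
not emulate: no amplification curves or melt artefacts, no
plate/batch-position effects, no heavy-tailed or censored ("Undetermined")
Ct beyond row dropping at load time, no correlated biological noise
between genes. Rankings on real data should therefore always be
cross-checked across the four methods — which disagree in instructive
ways — rather than read off a single statistic.

## Estimation limits worth knowing

Two quantitative limits surfaced during validation and are inherent to
the methods, not implementation artefacts:

- NormFinder's variance decontamination amplifies sampling noise by
  `1/(1 − 2/k)` (a factor of 3 at k = 3 genes) and the centred residuals
  carry a noise floor of `sum(sigma^2)/k^2` shared by all genes. Genes
  whose true variance sits below that floor (the quietest pair of the
  default design) cannot be resolved to within 20% even at 200 samples;
  genes above it recover comfortably. Panels of 10+ genes behave well.
- With triplicate samples, biological SDs of 0.05 vs 0.07 cycles are
  statistically indistinguishable under realistic technical noise; the
  default design's "uniquely stable pair" is therefore recoverable as a
  pair, while the ordering within the pair is essentially arbitrary.

## Problem sizes used in validation

The shipped tests run the four statistics on matrices up to 6 × 10
against naive oracles (50 random cases), 200 randomised invariance
trials, 200 simulated studies of the default 16 × 24 design for recovery
rates, screening matrices of 40–150 genes × 14 stages, and a 16 × 200
single-group matrix for variance recovery. These sizes make the full
suite run in about two minutes while keeping every Monte-Carlo rate
estimate stable to a few percent.

## A worked run

```{r example}
sim <- simulate_ct_dataset(ct_sim_design(seed = 7))
qc <- merge_technical_replicates(sim$ct)
nrow(qc$rejected)                       # discordant wells caught

fit <- ref_stability(qc$ct)
fit
head(stability_ranks(fit), 4)
recommended_references(fit)
sim$truth$stable_pair                   # designed answer
```

The command-line runner (`exec/refstab.R`) chains the same steps —
`simulate`, `qc`, `efficiency`, `screen`, `stability`, `foldchange` —
writing one CSV per result plus a JSON run manifest.
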