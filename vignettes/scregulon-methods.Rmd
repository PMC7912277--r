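---
title: "Methods: regulon activity and signature analysis in single cells"
author: "scregulon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulon activity and signature analysis in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical choices behind scregulon: the
models, their assumptions, the tunable parameters, and the numerical
conventions that make results deterministic. The package targets
single-cell RNA-seq of cultured cell lines — settings with two (or a few)
well-defined populations rather than complex tissue — and builds master
regulator and pathway analysis on top of standard normalization.

## Normalization and gene filtering

Two scales coexist deliberately:

* **TPM** (`tpmNormalize()`): counts divided by gene length in kb, then
  rescaled per cell to sum to 10^6. Displayed and analysed as
  `log10(TPM + pseudo)` with `pseudo = 1e-4`, so undetected genes sit at
  exactly −4 and the most expressed near 6. Used for per-gene statistics,
  per-cell signatures, and bulk comparison, where length bias matters.
* **LogNormalize** (`logNormalizeCounts()`): `ln(1 + count/colsum * 1e4)`.
  Used for differential expression and cell-cycle module scores — the
  operating scale of the standard clustering toolchain, so DE results are
  directly comparable to that ecosystem.

`filterGenes()` removes genes with a nonzero count in fewer than 3 cells.
"Measured" means `count > 0`: with ~38,000 reads per cell a single read is
already informative, and any higher threshold would interact badly with
the TPM pseudo-value convention. Filtering happens once, before
normalization and DE; running DE on the unfiltered matrix would only add
genes whose test statistics are driven by one or two cells.

## Per-gene statistics and variance de-trending

`geneStats()` reports mean, variance and detection per gene on log10 TPM,
plus the **residual variance** after subtracting a loess fit of variance on
mean (span 0.3, degree 2). Raw variance is strongly confounded with mean
expression; the residual ranks genuine heterogeneity. Span 0.3 is the
common variance-trend choice: wide enough to be stable on a few thousand
genes, narrow enough to track the sharp drop at the detection boundary. A
locally quadratic fit reproduces smooth polynomial trends exactly, which
the tests exploit (a constructed variance = f(mean) dataset must yield
residuals ~0, and the residual's Spearman correlation with the mean stays
below 0.1 on simulated data).

## Differential expression and signatures

`wilcoxonDE()` runs a two-sided Wilcoxon rank-sum test per gene. The exact
null distribution is used when a gene has no ties and both groups have at
most 50 cells; otherwise the tie-corrected normal approximation with
continuity correction (the same policy as `stats::wilcox.test`, against
which the implementation is tested, alongside an exact-enumeration oracle
on 5-vs-5 splits). The fold change is `ln(mean(expm1(a)) + 1) −
ln(mean(expm1(b)) + 1)` and detection fractions are reported per group;
genes tied across both groups keep p = 1 rather than disappearing.
Adjustment is Benjamini–Hochberg over all tested genes. The Wilcoxon test
was fixed as the DE engine because it is the default of the toolchain the
package mirrors; a count-model alternative is out of scope.

`groupSignature()` converts the table into per-gene scores
`sign(logFC) · Φ⁻¹(p/2)`, with p floored at 1e-300 to keep z finite. The
signed-z scale — rather than raw fold change — makes scores comparable
across genes of very different expression, so a single permutation null is
meaningful for every regulon.

## Enrichment, permutation null and NES

Two enrichment statistics share one significance machinery:

* `gseaES()` — the weighted Kolmogorov–Smirnov running sum (weight
  exponent 1 by default). Genes are ranked by descending score with ties
  broken lexicographically by gene id, for bit-reproducibility. The ES is
  the maximal signed deviation; on a (structural) exact tie between the
  positive and negative extreme the negative branch wins, decided with a
  1e-9 tolerance so floating-point noise cannot flip the sign.
* `regulonES()` — the likelihood-weighted, mode-signed mean of target
  scores, the natural two-tailed statistic for a weighted regulatory
  network, and linear in the signature.

The null (`permutationNull()`) shuffles **gene labels** (randomizing which
genes a network points at), **sample labels** (recomputing the signature
from permuted group assignments; requires the expression context), or
alternates both. Batch runs (`mra()`, `gseaBatch()`) default to gene
shuffling, which needs no expression matrix and is the component that
randomizes the network-signature correspondence; the sample scheme remains
available when the contrast context is supplied.

`nesFromNull()` defines `NES = ES_obs / mean(|ES_perm| of matching sign)`.
A raw signed mean of permuted scores is ~0 by symmetry and would make the
ratio numerically unstable, so the sign-matched absolute mean is used —
the closest well-defined reading of "divided by the mean enrichment score
of all permutations". p-values use the add-one estimator
`(1 + #{|ES_perm| ≥ |ES_obs|})/(nPerm + 1)`, bounded below by
`1/(nPerm+1)`, and are BH-corrected across regulons or sets. Batch runs
draw **one seeded permutation pool shared by all regulons**: this keeps
TFs on a common scale, makes sign antisymmetry exact under a shared seed,
and cuts cost by the number of regulons; with 1000 permutations the
pool-induced correlation between TFs is negligible next to sampling noise.
Sets or regulons with fewer than 10 members in the signature universe are
skipped in batch mode (tiny sets produce noise, not enrichment) and are an
error in single-object calls.

## Per-cell activity and cell-cycle phases

`cellSignatures()` z-scores each gene across cells on log10 TPM
(population sd, floored at 1e-8; zero-variance genes dropped). log10 TPM
was chosen over the LogNormalize scale because per-cell signatures feed
the same enrichment statistics as group signatures and should live on the
package's display unit; the alternative only rescales scores
monotonically. `scActivity()` then computes ES and NES per cell and per
regulon, with 100 permutations per object pooled **across cells** — a
shared null keeps cells comparable and keeps cost linear in cells. The
defaults trade permutation depth for the number of cells scored; a
per-cell p-value at fine resolution would need the full 1000.

Cell-cycle scoring (`cellCycleScores()`) is the standard module score:
mean expression of a phase gene list minus the mean of `nCtrl = 100`
control genes per list gene, drawn from the same of `nBins = 24`
dataset-wide average-expression quantile bins (list genes are sorted
internally so the control draw does not depend on input order). `assignPhase()`
calls G1 when both scores are negative, otherwise the larger score (S on
an exact tie). These binning constants follow the established
module-scoring convention.

## Pseudobulk and bulk matching

`pseudobulk()` sums TPM across cells and rescales to 10^6;
`matchBulk()` Spearman-correlates `log10(TPM + 1e-4)` profiles over the
shared-gene intersection (at least 100 genes). Spearman makes the log and
pseudo-value choices inconsequential — rank correlation is invariant to
monotone transforms — which is exactly why it is used; correlation ties
are broken by sample label for a deterministic ranking.

## The synthetic-data generator

`simConfig()` defaults describe the validation conditions used throughout
the tests: 2000 genes, 20 TFs with 50 disjoint targets each (modes ±1
with 70% activating, likelihoods uniform on [0.2, 1]), two populations of
300 cells, and TFs 1–5 active (+2 on the log scale) in population A only.
Full-scale runs (e.g. 962 and 1105 cells, whole transcriptome) are a
configuration choice, not a different code path. Phase programs are 40 S
and 40 G2M genes shifted +1 (natural log) in their phase; phase fractions
default to (0.29, 0.45, 0.26) for population A and (0.20, 0.57, 0.23) for
B, emulating an S-phase-heavy line against a more evenly cycling one. The
planted high-variance group (30 genes, confined to population B) is
bimodal: each cell turns each gene "on" with probability 0.3 at a +3
log shift from a lowered baseline — the mixture that makes genes
high-mean *and* high-variance in one population only, as metallothionein
genes behave in culture.

Counts are negative binomial (size = `dispersion`, default 1) around
softmax-normalized per-cell means scaled by a lognormal library size
(mean 38,000 reads, sigma 0.35 — a long right tail with few cells beyond
100,000 reads), then thinned by multiplicative logistic dropout with keep
probability `mu/(mu + dropoutMidpoint)` (midpoint 1 count). `librarySigma`
is exposed so the Poisson limit (`dispersion → ∞`, sigma 0, midpoint → 0,
variance/mean → 1) can be verified; with library-size variation on, the
ratio exceeds 1 by construction. Bulk profiles come from the same
expected abundances without dropout, plus mild lognormal replicate noise
(sd 0.1).

What the generator does **not** emulate: ambient RNA, doublets, batch
effects, UMI saturation, gene–gene correlation beyond the regulon/phase
programs, and realistic gene-length/expression covariance. Passing
recovery tests therefore demonstrates the statistics behave as designed
under a clean generative model — not that real data meet the model's
assumptions.

## Determinism and degenerate inputs

Every stochastic function takes a seed and restores the caller's RNG
state. The generator derives distinct streams for truth (seed), counts
(seed + 1) and bulk noise, so components can be re-drawn independently.
Degenerate inputs fail loudly: all-zero cells (TPM undefined), empty gene
sets, regulons below the minimum size in single-object mode, all-zero
permutation nulls, fewer than 2 cells for signatures, fewer than 5 phase
genes, fewer than 100 shared genes for bulk matching. Readers reject
malformed files (dimension mismatches, non-integer counts, out-of-range
modes/likelihoods, self-edges) rather than coercing them.

## Validation scale

The test suite validates oracle equalities exactly (brute-force GSEA on
every subset of a 10-gene universe; hand-computed regulon means; a
step-up BH oracle; exact Wilcoxon enumeration) and runs the recovery
studies at the generator's default scale — 600 cells, 2000 genes, 10–20
seeds per property — which is large enough for the claimed effects to be
unambiguous while keeping the whole suite inside a few minutes on one
core. Known limitations: NES magnitudes depend on the permutation scheme
and are not comparable across schemes; per-cell NES with 100 permutations
resolves activity differences, not fine-grained per-cell significance;
and the BH-FDR across TFs inherits whatever dependence the shared
permutation pool induces, which is mild at 1000 permutations but not
zero.
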