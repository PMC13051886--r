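---
title: "Models and methods behind autoimmir"
author: "autoimmir authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Models and methods behind autoimmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`autoimmir` reimplements, as tested and reusable functions, an integrative
transcriptomic workflow for immune-cell profiling in autoimmunity: bulk
differential expression of miRNAs and genes, set-level and binding-site
enrichment with directional activity inference, RT-qPCR validation
arithmetic, and a single-cell arm quantifying rare Tc17 and CD8 Treg
programs. Every stage is exercised end to end on seeded synthetic cohorts
with planted ground truth, so the package's claims are about *recovery of
known structure*, not about any particular clinical dataset. This vignette
explains the models, the tunable parameters, the synthetic-data generator,
and the numerical choices; it states no empirical result beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## The bulk model: moderated t with Storey FDR

Bulk inputs are log2 expression matrices (features x samples) with a
two-level group factor (`control`/`case`), optional batch and donor labels.
The workflow assumes normalization happened upstream; CEL parsing, RMA, and
array-QC outlier flagging are deliberately out of scope because they add
platform plumbing but no statistical content.

For each feature `g` a linear model with intercept, case indicator, and
optional sample-level covariates is fitted. Residual variances `s_g^2` with
`d_g` degrees of freedom are shrunk toward a prior `(d0, s0^2)`:

    s~_g^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)

and the moderated statistic `t~_g = beta_g / (s~_g sqrt(v_g))` is referred
to a t distribution on `d0 + d_g` degrees of freedom. The prior is estimated
by moment matching of `log s_g^2` (digamma/trigamma inversion, Newton
solver), with `d0` capped at 1e6 and reported finite. Setting `d0 = 0`
recovers the classical per-feature t-test — this is the oracle equivalence
the tests verify to 1e-9 — and the estimated-prior path is cross-checked
against `limma::eBayes` on random instances. Supplying `d0 = Inf` pools
every variance to `s0^2` exactly.

Storey q-values estimate the null proportion `pi0` on the lambda grid
0.05..0.95 (step 0.05) with a cubic smoothing spline (df = 3) evaluated at
lambda = 0.95, clamped to (0, 1]. The step-up pass reuses the exact
floating-point arithmetic of `p.adjust(..., "BH")`, so fixing `pi0 = 1`
reproduces Benjamini-Hochberg bit for bit (a tested identity).

Unwanted sample-level structure is absorbed by surrogate covariates: the
right singular vectors of the residual matrix after removing the group fit.
Under `n_sv = "auto"` the count comes from parallel analysis — each *raw*
data row is independently permuted (20 draws) and residualized, and a
component survives while its observed singular value exceeds the 95th
percentile of the matching permuted values. Permuting the raw rows rather
than the residuals matters: residual rows live in an (n - rank)-dimensional
subspace, and re-projecting a permuted residual shrinks the null singular
values, which made the first component fire on pure noise roughly half the
time during development. With the raw-row scheme the null keeps zero
components in ~95% of seeded draws while a planted batch shift of twice the
noise SD is recovered with |r| > 0.99 against the true batch label.

Array quality weights are a simplified heuristic — inverse mean squared
residual per array from an unweighted fit, normalized to mean 1, applied as
observation weights in a second fit — not the gene-wise REML of the original
tooling. They are optional in both bulk paths.

Other bulk conventions: the top-K expression filter (default 400; 500 for
monocyte-style runs) breaks ties lexicographically for determinism; the
low-intensity filter summarizes a feature by its *median* log2 intensity
(robustness choice; the boundary keeps values exactly at the threshold);
quantile normalization delegates to `limma::normalizeQuantiles` with
tie-averaging; DEG calling uses strict inequalities (`q < 0.1`,
`|log2FC| > log2(1.5)`). Classical MDS uses a pairwise distance defined as
the root mean square of the `top_features` largest absolute per-feature
differences, Torgerson double-centering, eigenvalue-descending axes, and a
sign fix (largest-|loading| sample positive) for reproducible plots.

## Set-level statistics

Overrepresentation uses the upper-tail hypergeometric probability with an
explicit universe argument (never implicit), dropping sets with fewer than 8
members inside the universe — the minimum-set-size convention of curated
miRNA category collections. When the DE list is split by direction the
directional score `z = (u - d) / sqrt(n)` is attached; `u`, `d`, `n` are
stored so any variant of the score can be recomputed.

Preranked GSEA sorts by the statistic descending (ties by feature id), adds
`|stat|^p / N_R` at set members and subtracts `1/(N - |S|)` elsewhere, and
takes the signed extremum of the walk; on a magnitude tie between the
positive and negative extremum, the positive one is reported. The null
shuffles feature labels (the only permutation scheme available for a
preranked input) with a fixed seed; NES divides ES by the mean |null ES| of
matching sign, and the p-value uses the `(1 + b)/(1 + B)` convention so a
finite null never yields p = 0. Enrichment scores are verified against
exhaustive evaluation of the walk for small rankings and against `fgsea` on
larger ones. The pseudobulk arm ranks genes by `-log10(p) * sign(log2FC)`
with p clamped at 1e-300.

## Binding-site enrichment and activity direction

For each 7-mer motif and each DEG direction a gene-level 2x2 table is built
(carriers among DEGs of that direction, carriers among the rest of the
universe, and complements) and tested with the two-sided Fisher exact test
(minimum-likelihood convention). The odds ratio is the sample OR with the
Haldane-Anscombe +0.5 correction when any cell is zero, reported on the
log2 scale. Gene-level presence (not site counts) drives the table — site
counts are reported descriptively as `site_overlap` — because the
site-level variant is not reconstructible from the tabulated schema.
Benjamini-Hochberg runs across all motif x direction tests and rows with
adjusted p < 0.05 and OR > 1 are kept.

The direction logic mirrors de-repression: a motif enriched among
*up*-regulated genes implies its miRNAs lost activity ("Downregulated"),
and vice versa. Influential miRNAs are those whose own differential
expression matches the estimated activity; the motif-to-miRNA multiplicity
(families sharing a seed match) is preserved as a miRNA list per motif row.
Network assembly keeps interactions whose miRNA is influential and whose
target gene moved opposite to the miRNA's activity, filters predicted edges
to configured confidence classes (default very high/high), and annotates
target genes by ORA against pathway sets over the universe of all genes
carrying at least one interaction.

## qPCR arithmetic

Standard curves are ordinary least squares of Ct on log10(dilution), with
`E% = (10^(-1/slope) - 1) * 100`; a slope of -1/log10(2) = -3.3219 is 100%
efficiency, and primer pairs pass at r^2 > 0.99. Efficiency is reported but
not used to correct folds — the workflow validates near-equal efficiencies
and then uses plain `2^-ddCt`. Replicate Cts are averaged per (sample,
assay); dCt subtracts the reference assay, ddCt subtracts the mean control
dCt, so the control folds have geometric mean exactly 1. Housekeeping
selection computes the coefficient of variation on the *linear* scale
(the scale is a documented choice; the source material states no scale),
requires group invariance (Welch p > 0.5 — a deliberately conservative cut
since no number is stated) and top-quartile abundance, then minimizes CV.
Welch tests carry a Shapiro-Wilk screen that is reported, never enforced.

## The single-cell arm

Cells pass CD8 gating (CD3G detected and CD8A or CD8B detected; "detected"
means count > 0, since droplet data carry no natural cutoff), then a
median ± 3 MAD outlier filter on log1p totals, log1p detected genes, and
mitochondrial percentage. Counts are scaled to the median library size and
log2(x+1)-transformed. HVGs come from a loess mean-variance trend on the
log layer (residual variance ranking, ties by gene id); a lone gene at an
extreme mean can be absorbed by the local trend — a known leverage
limitation of any local fit, which is why the tests anchor the trend across
a range of abundances.

Batch correction is deliberately "MNN-lite": PCA on the HVG layer, then for
each batch beyond the first, mutual k-nearest-neighbor pairs against the
already-integrated cells define difference vectors, smoothed per incoming
cell with a Gaussian kernel (bandwidth = median pair distance). It removes
additive batch structure on synthetic data (centroid gap reduced by more
than 80% in the tests) but makes no claim of reproducing the original
published correction. Clustering builds a k = 5 nearest-neighbor graph,
weights edges by the Jaccard index of neighbor sets (zero-weight edges
dropped), and runs seeded Louvain; labels are size-ordered for determinism.
Label transfer is a simplified nearest-profile classifier (Spearman over
the HVG-reference gene intersection, argmax, no iterative fine-tuning);
synthetic-truth labels, not transfer, define populations in the tests.

Pseudobulk analysis sums counts per donor (donors under 10 cells dropped),
computes TMM normalization factors in-package (trim 0.3 on M, 0.05 on A,
inverse-variance weights, reference = the column whose upper-quartile ratio
is closest to the mean; factors rescaled to geometric mean 1; cross-checked
against `edgeR::calcNormFactors`), and delegates the NB quasi-likelihood
F-test to edgeR's `estimateDisp`/`glmQLFit`/`glmQLFTest` — the
field-standard implementation of exactly this test — behind the module's
own interface, attaching Storey q-values. Detection filtering keeps genes
with CPM above 1 in at least as many samples as the smaller group.

## Program quantification

TF activities are impurity-reduction importances from a seeded
regression-tree ensemble (ranger; 100 trees, depth 3, bootstrap over genes)
predicting each cell's expression from the gene x TF signed membership
matrix, normalized to sum 1 per cell; constant cells return uniform
activities with a degenerate flag. Because the ensemble bootstraps gene
rows, importances are only approximately invariant to gene order; the tests
assert that the dominant TF is stable rather than bitwise invariance.
Donor-mean activities are compared with Welch tests *without* multiplicity
correction — mirroring the workflow this package reimplements — with a BH
column provided for convenience and a flag emitted.

AUC signature scores rank each cell's genes by descending raw count, ties
broken by one seeded permutation fixed per run so zero-inflation cannot
bias the score deterministically. The recovery curve counts signature genes
within the top x ranks up to `ceiling(top_fraction * n_genes)`; the score
normalizes the area under that step curve by its maximum. `top_fraction`
defaults to 0.05 (the customary default of this scorer family; unstated in
the source material). Cells at or above the fixed thresholds — 0.17 for the
CD8 Treg signature, 0.22 for Tc17, taken as given constants — are labeled
positive; the shipped signature lists (FOXP3/IKZF2/... and RORC/BATF/...)
live in `inst/extdata/program_signatures.gmt` and are editable. Called
populations are verified by ORA of their top 250 markers (mean pairwise
AUC), and per-donor positive fractions are compared with Welch tests.

## What the generator emulates — and what it does not

The synthetic module is first-class, tested code. Bulk layers are Gaussian
on the log2 scale (matching array intensities) with per-feature baselines
N(8, 2), residual SD 0.3, additive per-batch per-feature shifts (SD 0.5,
shared within batch, balanced over groups so surrogate-variable recovery is
a meaningful test), and planted case-minus-control effects of 1 log2 unit.
The mRNA layer up-shifts each suppressed miRNA's 60 disjoint targets by
`suppression * |effect|`, decorates every target with the regulator's motif
(1-3 sites), adds background decoration of 5% of genes per motif, and emits
planted edges as "validated" plus random decoys as "predicted" with
confidence classes. Single-cell counts are negative binomial (dispersion
0.5) with log-normal gene means around 0.5, mild log-normal donor scaling
(SD 0.1), well-detected lineage genes, a 13-gene mitochondrial block at
~2% of reads, and signature genes at a moderate baseline so a 4-fold
amplification lifts them into a cell's top ranks. Default cohort: 12 donors
per group, 400 cells per donor, 2000 genes, Tc17/Treg at 2% in controls and
4% in cases. qPCR standards follow `Ct = 24 - 3.3219 log10(dilution)`
noiselessly by default; unknowns add N(0, 0.2) replicate noise and shift
case Cts by `-log2(fold)`.

The generator does **not** emulate probe-level array artifacts, doublets or
ambient RNA, sequence-level motif discovery (sites are tabulated, not
scanned), zero-inflation beyond NB, or donor-level biological covariance.
Passing tests therefore demonstrate that the statistics recover structure
under their own model assumptions at realistic sizes — not that any
particular accession-level result reproduces. Recovery of planted
subpopulation frequencies is scored against the truth object's *realized*
per-donor fractions rather than the nominal 2%/4% constants: at 4800 cells
per group the realized frequency itself fluctuates by ~0.3 percentage
points, and the truth record exists precisely to separate that sampling
noise from estimator error. The published cohort numbers
(e.g. DEG counts from public accessions) additionally depend on upstream
parameters that are not recoverable from the text, and re-deriving them
requires downloads; they are documented as out of desk scope.

## Problem sizes and determinism

The replicated evaluations run at the stated study conditions: 100 null
bulk cohorts of 400 features x 20 samples; 1000 null motif draws; 50 null
pseudobulk cohorts of 2000 genes x 12 donors; 20 integrative cohorts with
10 planted regulators over 4000 genes; 20 single-cell cohorts of 9600
cells. These sizes were chosen so each property is measured with enough
replicates to be stable while a full evaluation completes in minutes on one
CPU. All randomness flows through explicit seeds — generators take a seed
in their config and restore the caller's RNG state — so identical configs
give byte-identical outputs, and pipeline manifests (config, stage counts,
output checksums) are reproducible across runs.

## Known limitations

* The surrogate-variable count rule is a reproducible stand-in, not the
  original package's estimator; the number of components used by the
  original analyses is unstated.
* Batch correction, label transfer, and the QL dispersion machinery are
  simplified or delegated versions of their reference methods, adequate for
  the synthetic recovery tasks but not drop-in reproductions.
* Whether binding-site contingency tables should count genes or sites is
  ambiguous in the tabulated schema; genes are tested, sites reported.
* The AUC thresholds (0.17/0.22) and scorer top fraction are fixed
  constants here; no threshold-learning procedure is provided.
* Hypergeometric and Fisher tests are discrete and therefore conservative;
  null calibration checks use one-sided bounds accordingly.
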