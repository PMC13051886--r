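# autoimmir

Integrative miRNA–mRNA and single-cell analysis of immune-cell dysregulation
in autoimmunity, as a tested R package.

## What problem this addresses

In autoimmune disease, dysregulated microRNAs reshape the transcriptome of
specific immune cell types: a miRNA that loses expression de-represses its
target genes, and the accumulated de-repression can push CD8⁺ T cells toward
particular fates such as IL-17-producing Tc17 cells or regulatory CD8⁺ Tregs.
Detecting this requires stitching together several analyses — moderated
differential expression of miRNAs and genes, binding-site enrichment that
infers each miRNA's *activity direction* from its targets, set-level
statistics, qPCR validation arithmetic, and single-cell quantification of
rare cell programs. `autoimmir` implements that whole chain as composable,
seeded, unit-tested functions, and ships a synthetic-data module that plants
known regulatory structure so every stage can be validated end to end
against ground truth.

It is aimed at computational biologists who want the statistics of such an
integrative workflow as reusable pieces with explicit contracts, rather than
a one-off analysis script.

## The core statistics

* **Moderated t** — per-feature linear fits with empirical-Bayes variance
  shrinkage `s̃²_g = (d₀s₀² + d_g s²_g)/(d₀+d_g)`, the prior moment-matched
  from log residual variances; `d₀ = 0` reduces exactly to the classical
  pooled t-test. FDR by Storey q-values (π₀ from a smoothed λ-grid; with
  π₀ = 1 the result is Benjamini–Hochberg, bit for bit).
* **Directional miRNA activity** — per 7-mer binding motif, a gene-level 2×2
  Fisher exact test of motif carriage among up- (or down-) regulated genes;
  enrichment among up-genes ⇒ the miRNA's activity is "Downregulated"
  (log2 odds ratio with Haldane–Anscombe correction). Activity calls are
  intersected with the observed DE-miRNAs and expanded into a
  miRNA→target network.
* **Preranked GSEA** — running-sum enrichment scores with sign-matched
  permutation NES/p, and the signed `-log10(p)·sign(log2FC)` ranking for
  pseudobulk contrasts.
* **qPCR** — standard-curve efficiency `E% = (10^(−1/slope) − 1)·100`,
  `2^−ΔΔCt` quantification, CV-based housekeeping selection, Welch tests,
  Pearson miRNA–target correlations.
* **Single cell** — CD8 gating, MAD-based QC, SNN-Jaccard/Louvain
  clustering, per-donor pseudobulk with in-package TMM factors and the
  edgeR NB quasi-likelihood F-test, tree-ensemble TF activities, and
  AUC recovery-curve signature scoring with fixed thresholds
  (CD8 Treg 0.17, Tc17 0.22) feeding per-donor frequency comparisons.

## Worked example

Plant ten suppressed miRNAs (effect −1 log2, 60 targets each, de-repression
+1 log2 in cases) and recover them from the data alone:

```r
library(autoimmir)

cfg <- sim_config(seed = 11, n_de = 10, de_direction = "down",
                  targets_per_mirna = 60, n_genes = 4000, suppression = 1)
mir <- simulate_mirna_matrix(cfg)

mm  <- filter_top_expressed(mir$matrix, 400)
sv  <- estimate_surrogate_variables(mm, seed = 11)
mde <- moderated_t_test(mm, covariates = sv)
mh  <- call_de(mde, q_max = 0.05, min_abs_fc = 1)

tx  <- simulate_regulated_transcriptome(cfg, mir$truth)
gm  <- filter_low_intensity(quantile_normalize(tx$matrix), 6)
gde <- moderated_t_test(gm)
gh  <- call_de(gde, q_max = 0.1, min_abs_fc = 1.5)

rows <- site_enrichment(tx$sites, gh$up, gh$down, rownames(gm$values))
dirs <- data.frame(mirna = c(mh$up, mh$down),
                   direction = rep(c("up", "down"), c(length(mh$up), length(mh$down))))
infl <- intersect_influential(rows, dirs)
```

On this seed the run prints, via the driver in `analysis/03_site_activity.R`:

```
significant motifs (adj p < 0.05): 10
planted suppressed miRNAs recovered: 10 / 10
network edges: 527 (522 validated)
```

meaning all ten planted regulators surface as motifs enriched among
up-regulated genes with estimated activity "Downregulated", concordant with
their own down-regulation, and their validated target edges dominate the
assembled network. The numbered scripts under `analysis/` run the full
story — simulation, bulk DE, site activity, qPCR validation, the single-cell
arm, and program quantification — writing their tables under `results/`.

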