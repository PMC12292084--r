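---
title: "Methods: stage-resolved single-cell tumor progression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-resolved single-cell tumor progression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`oncostage` re-implements, as a tested and reusable pipeline, the
computational core of a stage-resolved tumor single-cell analysis: QC and
normalization, expression-derived copy-number scoring with a
malignant-cell classification rule, cluster stage-homogeneity metrics,
stage-marker extraction, consensus transcription-factor networks with
regulon activity and specificity scoring, marker-based bulk-cohort
survival stratification, and permutation-tested ligand–receptor
communication. This vignette records the models, the parameters that
matter, and the design choices made where the design was genuinely open.

## QC and normalization

Cells and genes are filtered with the standard droplet-data recipe, all
bounds exposed in `qc_thresholds()`:

* genes detected (count > 0) in fewer than `ceiling(0.001 * n_cells)`
  cells are dropped — the ceiling keeps "less than 0.1%" strict;
* cells are dropped when the mitochondrial count fraction *exceeds* 20%
  or the detected-gene count lies outside [200, 5000]; removal conditions
  are strict, so a cell at exactly 20% mito or exactly 200 genes is kept.
  Mito genes are identified by the `MT-` prefix or an explicit list, and
  the fraction is computed on the raw counts as passed;
* normalization is `ln(1 + count * 1e4 / cell_total)` (natural log, the
  Seurat convention; log2 is reserved for fold changes);
* `center_and_clip()` removes the per-gene mean and caps values at 10
  with no variance scaling and no lower clip, so post-centering means are
  ≤ 0 with equality exactly when nothing clipped;
* `select_hvg()` ranks genes by plain variance of the log-normalized
  values with ties broken by gene id. This deviates from Seurat's `vst`
  deliberately: the criterion is stated, deterministic, and testable
  without a fitted mean–variance trend.

## Expression-derived CNV and the malignancy rule

The malignancy module works on `log2(1 + count * 1e4 / total)` — not the
natural-log matrix above — because its gene filter ("mean expression
below 0.1 on the log2 scale") is stated on that scale. The steps:

1. **Dilution.** Normal reference cells are added until tumor cells are
   at most 20% of the mix (`assemble_reference_mix()`); z-scores are then
   computed on the combined mix, which exists precisely to dilute the
   influence of malignant cells on per-gene statistics. If the normal
   pool is too small, all normals are used and the achieved fraction is
   recorded with a warning rather than failing.
2. **Gene filter.** Keep genes expressed in ≥ 10 cells with mean log2
   expression ≥ 0.1 (strict removal).
3. **Z-scores.** Per gene over all cells of the mix, with the sample
   (n−1) standard deviation — the denominator is unstated upstream; n−1
   is chosen and documented — then clipped to ±3. Constant genes map to
   zero.
4. **Windows.** Genes are ordered by chromosome and position and averaged
   over dense sliding windows of exactly 100 genes (step 1). Windows
   never cross a chromosome boundary; a chromosome with fewer retained
   genes than one window collapses to a single window rather than mixing
   chromosomes.
5. **Centering.** "Adjusted using centered values" is read as per-cell
   centering of the window vector (removing each cell's baseline); the
   per-window alternative is exposed via `cnv_params(center = "window")`.
6. **Scores.** `ms_score` is the mean squared window signal; the
   reference profile is the window-wise mean of the top ⌈5%⌉ of cells by
   `ms_score` (minimum 2), and `corr_score` the Pearson correlation with
   it, with 0 substituted for degenerate vectors.
7. **Rule.** A tumor-origin cell is malignant iff `ms > 0.02` **or**
   `corr > 0.2`, both strict; reference normals are never called
   malignant.

## Purity and entropy

`purity()` is the standard external clustering purity
$\mathrm{Purity} = \frac{1}{N}\sum_i \max_j n_{ij}$; per-cluster purity
divides by the cluster size. `cluster_entropy()` reports the Shannon
entropy of each cluster's stage proportions in bits and, because the raw
quantity is bounded by $\log_2 C$ rather than 1 when more than two stages
exist, also a normalized version (raw / $\log_2 C$) so the advertised
[0, 1] range holds for any number of stages.

## Stage markers

`wilcoxon_de()` mirrors `FindMarkers` semantics: only genes expressed in
≥ 25% of at least one group are tested; the fold change is
$\log_2\frac{\overline{\mathrm{expm1}(x)}_{\text{late}} + 1}
{\overline{\mathrm{expm1}(x)}_{\text{early}} + 1}$; the two-sided
rank-sum p-value is exact (full enumeration of assignments, ties
included) when both groups have ≤ 8 cells and otherwise uses the
tie-corrected normal approximation with continuity correction.
Benjamini–Hochberg runs over the tested genes only. Marker retention is
strict at `p_adj < 0.01` and `log2FC > 1`; ranking is by `p_adj`, then
|log2FC|, then gene id (the upstream "top 55" rule does not state its
ranking; this one is the package's own deterministic choice).

## Consensus regulatory networks

The stochastic importance learner is pluggable. The built-in backend
bootstrap-resamples cells, computes |Pearson r| between every candidate
TF and every non-TF gene, and emits the top 10 TFs per target. It is
deliberately simple: the contribution under test is the consensus
aggregation — run the backend 100 times with consecutive seeds, keep
edges appearing in ≥ 80 runs (inclusive), and average importance over the
runs where the edge appeared (not over all runs; the upstream phrasing is
"across these retained occurrences" and is implemented literally).

Why consensus helps, and what the recovery test assumes: a null edge
survives only if its |r| rank stays inside the per-target top-k across
bootstrap resamples. With a realistically large candidate list (hundreds
of TFs, most irrelevant), the top-k boundary sits in a dense field of
near-tied correlations, so null edges flicker and fall below 80/100 while
true edges persist. With only a handful of candidate TFs the same
aggregation cannot discriminate (everything is always in the top k). The
planted-regulon test therefore uses 5 true + 200 decoy TFs over a panel
of targets plus 100 distractor genes — the smallest world in which the
method's premise (rank instability of null edges) is actually present.

Motif-based pruning requires external motif databases and is replaced by
an allowlist hook in `build_regulons()` that preserves the pipeline
position of that filter.

**Regulon activity** is the AUCell-style area under the recovery curve:
per cell, genes are ranked by expression (ties broken by one seeded
permutation shared across cells) and the curve counts regulon genes among
the top ⌈5%⌉ ranks; the area is normalized so a regulon occupying the
topmost ranks scores exactly 1. **Specificity** is the SCENIC-style
$\mathrm{RSS} = 1 - \sqrt{\mathrm{JSD}(P_r, I_s)}$ with base-2 JSD, where
$P_r$ is the activity normalized over cells and $I_s$ the uniform
indicator over a stage's cells.

## Bulk stratification and survival

Samples are clustered on the marker-gene submatrix with `hclust`'s
classic `ward.D` update on unsquared Euclidean distances (matching the
quoted R method name, not `ward.D2`), genes on the transpose; both trees
are cut at fixed k (k over height cutting: the upstream rule is unstated,
fixed k is implemented). Defaults k_samples = 3, k_genes = 4. Subgroup
labels are ordered by decreasing mean marker expression so labeling is
deterministic; clinical names like C1–C3 are cosmetic.

`km_estimate()` is the product-limit estimator over distinct event times;
`logrank_test()` is the k-sample log-rank with the hypergeometric
variance–covariance form on k−1 groups. Both are implemented from
scratch; `survival::survfit`/`survdiff` serve only as independent test
oracles.

## Ligand–receptor communication

Strength of (sender, receiver, interaction) is mass-action:
mean ligand expression in the sender type × mean receptor expression in
the receiver type, on the expm1 scale of the log-normalized matrix.
Multi-subunit complexes aggregate by geometric mean, so any silent
subunit zeroes the complex (AND-logic). Significance comes from global
cell-label permutation with the positively biased estimator
$p = (1 + \#\{S^{perm} \ge S^{obs}\}) / (1 + n_{perm})$, which never
returns 0 at 100 permutations and makes zero-strength triples
automatically non-significant. The p-value is one-sided greater and the
permutation global (not stratified by sample) — both unstated upstream,
both chosen as the simplest defensible reading. Condition networks count
and sum significant interactions per ordered type pair; pathway flow sums
significant strengths per pathway, and a pathway is exclusive to a
condition when its flow is positive there and exactly zero in the other.
Conditions are scored independently with no cross-condition
normalization — a documented limitation: strengths are comparable within,
not across, conditions.

## The synthetic world

`sim_config()` fixes a stated world rather than a tuning surface. Counts
are negative binomial (gene-level dispersion `size = 2` — the upstream
analysis never models counts; overdispersion is what every downstream
stage assumes) with mean = baseline × cell size factor (lognormal, sd
0.3) × CNV dosage × DE effect × regulon activity:

* **CNV** acts multiplicatively on the NB mean — the dosage model that
  expression-derived CNV inference presupposes. The default world plants
  one 300-gene amplification (ratio 1.5) in tumor epithelial cells; the
  recovery world uses lognormal(log 5, 0.5) baselines so the stated
  "baseline mean ≥ 2" holds for essentially all spanned genes.
* **DE**: 50 genes at log2 effect 2 in late-stage epithelial cells,
  baseline mean pinned at 5 (the stated power condition).
* **Regulons**: per-cell latent TF activity ~ lognormal(0, 1); target
  means scale by activity^strength and the TF's own mean by activity —
  the simplest structure yielding detectable co-expression. A
  stage-specific regulon has its activity collapsed to 0.1 outside its
  stage.
* **Ligand–receptor**: pair genes are silent (mean 0) except in the
  stated sender/receiver type under the stated condition, where the mean
  equals the configured amplitude. Exclusive-late pathways therefore have
  exactly zero early strength, matching the definition of exclusivity.
* **Bulk cohort**: log2-scale Gaussian profiles (sd 1) with a +3 marker
  block per subgroup (≥ 2 sd separation), exponential survival at hazards
  0.02/0.05/0.10 per month over a 60-month uniform censoring window —
  ordinary numbers for a three-arm cancer cohort.

One RNG stream per logical block (baseline, library size, counts,
regulon activity, bulk noise, survival) is derived from the master seed,
so adding a block never perturbs the draws of another, and identical
configs give byte-identical serialized datasets.

What the generator does **not** emulate: pathway-level co-regulation,
doublets, ambient RNA, batch effects, or real transcriptome topology. A
green recovery test therefore establishes that the implementation
recovers the structures it claims to recover under its own stated
assumptions — not that those assumptions hold in any particular real
dataset.

## Numerical choices and degenerate inputs

* Zero-variance genes z-score to 0; zero-variance window vectors get
  correlation 0; all-zero regulon activity rows get specificity 0 with a
  warning; cells with zero totals are an error, not a silent NaN.
* The log-rank covariance matrix is inverted with a pseudoinverse
  fallback when singular (e.g. a group with no events at any shared risk
  time).
* BH is computed by the explicit step-up formula and capped at 1.
* Thresholds compare strictly everywhere the upstream wording is strict
  ("larger than", "less than"); boundary cases are pinned by table-driven
  tests.

## Known limitations

* The built-in importance backend measures marginal |r| only; it cannot
  separate direct from indirect regulation the way a tree-ensemble
  learner can. The consensus layer is agnostic to the backend, which is
  the point of the contract.
* The mass-action score has no Hill-function saturation or cofactor
  modulation; strengths are bilinear in expression.
* Clustering, PCA/UMAP and pseudotime are out of scope; the metrics
  operate on any externally supplied labels.
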