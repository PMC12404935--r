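---
title: "netrewire: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netrewire: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind each stage of the
package, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the places
where the design was genuinely open and a choice had to be made.

## The analysis problem

The package compares two disease transcriptomes — the motivating case
is type 2 diabetes mellitus (T2DM, pancreatic islet arrays) versus
hypertension (HTN, kidney/blood arrays) — each assembled from several
case/control series. Because every series contributes one batch *and*
one disease, batch and disease context are confounded by design; the
preprocessing stage must respect that geometry. Downstream, the
package asks the same question at several scales: which genes shift in
mean (differential expression), which co-vary as modules, which
*rewire* — change their correlation connectivity between diseases —
which proteins are interaction hubs, and which transcription factors
change regulon activity.

## Synthetic data: what is planted and why

`sim_config()` defaults describe a desk-scale version of that design:
1000 genes; 15 samples per context × case/control cell (60 samples,
close to the tens-of-samples scale of merged array series); 5 batches
nested within context (each original series is one batch of one
disease); log2 baselines ~ N(8, 1), matching the average-expression
range typical of RMA-processed arrays (roughly 7–10); residual noise
`noise_sd = 1` on the log2 scale; per-gene batch offsets with
`batch_sd = 0.5`.

Planted structure, all recorded in the returned ground truth:

* **Modules** — each module shares a latent factor per sample with
  loading `noise_sd * sqrt(c/(1-c))` on top of `noise_sd` residual
  noise, so the within-module pairwise correlation is exactly
  `module_cor = c` (default 0.8). The factor adds variance, so module
  genes sit above background variance — as real co-regulated genes do —
  and survive the variance filter.
* **DEGs** — `deg_effect` (default 2, i.e. a 4-fold change) added to
  case samples with alternating sign.
* **Rewired hubs** — the hub's own (standardized) expression serves as
  the latent factor; each partner equals
  `rc·hub + sqrt(1-rc²)·noise` in the T2DM context only, giving
  hub–partner correlation `rewired_cor` there and ~0 in HTN.
  Partner–partner correlation is then `rc²`, the minimum achievable
  when partners are conditionally independent given the hub, which is
  what makes the hub itself the strongest gainer of connectivity.
* **TF regulons** — each planted TF has `targets_per_tf` targets with
  modes of regulation ±1 (70% activating); active TFs (half of them,
  alternating sign) shift their targets by `tf_effect · noise_sd · mor`
  in T2DM case samples. Decoy TFs at confidences C–E exercise the
  confidence filter.

One global seed expands into fixed per-component child seeds, so e.g.
the regulon table can be regenerated without re-simulating expression.

What the generator does **not** emulate: probe-level noise and
platform-specific intensity distributions, heavy-tailed or correlated
background noise, mean–variance coupling, missing values, and any
overlap between the planted gene classes (they are disjoint by
construction). Passing the recovery tests therefore shows the methods
are correct and well-calibrated under a clean additive Gaussian model,
not that they are robust to every artifact of real arrays.

## Preprocessing

Default order: QC → quantile normalization → batch adjustment →
variance filter. The order is not dictated by the method itself and is
exposed to the caller; filtering variance *after* batch adjustment
avoids keeping genes solely because of batch offsets.

* `quantile_normalize()` maps each column onto the row-means of the
  column-sorted matrix; it is idempotent and an exact fixed point for
  already-identical columns.
* `correct_batch()` deliberately replaces the usual empirical-Bayes
  batch model with condition-mean-preserving residual centering:
  design-cell (condition × context) means are computed, each batch's
  mean residual is removed, and the cell means are restored. Because
  batches coincide with disease context in this design, per-batch
  standardization would erase the disease signal; mean-centering within
  cells cannot. The cost is that only location effects of batch are
  removed, not scale effects — a documented limitation.
* `filter_variance()` uses the linear-interpolation (type-7) percentile
  with a *strict* inequality, so "above the 70th percentile" keeps
  just under 30% of genes.
* `detect_outlier_samples()` flags samples whose first merge into the
  average-linkage tree happens above `mean(h) + 2.5·sd(h)` — about the
  point where a merge height stops being explainable by the bulk of
  the merge-height distribution.

## Moderated differential expression

Per gene, an OLS two-group fit; residual variances are shrunk toward a
common prior via the scaled-F model fitted by method of moments on
`log s²` (digamma/trigamma identities, Newton inversion of the
trigamma function). Estimated prior df above 1e6 is treated as
infinite. The moderated t uses `d0 + d` degrees of freedom, so
zero-variance genes still get a finite statistic. DEG calls use strict
thresholds (|log2FC| > 1, FDR < 0.05).

The optional B statistic (log-odds of differential expression, prior
proportion 0.01) estimates the prior coefficient variance `v0` by a
single-quantile match between the observed |t| distribution and its
null — a deliberate simplification of the full mixture fit used by the
established implementation; it is reported for completeness and never
used for calls.

## Co-expression stage

* **Soft threshold.** For each candidate β the signed scale-free index
  regresses log10(bin frequency) on log10(bin-mean k) over 10
  equal-width bins on the *k* scale (the convention of the established
  co-expression tooling; equal-width bins on log10 k degenerate on
  block-structured data, collapsing into two occupied bins). The
  smallest β reaching R² ≥ 0.80 is chosen, else the argmax with a
  warning. The default grid stops at 16: with a few dozen samples the
  relative sampling error of r^β grows with β, and beyond ~16 the TOM
  compresses toward dissimilarity 1 faster than the network sharpens,
  fragmenting module detection.
* **Modules.** Average-linkage clustering of 1 − TOM with a static cut
  at 0.99; clusters under `min_module_size` (default 200, the
  conventional genome-scale choice; synthetic analyses use 20) become
  unassigned (label 0). Modules whose eigengenes correlate above 0.80
  (merge cut height 0.20) are merged iteratively, highest correlation
  first, ties toward the smallest label pair. A static cut plus
  eigengene merge was chosen over dynamic tree cutting because it is
  deterministic and directly testable while keeping the merge
  semantics; dynamic hybrid cutting is out of scope.
* **Eigengenes.** First singular direction of the gene-standardized
  module submatrix, unit variance, sign-aligned to the module's mean
  profile; variance explained is reported. Constant genes contribute a
  zero row after standardization.

## Rewiring

Connectivity is the signed sum of a gene's correlations with all other
analyzed genes. By default only *significant* correlations enter the
sum (per-pair Pearson test, two-sided p < 0.05, other entries zeroed):
the condition networks are defined by significant co-expression edges,
and summing noise correlations over ~100 genes otherwise injects
enough variance to mask a genuine hub. `edges = "all"` gives the raw
all-pairs sum; the antisymmetry and sum identities hold in both modes.
Gain/loss classes use the 95th/5th percentiles of the *current* score
distribution rather than absolute cutoffs, because absolute rewiring
scores scale with the analyzed gene count and sample correlation noise
and are therefore dataset-specific. Edge-level rewiring uses Fisher's
r-to-z (the standard two-sample correlation comparison; the choice of
test was open) with BH adjustment across all pairs, clamping |r| at
1 − 1e−7 before the transform.

## PPI stage

Combined scores are auto-detected as 0–1000 or 0–1 scale and
thresholded strictly at 0.9; the analysis graph is unweighted
thereafter (scores filter, they do not weight centralities, matching
the degree-based hub definition). Hubs rank by degree, then
betweenness, then id. Communities come from Clauset–Newman–Moore
greedy agglomeration; the merge level with maximal modularity is taken
(ties toward fewer communities) and a deterministic single-node
refinement pass follows — each node, in vertex order, moves to the
adjacent community that most increases Q until no strictly improving
move remains. Pure agglomeration can stall several hundredths of Q
below the optimum even on 7-node graphs; the refinement closes that
gap while keeping determinism.

## TF activity

Expression is gene-wise z-scored across all samples of the analyzed
matrix ("scale" signature). A TF's activity in a sample is the
mor-weighted mean of its targets' signatures normalized by the weight
norm, so under pure noise NES has mean ~0 and variance ~1 per TF. This
analytic form deliberately replaces the three-tail
enrichment-with-pleiotropy machinery of the established regulon tool:
it is deterministic, sign-faithful, and its null behaviour is known in
closed form; likelihood weights are treated as 1. Differential
activity uses the pooled-variance (Student's) two-sample t-test, per
the stated testing convention, at p < 0.05.

## Enrichment, integration, tissue profiles

Over-representation uses the upper-tail hypergeometric probability
with the post-QC expression gene set as the default universe (the
standard over-representation choice; configurable), set-size bounds
5–500 after universe intersection, and BH across tested sets. The
multilayer network joins all layer pairs sharing a gene (the pairwise
rule, so a gene in L layers contributes C(L,2) inter-layer edges);
node scores are the layer's natural statistic (log2FC, module
membership correlation, rewiring score, NES difference) — the layer
attributes had to be defined here, as visualization conventions leave
them unspecified. GraphML export orders nodes by (layer, gene) so
identical networks yield byte-identical files. Tissue Z-scores
standardize each gene across tissues after optional log2(TPM+1);
constant rows map to zero rows by convention, and clustering orders
(genes: correlation distance; tissues: Euclidean) are returned for
heatmap display.

## Problem sizes used in the shipped checks

The test-suite and acceptance script run at the planted-ground-truth
scales the package's recovery claims refer to: rewiring, 100 genes ×
40 samples/condition × 50 seeds; modules, 1000 genes (4 × 50 planted)
× 40 samples × 20 seeds; DEG error control, 220 genes × 40 samples ×
50 seeds; TF activity, 300 genes × 80 samples × 50 seeds; communities,
30-node planted partitions × 100 seeds; and one full pipeline run at
1000 genes × 80 samples. These sizes were chosen as the smallest at
which the corresponding effects are comfortably identifiable, keeping
a complete run fast on a single CPU.

## Known limitations

* Batch adjustment removes location effects only; no empirical-Bayes
  shrinkage of batch scale effects.
* Module detection uses a static cut; nested or close modules that
  dynamic cutting might separate can merge or fragment.
* The B statistic and NES are documented simplifications of their
  reference implementations and are not expected to match them
  numerically.
* The rewiring analysis is limited to two conditions and marginal
  Pearson correlation; partial-correlation rewiring is out of scope.
* Exact reproduction of published genome-scale counts (module sizes,
  hub degrees, absolute rewiring thresholds) requires the original
  external compendia and is outside what synthetic data can check.
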