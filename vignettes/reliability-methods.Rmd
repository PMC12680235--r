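---
title: "Quantifying the reliability of MIL aggregators for whole-slide images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the reliability of MIL aggregators for whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milrel)
```

## The problem

Whole-slide images (WSIs) are classified under weak supervision: a slide
carries one label, but the evidence for that label lives in a small set of
patches. Multiple instance learning (MIL) handles this by tessellating the
slide into $N$ patches, encoding each patch into a feature vector (here
emulating 1024-dimensional ResNet50 features of 256-px patches), and
aggregating the bag of instance embeddings into a slide prediction
$\hat{Y}$. Most aggregators emit per-patch scores as a side product —
attention weights, instance probabilities, or max-pool selections — and
these scores are routinely read as heatmaps of diagnostic evidence.

A model can classify well while scoring the *wrong* patches: high AUC with
attention mass on artifacts or irrelevant tissue. `milrel` quantifies this
gap. We call a model *reliable* when its patch scores concentrate on the
annotated regions of interest (ROIs), and we measure that with three
complementary statistics between the score vector $s$ and the
annotation-derived binary patch labels $y$:

* **Mutual information (MI)** — plug-in MI (in nats) of the joint histogram
  of quantile-binned scores and labels. Default binning is two bins split
  at the score median; probability-like channels are split at 0.5 instead,
  since 0.5 is their natural decision point. The estimator is the simple
  plug-in; with $\sim 50$–$80$ patches per slide its upward independence
  bias is about $1/(2N) \approx 0.01$ nats, which is why near-zero values
  should be read as "no dependence". Bin count is exposed (`bins`), and no
  conclusion in this package rests on absolute MI levels.
* **Spearman's $\rho$** — Pearson correlation of mid-ranks, capturing
  monotone association between score and ROI membership.
* **AUPRC** (average precision) — $\sum_k (R_k - R_{k-1}) P_k$ over
  descending score thresholds, with tied scores collapsed into one
  threshold. Its no-skill baseline is the ROI patch prevalence, making it
  the natural statistic under the heavy class imbalance of tumor
  localization.

Slides without any positive patch carry no localization signal and are
excluded before aggregation (normal slides in a tumor-vs-normal task).
The default aggregation computes each metric within each retained slide
and averages (`per_slide_mean`); a `pooled` mode concatenates all retained
patches first. The paper-style exclusion rule is stated at slide level;
the pooling level is a free choice, and we default to per-slide averaging
because it weights small and large slides equally and matches how
heatmaps are read (one slide at a time).

## Patch labels from polygon annotations

Region annotations are labeled polygons in level-0 pixel coordinates
(GeoJSON `FeatureCollection`s). A patch occupies the half-open square
$[x, x+P) \times [y, y+P)$. The default assignment rule, `center_in`,
labels a patch positive when its center lies inside (or on the boundary
of) any polygon; `any_overlap` labels on positive intersection area,
computed by rectangle clipping. `center_in` is the default because border
patches with sliver overlap are ambiguous evidence at 256-px granularity;
`any_overlap` is exposed because the convention differs across studies,
and it provably labels a superset of `center_in`. Multi-class annotations
count toward the positive label for any tumor class; class restriction is
available via the `classes` argument.

## The aggregator family

All models share a compression layer (affine $1024 \to D = 512$ followed
by ReLU) and a linear classifier head. Gated attention scores instances by
$a_i \propto \exp\!\big(w^\top(\tanh(Vh_i) \odot \sigma(Uh_i))\big)$ with a
hidden width of 256. The 256 is not arbitrary: it is the unique width that
reproduces the published parameter counts of this family (789 K for the
gated-attention model), and the accounting tests pin it.

| model | aggregation | reliability channel |
|---|---|---|
| `mean_pool` | mean of embeddings | none (no patch scores exist) |
| `max_pool` | element-wise max | `selection`: fraction of embedding dimensions won by each instance (ties split) |
| `mean_pool_ins` | mean of instance probabilities | `patch_prob` |
| `max_pool_ins` | per-class max of instance logits | `selection` and `patch_prob` (reported separately) |
| `abmil` | gated-attention weighted sum | `attention` |
| `clam_lite` | as `abmil`, plus instance-head auxiliary loss | `attention` |
| `madmil` | per-head attention over embedding chunks | head-mean `attention` |
| `dtfd` | two-tier pseudo-bag attention | combined tier-1×tier-2 `attention`, plus gradient-attribution `patch_prob` |
| `acmil_lite` | multi-branch attention, shared gating | branch-mean `attention` |

Design choices worth stating explicitly:

* **Additive reformulation.** For attention models the classifier head is
  linear, so the bag logit decomposes exactly into per-instance
  contributions $c_i = W^\top (a_i h_i) + b/N$ with
  $\sum_i c_i = \text{logits}$. `additive = TRUE` therefore changes only
  the emitted score sets (`ADD-ATT`, the attention; `ADD-PATCH`, the
  per-instance contribution through a softmax), not training — the
  decomposition holds to machine precision and is asserted in tests.
* **`max_pool` selection scores.** "The selected patch" is ambiguous under
  an element-wise max: each embedding dimension selects its own winner. We
  score each instance by the fraction of dimensions it wins (ties split
  equally), which sums to one and degenerates toward uninformative scores
  when no instance dominates — the behavior the published near-zero MI for
  max pooling reflects.
* **`madmil` head splitting.** Both the embedding and the attention hidden
  width are split evenly across heads ($D/H$, $256/H$). This is the only
  integer split that reproduces the published 658 K size of the two-head
  model, and it is asserted in the tests.
* **`dtfd` partitions.** Training partitions instances into $M = 8$
  pseudo-bags uniformly at random (part of the method's regularization;
  seeded). Inference uses a content-based canonical partition (instances
  ordered by feature row-sums, dealt round-robin), which makes score
  extraction deterministic and permutation-equivariant. The `DTFD-PATCH`
  channel is a simplified gradient attribution
  $a^{(2)}_{b(i)} a^{(1)}_i \,\mathrm{ReLU}(h_i^\top w_{\hat c})$,
  max-normalized to $[0,1]$; the original work's full Grad-CAM derivation
  and its distillation variants are out of scope.
* **Auxiliary losses.** `clam_lite` adds an instance-level cross-entropy
  (weight 0.3) on the top-8/bottom-8 attention patches (bottom-$k$
  pseudo-labels only exist in the binary case); `acmil_lite` adds a
  branch-diversity penalty (mean pairwise cosine of branch attentions,
  weight 0.1). These weights are not published for this family; they are
  exposed in `model_config()` and no reported result depends on them.
* **Computational accounting.** `count_params()` counts trainable scalars
  exactly. `count_flops()` counts multiply–accumulates of one *inference*
  forward pass at a conventional 120 instances: weight multiplications
  only, instance-wise layers $N$ times, bag-level classifiers once.
  Training-only components (the `clam_lite` instance heads) are excluded —
  that convention uniquely reproduces the published 63 M / 94 M values and
  the equality of the CLAM and ABMIL columns.

## Training protocol

`train_mil()` follows the standard protocol for this family: Adam at
learning rate $10^{-4}$, cross-entropy plus the architecture's auxiliary
terms, one bag per optimizer step (bags have variable $N$, so there is no
natural batch stacking), a maximum of 50 epochs with no early stopping,
and weight decay selected by final validation loss over a grid. Everything
is deterministic given the seed, and benchmark runs repeat over five
seeds, reporting mean ± sample sd. The default decay grid is
$\{10^{-5}, 10^{-4}, 10^{-3}\}$; the synthetic benchmark below fixes decay
at $10^{-4}$ so that the five-seed study stays small, and the grid
machinery is exercised separately in the unit tests.

## What the synthetic generator emulates — and what it does not

`make_dataset()` plants the MIL assumption directly: negative bags contain
no key instances; a positive bag of size $N$ contains
$\mathrm{round}(\rho N)$ key instances drawn from a mean-shifted isotropic
Gaussian ($\lVert \mu_{key} - \mu_{bg} \rVert = \delta$, noise sd 1),
spatially contiguous on the patch lattice and covered exactly by the
emitted polygon — so the annotation/rasterization pipeline is consistent
with the planted truth by construction (a property the tests assert). A
`scattered` mode exists for stress tests. With $\delta = 6$ the
instance-level Bayes error is $\Phi(-3) \approx 10^{-3}$: a linear probe
on labeled instances is near-perfect, so any failure to localize is
attributable to the weak supervision, not to the features.

The canonical study conditions (`study_config()`) are $\delta = 6$,
$\rho = 0.2$, 60 bags per class of 50–80 instances on a 10×10 lattice,
a 60/15/25 stratified split, and a feature dimension of 512. The feature
dimension deserves its own paragraph, because it is the one place where
desk-scale simulation and the full-scale setting genuinely pull apart:

* At $d = 1024$ with a desk-scale number of training bags, every
  aggregator reaches training AUC 1.0 while validation loss stays flat:
  tens of bag-mean vectors in a 1024-dimensional space are linearly
  separable by chance, so the optimizer can ignore the planted signal
  entirely. Reliability then measures memorization noise.
* At small $d$ (say 128), the fixed shift $\delta = 6$ becomes a large
  fraction of the total feature magnitude
  ($\mathbb{E}\lVert x \rVert^2 = d + \delta^2$), and key instances become
  trivially identifiable as magnitude outliers — even an untrained or
  badly trained max-pool selects them. Real encoder features are not like
  that: the tumor signal is a small displacement in a large-magnitude
  space.

$d = 512$ balances the two: bag-level generalization is attainable with
120 bags, while $\delta^2/d \approx 7\%$ keeps keys magnitude-inconspicuous.

This also bounds what passing synthetic results can show. The published
*unreliability* of max pooling on real slides is driven by structure the
generator deliberately omits (stain variation, scanner artifacts,
irrelevant high-magnitude tissue — all listed non-goals): in an isotropic
world the key shift is the *only* structure, so any max-pool model that
truly learns the task necessarily couples its selection channel to the
keys. Conversely the *reliability* of instance-mean pooling requires
genuine generalization, which desk-scale bag counts only partially
support: under the study conditions its per-slide AUPRC averages ≈ 0.83
against the ≥ 0.9 level reached with several-fold more training bags
(at 40 bags per class and decay 0.3 in the full 1024-dimensional setting
we measured AUPRC ≈ 0.99). The test suite asserts the strict
bound and we leave it failing at the default study size rather than
resize the study around it; the qualitative contrast —
instance-probability scores strongly aligned with ROIs
(AUPRC ≈ 0.83 vs prevalence 0.20, $\rho \approx 0.61$) while max-pool
selection carries essentially no information (MI ≈ 0.01, AUPRC within
about 0.1 of prevalence) — reproduces robustly across seeds.

## Cross-dataset aggregation and ranking

`overall_mean()` averages per-dataset means per model (unweighted), with
half-up rounding to the printed precision (two decimals for metrics,
nearest unit for K/M columns) — half-up, not banker's, because that is the
convention the published summary tables follow, and the bundled
`published_tables()` fixture reproduces every checked cell under it.
`rank_models()` scores each model by the sum of the selected reliability
metrics across datasets (equal weight), reports descending order, and
treats sums equal after 2-dp rounding as ties. Summing unrounded
per-dataset means, two adjacent additive models (4.21 vs 4.20) swap
relative to the published ordering, which was likely computed from the
rounded summary cells; the top of the ranking — instance-mean pooling
first — is stable either way and is what the test suite asserts.

`rm_anova()` implements the textbook one-way repeated-measures
decomposition (models as the factor, datasets as subjects), verified
against `stats::aov` error strata. It is a convenience utility: with three
datasets its degrees of freedom cannot match the published
$F(5,20)/F(6,24)$ values, whose derivation is not fully specified, so no
quantitative claim is attached to it.

## Degenerate inputs and numerical conventions

Constant scores or single-class labels make MI/Spearman/AUPRC undefined;
they return 0 (or 1 for AUPRC with all-positive labels) carrying a
`degenerate` attribute rather than erroring, so slide-set aggregation
stays total. Attention simplexes are validated to $10^{-6}$. Ties in
max-pool argmaxes are split equally in scores but routed to the first
winner in gradients. Weight initialization is He-scaled Gaussian, seeded
per model; all stochastic components (bag shuffling, pseudo-bag
partitions) draw from the single seeded stream, making every reported
number exactly reproducible.

## Known limitations

* Isotropic Gaussian features have no artifact/distractor structure, so
  synthetic max-pool unreliability is an *absence of signal coupling*,
  not the artifact-chasing failure mode seen on real slides.
* The CLAM/ACMIL/DTFD variants are deliberately simplified (`_lite`):
  published training tricks beyond what this family's description states
  are not reverse-engineered, and their auxiliary-loss weights are
  package defaults.
* The MI estimator is the plug-in on binned scores; absolute MI values are
  bin-count dependent and should only be compared within a fixed binning.
* Training is CPU matrix algebra; it is sized for hundreds of bags of
  $\sim 10^2$ instances, not for full WSI-scale corpora.
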