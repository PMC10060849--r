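---
title: "Multi-layer connectivity networks and domain-adversarial classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-layer connectivity networks and domain-adversarial classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hofcnet)
```

## The problem

Resting-state fMRI classification of major depressive disorder (MDD) from
functional connectivity faces two structural obstacles. First, the standard
Pearson connectivity network (low-order functional connectivity, LOFC)
discards information about *how regions attach to the rest of the brain*,
which higher-order constructions can expose. Second, usable sample sizes only
arise by pooling scanners: multi-site cohorts carry site-specific
distributional shifts that a classifier happily exploits, inflating
within-site results and collapsing on new sites. `hofcnet` implements a
pipeline that addresses both: three network layers per subject, edgewise
t-test feature selection, multi-layer feature fusion, and either a linear SVM
or a domain-adversarial neural network (DANN), all evaluated by
leave-one-site cross-validation (LOSCV), the only protocol that measures
generalization to an unseen scanner.

## The three network layers

For a subject with time-series matrix $X \in \mathbb{R}^{T\times N}$
(columns $x_i$, one per region of interest):

* **LOFC**: $W_{ij} = \mathrm{corr}(x_i, x_j)$, the Pearson correlation of
  the two regional signals. Symmetric, unit diagonal.
* **tHOFC** (topographical high-order FC):
  $\mathrm{tHOFC}_{ij} = \mathrm{corr}(w_{i\cdot}, w_{j\cdot})$ over
  partners $k \neq i, j$, where $w_{i\cdot}$ is region $i$'s row of the
  LOFC matrix. Two regions are coupled here when their *connectivity
  profiles* agree, regardless of their direct correlation.
* **aHOFC** (associated high-order FC): the correlation between region
  $i$'s tHOFC profile and region $j$'s LOFC profile, again over
  $k \neq i,j$. The raw matrix $A$ is not symmetric; it is symmetrized as
  $(A + A^\top)/2$ before vectorization.

Both indices $i$ and $j$ are excluded from the profiles — a profile of
length $N-2$ — so neither self-connections nor the pair's direct edge
contaminates the profile correlation. Each layer is vectorized by its strict
upper triangle in row-major order (`edgePairs()`), yielding $N(N-1)/2$ edge
features — 6670 for the 116-region AAL atlas.

**Degenerate profiles.** If a profile has zero variance after the
exclusions (e.g. an artificially constant LOFC row), the correlation is
undefined. We set the entry to 0 with a warning rather than aborting: an
undefined profile similarity is treated as absent connectivity, which keeps
cohort-scale batch runs alive and never selects such an edge spuriously
(its group difference is identically zero). An explicit error is reserved
for zero-variance *time series*, which indicate broken input data.

## Selection, fusion, classification

Per training fold, every edge gets a two-sided two-sample t-test p-value
(patients vs controls); edges with $p$ below the threshold (0.01 or 0.05 in
the study design, on raw p-values — deliberately no multiple-testing
correction, mirroring the reference protocol) are retained. We default to
the pooled-variance Student test; Welch is available via `welch = TRUE`.
Selected features from multiple layers are concatenated in fixed layer
order (LOFC, tHOFC, aHOFC) with per-column provenance, then z-scored with
training-fold statistics.

The linear SVM (cost 1) comes from `e1071`. The DANN is implemented in the
package itself: a feature extractor (one fully connected layer with
BatchNorm–ReLU–Dropout), a label predictor and a domain classifier — the
two heads identical two-layer stacks whose widths halve layer to layer,
with sigmoid outputs per class. Between extractor and domain classifier
sits the gradient-reversal layer (GRL): identity forward, multiply the
back-propagated sensitivity by $-\lambda$. The extractor is thereby pushed
to *increase* domain-classification loss, i.e. to produce site-invariant
features, while the label predictor pulls those same features toward
diagnostic separability.

Both losses are class-weighted binary cross-entropy
$$L = \frac{1}{N_{all}} \sum_n \sum_c W_c\, E(y_{nc}, \hat y_{nc}), \qquad
W_c = \frac{e^{1/N_c}}{\sum_{c'} e^{1/N_{c'}}},$$
with $E$ the standard nonnegative binary cross-entropy
$-[y \log \hat y + (1-y)\log(1-\hat y)]$ and predictions clamped to
$[10^{-7}, 1-10^{-7}]$. The exponential inverse-count weights give the
minority class the strictly larger weight and reduce to uniform for
balanced groups.

### Numerical and design choices

* **Optimizer**: Adam at learning rate 0.001 (per-parameter moments,
  $\beta = (0.9, 0.999)$), default 200 epochs, batch size 64; all
  configurable through `DannConfig()`.
* **$\lambda$** is constant over training (default 1), not ramped.
* **Determinism**: every stochastic component (each layer's
  initialization, each dropout mask, shuffling, target-domain sampling)
  draws from its own counter-indexed substream of the configuration seed.
  Two consequences we consider part of the contract: identical
  configurations give bit-identical training logs, and training with
  $\lambda = 0$ gives *exactly* the plain-MLP trajectory of the extractor
  and label predictor, because removing the domain head removes no draws
  from any other component's stream.
* **BatchNorm running statistics** are updated only on the label path. The
  domain path's forward passes use batch statistics for their own
  gradients but never touch the running estimates: the deployed network is
  the extractor + label predictor, and its inference-time normalization
  must reflect labeled source data only — updating it from domain batches
  would leak unlabeled target-site data into the deployed path.
* **Head widths**: the halving rule is the default
  (`extractorWidth = inputDim / 2`, head hidden width half of that). At
  the reference scale (hundreds to thousands of selected edges) this is a
  gentle funnel; at toy dimensionality it degenerates to 1-unit layers, so
  small-scale experiments should set `extractorWidth` explicitly (tests in
  this package use 8–16).
* **Reporting senses**: the per-epoch log supports both "test" (held-out
  accuracy at the epoch of best training accuracy) and "best_test"
  (maximum held-out accuracy over epochs). The latter dominates the former
  by construction; it is an optimistic oracle for early stopping and is
  reported alongside, never instead.

## Leave-one-site cross-validation

`runLoscv()` holds out each site in turn. Selection, standardization and
class weights are computed on the training sites only — the held-out site
influences nothing about the fitted pipeline (a property asserted by a
dedicated leakage test that replaces held-out features with noise and
checks the fold's selection is unchanged). For the DANN, the held-out
site's *features* (never labels) serve as the unlabeled target domain of
the adversarial task, the standard transductive DANN setting; set
`useTargetDomain = FALSE` to disable. Accuracy is plain correct/total per
fold, in percent, aggregated as an unweighted mean ± sd across folds
(subject-weighted pooled accuracy is also recorded).
`compareConfigurations()` contrasts two configurations with a two-sided
paired t-test across folds, pairing by held-out site — the comparison test
is our choice, as the reference protocol does not name one; with ten sites
it has nine degrees of freedom, enough for the large differences of
interest. Identical reports return difference 0 and $p = 1$ rather than
the undefined 0/0 statistic.

## The synthetic cohort generator

Access to the clinical multi-site cohort this design targets is
restricted, so the package ships a generator whose cohorts exercise every
pipeline property end to end:

* A **base latent correlation matrix**: sparse random symmetric entries at
  `baseDensity` (default 0.15, uniform in ±0.6), projected to the nearest
  SPD correlation matrix by eigenvalue clipping (floor $10^{-4}$) and
  rescaling to unit diagonal — a congruence by a positive diagonal, so a
  single pass guarantees positive definiteness.
* A **group effect**: the patient matrix adds `effectSize` to the latent
  correlation on `effectEdges`, then re-projects. Projection shrinks the
  shift, so `realizedEffect()`/`latentStructure()` report the *realized*
  patient − control difference; tests and power reasoning use that, never
  the nominal value.
* **Site effects**, two kinds. Per-ROI lognormal gain and additive offset
  (`siteShiftSd`) emulate scanner units and baselines; being affine per
  column, they are provably invisible to Pearson correlation and exist to
  keep raw-signal handling honest. Separately, a per-site symmetric
  perturbation of the latent correlation matrix (`siteCorrSd`, shared by
  both groups within a site, SPD-projected) produces the site-separable
  connectivity structure that makes multi-site pooling hard — without it,
  affine scanner effects alone would leave nothing for domain-adversarial
  training to fight.
* Subject time series are i.i.d. multivariate normal rows under the
  group-and-site latent matrix. Defaults (116 ROIs, 230 timepoints, ten
  sites of 60 patients + 56 controls — a 1160-subject cohort with a mild
  patient excess, matching the reference cohort's totals; its exact
  per-site split is not public) mirror the target setting; unit tests run
  at 10–20 ROIs.

What the generator deliberately does *not* model: hemodynamic response,
temporal autocorrelation of BOLD noise, motion artifacts, or preprocessing
(the pipeline consumes extracted regional time series). Passing tests
therefore demonstrate correctness of the statistical machinery and the
advertised invariances — not that real resting-state data satisfy the
generator's i.i.d. Gaussian assumptions.

## A small end-to-end run

```{r example, eval = FALSE}
cfg <- CohortConfig(
  nRois = 20, nTimepoints = 150,
  sites = data.frame(site_id = c("a", "b", "c"),
                     n_patients = c(17, 17, 16),
                     n_controls = c(17, 17, 16)),
  effectEdges = rbind(c(1, 2), c(4, 7), c(6, 13), c(9, 16), c(15, 20)),
  effectSize = 0.45, baseDensity = 0.1,
  siteShiftSd = 0.1, siteCorrSd = 0.05, seed = 1)
realizedEffect(cfg)            # ~0.43: the effect that actually survives
cohort <- generateCohort(cfg)  # 100 subjects across 3 sites
tabs <- buildEdgeFeatures(cohort, c("LOFC", "tHOFC", "aHOFC"))
runLoscv(tabs, layers = "LOFC", classifier = "svm", pThreshold = 0.01)
```

## Known limitations

* The t-test selection is univariate and uncorrected by design fidelity to
  the reference protocol; it will admit ~$\alpha E$ false edges under the
  null, which the classifier must tolerate.
* The DANN's feature extractor depth (one layer) and training schedule are
  package decisions where the reference architecture is underspecified;
  they are exposed in `DannConfig()` rather than hidden.
* Accuracy on sites whose test fold contains a single class is
  well-defined and used; a training fold with a single class aborts the
  fold, since neither loss is estimable.
* LOSCV sd across folds conflates site difficulty with sampling noise; it
  is reported because the reference convention reports it, with pooled
  accuracy logged alongside.
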