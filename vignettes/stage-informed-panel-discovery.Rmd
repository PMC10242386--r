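---
title: "Stage-informed biomarker panel discovery and PCA/k-means diagnosis"
author: "panelDx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-informed biomarker panel discovery and PCA/k-means diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Transcriptome-based cancer diagnosis usually leans on large gene signatures,
which are expensive to assay and hard to interpret. panelDx implements a
pipeline that compresses a stage-annotated expression cohort (controls plus
stage I--IV tumours) into a minimal biomarker panel and an unsupervised
cancer-vs-normal classifier over that panel. The pipeline has three parts:

1. **Stage-informed gene ranking.** Every gene is fit with two weighted
   per-gene models on voom-transformed log-CPM values:
   the *linear stage model*
   $Y = \alpha + \beta_1 x_1 + \beta_2 x_2 + \beta_3 x_3 + \beta_4 x_4$,
   where $x_s$ indicates tumour stage $s$, the intercept $\alpha$ is the
   control baseline and the $\beta_s$ are per-stage log2 fold-changes
   relative to controls; and the *ordinal model* $Y = aX + b$ with the stage
   treated as the numeric covariate $X \in \{0,1,2,3,4\}$ (0 = control).
   Residual variances are moderated across genes by empirical Bayes
   (prior $(d_0, s_0^2)$ estimated by moment matching on the scaled-F
   distribution of the per-gene variances; posterior variance
   $(d_0 s_0^2 + d\,s^2)/(d_0 + d)$), and p-values are BH-adjusted.
2. **Feature-space minimisation.** Genes are ranked per model by adjusted
   p-value; the consensus is the intersection of the two top-15 lists
   restricted to genes with adjusted $p < 10^{-5}$ in *both* models. The
   consensus is then reduced by Boruta (all-relevant selection against
   shuffled shadow features), recursive feature elimination (backward
   selection with cross-validated subset-size choice), and iterative
   variance-inflation-factor elimination with
   $\mathrm{VIF} = 1/(1 - R^2) > 2$ flagging multicollinearity.
3. **Unsupervised diagnosis.** PCA (covariance, centered, unscaled) of the
   panel subspace; the retained component count $q$ reconciles the
   Kaiser--Guttmann rule ($\lambda > 1$), the scree elbow, and an 85%
   cumulative-variance threshold; k-means with $k = 2$ clusters the training
   scores and each cluster takes its majority training class. A new sample is
   log2-preprocessed, centered with the training means, projected onto the
   top-$q$ loadings and assigned to the nearest centroid; the margin
   $d(\text{normal centroid}) - d(\text{cancer centroid})$ doubles as a
   ranking score for ROC analysis.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `filterThreshold` | 1.0 | genes with expression sd (input scale) strictly below this are dropped before modelling |
| `splitRatio` | 0.8 | stratified train fraction; per-class counts rounded half away from zero |
| `topN` | 15 | per-model top list size feeding the consensus |
| `alpha` | 1e-5 | adjusted-p gate both models must pass |
| `vifThreshold` | 2.0 | iterative elimination cutoff on VIF |
| `varThreshold` | 85 (%) | cumulative-variance criterion for the PC count |
| `kRange` | 2..8 | silhouette search range for k |
| `folds` | 5 | cross-validation folds (classifier evaluation and RFE) |

All defaults are the study settings of the pipeline this package
re-implements; each is overridable through `pipelineConfig()`.

## The synthetic cohort generator

Real stage-annotated cohorts of useful size cannot ship with a package, so
`simulateCohort()` generates one with known ground truth; it is a first-class,
tested module, and the default configuration defines the package's study
conditions:

* 300 samples: 30 controls and 68/68/67/67 tumours in stages 1--4 (90%
  cancer, matching the heavy class imbalance of public tumour archives);
* 2000 genes, of which 9 are planted biomarkers, 50 are near-constant "flat"
  genes (drawn with sd 0.1 on the output scale, below the variation filter),
  and the rest are null;
* planted biomarkers carry graded monotone stage profiles
  $\beta_s = \pm\,\mathrm{effect}\times(1 + 0.18(s-1))$ with effect size 2.5
  log2 units, so each is strong under *both* stage models — as published
  diagnostic panels are — while the cancer-vs-normal contrast remains the
  dominant axis of variation; pure monotone-trend genes
  ($\mathbb{E}[Y] = \mathrm{base} + aX$) are available through
  `nOrdinalSignal` but default to zero, because their early-stage offsets
  are too small to clear the dual $10^{-5}$ gate at ~25 training controls;
* expression is $2^{\mathrm{base} + \mathrm{offset} + N(0,\sigma)}$ with
  $\sigma = 1.5$ log2 units of residual biological noise, scaled by a
  per-sample library factor from $U(0.7, 1.3)$ (flat genes are not
  library-scaled — scaling would push their output-scale sd past the filter
  threshold and defeat their purpose);
* one integer seed drives every draw; equal seeds give bitwise-equal
  cohorts.

The noise level 1.5 was chosen once as a realistic inter-tumour residual
spread for bulk expression; it also keeps any single planted gene from being
individually class-separating, which matters because backward elimination
against cross-validated accuracy will happily discard features once accuracy
saturates. The effect size 2.5 is conservative relative to the |lfc| range
(4.2--7.1) reported for real panels of this kind.

**What the generator does not emulate:** negative-binomial count noise,
batch effects, correlated gene modules, tumour subtype structure, and
stage-label noise. Passing tests on this generator therefore demonstrate the
pipeline's correctness and its behaviour under a clean planted-signal model,
not clinical performance on real cohorts.

## Numerical and design choices

* **Ranking statistic.** The linear model is ranked by the moderated F over
  the four stage coefficients (one significance per gene per model, matching
  a single reported adjusted p per model); the ordinal model by the moderated
  t of the slope. The reported `lfc` is the largest-magnitude stage
  coefficient, signed.
* **Tie-breaks.** Gene ranking: adjusted p, then raw p, then descending
  |lfc|, then gene id. VIF elimination removes the lexicographically
  smallest id among tied maxima. RFE resolves exact accuracy ties toward the
  smaller subset. An equidistant sample in prediction is called normal
  (conservative margin-0 rule).
* **Boruta.** Out-of-bag permutation importance scaled by its standard error
  (the Z-score measure of the published algorithm; impurity importance is
  vulnerable to persistent chance correlations), two-sided binomial hit
  tests at each iteration with Bonferroni correction over the undecided
  features, tentative at `maxIter` treated as not selected. Features are
  canonicalised by name internally, so results do not depend on column
  order.
* **RFE.** Random-forest ranking with repeated (5x) 5-fold cross-validation;
  the repetition stabilises the subset-size choice, whose single-run
  sampling noise otherwise discards informative features near accuracy
  saturation. Even so, backward elimination may drop one panel gene whose
  marginal accuracy contribution is within cross-validation noise; this is
  inherent to accuracy-driven selection, not a defect of the planted signal.
* **PCA.** Covariance (not correlation) eigendecomposition of centered
  features — consistent with eigenvalue magnitudes far above 1 in the
  reference results; deterministic sign convention (largest-|entry| loading
  element positive). Kaiser--Guttmann implemented strictly as
  $\lambda > 1$; the scree elbow is formalised as the point of maximum
  perpendicular distance to the chord joining $(1, \lambda_1)$ and
  $(p, \lambda_p)$; the three criteria are reconciled by their median.
* **k-means.** `stats::kmeans` with 10 seeded restarts; cluster-to-class
  mapping requires exactly one majority-cancer and one majority-normal
  cluster and errors otherwise (a tied vote is not silently broken).
* **Prediction scale.** Deployment inputs on the linear scale are mapped
  through $\log_2(x + 1)$; the offset avoids $\log 0$ and the flag
  `inputScale = "log2"` bypasses the transform for already-logged data. No
  CPM re-scaling is applied at prediction time; the panel features are
  matched by id, so column order is irrelevant.
* **Pipeline order.** Filter, then voom on the filtered matrix, then the
  stratified split; the selectors run sequentially
  (consensus, Boruta, RFE, VIF). The silhouette-optimal k is computed and
  reported, while the deployed classifier always uses k = 2 — the diagnosis
  task is binary by construction.

## Problem sizes used by the test suite

Unit tests run on purpose-built fixtures of tens of samples. The end-to-end
validation uses the default study conditions above (2000 genes, 300
samples); empirical-Bayes hyperparameter recovery uses 1000 simulated genes;
the Boruta null check uses 20 repeats of a 100-sample, 10-feature
permuted-label design; oracle-equivalence checks (BH step-up, weighted least
squares, AUROC, VIF) use random instances up to a few hundred elements
against brute-force reference implementations written independently in the
tests.

## Known limitations

* The unsupervised classifier presumes the class contrast dominates the
  panel subspace's variance; on cohorts where progression (stage) variance
  rivals the cancer-normal gap, k = 2 clusters can align with early/late
  stage instead of class, and the cluster-mapping step will fail loudly.
* Accuracy-driven RFE can trim a genuinely informative feature whose
  marginal contribution is below cross-validation resolution.
* AUROC of a hard clusterer is defined here through the centroid-distance
  margin; other margin conventions would give different (equally defensible)
  curves.
* The voom weights are computed once on the full filtered matrix before the
  split; test samples therefore contribute to the mean-variance trend (but
  not to any model coefficient or selection decision).
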