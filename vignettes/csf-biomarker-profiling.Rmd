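---
title: "Data-driven profiling of CSF Alzheimer biomarkers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven profiling of CSF Alzheimer biomarkers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfprofiler)
```

## The problem

Cerebrospinal-fluid (CSF) core biomarkers of Alzheimer's disease (AD) —
the amyloid-beta 42/40 concentration ratio, tau phosphorylated at
threonine-181 (p-tau) and total tau (t-tau) — are routinely used to
support the differential diagnosis of dementia. Diagnostic cut-offs for
these markers are usually derived from clinically defined AD and control
groups, which makes them sensitive to misdiagnosis in the AD group and to
the heterogeneity of "other neurological diseases" (OND) control groups.
`csfprofiler` implements an alternative, data-driven route: cluster the
joint biomarker distribution of an entire mixed neurology cohort with a
Gaussian mixture model (GMM), identify the clusters that behave like
controls and like AD from the *prevalences* of clinically defined OND and
AD subjects within them, and derive cut-offs from cluster membership
rather than from the clinical labels directly. Because only the majority
composition of each cluster matters, the approach tolerates a substantial
fraction of misdiagnosed subjects (quantified by
`misdiagnosis_tolerance()`).

The package covers the full pipeline:

1. **Concordance** between two measuring centers before pooling their
   cohorts: Passing-Bablok regression with bootstrap confidence
   intervals, inter-assay coefficients of variation (CV), and a
   principal-component overlap check with per-cohort 95% ellipses.
2. **Clustering** of z-scored biomarker triples by a full-covariance GMM
   fitted with expectation-maximization (EM), with the number of
   components chosen by the Bayesian information criterion (BIC).
3. **Reporting**: per-cluster medians with 95% data ranges, a
   diagnosis-by-cluster prevalence heatmap ordered by average-linkage
   hierarchical clustering, prevalence-based cluster labels, and a
   Fisher's-exact comparison of stage composition.
4. **Cut-offs**: Youden-index thresholds with stratified bootstrap CIs
   for clinical (AD vs OND) and cluster-based comparisons.
5. **Matching**: age-histogram and sex rebalancing, validated by a
   self-contained logistic regression, followed by cut-off recomputation
   on the matched subset.
6. A **synthetic-cohort generator** that emulates the statistical
   structure such an analysis assumes, so every stage can be exercised
   and validated without patient data.

## The mixture model

Let \(x_i \in \mathbb{R}^3\) be the z-scored (ratio, p-tau, t-tau) triple
of subject \(i\). The model is

\[ p(x) = \sum_{k=1}^{K} \pi_k \, \mathcal{N}(x \mid \mu_k, \Sigma_k), \]

with unrestricted (full) covariances \(\Sigma_k\) — tau markers are
strongly anisotropic and correlated, which is why k-means-style spherical
clustering is not appropriate here. Fitting is by EM. The number of free
parameters for \(d = 3\) is \(p = (K-1) + 3K + 6K\), and model selection
minimizes \(\mathrm{BIC} = -2\log L + p \ln n\), ties going to the
smaller \(K\).

Z-scoring uses the *pooled* merged cohort (both centers) with the sample
standard deviation (\(n-1\)): the pipeline merges first and clusters the
merged set, so per-cohort standardization would reintroduce exactly the
center effect the concordance stage has just ruled out. The
`standardization.scope` of the transform is therefore pooled by design;
the transform object is invertible so all reporting is in natural units.

### Numerical choices in the EM fit

* **Initialization.** Each of `n_init = 10` runs starts from a k-means
  partition: k-means++ seeding refined by Lloyd iterations, converted to
  one-hot responsibilities, with EM starting on an M-step. Pure random
  seeding without the k-means refinement frequently leaves the
  six-component fit in poor local optima.
* **Convergence.** Relative log-likelihood change below `tol = 1e-6`,
  at most 500 iterations. The E-step works in log space (log-sum-exp).
* **Regularization.** `reg = 1e-6` is added to covariance diagonals at
  every M-step.
* **Degeneracy guard.** Mixture likelihoods are unbounded: a component
  can collapse onto a handful of nearly coplanar points, buying a large
  spurious likelihood gain. A run whose solution contains a component
  with smallest covariance eigenvalue below `min_eig = 1e-3` (z-scored
  units; legitimate biomarker components sit around 1e-2) or with fewer
  than \(d+1\) effective members is treated as degenerate and only used
  if every initialization degenerates. Without this guard, BIC model
  selection is intermittently dragged to spurious \(K+1\) solutions.
* **Hard labels** are the responsibility argmax; downstream analyses are
  hard-assignment by design.

## Cluster semantics and misdiagnosis tolerance

The **control** cluster is the single cluster holding the largest share
of all OND subjects (ties broken toward the higher median ratio, i.e.
the less amyloid-like cluster). **AD-like** clusters hold at least 10%
of all AD subjects *and* have more AD than OND members; the rest are
**intermediate**. A control cluster that simultaneously qualifies as
AD-like is refused as pathological rather than silently resolved.

`misdiagnosis_tolerance()` asks how many OND subjects would need to be
relabeled as AD before the control designation or the AD-like set
changes. Relabeling an OND subject inside the control cluster is always
weakly optimal for flipping the OND-share argmax, so the minimum is
obtained by closed-form counting over clusters (three mechanisms:
control flip, intermediate promotion, AD-like dilution); the smallest
case is verified against brute force in the tests.

The prevalence heatmap includes diagnoses with at least `min_n = 5`
subjects. Rows and columns are ordered by agglomerative clustering with
Euclidean distance and average (UPGMA) linkage via `stats::hclust()`.

## Cut-offs

Youden's index \(J = \text{sensitivity} + \text{specificity} - 1\) is
maximized over candidate thresholds placed at midpoints between adjacent
distinct values (plus infinite sentinels) — deterministic, symmetric,
and the convention of common ROC software. Directions are fixed a
priori by disease biology: low ratio is AD-positive, high p-tau/t-tau
are AD-positive. Ties on \(J\) resolve toward the highest sensitivity,
then toward the more specificity-conservative edge (smaller threshold
for higher-is-positive, larger for lower-is-positive). Confidence
intervals are percentile intervals over 2000 bootstrap replicates,
stratified by class so no replicate loses a class; the bootstrap flavor
is percentile rather than BCa because the simpler estimator is stable at
these group sizes and the pipeline only uses the CI for agreement
checks. For intermediate-vs-AD comparisons both the threshold and its
direction field are reported, since a heterogeneous cluster (e.g. one
dominated by prion disease) can exceed AD clusters in t-tau.

## Concordance stage

The Passing-Bablok slope is the shifted median of all pairwise slopes
\(S_{ij} = (y_j - y_i)/(x_j - x_i)\), excluding slopes exactly \(-1\)
and undefined ones, with the median rank offset by the number of kept
slopes below \(-1\) (the original 1983 procedure; ties kept as
duplicates). The intercept is \(\mathrm{median}(y - bx)\). CIs are
percentile bootstrap over paired resamples (2000 by default). Two
centers are declared mergeable for an analyte when the slope CI contains
1 and the intercept CI contains 0 *or* the absolute intercept is below
5% of the median measured value — a small systematic offset, e.g. in
t-tau, need not preclude pooling; the threshold is configurable.

Per-sample inter-assay CV for a pair \((a, b)\) is
\(|a-b| / (\sqrt{2}\,\bar{x})\) (two-point \(n-1\) SD over the mean);
the analyte summary is the arithmetic mean over samples.

The PCA overlap check eigendecomposes the sample covariance of the
z-matrix (loadings signed so the largest element is positive), and draws
per-cohort 95% regions in the PC1–PC2 plane as Mahalanobis ellipses with
squared radius \(\chi^2_{2,0.95} \approx 5.991\) — the "95% data range"
of a cohort under approximate binormality of its scores.

## The synthetic generator

Real cohorts of this kind are not publicly distributable, so
`default_mixture_spec()` defines a generating model that emulates the
structure the analysis assumes, at the study's scale (616 subjects, two
centers, 40 paired remeasurements):

* six components over (ratio, p-tau, t-tau) in natural units — one
  control-like component (ratio 0.095 ± 0.012, low tau, 30% weight),
  one wide heterogeneous component (ratio 0.075 ± 0.020, t-tau
  900 ± 600 pg/mL, 10%), and four AD-like components (ratio
  0.045 ± 0.008) with tau graded upward (p-tau means 55/80/110/150,
  t-tau means 350/550/800/1200 pg/mL; weights 0.20/0.15/0.15/0.10);
* within-component tau spreads of roughly 10–15% of the component mean
  with a modest residual p-tau/t-tau correlation (0.15 in the AD strata,
  where the tau gradient itself is carried by the component means; 0.5
  in the control component). These spreads are what make the graded
  strata resolvable at \(n = 616\), which is the regime the pipeline is
  designed for;
* a per-component diagnosis composition placing most OND/PD/MS/PSP/MSA
  mass in the control component, most AD/DLB/PDD mass in the AD-like
  components (about 96% of AD subjects in expectation), and the
  CJD/NPH/FTD/encephalopathy mass in the heterogeneous component;
* deliberately imbalanced age models (AD ~ N(72, 8), OND ~ N(58, 12),
  others N(68, 10), truncated to 40–90 years) and mildly imbalanced sex
  models, so the matching stage has real work to do;
* positivity enforced by rejection resampling of the whole triple (at
  most 100 redraws, then clamping at 1e-6), which distorts the intended
  covariance less than per-coordinate truncation would;
* paired remeasurements with independent per-center proportional noise
  at configurable CVs (defaults 7% ratio, 4% p-tau, 9% t-tau).

What the generator does **not** emulate: longitudinal trajectories,
missing data, assay drift beyond proportional noise, floor/ceiling
effects of real immunoassays, and the long right tail of real t-tau in
prion disease (the heterogeneous component is a single truncated
Gaussian). Tests passing on synthetic cohorts therefore demonstrate the
correctness and stability of the estimators under the stated model, not
clinical performance on real data.

Hidden generating-component indices (`.component`) are retained only
when `with_truth = TRUE`, keeping production outputs clean while
enabling parameter-recovery tests.

## Matching stage

Age matching anchors 5-year bins at age 0 (`[70, 75)` rather than
data-driven bins — deterministic and reproducible), randomly
down-samples the larger group within each bin, and drops bins populated
in only one group. Sex rebalancing then iterates: fit
`group ~ age + sex` by the package's own IRLS logistic regression; stop
when both Wald p-values exceed 0.25; otherwise remove one random subject
of the over-represented sex from the group where it is over-represented
(one subject per iteration — the smallest perturbation that can cross
the threshold; seeded). The outcome coding (group indicator on age +
sex) is the minimal model consistent with checking balance "both for age
and gender". Complete separation is detected and flagged rather than
silently reported with meaningless standard errors.

## Problem sizes and determinism

All simulation-based checks run at the scale the pipeline targets:
cohorts of 616 subjects, 40-sample concordance experiments, 2000
bootstrap replicates, and 5–20 seed replications for stochastic
properties; smaller sizes appear only in exact-oracle comparisons where
exhaustive enumeration is the reference. Every stochastic function
takes an explicit integer seed and is bit-reproducible given (inputs,
seed).

## Known limitations

* Cluster labeling assumes clinical AD and OND diagnoses are majority
  correct; the misdiagnosis-tolerance analysis quantifies, but does not
  remove, this assumption.
* The GMM is fitted with hard BIC selection; plateau-shaped BIC curves
  near the optimum are resolved by parsimony (smaller K within 1e-9),
  not by model averaging.
* Percentile conventions matter at small cluster sizes: the 95% data
  range uses linear interpolation between order statistics (type 7), so
  values from other conventions can differ by a few percent.
* The mergeability rule's 5% relative-intercept escape hatch is a
  pragmatic default, not an equivalence test.
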