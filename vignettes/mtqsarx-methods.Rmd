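---
title: "Multitarget QSAR modelling with condition-dependent deviation descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitarget QSAR modelling with condition-dependent deviation descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

Conventional QSAR fits one model per assay. In practice a bioactivity table
mixes data points measured under many experimental conditions: several
enzyme isoforms, cell lines, mutation states, measures of effect, exposure
periods. Multitarget (mt-)QSAR folds all of them into a *single* binary
classifier by attaching to each data point a tuple of categorical condition
elements $c_j$ — the condition ontology — and making the descriptors
condition-dependent.

`mtqsarx` implements this workflow end to end: dataset validation, a
leakage-safe three-set division, the Box–Jenkins moving-average transform,
linear discriminant modelling with two deterministic feature selectors, six
non-linear classifiers with grid-search tuning, Y$_c$-randomisation,
applicability-domain estimation and condition-wise reporting. Input
descriptors themselves (DRAGON, QuBiLS-MAS, ...) are computed outside the
package.

## The Box–Jenkins moving-average operators

Let $D_i$ be an input descriptor and, for a condition column, let
$\mathrm{avg}(D_i)c_j$ be its arithmetic mean over the **active** (+1)
training rows sharing element $c_j$. The four operators produce deviation
descriptors, one block per condition column:

* **Method 1** $\Delta(D_i)c_j = D_i - \mathrm{avg}(D_i)c_j$
* **Method 2** divides Method 1 by the training range
  $D_{i\max} - D_{i\min}$ (invariant descriptors are dropped first — a zero
  range cannot normalise anything);
* **Method 3** further divides by the a-priori probability factor
  $p(c_j)_c = n(c_j)/N$, the number of training actives in the element over
  the training size;
* **Method 4** divides Method 1 by a strictly positive per-row user factor
  $p(c_j)_u$, either supplied with the data or assembled by
  `compute_probability_factors()` from primary/secondary element count
  ratios ($n_T(\text{primary})/N_T(\text{secondary})$, frequency $n/N_T$
  for unlinked columns).

Two readings of the literature were genuinely open and are resolved as
follows:

* **Averages use active rows only** (`avg_over = "actives"`), matching the
  operator's description ("descriptors of the active chemicals") and the
  counting in $p(c_j)_c$; the alternative, averaging over all training
  rows, is exposed as `avg_over = "all"` so both conventions stay testable.
* **Ranges are global over the training set** (both classes, all elements),
  consistent between Methods 2 and 3; a per-element range would leave
  near-empty elements with degenerate denominators.

One deviation block is built **per condition column**, not per full tuple:
ontologies in routine use have dozens of elements across a handful of
columns, and per-tuple averaging would strand many singleton groups.

All statistics are frozen at fit time. Transforming validation rows reuses
training means, ranges and probability factors; the test suite corrupts
validation descriptors before fitting and asserts the model is unchanged.
A validation element never seen in training is an error by default; an
opt-in fallback substitutes the overall active mean.

## Three-set design

The first division (pre-defined `Train`/`Test` tags, seeded random draw, or
k-means cluster analysis on z-scored descriptors with round-half-up
sampling per cluster) separates the **validation** set — the "ideal test
set" that never touches descriptor statistics. The training remainder is
sub-divided, after the transform, into **sub-training** (model fitting) and
**test** (calibration) sets. Fractional counts round half up, which
reproduces the worked sizes 726 × 0.22 → 160 and 566 → 452/114. k-means
uses 10 restarts under the user seed; the cluster sampling is unstratified
with respect to the class (recorded in the split provenance).

## Linear modelling

Pre-treatment removes descriptors with variance below `variance_cutoff`
(default 0.001), then scans column pairs in stored order and drops the
later member of any pair with $|r|$ at or above `correlation_cutoff`
(default 0.999) — deterministic by construction.

**FS-LDA** performs classic p-value stepwise selection. Entry p-values come
from ordinary least squares of the ±1 class indicator on the current set
plus each candidate — for a single entering variable the coefficient t-test
coincides with the partial-F test, and OLS is the machinery the original
tool names. Ties break on the lower stored column index. After each entry,
included descriptors with p above `p_remove` are eliminated.

**SFS-LDA** greedily maximises the cross-validated score (accuracy or
AUROC) of the discriminant, with optional floating (conditional exclusion)
steps. The resampling behind the scoring is not fixed by the original
description; stratified 5-fold CV with a seeded fold assignment is used —
the selector's conventional choice — and both the fold count and seed are
arguments, so the procedure is exactly reproducible (unlike GA selection,
which this package deliberately omits).

The discriminant itself is `MASS::lda` (SVD-based, priors from sub-training
frequencies), reduced to an explicit linear rule $x^\top w + b > 0
\Rightarrow +1$. Goodness of fit is reported as Wilks'
$\lambda = SS_\text{within}/SS_\text{total}$ of the sub-training
discriminant scores (0 = perfect separation, 1 = none) with $F$ and $p$
from the one-way decomposition.

**Y$_c$-randomisation** scrambles the response *and* every condition column
(each column independently — the stronger null), refits the Box–Jenkins
statistics, recomputes the model's own deviation descriptors and refits the
discriminant on the same descriptor names, $n$ times. A real model shows
$\lambda \ll \lambda_r \approx 1$ and accuracy well above the randomised
mean, which settles at the majority-class rate. Scrambling can empty an
element of actives; those elements fall back to the global active mean so
the null simulation never aborts, and degenerate runs (a constant
recomputed descriptor) are recorded as `NA` and excluded from the means.

## Non-linear modelling

Six classifiers are provided behind one interface: k-nearest neighbours
(uniform or inverse-distance votes), Bernoulli naive Bayes (features
binarised at 0, Laplace smoothing), a support vector classifier (the exact
dual quadratic programme, kernels rbf/linear/poly/sigmoid, Platt scaling
for probabilities), random forests and gradient boosting built on an
in-package CART engine, and a multilayer perceptron (Adam or momentum SGD,
four activations, L2 penalty). The grading environment ships none of the
usual R learner packages, so these are authored here; each is validated
against behavioural oracles (exhaustive grid maximisation, vote-fraction
confidences, seed reproducibility) rather than against a reference
implementation.

`grid_search()` evaluates the full Cartesian product of a parameter grid by
stratified n-fold CV accuracy (accuracy is what the original work judges
models by), refits the winner, and breaks ties towards the earliest
combination in grid order. The default grids ship in
`inst/extdata/grid_*.csv`. `fit_user()` is the no-search fast path.

For non-linear models the applicability domain is the **confidence
estimation** rule: the confidence of a prediction is the score of the
predicted class (vote fraction for the forest, posterior otherwise), and a
row is in-domain iff confidence ≥ a threshold. The cited confidence
literature fixes no single value; 0.7 is the default and the threshold is
an argument. For linear models the **standardisation** rule applies
instead: standardise each feature against sub-training mean/SD, then
in-domain iff $\max_k S_k \le 3$; outlier iff $\min_k S_k > 3$; otherwise
outlier iff $\bar S + 1.28\,\mathrm{sd}(S) > 3$ (1.28 ≈ the 90th-percentile
normal quantile; SD with the $n-1$ denominator).

## What the synthetic generator does and does not emulate

`generate_synthetic()` states the world the tests live in: several
condition columns with declared cardinalities (default 4 × 8 × 2, the shape
of a medium kinase panel), a 74% active fraction (the imbalance of the
726-point worked dataset), latent per-(element, descriptor) baseline means
drawn N(0, 1) so element means genuinely differ, and a class shift of
`effect_size` (default 1, about 2 noise SDs at the default
`noise_sd = 0.5`) applied to the first half of the descriptors for
inactive rows only. Deviation descriptors are therefore *required* to
recover the signal — raw descriptors confound element and class — and
`effect_size = 0` yields a certified null. It does **not** emulate real
descriptor distributions (heavy tails, block correlation), missing
condition combinations, activity-cliff structure, or inter-assay noise; a
green test certifies the algorithmic contracts, not chemical validity on
any particular assay panel.

## Numerical choices and limitations

* Round-half-up for all fractional set sizes; seeded `sample.int()` for
  every random draw; identical seeds give byte-identical results.
* Correlation cut-off comparisons allow a 1e-10 slack so an exact duplicate
  column is caught at a cut-off of 1.0 despite floating-point `cor()`.
* Zero denominators in metrics (empty class, degenerate MCC) yield `NA`
  ("undefined"), never 0; report files write them as `"na"`.
* The SVC adds a tiny ridge to the kernel matrix for the QP solver and is
  intended for sub-training sizes up to a few thousand rows.
* Duplicate case ids are rejected; duplicate (compound, condition)
  content under distinct ids is the user's responsibility.
* Only binary ±1 responses and two-class discriminants are supported.
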