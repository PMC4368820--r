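---
title: "Heterogeneity-aware differential expression testing and reliability benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneity-aware differential expression testing and reliability benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hta)
```

## The problem

Two-cohort expression contrasts are classically tested feature by
feature with a t-test, whose denominator estimates error variance from
the handful of replicates of that one feature. Two things break this in
practice. First, with 3--10 replicates the per-feature variance
estimate is extremely noisy, so the t ranking is easily rearranged by
chance. Second, and more fundamentally, cohorts of genetically
different samples (patients, outbred animals -- "type II" samples)
carry *molecular heterogeneity*: one phenotype, several genotypes. If a
patient cohort contains two disease subtypes, each driven by a
different pathway, the member genes of either pathway are genuinely
differentially expressed in only part of the cohort. Their sample
variance is inflated by real biology, not by technical error. A t-test
mistakes this non-error spread for noise and deprioritizes exactly the
disease-relevant genes; the signature of the effect is per-feature
variance that expands with absolute fold-change. Larger cohorts do not
fix it, because the bias is in the ranking, not in the power. The
popular patch -- a loose p cutoff combined with a fold-change cutoff --
buys reproducibility at the price of statistical control and of
discarding coordinated low-magnitude signals (a pathway whose members
all move 20% is biologically potent but falls far below a |log2 FC| > 1
cutoff).

## The testing model

The z-test implemented in `hta_test()` takes the opposite variance
model: technical error is *homogeneous across features* but
*heterogeneous across arrays* (arrays differ in quality). The pipeline:

1. **Samplewise error variances.** For arrays $r_i, r_j$ of one cohort,
   the per-feature log2 differences $d_f = x_{fi} - x_{fj}$ cancel the
   shared biology, so with normal errors
   $\sigma^2_{r_i,r_j} = \mathrm{Var}_f(d) = \sigma^2_{r_i} + \sigma^2_{r_j}$.
   Taking $\sigma^2_{r_i,r_j}/2$ as one estimate of $\sigma^2_{r_i}$
   and averaging over the $n-1$ partners gives
   $\hat\sigma^2_{r_i} = \tfrac12 (n-1)^{-1} \sum_{j\neq i}\sigma^2_{r_i,r_j}$.
   All features enter the estimate (most are assumed non-differential),
   so its effective degrees of freedom are enormous and the sample-size
   limitation of per-feature estimation disappears.
2. **Scaling normalization.** `scaling_normalize()` shifts each array
   additively on the log2 scale to the grand mean of the per-array
   means (equivalently, scales raw intensities to the global geometric
   mean). Because the shift is additive per array, it cancels in every
   pairwise difference: the error-variance estimates are provably
   identical before and after normalization, and a regression test
   asserts this to 1e-12. The estimation-before-normalization ordering
   is therefore a presentation choice with no numerical consequence.
3. **Cohort posteriors.** Each measurement carries a Gaussian density
   centred on its observed value with its array's error variance.
   Multiplying a cohort's Gaussians (flat prior) gives the
   precision-weighted posterior of the cohort's true mean:
   $\sigma^2 = (\sum_i 1/\sigma^2_{r_i})^{-1}$,
   $\mu = \sigma^2 \sum_i x_i/\sigma^2_{r_i}$. `cohort_posterior()` is
   verified against numerical multiplication of the densities on a fine
   grid to 1e-6.
4. **The z statistic.** The log2 fold-change posterior is Gaussian with
   mean $\mu_t - \mu_c$ and variance $\sigma_t^2 + \sigma_c^2$, so
   $z = (\mu_t - \mu_c)/\sqrt{\sigma_t^2+\sigma_c^2}$ is referred to
   the standard normal (two-sided; sidedness only affects the p scale,
   not the ranking or FDR ordering, and unsigned significance is what
   selection uses). FDR is Benjamini-Hochberg over all tested features,
   with no independent filtering.

Two consequences matter. Per-feature variance never enters, so subtype
spread cannot deprioritize a gene: when array quality is even, the |z|
ranking *is* the |fold-change| ranking (the variance is a single shared
constant). When quality is uneven, the precision weights downweight
noisy arrays. Note the samplewise estimates are shrunk: splitting each
pairwise variance in half gives
$\hat\sigma^2_{r_i} = (\sigma^2_{r_i} + \overline{\sigma^2_{r_{j\neq i}}})/2$,
which recovers the cohort-average variance exactly and preserves the
quality ordering but halves the contrast between arrays. The weighting
is therefore conservative; the test stays calibrated because the total
fold-change variance is unbiased.

### Tunable parameters

* `variance_floor` (default `1e-12`, log2² units): lower bound on the
  samplewise variances, guarding against infinite precision on
  degenerate inputs such as duplicated arrays; applications are
  flagged in the fitted model.
* `robust` (default off): replaces each pairwise difference variance by
  the squared scaled MAD, for heavy-tailed contamination. Off by
  default because with mostly non-differential features the plain
  variance is the efficient estimator.
* Baseline thresholds: the hybrid method defaults to p < 0.05 and
  |log2 FC| > 1 (both strict), enrichment detection to Fisher
  p < 0.001 (one-sided, uncorrected -- a fixed raw significance level),
  FDR selection to q < 0.05.

## Reference methods

`pooled_t_test()` implements the pooled-variance two-sample t-test
(pooled, not Welch, matching the classical pooled common-SD
denominator $S_c^2 = ((n_1-1)S_1^2 + (n_2-1)S_2^2)/(n_1+n_2-2)$), and
`hybrid_select()` the joint p + fold-change selection. Inside the
benchmarking report both baselines run on the same scaling-normalized
matrix the z-test sees, so method comparisons are not confounded by
preprocessing differences. Moderated-variance methods and gene-set-level
tests are deliberately out of scope.

## Reliability benchmarking without known truth

On real biological data the truly differential genes are unknown, so
methods cannot be scored by recovery. The platform in `bmorr_report()`
scores them by biologically motivated proxies, each normalized by a
reference method (so the reference scores exactly 1 by construction):

* **Relative specificity** -- the number of functions overrepresented
  (Fisher p < 0.001) in the features a method selects at p < 0.05,
  divided by the reference's count. Coexpressed genes are functionally
  coherent; random selections are not. The loose 0.05 cutoff keeps the
  estimate based on enough genes even for insensitive methods.
* **Relative sensitivity** -- relative specificity times the number of
  features selected at FDR < 0.05, normalized by the reference's
  product; under proportionality of relative to absolute specificity
  this is proportional to the number of true positives.
* **Relative reproducibility** -- across data sets of similar studies,
  the mean over detected function *instances* (a function counted once
  per data set detecting it) of that function's occurrence count,
  normalized. Averaging over instances rather than unique functions
  weights functions by how often they recur, which is the quantity a
  reproducibility claim is about; the per-unique-function alternative
  is exposed via `per = "function"`.
* **Detection rate** -- the fraction of designated disease-specific
  functions present in the derived function set, averaged per data set
  (detection in at least one data set is available as an option).
* **AUC misanalysis** -- content agreement of a method's function
  ranking with a reference function set, as a Mann-Whitney AUC;
  AUC < 0.5 marks a contrast as misanalyzed. The derived function sets
  carry no intrinsic order, so the ranking is the minimal one
  consistent with them: ascending enrichment p on the method's own
  selection, unevaluated functions tied last, midrank ties. The AUC is
  invariant to monotone transformations of the scores, so any
  consistent scoring would give the same value. The hybrid method has
  a single joint selection and no FDR notion; it contributes that one
  selection to both the function-derivation and the FDR-count roles.

Undefined ratios (a reference count of zero) are reported as flagged
missing values, never silently as zero.

`progressive_degradation()` validates the specificity proxy: from a
paired contrast it builds replicates 0..P in which the arrays of the
first *i* pairs have their intensities permuted across features, so
specificity degrades monotonically by construction; a valid proxy must
decline along the series, and `degradation_curve()` confirms the
detected-function counts do, both for p < 0.05 selections and for
fixed top-5/10/15% selections (showing the decline is driven by
ranking derangement, not selection shrinkage).

## What the simulator emulates

`simulate_type1()` generates genetically identical cohorts: a common
template array (baseline log2 levels Normal(7, 2) clipped to [2, 15],
spanning a realistic array intensity range) plus optional cohort-level
shifts on a `deg_fraction` of features plus iid per-array Gaussian
error. Planted effect sizes default to |log2 shift| ~ Uniform(0.3, 2),
deliberately including coordinated effects below the conventional
|log2 FC| > 1 cutoff. The default error SD of 0.2 log2 units is a
typical single-array technical noise level; any per-array vector can
be supplied to exercise the quality weighting.

`simulate_type2()` overlays molecular heterogeneity: the test cohort
(optionally both cohorts) is partitioned as evenly as possible into
latent subtypes, each with a disjoint block of features receiving a
subtype-specific signed shift (magnitude Uniform(s/2, s) with
`subtype_shift` s defaulting to 1.5 log2 units -- a pathway-scale
effect). Block features then show exactly the pathology of interest:
within-cohort variance inflated by real differential expression, and
sample SD rank-correlated with |fold-change|. Setting the shift to 0
reproduces the type I matrix bit for bit, a continuity property the
tests assert. `simulate_study_collection()` draws the biology once and
re-draws only technical error per data set, emulating repeated studies
of one condition with matched designs -- which is what cross-data-set
reproducibility scoring assumes. Gene-set layers plant `signal_fraction`
of sets enriched (at `signal_purity`) in the differential features,
with the remainder as random decoys.

The generator is Gaussian-error only and feature-independent: it does
not emulate probe-level effects, intensity-dependent variance,
correlated gene programs beyond the planted blocks, or non-Gaussian
technical artifacts. Passing tests on it therefore demonstrate
correctness of the statistics and the direction of the methodological
claims (calibration, variance-fold-change coupling, degradation
decline), not performance on any particular real platform.

## Numerical choices and degenerate inputs

* All randomness is a deterministic function of (configuration, seed);
  regeneration is asserted bit for bit in the tests.
* Missing or non-finite values are rejected at the boundary, with the
  offending cell named; the method has no missing-data mechanism, so
  imputation would silently change its input distribution.
* p-values are floored at the smallest positive double so the (0, 1]
  contract survives tail underflow at |z| > 38.
* Ranking ties are broken by feature identifier, making top-fraction
  selections reproducible across platforms.
* Degenerate t-test features (zero pooled SD, zero difference) report
  t = 0, p = 1 with a flag rather than NaN.
* Problem sizes in the test suite (up to 20000 features for estimator
  recovery, 50 replications of 10000-feature null contrasts for
  calibration, 3000-feature paired contrasts for degradation) were
  chosen as the smallest at which the Monte-Carlo tolerances stated in
  the tests are comfortably resolvable.

## Known limitations

* The error model is additive Gaussian on the log scale with a single
  variance per array; intensity-dependent error is not modelled, and
  on real arrays the homogeneity assumption is an approximation.
* The shrinkage of samplewise variance estimates toward the cohort
  mean (derived above) weakens -- but never inverts -- the intended
  downweighting of poor-quality arrays.
* Only two-cohort contrasts are supported; multi-group designs are out
  of scope.
* Enrichment treats gene sets as flat (no ontology propagation,
  no redundancy reduction, no gene-length correction).
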