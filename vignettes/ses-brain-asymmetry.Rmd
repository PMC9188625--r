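---
title: "Mapping socioeconomic status onto brain structure: methods and design"
author: "sesBrainMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping socioeconomic status onto brain structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sesBrainMap)
```

# The analysis problem

Socioeconomic status (SES) is a latent construct usually measured through a
portfolio of indicators — education, income, occupation, neighborhood
deprivation and material wealth. Population imaging cohorts provide, for each
participant, a vector of image-derived brain phenotypes: gray-matter volumes
for atlas regions and mean fractional anisotropy (FA) for white-matter
tracts. `sesBrainMap` estimates how six SES indicators map jointly onto such
feature tables, quantifies the uncertainty of every coefficient by bootstrap
aggregation, assigns family-wise-error (FWE) corrected significance by a
permutation max-statistic procedure, and tests a specific structural
hypothesis: that SES associations are **hemispherically asymmetric**, with
positive effects concentrating in left-hemisphere features and negative
effects in their right-hemisphere homologues.

# The model

## Multi-output ridge regression

With $Y \in \mathbb{R}^{n \times k}$ the z-scored indicator matrix
($k = 6$), $X \in \mathbb{R}^{n \times p}$ the z-scored design matrix (brain
features after deconfounding, followed by the covariate block), the
estimator solves

$$\hat W = \arg\min_{W \in \mathbb{R}^{p \times k}}
  \frac{1}{2n}\,\lVert Y - XW \rVert_F^2
  + \frac{\alpha}{2}\,\lVert W \rVert_F^2 .$$

Stationarity gives the closed form
$\hat W = (X^\top X/n + \alpha I)^{-1} X^\top Y / n$. Because the penalty is
a pure Frobenius norm, the problem is **separable across outcomes**: column
$j$ of $\hat W$ equals the single-output ridge fit of indicator $j$ alone.
This is an exact algebraic identity, and the test suite uses it as an
oracle. The multi-output formulation is still the right container for this
analysis — one coefficient matrix, one bootstrap, one permutation null and
one laterality summary cover all six indicators coherently — but any
statistical coupling between outcomes would require a different penalty, so
none is claimed.

Note the $1/n$ scaling of the loss: relative to the common un-normalized
ridge convention the equivalent penalty is $n\alpha$. The default
$\alpha = 0.01$ refers to the normalized objective above.

Two solvers are provided. `closed_form` solves the normal equations;
`coordinate_descent` performs cyclic full passes in fixed column order with
convergence declared when the maximum absolute coefficient change in a sweep
falls below `tol` ($10^{-8}$ by default, capped at `maxIter = 10000`
sweeps; non-convergence is an error, never silent). The two agree to
$10^{-8}$ elementwise on well-conditioned problems, which the acceptance
checks enforce. The permutation null always uses the closed form, a purely
numerical shortcut within solver tolerance.

## Preprocessing contract

1. **Orientation.** Each indicator is flipped where needed so that a larger
   value always means higher SES; the neighborhood indicator (a deprivation
   index) is the one inverted by default. The binary job indicator is coded
   1 = knowledge worker, 0 = manual worker.
2. **Deconfounding.** Head size and body-mass index are regressed out of
   every brain feature (least squares with intercept) *before* modeling;
   residuals are exactly orthogonal to the nuisance columns. The fit is
   learned once on the analysis sample and reused inside resampling,
   matching the preparatory-step ordering of the analysis design;
   `crossvalBenchmark()` instead refits it per training fold because its
   metrics must be honestly out-of-sample.
3. **Covariates.** Age, sex, age², age×sex, age²×sex and fluid IQ (plus
   optional handedness) are appended after the brain features. Age is
   centered before powers are formed — the paper-level design is silent
   here, and centering reduces collinearity without changing the fitted
   subspace. Degenerate (constant) covariate columns are flagged and
   dropped before standardization.
4. **Standardization.** Every design and outcome column is z-scored with
   the sample (n−1) standard-deviation convention; the recorded
   means/scales are reused verbatim on held-out data. Covariates are
   z-scored like brain features (interaction columns are built first, then
   scaled), so all design columns sit in one penalized block; a separate
   unpenalized treatment of covariates was considered and rejected to keep
   the single-block design matrix of the published objective.

Complete cases are required; `dropIncompleteRows()` removes and counts
incomplete participants. No imputation is attempted.

## Resampling inference

- **Bagging.** `bootstrapBag()` refits the model on `B` (default 100)
  n-out-of-n resamples and summarizes each cell by ensemble mean, standard
  deviation, and 5%/95% percentile bounds (type-7 quantiles). A resample
  that makes a non-constant outcome column constant is redrawn and logged;
  columns constant in the original data pass through, so degenerate inputs
  collapse to zero-width intervals instead of looping.
- **Permutation null.** `permutationNull()` shuffles outcome rows as a
  block — all six indicators travel together, the design matrix held fixed
  — refits, and records the maximum absolute coefficient over all
  $p \times k$ cells (`R` = 1000 by default). Shuffling rows jointly
  preserves the inter-indicator correlation structure under the null.
- **FWE p-values.** $p = (1 + \#\{r : \max_r \ge |w|\})/(1 + R)$,
  two-sided via absolute values. The add-one convention makes $p = 0$
  impossible and $1/(R+1)$ the attainable floor, so "all $p < 0.001$" at
  $R = 1000$ means beating every null maximum. Ties count against
  significance. Max-statistic p-values dominate per-cell uncorrected ones
  by construction — a property test verifies this on shared null draws.
- **Observed statistic.** Whether the permutation statistic should itself
  be bagged is ambiguous in the source design; the default compares a
  bagged observed statistic against a plain-fit null
  (`statistic_mode = "plain_fit"`), which keeps $R \times B$ refits out of
  the default path. A fully nested `"bagged_fit"` mode is available.

## Laterality statistics

Homologous left/right features are paired by shared `homologue_id`;
midline features never enter laterality statistics. Two complementary
views:

- **Sign counts.** Every significant (feature, indicator) cell contributes
  one count to (hemisphere, coefficient sign); a region significant for two
  indicators counts twice (a deduplicated per-feature mode is a switch).
  Independence of hemisphere and sign is tested by the plain Pearson
  chi-squared statistic on the 2×2 table (df = 1), with Yates correction
  optional; the plain statistic is the default because the reference
  analyses in this ecosystem report uncorrected Pearson values. Zero
  margins make the test undefined and raise an error rather than a value.
- **Homologue correlations.** Pearson correlation between left-member and
  right-member coefficients across pairs. "Bootstrap-uncertainty-adjusted"
  is interpreted as bagged mean divided by bootstrap sd (a z-like map,
  `adjust = "z"`); the plain bagged-mean variant is always reported
  alongside. The pooled mode concatenates the six indicator columns;
  because averaging per-indicator correlations is an equally defensible
  reading, `asymmetrySummary()` reports both.

## SES structure and annotation

`pairwiseCorrelation()` and `pcaDecompose()` describe the indicator
portfolio; PCA is an eigendecomposition of the correlation matrix
(equivalent to PCA of z-scored indicators), with explained-variance ratios
eigenvalues/k and a deterministic sign convention (largest-magnitude
loading positive) for reproducibility. `pcRegression()` refits the brain
model on standardized component scores, by default unpenalized.

`profileTerms()` correlates coefficient maps over gray-matter regions with
each column of a region-by-term association matrix (the format exported by
meta-analytic decoding databases; the database itself is neither bundled
nor downloaded — any conforming TSV drops in, and `makeTermMatrix()`
generates test fixtures, optionally with a term planted collinear to a
designated map). Per-hemisphere profiles restrict the correlation to one
hemisphere's regions; `uniqueProfile()` residualizes one indicator's map on
the other five (least squares with intercept, across regions) before
correlating, isolating uniquely explained term associations. Pearson
correlation is the default; profiles are invariant to affine rescaling of
maps and term columns by construction. Profiling uses bagged means, not
significance-thresholded maps; thresholding is possible by masking the map
first.

# The synthetic cohort generator

The source study analyzed a restricted-access population cohort, and no
generative model for it exists; `simulateCohort()` therefore emulates the
*statistical structure the analysis assumes*, with ground truth exposed for
recovery testing. It is first-class, tested code — not a fixture.

- **Atlas.** Configurable counts of homologous cortical, subcortical and
  tract pairs plus midline features (defaults: 20 + 5 + 3 pairs, 3 midline;
  59 features). This mirrors, at desk scale, an analysis with ~111 regions
  and 48 tracts; midline features (e.g. brainstem) carry effects but are
  never paired.
- **Indicators.** A single latent factor with loadings
  $(0.6, 0.6, 0.5, 0.5, 0.4, 0.4)$ and unit unique noise keeps all pairwise
  correlations below 0.5 — the closed form is
  $\lambda_i\lambda_j/\sqrt{(\lambda_i^2+\sigma^2)(\lambda_j^2+\sigma^2)}$,
  maximum ≈ 0.27, and the brain-mediated share raises the realized values
  while staying under the 0.5 regime. The single-factor choice is the
  minimal structure consistent with moderate positive inter-correlations.
- **Planted effects.** Every homologous pair carries an effect of
  magnitude `effectScale` (default 0.1 standardized). A fraction
  `asymmetryFraction` (default 0.5) of pairs is **mirrored**: left
  $+$`effectScale` on all six indicators, right the exact negative — the
  left-positive/right-negative motif under test. The remaining pairs carry
  a one-sided effect (random hemisphere, random sign per indicator), and
  midline features random-sign effects. The one-sided remainder matters:
  if non-mirrored pairs were bilaterally symmetric, their $+1$-direction
  contribution would cancel the mirrored pairs' $-1$ direction and the
  pooled homologue correlation would vanish at fraction 0.5. With this
  design the expected pooled correlation at fraction 0.5 is about $-0.5$,
  and fraction 0 gives a calibrated null. Note the degenerate extreme:
  at fraction 1 every left value equals $+$`effectScale`, the planted
  pattern has no across-pair variance, and the homologue correlation is
  driven by estimation noise alone.
- **Noise model.** `indicator = X w + outcomeNoiseSD · (λ g + sesNoiseSD ε)`.
  The master scale on the whole non-brain part makes `outcomeNoiseSD = 0`
  an exactly noiseless linear system (recoverable to numerical tolerance),
  which anchors the oracle tests.
- **Confounds.** Head size and BMI load linearly onto brain features only
  (loadings $N(0, 0.3^2)$ by default); a `confoundOnSES` switch leaks them
  into the indicators for deconfounding stress tests. Marginals are
  conventional choices, not calibrated to any cohort: head size, BMI, IQ
  standard normal (standardized units); age uniform on 40–70 years (the
  recruitment window of population imaging cohorts); sex Bernoulli(0.52);
  handedness Bernoulli(0.9).
- **Encodings.** Income and degree are quantile-binned into 5 bands,
  vehicle count into 4, job is a median split coded 0/1, education years
  and neighborhood stay continuous; the raw neighborhood column is stored
  in deprivation direction so the orientation step has real work to do.
  Band frequencies are conventional (quantile) because none are published.

What the generator does **not** emulate: non-Gaussian marginals and floor/
ceiling effects of real questionnaire data, site/scanner structure, spatial
correlation between neighboring regions, nonlinear confound effects, and
missingness. Passing recovery tests therefore demonstrates correctness of
the estimation machinery under the stated model, not robustness to
everything real cohorts do.

# Numerical choices and problem sizes

- Tolerances: standardization and orthogonality contracts at $10^{-10}$ /
  $10^{-8}$; solver agreement $10^{-8}$; separability $10^{-10}$.
  Constant-column detection at sd $\le 10^{-12}$.
- The chi-squared tail is the exact survival function `pchisq(..., lower
  .tail = FALSE)`; for df = 1 it equals the two-sided normal tail of
  $\sqrt{\chi^2}$.
- Percentile bounds use R's default type-7 quantiles.
- Seeds: every stochastic routine takes an explicit integer seed; the
  pipeline derives per-stage seeds deterministically from its master seed,
  and reruns are byte-identical.
- Validation sizes are the package's own choices, balancing statistical
  resolution against a laptop-scale run: cohorts of $n = 5000$ with ~60
  features for recovery and laterality sweeps (20 seeds), $n = 1000$ with
  20 features and $R = 200$ for null calibration, $B = 100$ bootstraps
  throughout. At $n = 5000$ the planted effects are read at FWE $p < 0.01$;
  the stricter $p < 0.001$ of the population-scale analysis (floor
  $1/1001$ at $R = 1000$) is appropriate at roughly twice this sample
  size, and remains the pipeline default.

# Known limitations

- The benchmark registry implements ridge, OLS and a k-nearest-neighbor
  learner and accepts user-supplied learners; tree ensembles, kernel ridge
  and deep models are intentionally out of scope, so published benchmark
  tables for those families cannot be reproduced here.
- Published effect sizes, demographic tables and PCA variance percentages
  of the motivating population study derive from restricted-access data
  and are not reproduction targets; the package validates *analytic*
  identities and *recovery* on synthetic cohorts instead.
- Residualization is linear; no nonlinear deconfounding or site
  harmonization is provided.
- The laterality machinery assumes an atlas with exact left/right
  homologue pairing; asymmetric parcellations without pairing cannot use
  it.

# A worked micro-example

```{r example, eval = FALSE}
cfg <- pipelineConfig(generator = cohortConfig(nParticipants = 1000),
                      B = 50, R = 200, threshold = 0.01,
                      seed = 7, outDir = tempfile("ses_"))
res <- runPipeline(cfg)
res$asymmetry          # sign tables, chi-squared tests, homologue r grid
res$summary            # machine-readable run summary (also summary.json)
```

The README shows a full run with the numbers it prints.
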