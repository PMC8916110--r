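---
title: "Methods: population-connectome analysis of age-related connectivity decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-connectome analysis of age-related connectivity decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agefc)
```

# Scope and model

`agefc` implements a statistical pipeline for cohort studies of
resting-state functional connectivity (FC) and aging. The subject-level
object is an ROI x ROI matrix of Pearson correlations between regional
BOLD time series; the cohort-level questions are (i) whether mean FC —
global, within-network, between-network and per network — declines with
age after adjustment for sex and education, (ii) which *connected
subnetworks* of edges carry the decline, assessed with the network-based
statistic (NBS), and (iii) whether structural damage (cortical thinning,
PSMD) mediates the age-FC association, and FC in turn mediates the
age-executive-function association.

All models are linear in age. That is an assumption, not a finding: with
a cohort restricted to ages 45-74 a linear term is a reasonable local
approximation, and the package deliberately fits nothing more flexible.

## Connectome construction

`correlation_matrix()` computes Pearson correlations across time
(requiring at least 3 timepoints and no constant series). The primary
mode takes absolute values, treating anticorrelations by magnitude; the
signed mode is retained as a control because absolute values can mask
age-related *weakening of anticorrelations* as apparent stability.

`proportional_threshold()` retains the strongest
`k = round(p * E)` of the `E = n(n-1)/2` upper-triangle edges.
Conventions, chosen once and applied everywhere:

* **Rounding**: halves round up (`k = floor(p*E + 0.5)`), so `p = 0.5`
  on an odd `E` keeps the extra edge.
* **Tie-break**: stable ordering by (weight descending, row ascending,
  column ascending). Exactly `k` edges survive even on constant
  matrices, and results are platform-independent.
* **"Strongest"** means largest value in absolute mode, largest
  magnitude in signed mode.
* Thresholding is **per subject**: each subject keeps their own
  strongest edges, which keeps the retained fraction fixed while letting
  the retained set vary.

`mean_connectivity()` averages the retained (nonzero) edges only —
thresholded-out edges do not enter the denominator. The alternative
(counting zeros) would conflate the retention rule with the FC level.
A consequence worth knowing: with very small networks (a handful of
internal edges) a subject can retain no internal edge and the network's
mean is undefined for that subject; `network_means()` flags this rather
than imputing, and downstream regressions drop such rows listwise with a
message.

PSMD is the 95th minus 5th percentile of skeletonized mean-diffusivity
values (units mm²/s). The percentile convention is linear interpolation
between closest ranks (`stats::quantile` type 7); the original marker
tooling does not pin this down, so it is exposed as an argument. PSMD is
translation-invariant and scales linearly with positive rescaling, which
the tests assert.

## Regression and the multiplicity gate

`univariate_fit()` and `multiple_regression()` are ordinary least
squares via `stats::lm`, reporting unstandardized and standardized
coefficients. Standardized betas use sample SDs (n − 1 denominator):
`std_beta = beta * sd(x) / sd(y)`. The family threshold is Bonferroni:
with four networks and three global measures, `0.05 / 7`, reported
rounded to three decimals (0.007) in output tables. In the pipeline the
gate is applied to the **covariate-adjusted** age p-value, not the
univariate one, and networks failing it are excluded before the NBS.

## Network-based statistic

For each edge, the t statistic of the age slope across subjects
(simple regression by default). The primary threshold defaults to
`t = 3.2`; at the residual degrees of freedom of a ~1000-subject cohort
this corresponds to a one-sided tail probability of about 0.0007.
Edges beyond the threshold in the tested direction (negative — i.e.
age-related decline — is the primary test; positive is run separately)
form a graph; its connected components (via `igraph`) are the candidate
subnetworks, sized by edge count (extent, not intensity).

The null distribution of the **maximal component size** comes from
permuting age across subjects (default 5,000 permutations), and each
observed component gets
`fwe_p = #(null max >= observed size) / n_permutations` — the plain
proportion; the `(k+1)/(B+1)` variant is available via
`nbs_config(p_variant = "plus_one")` for users who prefer a p-value that
is never exactly zero.

Numerical and design choices:

* **Perfect-fit edges** (residual variance numerically zero) have
  unbounded t; they are capped at a sentinel of 1e6 — above any finite
  threshold — and the cap is visible in the t map rather than silently
  dropped. Constant edges have no defined statistic and are excluded
  with a message.
* **Covariates**: the default edge model is unadjusted, with adjustment
  available as a flag. When covariates are included the permutation
  scheme switches to Freedman-Lane (permuting residuals of the reduced,
  covariate-only model), the standard choice for permutation inference
  in the presence of nuisance terms. Both modes are exposed because
  published descriptions of such analyses often leave the edge-model
  covariates unstated.
* **Input matrices**: the NBS consumes unthresholded absolute matrices
  by default. Per-subject thresholded input is allowed (zeros are then
  treated as observed values), and subnetwork mean FC fed into
  mediation always uses unthresholded values so every subject has the
  same denominator.
* Permutation statistics are computed as one matrix product per chunk of
  permutations (edges x permutations), with component finding only on
  the permutations that have any suprathreshold edge; this is what makes
  hundreds of replicated NBS runs cheap.

The headline guarantee — that under the global null the probability of
declaring any component at level alpha is at most alpha (within
Monte-Carlo error) — is asserted directly by a 200-replicate simulation
in the test suite, alongside a power test on a planted 20-edge component.

## Mediation

`fit_paths()` estimates the standard parallel-mediator model: each
a-path regresses a mediator on the exposure (+ covariates); the outcome
equation contains the exposure and **all** mediators jointly, giving the
b-paths and the direct effect c'; the total effect c comes from the
outcome-on-exposure regression. Indirect effects are `a_j * b_j`, and
for this model `c = c' + sum_j a_j b_j` is an exact OLS identity
(asserted to 1e-8 on every fit in the tests; it holds to machine
precision). The phrase "each mediator was a covariate for the others"
is ambiguous between this standard model and one whose a-path equations
also adjust for the other mediators; both are implemented
(`a_paths_adjust`), the standard model is the default, and the identity
is only guaranteed in the default mode.

`bootstrap_mediation()` resamples subjects with replacement (default
10,000 iterations), refits the full path model on each resample, and
reports percentile CIs (bias-corrected optionally) and a two-sided
bootstrap p-value `2 * min(P(est <= 0), P(est >= 0))` — a definition
chosen explicitly because bootstrap "p-values" are often reported
without one. Resamples with a constant exposure are redrawn and counted.
Standardized effects are the unstandardized effects scaled by
`sd(exposure) / sd(outcome)`.

## The synthetic cohort generator

No cohort of this kind is publicly distributable, so the generator is a
first-class, tested module that emulates the *statistical structure* the
analysis assumes, with known ground truth:

* **Ages** are uniform integers on [45, 74]; sex is
  Bernoulli(0.454), coded 0 = male / 1 = female; education is uniform
  integer years 8-18 (the marginal education distribution of such
  cohorts is not well pinned down; uniform is an explicit, arbitrary
  choice).
* **Correlation targeting is analytic, not post hoc**: for a variable
  with age slope `b` and target correlation `r`, the noise SD is set to
  `|b| * sd(age) * sqrt(1/r^2 - 1)`, which makes the population
  correlation exactly `r` while keeping the generating slopes
  interpretable — essential for mediation recovery, where the same `a`
  and `b` that generate the data must be the estimands.
* **Marginal anchors**: thickness 2.32 mm center with slope
  −0.005 mm/yr (target r = −0.4; this slope keeps the marginal SD near
  0.11 mm, the scale seen in population cohorts); PSMD centered at
  2.17e−4 mm²/s with slope +2e−6 /yr (target r = +0.5); TMTB centered
  at 79 s (slope 1 s/yr) and TMTA at 36 s (slope 0.5 s/yr), both with
  target r = +0.3 and truncated below at 5 s so completion times stay
  positive.
* **Connectomes**: every edge is baseline 0.36 plus a fixed per-edge
  offset (SD 0.02) plus subject noise (SD 0.03, roughly matching an
  interquartile range of 0.04 around the global mean), clipped to
  [0.01, 0.99]. A connected random subgraph inside the default network —
  a random recursive tree plus extra edges, covering
  `planted_edge_fraction` of the network's edges — carries the age
  effect. `planted_slope` (default −0.002 FC/yr) is the **marginal**
  slope a simple edge-on-age regression recovers; it decomposes into a
  direct part and a thickness-mediated part
  (`planted_slope = c' + a*b`, with `b = 0.1` FC per mm by default), so
  the planted mediation structure is partial, as observed in real
  cohorts. When `outcome_b_fc` is nonzero (default −40 s per FC unit),
  the planted-subnetwork mean FC feeds back into TMTB, planting the
  age -> FC -> executive-function path with a positive indirect effect
  (less connectivity, slower completion).
* **Time series** for exercising the correlation step are Gaussian with
  a specified correlation matrix via its Cholesky factor (125 volumes at
  TR 2.5 s by default, i.e. a 5.2-minute acquisition).

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: BOLD autocorrelation and
spectra, head motion and its denoising residuals, spatial smoothness and
parcellation boundary effects, non-Gaussian and heavy-tailed edge
distributions, heteroscedasticity across age, and any nonlinearity in
age. Recovery results on synthetic cohorts demonstrate correctness of
the estimators under the stated model, not robustness to those
violations.

## Pipeline, determinism and conventions

`run_full_pipeline()` chains the stages in the order univariate fits →
adjusted regressions with the Bonferroni gate → NBS on the whole brain
and each surviving network → subnetwork extraction → mediation (model
one: thickness and PSMD mediating age -> subnetwork FC; model two:
subnetwork FCs in parallel mediating age -> TMTB and age -> TMTA). An
empty NBS result short-circuits mediation with a logged notice; a
subnetwork numerically identical to one already included (the
whole-brain component can coincide with a network's) enters model two
only once.

One master seed derives all stage seeds, and two runs with the same
configuration produce byte-identical output tables (asserted by md5 in
the tests; wall-clock timings go to the log stream, never into files).
ROI indices are 1-based everywhere, inside and out, matching R
convention; edges are stored as upper-triangle (i < j) pairs in
column-major order. Cohort medians and IQRs use the interpolated
(type 7) quantile convention.

## Problem sizes used in the tests

The simulation tests run at sizes chosen to make Monte-Carlo error small
relative to the asserted bounds while keeping the suite quick: FWE
control uses 200 null replicates of 150 subjects x 60 ROIs with 500
permutations each (bound 0.05 + 3 Monte-Carlo SEs); power uses 100
replicates of a planted 20-edge component at per-edge |t| ≈ 6 and n =
200; mediation calibration uses 500 datasets of n = 1,000 with 1,000
bootstrap draws each (the pipeline default remains 10,000 draws — the
reduced count is for replication across many datasets, and coverage is
insensitive to it at this n). Fisher-z 3-sigma bands (±3/sqrt(n−3))
define the calibration tolerances for the generator's correlation
targets.

## Known limitations

* Only linear age effects; no robust or penalized variants.
* Component size is edge count; intensity weighting and threshold-free
  enhancement are out of scope.
* The mediation module fits observed-variable path models only — no
  latent variables, fit indices, serial or moderated mediation.
* Absolute-value connectomes fold anticorrelation changes into apparent
  positive-FC changes; the signed mode exists precisely to check
  sensitivity to that choice.
* The bootstrap p-value is a resampling-sign summary, not an exact test;
  with moderate effects it agrees with the Sobel normal-theory test in
  the large majority of simulated datasets (asserted ≥ 90% in the
  tests), but neither is privileged.
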