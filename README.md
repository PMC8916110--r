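# agefc

Statistical analysis of age-related change in resting-state functional
connectomes, built for population-scale imaging cohorts of middle-aged to
older adults. The package answers the questions such studies pose: does
mean functional connectivity (FC) decline with age, globally and within
resting-state networks; which connected subnetworks of edges carry that
decline; and is the decline mediated by structural brain damage (cortical
thinning, diffuse white-matter injury), or does it in turn mediate the
age-related decline in executive function?

## What it computes

**Connectome construction and thresholding.** Per subject, the connectome
is the ROI x ROI matrix of Pearson correlations between regional BOLD time
series (absolute values by default, signed as a control). Matrices are
proportionally thresholded: the strongest `k = round(p * E)` of the
`E = n(n-1)/2` edges are retained (default p = 0.5; 0.7 / 0.3 / 0.1 as
controls), and mean FC is the average of the retained edges — globally,
within / between networks, and per network. The package also computes PSMD
(peak width of skeletonized mean diffusivity, the 95th minus 5th
percentile of skeleton MD values) and the Trail Making Test B/A ratio.

**Regression.** Univariate fits and multiple linear regressions of FC on
age, cortical thickness and PSMD, adjusted for sex and years of education,
with unstandardized and standardized coefficients and a Bonferroni family
threshold (0.05 / 7 = 0.007 for four networks plus three global measures).

**Network-based statistic (NBS).** For each edge, the t statistic of the
age slope across subjects; edges with t beyond the primary threshold
(|t| > 3.2) form a graph whose connected components are the candidate
subnetworks. Family-wise error is controlled by permuting age across
subjects (default 5,000 permutations), recording the maximal component
size of each permutation, and assigning each observed component
`fwe_p = #(null max sizes >= observed size) / n_permutations`.
Freedman-Lane residual permutation is used when covariates are included.

**Mediation.** Parallel-mediator path models estimated by OLS —
`a_j` (exposure -> mediator), `b_j` and `c'` (outcome on exposure and all
mediators jointly), indirect effects `a_j * b_j`, with the exact OLS
identity `c = c' + sum_j a_j b_j` — and non-parametric bootstrap
inference (default 10,000 case resamples; percentile or bias-corrected
CIs).

**Synthetic cohorts.** Because cohort MRI data of this kind are not
public, the package ships a generator that emulates the statistical
structure the analysis assumes: ages 45-74, ~45% female, thickness
declining with age (r = -0.4), PSMD rising with age (r = 0.5), TMT scores
worsening with age, 0.36 mean-FC connectomes, and a planted connected
subnetwork whose edges decline with age partly through a thickness
pathway — with ground truth returned for recovery testing.

## Worked example

```r
library(agefc)

cfg    <- generator_config(n_subjects = 300, n_rois = 100, seed = 2024)
cohort <- generate_cohort(cfg)
gen    <- generate_connectomes(cfg, cohort)

univariate_fit(gen$cohort, "cortical_thickness", "age")
#>   outcome   term      beta      se std_beta     t        p      r    r2
#> 1 cortical… age   -0.00517 6.16e-4   -0.437 -8.38 2.05e-15 -0.437 0.191
```

Thickness declines by ~0.005 mm per year with r = -0.44, matching the
generator's calibration target of -0.4 within sampling error.

```r
res <- nbs_test(gen$matrices, gen$cohort$age,
                nbs_config(n_permutations = 1000, seed = 99))
tidy(res)
#>   component  size n_nodes fwe_p
#> 1         1    30      21 0
#> 2         2     1       2 0.981
```

The NBS finds one large age-declining component (30 edges over 21 nodes)
that no permutation matched (fwe_p = 0); a stray single edge is correctly
non-significant.

```r
dat <- gen$cohort
dat$subnet_fc <- subnetwork_mean_fc(gen$matrices,
                                    component_edge_mask(res$components[[1]]))
fit <- bootstrap_mediation(dat,
  mediation_model("age", c("cortical_thickness", "psmd"), "subnet_fc"),
  n_boot = 2000, seed = 7)
tidy(fit)
#>   effect         mediator  estimate std_estimate      se   ci_low  ci_high     p
#> 1 total          <NA>      -1.93e-3      -0.852  7.61e-5 -2.07e-3 -1.78e-3 0
#> 2 direct         <NA>      -1.41e-3      -0.622  4.86e-5 -1.50e-3 -1.32e-3 0
#> 3 indirect       cortical… -4.94e-4      -0.218  6.43e-5 -6.15e-4 -3.64e-4 0
#> 4 indirect       psmd      -2.75e-5      -0.0121 2.75e-5 -8.59e-5  2.17e-5 0.296
#> 5 total_indirect <NA>      -5.21e-4      -0.230  6.98e-5 -6.54e-4 -3.80e-4 0
```

Subnetwork FC falls by ~0.0019 per year of age in total; cortical
thickness carries a significant indirect share (estimate -4.9e-4 against
a generating truth of a x b = -5e-4), while PSMD — which the generator
does not route into FC — is correctly a null mediator. The end-to-end
pipeline (`run_full_pipeline()`, or the `all` subcommand of
`inst/scripts/agefc.R`) chains these stages with a Bonferroni gate
between the regressions and the NBS and writes Table-1/Table-2-style TSV
outputs with a provenance block.

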