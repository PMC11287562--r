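---
title: "Validating 5-year breast-cancer risk models in BRCA1/2 carriers: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validation methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcriskval)
```

# The problem

Multifactorial absolute-risk models for *BRCA1*/*BRCA2* carriers combine
the pathogenic variant (PV), a polygenic risk score (PRS), questionnaire
risk factors (QRFs) and family history (FH) into a short-term absolute
breast-cancer (BC) risk. Prospective validation of such a model in a
clinic-ascertained carrier cohort raises four methodological problems that
this package implements as reusable, separately testable components:

1. deriving follow-up and a fixed-horizon binary outcome under a strict
   censoring hierarchy and eligibility rules;
2. computing individual absolute risks over the landmarked window from a
   transparent hazard model;
3. correcting for outcome-dependent subcohort inclusion with
   inverse-probability weights;
4. estimating weighted calibration, discrimination and risk-stratification
   statistics with defensible confidence intervals.

A fifth component, the synthetic-cohort generator, exists so that each of
the four can be exercised under a known truth.

# The risk model

The individual cause-specific BC hazard is multiplicative on an age-banded
baseline (5-year bands from 20 to 80 by default):

$$\lambda_i(t) = \lambda_0(t)\,
  e^{\beta_{gene}(t) + z_i \beta_{PRS}(t) + \sum_f \beta_{QRF}(f, x_{if})
     + n_i \beta_{FH}}$$

where $z_i$ is the standardized PRS (SD units; raw scores are standardized
with the published constants, mean $-0.424$ and SD $0.611$), $x_{if}$ are
QRF category levels, and $n_i$ counts affected first-degree relatives. The
gene and PRS log relative hazards are age-dependent (both decline with
age); QRF and FH effects are age-constant. Non-BC mortality $\mu(t)$ is the
only competing event inside the predictor; mastectomy and RRSO are treated
as censoring, matching how the cohort is followed.

The absolute risk between ages $s$ and $e$, conditional on being alive and
BC-free at $s$, is the competing-risk cumulative incidence

$$P_i(s,e) = \int_s^e \lambda_i(u)\,
  e^{-\int_s^u \lambda_i(v)+\mu(v)\,dv}\,du,$$

evaluated in closed form on the piecewise-constant grid: per band,
$S \cdot \frac{\lambda}{\lambda+\mu}\left(1 - e^{-(\lambda+\mu)L}\right)$
with $S$ the survival accumulated over earlier bands and $L$ the band
overlap with the window. This form makes the generator's truth the exact
expectation of simulated outcomes, which is what enables
calibration-by-construction testing; it deliberately does not attempt to
reproduce any pedigree-likelihood machinery, whose internal treatment of
competing mortality and landmark conditioning is not published in a form
that could be reimplemented faithfully.

Predictions default to the window $[b+1, b+6)$ for entry age $b$ — a
one-year landmark excludes prevalent undiagnosed disease — and are clamped
at age 80. Women leaving follow-up before the landmark are excluded rather
than scored.

Tunable parameters, with defaults: `landmark` (1 year), `horizon` (5
years), age grid and per-band rates of the `hazard_model` (per-year
hazards), `max_age` (80). The bundled `default_hazard_model()` uses
population-scale baseline incidence and mortality and carrier-scale
relative hazards chosen so cumulative risk to age 80 is roughly 70% for
both genes, with earlier onset for *BRCA1*; the PRS effect declines from
about 1.65 to 1.25 per SD across the age range; three QRFs (parity, MHT
use, BMI category) have modest effects (0.92–1.30); FH contributes 1.8 per
affected first-degree relative. These are illustrative of the carrier
literature, not fitted estimates.

# Censoring, eligibility, outcome

Follow-up ends at the earliest of: BC diagnosis (invasive or DCIS),
bilateral risk-reducing mastectomy, last follow-up, death, baseline + 6
years, age 80. Ties are resolved in exactly that order, so a BC diagnosis
coinciding with another endpoint counts as an event; ties have measure zero
in continuous time, so this choice only matters for discretized inputs.
Eligibility requires entry age < 74, no cancer or mastectomy before
baseline, more than one year of follow-up (applied after deriving
follow-up, which is the stricter reading since censoring can only shorten
it) and complete PRS/QRF data; the exclusion log records the first failing
rule per woman in that order. Two sensitivity switches mirror common
analyses: `dcis_policy = "censor"` treats a DCIS diagnosis as censoring at
the diagnosis age, and `censor_at_rrso = TRUE` adds RRSO as a censoring
endpoint.

# Sampling weights

Inclusion probabilities are fitted by country (countries below
`min_group_size`, default 200, are pooled — the default mirrors the pooling
of small countries in multi-national carrier cohorts, whose exact threshold
is never published) with exactly six terms: intercept, baseline age,
follow-up duration (exit minus baseline, i.e. the observable post-censoring
quantity), incident BC status, BC-by-age and BC-by-follow-up. Weights are
inverse fitted probabilities, floored at `floor` (default 0.01, capping
weights at 100) to bound variance; the floor is configurable and the
fitted probabilities are reported alongside the weights so uncapped
analyses can be reproduced. Single-class or separated groups raise errors
naming the group rather than returning degenerate weights. Weights enter
the discrimination metrics as well as calibration (whether the original
analyses weighted AUC and C is not documented; here both are weight-aware,
and unit weights reproduce the unweighted forms exactly).

# Validation statistics

**E/O.** $E=\sum_i w_i p_i$, $O=\sum_i w_i y_i$. For women censored inside
the prediction window, $p_i$ is the risk truncated at the censoring age
(`predict_to_censoring`): without truncation $E$ counts risk over exposure
the woman never had and E/O is biased upward by roughly the censored
fraction of person-time. The CI is log-normal with a weight-aware
Poisson-type standard error $\sqrt{\sum w_i^2 y_i}/O$ on the log scale —
the CI method used in the original analyses is not documented, so this
choice is recorded in the report metadata.

**Calibration slope.** Logistic regression of the outcome on
$\mathrm{logit}(p_i)$, Wald CI with a robust (sandwich) standard error.
Predictions are clipped to $[10^{-6}, 1-10^{-6}]$ before the logit. Which
predictions to regress on is a genuinely open design point under
censoring, and the package resolves it as follows: using censoring-truncated
predictions as the covariate biases the slope upward (women censored early
are assigned small predictions and are simultaneously forced to be
non-cases), while ignoring censoring attenuates it (the observable outcome
is "case and not censored first", so $E[y\mid p] \approx c\,p$ with
$c<1$). The report therefore keeps the full-horizon $\mathrm{logit}(p_i)$
as covariate and absorbs each woman's known censoring exposure as a fixed
offset, $\mathrm{logit}(p_i^{trunc}) - \mathrm{logit}(p_i^{full})$; under
a perfectly calibrated model the slope is then centred at 1, which the
acceptance suite checks by simulation.

**Quintile calibration.** Bins at weighted quantiles (type-1 inverse
weighted ECDF) of the predicted risk; observations tied at an edge go to
the lower bin, and duplicated edges are collapsed with a warning. Per-bin
E sums to overall E exactly (a partition). Weighted rather than unweighted
quantiles are the default — the alternative is switchable by passing unit
weights — because the weighted ECDF is what the weighted E/O integrates
over.

**AUC.** Weighted Mann-Whitney form (ties one half) against the binary
landmarked outcome, computed on full-horizon predictions by default; CI by
stratified bootstrap (cases and non-cases resampled separately, percentile
interval, default 2000 replicates). Truncated predictions are available as
a flagged alternative, but they leak follow-up duration into the score and
inflate the AUC, which is why Harrell's C is reported alongside.

**Harrell's C.** Pairwise concordance over time from the landmark: a pair
is comparable iff the strictly earlier time is an event; the pair is
concordant iff that member has the higher prediction; prediction ties count
one half; tied times are not comparable; pair weight is the product of
member weights. The implementation is an $O(n\log n)$ Fenwick-tree count
(compiled), verified in the tests against an $O(n^2)$ brute-force
enumeration at $10^{-12}$ and against `survival::concordance` on tie-free
data; the CI is a grouped (delete-a-group) jackknife, default 100 groups.
Note that no inequality between C and AUC is asserted anywhere: none holds
in general, and each statistic is checked against its own oracle.

**Stratification.** Weighted proportions below the 1.65%, 3% and 5%
5-year-risk counselling thresholds, the NPV among women below each
threshold, breakdowns by entry-age group (<30, 30–50, ≥50) and gene, and
the weighted fraction of incident cases in the top predicted-risk half
(ties resolved by strict comparison against the weighted median).

# The synthetic cohort

`simulate_cohort()` emulates a clinic-ascertained carrier cohort:

- entry ages $20 + 50\,\mathrm{Beta}(1.8, 2.6)$ (median around 40, the
  typical counselling age range), 54% *BRCA1*, six country labels with
  fixed frequencies;
- raw PRS normal with the published mean/SD so the standardized PRS is
  standard normal; QRF levels multinomial; FH score Poisson (population
  mean 0.3 affected first-degree relatives);
- family-history-enriched ascertainment: candidate profiles are accepted
  with probability $\mathrm{logit}^{-1}(-0.4 + 0.9\,n_{FH})$, reflecting
  referral "primarily on the basis of family history" — the strength is a
  free simulation parameter, not an estimate, since clinic ascertainment
  is never quantified;
- latent BC ages by inverse-transform sampling from the woman's
  piecewise-constant hazard (full truth: gene, PRS, QRFs and FH all
  active); death from the model's age-banded competing mortality, so the
  predictor's competing-risk treatment is the generator's exact inverse;
  mastectomy (0.015/yr), RRSO (0.025/yr) and dropout (0.02/yr) as
  independent constant-rate censoring; administrative follow-up capped at
  8 years; 12% of incident BCs flagged DCIS;
- optional outcome-dependent subcohort inclusion from a configurable
  six-coefficient logistic truth, for exercising the weighting scheme.

Every draw for woman $i$ comes from her own substream, seeded by a fixed
function of `(seed, i)` whose multiplier is coprime with the modulus
$2^{31}-1$; distinct women therefore never share a stream and changing the
cohort size leaves earlier women's records bit-identical. Ages are
continuous years; all intervals are half-open $[a, b)$.

What the generator does **not** emulate: pedigree structure (FH is a
scalar count, not a pedigree), genotypes at the 313 PRS SNPs, mammographic
density, birth-cohort trends in incidence, country-specific registry
behaviour, and dependence between censoring and risk factors (censoring is
independent given covariates). Passing tests therefore demonstrate that
the pipeline's statistics do what they claim under a correctly specified
multiplicative world — they cannot demonstrate that any particular risk
model is correct for real carriers, where ascertainment, missingness and
censoring are all messier.

# Numerical choices and degenerate inputs

- Closed-form band integration throughout; no quadrature in the package
  (the tests compare against Simpson quadrature at step 0.001 y).
- Bands with $\lambda + \mu = 0$ contribute zero risk, avoiding 0/0.
- Risk windows are clamped at `max_age`; an `end_age` beyond it raises an
  error unless clamping is requested explicitly.
- Slope: clipping at $10^{-6}$; constant predictions, or inputs without
  both a case and a non-case, raise errors.
- E/O with $O=0$ is an error (undefined), as is an AUC or C on
  single-class input or without comparable pairs; empty below-threshold
  strata report NPV as `NA`.
- Inclusion-model fits convert the "fitted probabilities numerically 0 or
  1" warning into an error naming the group (perfect separation should
  halt a weighting analysis, not produce infinite weights).
- Bootstrap and jackknife sizes are configuration, not constants: the
  report records them in its metadata. The test suite runs its end-to-end
  checks at cohorts of 4,000–50,000 women with 200–2,000 resamples, sizes
  at which the Monte-Carlo error of each check is small relative to the
  tolerance being asserted.

# Known limitations

- The offset-based calibration slope assumes the censoring-truncated
  risk is a faithful summary of each woman's observation window; with
  informative censoring it, like every method here, would be biased.
- The E/O standard error treats expected counts as fixed, ignoring the
  (deterministic, given covariates) predictions' dependence on the fitted
  weight model; with strongly variable weights the interval is
  approximate.
- Harrell's C treats tied times as non-comparable; implementations that
  partially credit tied times will differ in heavily discretized data.
- The null (age-only) variant predicts from the population-scale baseline;
  it is a floor for discrimination comparisons, not a clinically
  meaningful carrier model.
- Small-sample behaviour of the jackknife C interval (fewer than ~10
  events per group) is untested territory; prefer more groups only when
  events are plentiful.
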