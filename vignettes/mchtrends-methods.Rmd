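---
title: "Methods: two-stage small-area estimation of MCH trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage small-area estimation of MCH trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mchtrends)
```

## The estimation problem

Household surveys (DHS, MICS, MIS and similar programs) measure maternal and
child health indicators — immunization coverage, antenatal care, insecticide-
treated net ownership, under-5 mortality — but only in scattered years, and a
state-level sample is far smaller than the national one. The goal is a
complete annual series 2000–2013 for each of 37 subnational units (36 states
plus the FCT, grouped into 6 geopolitical zones), with honest uncertainty,
from perhaps five to seven unevenly spaced survey estimates per state.

`mchtrends` implements this as a two-stage model on the logit scale, preceded
by explicit survey-harmonization rules and followed by draw-level
aggregation.

## Harmonization of survey estimates

Microdata are collapsed with their sampling weights into one estimate per
state and event year: `p = Σ w·o / Σ w`, with the design-weighted
ratio-estimator variance `Σ w²(o − p)² / (Σ w)²`. The microdata interface
carries weights but not stratum/PSU identifiers, so this is the variance
estimator throughout; over repeated simple-random surveys it averages to the
binomial variance (a calibration the test suite checks to 5%).

Three rules make estimates comparable across instruments:

* **Event-year attribution.** ANC1, ANC4, skilled birth attendance and
  in-facility delivery are attributed to the *birth year* of the child, not
  the survey year; full-birth-history sources contribute births up to six
  years before the survey, most-recent-birth sources only two.
* **Card-only crosswalk.** Surveys that ascertain vaccination only from
  child health cards understate coverage. Sources recording both bases give
  paired estimates; the unweighted mean of `total / card_only` ratios is
  applied multiplicatively (variance scaled by the squared ratio). A single
  pooled ratio per vaccine is used; heterogeneity by zone is not modelled.
* **Pre-policy imputation.** Malaria interventions are pinned at 0.01%
  coverage (p = 1e-4) before their adoption year (ITN ownership and ITN/IRS
  before 2000, IPTp2 before 2001, ACTs before 2004; IRS supports per-state
  roll-out years). The pseudo-observations carry variance 1e-8: pre-policy
  coverage is treated as known-near-zero, and a tiny but non-zero noise term
  pins the smoother there without a singular system.

Proportions are clamped into [0.001, 0.999] before the logit transform
(pseudo-observations are deliberately below the floor and exempt); the
variance travels by the delta method, `var(y) = var(p)/(p(1−p))²`.
Judgement-based exclusions are an explicit configuration table, never
auto-detected — automating "implausibility" would invent a rule — and
excluded rows never enter any fit.

## Stage 1: the mixed-effects prior

On logit-transformed estimates the prior mean function is

$$y_{s,t} = \alpha + \mathbf{T}(\beta + b_s + b_z) + u_s + u_z +
\varepsilon_{s,t},$$

with time **T** entering either linearly (centered at the grid midpoint) or
through the two bases of a natural cubic spline with a single interior knot;
$u_s, u_z$ are IID mean-zero random intercepts for state and zone and
$b_s, b_z$ IID random slopes on the time bases. Knot placement is the median
observed year, boundary knots at the observed range, so the spline is linear
beyond the data — a deliberately tame extrapolation rule for grid edges.

Candidate models form a lattice: a slope is only allowed alongside its
matching intercept, giving 7 random structures; crossed with the 2 bases
that is 14 candidates, from plain OLS to the fully loaded spline model.
Mixed models are fitted by REML (`lme4`), the no-random-terms member by OLS.
Observations are equally weighted at this stage; the sampling variance of
each estimate enters only the stage-2 likelihood.

Selection is by predictive validity: 20% of state-year observations held
out at random, 100 times by default, scoring logit-scale RMSE; the holdout
unit is the individual observation (the description "20% random hold-out
pattern" leaves stratification open, and unstructured sampling is the
simplest faithful reading). Replicates where a specification fails to
converge drop out of its mean with logged counts. Ties break toward fewer
random terms, then the linear basis — parsimony, deterministically.

## Stage 2: Gaussian process regression

Each state's residual trend around the stage-1 mean is smoothed by GP
regression with a Matérn covariance. Defaults: smoothness ν = 3/2
(once-differentiable trends; annual health series are smooth but not
infinitely so), length-scale 5 years, both exposed in `gp_config()`. The
amplitude is self-tuned per indicator as 1.4826 × the median absolute
stage-1 residual — a robust scale estimate of how far the data stray from
the prior — and can be overridden. Observation noise is the delta-method
logit variance of each estimate, independent across observations; no
additional non-sampling error term is added. States are smoothed
independently: cross-state structure enters only through the stage-1 prior.

Conditioning is exact dense Gaussian conditioning; the Cholesky adds
diagonal jitter starting at 1e-10 × amplitude², escalating tenfold to at
most 1e-6 × amplitude² before failing, so results are bit-reproducible.
Uncertainty is carried by 1,000 seeded posterior draws per state; the median
is the mean of the 500th/501st ordered draws and the 95% interval the
25th/975th, all back-transformed to the proportion scale (a general quantile
rule is available for other draw counts).

## Aggregation, composite, reporting

National series are built *at the draw level*: per year and draw, the
population-weighted mean of state proportions (weights renormalized within
year). Aggregation happens on the proportion scale — the estimand is a
weighted mean of proportions, and averaging logits would bias it — and the
result is re-logit-transformed for storage so it composes with the draw
summaries. Coverage indicators weight by total population, the mortality
series by live births, the natural denominator for a birth-cohort
probability; the basis is selectable. The population table is a required
user input (synthetic by default): no particular demographic series is
bundled.

The composite coverage index is the equally weighted (1/11) mean of 11
member indicators — three malaria interventions, four vaccines, ANC4, SBA,
EBF, and "not wasted" (wasting enters as its complement). When member draws
are available the composite is computed per draw so it carries uncertainty;
otherwise from medians.

Reporting helpers compute the benchmarking arithmetic used in headline
statements: extremal state ranges, signed continuum-of-care gaps (ANC1−ANC4,
DPT3−OPV3), and relative declines `100(v₀ − v₁)/v₀`.

## Under-5 mortality stage

Period 5q0 comes from complete birth histories by the synthetic-cohort
method over the standard age segments 0, 1–5, 6–11, 12–23, 24–35, 36–47,
48–59 months. Each segment's death probability is weighted deaths over
weighted *potential* exposure — the fraction of the segment a child would
spend inside the calendar period if it survived it; deaths do not truncate
their own segment's denominator. This actuarial convention keeps each q in
[0,1] and makes the estimator monotone in deaths. Variances combine
per-segment binomial approximations (Kish effective n) on the log-survival
scale. Summary (truncated) birth histories are not supported: their
regression-based conversion is a separate method in its own right.

State series are smoothed with a one-knot natural spline mixed model with
IID state and survey-source intercepts; source intercepts absorb systematic
survey offsets and are marginalized out of predictions. Uncertainty uses
1,000 parametric-bootstrap draws (fixed effects from their estimated
sampling distribution, state intercepts from their conditional
distribution) rather than GPR — the mortality stage is a spline mixed model,
not a GP. Finally the state series are scaled so that their births-weighted
national aggregate reproduces an external reference series; the factor is
year-specific and multiplicative on the q5 scale, the minimal rule that
makes the aggregate match exactly while preserving between-state ratios
within each year. Whether a single constant factor would suffice is
underdetermined; the year-specific rule nests the constant one.

## The synthetic-data generator

`simulate_truth()` is the generative twin of the stage-1 model: zone and
state intercepts/slopes drawn from mean-zero normals, truth =
invlogit(α + T(β + b_s + b_z) + u_s + u_z), realized effects stored for
recovery tests. `simulate_surveys()` adds binomial sampling with a design
effect (successes at n/deff); `simulate_birth_histories()` uses
piecewise-constant hazards over the standard age segments with censoring at
the survey date; `simulate_population()` gives log-normal state sizes with
constant growth.

Defaults describe the conditions the pipeline is meant for: 37 states in 6
zones, grid 2000–2013, a rising coverage trend (about 0.40 at the midpoint),
intercept SDs of 0.5 (state) and 0.3 (zone) on the logit scale, small slope
SDs, six irregular survey years (2003, 2007, 2008, 2010, 2011, 2013),
n = 400 per state per survey, design effect 1.5 — DHS-scale state samples
and sparsity. The default hazard schedule implies 5q0 ≈ 130 per 1,000.

What the generator does *not* emulate: nonresponse and recall-bias
mechanisms, cluster-level correlation beyond a scalar design effect,
instrument effects other than a constant offset, or migration between
states. Passing calibration tests on this generator shows the pipeline is
statistically sound under its own assumptions; it does not certify any
particular real-world series.

## Problem sizes and numerical choices

The validation suite uses these simulation sizes, chosen to give stable
Monte-Carlo checks: 200 replicates for interval calibration (37 states × 14
years each; pooled 95%-interval coverage is required to land in 90–98%) and
for fixed-effect recovery (bias within 2 Monte-Carlo SEs); 50 independent
selection runs with 10 hold-out replicates each for the curvature
experiment (spline family selected in ≥ 80%); 50,000 children for the
constant-hazard 5q0 closed-form check (agreement within 3 SEs). Cross-
validation inside the selection experiment uses 10 replicates rather than
the pipeline default of 100 because selection under strong curvature is
insensitive to the replicate count while fit cost scales linearly in it.

Degenerate inputs are handled explicitly: empty tabulation groups emit no
estimate; all-0/all-1 cells are clamped and given a binomial-fallback
variance; single-level grouping factors drop the corresponding random terms
with a warning; a GP with zero amplitude degenerates to the prior mean;
`summarize_draws()` refuses the canonical ordered-draw rule unless exactly
1,000 draws are present.

## Known limitations

* The 14-model lattice is one defensible enumeration of "up to 14" — the
  slope-requires-intercept rule is a design choice, not the only reading.
* GP hyperparameters are fixed defaults, not learned by marginal
  likelihood; they are exposed in configuration instead.
* In-sample RMSE is not exactly monotone across nested specifications under
  REML (shrinkage can raise it by ~1e-5); tests carry a matching slack.
* No spatial adjacency priors, no covariates, no wealth-quintile equity
  decompositions; summary birth histories and maternal mortality are out of
  scope.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config()
sim <- simulate_truth(cfg, seed = 3)
est <- simulate_surveys(sim$truth, cfg, seed = 4)

trends <- estimate_trends(est, seed = 5)          # CV + GPR, 1,000 draws
pop <- population_weights(simulate_population(cfg, seed = 6))
national <- summarize_draws(national_aggregate(trends$draws, pop))
```
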