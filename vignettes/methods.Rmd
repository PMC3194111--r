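---
title: "Methods: the radon-smoking risk chain and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the radon-smoking risk chain and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Residential radon causes lung cancer, and its unit risk per working level
month (WLM) is several times larger for ever-smokers than for
never-smokers. Because indoor radon depends on geology, climate and house
construction, while smoking and housing depend on demographics, the two
exposures are correlated through where and how people live. `radonrisk`
implements a cumulative risk chain that carries these correlations
explicitly: three regressions — radon concentration, house type,
ever-smoking — feed a deterministic lifetime-risk algorithm evaluated per
demographic bin (county × age × sex × race × poverty cell) and aggregated
population-weighted.

This vignette records the modelling assumptions, the tunable parameters,
the numerical choices, what the synthetic-data generators do and do not
emulate, and the known limitations. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

# The three models

## Radon concentration

A log-linear mixed model of annual-average living-area concentration
(pCi/L) with fixed effects for Census region (reference Midwest),
geological radon potential class (Low/Medium/High, reference Low), two
county-level meteorological covariates — annual heating-infiltration
degree-days and average diurnal temperature swing — and a five-category
house type (reference: single detached with basement). Random intercepts
follow the survey nesting: houses within census tracts (SSUs) within
counties (PSUs) within states.

Predictions exponentiate the fixed-effect sum plus the county's state (and,
where available, county) residuals. This is a **geometric-scale**
(median-type) prediction: no +σ²/2 lognormal retransformation is applied,
because the chain is defined by summing fixed effects and using the result
directly as the concentration. `predict_concentration(...,
mean_correction = TRUE)` provides the arithmetic-mean convention for
sensitivity analysis; at the packaged variance components the correction
would multiply all concentrations by a constant `exp(0.625)`, so it changes
levels, not patterns.

Unsampled states and counties carry zero residuals — prediction falls back
to fixed effects. Raw survey measurements can be non-positive (instrument
noise); `preprocess_concentration()` clamps them to a configurable floor
(default 0.1 pCi/L, about the minimal outdoor concentration) before
log-scale fitting. The published scaling procedure for negative readings is
not reproducible from available detail; the floor clamp is this package's
documented replacement.

`fit_radon_model()` delegates estimation to REML via `lme4::lmer`. Reported
standard errors are Kenward–Roger small-sample adjusted (`pbkrtest`): with
~44 states and ~125 counties, naive model-based SEs of cluster-level
covariates are mildly anticonservative, and Kenward–Roger is the standard
correction. Set `adjust_se = FALSE` for the naive SEs.

The model's level-specific variance components are not published; the
packaged values (state 0.05, PSU 0.10, SSU 0.10, residual 1.00, log scale)
are **assumptions**, chosen so that most variation is within-tract, as is
typical for indoor radon; they matter only for the synthetic generator and
for the optional mean correction, never for fixed-effect prediction.

## House type

A single-level multinomial logistic model over five mutually exclusive
types — detached with basement (reference), attached, detached with crawl
space, detached with slab, other detached — on poverty status, sex, race,
Census region (reference South) and age group (reference 45–54). The
outcome is a household characteristic shared by all residents, so no
multilevel structure is possible; clustering of individuals within
households is not modelled.

Covariate effects are published as odds ratios to two decimals and stored
as their natural logs; intercepts are published on the log-odds scale and
stored as-is. Consequently any refit comparison inherits up to ±0.005/OR of
rounding on the log scale, which is material for small ORs (e.g. 0.03–0.04
for some region effects) and is allowed for in test tolerances.

Two vocabulary conventions: the Pacific-Islander race level exists in the
smoking model but not here, and maps to `"other"` for housing prediction
(configurable via `islander_map`; "other" is the closest residual
category). The under-18 age coefficients are retained for completeness but
never used by the risk engine, which is adults-only.

`fit_housing_model()` is maximum likelihood via `nnet::multinom`
(`reltol = 1e-12` so saturated toy problems match closed-form
contingency-table log-odds). Covariates constant in the data are dropped
and reported as zero. Cells with no events produce infinite MLEs (complete
separation); recovery checks exclude estimates with |log-odds| > 8, the
standard handling.

## Ever-smoking

A multilevel logistic model of ever-smoking (current or former — the
stratum that modifies the radon unit risk) on sex, age group, poverty,
race, race×male interactions, state cigarette excise tax, previous state
smoking prevalence (2003), an indoor-smoking-restriction flag, and two
CBSA flags; random effects are a state intercept and a state-level random
slope for Black race (jointly normal with covariance), a CBSA intercept,
and a household intercept.

Prediction for a bin sums the fixed effects and the state/CBSA residuals,
plus the state's Black-slope residual for Black bins. Two deliberate
conventions:

* The **household random effect is omitted with no marginalisation
  correction**. The resulting probability is conditional on an average
  household; with household variance 0.521 the population-average
  (marginal) probability is measurably closer to 0.5.
  `smoking_attenuation_diagnostic()` quantifies the gap by Monte Carlo
  rather than silently correcting it, because the chain is defined as the
  inverse logit of the summed effects.
* The `income_not_reported` coefficient applies only to records explicitly
  so flagged — never to Census-derived bins, whose poverty cross-tabs have
  no such level.

The published table reports the excise-tax coefficient as +0.08 (OR 1.08)
while the accompanying text describes a negative association; the package
implements the table as printed and flags the discrepancy here. The tax
and previous-prevalence covariates are applied to values "as scaled" in
the source table (tax in its published units, prevalence in percentage
points); centering is not documented in the source, so coefficients are
applied to raw supplied values.

`fit_smoking_model()` uses the Laplace approximation via
`glmmTMB` — the only feasible approximation class with three random-effect
factors. A known property of Laplace for binary responses in very small
clusters applies directly here: with households of two persons, the
household variance (and with it the small state/slope covariance) is
shrunk toward zero by roughly half, while fixed effects and the state/CBSA
variances are much less affected. This is documented rather than patched;
the corresponding recovery check in the acceptance suite exposes it and
fails at the published household variance, by design of the tolerance.
A boundary variance estimate (true state variance is only 0.005) can make
the optimizer report "singular convergence"; the fit is kept with a
warning unless coefficients are non-finite.

# The risk algorithm

With exposure constants `wl_per_pci = 0.004` WL/(pCi/L) (embodying a 40%
progeny equilibrium fraction), `wlm_per_wl_year = 51.6`,
`occupancy_fraction = 0.70`, the exposure rate is their exact product,
0.14448 WLM/yr per pCi/L (quoted conventionally as 0.144). The exposure
duration `D` is not published; the default 75 years is chosen because it
makes the engine reproduce the EPA benchmark — 0.73% lifetime risk at 1.25
pCi/L with the general-population unit risk 0.00054/WLM — to two decimals,
and it is configurable and logged. Unit risks per WLM by sex × ever/never
are packaged in `risk_constants.yaml`; all constants can be overridden via
`load_risk_constants(overrides = ...)`.

Per bin, lifetime risk factorises as

```
R = (Σ_h P(h)·C(h)) × rate × D × [ p·UR(sex, ever) + (1−p)·UR(sex, never) ]
```

which equals the exhaustive enumeration over the ten (house type × smoking
status) combinations exactly, **because** smoking status is assumed
independent of house type within a bin (no differential distribution of
smokers across house types). The test suite asserts the equivalence to
1e-12 over randomized bins. The linear excess-risk formula can exceed 1
for absurd inputs; risks are clipped to [0, 1) with a warning rather than
silently returned. Whether individuals should instead be simulated is a
genuinely open design point; the factorised expectation is exact under the
stated independence assumption and is adopted. A fixed-duration,
constant-concentration approximation is used throughout — no life-table
survival weighting.

Aggregation is a population-weighted mean (weights = bin counts) at
county, state or national level, plus an unweighted across-county summary
(mean/median/sd/range). Zero-population groups are excluded with a
warning. Weighted means are invariant to splitting any bin into identical
halves and bounded by member extremes; both are asserted as properties.

# Synthetic data: what it emulates, what it does not

The generators produce every input the chain needs, each drawn exactly
from the corresponding model's assumed structure, so parameter-recovery
tests have a known truth:

* `generate_geography()`: counties nested in states (regions cycling over
  the four Census regions), CBSAs nested in states, geological class drawn
  Low/Medium/High (0.4/0.4/0.2), meteorology uniform on documented design
  ranges (HDD 0–9000 degree-days/yr, diurnal swing 10–35 degrees), and all
  residuals drawn from the normal distributions implied by the parameter
  bundles' variance components (the state intercept/Black-slope pair drawn
  jointly with the published covariance).
* `generate_census_bins()`: all 168 adult cells per county, counts
  Poisson(`mean_pop` × cell weight) with documented marginal mixes.
* `generate_nrrs_like()` / `generate_ahs_like()` / `generate_cps_like()`:
  measurement and person records simulated exactly from the radon, housing
  and smoking models respectively.

Deliberate simplifications, and therefore the limits of what passing tests
show: covariate mixes are package defaults meant to span the design space,
not U.S. margins; meteorology is uniform rather than population-weighted,
so synthetic concentrations (and hence risks) run higher than the real
national average; the state tobacco covariates are drawn as centered
deviations from national norms (uniform ±0.5 tax units, ±5 prevalence
points) so the published intercept keeps its reference-bin meaning and
synthetic prevalence stays near the survey benchmark; there is no spatial
autocorrelation beyond the nesting; household size is a constant (default
2); and real-survey features — survey weights, nonresponse, measurement
error beyond the lognormal residual — are absent. Recovery of parameters
from these generators validates the estimators and the chain's internal
consistency, not the models' fit to real data.

All generators are seed-deterministic (`set.seed(seed)` internally) and
emit tables every fitter and predictor consumes unmodified.

# Problem sizes and tolerances in the test suite

Recovery tests run at survey-like sizes chosen to finish quickly while
keeping estimator behaviour representative: the radon model at 5,000
houses / 1,000 tracts / 125 counties / 44 states over 20 replicate seeds;
the housing model at n = 50,000 persons; the smoking model at 40 states /
400 CBSAs / 30,000 households × 2 persons. Coverage checks pool all
(coefficient × seed) recovery z-scores and require the fraction inside
±2 SE to reach 0.95, the interval's nominal coverage. Exact identities
(exposure rate, EPA benchmark, odds-ratio round-trips, softmax hand
values) are asserted at printed precision; enumeration equivalence at
1e-12; noiseless-limit fits at 1e-6.

# Known limitations

* Laplace shrinkage of the household variance (above) — the one recovery
  tolerance the estimator class cannot meet at household size 2.
* Housing coefficients inherit two-decimal odds-ratio rounding.
* Concentration predictions are geometric-scale; arithmetic means require
  the optional correction and trustworthy variance components.
* Smoking predictions are conditional (median-household), not marginal.
* No uncertainty propagation through the chain: standard errors are
  reported per model but never combined into risk intervals.
* The exposure duration and occupancy are population constants; real
  occupancy varies by demographics, and lifetime exposure assumes a
  stationary residence.
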