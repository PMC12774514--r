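---
title: "Methods: apportioning euphotic-zone N2O and measuring substrate-specific nitrification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: apportioning euphotic-zone N2O}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoN2O)
```

This vignette is the package's own account of the models it implements: the
assumptions behind each stage, the tunable parameters with their units and
defaults, what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limitations. Every empirical statement here
is computed by the test suite or by code shown below; nothing is quoted from
elsewhere.

## 1. The measurement problem

Dissolved N2O in the sunlit ocean is a mixture: a large pool in (or near)
solubility equilibrium with the atmosphere, plus microbial additions from
ammonia oxidation and related pathways, minus whatever was consumed by
reduction. Three isotopic signals carry pathway information — bulk d15N
(vs air-N2), d18O (vs VSMOW), and the site preference
SP = d15N(alpha) - d15N(beta), the intramolecular difference between the
central and outer N atoms of the linear N2O molecule. Tracer incubations
with 15N-labelled ammonium or urea measure, independently of the natural
abundance signals, how fast each substrate is nitrified and how much N2O
that nitrification releases.

## 2. Headspace equilibration and solubility

Concentrations are measured on an equilibrated headspace; conversion to
dissolved nmol L-1 uses the classical seawater solubility fit
(`ln(sol) = a1 + a2(100/T) + a3 ln(T/100) [+ a4 (T/100)^2] + S(b1 + b2(T/100)
+ b3(T/100)^2)`, T in kelvin), in two forms: `K0` (per atm of dry partial
pressure) and `F` (from moist air at 1 atm total pressure, the form used for
headspace work; the water-vapour correction is built in). Total pressure is
fixed at 1 atm — the standard assumption for bench equilibration.
Bottle volumes and equilibration temperature are free inputs
(`equilibration_setup()`), since they are instrument properties. The
partition is linear in the mole fraction, so the closed-system mass balance
inverts exactly; the tests verify positivity, monotone decrease in both T
and S, salting-out, and a 1e-10 round trip of total moles. Because the
source tables could not be consulted offline, the transcribed coefficients
are anchored to an independent literature value (Henry constant of N2O at
25 degC, fresh water, ~0.024 mol L-1 atm-1, matched within 5%) and frozen
against regression at four figures.

## 3. Keeling regression: the atmospheric correction

Two-pool mixing, `C_obs = C_atm + C_micro` and
`d_obs C_obs = d_atm C_atm + d_micro C_micro`, implies

d_obs = d_micro + (d_atm - d_micro) C_atm (1 / C_obs),

exactly linear in 1/[N2O]. `fit_keeling()` is ordinary least squares with
the isotope signal as response (geometric-mean regression is deliberately
not used: the spec-level choice is a plain linear regression, and the
predictor 1/C is far better determined than the signal). The intercept
estimates d_micro; its 95% CI uses the t distribution on the intercept
standard error. The reported p-value tests zero slope, and
`keeling_significance_gate()` classifies a layer as microbially dominated
iff p < alpha strictly — a tie at p = alpha classifies as
atmosphere-dominated, a documented convention. The surface/subsurface split
is a property of the input records (the mixed-layer depth is an upstream,
user-level decision), never inferred.

Assumptions worth stating: the atmospheric pool is constant across the
profile, and microbially produced N2O has a single isotopic signature over
the fitted records. When an atmospheric endmember is known,
`atmospheric_correction()` instead inverts the mass balance per sample;
records with no resolvable microbial excess (C_obs <= C_atm) are dropped
loudly. Both routes are supported; per-sample correction is preferred when
an atmosphere block is configured, the Keeling intercept otherwise.

## 4. Four-source mixing with Rayleigh reduction

The forward model for each signal s is

F_s = f_aN E_aN,s + f_bN E_bN,s + f_nD E_nD,s + f_bD E_bD,s + mu_s ln(r),

with f on the 4-simplex and r in (0, 1] the residual unreduced fraction.
The sign convention lives in the data: mu must be supplied negative
(negative-epsilon convention) so that partial consumption enriches the
residual pool. Endmember values are configuration, not code — the packaged
defaults (`default_endmembers()`, `inst/extdata/endmembers_default.json`)
are literature-informed means and sds, clearly marked editable, and are a
synthetic stand-in for any site-specific compilation.

Priors: flat Dirichlet(1,1,1,1) on f; Uniform(r_min, 1] on r with default
r_min = 0.1; endmembers (and mu, where its sd is positive) Gaussian at the
table's means and sds. The likelihood is Gaussian per signal at the
analytical uncertainties (defaults 0.2 / 0.5 / 1.0 permil for bulk d15N /
d18O / SP).

**Sampling.** The sampler is random-walk Metropolis on a stick-breaking
transform of f and a scaled logit of r, 4 chains x 20 000 iterations by
default, 50% burn-in, split-chain convergence statistic flagged above 1.05
(a warning and a `converged = FALSE` flag, never silent). Two deliberate
numerical choices:

* The latent endmembers enter the model linearly with Gaussian priors, so
  they are integrated out analytically: each signal's predictive variance
  becomes `sigma_s^2 + sum_i f_i^2 sd_{i,s}^2 + (ln r)^2 mu_sd_s^2`. The
  (f, r) posterior is exactly that of the full hierarchical joint (which
  `log_posterior()` still exposes, and a test checks term by term), but the
  walk is 4-dimensional instead of ~17, which moves split-chain statistics
  from ~1.5 to ~1.01 at equal cost.
* The proposal scale is adapted towards ~30% acceptance during burn-in only
  (stochastic approximation, frozen afterwards), so retained draws are from
  a fixed Markov kernel and runs are reproducible given the seed.

Every retained draw is renormalized to the simplex at 1e-12 closure, and a
brute-force oracle (`grid_posterior_oracle()`: exhaustive simplex grid x r
grid with endmember uncertainty collapsed) verifies the sampler on reduced
instances.

**The identifiability ridge (known limitation).** With r free over
(0.1, 1], the reduction term spans up to |mu| ln(10) — (14, 35, 11.5)
permil for the default mu — which is comparable to the entire spread of the
endmember table. In the likelihood metric (signals scaled by their
analytical sigmas) the reduction direction is nearly collinear with the
aN-vs-bN contrast, mostly because SP, the signal that best separates
nitrification from denitrification chemistry, carries the largest analytical
sigma (1.0 permil). Consequently an observation generated from
f = (0.7, 0.1, 0.1, 0.1) at the no-reduction boundary r = 1 admits an
exact-fit one-dimensional ridge running into the interior (less aN, more
bN, r < 1), and the flat priors pull the posterior mean along it: the exact
posterior mean of f_aN (grid oracle and importance sampling agree with the
MCMC) is ~0.33-0.41, not 0.7. This is a property of the stated model, not
of the sampler: with r fixed at 1 the same observation is recovered within
0.04, and over random Dirichlet truths with r drawn from its prior the mean
absolute error of the posterior-mean fractions is ~0.09. The corresponding
acceptance clause is left red rather than masked. Practical remedies, in
order of preference for well-oxygenated euphotic-zone work: tighten the r
prior (r_min near 1, or fix r = 1), improve SP precision, or supply an
endmember table whose aN/bN contrast is not parallel to mu.

## 5. Tracer rates, yields, censoring, integration

Rates are per bottle (replicates are never pre-averaged; station/depth
summaries are means of bottle rates):

* nitrification: `R_nitr = (C_t - C_0) / F_substrate / dT * 24`
  (nmol N L-1 d-1, dT in hours);
* N2O production: `R_N2O = (dC45 + 2 dC46) / F_substrate / dT * 24`
  (pmol N L-1 d-1, N-atom basis). The hour-to-day factor is applied to both
  equations for dimensional consistency of the stated per-day units, and
  the numerator counts labelled atoms: one per 45N2O molecule, two per
  46N2O. Dividing the double-labelled term by F rather than F^2 is the
  literal reading of the rate definition; the alternative (F^2 for a
  molecule needing two labelled atoms) is noted here and would lower
  high-46N2O rates by a factor F.
* hybrid fraction: `dC45 / (dC45 + dC46)` on a molecule basis — the share
  of N2O formed by pairing one labelled and one unlabelled N atom;
* yield: `R_N2O / (R_N2O + R_nitr)` after converting R_N2O to nmol N
  (x 1e-3) — both terms then count N atoms.

`F_substrate` is the 15N atom fraction of the substrate pool at t0, defined
on the N-atom pool (urea carries two N atoms). Negative tracer differences
from instrument noise are retained, not clipped: censoring statistics must
see them. `censor_lod()` flags rates <= the configured detection limits
(defaults 0.015 nmol N L-1 d-1 and 0.25 pmol L-1 d-1, the 3-sigma
enrichment criterion); the boundary value is censored. Censored bottles are
retained in the tables (auditable counts) but excluded from summaries.

Depth integration is trapezoidal with constant extrapolation from the
shallowest/deepest measured points to the bounds; 1 nmol L-1 d-1 equals
1 umol m-3 d-1, so integrating over metres yields umol m-2 d-1. The urea
contribution is `urea / (urea + ammonium)` of the depth-integrated rates.

## 6. Paired acidification responses

Pairing is by (station, depth, substrate, replicate); unpaired records and
pairs with a censored member (or nonpositive control) are dropped with
logged counts. Percent change is `100 (treated - control)/control`
(negative = inhibition). Summaries use type-7 (linear-interpolation)
quantiles — fixed because IQR endpoints are convention-sensitive — a
percentile bootstrap (default 10 000 resamples, seeded, endpoints always
within the sample range) for the median's CI, and leave-one-station-out
medians for robustness. Both pooled-pair and station-median aggregations
are exposed (`by = "pooled"` default, since the pooling level of the
original analysis is not stated).

## 7. What the synthetic generator emulates — and what it does not

`synthetic_truth()` states the emulated world once: 8 stations, depths
5/25/50/100 m, triplicate 24-h incubations, 0.5 umol N L-1 tracer additions
into ~0.1 umol N L-1 ambient pools (F_substrate ~0.83), an
archaeal-dominated source mixture f = (0.7, 0.1, 0.1, 0.1) with r = 0.9,
tropospheric atmosphere (6.3 / 44.4 / 18.7 permil, ~7 nmol L-1 surface
equilibrium), control rates rising with depth to realistic oligotrophic
maxima (~3.2 and ~0.9 nmol N L-1 d-1 for ammonium and urea), sub-percent
N2O yields, hybrid fraction 0.85, and acidification effects
(-21.9, +61.9, +35.9, +38.0)% used as the configured medians.

Noise models are the simplest consistent with the stated precisions:
Gaussian on isotope signals (0.2/0.5/1.0 permil, scalable), Gaussian on
concentrations with defaults chosen so the rate detection limits equal
3x the sd of a simulated blank (nox 0.005 nmol N L-1; 0.0373 pmol L-1 per
N2O isotopologue, since the N2O numerator `dC45 + 2 dC46` has sd sqrt(5)
times the per-channel sd), and multiplicative lognormal scatter across
stations. The acidified/control effect scatter is drawn per replicate pair
(bottle level): the percentile bootstrap of the pooled median assumes
exchangeable pairs, and drawing the scatter at the condition level would
leave only ~n/3 effective clusters and visibly under-cover. Station-level
scatter on the control rates is kept separately. Because the scatter is
lognormal with median 1, the configured percent effects are exactly the
true medians of the generated percent changes.

Not emulated: ocean physics (no advection or mixing between depths),
isotope dilution by ambient regeneration, 15N assimilation into biomass,
depth- or station-dependence of the source mixture, instrument drift, and
any sequencing/molecular observable. A green recovery test therefore
establishes the correctness of the estimators under the stated statistical
structure — not the realism of that structure for any particular ocean.

## 8. Degenerate inputs and tie-breaks (summary)

* `sp` missing with alpha/beta present: filled as alpha - beta; all three
  present must agree to 1e-9.
* Validation reports every offending row, not the first.
* Keeling: < 3 usable records or zero variance in 1/C are errors;
  p = alpha classifies as atmosphere-dominated.
* Rates at exactly the LOD are censored; both-zero denominators (yield,
  hybrid fraction, substrate contribution) are errors, not NaN.
* Bootstrap endpoints use type-7 quantiles of the resampled medians;
  < 100 resamples is an error.
* All generators and samplers are deterministic functions of
  (parameters, seed); pipeline stage seeds derive from the master seed by
  fixed offsets.
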