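---
title: "Methods: small-area storm-rain exposure and one-year mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-area storm-rain exposure and one-year mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Hurricanes kill far more people than the official storm-death tallies
suggest, and much of the excess unfolds over the months after landfall,
concentrated among older adults whose health depends on uninterrupted
access to care. `stormcohort` implements a complete, testable pipeline for
studying this: it turns raw storm-track and rain-gauge data into a
small-area (ZCTA-style) binary *high-rain exposure*, joins it to a cohort
of older adults followed for one year, and estimates both unadjusted
population measures (mortality rates, relative risk, attributable
fraction and attributable deaths) and covariate-adjusted hazard ratios
from Cox models with area-level shared frailty, overall and within
vulnerable subgroups (chronic conditions such as ADRD, CHF, COPD,
diabetes and CKD; the oldest old; dual-eligible beneficiaries;
minoritised racial and ethnic groups).

Because cohorts of this kind come from restricted administrative claims,
the package ships a synthetic-data generator that emulates all four
inputs with known true effects, so every stage of the pipeline can be
validated end to end without any restricted data.

## Exposure construction

**Track densification.** The storm best track (6-hourly centre fixes) is
interpolated to 15-minute resolution, linearly in latitude and longitude
against time. Linearity is a deliberate choice: at 15-minute spacing a
hurricane centre moves only a few kilometres, so spline-versus-linear
differences are far below the scale of area centroid distances, and the
linear scheme is exactly reproducible by an independent calculation —
which the test suite exploits. The interpolated track has
`floor(span/step) + 1` points; for 6-hourly fixes at a 15-minute step the
final point always coincides with the last fix. For a hypothetical track
whose span is not a multiple of the step, the grid remains regular and
the terminal partial segment carries no interpolated point.

**Closest approach.** For each area centroid the nearest interpolated
track point (great-circle distance, IUGG mean Earth radius 6371.0088 km)
supplies the approach distance and its timestamp; ties go to the earliest
time. The *approach date* is the calendar day of that instant under a
fixed UTC−6 convention (local standard time for the Gulf region):
daily rain gauges report local days, and the rain window is defined in
calendar days. The offset is configurable. Longitudes are kept in
[−180, 180] with no antimeridian handling; a crossing track is an
explicit error, which is the honest behaviour for a Gulf-of-Mexico-scale
tool.

**Rainfall at centroids.** Daily precipitation at each centroid is
estimated from surrounding stations by inverse-distance weighting with
power 2 — the conventional exponent for gauge interpolation — over
stations within 150 km. If fewer than 3 reporting stations fall inside
the radius it doubles until the quorum is met, capped at 600 km; at the
cap whatever stations are available are used, and only a day with no
reporting station within 600 km errors. These defaults suit gauge
densities typical of the Gulf coast and are all exposed in
configuration. Stations missing a value on a day are excluded from that
day's weights — gauge missingness is not zero rain. A station within 1 m
of the centroid returns its value directly, the correct limit of the
weighting. IDW output is always a convex combination of the
contributing station values, a property the tests check.

**Classification.** Exposure is cumulative rain over the four calendar
days from two days before to one day after the closest approach,
compared *strictly* against 75 mm (approximately 3 in.). The rule is
rain-only: track distance enters only through window timing. An optional
maximum-distance-to-track cap exists in configuration for users whose
convention requires proximity, but it is off by default. Inch values are
reported at one decimal (25.4 mm/in, round-half-even).

## Cohort construction

Inclusion rules are applied in a fixed order — age ≥ 65, complete
covariates, and (in primary analyses) no relocation during follow-up —
with each subject counted against the first rule that removes it, so the
exclusion ledger is comparable across runs and always satisfies
`retained + excluded = input`. Complete-case analysis is the intended
design for low missingness; the builder warns when the complete-case
exclusion exceeds 3% of input, the level above which assuming
missingness completely at random deserves scrutiny. Follow-up is 365
days from landfall; deaths on the landfall day itself are timed at 0.5
days, the standard device for keeping origin-tied event times positive —
any positive convention would do, and this one is declared and tested.

## Statistical models

**Unadjusted measures.** One-year mortality "rates" are cumulative
incidence proportions (fixed 365-day follow-up, no person-time
denominators). Relative risk is the ratio of these proportions;
the attributable fraction among the exposed is `(RR − 1)/RR`; and
attributable deaths are `n_exposed × (rate_exposed − rate_unexposed)`,
algebraically identical to `AF × deaths_exposed`. Negative values are
reported as computed, never floored, so protective contrasts remain
visible. Subgroup measures use subgroup-restricted denominators.
Kaplan–Meier cumulative incidence (`1 − S(t)`) and two-sided log-rank
tests compare exposed with unexposed; the characteristics table uses
t-tests for means, Mann–Whitney for medians and Pearson chi-squared
(no continuity correction) for proportions, with α = 0.05 throughout
and no multiplicity adjustment.

**Adjusted models.** The core model is a Cox proportional hazards fit
with a gamma-distributed shared frailty on areas, estimated by penalized
partial likelihood with an EM outer loop for the frailty variance θ, as
implemented in the `survival` package — the canonical, oracle-checkable
choice of "area-level random effects" when the literature does not name
a distribution. Ties are handled by Breslow's method by default because
it is the simplest exactly specifiable scheme: the test suite maximises
the explicit Breslow partial likelihood by brute force on tiny fixtures
and demands agreement to 1e-6 when the frailty is off, and the θ = 0
path reduces exactly to the ordinary Cox partial likelihood. Efron ties
are available behind a flag. Covariates follow the standard adjustment
set: exposure, age (continuous), sex, race/ethnicity, comorbidity count
and rurality, with reference levels female / non-Hispanic White / metro.
Hazard ratios are exponentiated coefficients with Wald 95% intervals
(z = 1.96).

Subgroup models refit the same specification within each subgroup with
two adjustments: race-defined subgroups drop the race covariate (it is
constant there), and a condition-defined subgroup removes its own flag's
contribution from the comorbidity count, where it no longer varies as a
comorbidity. Subgroups too sparse to fit are reported with an explicit
skip reason rather than aborting the table.

## Sensitivity analyses

**E-values** quantify the minimum confounder strength, on the risk-ratio
scale, needed to explain an association away:
`E = RR + sqrt(RR(RR − 1))`, inverting protective ratios first, with the
CI limit closer to the null transformed the same way (1 when the
interval crosses the null). With one-year mortality around 4–9% the
hazard ratio is used as the risk ratio; this rare-outcome approximation
is noted in the output.

**Moran's I** screens area-averaged martingale residuals (observed event
minus model-expected cumulative hazard, averaged within area) for
residual spatial autocorrelation. Martingale residuals are a declared
choice — the natural subject-level residual whose whole-sample sum is
zero, another tested identity. Weights are row-standardised
k-nearest-neighbour (k = 5) on centroid great-circle distance, since
polygon adjacency is out of scope when only centroids exist; rook grid
weights are provided for analytically tractable checks (a checkerboard
attains I = −1 exactly). Significance comes from a seeded 999-permutation
Monte Carlo with a two-sided p (twice the smaller tail, capped at 1);
the one-sided permutation p is also returned, and on independent fields
it is uniform — a property the acceptance suite verifies by a KS test
over 1000 simulated fields.

**Relocation.** The primary cohort excludes those who relocated during
follow-up (~2.7% in the emulated setting); the sensitivity suite refits
every subgroup model including them and reports the two runs side by
side. In the generator, relocation is independent of the event process
by default, so the two columns should agree within sampling noise; an
outcome-dependent relocation stress configuration can be built by the
user from the generator primitives.

## The synthetic-data generator

The generator is a deterministic function of its configuration and seed,
with independent sub-streams per stage so regenerating one input does
not shift another. Defaults emulate a Gulf-coast Medicare-style study
population: mean age 75.8 (SD 7.3, truncated at 65), 56.3% female, 7.7%
dual-eligible, condition prevalences ADRD 12.5%, CHF 17.2%, COPD 13.9%,
DM 30.8%, CKD 27.4%, 2.7% relocation, rurality 77.8/11.9/10.3%
metro/micro/rural, a 7-day storm crossing the region at 6-hourly fixes,
and one-year baseline mortality of 4% at the covariate reference. These
marginals are emulation targets, not reproductions of any restricted
dataset.

Station-day rainfall is `background + peak · exp(−d/decay)` on days the
track passes (d = distance from the station to that day's track
positions; defaults background 2 mm, peak 120 mm, decay 80 km), times
multiplicative gamma noise with unit mean and CV 0.3 — chosen so that,
through the IDW-and-threshold pipeline, roughly half of areas end up
exposed, mirroring the near-even exposure split such storms produce at
state scale. Event times are exponential with hazard
`λ₀ exp(β_E·exposed + βᵀx + b_area)`; the constant baseline is the
simplest proportional-hazards-consistent choice, and nothing downstream
uses baseline shape. Area effects are normal on the log hazard
(log-normal frailty) with SD 0.1 even though the fitter assumes a gamma
frailty: the mild distributional mismatch is deliberate, making
parameter-recovery tests a check of robustness rather than of a
self-fulfilling identity. The default true exposure log-hazard is
log(1.05), with modest covariate effects (e.g. 0.085 per year of age,
0.35 for male sex, 0.12 per comorbidity) of the size seen in mortality
models for this age group; optional condition-specific interaction terms
support subgroup-effect recovery experiments.

What the generator does *not* emulate: spatially correlated rainfall
beyond track-distance decay, exposure-covariate confounding (covariates
are drawn independently of area), informative censoring, claims-level
utilisation, or migration dynamics. Passing tests therefore demonstrate
that the estimators recover the truth under a clean proportional-hazards
world with clustered baseline risk — not that any particular real-world
estimate is unbiased.

## Numerical choices and problem sizes

Validation suites are sized to run comfortably on a single CPU: the
parameter-recovery experiment uses 50 independent synthetic studies of
200,000 beneficiaries across 120 areas (regenerating areas, storm
rainfall, exposure and cohort each replicate, so that interval coverage
is assessed across designs, not conditional on one exposure map); the
log-rank type-I-error suite uses 1000 null replicates of 300 subjects;
Moran's I null-uniformity uses 1000 fields on a 6×6 rook grid with 999
permutations each. The bundled acceptance script runs one full pipeline
at 50,000 beneficiaries — large enough that the exposure hazard ratio is
estimated to about ±7% — and reports the headline quantities as JSON.
Reference tolerances used by the oracle tests: 1e-6 for Cox coefficients
against brute-force likelihood maximisation, 1e-10 relative for IDW
against the direct weighted sum, exact (1e-9 km-scale) for geometry.

## Known limitations

Centroid-based exposure inherits the usual ecological caveats: rainfall
is assumed uniform within an area, and misclassification near the 75 mm
threshold is expected (in real use, non-differential). IDW ignores
orographic and convective structure; kriging is deliberately out of
scope. The frailty model estimates a single global θ; spatially
structured random effects (CAR/SAR) are not provided, only a Moran's I
screen for whether they would have been needed. The E-value treats the
HR as an RR, adequate for rare outcomes only. The HURDAT2 reader parses
the standard data rows but not header/metadata lines, and tracks
crossing the antimeridian are rejected rather than handled.
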