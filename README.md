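# stormcohort

Severe-weather epidemiology for older-adult cohorts: `stormcohort` builds
small-area (ZCTA-level) **high-rain exposure** from a hurricane best track
and daily station precipitation, and estimates the association between that
exposure and **one-year all-cause mortality**, overall and within
vulnerable subgroups — people living with ADRD, CHF, COPD, diabetes or CKD,
the oldest old (85+), dual-eligible beneficiaries, and minoritised racial
and ethnic groups. It is written for epidemiologists and health-services
researchers who study post-disaster mortality in administrative cohorts but
cannot share the underlying claims data: a fully synthetic study with known
true effects exercises every stage.

## What it computes

**Exposure.** The best track (6-hourly fixes) is interpolated to 15-minute
resolution; each area centroid's closest approach (great-circle distance
and time) anchors a 4-day rain window, *D−2 … D+1*. Daily rain at the
centroid is inverse-distance-weighted from surrounding gauges
(power 2, 150 km radius with quorum doubling), and an area is **exposed**
when the 4-day cumulative rain strictly exceeds 75 mm (≈ 3 in.).

**Unadjusted measures.** With one-year cumulative-incidence mortality
proportions r₁ (exposed) and r₀ (unexposed):

- relative risk `RR = r₁ / r₀`
- attributable fraction among the exposed `AF = (RR − 1) / RR`
- attributable deaths `n₁ (r₁ − r₀) ≡ AF × deaths₁`

plus Kaplan–Meier cumulative incidence, log-rank tests and a
Table-1-style characteristics summary (t / Mann–Whitney / chi-squared).

**Adjusted model.** Cox proportional hazards with a gamma shared frailty
on areas,

    λᵢⱼ(t) = λ₀(t) · uⱼ · exp(β_E·exposed + βᵀxᵢⱼ),   uⱼ ~ Gamma(1/θ, 1/θ)

fitted by penalized partial likelihood (Breslow ties; θ by an EM outer
loop), adjusting for age, sex, race/ethnicity, comorbidity count and
rurality; hazard ratios are exp(β) with Wald 95% CIs, refitted within each
subgroup.

**Sensitivity.** E-values (`E = RR + √(RR(RR−1))`), Moran's I with a
seeded permutation test on area-averaged martingale residuals, and a
relocation-inclusive re-analysis of the whole model suite.

## Worked example

```r
library(stormcohort)

cfg <- run_config(out_dir = "stormcohort_out", seed = 1,
                  sim = sim_config(n_beneficiaries = 20000))
res <- run_pipeline(cfg)

res$cohort
#> Analytic cohort: 19458 of 20000 beneficiaries retained
#>   excluded  age<65: 0  incomplete: 0  relocated: 542
#>   exposed: 6188 (31.8%)  deaths: 1761 (9.05%)

res$overall_fit
#> Cox shared-frailty (gamma) model: n = 19458, events = 1761, clusters = 120, theta = 5e-09
#>                          HR       95% CI
#> exposedTRUE            1.04 (0.94, 1.15)
#> age                    1.09 (1.08, 1.10)
#> sexmale                1.59 (1.45, 1.75)
#> ...

res$morans
#> Moran's I = 0.0382 (expected -0.0084), z = 0.88, p = 0.3840
#> [row-standardised 5-nearest-neighbour, 999 permutations]
```

The cohort report says 542 of 20,000 simulated beneficiaries were excluded
as relocated (none under 65, none incomplete), 31.8% of the retained
cohort lived in high-rain areas, and 9.05% died within the year. The
adjusted exposure hazard ratio is 1.04 (95% CI 0.94–1.15) against a
generator truth of 1.05 — a single study of this size brackets the true
effect but cannot distinguish it from the null, which is exactly the
regime the method targets at administrative scale (millions of subjects).
The frailty variance θ ≈ 0 and the non-significant Moran's I say this
realisation shows little residual area-level clustering. Every table is
also written to `stormcohort_out/` as CSV together with a JSON manifest
(config hash, seed, per-stage row counts) that makes reruns byte-identical.

A thin command-line wrapper (`inst/scripts/stormcohort.R`) exposes
`simulate`, `run` and `dump-defaults` subcommands over the same functions.

## Package layout

| Area | Functions |
| --- | --- |
| Track geometry | `read_track`, `interpolate_track`, `closest_approach` |
| Rainfall | `read_stations`, `read_daily_rain`, `idw_estimate`, `window_rain` |
| Exposure | `classify_exposure`, `build_exposure_table`, `exposure_summary` |
| Synthetic data | `sim_config`, `generate_storm`, `generate_rainfall`, `generate_cohort`, `simulate_inputs` |
| Cohort | `build_cohort`, `elapsed_days` |
| Descriptive | `epi_measures`, `km_curve`, `logrank_test`, `table_one` |
| Models | `fit_cox_frailty`, `subgroup_hrs`, `default_subgroups` |
| Sensitivity | `evalue`, `morans_i`, `residuals_by_area`, `relocation_sensitivity` |
| Orchestration | `run_config`, `run_pipeline` |

The methods vignette (`vignettes/stormcohort-methods.Rmd`) documents the
model assumptions, every tunable default and why it was chosen, and what
the synthetic validation does and does not demonstrate about real data.
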