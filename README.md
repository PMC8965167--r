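# alehosp

Comparative analysis of **active living environments (ALEs) and
hospitalization**, as an R package. It is written for population-health
researchers who work with linked survey–administrative microdata (e.g.
Welsh Health Survey × PEDW inside SAIL; CCHS × DAD inside the Canadian
research data centres) and need the full pipeline — exposure derivation,
outcome construction, descriptive utilization, adjusted models — in a
reusable, testable form, together with a synthetic-world generator that
stands in for the confidential data.

## What it computes

**ALE typology.** For each areal unit, three components within a 1000 m
Euclidean buffer of its centroid: density of ≥3-way street intersections
(per km²), count of points of interest, and dwelling density (per km²).
Components are z-scored and clustered with **k-medians** (L1 distance,
coordinate-wise medians, restarts plus relocation refinement) into five
classes, ordered so class 1 is least and class 5 most favourable for
active living.

**Hospital episodes.** Discharge records become inpatient events under
either national convention: Welsh *person-spells* (strictly contiguous
records merge; same-day spells are day cases, removed after merging) or
Canadian *episodes of care* (day procedures flagged `"A"` removed first;
records within 24 h merge). Causes are flagged from ICD-10 codes in any
diagnostic position — circulatory I00–I99, endocrine/nutritional/metabolic
E00–E88, respiratory J00–J98, cancer C00–D48, cardiometabolic
{I10–I15, I20–I25, I61–I69, I50, E11–E14} — and episodes with a primary
pregnancy/childbirth code (O00–O99) are excluded from all-cause counts.

**Models.** For binary outcome $y_i$ with ALE class indicators
(reference class 1):

```
logit Pr(y_i = 1) = β0 + Σ_c β_c 1[ALE_i = c] + γ1 age + γ2 age² +
                    γ3 female + γ4' education + γ5' smoking (+ log t_i)
```

fitted by IRLS with an HC0 sandwich covariance, a log follow-up offset
(hospitalization outcomes only), odds ratios `exp(β)` with normal-quantile
CIs, and **average adjusted predicted probabilities** per class with
delta-method CIs (gradient `mean(p(1−p)x)` through the robust covariance).

## Worked example

```r
library(alehosp)

sc  <- scenario_preset("canada", n = 40000, seed = 3)  # Canada-like world
sim <- simulate_scenario(sc)                           # cohort + records
ep  <- build_episodes(sim$records, "canada")           # episodes of care
summarize_utilization(sim$cohort, ep)
#> Hospital utilization over 176102 person-years (n = 40000 )
#>            cause  hospitalized episodes rate_per_100py         los
#>        all_cause 10148 (25.4%)    20729           11.8  9.7 (16.9)
#>      circulatory   3361 (8.4%)     3941            2.2  9.7 (15.3)
#>              enm   1385 (3.5%)     1487            0.8  9.0 (12.3)
#>      respiratory   1592 (4.0%)     1710            1.0 10.0 (17.2)
#>           cancer   1683 (4.2%)     1812            1.0  9.3 (14.0)
#>  cardiometabolic   2356 (5.9%)     2604            1.5  9.9 (16.0)

d <- prepare_cohort(sim$cohort)
d$hosp <- d$person_id %in% unique(ep$person_id[ep$all_cause])
fit <- ale_logit(hosp ~ ale_class + age + age_sq + sex + education + smoking,
                 data = d, offset = log(d$followup_years))
odds_ratio_table(fit)[2:5, ]
#>         term        or    ci_low   ci_high
#> 2 ale_class2 0.9298576 0.8806279 0.9818394
#> 3 ale_class3 0.7925606 0.7423679 0.8461469
#> 4 ale_class4 0.7800404 0.6917397 0.8796127
#> 5 ale_class5 0.6798645 0.5644459 0.8188841

marginal_predictions(fit)
#> Average adjusted predicted probabilities (delta-method CIs)
#>  level         predicted
#>      1 0.27 (0.26, 0.27)
#>      2 0.25 (0.25, 0.26)
#>      3 0.23 (0.22, 0.24)
#>      4 0.22 (0.20, 0.24)
#>      5 0.20 (0.17, 0.23)
```

A quarter of the synthetic cohort is ever hospitalized (25.4%) at 11.8
episodes per 100 person-years; the fitted class-5 odds ratio 0.68
(0.56–0.82) recovers the preset's encoded protective gradient (truth
0.66), and the predicted probability of hospitalization falls from 0.27
in the least to 0.20 in the most activity-friendly neighbourhoods. The
Wales-like preset (`scenario_preset("wales")`) encodes the opposite,
adverse gradient (truth 1.37).

The typology itself runs on any conforming GeoJSON layers:

```r
g  <- generate_geography(geography_config(extent_m = 5000, n_units = 150,
                                          seed = 21))
cl <- classify_units(g$units, g$streets, g$pois, k = 5, seed = 2)
plot(cl)   # component boxplots by ALE class
```

## Package layout

- `R/geography.R`, `R/cohort-sim.R`, `R/records-sim.R`, `R/presets.R` —
  synthetic world (geography, cohort, discharge records, national presets)
- `R/kmedians.R`, `R/ale-metrics.R` — clustering and the ALE typology
- `R/icd.R`, `R/episodes.R` — ICD-10 taxonomy and episode construction
- `R/cohort-prep.R`, `R/utilization.R` — covariate harmonization,
  disclosure rounding, crude utilization statistics
- `R/models.R` — `ale_logit()` and delta-method margins
- `R/reference-data.R` — published cohort margins used for descriptive
  recomputation
- `vignettes/ale-hospitalization-methods.Rmd` — models, assumptions,
  design decisions, limitations
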