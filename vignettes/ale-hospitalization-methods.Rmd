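---
title: "Active living environments and hospitalization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active living environments and hospitalization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alehosp)
```

## The problem this package addresses

Neighbourhoods that combine well-connected street networks, many nearby
destinations, and high residential density are considered favourable
*active living environments* (ALEs): places where daily physical activity
is easy. Whether living in such a place translates into lower hospital
burden is an empirical question that requires linking individual survey
responses to administrative hospitalization records — data that live in
trusted research environments and cannot leave them.

`alehosp` implements the full analysis pipeline for this question in
reusable, tested form:

1. **ALE typology** (`classify_units()`): three built-environment
   components within 1000 m Euclidean buffers of areal-unit centroids —
   density of ≥3-way street intersections, count of points of interest,
   and dwelling density — clustered into five ordered classes with
   k-medians, class 1 least to class 5 most favourable for active living.
2. **Episode construction** (`build_episodes()`): hospital discharge
   records merged into inpatient events under Welsh *person-spell* or
   Canadian *episode-of-care* rules, with day-case removal and ICD-10
   cause grouping.
3. **Utilization** (`summarize_utilization()`): percent ever hospitalized,
   crude rates per 100 person-years, length-of-stay summaries.
4. **Association models** (`ale_logit()`, `marginal_predictions()`):
   logistic regression of binary outcomes on ALE class indicators adjusted
   for sex, age, age², education, and smoking, with HC0 sandwich variance,
   a log follow-up offset for hospitalization outcomes, and delta-method
   confidence intervals for average adjusted predicted probabilities.
5. **Synthetic world** (`generate_geography()`, `generate_cohort()`,
   `generate_hospital_records()`, `scenario_preset()`): a generator with
   the statistical structure the analysis assumes, so that every stage is
   testable without confidential microdata.

## The ALE measure

For each areal unit (a dissemination-area or output-area analogue) we take
the Euclidean 1000 m buffer around its centroid in a planar metre
coordinate system. Membership is boundary-inclusive (distance ≤ radius); a
measure-zero convention, fixed for bit-reproducibility, and applied by the
same predicate to intersections, POIs and dwellings.

*Intersections.* Street-network nodes closer than a snap tolerance
(default 1 m) are merged, duplicate edges between a node pair collapse to
one, and a node is an intersection when its degree — distinct incident
street approaches — is at least 3. Footpaths are ordinary edges; there is
no filtering by road class.

*Dwelling density.* Census-style dwelling counts attach to areal units,
not points. By default a unit's count is attributed to a buffer when the
unit's centroid falls inside it; when an explicit dwelling point layer
exists, points are counted directly. Both conventions divide by the buffer
area (π km²).

*Clustering.* The three components are z-scored before k-medians
(`standardize = TRUE`, the default), because the raw scales differ by
orders of magnitude and unstandardized L1 distances would be dominated by
dwelling density; `standardize = FALSE` clusters literal raw scores for
users who want the alternative reading of the protocol. K-medians
alternates L1-nearest-median assignment with coordinate-wise median
updates; the best of `n_init = 10` restarts (k-means++-style seeding
adapted to L1) is refined by single-point relocation moves with exact
objective evaluation, which removes most of the local optima that plain
alternation leaves behind. Empty clusters are re-seeded at the point
farthest from its median. Convergence is declared when the objective
changes by less than `tol = 1e-6`.

*Ordering.* The raw cluster ids carry no meaning, and no canonical
ordering rule exists for this typology, so the package defines one
explicitly: clusters are labelled 1..k by ascending sum of the three
standardized component medians, with ties broken by intersection-density,
then POI, then dwelling medians. On gradient geographies this produces
monotone component means across classes, matching how the typology is
described (class 1 "very active living-unfriendly" up to class 5 "very
active living-friendly").

## Episodes and causes

Both destination systems treat contiguous inpatient records as one event,
but operationalize it differently:

* **Wales (person-spells)**: records merge when the next admission is on
  or before the current discharge date (gap 0 at date resolution — dates,
  not timestamps, are what discharge abstracts carry). Day cases are
  merged spells with same-day start and end, removed *after* merging.
* **Canada (episodes of care)**: records flagged as day procedures
  (facility type `"A"`) are removed *first*; remaining records within 24 h
  merge.

A merged episode spans first admission to last discharge; length of stay
is the whole-day difference (gaps inside the merge window count, since the
event is a single episode of care). Cause flags use every diagnosis in any
position: circulatory I00–I99, endocrine/nutritional/metabolic E00–E88,
respiratory J00–J98, cancer C00–D48, and a cardiometabolic subset
(I10–I15, I20–I25, I61–I69, I50, E11–E14 — E10, type 1 diabetes, is
excluded on purpose). Matching is on 3-character stems; subdigits never
exclude a code whose stem qualifies.

All-cause counting excludes pregnancy/childbirth. The operational rule —
not fully determined by the phrase "any cause except pregnancy or
childbirth" — is: an episode whose *primary* diagnosis lies in O00–O99 is
excluded from all-cause and cause-specific counts. Primary-position
scoping avoids discarding episodes with incidental pregnancy codes;
`pregnancy_rule = "any"` switches to any-position exclusion for
sensitivity analyses.

## Utilization definitions

Crude rates divide the aggregate episode count by the **whole cohort's**
person-time, × 100. A hospitalized-only denominator is arithmetically
inconsistent with the reported quantities (it would imply fewer episodes
than hospitalized persons is possible); the whole-cohort definition is the
one the reported tables use, and the one implemented. Length-of-stay
summaries average over episodes (not persons), with the sample SD.
Percentages and rates are stored at full precision; display rounding is
one decimal. Disclosure rounding (`disclosure_round()`, base 5,
half-away-from-zero) exists purely at the reporting layer — rounded cells
may fail to sum to rounded totals, and the package deliberately does not
"fix" that.

## The association models

For outcome $y_i \in \{0,1\}$ (a baseline flag, or ever-hospitalized over
follow-up):

$$\operatorname{logit}\Pr(y_i = 1) = \beta_0 + \sum_{c=2}^{5}\beta_c
\mathbf{1}[\text{ALE}_i = c] + \gamma_1 \text{age}_i + \gamma_2
\text{age}_i^2 + \gamma_3 \mathbf{1}[\text{female}_i] +
\boldsymbol{\gamma}_4' \text{edu}_i + \boldsymbol{\gamma}_5'
\text{smoke}_i \; (+ \log t_i)$$

with reference levels ALE class 1, education low, smoking never, and —
for hospitalization outcomes only — an offset $\log t_i$ of follow-up
years with coefficient fixed at 1. Baseline outcomes (obesity, no
activity, type 2 diabetes) measured at survey response carry no offset:
differential follow-up exists only after the survey. Age enters raw (not
centred) with its square; a centring option is unnecessary for the fit
itself and omitted to keep the coefficient scale conventional.

Estimation is IRLS (via `stats::glm`); inference defaults to the HC0
sandwich estimator (via `sandwich::vcovHC`) without small-sample
correction — the robust-variance convention of the large-sample software
this mirrors — switchable back to the model-based covariance. Confidence
intervals use the normal quantile 1.959964. Separation and rank
deficiency raise errors rather than returning penalized or silently
dropped estimates, because silent remedies would change the estimand.

*Margins.* `marginal_predictions()` computes average adjusted
predictions: for each class $c$, every row's exposure is set to $c$,
covariates and offsets stay as observed, and predictions are averaged:
$\bar p_c = \tfrac1n \sum_i \operatorname{expit}(x_{ic}'\hat\beta +
\log t_i)$. The delta-method standard error uses the gradient
$g_c = \tfrac1n \sum_i p_{ic}(1-p_{ic})x_{ic}$ and
$\widehat{\operatorname{Var}}(\bar p_c) = g_c' \hat V g_c$ with $\hat V$
the robust covariance. This is the *average adjusted prediction at
observed covariates* convention (counterfactual exposure, observed
offsets), the default behaviour of the `margins` postestimation this
reproduces.

## The synthetic world

The generator exists so that the full pipeline — buffers, clustering,
merging, modelling — can be exercised and validated end to end. Two
presets encode the two study populations' published structure:

| parameter | Wales-like | Canada-like |
|---|---|---|
| cohort size | 9,968 | 40,335 |
| follow-up (truncated normal, min 0.5 y) | 3.9 (0.7) y | 4.4 (0.6) y |
| respondent ALE shares, class 1–5 (%) | 28.5/29.4/27.1/11.4/3.6 | 48.8/27.4/17.6/4.3/1.9 |
| unit ALE shares, class 1 (%) | 25.5 | 36.9 |
| true class-5 all-cause hospitalization OR | 1.37 | 0.66 |
| ever hospitalized (target) | 23.4% | 25.4% |

The latent ever-hospitalized indicator is drawn from the logistic model
above (true ALE log-odds spanning the published gradients, modest
covariate effects, log follow-up offset). Intercepts were calibrated
numerically — solving $\mathbb{E}[\operatorname{expit}(\alpha + \eta_i)] =
\text{target prevalence}$ over a large draw of the preset covariate
distribution — and hard-coded, so realized prevalences sit at the
published values without run-time calibration. Latent-positive persons
receive a zero-truncated Poisson number of inpatient episodes
(`episode_rate` per follow-up year; 0.37 for the Canada-like preset, 0.40
otherwise — chosen so episodes per 100 person-years land near the
published crude rates), placed inside the follow-up window with
inter-episode gaps strictly wider than the merge threshold. That spacing
is what makes the round-trip property exact: the episode builder recovers
the generator's emitted truth record for record, including when every
episode is split into two transfer records (`p_split = 1`) and day-case
records are mixed in.

Length of stay is log-normal (median 5 days, σ = 1.15, rounded to whole
days, minimum 1), giving mean ≈ 9.6 and SD ≈ 16 days as published.
Primary diagnoses follow a cause mix chosen so cause-specific
ever-hospitalized shares approximate the published ones; secondary
diagnoses are mostly incidental codes. The default mix puts zero mass on
pregnancy-primary codes so that the latent indicator coincides exactly
with ever-hospitalized-for-all-cause; pregnancy exclusion is exercised
with explicit fixtures instead.

Geography is stylized: a square planar region, areal-unit placement and
dwelling counts and POI intensity all decaying exponentially from an
urban core (an inhomogeneous Poisson process by thinning, for POIs), and
three street styles — `grid` (uniform lattice), `radial` (spokes and
rings), `sparse-rural` (a low-degree meandering chain). One root seed
drives deterministic per-layer sub-streams, so partial re-runs reproduce.

**What the generator does not emulate.** Real joint dependence between
covariates and ALE class (only class margins and outcome models are
encoded — published tables give no joint distribution); residential
self-selection; spatial autocorrelation of outcomes; realistic road
topology; seasonality of admissions; coding noise in diagnoses. Passing
parameter-recovery tests therefore demonstrates the *estimator* is
correct under the assumed data-generating process, not that the published
estimates are themselves confirmed — those depend on confidential
microdata this package cannot see.

## Numerical and design choices

* Boundary-inclusive buffers; planar Euclidean distance only (the method
  prescribes Euclidean buffers; no geodesy, no network-distance buffers).
* K-medians defaults `k = 5`, `n_init = 10`, `max_iter = 100`,
  `tol = 1e-6`; ties in assignment break to the lowest cluster index;
  label ordering ties break by component medians as above.
* Education harmonization is total and deterministic over the packaged
  vocabularies and *errors* on unknown labels — silent imputation would
  be worse than failure. The packaged vocabularies cover the label sets
  the harmonization was defined over; the `map` argument extends them.
* Obesity is BMI strictly exceeding 30 kg/m²; BMI exactly 30 is not
  obese; missing BMI propagates to a missing flag (complete-case per
  model downstream).
* Model fits drop nothing silently: non-convergence, separation
  (|coefficient| > 15), and rank deficiency are errors.
* Test problem sizes: oracle suites use exhaustive enumeration up to
  n = 12 (k = 2) and n = 8 (k = 3); parameter recovery uses 50 replicates
  at n = 40,000 (Canada-like) and n = 10,000 (Wales-like), the sizes at
  which the published class-5 effects are detectable with the published
  precision.

## Known limitations

* The cluster→label ordering rule is this package's explicit convention;
  other orderings (e.g. by a single component) would permute labels.
* Unweighted aggregation is the default when coarsening unit-level
  metrics to larger zones; population weighting is the caller's choice.
* The Welsh day-case definition (same-day person-spell) cannot
  distinguish a genuine day procedure from a same-day emergency
  admission-discharge; that ambiguity is inherent to date-resolution
  records.
* No survey weights, no spatial random effects, no pooling of the two
  countries — within-country estimates only, by design.

## A worked run

```{r example, eval = FALSE}
sc <- scenario_preset("canada", n = 40000, seed = 3)
sim <- simulate_scenario(sc)
ep <- build_episodes(sim$records, "canada")
summarize_utilization(sim$cohort, ep)

d <- prepare_cohort(sim$cohort)
d$hosp <- d$person_id %in% unique(ep$person_id[ep$all_cause])
fit <- ale_logit(hosp ~ ale_class + age + age_sq + sex + education + smoking,
                 data = d, offset = log(d$followup_years))
odds_ratio_table(fit)
marginal_predictions(fit)
```
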