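# owncontrol

Own-control (self-controlled) analysis of osteoporosis treatment
effectiveness from administrative claims.

Claims databases are the only place to watch osteoporosis drugs work in
routine care, but treatment cohorts differ so much at baseline that naive
between-drug comparisons are uninterpretable. `owncontrol` implements the
within-cohort design used in real-world effectiveness studies of
anti-resorptive therapy: each patient's fracture rate during the first
three months on treatment — too early for a measurable protective effect —
serves as her own baseline, and effectiveness is the change in the rate
over successive on-treatment windows,

    IRR_w = (N_w / PY_w) / (N_early / PY_early),

with person-time counted as treated (censoring at discontinuation, switch,
death, disenrollment or end of study). Time-stable confounders cancel in
the ratio.

The package is aimed at pharmacoepidemiologists who want a tested,
reusable implementation of the whole chain:

* **`generate_bundle()`** — a synthetic claims generator (enrollment,
  prescriptions, diagnoses, procedures) with piecewise-constant fracture
  hazards anchored at the index date, so every downstream stage can be
  validated against known ground truth;
* **`select_cohort()`** — the eligibility funnel (women ≥ 50, 24-month
  history, exclusion diagnoses, new-user washout) with hierarchical
  treatment-class assignment and an attrition table;
* **`build_episodes()`** — treatment episodes under the 60-day refill-gap
  persistence rule, with discontinuation vs switch classification;
* **`find_fracture_events()`** — fracture adjudication (inpatient
  diagnosis, or outpatient diagnosis plus procedure) and transitive
  merging of same-site diagnoses within 90 days;
* **`owncontrol()`** — the central fit: windowed rates per 1000
  person-years and IRRs with Wald or exact-conditional 95% CIs, overall
  or stratified, returned as a classed object with `print`, `summary`,
  `coef`, `confint` and `plot` methods;
* **`fit_trend()`**, **`fit_age_adjusted()`** — the secondary analyses: a
  weighted linear trend of on-treatment rates, and an age-adjusted
  person-stratified (conditional) Poisson model.

See `vignettes/owncontrol-methods.Rmd` for the model, its assumptions and
all tunable parameters.

## Worked example

Simulate a 20 000-person single-class cohort at the package's default
study conditions (baseline 87.6 all-fracture events per 1000 PY, window
rate ratios 0.62/0.50/0.44/0.33) and run the full analysis:

```r
library(owncontrol)
cfg <- sim_config(
  n_patients = 20000, seed = 42,
  drug_mix = c(denosumab = 1, oral_bisphosphonate = 0, iv_ibandronate = 0,
               iv_zoledronate = 0, teriparatide = 0, raloxifene = 0, hrt = 0))
study <- run_study(cfg, with_models = TRUE)
study$fit$rates[study$fit$rates$fracture_type == "all", ]
```

```
    cohort fracture_type window events person_years rate_per_1000py
 denosumab           all  early    246       2939.9            83.7
 denosumab           all  m4_12    423       8113.3            52.1
 denosumab           all m13_24    307       7154.1            42.9
 denosumab           all m25_36    150       3937.4            38.1
 denosumab           all m37_48     71       2022.6            35.1
```

The early-treatment window estimates the baseline rate (83.7 here; a
single cohort scatters around the configured 87.6), and the on-treatment
rates fall as the generator's effect series dictates. The corresponding
IRR block of `print(study)`:

```
    cohort fracture_type window   N              IRR
 denosumab           all  m4_12 423 0.62 (0.53-0.73)
 denosumab           all m13_24 307 0.51 (0.43-0.61)
 denosumab           all m25_36 150 0.46 (0.37-0.56)
 denosumab           all m37_48  71 0.42 (0.32-0.55)
```

Each row compares an on-treatment window with the early window: `N`
on-treatment events, the rate ratio, and its 95% CI (Wald on the log
scale; exact-conditional for small counts). An IRR of 0.62 is a 38%
lower fracture rate than the patient's own baseline. The secondary
models:

```r
study$trend[["denosumab"]]
#> On-treatment fracture-rate trend (weighted least squares)
#>   slope: -6.21 per 1000 PY per period (weights: person_years, 4 windows)
study$age_model
#> Age-adjusted conditional Poisson model (person-stratified)
#>   persons with events: 1128; converged: TRUE
#>   IRR per year of age: 1.517 (95% CI 0.612-3.759)
```

The trend slope is the change in the all-fracture rate per on-treatment
period; the conditional Poisson model reports the fracture rate ratio per
additional year of age. This scenario simulates no age effect, and the
interval duly covers 1; it is wide because, with everyone entering
follow-up at day 0, age is nearly collinear with the analysis windows —
see the vignette.

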