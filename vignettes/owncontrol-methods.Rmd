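---
title: "Own-control estimation of fracture-rate changes from claims data"
author: "owncontrol package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Own-control estimation of fracture-rate changes from claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owncontrol)
```

## The design

Randomised trials establish that anti-resorptive therapies (denosumab,
bisphosphonates) and other osteoporosis medications reduce fracture risk,
but administrative claims are the only way to watch these drugs work in
routine care. Claims cohorts, however, differ systematically between
treatments — channelling by baseline risk makes naive between-drug
comparisons uninterpretable.

The design implemented here sidesteps between-cohort confounding by using
each patient as her own control. Clinical studies show no measurable
fracture-protective effect during the first months of anti-resorptive
therapy, so the first three months after the index prescription
(the *early-treatment window*, days 0–89) estimate a patient's baseline
fracture rate. Treatment effectiveness is then the change in the fracture
rate from that window to successive *on-treatment windows* (months 4–12,
13–24, 25–36, 37–48; fixed day boundaries 90/365/730/1095/1460, closed-open),
expressed as an incidence rate ratio

$$\mathrm{IRR}_w \;=\;
  \frac{N_w / \mathrm{PY}_w}{N_{\mathrm{early}} / \mathrm{PY}_{\mathrm{early}}},$$

with person-time accumulated *as treated*: follow-up ends at the earliest
of treatment discontinuation, a switch to another osteoporosis class,
death, disenrollment, or the administrative end of study
(31 December 2018). Time-stable confounders cancel in the ratio; anything
time-varying (ageing, differential censoring) does not, which motivates
the two secondary models below.

## Pipeline stages and their parameters

**Cohort selection.** Women aged 50 or older with at least one qualifying
osteoporosis prescription in 2013–2017, at least 24 months of continuous
pre-index enrollment, no history of cancer, Paget's disease or
osteogenesis imperfecta (a blanket exclusion applied over all available
pre-index history — the stricter of the readings, chosen deliberately),
and no fill of the index class in the 24 months before index (new users).
Patients are assigned to exactly one treatment class by the hierarchy
denosumab > intravenous bisphosphonates > oral bisphosphonates >
teriparatide > raloxifene > HRT; within the intravenous tier — reported
as separate ibandronate and zoledronate cohorts but listed as one tier —
the first-filled sub-class wins and sets the index date. Oestrogen-only
preparations count as HRT only for women with a hysterectomy procedure on
record. The washout is applied at the *class* level (molecule-level
washout is a configuration choice we expose but do not default to).
Members with less than 6 months of available follow-up (183 days from
index to the earliest of death, disenrollment, administrative end) are
retained for treatment-pattern analyses but flagged out of the fracture
analysis; this reading of the minimum-follow-up rule matches the very
small size of that attrition step in the published funnel.

**Episodes.** A treatment episode runs from the index fill while each next
index-class fill arrives no more than 60 days (`gap_days`) after the
*expected refill date* (previous fill date + days supplied). Supplies are
not stockpiled: an early refill resets the expected refill date rather
than extending it — the plainest reading of "expected refill date", and a
configurable point because the source is silent. A discontinued episode
ends at the expected refill date, not at the end of the grace window, so
as-treated person-time contains no unexposed grace days (`end_at =
"grace_end"` is available as the alternative). A fill of a *different*
osteoporosis class within 60 days after the expected refill date ends the
episode as a switch at that fill's date; a different class started while
index supply is still active is ignored (combination use, consistent with
single-group assignment). Death, disenrollment and the administrative end
truncate episodes earlier.

**Fracture events.** A fracture diagnosis qualifies if inpatient, or if
outpatient with a fracture-related procedure within ±30 days
(`proc_window_days`; the linkage window is not pinned down by the design
and is configurable). Qualified same-site diagnoses of one person are
chained transitively — each diagnosis within 90 days of the previous one
in the chain is the same clinical event ("three months" is fixed at 90
days for determinism) — and the event is dated at the chain's first
diagnosis. Different body sites never merge. Sites are assigned by first
prefix match over an *ordered* code map; the exact published code lists
live in non-redistributable supplementary material, so the package ships
a small ICD-10-GM/OPS-like placeholder map (`inst/extdata/code_map.yaml`)
that is a configuration artifact, not a hard-coded truth.

**Intervals.** The interval construction behind the published tables is
unstated, so two methods are implemented and the method used is recorded
in every output row: a log-scale Wald interval
$\exp(\log \mathrm{IRR} \pm z_{0.975}\sqrt{1/N_w + 1/N_{\mathrm{early}}})$,
and an exact-conditional interval (given total events, the on-treatment
count is binomial with success probability
$\mathrm{PY}_w\,\mathrm{IRR}/(\mathrm{PY}_w\,\mathrm{IRR} +
\mathrm{PY}_{\mathrm{early}})$; a Clopper–Pearson interval on that
probability is transformed to the ratio scale). The default (`auto`) uses
Wald and falls back to exact when either count is below 5, since
published cells go as low as one event. Zero events in the early window
leave the ratio undefined but still produce a flagged row with an exact
bound rather than an error. Within-person correlation across windows is
*not* adjusted for (recurrent events are all counted, and nothing in the
source indicates a clustering adjustment) — a documented limitation.

**Trend.** A weighted linear model of the on-treatment rates per 1000 PY
on period index 1–4. Only "weighted" is stated; person-years weighting
(precision weighting) is the default, recorded in the output, with equal
weights as the alternative.

**Age-adjusted sensitivity model.** A person-stratified (conditional)
Poisson model of window event counts with a log person-years offset,
window indicators, and age at the person's observed window midpoint as a
time-varying covariate. Conditioning on each person's total event count
turns the likelihood into a multinomial over that person's windows,
eliminating one nuisance baseline per person; we maximise it directly
with BFGS and an analytic gradient rather than fitting thousands of fixed
effects. Persons with no events drop out by construction. Because every
member enters follow-up at day 0, within-person age variation is almost
collinear with the window indicators; the age coefficient is identified
only through partial windows (members censored mid-window), so its
confidence interval is wide at simulation scale — the package reports
that honestly rather than dropping the window terms.

## The synthetic claims generator

Real claims from the source database cannot be redistributed, so
`generate_bundle()` emulates their structure with known ground truth —
every downstream stage is validated against the generator's parameters
rather than against irreproducible proprietary data.

Fracture events are drawn from a piecewise-constant-rate Poisson process
via per-segment counts and uniform placement — this matches the IRR
estimand exactly and is cheap. The clock is anchored at each person's
index date, per-site baseline hazards apply on days 0–89, and inside
window $w$ the total hazard is multiplied by the configured ratio $r_w$
(continuing the last ratio beyond month 48). Defaults are the package's
statement of the study conditions:

* per-site baseline hazards summing to 87.6 all-fracture events per
  1000 PY, 50.7 of them clinical vertebral — the reported highest-risk
  (denosumab) cohort baseline;
* window ratios $r_w = (0.62, 0.50, 0.44, 0.33)$, the reported
  all-fracture effect series for that cohort;
* a drug mix equal to the reported cohort composition
  (3 495 / 13 134 / 1 801 / 379 / 43 / 120 / 22 889 of 41 861);
* per-class days supplied (180 d denosumab, 30 d oral bisphosphonates,
  90 d IV ibandronate, 365 d IV zoledronate, 28 d teriparatide, 30 d
  raloxifene, 90 d HRT — stated assumptions, surfaced in configuration,
  because real-world days-supplied conventions are not documented) and
  per-refill stopping probabilities calibrated by simulation at design
  time — with study-end and mortality censoring included — so that the
  median episode duration under the 60-day gap rule reproduces the
  reported medians (587 / 258 / 451 / 389 days for the anti-resorptive
  classes; HRT saturates near 180 days because a 90-day supply makes
  shorter medians unreachable under the gap rule);
* a latent high-risk stratum (prevalence 0.15, hazard ratio 2, seeded
  with a pre-index fracture diagnosis) mirroring the reported 1.8- to
  2.7-fold higher baseline rates of patients with prior fracture.
  Within-stratum hazards are renormalised so the *marginal* early rate
  stays at the configured baseline.

Each simulated fracture presents as an inpatient diagnosis with
probability 0.6, otherwise as an outpatient diagnosis plus a same-day
fracture-related procedure, so both arms of the case definition are
exercised; 20% of events emit a follow-up same-site diagnosis within 60
days to exercise event merging. Washout violators and prior other-class
treatment are seeded strictly before the 2013 inclusion-window start so
that the generator's index date and the cohort builder's reconstructed
index date always agree. Pre-index fracture *history* is seeded as a
flag, not simulated as a second event process, keeping the prior-fracture
stratifier exactly aligned with the generator's high-risk stratum.

What the generator does **not** emulate: German billing semantics
(quarterly outpatient aggregation, EBM catalogues), morbidity-adjusted
sampling, comorbidity structure, seasonality, and informative censoring
(death is independent of fracture risk). Passing tests therefore
demonstrate the *algorithms* are correct and the *estimators* are
calibrated under the stated data-generating process — not that real
claims meet those assumptions.

## Numerical and degenerate-input choices

All date intervals are closed-open. Months map to days as 24 months =
730 days and 6 months = 183 days. Person-years use 365.25 days. Ages use
the mid-year (July 1) birth-date convention, as only a birth year is
carried. Duplicate same-day fills collapse with a warning; fills after
the censor date drop with a warning; a negative episode duration is a
hard error (invariant breach upstream). Empty inputs flow through every
stage as empty tables with headers. The conditional Poisson fit flags
itself instead of estimating when fewer than two informative persons
remain.

## Validation and problem sizes

The test suite validates each stage against an independent oracle: the
episode builder against a literal day-by-day walk of the grace-period
rule (1000 random fill sequences), event merging against a
transitive-closure computation on the pairwise 90-day relation (1000
random diagnosis sets), weighted least squares against the closed-form
normal equations, and the conditional likelihood against a Poisson
fixed-effects GLM (whose profile likelihood coincides with the
conditional one). Statistical calibration uses the generator: pooled
IRRs over 50 cohorts of 5 000 patients recover $(0.62, 0.50, 0.44,
0.33)$ to within 0.05 per window; at a true ratio of 0.6 the Wald
interval covers the truth in 93–97% of 500 replicates; under a null
generator ($r_w = 1$) the interval for every window covers 1 in at least
90% of 200 replicates of 5 000 patients; and a generator ageing effect
of 1.05 per year is recovered within the conditional model's interval.
These sizes were chosen to put the estimators in their working regime
(tens of events per window) while keeping a full validation run on a
single CPU in minutes.

## Known limitations

* Confidence intervals ignore within-person correlation of recurrent
  fractures across windows.
* The own-control contrast removes only time-stable confounding; the
  age model addresses ageing but not other time-varying risk factors or
  differential censoring.
* The shipped code map is a structural placeholder; real analyses must
  supply validated code lists.
* The trend model treats window rates as observations; it is a
  descriptive summary, not an inferential model for the rate process.
* Between-treatment comparisons are deliberately out of scope: baseline
  rates differ across cohorts by design, and the package surfaces
  per-cohort contrasts only.
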