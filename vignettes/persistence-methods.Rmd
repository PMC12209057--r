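---
title: "Methods: gap-based persistence and PDC adherence from claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gap-based persistence and PDC adherence from claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persistkit)
```

## The study design this package implements

`persistkit` implements a new-user cohort study of persistence and
adherence to SGLT2 inhibitor (SGLT2i) monotherapy, as conducted on
Japanese employee-insurance claims databases. The design rests on four
flat tables (enrollment, prescription claims with ATC code and days of
supply, diagnosis claims with ICD-10 code and a suspected-diagnosis flag,
and outpatient visit claims) and the following conventions:

* **Date imputation.** Some fields are stored at year-month resolution;
  they are completed to day resolution with the conventional imputed day
  of month 15 (`parse_claim_date("202208")` is 2022-08-15). All window
  arithmetic is in integer days over half-open intervals `[start, end)`.
* **New-user definition.** The index date is the first SGLT2i (ATC
  prefix `A10P`) fill with no antidiabetic (prefix `A10`) fill of any
  kind in the 180-day pre-index window, and enrollment covering
  `[index - 180, index + 365)`. Patients are then excluded if the index
  prescription is a combination start (another antidiabetic the same
  day), a fixed-dose combination tablet, if only one SGLT2i fill occurs
  in follow-up, or if fewer than two outpatient visits occur pre-index.
  `build_cohort()` computes all violation flags before attributing
  patients to stages, so the *set* of excluded patients is independent of
  stage order while the per-stage counts remain auditable.
* **Persistence.** A discontinuation event is the first occurrence of
  either (i) a gap between two consecutive prescription dates exceeding
  the permissible gap (90 days primary, 30 days sensitivity), dated at
  the earlier fill's supply run-out `min(fill + supply, 365)`; (ii) a
  trailing gap between the last fill and day 365; or (iii) initiation of
  combination therapy, dated at the other agent's first fill. Patients
  with no event are censored persistent at day 365. Restart is evaluated
  for gap discontinuers only: a switcher is still on antidiabetic
  therapy, so restart is not meaningful there (a flag reverses this).
* **Adherence.** The proportion of days covered is
  `PDC = covered_days / 365`, where covered days are the union of fill
  intervals `[fill, fill + supply)` clipped to follow-up — overlap from
  early refills counts once and there is no stockpiling carry-forward.
  PDC deliberately ignores gap events. `PDC >= 0.80` defines adherent.

Two readings of the definitions deserve a note. The gap comparison is
*strict*: a gap of exactly 90 days is allowed, because the permissible
gap is "the maximum allowable period without treatment"
(`gap_policy(strict = FALSE)` gives the inclusive reading). A trailing
gap counts as discontinuation; without it, persistence, restart and
person-year incidence figures of such studies cannot be mutually
consistent. When a gap run-out and a switch fall on the same day, the
gap wins — the supply had already lapsed when the new agent was started.

## Covariates

Baseline covariates come from the 180-day pre-index window except
calendar year, age and sex, which are index-date attributes: visit count
(every claim counts; one claim is one visit) and mean inter-visit
interval (computed over *distinct* dates, `(last - first)/(n - 1)`);
the count of distinct concomitant drug classes among RAS agents (C09),
beta blockers (C07), calcium channel blockers (C08), diuretics (C03) and
lipid-lowering agents (C10), with fixed-dose products counting toward
every matching class; six comorbidity flags from non-suspected ICD-10
diagnoses (hypertension I10, dyslipidemia E78, depression F32-F33,
obesity E66, hyperuricemia E790, diabetic nephropathy E112/E142/
N083/N189); and the Charlson comorbidity index. Code matching is by
prefix on normalized codes (dots stripped, upper case), and the code map
is user-overridable — published claims studies occasionally transpose
code assignments (one widely read paper prints hypertension as E78 and
dyslipidemia as I10), so the map is data, not code.

The Charlson index uses the Quan 2005 ICD-10 category coding with the
original 17-category weights, honouring the severity hierarchies
(complicated diabetes supersedes uncomplicated, moderate/severe liver
disease supersedes mild, metastasis supersedes other malignancy). In an
antidiabetic-naive cohort the score is dominated by the diabetes
category itself, so means near 1 are expected.

## Statistical layer

Persistence is summarised by the Kaplan-Meier product-limit estimator
(`km_estimate()`, backed by `survival::survfit`, censoring only at day
365), by the 365-day persistence rate, and by events per 1000
person-years with person-time equal to persistence days. Factors are
assessed by logistic regression on two binary outcomes — non-persistence
and poor adherence (PDC < 80%) — in two modes: *crude* (one
single-covariate model per factor) and *adjusted* (all factors jointly).
Odds ratios are exponentiated coefficients with Wald 95% confidence
intervals; Wald rather than profile-likelihood intervals match common
claims-study practice. Continuous covariates (age per year, visit count,
visit interval, drug-class count, CCI) enter linearly. Separation or
aliasing is reported per term (`fit_ok = FALSE`), never thrown.
Multicollinearity is screened by variance inflation factors computed
directly as `1/(1 - R^2)` from auxiliary least-squares fits, so constant
or perfectly collinear columns are reported as degenerate rather than
crashing; the conventional flag level is VIF > 10. The additional
analyses regress PDC and follow-up days on age and on visit interval by
ordinary least squares.

Report tables render counts with row percentages rounded half-up to one
decimal (matching how published tables render, e.g., 1029/1327 as 77.5),
and every rendered count is taken verbatim from the covariate or
exposure tables — the renderer recomputes nothing.

## The synthetic claims generator

Real claims databases of this kind are proprietary, so the package
ships a generator (`simulate_claims()`) whose defaults encode the study
conditions: observation window 2017-10-01 to 2020-09-30; age normal with
mean 51.9 and SD 9.1 years (truncated to 20.5-72 so that no patient
reaches the age-75 coverage limit under observation); 73.4% male;
comorbidity prevalences 61.1/65.1/8.5/5.7/21.4/7.8% and concomitant drug
class prevalences 44.8/12.9/29.9/9.4/48.3%; days of supply over
{14, 30, 60, 90} with median 30; a per-day baseline discontinuation
hazard of 0.0016; a restart probability of 0.454 among discontinuers;
and planted covariate effects on discontinuation equal to the study's
adjusted estimates (log odds -0.033 per year of age, -0.33 hypertension,
-0.30 dyslipidemia, -0.28 hyperuricemia). Index dates are drawn
uniformly over the dates admitting complete pre- and post-index windows,
which makes the calendar-year covariate take both its 2018 and 2019
values. Small fractions of patients exercise each selection branch:
prevalent users (8%), combination starts at index (3%), fixed-dose
combination starts (2%), short enrollment (2%); single-prescription and
few-visit exclusions arise naturally from early stopping and the
Poisson(6.2) visit process.

Two generator design choices matter enough to spell out:

* **Logit link for the planted effects.** The 365-day discontinuation
  *indicator* is Bernoulli with
  `logit(p) = logit(1 - exp(-365 h)) + sum(beta_k x_k)`; the
  discontinuation *day*, given an event, follows the hazard's truncated
  exponential. Planting effects on the log-odds scale — rather than as
  proportional hazards — is what makes the generator's ground truth
  directly recoverable by the downstream logistic model: a hazard-ratio
  plant of the same magnitude would bias the estimated log-OR by more
  than one standard error at n = 5000 (odds ratios are not collapsible
  over a hazard model), and no finite sample could then attain nominal
  CI coverage of the planted value. The hazard still controls both the
  baseline event probability and the timing distribution.
* **Observable event days.** Simulated stop days are truncated to
  days 1-260. Under the 90-day-gap measurement rule, a patient whose
  last fill falls later than about day 275 is persistent *by
  definition* — a later "stop" is not a study event at all. Aligning
  the planted truth with the outcome definition keeps the measured and
  planted classifications identical, which the test suite asserts
  exactly.
* **Refill timing.** Refills occur at the previous fill plus days of
  supply plus a jitter that is centred at -2 days, capped at zero and
  truncated at -7: patients refill on or shortly before supply
  exhaustion. Early refills deliberately create overlapping supply to
  exercise the no-double-counting rule. The cap at zero reflects the
  sensitivity-analysis arithmetic of such studies: if monthly refillers
  routinely ran a few days late, a 30-day permissible gap would classify
  nearly everyone non-persistent, whereas observed 30-day-gap
  persistence rates sit only a handful of points below the 90-day-gap
  rates. Restarters resume after a gap of 91-210 days and refill to the
  window end; switchers receive a second antidiabetic agent uniformly
  between days 30 and 300.

### What the generator does and does not emulate

Passing tests on synthetic data demonstrate that the pipeline measures
what the generator planted — cohort branches, event days, restarts,
prevalences, planted odds ratios — under refill behaviour that is more
punctual than reality. Two consequences are worth knowing. First,
synthetic persistent patients are almost fully covered, so synthetic
mean PDC (mid-80s %) and adherent share (~70%) run higher than the
low-70s/high-50s typically observed in practice, where covered time
erodes through small irregular gaps that no simple renewal process
reproduces without also wrecking the 30-day-gap sensitivity arithmetic.
Second, the generator bills one claim row per event with clean codes; it
does not emulate fee-schedule detail, miscoding, duplicate billing or
inpatient claims. Conclusions about the *pipeline* transfer to real
data; conclusions about *rates* do not.

## Validation sizes and numerical choices

The test suite validates covered days against a brute-force 365-slot
boolean-array oracle (exactly, on 300 random schedules and on every
patient of a ~2000-patient synthetic cohort), event detection against an
exhaustive day-walk oracle (300 random schedules under both policies),
the Kaplan-Meier curve against hand product-limit arithmetic and against
the empirical survival function (exact when censoring occurs only at day
365), crude odds ratios against the 2x2 cross-product closed form (to
1e-6 relative), VIFs against an independent implementation, and CI
coverage of a single planted log-odds effect of -0.3 across 100
replicates of n = 5000 (expecting at least 90% coverage). These sizes
were chosen so the whole suite completes in a few minutes on one core
while leaving binomial/sampling noise well inside the asserted margins.

Degenerate inputs are contracts, not silent paths: an empty fill list
for a cohort member, fewer than two pre-index visits, zero person-years,
one-class outcomes and zero-variance predictors all raise errors naming
the violated precondition, because each is excluded upstream by
construction. Fills entirely outside the follow-up window are dropped
with a warning. Ties among same-day events are processed together in the
product-limit estimator; same-day duplicate visit claims count as visits
but collapse for the interval.

## Known limitations

* Adherence is measured from dispensing, not ingestion; PDC is an upper
  bound on consumption.
* The PDC denominator is fixed at 365 regardless of discontinuation, per
  the study definition; it is not a time-on-treatment PDC.
* Only the first discontinuation is analysed; restarters are not
  re-indexed.
* The crude odds ratios are univariate logistic estimates; published
  "crude" columns in some studies are not reproducible as 2x2
  cross-products of their own printed counts, and no attempt is made to
  reverse-engineer undocumented adjustments.
* Laboratory values, BMI, diabetes duration and questionnaire adherence
  scores are outside the claims data model.
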