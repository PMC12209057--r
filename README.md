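# persistkit

Medication **persistence** and **adherence** analysis for prescription
claims data, built around the new-user cohort design used to study SGLT2
inhibitor (SGLT2i) monotherapy in Japanese employee-insurance claims
databases — for pharmacoepidemiologists who need the whole chain, from
raw claims tables to factor tables, as tested, reusable functions.

## What it computes

Given four claims tables (enrollment; prescriptions with ATC code and
days of supply; diagnoses with ICD-10 code and a suspected flag;
outpatient visits), the package:

* builds the **new-user cohort**: index date = first SGLT2i fill
  (ATC prefix `A10P`) with no antidiabetic fill (prefix `A10`) in the
  180-day washout and enrollment covering `[index − 180, index + 365)`,
  then applies the exclusion cascade (combination start at index,
  fixed-dose combination at index, a single post-index fill, fewer than
  two pre-index visits) with auditable flow counts;
* measures **persistence**: the first of a prescription-date gap
  exceeding the permissible gap *g* (90 days primary, 30 days
  sensitivity; event dated at the earlier fill's supply run-out
  `min(t_fill + supply, 365)`), a trailing gap, or a switch to
  combination therapy; no event means censored persistent at day 365.
  Restart = any further SGLT2i fill after a gap event;
* measures **adherence**: `PDC = |∪ [t_fill, t_fill + supply) ∩ [0, 365)| / 365`
  (overlapping supply counted once, no stockpiling), adherent iff
  PDC ≥ 0.80;
* derives **baseline covariates** from the pre-index window: visit count
  and mean inter-visit interval, concomitant drug classes
  (C09/C07/C08/C03/C10), six comorbidity flags from non-suspected
  diagnoses, and the Charlson comorbidity index (Quan 2005 ICD-10
  coding, original weights, hierarchies honoured);
* fits the **statistical layer**: Kaplan–Meier persistence
  S(t) = Π (1 − dᵢ/nᵢ), events per 1000 person-years, crude (univariate)
  and adjusted (joint) logistic odds ratios with Wald 95% CIs for
  non-persistence and poor adherence, VIF multicollinearity screening,
  and OLS of PDC / follow-up on age and visit interval;
* ships a **synthetic claims generator** with planted ground truth
  (cohort branches, event days, restart flags, covariate effects on the
  log-odds of discontinuation) so every stage is testable end to end.

Six-digit year-month dates are completed with the conventional imputed
day 15 (`parse_claim_date("202208")` → `2022-08-15`).

## Worked example

A hand-authored 13-patient bundle covers every selection and exposure
branch:

```r
library(persistkit)
wf <- worked_fixture()
cb <- build_cohort(wf$bundle)
cb$flow
#>                            stage n_excluded n_remaining
#>                       candidates          0          11
#>                  missing_rx_date          0          11
#>       single_sglt2i_prescription          1          10
#>             combination_at_index          1           9
#>  fixed_dose_combination_at_index          1           8
#>            fewer_than_two_visits          1           7
#>                     final_cohort          0           7
```

Two of thirteen patients never become candidates (prior antidiabetic
use; enrollment too short), four violate one cascade rule each, seven
enter the cohort. Exposure under the primary 90-day gap:

```r
compute_exposure(cb$cohort, wf$bundle, gap_policy(90))
#>    patient_id persistence_days reason restarted covered_days   pdc adherent
#> 1   P_persist              365   none     FALSE          360 0.986     TRUE
#> 2    P_gap100               30    gap      TRUE           60 0.164    FALSE
#> 3     P_gap60              365   none     FALSE          335 0.918     TRUE
#> 4    P_switch               40 switch     FALSE           60 0.164    FALSE
#> 5  P_trailing               60    gap     FALSE           60 0.164    FALSE
#> 6 P_censor365              365   none     FALSE          365 1.000     TRUE
#> 7     P_y2019              365   none     FALSE          365 1.000     TRUE
```

`P_gap100` fills on days 0 and 100 with 30-day supplies: the 100-day gap
exceeds 90, so the event is dated at the day-0 fill's run-out (day 30),
and the day-100 fill makes the patient a restarter. `P_censor365` has
exactly-90-day gaps — the boundary is allowed — and full coverage.

At scale, on a synthetic population with the generator's default study
conditions:

```r
sim <- simulate_claims(sim_config(n_patients = 2500, seed = 1))
res <- run_study(sim$bundle)
res
#> <study_result>
#>   cohort: 2070 patients
#>   gap90: persistence 64.1%, restart 47.1%, incidence 458.2 /1000 PY
#>   gap30: persistence 52.3%, restart 56.8%, incidence 679.1 /1000 PY
#>   mean PDC 85.9%, adherent 70.6%

res$table_persistence[c(7, 8, 11), ]
#>             term reference_group outcome_group         crude_or_ci      adjusted_or_ci
#> 7   hypertension      852 (66.6)    428 (33.4) 0.754 (0.627-0.905) 0.749 (0.622-0.902)
#> 8   dyslipidemia      889 (65.9)    461 (34.1) 0.801 (0.664-0.966) 0.782 (0.647-0.946)
#> 11 hyperuricemia      290 (67.9)    137 (32.1) 0.806 (0.643-1.011) 0.837 (0.666-1.053)
```

Persistence falls when the permissible gap tightens from 90 to 30 days
(64.1% → 52.3%), and the adjusted odds ratios recover the planted
protective effects of hypertension, dyslipidemia and hyperuricemia on
discontinuation (planted at log-odds −0.33, −0.30, −0.28). Synthetic
mean PDC runs higher than real-world reports because simulated refills
are punctual; see the methods vignette
(`vignettes/persistence-methods.Rmd`) for what the generator does and
does not emulate.

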