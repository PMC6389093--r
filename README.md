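# tiaqueue

Time-dependent, diagnosis-weighted triage for outpatient TIA (transient
ischemic attack) assessment units — and the survival-analysis pipeline to
evaluate it.

## The problem

TIA units book referred patients into a finite number of appointment slots.
Roughly 40–50% of referrals are *mimics* (migraine, seizure, …) with no
recurrent-stroke risk, and for true TIA/minor stroke the risk of a recurrent
event is front-loaded: it decays rapidly in the days after symptom onset.
The conventional triage instrument — the ABCD2 score (Age, Blood pressure,
Clinical features, Duration, Diabetes; 0–7) — presupposes a TIA diagnosis
and is static in time, so it neither discounts mimics nor reflects a
patient's shrinking risk window while they wait.

`tiaqueue` implements a weighted triage score that does both:

```
w(t) = P(TIA | referral form) × R_s(t)
```

where `P(TIA | form)` is a configurable logistic classifier over the referral
form's symptom checkboxes (structure: intercept + main effects +
interactions), and `R_s(t) = 1 − S_s(H)/S_s(t)` is the remaining conditional
recurrent-stroke risk for the patient's ABCD2 stratum `s` (LOW 0–3,
MODERATE 4–5, HIGH 6–7) at elapsed time `t` since onset, from a
piecewise-exponential hazard fitted exactly to literature cumulative-risk
anchors. Referrals are re-ranked by `w(t)` at every business-day triage
session (weekend faxes batch to Monday).

The package contains, as separately usable modules:

* referral data model, file I/O (CSV/JSON), and the missing-data filter
  cascade (`referral_cohort`, `read_referrals`, `apply_cohort_filters`)
* ABCD2 scoring with mean-substitution imputation and legacy ABCD
  conversion (`compute_abcd2`, `impute_missing`, `abcd_to_abcd2`,
  `risk_stratum`)
* the pluggable classifier (`classifier_model`, `read_classifier_model`,
  `predict_tia_probability`, `model_audit`)
* stratum risk curves (`fit_risk_curve`, `remaining_risk`)
* the dynamic queue and a discrete-event booking simulator under competing
  policies — weighted queue vs historical ABCD-descending vs FIFO
  (`weighted_triage_score`, `rank_referrals`, `refresh_scores`,
  `simulate_unit`)
* the evaluation pipeline: calendar-day time-to-unit, 28-day right
  censoring, Kaplan–Meier medians, Peto–Peto modified Gehan–Wilcoxon tests,
  and the six-stratum (risk group × diagnosis) comparison report
  (`days_to_unit`, `censor_at`, `km_estimate`, `peto_peto_test`,
  `stratified_report`)
* a reproducible synthetic referral-stream generator with the marginal
  structure of a real two-era referral population (`generate_cohort`,
  `default_specs`) and an end-to-end orchestrator (`run_experiment`).

The bundled classifier (`example_classifier.yaml`) is **synthetic** — it has
the published structure of a real unit classifier (50 main effects / 12
interactions, 31 / 8 positive) but fabricated coefficients — and the bundled
risk anchors are literature defaults. Both are configuration files meant to
be replaced with locally validated values.

## Worked example

Score and rank a handful of synthetic referrals:

```r
library(tiaqueue)
model  <- read_classifier_model(tiaqueue_example("example_classifier.yaml"))
curves <- fit_risk_curves()   # bundled literature anchors

rc <- generate_cohort(cohort_spec(n = 6, missing_onset = 0, missing_age = 0,
                                  missing_bp = 0, spectra_rate = 0,
                                  other_rate = 0, unknown_rate = 0), seed = 42)
rc <- derive_abcd2(rc)
rc$referrals$p_tia <- predict_tia_probability(model, impute_missing(rc))$p_tia
```

ranking inputs at a triage snapshot (elapsed time capped at 10 days here):

```
          id        diagnosis abcd2  p_tia remaining_risk      w
1 POST-00001            MIMIC     1 0.4741         0.0185 0.0088
2 POST-00002 TIA_MINOR_STROKE     3 0.7550         0.0185 0.0140
3 POST-00003            MIMIC     3 0.0394         0.0185 0.0007
4 POST-00004            MIMIC     1 0.6344         0.0185 0.0118
5 POST-00005 TIA_MINOR_STROKE     7 0.9657         0.0667 0.0644
6 POST-00006            MIMIC     4 0.0025         0.0400 0.0001
```

Read: referral 5 (high-stratum, classifier is confident it is a true TIA)
dominates; referral 6 sits in the MODERATE stratum but the classifier is
nearly certain it is a mimic, so it ranks last — exactly the reshuffling a
diagnosis-blind ABCD ranking cannot do.

A full two-cohort experiment (2000 referrals per 18-month era, 5
appointments/day — a demand-sized, congested unit; historical ABCD triage vs
the weighted queue):

```r
specs <- default_specs(n_pre = 2000, n_post = 2000)
ex <- run_experiment(experiment_config(pre_spec = specs$pre,
                                       post_spec = specs$post,
                                       unit = unit_config(5L), seed = 1))
ex$report
```

```
   stratum        diagnosis n_pre median_pre n_post median_post chi_squared  p_value
1      LOW            MIMIC   198         10    343           8      5.9295 1.49e-02
2      LOW TIA_MINOR_STROKE   392          9    473           6     76.3836 2.34e-18
3 MODERATE            MIMIC   268          5    321           6     14.7787 1.21e-04
4 MODERATE TIA_MINOR_STROKE   508          5    401           5      0.0336 8.55e-01
5     HIGH            MIMIC    94          4     79           6      7.0556 7.90e-03
6     HIGH TIA_MINOR_STROKE   162          5     99           5      0.1797 6.72e-01
```

Each row compares the two eras within one ABCD2-stratum × diagnosis cell:
`median_*` are Kaplan–Meier median calendar days from symptom onset to unit
arrival (right-censored at 28 days), and the χ²/p columns are the Peto–Peto
Gehan–Wilcoxon test of the two survival curves. Low-stratum true-TIA
patients arrive a median 3 days earlier under the weighted queue, high-stratum
TIA patients are unchanged (already top-priority under ABCD triage), and
mimics gain less than their TIA counterparts — moderate and high mimics lose
priority. See the methods vignette (`vignettes/triage-methods.Rmd`) for why
the moderate-TIA median does not move under a deterministic ABCD priority
baseline.

## Command line

A thin CLI over the same functions is installed at `exec/tiaqueue`:

```sh
tiaqueue generate --n 500 --label POST_QUEUE --seed 1 --out referrals.csv
tiaqueue simulate --in referrals.csv --policy queue --capacity 5 --seed 1 --out arrivals.csv
tiaqueue experiment --config config.yaml --out-dir results/
```

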