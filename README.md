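# parrisk

External validation toolkit for points-based hospital readmission risk
scores, built around the PAR-Risk Score — a 12-item model predicting
30-day *potentially avoidable readmissions* (PAR) in older internal
medicine patients.

## Who this is for

Clinical epidemiologists and hospital data scientists who want to validate
a published points-based readmission score on their own EHR extract:
admissions, ICD-10 coded diagnoses, ATC-coded drug dispensings, potassium
lab values and prior-admission dates. Readmission adjudication itself
(e.g. the proprietary SQLape screening algorithm) is out of scope: the
binary PAR label is an input.

## What it computes

For each patient the 12 predictor flags at discharge — length of stay
> 4 days, admission in the previous 6 months, anaemia, hypertension,
heart failure, acute myocardial infarction, chronic ischaemic heart
disease, diabetes with organ damage, cancer, metastatic carcinoma,
in-stay opioid dispensing (ATC `N02A*`), and hyperkalaemia (serum K⁺
> 5.5 mmol/L in the last 7 days, last observation carried forward) — and
the raw score

&nbsp;&nbsp;&nbsp;&nbsp;*S* = Σⱼ wⱼ·xⱼ,

the sum of integer points *wⱼ* over predictors present. Validation then
follows the standard external-validation playbook:

- **Discrimination** — C statistic of the univariable logistic model
  logit P(Y=1) = α + β·S, with a DeLong 95% CI.
- **Accuracy** — Brier score, mean (yᵢ − p̂ᵢ)².
- **Global goodness of fit** — le Cessie–van Houwelingen–Copas–Hosmer
  unweighted sum-of-squares test: T = Σ(yᵢ − p̂ᵢ)², standardised by its
  estimated null mean and variance (coefficient-estimation corrected),
  referred to N(0,1).
- **Calibration** — observed vs predicted risk per score point, weighted
  by patient counts.
- **Risk stratification** — low/medium/high groups under original cuts
  (< 3, 3–10, > 10) and tertile-adapted cuts recomputed from the cohort;
  per-group odds ratios vs the low-risk reference (Woolf CIs),
  sensitivity/specificity/PPV/NPV, and observed vs mean predicted risk.
- **Missing-data sensitivity analyses** — hyperkalaemia set to 1 where
  potassium is entirely missing; dispensing-missing patients re-admitted
  with opioids forced to 0 or 1.

A seeded synthetic cohort generator emulates the published cohort
structure (predictor prevalences, ~5.7% PAR rate, 7.2% missing potassium,
1.5% missing dispensings) so the whole pipeline is testable without
patient data.

**Note on the bundled score table:** only the anaemia weight (2 points) of
the PAR-Risk Score is public in the validation paper's main text; the
bundled `par_risk_score_synthetic.yaml` is a clearly-labelled synthetic
stand-in. Supply your own transcription via
`read_score_definition()` to validate the real score.

## Worked example

```r
library(parrisk)

cfg    <- cohort_config(n_patients = 5985, seed = 42)
cohort <- generate_cohort(cfg)
dir    <- file.path(tempdir(), "demo")
write_cohort(cohort, dir)

res <- run_pipeline(dir, file.path(tempdir(), "demo_out"), seed = 42)
print(res$performance)
res$strata$adapted
```

```
[include] 5985 -> 5985 after inclusion criteria (>=48 h, age >=65)
[exclude] death: 285
[exclude] transfer: 752
[exclude] non_swiss: 572
[exclude] dispensing_missing: 52
[extract] 4324 predictor vectors, 251 PAR cases
[validate] C 0.604 (0.568-0.640), Brier 0.0542, GOF p 0.937
[stratify] adapted tertile cuts: 8 / 11

<performance_summary>
  C statistic 0.604 (95% CI 0.568-0.640)
  Brier score 0.054
  GOF (unweighted SS): z = -0.08, p = 0.937

# A tibble: 3 x 9
  threshold_set cut_low cut_high group  n_par n_nonpar odds_ratio ci_low ci_high
1 adapted             8       11 low       53     1408       1     NA      NA
2 adapted             8       11 medium    81     1413       1.52   1.07    2.17
3 adapted             8       11 high     117     1252       2.48   1.78    3.46
```

Reading this: of 5,985 simulated admissions, 4,324 survive the
exclusion cascade; the score discriminates weakly (C ≈ 0.60 — a randomly
chosen readmitted patient outscores a non-readmitted one 60% of the
time), the Brier score is dominated by the low 6% event rate, the GOF
test does not reject (the outcomes were generated from a compatible
model), and patients in the top tertile have ~2.5-fold higher odds of
readmission than the bottom tertile.

The run also writes `performance.csv`, `calibration.csv`, `strata.csv`,
`classification.csv`, `observed_predicted.csv`, `sensitivity.csv`,
`characteristics.csv`, `manifest.json` and `run.log` to the output
directory. A thin CLI wraps the same functions:

```sh
inst/cli/parrisk simulate --input cohort --seed 7
inst/cli/parrisk run --input cohort --out results
```

## Acceptance script

`scripts/acceptance.R` regenerates a seeded 5,985-patient synthetic
cohort, runs the complete pipeline on it (extraction, scoring, both
threshold sets, validation statistics, sensitivity variants) and writes a
JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
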