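---
title: "Validating points-based readmission risk scores with parrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating points-based readmission risk scores with parrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parrisk)
```

## The problem

Roughly one in twenty older internal-medicine patients in Swiss hospitals
experiences a *potentially avoidable readmission* (PAR) within 30 days of
discharge. Screening algorithms that label PARs (such as SQLape) work
only in retrospect, so points-based prediction scores are used to flag
high-risk patients *before* discharge. The PAR-Risk Score is one such
model: 12 binary predictors, each worth an integer number of points, with
the raw score being the sum of points for predictors present at
discharge, and cut-offs < 3 / 3–10 / > 10 defining low, medium and high
risk. A score developed in one hospital system rarely transports
unchanged; `parrisk` packages the external-validation workflow — predictor
extraction from EHR tables, scoring, stratification, and the standard
battery of validation statistics — so it can be rerun on any local
cohort.

## The model and its assumptions

Validation centres on the univariable logistic regression of the outcome
on the raw score,

$$\operatorname{logit} \Pr(Y_i = 1) = \alpha + \beta S_i,$$

fitted by maximum likelihood (IRLS, deviance tolerance $10^{-8}$, at most
100 iterations, covariance from the inverse observed information — the
textbook fit, delegated to `stats::glm`). From it:

* **C statistic.** $\Pr(S_{\text{case}} > S_{\text{control}})$ with ties
  counted $\tfrac12$; computed by the midrank algorithm, which agrees
  exactly with the $O(n^2)$ all-pairs definition (this identity is a
  standing test). Because $C$ is invariant under monotone transforms, the
  C of the fitted probabilities equals the C of the raw score. The 95% CI
  uses the DeLong structural-component variance; the validation paper this
  mirrors does not state its CI method, so DeLong is our documented
  default.
* **Brier score.** $n^{-1}\sum_i (y_i - \hat p_i)^2$. With a ~6% event
  rate even a useless model scores ≈ 0.054, so Brier is reported alongside
  discrimination, never instead of it.
* **Unweighted sum-of-squares goodness of fit**
  (le Cessie–van Houwelingen–Copas–Hosmer).
  $T = \sum_i (y_i - \hat p_i)^2$ with $\mathrm{E}[T] = \sum_i \hat p_i
  (1 - \hat p_i)$ and, writing $d_i = 1 - 2\hat p_i$ and
  $V = \operatorname{diag}(\hat p_i (1 - \hat p_i))$,
  $$\operatorname{Var}(T - \mathrm{E}[T]) =
    d^\top\!\left(V - V X (X^\top V X)^{-1} X^\top V\right) d,$$
  which accounts for the estimated coefficients; $z = (T -
  \mathrm{E}[T]) / \sqrt{\operatorname{Var}}$ is referred to a standard
  normal, two-sided. In the saturated limit the variance vanishes and $T
  = \mathrm{E}[T]$ exactly; we define $z = 0$ there. A 1,000-replicate
  null simulation keeps the type-I error of this implementation inside
  [0.03, 0.07] in the test suite.
* **Calibration.** One row per distinct score value: patients at that
  score, observed event proportion, and $\operatorname{logit}^{-1}(\alpha
  + \beta s)$; weights sum to the cohort size.

Group-level statistics come from the low/medium/high contingency table:
cross-product odds ratios against the low-risk reference with Woolf
intervals $\exp(\ln \widehat{OR} \pm z_{0.975}\sqrt{1/a + 1/b + 1/c +
1/d})$ — a hand check reproduces every published interval of the
validation study's contingency table at printed precision — and, for each
comparison group against low, sensitivity $a/(a+c)$, specificity
$d/(b+d)$, PPV $a/(a+b)$, NPV $d/(c+d)$. PPV and NPV are verified against
Bayes' rule at the restricted prevalence on every run of the test suite.
Coefficient CIs default to Wald; a profile-likelihood option exists
because sparse 2×2 tables (e.g. hyperkalaemia with 2 exposed cases) give
likelihood intervals visibly different from Woolf/Wald, and published
intervals for such rows are not always reproducible by either method.

## Predictor extraction rules

The extraction layer makes the published definitions operational; where
the prose is silent a choice had to be fixed once:

* *Length of stay > 4 days* is strict on exactly 96 elapsed hours;
  *at least 48 hours* (inclusion) is inclusive on exactly 48 h.
* *Admission in previous six months* means any prior discharge date in
  the 183 days before the index admission, window start inclusive. The
  source gives no day count; 183 days is our fixed reading of "six
  months".
* *Comorbidities* match ICD-10 codes by prefix after uppercasing and
  dot-stripping; malformed codes warn and are skipped. ICD-9 or local
  dialects are not mapped. Anaemia uses ICD-10 codes only (the validation
  study explicitly lacked haemoglobin values).
* *Opioids*: any dispensing with ATC code beginning `N02A` timestamped
  between admission and discharge inclusive. Free-text drug names are not
  parsed; inputs must be ATC-coded.
* *Hyperkalaemia*: potassium > 5.5 mmol/L (strict) among draws in the
  last 7 days of the stay; if that window is empty the single most recent
  earlier in-stay value is carried forward. Patients with no potassium
  at all are assumed normal (treated as not missing at random) and
  flagged `potassium_missing` for the sensitivity variant.
* *Exclusions* are evaluated in the fixed order death → transfer →
  non-Swiss → dispensing-missing so each patient is tallied exactly once;
  the source does not state an order, and the order only affects the
  tally attribution, never the retained set.

## Tertile-adapted thresholds

The adapted cuts regroup patients into tertiles of the raw score. On a
discrete score exact thirds are usually unattainable, so among candidate
integer cut pairs $(c_1, c_2)$ drawn from the observed score values we
choose the pair minimising $\max_g |n_g - n/3|$, breaking ties toward the
smaller $c_1$, then the smaller $c_2$. This is deterministic and is
checked against an independent exhaustive search in the tests. The
quantile convention that produced the original study's adapted cuts on
its own cohort cannot be verified without patient-level data; the minimax
rule is this package's documented choice, and on a uniform score
distribution it reproduces exact thirds.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` states a fixed world taken from the published cohort
tables: 5,985 eligible admissions; marginal predictor prevalences from
the patient-characteristics table (e.g. 73.8% stays > 4 days, 26.5%
opioids, 0.3% hyperkalaemia); outcome drawn from a logistic model whose
per-predictor log odds ratios are the logs of the published *unadjusted*
ORs — a convenience default, not a claim about the true joint model — and
whose intercept is calibrated by bisection (exact expectation over all
$2^{12}$ predictor configurations, tolerance $10^{-4}$) to a marginal
PAR rate of 5.7%; 7.2% of patients with no potassium value; 1.5% with
missing dispensing records. Death/transfer/non-Swiss exclusion triggers
default to 5% / 12% / 10%: the published flow diagram's per-reason
breakdown is not available in our source text, so these were chosen once
to land the simulated cascade near the published retained fraction
(8,252 → 5,985 ≈ 73%) and are documented here rather than tuned.

Every flag is materialised as raw records (a mapped ICD-10 code, an
in-stay `N02A` dispensing, a high potassium draw in — or carried forward
into — the final week, date arithmetic for the administrative flags),
plus deliberate decoys: unmapped diagnosis codes, non-opioid and
pre-admission opioid dispensings, non-potassium lab rows. Extraction on
the emitted tables reproduces the generator's ground-truth flags exactly
for fully observed patients, and this lossless round trip is an
acceptance-level test.

Predictors are generated *independently* (the source reports only
marginal prevalences), one admission per patient, and readmission
adjudication is not emulated. A green test suite therefore establishes
that the machinery is correct under the stated world — it does not
establish that the real cohort's statistics (C = 0.605, Brier = 0.053,
adapted cuts 12/25, the adjusted ORs) are reproduced; those require the
hospital's patient-level data and are deliberately replaced by
property-based checks: estimator-vs-oracle identities, null calibration
of the GOF statistic, and 95% CI coverage of all 12 generating log-ORs
within [0.92, 0.98] over 500 simulated cohorts of n = 20,000.

## Numerical and degenerate-input choices

* Scores are integers; non-integer point weights are rejected as
  mis-transcribed definitions.
* Risk-group bands are strict-below / inclusive-middle / strict-above,
  reading "< 3, 3–10, > 10" as integer bands.
* A zero cell in an odds-ratio table is an explicit error; the documented
  remedy (`continuity = TRUE`, 0.5 added to all four cells) is applied
  automatically inside `run_pipeline()` with a log note, so small
  simulated cohorts do not abort the report stage.
* Quasi-complete separation in a logistic fit is reported as
  non-convergence with a diagnostic rather than returning runaway
  estimates silently; rank-deficient designs name the collinear columns.
* The pipeline writes all outputs or none (staging directory moved into
  place on success), records no wall-clock timestamps, and draws all
  randomness from a single recorded seed, so reruns are byte-identical.

## Known limitations

* The bundled point table and comorbidity code lists are synthetic
  stand-ins (only the anaemia weight, 2 points, is public in our source);
  both files say so in their headers and should be replaced with
  transcriptions of the original supplements before validating the real
  score.
* Predictor correlation structure in real cohorts is unknown from
  published marginals; the generator's independence assumption makes the
  synthetic raw-score distribution narrower than a real one.
* Only one index admission per patient is modelled; multi-stay histories
  enter solely through the prior-admission flag.
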