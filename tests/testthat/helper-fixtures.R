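# Shared fixtures: published summary counts and small hand-built cohorts.

Sys.setenv(TZ = "UTC")

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# Unadjusted associations (validation cohort, n = 5,985; 340 PAR / 5,645
# non-PAR): exposed-case and exposed-noncase counts per predictor with the
# printed univariable odds ratio.
TABLE2 <- tibble::tribble(
  ~predictor,        ~par_exp, ~nonpar_exp, ~or_printed,
  "prior_adm_6m",         106,        1254,        1.59,
  "los_gt4",              269,        4146,        1.37,
  "anaemia",              101,        1134,        1.68,
  "heart_failure",        105,        1256,        1.56,
  "hypertension",         246,        3919,        1.15,
  "acute_mi",              16,         259,        1.03,
  "chronic_ihd",           92,        1420,        1.10,
  "diabetes_organ",        35,         432,        1.38,
  "cancer",                45,         584,        1.32,
  "metastatic_ca",         32,         376,        1.46,
  "opioids",              123,        1466,        1.62,
  "hyperkalaemia",          2,          14,        2.38
)
N_PAR <- 340L
N_NONPAR <- 5645L

# Risk-group contingency counts (PAR / non-PAR) under both threshold sets.
strata_original <- function() {
  build_strata_table(
    factor(rep(c("low", "medium", "high"), c(302, 2953, 2730)),
           levels = c("low", "medium", "high")),
    c(rep(1:0, c(9, 293)), rep(1:0, c(127, 2826)), rep(1:0, c(204, 2526)))
  )
}
strata_adapted <- function() {
  build_strata_table(
    factor(rep(c("low", "medium", "high"), c(2116, 1934, 1935)),
           levels = c("low", "medium", "high")),
    c(rep(1:0, c(72, 2044)), rep(1:0, c(116, 1818)), rep(1:0, c(152, 1783)))
  )
}

# One admission row with sensible defaults, overridable per test.
make_admission <- function(patient_id, age = 80,
                           admission_ts = ts_utc("2017-03-01 08:00:00"),
                           los_hours = 120,
                           residency = "Swiss", disposition = "home",
                           dispensing_available = TRUE, sex = "female") {
  tibble::tibble(
    patient_id = patient_id, age = age, sex = sex,
    admission_ts = admission_ts,
    discharge_ts = admission_ts + los_hours * 3600,
    residency = residency, disposition = disposition,
    dispensing_available = dispensing_available
  )
}

empty_tables <- function() {
  list(
    diagnoses = tibble::tibble(patient_id = character(0),
                               icd10_code = character(0)),
    dispensings = tibble::tibble(patient_id = character(0),
                                 atc_code = character(0),
                                 dispense_ts = ts_utc(character(0))),
    labs = tibble::tibble(patient_id = character(0), analyte = character(0),
                          value = numeric(0), unit = character(0),
                          draw_ts = ts_utc(character(0))),
    prior_admissions = tibble::tibble(patient_id = character(0),
                                      prior_discharge_ts = ts_utc(character(0)))
  )
}

# Materialise a hand-specified flag table as raw EHR records (deliberately
# simple and independent of generate_cohort): one canonical record per flag.
materialize_manual_cohort <- function(flags, par) {
  n <- nrow(flags)
  adm <- purrr::map_dfr(seq_len(n), function(i) {
    make_admission(flags$patient_id[i],
                   los_hours = if (flags$los_gt4[i]) 150 else 72)
  })
  tb <- empty_tables()
  code_for <- c(
    anaemia = "D50.0", hypertension = "I10", heart_failure = "I50.1",
    acute_mi = "I21.0", chronic_ihd = "I25.9", diabetes_organ = "E11.2",
    cancer = "C18.9", metastatic_ca = "C78.0"
  )
  for (i in seq_len(n)) {
    id <- flags$patient_id[i]
    a <- adm[adm$patient_id == id, ]
    for (p in names(code_for)) {
      if (flags[[p]][i]) {
        tb$diagnoses <- dplyr::bind_rows(tb$diagnoses, tibble::tibble(
          patient_id = id, icd10_code = unname(code_for[p])))
      }
    }
    if (flags$opioids[i]) {
      tb$dispensings <- dplyr::bind_rows(tb$dispensings, tibble::tibble(
        patient_id = id, atc_code = "N02AA01",
        dispense_ts = a$admission_ts + 3600))
    }
    tb$dispensings <- dplyr::bind_rows(tb$dispensings, tibble::tibble(
      patient_id = id, atc_code = "A02BC02",
      dispense_ts = a$admission_ts + 7200))
    k_val <- if (flags$hyperkalaemia[i]) 5.8 else 4.2
    tb$labs <- dplyr::bind_rows(tb$labs, tibble::tibble(
      patient_id = id, analyte = "potassium", value = k_val, unit = "mmol/L",
      draw_ts = a$discharge_ts - 3600))
    if (flags$prior_adm_6m[i]) {
      tb$prior_admissions <- dplyr::bind_rows(tb$prior_admissions,
        tibble::tibble(patient_id = id,
                       prior_discharge_ts = a$admission_ts - 30 * 86400))
    }
  }
  c(list(admissions = adm), tb,
    list(ground_truth = tibble::tibble(patient_id = flags$patient_id,
                                       par = par)))
}

# All-pairs concordance oracle: the O(n^2) definition, ties counted half.
cstat_oracle <- function(scores, y) {
  cases <- scores[y == 1]
  controls <- scores[y == 0]
  cmp <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Random predictor-flag tibble for property tests.
random_flags <- function(n, p = 0.3) {
  out <- tibble::tibble(patient_id = sprintf("R%03d", seq_len(n)))
  for (nm in parrisk:::PREDICTOR_NAMES) out[[nm]] <- runif(n) < p
  out$potassium_missing <- FALSE
  out$dispensing_missing <- FALSE
  out
}
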