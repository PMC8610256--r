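test_that("inclusion keeps stays >= 48 h and age >= 65, boundaries inclusive", {
  adm <- dplyr::bind_rows(
    make_admission("A", age = 64, los_hours = 72),   # too young
    make_admission("B", age = 65, los_hours = 48),   # exactly at both bounds
    make_admission("C", age = 90, los_hours = 47.9), # too short
    make_admission("D", age = 70, los_hours = 500)
  )
  kept <- apply_inclusion(adm)
  expect_equal(kept$patient_id, c("B", "D"))

  # 10 synthetic records, 3 violating the rules
  adm10 <- purrr::map_dfr(1:10, function(i) {
    make_admission(sprintf("P%02d", i),
                   age = ifelse(i <= 2, 60, 80),
                   los_hours = ifelse(i == 3, 24, 96))
  })
  expect_equal(nrow(apply_inclusion(adm10)), 7)
})

test_that("exclusion tallies each record once, in fixed reason order", {
  adm <- dplyr::bind_rows(
    make_admission("ok"),
    make_admission("dead", disposition = "death"),
    # death and non-Swiss: counted under death (first matching reason)
    make_admission("dead_foreign", disposition = "death",
                   residency = "non-Swiss"),
    make_admission("moved", disposition = "transfer"),
    make_admission("foreign", residency = "non-Swiss"),
    make_admission("nodrugs", dispensing_available = FALSE)
  )
  res <- apply_exclusion(adm)
  expect_equal(res$retained$patient_id, "ok")
  expect_equal(res$tally$reason,
               c("death", "transfer", "non_swiss", "dispensing_missing"))
  expect_equal(res$tally$n, c(2L, 1L, 1L, 1L))
  expect_equal(
    res$excluded$exclusion_reason[res$excluded$patient_id == "dead_foreign"],
    "death")
  expect_equal(sum(res$tally$n) + nrow(res$retained), nrow(adm))
})

test_that("length-of-stay flag is strict at 96 hours", {
  adm <- dplyr::bind_rows(
    make_admission("a", los_hours = 96),
    make_admission("b", los_hours = 96 + 1 / 60),
    make_admission("c", los_hours = 48)
  )
  expect_equal(extract_los_flag(adm), c(FALSE, TRUE, FALSE))
})

test_that("prior-admission window is 183 days, start inclusive", {
  adm <- make_admission("p")
  prior <- function(days_before) tibble::tibble(
    patient_id = "p",
    prior_discharge_ts = adm$admission_ts - days_before * 86400
  )
  expect_true(extract_prior_admission_flag(adm, prior(30)))
  expect_false(extract_prior_admission_flag(adm, prior(200)))
  expect_true(extract_prior_admission_flag(adm, prior(183)))
  expect_false(extract_prior_admission_flag(adm, prior(183.001)))
  expect_error(extract_prior_admission_flag(adm, prior(-1)),
               class = "parrisk_data_error")
})

test_that("comorbidity flags prefix-match normalised ICD-10 codes", {
  map <- read_comorbidity_map()
  adm <- make_admission("p")
  dx <- function(code) tibble::tibble(patient_id = "p", icd10_code = code)

  none <- extract_comorbidity_flags(adm, dx(character(0)), map)
  expect_false(any(unlist(none[-1])))

  expect_true(extract_comorbidity_flags(adm, dx("I50.9"), map)$heart_failure)
  expect_true(extract_comorbidity_flags(adm, dx("i509"), map)$heart_failure)
  # unmapped and malformed codes flag nothing; malformed codes warn
  expect_false(any(unlist(
    extract_comorbidity_flags(adm, dx("J18.9"), map)[-1])))
  expect_warning(
    res <- extract_comorbidity_flags(adm, dx(c("garbage", "I21.0")), map),
    "garbage")
  expect_true(res$acute_mi)
  # metastatic codes do not bleed into the primary-cancer flag
  one <- extract_comorbidity_flags(adm, dx("C78.1"), map)
  expect_true(one$metastatic_ca)
  expect_false(one$cancer)
})

test_that("opioid flag needs an ATC N02A dispensing inside the stay", {
  adm <- make_admission("p")
  disp <- function(atc, offset_h) tibble::tibble(
    patient_id = "p", atc_code = atc,
    dispense_ts = adm$admission_ts + offset_h * 3600
  )
  expect_true(extract_opioid_flag(adm, disp("N02AA01", 10)))
  expect_false(extract_opioid_flag(adm, disp("N02BE01", 10)))
  expect_false(extract_opioid_flag(adm, disp("N02AA01", -24)))
  expect_false(extract_opioid_flag(adm, disp("N02AA01", 200))) # after discharge

  missing_adm <- make_admission("p", dispensing_available = FALSE)
  expect_error(extract_opioid_flag(missing_adm, disp("N02AA01", 10)),
               class = "parrisk_missing_dispensing")
  expect_true(is.na(extract_opioid_flag(missing_adm, disp("N02AA01", 10),
                                        allow_missing = TRUE)))
})

test_that("hyperkalaemia uses the last 7 days with carry-forward", {
  adm <- make_admission("p", los_hours = 14 * 24) # two-week stay
  lab <- function(value, days_before_discharge) tibble::tibble(
    patient_id = "p", analyte = "potassium", value = value, unit = "mmol/L",
    draw_ts = adm$discharge_ts - days_before_discharge * 86400
  )
  # strict threshold: 5.5 exactly is normal
  expect_false(extract_hyperkalaemia_flag(adm, lab(5.5, 0.5))$hyperkalaemia)
  expect_true(extract_hyperkalaemia_flag(adm, lab(5.6, 0.5))$hyperkalaemia)
  # carry-forward: high value 10 days out, nothing later
  expect_true(extract_hyperkalaemia_flag(adm, lab(5.6, 10))$hyperkalaemia)
  # a later normal value supersedes the old high one
  both <- dplyr::bind_rows(lab(5.6, 10), lab(4.0, 2))
  expect_false(extract_hyperkalaemia_flag(adm, both)$hyperkalaemia)
  # no potassium at all: assumed normal, flagged missing
  res <- extract_hyperkalaemia_flag(adm, lab(5, 1)[0, ])
  expect_false(res$hyperkalaemia)
  expect_true(res$potassium_missing)
  # non-potassium analytes are ignored
  na_lab <- lab(6.5, 1)
  na_lab$analyte <- "sodium"
  res2 <- extract_hyperkalaemia_flag(adm, na_lab)
  expect_false(res2$hyperkalaemia)
  expect_true(res2$potassium_missing)
  bad <- lab(-1, 1)
  expect_error(extract_hyperkalaemia_flag(adm, bad),
               class = "parrisk_data_error")
})

test_that("carry-forward is idempotent when a window value exists", {
  adm <- make_admission("p", los_hours = 20 * 24)
  lab <- function(value, days_before) tibble::tibble(
    patient_id = "p", analyte = "potassium", value = value, unit = "mmol/L",
    draw_ts = adm$discharge_ts - days_before * 86400
  )
  set.seed(21)
  for (i in 1:20) {
    in_window <- lab(round(runif(1, 3.5, 7), 1), runif(1, 0, 6.9))
    flag1 <- extract_hyperkalaemia_flag(adm, in_window)$hyperkalaemia
    with_history <- dplyr::bind_rows(
      in_window, lab(round(runif(1, 3.5, 7), 1), runif(1, 8, 18)))
    flag2 <- extract_hyperkalaemia_flag(adm, with_history)$hyperkalaemia
    expect_identical(flag1, flag2)
  }
})

test_that("extraction is invariant to record order", {
  co <- generate_cohort(cohort_config(n_patients = 150, seed = 5))
  base <- extract_predictors(co)
  shuffled <- co
  set.seed(99)
  for (tb in c("diagnoses", "dispensings", "labs", "prior_admissions")) {
    shuffled[[tb]] <- shuffled[[tb]][sample(nrow(shuffled[[tb]])), ]
  }
  expect_equal(extract_predictors(shuffled), base)
})

test_that("sensitivity variants flip exactly the missing subsets", {
  set.seed(31)
  pred <- random_flags(60)
  pred$potassium_missing <- runif(60) < 0.2
  pred$hyperkalaemia[pred$potassium_missing] <- FALSE
  excl <- random_flags(5)
  excl$patient_id <- sprintf("X%02d", 1:5)
  excl$dispensing_missing <- TRUE
  excl$opioids <- NA

  v <- sensitivity_variants(pred, excl)
  expect_named(v, c("base", "potassium_to_1", "opioids_to_0", "opioids_to_1"))
  expect_identical(v$base, pred)
  flipped <- v$potassium_to_1$hyperkalaemia != pred$hyperkalaemia
  expect_identical(flipped, pred$potassium_missing & !pred$hyperkalaemia)
  # everything but hyperkalaemia untouched
  expect_equal(v$potassium_to_1[setdiff(names(pred), "hyperkalaemia")],
                   pred[setdiff(names(pred), "hyperkalaemia")])
  expect_equal(nrow(v$opioids_to_0), 65)
  extra0 <- dplyr::anti_join(v$opioids_to_0, pred, by = "patient_id")
  extra1 <- dplyr::anti_join(v$opioids_to_1, pred, by = "patient_id")
  expect_false(any(extra0$opioids))
  expect_true(all(extra1$opioids))
  # B and C differ only in the re-admitted patients' opioid flag
  diff_rows <- v$opioids_to_0$opioids != v$opioids_to_1$opioids
  expect_setequal(v$opioids_to_0$patient_id[diff_rows], excl$patient_id)

  no_missing <- random_flags(20)
  v2 <- sensitivity_variants(no_missing)
  for (nm in names(v2)) expect_equal(v2[[nm]], no_missing)
})

test_that("extracted prevalences converge to configured prevalences", {
  cfg <- cohort_config(n_patients = 10000, seed = 17,
                       exclusion_rates = c(death = 0, transfer = 0,
                                           non_swiss = 0),
                       missing_dispensing_rate = 0)
  co <- generate_cohort(cfg)
  pred <- extract_predictors(co)
  n <- nrow(pred)
  for (p in parrisk:::PREDICTOR_NAMES) {
    prev <- cfg$prevalence[[p]]
    se <- sqrt(prev * (1 - prev) / n)
    expect_lt(abs(mean(pred[[p]]) - prev), 4 * se + 1e-9)
  }
})
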