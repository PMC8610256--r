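# Defaults: marginal predictor prevalences and unadjusted odds ratios of the
# published external-validation cohort (n = 5,985, 5.7% PAR rate).
DEFAULT_PREVALENCE <- c(
  los_gt4 = 0.738, prior_adm_6m = 0.227, anaemia = 0.206,
  hypertension = 0.696, heart_failure = 0.227, acute_mi = 0.046,
  chronic_ihd = 0.253, diabetes_organ = 0.078, cancer = 0.105,
  metastatic_ca = 0.068, opioids = 0.265, hyperkalaemia = 0.003
)

DEFAULT_UNADJUSTED_OR <- c(
  los_gt4 = 1.37, prior_adm_6m = 1.59, anaemia = 1.68,
  hypertension = 1.15, heart_failure = 1.56, acute_mi = 1.03,
  chronic_ihd = 1.10, diabetes_organ = 1.38, cancer = 1.32,
  metastatic_ca = 1.46, opioids = 1.62, hyperkalaemia = 2.38
)

#' Configuration of the synthetic EHR cohort generator
#'
#' Defaults restate the published validation cohort: predictor prevalences
#' from the patient-characteristics table, per-predictor effects as the
#' logs of the published unadjusted odds ratios (a convenience default, not
#' a claim about the true joint model), a marginal PAR rate of 5.7%, 7.2%
#' of patients with no potassium measurement, 1.5% with missing dispensing
#' records, and exclusion-trigger rates chosen so a simulated cascade lands
#' near the published retained fraction.
#'
#' @param n_patients Number of eligible index admissions to simulate.
#' @param prevalence Named probabilities for the 12 predictor flags.
#' @param log_or Named per-predictor log odds ratios of the outcome model.
#' @param target_par_rate Marginal outcome probability the intercept is
#'   calibrated to (ignored when `intercept` is given).
#' @param intercept Optional fixed model intercept (log-odds).
#' @param missing_potassium_rate Probability of no potassium value at all.
#' @param missing_dispensing_rate Probability of an entirely missing
#'   dispensing record.
#' @param exclusion_rates Named probabilities for `death`, `transfer`,
#'   `non_swiss` exclusion triggers (mutually exclusive draws).
#' @param seed Integer RNG seed; all generator randomness flows from it.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 5985,
                          prevalence = DEFAULT_PREVALENCE,
                          log_or = log(DEFAULT_UNADJUSTED_OR),
                          target_par_rate = 0.057,
                          intercept = NULL,
                          missing_potassium_rate = 0.072,
                          missing_dispensing_rate = 0.015,
                          exclusion_rates = c(death = 0.05, transfer = 0.12,
                                              non_swiss = 0.10),
                          seed = 1L) {
  stopifnot(n_patients >= 1,
            all(prevalence >= 0 & prevalence <= 1),
            setequal(names(prevalence), PREDICTOR_NAMES),
            setequal(names(log_or), PREDICTOR_NAMES),
            missing_potassium_rate >= 0, missing_potassium_rate <= 1,
            missing_dispensing_rate >= 0, missing_dispensing_rate <= 1,
            all(exclusion_rates >= 0), sum(exclusion_rates) < 1)
  structure(list(
    n_patients = as.integer(n_patients),
    prevalence = prevalence[PREDICTOR_NAMES],
    log_or = log_or[PREDICTOR_NAMES],
    target_par_rate = target_par_rate,
    intercept = intercept,
    missing_potassium_rate = missing_potassium_rate,
    missing_dispensing_rate = missing_dispensing_rate,
    exclusion_rates = exclusion_rates,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Read a generator configuration from YAML or JSON
#'
#' Keys mirror the arguments of [cohort_config()]; absent keys keep their
#' defaults. `prevalence` and `log_or` are named maps.
#'
#' @param path Config file path.
#' @param seed Optional seed overriding the file's (the CLI `--seed` flag).
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path, seed = NULL) {
  raw <- read_structured(path)
  args <- list()
  for (k in c("n_patients", "target_par_rate", "intercept",
              "missing_potassium_rate", "missing_dispensing_rate", "seed")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  if (!is.null(raw$prevalence)) args$prevalence <- unlist(raw$prevalence)
  if (!is.null(raw$log_or)) args$log_or <- unlist(raw$log_or)
  if (!is.null(raw$exclusion_rates)) {
    args$exclusion_rates <- unlist(raw$exclusion_rates)
  }
  if (!is.null(seed)) args$seed <- seed
  do.call(cohort_config, args)
}

#' Calibrate the outcome-model intercept to a marginal event rate
#'
#' With independent Bernoulli predictors the marginal event rate at
#' intercept \eqn{\alpha} is the exact expectation of
#' \eqn{\mathrm{logit}^{-1}(\alpha + \sum_j \beta_j x_j)} over the
#' \eqn{2^{12}} predictor configurations. The intercept is found by
#' bisection until that expectation is within `tol` of `target_rate`.
#'
#' @param prevalence Named predictor prevalences.
#' @param log_or Named per-predictor log odds ratios.
#' @param target_rate Target marginal event probability in (0, 1).
#' @param tol Bisection tolerance on the event rate, default `1e-4`.
#' @return The calibrated intercept (log-odds scale).
#' @examples
#' calibrate_intercept(c(a = 0.5), c(a = 0), 0.057) # == qlogis(0.057)
#' @export
calibrate_intercept <- function(prevalence, log_or, target_rate, tol = 1e-4) {
  if (target_rate <= 0 || target_rate >= 1) {
    abort("`target_rate` must lie strictly between 0 and 1.",
          class = "parrisk_config_error")
  }
  stopifnot(setequal(names(prevalence), names(log_or)))
  log_or <- log_or[names(prevalence)]
  k <- length(prevalence)
  bits <- as.matrix(expand.grid(rep(list(0:1), k)))
  w <- rep(1, nrow(bits))
  for (j in seq_len(k)) {
    w <- w * ifelse(bits[, j] == 1, prevalence[j], 1 - prevalence[j])
  }
  lin <- as.numeric(bits %*% log_or)
  rate_at <- function(alpha) sum(w * plogis(alpha + lin))
  lo <- qlogis(target_rate) - abs(sum(log_or)) - 1
  hi <- qlogis(target_rate) + 1
  while (rate_at(lo) > target_rate) lo <- lo - 1
  while (rate_at(hi) < target_rate) hi <- hi + 1
  repeat {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (abs(r - target_rate) < tol) return(mid)
    if (r < target_rate) lo <- mid else hi <- mid
  }
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic EHR cohort
#'
#' Draws independent predictor flags at the configured prevalences, the
#' outcome from the logistic model
#' \eqn{y \sim \mathrm{Bern}(\mathrm{logit}^{-1}(\alpha + \sum_j \beta_j x_j))},
#' and materialises every flag as raw EHR records: an ICD-10 code drawn
#' from the comorbidity map for each comorbidity, an in-stay ATC `N02A`
#' dispensing for opioid use, a potassium value above 5.5 mmol/L in (or
#' carried forward into) the final seven days for hyperkalaemia, and
#' length-of-stay / prior-discharge date arithmetic consistent with the
#' administrative flags. Potassium and dispensing missingness and
#' death/transfer/non-Swiss exclusion triggers are injected at the
#' configured rates. Fully reproducible for a fixed seed; the caller's RNG
#' state is left untouched.
#'
#' @param config A [cohort_config()].
#' @param map Comorbidity map used to materialise (and later re-extract)
#'   diagnosis codes.
#' @return List of class `synthetic_cohort` with the tibbles `admissions`,
#'   `diagnoses`, `dispensings`, `labs`, `prior_admissions` and
#'   `ground_truth` (per-patient true flags, missingness, true outcome
#'   probability `p_true`, outcome `par`, `exclusion_reason`).
#' @export
generate_cohort <- function(config = cohort_config(),
                            map = read_comorbidity_map()) {
  missing_preds <- setdiff(names(map), names(config$prevalence))
  needed <- setdiff(PREDICTOR_NAMES,
                    c("los_gt4", "prior_adm_6m", "opioids", "hyperkalaemia"))
  if (!all(needed %in% names(map))) {
    abort(sprintf("comorbidity map lacks predictor(s): %s",
                  paste(setdiff(needed, names(map)), collapse = ", ")),
          class = "parrisk_config_error")
  }
  with_preserved_seed(config$seed, generate_cohort_impl(config, map))
}

generate_cohort_impl <- function(config, map) {
  n <- config$n_patients
  id <- sprintf("P%06d", seq_len(n))
  prev <- config$prevalence
  beta <- config$log_or

  # predictor flags; hyperkalaemia and total potassium missingness are
  # mutually exclusive (a measured high value cannot be absent)
  flags <- tibble::tibble(patient_id = id)
  for (p in PREDICTOR_NAMES) flags[[p]] <- runif(n) < prev[[p]]
  potassium_missing <- runif(n) < config$missing_potassium_rate
  potassium_missing[flags$hyperkalaemia] <- FALSE
  dispensing_missing <- runif(n) < config$missing_dispensing_rate

  alpha <- config$intercept %||%
    calibrate_intercept(prev, beta, config$target_par_rate)
  xmat <- as.matrix(as.data.frame(flags[PREDICTOR_NAMES])) * 1
  p_true <- plogis(alpha + as.numeric(xmat %*% beta))
  par <- as.integer(runif(n) < p_true)

  # exclusion triggers (mutually exclusive categorical draw)
  er <- config$exclusion_rates
  u <- runif(n)
  disposition <- rep("home", n)
  disposition[u < er[["death"]]] <- "death"
  disposition[u >= er[["death"]] & u < er[["death"]] + er[["transfer"]]] <- "transfer"
  residency <- ifelse(
    u >= er[["death"]] + er[["transfer"]] &
      u < er[["death"]] + er[["transfer"]] + er[["non_swiss"]],
    "non-Swiss", "Swiss")
  exclusion_reason <- rep(NA_character_, n)
  exclusion_reason[disposition == "death"] <- "death"
  exclusion_reason[is.na(exclusion_reason) & disposition == "transfer"] <- "transfer"
  exclusion_reason[is.na(exclusion_reason) & residency == "non-Swiss"] <- "non_swiss"
  exclusion_reason[is.na(exclusion_reason) & dispensing_missing] <- "dispensing_missing"

  # admission window ~ Dec 2016 .. Nov 2018, whole-second timestamps
  t0 <- as.POSIXct("2016-12-01 00:00:00", tz = "UTC")
  admission_ts <- t0 + round(runif(n, 0, 700 * 86400))
  los_hours <- ifelse(flags$los_gt4, runif(n, 97, 480), runif(n, 48.5, 95.5))
  discharge_ts <- admission_ts + round(los_hours * 3600)
  age <- pmax(65, round(stats::rnorm(n, 79.7, 7.7)))
  sex <- ifelse(runif(n) < 0.469, "male", "female")

  admissions <- tibble::tibble(
    patient_id = id, age = age, sex = sex,
    admission_ts = admission_ts, discharge_ts = discharge_ts,
    residency = residency, disposition = disposition,
    dispensing_available = !dispensing_missing
  )

  # diagnoses: one mapped code per true comorbidity + unmapped noise codes
  noise_pool <- c("J18.9", "N39.0", "R55", "F05.9", "M25.5", "K59.0", "G47.3")
  como_names <- intersect(PREDICTOR_NAMES, names(map))
  dx <- vector("list", length(como_names) + 1)
  for (i in seq_along(como_names)) {
    pred <- como_names[i]
    has <- which(flags[[pred]])
    if (length(has) == 0) next
    prefix <- map[[pred]][sample.int(length(map[[pred]]), length(has),
                                     replace = TRUE)]
    dx[[i]] <- tibble::tibble(
      patient_id = id[has],
      icd10_code = paste0(prefix, ".", sample(0:9, length(has), replace = TRUE))
    )
  }
  n_noise <- sample(0:3, n, replace = TRUE)
  dx[[length(dx)]] <- tibble::tibble(
    patient_id = rep(id, n_noise),
    icd10_code = sample(noise_pool, sum(n_noise), replace = TRUE)
  )
  diagnoses <- dplyr::arrange(dplyr::bind_rows(dx), .data$patient_id,
                              .data$icd10_code)

  dispensings <- make_dispensings(id, admissions, flags$opioids,
                                  dispensing_missing)
  labs <- make_labs(id, admissions, flags$hyperkalaemia, potassium_missing)
  prior_admissions <- make_priors(id, admissions, flags$prior_adm_6m)

  ground_truth <- dplyr::bind_cols(
    flags,
    tibble::tibble(potassium_missing = potassium_missing,
                   dispensing_missing = dispensing_missing,
                   p_true = p_true, par = par,
                   exclusion_reason = exclusion_reason)
  )

  structure(list(
    admissions = admissions, diagnoses = diagnoses, dispensings = dispensings,
    labs = labs, prior_admissions = prior_admissions,
    ground_truth = ground_truth,
    intercept = alpha, config = config
  ), class = c("synthetic_cohort", "list"))
}

make_dispensings <- function(id, admissions, opioid_flag, dispensing_missing) {
  n <- length(id)
  nonopioid_pool <- c("A02BC02", "C07AB07", "B01AC06", "N02BE01", "C10AA05",
                      "A06AD11", "C03CA01")
  opioid_pool <- c("N02AA01", "N02AX02", "N02AB03", "N02AA05")
  los_s <- as.numeric(admissions$discharge_ts - admissions$admission_ts,
                      units = "secs")
  rows <- vector("list", 3)
  n_other <- sample(1:4, n, replace = TRUE)
  keep <- rep(!dispensing_missing, n_other)
  rows[[1]] <- tibble::tibble(
    patient_id = rep(id, n_other),
    atc_code = sample(nonopioid_pool, sum(n_other), replace = TRUE),
    dispense_ts = rep(admissions$admission_ts, n_other) +
      round(runif(sum(n_other)) * rep(los_s, n_other))
  )[keep, ]
  has_op <- which(opioid_flag & !dispensing_missing)
  rows[[2]] <- tibble::tibble(
    patient_id = id[has_op],
    atc_code = sample(opioid_pool, length(has_op), replace = TRUE),
    dispense_ts = admissions$admission_ts[has_op] +
      round(runif(length(has_op)) * los_s[has_op])
  )
  # pre-admission opioid for some opioid-negative patients: must not flag
  pre_op <- which(!opioid_flag & !dispensing_missing & runif(n) < 0.05)
  rows[[3]] <- tibble::tibble(
    patient_id = id[pre_op],
    atc_code = sample(opioid_pool, length(pre_op), replace = TRUE),
    dispense_ts = admissions$admission_ts[pre_op] -
      round(runif(length(pre_op), 2, 30) * 86400)
  )
  dplyr::arrange(dplyr::bind_rows(rows), .data$patient_id, .data$dispense_ts)
}

make_labs <- function(id, admissions, hyper_flag, potassium_missing) {
  n <- length(id)
  adm <- admissions$admission_ts
  dis <- admissions$discharge_ts
  los_s <- as.numeric(dis - adm, units = "secs")
  window_start <- pmax(as.numeric(adm), as.numeric(dis) - 7 * 86400)
  rows <- vector("list", 4)
  # normal potassium draws for everyone with measurements
  measured <- which(!potassium_missing)
  rows[[1]] <- tibble::tibble(
    patient_id = id[measured],
    analyte = "potassium",
    value = round(runif(length(measured), 3.5, 5.0), 1),
    unit = "mmol/L",
    draw_ts = adm[measured] + round(runif(length(measured)) * los_s[measured])
  )
  # hyperkalaemic value: usually inside the 7-day window, sometimes only
  # before it (exercising carry-forward); pre-window placement needs a stay
  # longer than the window and removal of any later normal draws
  hy <- which(hyper_flag)
  if (length(hy) > 0) {
    locf <- runif(length(hy)) < 0.3 & window_start[hy] > as.numeric(adm[hy]) + 3600
    t_hy <- numeric(length(hy))
    t_hy[!locf] <- window_start[hy][!locf] +
      runif(sum(!locf)) * (as.numeric(dis[hy]) - window_start[hy])[!locf]
    t_hy[locf] <- as.numeric(adm[hy])[locf] +
      runif(sum(locf)) * (window_start[hy] - as.numeric(adm[hy]))[locf]
    rows[[2]] <- tibble::tibble(
      patient_id = id[hy],
      analyte = "potassium",
      value = round(runif(length(hy), 5.6, 7.0), 1),
      unit = "mmol/L",
      draw_ts = as.POSIXct(round(t_hy), origin = "1970-01-01", tz = "UTC")
    )
    # drop normal draws at/after the carry-forward value (it must be the
    # patient's most recent)
    locf_tbl <- rows[[2]][locf, c("patient_id", "draw_ts")]
    names(locf_tbl)[2] <- "hy_ts"
    r1 <- dplyr::left_join(rows[[1]], locf_tbl, by = "patient_id")
    rows[[1]] <- dplyr::select(
      r1[is.na(r1$hy_ts) | r1$draw_ts < r1$hy_ts, ], -"hy_ts")
  }
  # non-potassium analyte rows (must be ignored by extraction)
  na_idx <- which(runif(n) < 0.5)
  rows[[3]] <- tibble::tibble(
    patient_id = id[na_idx],
    analyte = "sodium",
    value = round(runif(length(na_idx), 133, 146), 0),
    unit = "mmol/L",
    draw_ts = adm[na_idx] + round(runif(length(na_idx)) * los_s[na_idx])
  )
  dplyr::arrange(dplyr::bind_rows(rows), .data$patient_id, .data$analyte,
                 .data$draw_ts)
}

make_priors <- function(id, admissions, prior_flag) {
  n <- length(id)
  adm <- admissions$admission_ts
  rows <- vector("list", 2)
  has <- which(prior_flag)
  rows[[1]] <- tibble::tibble(
    patient_id = id[has],
    prior_discharge_ts = adm[has] - round(runif(length(has), 1, 180) * 86400)
  )
  # distant priors outside the 183-day window for some flag-negative patients
  old <- which(!prior_flag & runif(n) < 0.3)
  rows[[2]] <- tibble::tibble(
    patient_id = id[old],
    prior_discharge_ts = adm[old] - round(runif(length(old), 200, 400) * 86400)
  )
  dplyr::arrange(dplyr::bind_rows(rows), .data$patient_id,
                 .data$prior_discharge_ts)
}

#' Write a synthetic cohort to CSV tables
#'
#' Emits the exact CSV schemas consumed by [read_cohort()] plus
#' `ground_truth.csv`, with ISO-8601 UTC timestamps.
#'
#' @param cohort A [generate_cohort()] result (or compatible list).
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tbl in c("admissions", "diagnoses", "dispensings", "labs",
                "prior_admissions", "ground_truth")) {
    readr::write_csv(cohort[[tbl]], file.path(dir, paste0(tbl, ".csv")))
  }
  invisible(dir)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients (seed %d)\n",
              nrow(x$admissions), x$config$seed))
  cat(sprintf("  PAR rate %.3f, intercept %.3f\n",
              mean(x$ground_truth$par), x$intercept))
  invisible(x)
}
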