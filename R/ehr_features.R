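#' Read an EHR-style cohort from CSV tables
#'
#' Expects the five-table layout emitted by [generate_cohort()] /
#' [write_cohort()]: `admissions.csv`, `diagnoses.csv`, `dispensings.csv`,
#' `labs.csv` and `prior_admissions.csv`, with ISO-8601 timestamps (parsed
#' as UTC). Missing dispensing records are signalled per patient by the
#' `dispensing_available` flag in `admissions.csv`, not by an absent row.
#'
#' @param dir Directory holding the CSV files.
#' @return Named list of tibbles: `admissions`, `diagnoses`, `dispensings`,
#'   `labs`, `prior_admissions` (plus `ground_truth` when present).
#' @export
read_cohort <- function(dir) {
  path <- function(f) file.path(dir, f)
  ts <- function(x) readr::col_datetime(format = "")
  cohort <- list(
    admissions = readr::read_csv(path("admissions.csv"), col_types = readr::cols(
      patient_id = readr::col_character(), age = readr::col_double(),
      sex = readr::col_character(), admission_ts = ts(), discharge_ts = ts(),
      residency = readr::col_character(), disposition = readr::col_character(),
      dispensing_available = readr::col_logical()
    )),
    diagnoses = readr::read_csv(path("diagnoses.csv"), col_types = readr::cols(
      patient_id = readr::col_character(), icd10_code = readr::col_character()
    )),
    dispensings = readr::read_csv(path("dispensings.csv"), col_types = readr::cols(
      patient_id = readr::col_character(), atc_code = readr::col_character(),
      dispense_ts = ts()
    )),
    labs = readr::read_csv(path("labs.csv"), col_types = readr::cols(
      patient_id = readr::col_character(), analyte = readr::col_character(),
      value = readr::col_double(), unit = readr::col_character(), draw_ts = ts()
    )),
    prior_admissions = readr::read_csv(path("prior_admissions.csv"),
      col_types = readr::cols(
        patient_id = readr::col_character(), prior_discharge_ts = ts()
      ))
  )
  gt <- path("ground_truth.csv")
  if (file.exists(gt)) {
    cohort$ground_truth <- readr::read_csv(gt, col_types = readr::cols(
      patient_id = readr::col_character(), .default = readr::col_guess()
    ))
  }
  bad <- with(cohort$admissions, discharge_ts < admission_ts)
  if (any(bad)) {
    abort(sprintf("discharge before admission for patient(s): %s",
                  paste(cohort$admissions$patient_id[bad], collapse = ", ")),
          class = "parrisk_data_error")
  }
  cohort
}

#' Apply the cohort inclusion criteria
#'
#' Retains index admissions of patients aged 65 years or older whose length
#' of stay was at least 48 hours (both boundaries inclusive, elapsed time).
#'
#' @param admissions Admissions tibble (see [read_cohort()]).
#' @return Filtered admissions tibble.
#' @export
apply_inclusion <- function(admissions) {
  los_h <- as.numeric(difftime(admissions$discharge_ts,
                               admissions$admission_ts, units = "hours"))
  dplyr::filter(admissions, admissions$age >= 65, los_h >= 48)
}

EXCLUSION_REASONS <- c("death", "transfer", "non_swiss", "dispensing_missing")

#' Apply the cohort exclusion criteria
#'
#' Removes admissions ending in death before discharge or transfer to
#' another hospital, non-Swiss residents, and patients whose drug dispensing
#' records are missing entirely (knowledge of opioid intake is required by
#' the score). Reasons are evaluated in the fixed order death, transfer,
#' non-Swiss, dispensing-missing, and each record is tallied once at the
#' first matching reason.
#'
#' @param admissions Admissions tibble.
#' @return List with `retained` (tibble), `excluded` (tibble with an added
#'   `exclusion_reason` column) and `tally` (tibble `reason`, `n` in fixed
#'   order, zero rows retained).
#' @export
apply_exclusion <- function(admissions) {
  reason <- rep(NA_character_, nrow(admissions))
  hit <- function(cond) is.na(reason) & cond
  reason[hit(admissions$disposition == "death")] <- "death"
  reason[hit(admissions$disposition == "transfer")] <- "transfer"
  reason[hit(admissions$residency != "Swiss")] <- "non_swiss"
  reason[hit(!admissions$dispensing_available)] <- "dispensing_missing"
  counts <- vapply(EXCLUSION_REASONS,
                   function(r) sum(reason == r, na.rm = TRUE), integer(1))
  tally <- tibble::tibble(reason = EXCLUSION_REASONS, n = unname(counts))
  list(
    retained = admissions[is.na(reason), , drop = FALSE],
    excluded = dplyr::mutate(admissions[!is.na(reason), , drop = FALSE],
                             exclusion_reason = reason[!is.na(reason)]),
    tally = tally
  )
}

#' Length-of-stay predictor flag
#'
#' `TRUE` iff the stay exceeded four days (96 hours) of elapsed time,
#' strictly: exactly 96 hours is `FALSE`.
#'
#' @param admissions Admissions tibble.
#' @return Logical vector aligned with the rows of `admissions`.
#' @export
extract_los_flag <- function(admissions) {
  los_h <- as.numeric(difftime(admissions$discharge_ts,
                               admissions$admission_ts, units = "hours"))
  los_h > 96
}

#' Admission-in-previous-six-months predictor flag
#'
#' `TRUE` iff any prior discharge date falls within the 183 days before the
#' index admission, window start inclusive, index admission itself excluded:
#' `admission_ts - 183 days <= prior < admission_ts`.
#'
#' @param admissions Admissions tibble.
#' @param prior_admissions Tibble with `patient_id`, `prior_discharge_ts`.
#' @param window_days Look-back window, default 183 days ("six months").
#' @return Logical vector aligned with the rows of `admissions`.
#' @export
extract_prior_admission_flag <- function(admissions, prior_admissions,
                                         window_days = 183) {
  joined <- dplyr::inner_join(
    dplyr::select(admissions, "patient_id", "admission_ts"),
    prior_admissions, by = "patient_id", relationship = "many-to-many"
  )
  if (nrow(joined) > 0 && any(joined$prior_discharge_ts >= joined$admission_ts)) {
    bad <- unique(joined$patient_id[joined$prior_discharge_ts >= joined$admission_ts])
    abort(sprintf("prior discharge on/after index admission for patient(s): %s",
                  paste(bad, collapse = ", ")), class = "parrisk_data_error")
  }
  flagged <- joined |>
    dplyr::filter(.data$prior_discharge_ts >=
                    .data$admission_ts - lubridate::ddays(window_days)) |>
    dplyr::distinct(.data$patient_id)
  admissions$patient_id %in% flagged$patient_id
}

#' Read a comorbidity-to-ICD-10 prefix map
#'
#' @param path YAML or JSON file mapping predictor name to a non-empty list
#'   of ICD-10 code prefixes. Defaults to the bundled synthetic stand-in
#'   built from standard ICD-10 chapter ranges.
#' @return Named list of character vectors.
#' @export
read_comorbidity_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "comorbidity_map_synthetic.yaml",
                                package = "parrisk", mustWork = TRUE)
  map <- read_structured(path)
  map <- lapply(map, function(x) toupper(unlist(x)))
  empty <- names(map)[lengths(map) == 0]
  if (length(empty) > 0) {
    abort(sprintf("comorbidity map has empty prefix list(s): %s",
                  paste(empty, collapse = ", ")), class = "parrisk_config_error")
  }
  map
}

#' Normalise ICD-10 codes
#'
#' Uppercases and strips dots. Codes that do not start with a letter
#' followed by two digits after normalisation are malformed: a warning names
#' them and they are dropped.
#'
#' @param codes Character vector of raw ICD-10 codes.
#' @return Character vector of normalised codes (malformed entries removed).
#' @export
normalize_icd10 <- function(codes) {
  norm <- gsub(".", "", toupper(trimws(codes)), fixed = TRUE)
  ok <- grepl("^[A-Z][0-9]{2}", norm)
  if (any(!ok)) {
    warn(sprintf("skipping malformed ICD-10 code(s): %s",
                 paste(unique(codes[!ok]), collapse = ", ")))
  }
  norm[ok]
}

#' Comorbidity predictor flags from diagnosis codes
#'
#' A comorbidity flag is `TRUE` iff any of the patient's diagnosis codes,
#' uppercased and dot-stripped, starts with any of the mapped ICD-10
#' prefixes for that predictor.
#'
#' @param admissions Admissions tibble (defines the patient set and order).
#' @param diagnoses Tibble with `patient_id`, `icd10_code`.
#' @param map Comorbidity map from [read_comorbidity_map()].
#' @return Tibble with `patient_id` and one logical column per map entry.
#' @export
extract_comorbidity_flags <- function(admissions, diagnoses,
                                      map = read_comorbidity_map()) {
  norm <- gsub(".", "", toupper(trimws(diagnoses$icd10_code)), fixed = TRUE)
  ok <- grepl("^[A-Z][0-9]{2}", norm)
  if (any(!ok)) {
    warn(sprintf("skipping malformed ICD-10 code(s): %s",
                 paste(unique(diagnoses$icd10_code[!ok]), collapse = ", ")))
  }
  dx <- tibble::tibble(patient_id = diagnoses$patient_id[ok], code = norm[ok])
  out <- tibble::tibble(patient_id = admissions$patient_id)
  for (pred in names(map)) {
    pat <- paste0("^(", paste(map[[pred]], collapse = "|"), ")")
    hits <- unique(dx$patient_id[grepl(pat, dx$code)])
    out[[pred]] <- out$patient_id %in% hits
  }
  out
}

#' Opioid-dispensing predictor flag
#'
#' `TRUE` iff any dispensing between admission and discharge (inclusive)
#' carries an ATC code equal to or beginning with `N02A` (opioid
#' analgesics). Patients whose dispensing record is missing entirely cannot
#' be assessed: by default this is an error (they must be excluded or routed
#' to a sensitivity variant); with `allow_missing = TRUE` their flag is `NA`.
#'
#' @param admissions Admissions tibble.
#' @param dispensings Tibble with `patient_id`, `atc_code`, `dispense_ts`.
#' @param allow_missing Return `NA` instead of erroring for patients with
#'   `dispensing_available == FALSE`.
#' @return Logical vector aligned with the rows of `admissions`.
#' @export
extract_opioid_flag <- function(admissions, dispensings, allow_missing = FALSE) {
  missing <- !admissions$dispensing_available
  if (any(missing) && !allow_missing) {
    abort(paste0(
      "dispensing records missing for patient(s): ",
      paste(utils::head(admissions$patient_id[missing], 5), collapse = ", "),
      if (sum(missing) > 5) ", ..." else "",
      "; exclude them or use a sensitivity variant."
    ), class = "parrisk_missing_dispensing")
  }
  opi <- dispensings[startsWith(toupper(dispensings$atc_code), "N02A"), ,
                     drop = FALSE]
  joined <- dplyr::inner_join(
    dplyr::select(admissions, "patient_id", "admission_ts", "discharge_ts"),
    opi, by = "patient_id", relationship = "many-to-many"
  )
  instay <- joined$dispense_ts >= joined$admission_ts &
    joined$dispense_ts <= joined$discharge_ts
  flagged <- unique(joined$patient_id[instay])
  out <- admissions$patient_id %in% flagged
  out[missing] <- NA
  out
}

#' Hyperkalaemia predictor flag with last-observation carry-forward
#'
#' Considers serum potassium draws in the last seven days of the
#' hospitalisation. If none exist, the most recent earlier in-stay value is
#' carried forward into the window. The flag is `TRUE` iff any considered
#' value exceeds 5.5 mmol/L (strictly). Patients with no potassium value at
#' all are assumed normal (not missing at random): flag `FALSE`,
#' `potassium_missing` `TRUE`.
#'
#' @param admissions Admissions tibble.
#' @param labs Labs tibble (`analyte == "potassium"` rows are used; values
#'   in mmol/L).
#' @param threshold Hyperkalaemia cut-off in mmol/L, strict; default 5.5.
#' @param window_days Evaluation window before discharge; default 7.
#' @return Tibble with `patient_id`, `hyperkalaemia`, `potassium_missing`.
#' @export
extract_hyperkalaemia_flag <- function(admissions, labs, threshold = 5.5,
                                       window_days = 7) {
  k <- labs[labs$analyte == "potassium", , drop = FALSE]
  if (nrow(k) > 0 && any(k$value <= 0 | !is.finite(k$value))) {
    abort("non-positive or non-finite potassium value(s) in labs.",
          class = "parrisk_data_error")
  }
  joined <- dplyr::inner_join(
    dplyr::select(admissions, "patient_id", "admission_ts", "discharge_ts"),
    k, by = "patient_id", relationship = "many-to-many"
  )
  joined <- joined[joined$draw_ts >= joined$admission_ts &
                     joined$draw_ts <= joined$discharge_ts, , drop = FALSE]
  if (nrow(joined) == 0) {
    return(tibble::tibble(patient_id = admissions$patient_id,
                          hyperkalaemia = FALSE, potassium_missing = TRUE))
  }
  per <- joined |>
    dplyr::mutate(in_window = .data$draw_ts >=
                    .data$discharge_ts - lubridate::ddays(window_days)) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      hyper = if (any(.data$in_window)) {
        any(.data$value[.data$in_window] > threshold)
      } else {
        # LOCF: the single most recent pre-window value stands in
        .data$value[which.max(.data$draw_ts)] > threshold
      },
      .groups = "drop"
    )
  out <- tibble::tibble(patient_id = admissions$patient_id)
  idx <- match(out$patient_id, per$patient_id)
  out$hyperkalaemia <- ifelse(is.na(idx), FALSE, per$hyper[idx])
  out$potassium_missing <- is.na(idx)
  out
}

#' Extract the full predictor vector for a cohort
#'
#' Runs all per-predictor extractors and assembles the 12 predictor flags
#' plus the two missingness indicators. Patients with missing dispensing
#' records get an `NA` opioid flag (route them to [apply_exclusion()] or a
#' sensitivity variant before scoring).
#'
#' @param cohort List of tables from [read_cohort()] (or a compatible list).
#' @param map Comorbidity map, see [read_comorbidity_map()].
#' @param admissions Optional admissions tibble overriding
#'   `cohort$admissions` (e.g. the post-exclusion set).
#' @return Tibble with `patient_id`, the 12 logical predictor columns in
#'   canonical order, `potassium_missing` and `dispensing_missing`.
#' @export
extract_predictors <- function(cohort, map = read_comorbidity_map(),
                               admissions = NULL) {
  adm <- admissions %||% cohort$admissions
  missing_preds <- setdiff(
    setdiff(PREDICTOR_NAMES,
            c("los_gt4", "prior_adm_6m", "opioids", "hyperkalaemia")),
    names(map)
  )
  if (length(missing_preds) > 0) {
    abort(sprintf("comorbidity map lacks predictor(s): %s",
                  paste(missing_preds, collapse = ", ")),
          class = "parrisk_config_error")
  }
  como <- extract_comorbidity_flags(adm, cohort$diagnoses, map)
  hyper <- extract_hyperkalaemia_flag(adm, cohort$labs)
  out <- tibble::tibble(
    patient_id = adm$patient_id,
    los_gt4 = extract_los_flag(adm),
    prior_adm_6m = extract_prior_admission_flag(adm, cohort$prior_admissions)
  )
  out <- dplyr::left_join(out, como, by = "patient_id")
  out$opioids <- extract_opioid_flag(adm, cohort$dispensings,
                                     allow_missing = TRUE)
  out <- dplyr::left_join(out, hyper, by = "patient_id")
  out$dispensing_missing <- !adm$dispensing_available
  dplyr::select(out, "patient_id", dplyr::all_of(PREDICTOR_NAMES),
                "potassium_missing", "dispensing_missing")
}

#' Published sensitivity-analysis variants of a predictor cohort
#'
#' Builds the three missing-data sensitivity variants alongside the base
#' cohort: `potassium_to_1` sets the hyperkalaemia flag to `TRUE` wherever
#' serum potassium was entirely missing; `opioids_to_0` / `opioids_to_1`
#' re-admit the dispensing-missing patients (excluded from the base cohort)
#' with their opioid flag forced to `FALSE` / `TRUE`. All other flags are
#' untouched.
#'
#' @param predictors Base predictor tibble from [extract_predictors()]
#'   (post-exclusion: no `dispensing_missing` rows).
#' @param excluded_predictors Predictor tibble for the patients excluded for
#'   missing dispensing data (their `opioids` flag is `NA`); may have zero
#'   rows.
#' @return Named list of predictor tibbles: `base`, `potassium_to_1`,
#'   `opioids_to_0`, `opioids_to_1`.
#' @export
sensitivity_variants <- function(predictors,
                                 excluded_predictors = predictors[0, ]) {
  stopifnot(all(!predictors$dispensing_missing))
  a <- predictors
  a$hyperkalaemia <- a$hyperkalaemia | a$potassium_missing
  readmit <- function(value) {
    extra <- excluded_predictors
    if (nrow(extra) > 0) extra$opioids <- value
    dplyr::bind_rows(predictors, extra)
  }
  list(
    base = predictors,
    potassium_to_1 = a,
    opioids_to_0 = readmit(FALSE),
    opioids_to_1 = readmit(TRUE)
  )
}
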