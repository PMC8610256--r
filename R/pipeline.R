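#' Cohort characteristics summary
#'
#' Count and percentage per predictor and per descriptive category
#' (age bands, sex, outcome when supplied), percentages to one decimal
#' place — the usual "Table 1" layout.
#'
#' @param predictors Predictor tibble from [extract_predictors()].
#' @param admissions Optional admissions tibble (adds age/sex rows).
#' @param y Optional binary outcome (adds the PAR-case row).
#' @return Tibble with `characteristic`, `n`, `pct`.
#' @export
characteristics_table <- function(predictors, admissions = NULL, y = NULL) {
  n <- nrow(predictors)
  if (n == 0) {
    abort("empty cohort: nothing to summarise.", class = "parrisk_data_error")
  }
  n_total <- n
  row <- function(label, count) {
    pct_val <- round(100 * count / n_total, 1)
    tibble::tibble(characteristic = label, n = as.integer(count),
                   pct = pct_val)
  }
  out <- list(tibble::tibble(characteristic = "total", n = as.integer(n),
                             pct = NA_real_))
  if (!is.null(y)) out <- c(out, list(row("par_cases", sum(as.numeric(y)))))
  if (!is.null(admissions)) {
    out <- c(out, list(
      row("age_65_75", sum(admissions$age <= 75)),
      row("age_76_plus", sum(admissions$age >= 76)),
      row("male_sex", sum(admissions$sex == "male"))
    ))
  }
  for (p in PREDICTOR_NAMES) {
    out <- c(out, list(row(p, sum(predictors[[p]], na.rm = TRUE))))
  }
  out <- c(out, list(
    row("potassium_missing", sum(predictors$potassium_missing)),
    row("dispensing_missing", sum(predictors$dispensing_missing))
  ))
  dplyr::bind_rows(out)
}

round_cols <- function(tbl, cols, digits) {
  for (cl in intersect(cols, names(tbl))) tbl[[cl]] <- round(tbl[[cl]], digits)
  tbl
}

strata_report <- function(scored, thresholds, label, log) {
  strata <- build_strata_table(scored$risk_group, scored$par)
  or <- tryCatch(group_odds_ratios(strata), parrisk_data_error = function(e) {
    log(sprintf("[stratify] zero cell under %s thresholds; using continuity correction", label))
    group_odds_ratios(strata, continuity = TRUE)
  })
  strata_out <- dplyr::mutate(
    tibble::as_tibble(strata), threshold_set = label,
    cut_low = thresholds$cut_low, cut_high = thresholds$cut_high,
    .before = 1
  )
  or_cols <- dplyr::bind_rows(
    tibble::tibble(comparison = "reference", odds_ratio = 1,
                   ci_low = NA_real_, ci_high = NA_real_),
    or
  )
  list(strata = dplyr::bind_cols(strata_out, dplyr::select(or_cols, -"comparison")),
       table = strata, or = or)
}

#' Run the full external-validation pipeline
#'
#' Executes extract, score, stratify, validate and report on an EHR-style
#' cohort directory and writes the result tables: `performance.csv`,
#' `calibration.csv`, `strata.csv`, `classification.csv`,
#' `observed_predicted.csv`, `sensitivity.csv`, `characteristics.csv` and
#' `manifest.json` (plus `run.log`). Output is all-or-nothing: files are
#' staged in a temporary directory and only moved into `output_dir` when
#' every stage has succeeded. All outputs are deterministic functions of
#' the inputs, so a rerun on the same data is byte-identical.
#'
#' The binary PAR outcome must be supplied as a `par` column in
#' `ground_truth.csv` (readmission adjudication itself is outside this
#' package's scope).
#'
#' @param input_dir Directory with the cohort CSVs (see [read_cohort()]).
#' @param output_dir Directory to write result tables into.
#' @param score_def A [score_definition()]; default the bundled (synthetic)
#'   PAR-Risk Score table with original thresholds `<3`, `3--10`, `>10`.
#' @param map Comorbidity map, see [read_comorbidity_map()].
#' @param thresholds `"both"` (default), `"original"` or `"adapted"`
#'   (tertile-recalculated cuts).
#' @param sensitivity `"all"` (default) to run the three missing-data
#'   sensitivity variants, `"none"` to skip them.
#' @param external_coefficients Optional `c(intercept, slope)` on the
#'   log-odds scale (e.g. the original study's score model) used for an
#'   additional external predicted-risk column.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed documents the upstream simulation).
#' @param quiet Suppress progress messages on stderr (the run log file is
#'   always written).
#' @return Invisibly, a list with the in-memory results (`predictors`,
#'   `scored`, `performance`, `strata`, `manifest`, ...).
#' @export
run_pipeline <- function(input_dir, output_dir,
                         score_def = par_risk_score(),
                         map = read_comorbidity_map(),
                         thresholds = c("both", "original", "adapted"),
                         sensitivity = c("all", "none"),
                         external_coefficients = NULL,
                         seed = NULL, quiet = FALSE) {
  thresholds <- match.arg(thresholds)
  sensitivity <- match.arg(sensitivity)
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
    invisible(NULL)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)), class = "parrisk_pipeline_error")
    })
  }

  cohort <- stage("read", read_cohort(input_dir))
  if (is.null(cohort$ground_truth) || !"par" %in% names(cohort$ground_truth)) {
    abort("ground_truth.csv with a `par` outcome column is required.",
          class = "parrisk_config_error")
  }
  n_read <- nrow(cohort$admissions)
  log(sprintf("[read] %d admissions", n_read))

  included <- stage("include", apply_inclusion(cohort$admissions))
  log(sprintf("[include] %d -> %d after inclusion criteria (>=48 h, age >=65)",
              n_read, nrow(included)))
  excl <- stage("exclude", apply_exclusion(included))
  for (i in seq_len(nrow(excl$tally))) {
    log(sprintf("[exclude] %s: %d", excl$tally$reason[i], excl$tally$n[i]))
  }
  log(sprintf("[exclude] %d retained", nrow(excl$retained)))

  predictors <- stage("extract", extract_predictors(cohort, map,
                                                    admissions = excl$retained))
  disp_missing_adm <- excl$excluded[
    excl$excluded$exclusion_reason == "dispensing_missing", , drop = FALSE]
  excluded_predictors <- stage("extract", extract_predictors(
    cohort, map, admissions = disp_missing_adm))

  outcome_of <- function(ids) {
    cohort$ground_truth$par[match(ids, cohort$ground_truth$patient_id)]
  }
  predictors$par <- outcome_of(predictors$patient_id)
  excluded_predictors$par <- outcome_of(excluded_predictors$patient_id)
  log(sprintf("[extract] %d predictor vectors, %d PAR cases",
              nrow(predictors), sum(predictors$par)))

  scored <- stage("score", score_cohort(predictors, score_def))
  log(sprintf("[score] raw scores %d..%d", min(scored$raw_score),
              max(scored$raw_score)))

  perf <- stage("validate", performance_summary(scored$raw_score, scored$par))
  log(sprintf("[validate] C %.3f (%.3f-%.3f), Brier %.4f, GOF p %.3g",
              perf$c_statistic$c, perf$c_statistic$ci_low,
              perf$c_statistic$ci_high, perf$brier, perf$gof$p_value))

  threshold_sets <- list()
  if (thresholds %in% c("both", "original")) {
    threshold_sets$original <- score_def$thresholds
  }
  if (thresholds %in% c("both", "adapted")) {
    threshold_sets$adapted <- tertile_thresholds(scored$raw_score)
    log(sprintf("[stratify] adapted tertile cuts: %d / %d",
                threshold_sets$adapted$cut_low, threshold_sets$adapted$cut_high))
  }

  strata_rows <- list(); class_rows <- list(); op_rows <- list()
  for (label in names(threshold_sets)) {
    th <- threshold_sets[[label]]
    sc <- score_cohort(predictors, score_def, thresholds = th)
    sc$par <- predictors$par
    rep_ <- stage("stratify", strata_report(sc, th, label, log))
    strata_rows[[label]] <- rep_$strata
    cls <- dplyr::bind_rows(
      pairwise_classification_metrics(rep_$table, "medium"),
      pairwise_classification_metrics(rep_$table, "high")
    )
    class_rows[[label]] <- dplyr::mutate(
      round_cols(dplyr::mutate(cls, dplyr::across(
        c("sensitivity", "specificity", "ppv", "npv"), ~ 100 * .x)),
        c("sensitivity", "specificity", "ppv", "npv"), 1),
      threshold_set = label, .before = 1)
    ovp <- observed_vs_predicted(rep_$table, sc$risk_group, sc$raw_score,
                                 fit = perf$fit)
    ovp <- dplyr::mutate(ovp, observed_pct = round(100 * .data$observed, 1),
                         predicted_pct = round(100 * .data$predicted, 1),
                         source = "internal_fit")
    if (!is.null(external_coefficients)) {
      ovpx <- observed_vs_predicted(rep_$table, sc$risk_group, sc$raw_score,
                                    coefficients = external_coefficients)
      ovpx <- dplyr::mutate(ovpx,
                            observed_pct = round(100 * .data$observed, 1),
                            predicted_pct = round(100 * .data$predicted, 1),
                            source = "external_coefficients")
      ovp <- dplyr::bind_rows(ovp, ovpx)
    }
    op_rows[[label]] <- dplyr::mutate(ovp, threshold_set = label, .before = 1)
  }

  sens_tbl <- tibble::tibble(variant = character(0), n = integer(0),
                             c_statistic = numeric(0), ci_low = numeric(0),
                             ci_high = numeric(0))
  if (sensitivity == "all") {
    variants <- stage("sensitivity", sensitivity_variants(
      predictors, excluded_predictors))
    sens_tbl <- purrr::map_dfr(names(variants), function(v) {
      sc <- score_cohort(variants[[v]], score_def)
      cs <- c_statistic(sc$raw_score, variants[[v]]$par)
      tibble::tibble(variant = v, n = nrow(sc), c_statistic = cs$c,
                     ci_low = cs$ci_low, ci_high = cs$ci_high)
    })
    log(sprintf("[sensitivity] %s: C %s",
                paste(sens_tbl$variant, collapse = "/"),
                paste(sprintf("%.3f", sens_tbl$c_statistic), collapse = "/")))
  }

  chars <- stage("report", characteristics_table(
    predictors, admissions = excl$retained, y = predictors$par))

  manifest <- list(
    package_version = as.character(packageVersion("parrisk")),
    input_dir = normalizePath(input_dir),
    score_definition = score_def$label,
    seed = seed,
    thresholds = lapply(threshold_sets, function(t) {
      list(cut_low = t$cut_low, cut_high = t$cut_high)
    }),
    counts = list(
      admissions_read = n_read,
      after_inclusion = nrow(included),
      excluded = as.list(setNames(excl$tally$n, excl$tally$reason)),
      cohort = nrow(predictors),
      par_cases = sum(predictors$par)
    )
  )

  # all-or-nothing: stage everything, then move into place
  staging <- tempfile("parrisk_out_")
  dir.create(staging, recursive = TRUE)
  readr::write_csv(perf$table, file.path(staging, "performance.csv"))
  readr::write_csv(perf$calibration, file.path(staging, "calibration.csv"))
  readr::write_csv(round_cols(dplyr::bind_rows(strata_rows),
                              c("odds_ratio", "ci_low", "ci_high"), 2),
                   file.path(staging, "strata.csv"))
  readr::write_csv(dplyr::bind_rows(class_rows),
                   file.path(staging, "classification.csv"))
  readr::write_csv(dplyr::select(dplyr::bind_rows(op_rows), "threshold_set",
                                 "group", "n", "observed_pct", "predicted_pct",
                                 "source"),
                   file.path(staging, "observed_predicted.csv"))
  readr::write_csv(sens_tbl, file.path(staging, "sensitivity.csv"))
  readr::write_csv(chars, file.path(staging, "characteristics.csv"))
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(staging, "run.log"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(staging)) {
    file.copy(file.path(staging, f), file.path(output_dir, f),
              overwrite = TRUE)
  }
  unlink(staging, recursive = TRUE)
  log(sprintf("[report] outputs written to %s", output_dir))

  invisible(list(
    predictors = predictors, scored = scored, performance = perf,
    strata = strata_rows, classification = class_rows,
    observed_predicted = op_rows, sensitivity = sens_tbl,
    characteristics = chars, manifest = manifest,
    thresholds = threshold_sets
  ))
}

#' Simulate a cohort and run the pipeline on it
#'
#' Convenience wrapper: generates a synthetic cohort, writes its CSVs and
#' runs [run_pipeline()] on them.
#'
#' @param output_dir Directory for pipeline outputs.
#' @param config A [cohort_config()].
#' @param input_dir Where to write the simulated CSVs (default a
#'   subdirectory `input` of `output_dir`).
#' @param ... Passed on to [run_pipeline()].
#' @return The [run_pipeline()] result, invisibly.
#' @export
simulate_and_run <- function(output_dir, config = cohort_config(),
                             input_dir = file.path(output_dir, "input"), ...) {
  cohort <- generate_cohort(config)
  write_cohort(cohort, input_dir)
  run_pipeline(input_dir, output_dir, seed = config$seed, ...)
}
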