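#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn `%||%`
#' @importFrom stats plogis qlogis qnorm pnorm quantile rbinom runif setNames
#' @importFrom utils packageVersion
NULL

# The 12 predictor flags of the PAR-Risk Score, in canonical order.
PREDICTOR_NAMES <- c(
  "los_gt4", "prior_adm_6m", "anaemia", "hypertension", "heart_failure",
  "acute_mi", "chronic_ihd", "diabetes_organ", "cancer", "metastatic_ca",
  "opioids", "hyperkalaemia"
)

RISK_LEVELS <- c("low", "medium", "high")

#' Risk-group thresholds for a points-based score
#'
#' Two integer cut points partition the non-negative integers into three
#' exhaustive, disjoint bands: scores strictly below `cut_low` are *low*
#' risk, scores from `cut_low` to `cut_high` inclusive are *medium* risk,
#' and scores strictly above `cut_high` are *high* risk. The PAR-Risk
#' Score's original bands are `<3`, `3--10` and `>10`
#' (`risk_thresholds(3, 10)`).
#'
#' @param cut_low Integer; scores strictly below are low risk.
#' @param cut_high Integer (`>= cut_low`); scores strictly above are high risk.
#' @return An object of class `risk_thresholds`.
#' @examples
#' assign_risk_group(2, risk_thresholds(3, 10))
#' @export
risk_thresholds <- function(cut_low, cut_high) {
  check_integerish(cut_low, "cut_low")
  check_integerish(cut_high, "cut_high")
  if (cut_low > cut_high) {
    abort("`cut_low` must be <= `cut_high`.", class = "parrisk_config_error")
  }
  structure(
    list(cut_low = as.integer(cut_low), cut_high = as.integer(cut_high)),
    class = "risk_thresholds"
  )
}

#' @export
print.risk_thresholds <- function(x, ...) {
  cat(sprintf(
    "Risk thresholds: low < %d <= medium <= %d < high\n", x$cut_low, x$cut_high
  ))
  invisible(x)
}

#' Define a points-based risk score
#'
#' A score definition is a table of named items with non-negative integer
#' point weights plus risk-group thresholds. The raw score of a patient is
#' the sum of the points of the items present at discharge.
#'
#' @param items A data frame (or list of `list(name=, points=)`) with columns
#'   `name` and `points`.
#' @param thresholds A [risk_thresholds()] object.
#' @param label Free-text label for the score.
#' @return An object of class `score_definition` with fields `label`,
#'   `items` (tibble) and `thresholds`.
#' @seealso [read_score_definition()], [par_risk_score()]
#' @export
score_definition <- function(items, thresholds, label = "unnamed score") {
  if (!inherits(thresholds, "risk_thresholds")) {
    abort("`thresholds` must be a risk_thresholds object.",
          class = "parrisk_config_error")
  }
  if (is.data.frame(items)) {
    tbl <- tibble::as_tibble(items)
  } else {
    tbl <- purrr::map_dfr(items, ~ tibble::tibble(
      name = .x$name, points = .x$points
    ))
  }
  if (!all(c("name", "points") %in% names(tbl)) || nrow(tbl) == 0) {
    abort("score items need non-empty `name` and `points` columns.",
          class = "parrisk_config_error")
  }
  if (anyDuplicated(tbl$name)) {
    abort(sprintf("duplicate score item name(s): %s",
                  paste(unique(tbl$name[duplicated(tbl$name)]), collapse = ", ")),
          class = "parrisk_config_error")
  }
  # points are integer by construction of a transposed scoring system;
  # non-integer weights indicate a mis-transcribed definition
  if (any(!is.finite(tbl$points)) || any(tbl$points < 0) ||
      any(tbl$points != round(tbl$points))) {
    abort("score item points must be non-negative integers.",
          class = "parrisk_config_error")
  }
  tbl$points <- as.integer(tbl$points)
  max_score <- sum(tbl$points)
  if (max_score < thresholds$cut_high) {
    abort(sprintf(
      "maximum attainable score (%d) is below the high-risk cut (%d).",
      max_score, thresholds$cut_high
    ), class = "parrisk_config_error")
  }
  structure(
    list(label = label, items = tbl, thresholds = thresholds),
    class = "score_definition"
  )
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("<score_definition> %s\n", x$label))
  cat(sprintf("  %d items, maximum score %d\n", nrow(x$items), sum(x$items$points)))
  print(x$thresholds)
  invisible(x)
}

#' Read a score definition from a YAML or JSON file
#'
#' The file must carry keys `label`, `items` (list of `{name, points}`) and
#' `thresholds` (`{cut_low, cut_high}`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [score_definition()].
#' @export
read_score_definition <- function(path) {
  raw <- read_structured(path)
  for (k in c("items", "thresholds")) {
    if (is.null(raw[[k]])) {
      abort(sprintf("score definition file lacks key `%s`: %s", k, path),
            class = "parrisk_config_error")
    }
  }
  score_definition(
    items = raw$items,
    thresholds = risk_thresholds(raw$thresholds$cut_low, raw$thresholds$cut_high),
    label = raw$label %||% basename(path)
  )
}

#' The bundled PAR-Risk Score definition (synthetic point table)
#'
#' Returns the score definition shipped with the package. Only the anaemia
#' weight (2 points) is fixed by the published validation study; the other
#' 11 weights are synthetic stand-ins for the unpublished point table (see
#' the file header of `par_risk_score_synthetic.yaml`). Thresholds default
#' to the original bands `<3`, `3--10`, `>10`.
#'
#' @return A [score_definition()] with 12 items.
#' @export
par_risk_score <- function() {
  read_score_definition(
    system.file("extdata", "par_risk_score_synthetic.yaml", package = "parrisk",
                mustWork = TRUE)
  )
}

#' Compute raw scores from predictor flags
#'
#' The raw score of a patient is the sum of the point weights of every score
#' item whose predictor flag is `TRUE` at discharge. `NA` flags (e.g. an
#' opioid flag for a patient with missing dispensing data) propagate to an
#' `NA` score.
#'
#' @param predictors A data frame with one logical column per score item
#'   (extra columns such as `patient_id` or missingness indicators are
#'   ignored).
#' @param definition A [score_definition()].
#' @return Integer vector of raw scores, one per row of `predictors`.
#' @examples
#' pv <- tibble::tibble(anaemia = TRUE, heart_failure = FALSE)
#' sd <- score_definition(
#'   tibble::tibble(name = c("anaemia", "heart_failure"), points = c(2L, 4L)),
#'   risk_thresholds(1, 5)
#' )
#' compute_raw_score(pv, sd)
#' @export
compute_raw_score <- function(predictors, definition) {
  stopifnot(inherits(definition, "score_definition"))
  items <- definition$items
  missing_items <- setdiff(items$name, names(predictors))
  if (length(missing_items) > 0) {
    abort(sprintf("score item(s) not found among predictor flags: %s",
                  paste(missing_items, collapse = ", ")),
          class = "parrisk_config_error")
  }
  flags <- as.matrix(as.data.frame(predictors)[, items$name, drop = FALSE])
  if (!is.logical(flags)) {
    abort("predictor flag columns must be logical.",
          class = "parrisk_config_error")
  }
  as.integer(flags %*% items$points)
}

#' Assign risk groups from raw scores
#'
#' @param score Integer vector of non-negative raw scores.
#' @param thresholds A [risk_thresholds()] object.
#' @return Factor with levels `low`, `medium`, `high`; `NA` scores yield
#'   `NA` groups.
#' @examples
#' assign_risk_group(c(2, 3, 10, 11), risk_thresholds(3, 10))
#' @export
assign_risk_group <- function(score, thresholds) {
  stopifnot(inherits(thresholds, "risk_thresholds"))
  if (any(score < 0, na.rm = TRUE)) {
    abort("scores must be non-negative.", class = "parrisk_data_error")
  }
  grp <- ifelse(score < thresholds$cut_low, "low",
         ifelse(score > thresholds$cut_high, "high", "medium"))
  factor(grp, levels = RISK_LEVELS)
}

#' Score a cohort of patients
#'
#' Convenience wrapper combining [compute_raw_score()] and
#' [assign_risk_group()].
#'
#' @param predictors Predictor-flag data frame with a `patient_id` column
#'   (and optionally an outcome column `par`).
#' @param definition A [score_definition()].
#' @param thresholds Optional [risk_thresholds()] overriding the
#'   definition's own (e.g. tertile-adapted cuts).
#' @return Tibble with `patient_id`, `raw_score`, `risk_group` and, when
#'   present in the input, the binary outcome `par`.
#' @export
score_cohort <- function(predictors, definition, thresholds = NULL) {
  thresholds <- thresholds %||% definition$thresholds
  out <- tibble::tibble(
    patient_id = predictors$patient_id,
    raw_score = compute_raw_score(predictors, definition),
    risk_group = assign_risk_group(
      compute_raw_score(predictors, definition), thresholds
    )
  )
  if ("par" %in% names(predictors)) out$par <- as.integer(predictors$par)
  out
}

# ---- shared helpers ---------------------------------------------------------

check_integerish <- function(x, what) {
  if (length(x) != 1 || !is.finite(x) || x != round(x)) {
    abort(sprintf("`%s` must be a single integer.", what),
          class = "parrisk_config_error")
  }
  invisible(x)
}

read_structured <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "parrisk_config_error")
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    abort(sprintf("unsupported config format (need .yaml or .json): %s", path),
          class = "parrisk_config_error")
  }
}
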