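#' Tertile-adapted risk thresholds
#'
#' Recomputes the low/medium/high cut points from the cohort's own raw
#' score distribution, so each group holds as close to one third of the
#' patients as the discrete scores allow. Among all candidate integer cut
#' pairs `(c1, c2)` (low: `s < c1`, medium: `c1 <= s <= c2`, high:
#' `s > c2`) the pair minimising the maximum absolute deviation of the
#' three group sizes from `n/3` is chosen; ties prefer the smaller `c1`,
#' then the smaller `c2`. Deterministic for a fixed input.
#'
#' @param scores Integer raw scores (at least 3 subjects, at least 3
#'   distinct values).
#' @return A [risk_thresholds()] object.
#' @examples
#' tertile_thresholds(rep(0:29, each = 100)) # cuts 10 and 19
#' @export
tertile_thresholds <- function(scores) {
  scores <- as.integer(scores)
  if (length(scores) < 3) {
    abort("need at least 3 subjects to form tertiles.",
          class = "parrisk_data_error")
  }
  if (length(unique(scores)) < 3) {
    abort("tertiles undefined: fewer than 3 distinct score values.",
          class = "parrisk_data_error")
  }
  n <- length(scores)
  vals <- sort(unique(scores))
  counts <- tabulate(factor(scores, levels = vals))
  cum <- cumsum(counts)
  # candidate cuts: c1, c2 drawn from observed values (cutting elsewhere
  # cannot change the partition), with c1 <= c2
  best <- NULL
  for (i in seq_along(vals)) {
    c1 <- vals[i]
    n_low <- if (i == 1) 0L else cum[i - 1]
    for (j in i:length(vals)) {
      c2 <- vals[j]
      n_mid <- cum[j] - n_low
      n_high <- n - n_low - n_mid
      dev <- max(abs(c(n_low, n_mid, n_high) - n / 3))
      if (is.null(best) || dev < best$dev - 1e-9) {
        best <- list(c1 = c1, c2 = c2, dev = dev)
      }
    }
  }
  risk_thresholds(best$c1, best$c2)
}

#' Cross-tabulate risk groups against the outcome
#'
#' @param groups Factor of risk groups (`low`/`medium`/`high`), e.g. from
#'   [assign_risk_group()].
#' @param y Binary outcome vector aligned with `groups`.
#' @return Tibble of class `strata_table` with one row per group (empty
#'   groups retained as zero rows): `group`, `n_par`, `n_nonpar`.
#' @export
build_strata_table <- function(groups, y) {
  groups <- factor(groups, levels = RISK_LEVELS)
  y <- as.numeric(y)
  stopifnot(length(groups) == length(y), all(y %in% c(0, 1)))
  out <- tibble::tibble(
    group = factor(RISK_LEVELS, levels = RISK_LEVELS),
    n_par = vapply(RISK_LEVELS, function(g) sum(y[groups == g]), numeric(1)),
    n_nonpar = vapply(RISK_LEVELS, function(g) sum(groups == g) -
                        sum(y[groups == g]), numeric(1))
  )
  out$n_par <- as.integer(out$n_par)
  out$n_nonpar <- as.integer(out$n_nonpar)
  class(out) <- c("strata_table", class(out))
  out
}

strata_cells <- function(strata, comparison) {
  ref <- strata[strata$group == "low", ]
  cmp <- strata[strata$group == comparison, ]
  list(a = cmp$n_par, b = cmp$n_nonpar, c = ref$n_par, d = ref$n_nonpar)
}

#' Risk-group odds ratios against the low-risk reference
#'
#' For each non-reference group the odds ratio is the 2x2 cross product
#' `(a*d)/(b*c)` with `a`/`b` the PAR / non-PAR counts in the comparison
#' group and `c`/`d` those in the low-risk group. The default confidence
#' interval is Woolf's: `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param strata A [build_strata_table()] result.
#' @param conf_level Confidence level, default 0.95.
#' @param continuity Add 0.5 to all four cells (use when a cell is zero);
#'   default off.
#' @return Tibble with `comparison`, `odds_ratio`, `ci_low`, `ci_high`.
#' @examples
#' st <- build_strata_table(
#'   factor(rep(c("low", "high"), c(302, 2730)), levels = c("low", "medium", "high")),
#'   c(rep(1:0, c(9, 293)), rep(1:0, c(204, 2526)))
#' )
#' group_odds_ratios(st) # high vs low: OR 2.63 (1.33-5.18)
#' @export
group_odds_ratios <- function(strata, conf_level = 0.95, continuity = FALSE) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  one_group <- function(g) {
    cl <- strata_cells(strata, g)
    cells <- c(cl$a, cl$b, cl$c, cl$d)
    if (any(cells == 0) && !continuity) {
      abort(sprintf(
        "zero cell in the %s-vs-low table; rerun with continuity = TRUE (adds 0.5 to all four cells).",
        g), class = "parrisk_data_error")
    }
    if (continuity) cells <- cells + 0.5
    lor <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
    se <- sqrt(sum(1 / cells))
    tibble::tibble(
      comparison = paste0(g, "_vs_low"),
      odds_ratio = exp(lor),
      ci_low = exp(lor - z * se),
      ci_high = exp(lor + z * se)
    )
  }
  dplyr::bind_rows(one_group("medium"), one_group("high"))
}

#' Classification metrics of a risk group against the low-risk reference
#'
#' Restricts the cohort to the comparison group plus the low-risk group;
#' membership of the comparison group is the "test positive" state and PAR
#' the condition. Sensitivity `a/(a+c)`, specificity `d/(b+d)`, positive
#' predictive value `a/(a+b)` and negative predictive value `d/(c+d)` are
#' returned as proportions (multiply by 100 for the conventional
#' percentage reporting, 1 decimal place).
#'
#' @param strata A [build_strata_table()] result.
#' @param comparison `"medium"` or `"high"`.
#' @return Tibble with `comparison`, `sensitivity`, `specificity`, `ppv`,
#'   `npv` (proportions in \[0, 1\]).
#' @export
pairwise_classification_metrics <- function(strata,
                                            comparison = c("medium", "high")) {
  comparison <- match.arg(comparison)
  cl <- strata_cells(strata, comparison)
  if (cl$a + cl$b == 0 || cl$c + cl$d == 0) {
    abort("both groups must be non-empty.", class = "parrisk_data_error")
  }
  if (cl$a + cl$c == 0) {
    abort("no PAR cases in the two groups: sensitivity undefined.",
          class = "parrisk_data_error")
  }
  tibble::tibble(
    comparison = paste0(comparison, "_vs_low"),
    sensitivity = cl$a / (cl$a + cl$c),
    specificity = cl$d / (cl$b + cl$d),
    ppv = cl$a / (cl$a + cl$b),
    npv = cl$d / (cl$c + cl$d)
  )
}

#' Observed versus predicted risk per risk group
#'
#' The observed proportion at risk is `n_PAR / n` per group; the mean
#' predicted risk averages per-subject predicted probabilities within the
#' group, from either the internal univariable fit or an externally
#' supplied per-score-point coefficient set (e.g. the original study's
#' scoring).
#'
#' @param strata A [build_strata_table()] result.
#' @param groups Factor of per-subject risk groups.
#' @param scores Integer per-subject raw scores.
#' @param fit Univariable [fit_logistic()] of outcome on score, or `NULL`
#'   when `coefficients` are given.
#' @param coefficients Optional external `c(intercept, slope)` on the
#'   log-odds scale, overriding `fit`.
#' @return Tibble with `group`, `n`, `observed`, `predicted` (proportions);
#'   empty groups are omitted with a warning.
#' @export
observed_vs_predicted <- function(strata, groups, scores, fit = NULL,
                                  coefficients = NULL) {
  if (is.null(coefficients)) {
    if (is.null(fit)) {
      abort("supply either `fit` or external `coefficients`.",
            class = "parrisk_config_error")
    }
    coefficients <- fit$coefficients
  }
  pred <- plogis(coefficients[1] + coefficients[2] * as.numeric(scores))
  empty <- as.character(strata$group[strata$n_par + strata$n_nonpar == 0])
  if (length(empty) > 0) {
    warn(sprintf("omitting empty risk group(s): %s",
                 paste(empty, collapse = ", ")))
  }
  strata |>
    dplyr::filter(.data$n_par + .data$n_nonpar > 0) |>
    dplyr::transmute(
      group = .data$group,
      n = .data$n_par + .data$n_nonpar,
      observed = .data$n_par / .data$n,
      predicted = vapply(as.character(.data$group), function(g) {
        mean(pred[as.character(groups) == g])
      }, numeric(1), USE.NAMES = FALSE)
    )
}
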