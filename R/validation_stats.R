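#' Fit a logistic regression by maximum likelihood
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (convergence when the deviance change is below `1e-8`, at most
#' 100 iterations), with the coefficient covariance taken as the inverse
#' observed information. An intercept is always included. Rank-deficient
#' design matrices are rejected naming the collinear columns; fits showing
#' quasi-complete separation are flagged as non-converged with a
#' diagnostic.
#'
#' @param x Covariate matrix or data frame (no intercept column), or a
#'   numeric vector for a univariable model.
#' @param y Binary outcome vector (0/1 or logical).
#' @return Object of class `logistic_fit`: `coefficients`, `vcov`, `fitted`
#'   (probabilities), `loglik`, `converged`, `diagnostic`, and the model
#'   matrix `x` (with intercept) and `y` used.
#' @examples
#' x <- rep(c(0, 1), c(50, 50))
#' y <- rbinom(100, 1, plogis(-1 + x))
#' fit_logistic(x, y)$coefficients
#' @export
fit_logistic <- function(x, y) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) {
    abort("`y` must be binary (0/1).", class = "parrisk_data_error")
  }
  X <- cbind("(Intercept)" = 1, x)
  if (nrow(X) <= ncol(X)) {
    abort("need more observations than coefficients.",
          class = "parrisk_data_error")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("design matrix is rank deficient; collinear column(s): %s",
                  paste(dropped, collapse = ", ")),
          class = "parrisk_data_error")
  }
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  p <- fit$fitted.values
  beta <- fit$coefficients
  # quasi-complete separation: boundary fitted values with runaway slopes
  separated <- any(p < 1e-10 | p > 1 - 1e-10) && any(abs(beta[-1]) > 15)
  converged <- isTRUE(fit$converged) && !separated
  w <- p * (1 - p)
  info <- crossprod(X, X * w)
  vcv <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  })
  dimnames(vcv) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = beta,
    vcov = vcv,
    fitted = p,
    loglik = sum(y * log(p) + (1 - y) * log1p(-p)),
    converged = converged,
    diagnostic = if (separated) {
      "coefficients diverging: quasi-complete separation suspected"
    } else if (!fit$converged) {
      "IRLS did not converge within 100 iterations"
    } else {
      NA_character_
    },
    x = X, y = y
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit>", if (x$converged) "converged" else
    paste("NOT CONVERGED:", x$diagnostic), "\n")
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  print(round(cbind(estimate = est, se = se, `exp(est)` = exp(est)), 4))
  invisible(x)
}

#' Wald and profile-likelihood confidence intervals for a logistic fit
#'
#' @param fit A [fit_logistic()] object.
#' @param level Confidence level, default 0.95.
#' @param method `"wald"` (log-odds scale, default) or `"profile"`
#'   (profile likelihood, via the signed-root deviance).
#' @return Tibble with `term`, `estimate`, `ci_low`, `ci_high` (log-odds
#'   scale) and the exponentiated columns `or`, `or_low`, `or_high`.
#' @export
confint_logistic <- function(fit, level = 0.95, method = c("wald", "profile")) {
  method <- match.arg(method)
  z <- qnorm(1 - (1 - level) / 2)
  est <- fit$coefficients
  if (method == "wald") {
    se <- sqrt(diag(fit$vcov))
    lo <- est - z * se
    hi <- est + z * se
  } else {
    glmfit <- stats::glm(fit$y ~ fit$x - 1, family = stats::binomial())
    ci <- suppressMessages(stats::confint(glmfit, level = level))
    lo <- ci[, 1]
    hi <- ci[, 2]
  }
  tibble::tibble(
    term = names(est), estimate = unname(est),
    ci_low = unname(lo), ci_high = unname(hi),
    or = exp(unname(est)), or_low = exp(unname(lo)), or_high = exp(unname(hi))
  )
}

#' Concordance (C) statistic with DeLong confidence interval
#'
#' The probability that a randomly chosen case scores higher than a
#' randomly chosen non-case, ties counted one half — equal to the area
#' under the ROC curve. Computed with the midrank algorithm, which equals
#' the all-pairs definition
#' \eqn{C = (\mathrm{concordant} + 0.5\,\mathrm{ties}) / (n_1 n_0)} exactly;
#' the confidence interval uses the DeLong structural-component variance.
#'
#' @param scores Numeric per-subject scores or fitted probabilities (any
#'   strictly monotone transform gives the same C).
#' @param y Binary outcome vector; both classes must be present.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `c`, `se`, `ci_low`, `ci_high` (CI truncated to
#'   \[0, 1\]).
#' @export
c_statistic <- function(scores, y, conf_level = 0.95) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    abort("C statistic undefined: only one outcome class present.",
          class = "parrisk_data_error")
  }
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r_all <- rank(scores, ties.method = "average")
  cases <- scores[y == 1]
  controls <- scores[y == 0]
  auc <- (sum(r_all[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong via midranks (Sun & Xu): structural components per subject
  v10 <- (r_all[y == 1] - rank(cases, ties.method = "average")) / n0
  v01 <- 1 - (r_all[y == 0] - rank(controls, ties.method = "average")) / n1
  var_auc <- stats::var(v10) / n1 + stats::var(v01) / n0
  se <- sqrt(var_auc)
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(
    c = auc, se = se,
    ci_low = max(0, auc - z * se),
    ci_high = min(1, auc + z * se)
  )
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the binary
#' outcome; lower is better, 0.25 is the score of an uninformative 0.5
#' prediction on a balanced outcome.
#'
#' @param prob Predicted probabilities in (0, 1) (boundary values allowed
#'   for degenerate perfect predictions).
#' @param y Binary outcome vector.
#' @return Single number in \[0, 1\].
#' @export
brier_score <- function(prob, y) {
  mean((as.numeric(y) - prob)^2)
}

#' Unweighted sum-of-squares global goodness-of-fit test
#'
#' The le Cessie-van Houwelingen-Copas-Hosmer test for logistic regression:
#' the statistic is \eqn{T = \sum_i (y_i - \hat p_i)^2} with null mean
#' \eqn{\sum_i \hat p_i (1 - \hat p_i)}. Writing \eqn{d_i = 1 - 2\hat p_i}
#' and \eqn{V = \mathrm{diag}(\hat p_i(1-\hat p_i))}, the variance of
#' \eqn{T - E[T]}, corrected for estimated coefficients, is
#' \eqn{d^\top (V - VX(X^\top VX)^{-1}X^\top V) d}. The standardised
#' statistic is referred to a standard normal, two sided.
#'
#' @param fit A converged [fit_logistic()] object.
#' @return List with `T`, `expected`, `z`, `p_value`.
#' @export
gof_unweighted_ss <- function(fit) {
  if (!fit$converged) {
    abort("goodness-of-fit test requires a converged fit.",
          class = "parrisk_data_error")
  }
  p <- fit$fitted
  y <- fit$y
  X <- fit$x
  Tstat <- sum((y - p)^2)
  expected <- sum(p * (1 - p))
  d <- 1 - 2 * p
  v <- p * (1 - p)
  XtVX <- crossprod(X, X * v)
  sol <- tryCatch(solve(XtVX, crossprod(X, d * v)),
                  error = function(e) abort(
                    "singular weighted information matrix in GOF test.",
                    class = "parrisk_data_error"))
  vd <- d * v
  variance <- sum(d * vd) - sum(crossprod(X, vd) * sol)
  if (variance < 1e-12) {
    # saturated limit: d lies in the column space of X, T equals E[T] and
    # the standardised statistic degenerates to 0
    z <- if (abs(Tstat - expected) < 1e-8) 0 else
      sign(Tstat - expected) * Inf
  } else {
    z <- (Tstat - expected) / sqrt(variance)
  }
  list(T = Tstat, expected = expected, z = z,
       p_value = 2 * pnorm(-abs(z)))
}

#' Calibration table of a univariable score model
#'
#' One row per distinct raw score value, ascending: the number of patients
#' at that score, the observed outcome proportion among them, and the
#' model-predicted risk \eqn{\mathrm{logit}^{-1}(\alpha + \beta s)}. Rows
#' are weighted by their patient counts (the weights sum to the cohort
#' size); this is the data behind a participant-weighted calibration plot.
#'
#' @param fit Univariable [fit_logistic()] of outcome on the raw score.
#' @param scores Integer raw scores per subject (same order as the fit).
#' @param y Binary outcomes per subject.
#' @return Tibble with `score`, `n`, `observed`, `predicted`.
#' @export
calibration_table <- function(fit, scores, y) {
  stopifnot(length(scores) == length(y))
  alpha <- fit$coefficients[1]
  beta <- fit$coefficients[2]
  tibble::tibble(score = as.integer(scores), y = as.numeric(y)) |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(n = dplyr::n(), observed = mean(.data$y),
                     .groups = "drop") |>
    dplyr::arrange(.data$score) |>
    dplyr::mutate(predicted = plogis(alpha + beta * .data$score))
}

#' Performance summary of the univariable raw-score model
#'
#' Fits the univariable logistic regression of the binary outcome on the
#' raw score and assembles the discrimination, accuracy, goodness-of-fit
#' and calibration statistics used for external validation.
#'
#' @param scores Integer raw scores per subject.
#' @param y Binary outcomes per subject.
#' @return List of class `performance_summary`: `fit`, `c_statistic`,
#'   `brier`, `gof` and `calibration`, plus a tidy `table` (tibble with
#'   `statistic`, `estimate`, `ci_low`, `ci_high`).
#' @export
performance_summary <- function(scores, y) {
  fit <- fit_logistic(scores, y)
  cs <- c_statistic(fit$fitted, y)
  brier <- brier_score(fit$fitted, y)
  gof <- gof_unweighted_ss(fit)
  tab <- tibble::tibble(
    statistic = c("c_statistic", "brier", "gof_T", "gof_z", "gof_p"),
    estimate = c(cs$c, brier, gof$T, gof$z, gof$p_value),
    ci_low = c(cs$ci_low, NA, NA, NA, NA),
    ci_high = c(cs$ci_high, NA, NA, NA, NA)
  )
  structure(list(
    fit = fit, c_statistic = cs, brier = brier, gof = gof,
    calibration = calibration_table(fit, scores, y),
    table = tab
  ), class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat("<performance_summary>\n")
  cat(sprintf("  C statistic %.3f (95%% CI %.3f-%.3f)\n",
              x$c_statistic$c, x$c_statistic$ci_low, x$c_statistic$ci_high))
  cat(sprintf("  Brier score %.3f\n", x$brier))
  cat(sprintf("  GOF (unweighted SS): z = %.2f, p = %.3g\n",
              x$gof$z, x$gof$p_value))
  invisible(x)
}
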