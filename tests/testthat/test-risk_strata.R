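# independent exhaustive-search oracle over observed cut values
tertile_oracle <- function(scores) {
  n <- length(scores)
  vals <- sort(unique(scores))
  best <- NULL
  for (c1 in vals) for (c2 in vals[vals >= c1]) {
    sizes <- c(sum(scores < c1),
               sum(scores >= c1 & scores <= c2),
               sum(scores > c2))
    dev <- max(abs(sizes - n / 3))
    if (is.null(best) || dev < best$dev - 1e-9) {
      best <- list(c1 = c1, c2 = c2, dev = dev)
    }
  }
  best
}

test_that("tertile thresholds balance a uniform score distribution exactly", {
  th <- tertile_thresholds(rep(0:29, each = 100))
  expect_equal(th$cut_low, 10)
  expect_equal(th$cut_high, 19)
  g <- assign_risk_group(rep(0:29, each = 100), th)
  expect_equal(as.integer(table(g)), c(1000, 1000, 1000))
})

test_that("tertile thresholds minimise the worst group imbalance", {
  set.seed(41)
  for (i in 1:25) {
    scores <- rbinom(sample(50:500, 1), 30, runif(1, 0.15, 0.5))
    if (length(unique(scores)) < 3) next
    th <- tertile_thresholds(scores)
    oracle <- tertile_oracle(scores)
    expect_equal(th$cut_low, oracle$c1)
    expect_equal(th$cut_high, oracle$c2)
    # ordering property: low < medium <= c2 < high
    g <- assign_risk_group(scores, th)
    expect_true(all(scores[g == "low"] < th$cut_low))
    expect_true(all(scores[g == "medium"] >= th$cut_low &
                      scores[g == "medium"] <= th$cut_high))
    expect_true(all(scores[g == "high"] > th$cut_high))
  }
  expect_error(tertile_thresholds(c(1, 2)), class = "parrisk_data_error")
  expect_error(tertile_thresholds(rep(c(1, 2), 50)),
               class = "parrisk_data_error")
})

test_that("strata tables cross-tabulate with conservation and zero rows", {
  g <- factor(rep(c("low", "high"), c(10, 15)),
              levels = c("low", "medium", "high"))
  y <- c(rep(1:0, c(2, 8)), rep(1:0, c(5, 10)))
  st <- build_strata_table(g, y)
  expect_equal(nrow(st), 3)
  expect_equal(st$n_par, c(2L, 0L, 5L))
  expect_equal(st$n_nonpar, c(8L, 0L, 10L))
  expect_equal(sum(st$n_par) + sum(st$n_nonpar), 25)

  # two independent paths agree: cross-tab vs per-patient dplyr count
  set.seed(42)
  scores <- rbinom(600, 25, 0.35)
  y2 <- rbinom(600, 1, 0.1)
  th <- tertile_thresholds(scores)
  g2 <- assign_risk_group(scores, th)
  st2 <- build_strata_table(g2, y2)
  direct <- tibble::tibble(g = g2, y = y2) |>
    dplyr::group_by(g, .drop = FALSE) |>
    dplyr::summarise(n_par = sum(y), n_nonpar = sum(1 - y), .groups = "drop")
  expect_equal(st2$n_par, as.integer(direct$n_par))
  expect_equal(st2$n_nonpar, as.integer(direct$n_nonpar))
})

test_that("group odds ratios follow the cross product with Woolf intervals", {
  st <- strata_original()
  or <- group_odds_ratios(st)
  expect_equal(or$comparison, c("medium_vs_low", "high_vs_low"))
  expect_equal(or$odds_ratio[2], (204 * 293) / (2526 * 9), tolerance = 1e-12)
  # identical compositions give OR 1
  same <- build_strata_table(
    factor(rep(c("low", "medium", "high"), each = 40),
           levels = c("low", "medium", "high")),
    rep(rep(1:0, c(8, 32)), 3))
  expect_equal(group_odds_ratios(same)$odds_ratio, c(1, 1))
  # zero cell: explicit error, continuity correction as the documented remedy
  zero <- build_strata_table(
    factor(rep(c("low", "medium", "high"), each = 10),
           levels = c("low", "medium", "high")),
    c(rep(0, 10), rep(1:0, c(2, 8)), rep(1:0, c(3, 7))))
  expect_error(group_odds_ratios(zero), "continuity",
               class = "parrisk_data_error")
  corrected <- group_odds_ratios(zero, continuity = TRUE)
  expect_equal(corrected$odds_ratio[1], (2.5 * 10.5) / (8.5 * 0.5))
})

test_that("classification metrics are Bayes-consistent with prevalence", {
  set.seed(43)
  for (i in 1:15) {
    cells <- sample(5:200, 4) # a, b (comparison), c, d (low)
    st <- build_strata_table(
      factor(rep(c("high", "low"), c(cells[1] + cells[2], cells[3] + cells[4])),
             levels = c("low", "medium", "high")),
      c(rep(1:0, cells[1:2]), rep(1:0, cells[3:4])))
    m <- pairwise_classification_metrics(st, "high")
    prev <- (cells[1] + cells[3]) / sum(cells)
    ppv_bayes <- m$sensitivity * prev /
      (m$sensitivity * prev + (1 - m$specificity) * (1 - prev))
    npv_bayes <- m$specificity * (1 - prev) /
      (m$specificity * (1 - prev) + (1 - m$sensitivity) * prev)
    expect_equal(m$ppv, ppv_bayes, tolerance = 1e-12)
    expect_equal(m$npv, npv_bayes, tolerance = 1e-12)
  }
  # degenerate: comparison group all PAR, reference none
  st <- build_strata_table(
    factor(rep(c("high", "low"), c(5, 8)), levels = c("low", "medium", "high")),
    rep(1:0, c(5, 8)))
  m <- pairwise_classification_metrics(st, "high")
  expect_equal(m$sensitivity, 1)
  expect_equal(m$npv, 1)
  empty_par <- build_strata_table(
    factor(rep(c("high", "low"), c(5, 8)), levels = c("low", "medium", "high")),
    rep(0, 13))
  expect_error(pairwise_classification_metrics(empty_par, "high"),
               class = "parrisk_data_error")
})

test_that("observed and predicted group risks are self-consistent", {
  set.seed(44)
  s <- sample(0:25, 5000, replace = TRUE)
  fit0 <- fit_logistic(s, rbinom(5000, 1, plogis(-3 + 0.08 * s)))
  # regenerate outcomes from the fitted model itself
  y <- rbinom(5000, 1, fit0$fitted)
  fit <- fit_logistic(s, y)
  th <- tertile_thresholds(s)
  g <- assign_risk_group(s, th)
  st <- build_strata_table(g, y)
  ovp <- observed_vs_predicted(st, g, s, fit = fit)
  se <- sqrt(ovp$predicted * (1 - ovp$predicted) / ovp$n)
  expect_true(all(abs(ovp$observed - ovp$predicted) < 4 * se + 0.01))
  expect_equal(ovp$observed, st$n_par / (st$n_par + st$n_nonpar))
  # external coefficients override the internal fit
  ovp_ext <- observed_vs_predicted(st, g, s,
                                   coefficients = c(qlogis(0.05), 0))
  expect_equal(ovp_ext$predicted, rep(0.05, 3), tolerance = 1e-12)
  # empty groups are dropped with a warning
  g2 <- factor(rep("low", 20), levels = c("low", "medium", "high"))
  st2 <- build_strata_table(g2, rbinom(20, 1, 0.3))
  expect_warning(res <- observed_vs_predicted(st2, g2, rep(1, 20), fit = fit),
                 "empty")
  expect_equal(nrow(res), 1)
})
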