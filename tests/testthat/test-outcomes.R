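test_that("ROC AUC matches hand-worked and degenerate fixtures", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  # pairs: (1 vs 3): lose, (1 vs 2): lose, (4 vs 3): win, (4 vs 2): win -> 0.5
  expect_equal(roc_auc(c(3, 1, 2, 4), c(0, 1, 0, 1))$auc, 0.5)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both")
})

test_that("curve-based AUC equals the Mann-Whitney pair statistic", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(10:120, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- sample(1:40, n, replace = TRUE)  # heavy ties on purpose
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(42)
  scores <- rlnorm(80, 3, 1)
  labels <- rbinom(80, 1, 0.5)
  base <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(log2(scores), labels)$auc, base)
  expect_equal(roc_auc(7 * scores + 3, labels)$auc, base)
  expect_equal(roc_auc(rank(scores), labels)$auc, base)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(43)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj <= 1))
    # monotone: adjusted values sorted like the raw ones
    expect_equal(order(adj[order(p)]), seq_along(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("logistic fit recovers a known slope and reports quartile probabilities", {
  set.seed(44)
  burden <- rlnorm(400, log(100), 1)
  beta <- 0.6
  p <- plogis(-4 + beta * log2(burden + 1))
  resp <- rbinom(400, 1, p)
  fit <- fit_response_model(burden, resp)
  expect_lt(abs(fit$slope - beta) / fit$se, 3)
  expect_gte(fit$response_prob_q75, fit$response_prob_q25)  # positive slope
  expect_equal(fit$n, 400)
  # odds increase transform: slope of ln(2.208) per log2 -> 120.8%
  expect_equal((exp(log(2.208)) - 1) * 100, 120.8, tolerance = 1e-10)
  expect_error(fit_response_model(1:5, c(0, 1, 0, 1, 0)), "at least 10")
})

test_that("therapy covariate yields per-arm and marginalized probabilities", {
  set.seed(45)
  n <- 300
  therapy <- sample(c("aPD1", "aCTLA4"), n, replace = TRUE, prob = c(0.3, 0.7))
  burden <- rlnorm(n, log(200), 0.9)
  p <- plogis(-3 + 0.4 * log2(burden + 1) - 0.8 * (therapy == "aCTLA4"))
  resp <- rbinom(n, 1, p)
  fit <- fit_response_model(burden, resp, therapy = therapy)
  expect_equal(nrow(fit$per_arm), 2)
  # aPD1 response probability exceeds aCTLA4 at the same burden
  pr <- setNames(fit$per_arm$prob_q25, fit$per_arm$therapy)
  expect_gt(pr["aPD1"], pr["aCTLA4"])
  # marginal lies between the arms
  expect_true(fit$response_prob_q25 >= min(pr) && fit$response_prob_q25 <= max(pr))
})

test_that("separation is flagged rather than silently diverging", {
  burden <- c(1:10, 101:110)
  resp <- rep(c(0, 1), each = 10)
  fit <- fit_response_model(burden, resp)
  expect_true(fit$separation)
})

test_that("high/low classification exceeds the percentile strictly", {
  hl <- classify_high_low(1:10, 80)
  # type-7 80th percentile of 1..10 is 8.2: only 9 and 10 exceed it
  expect_equal(which(hl), c(9L, 10L))
  expect_false(any(classify_high_low(rep(5, 8), 80)))
  expect_equal(sum(classify_high_low(1:100, 1)), 99)
  expect_error(classify_high_low(numeric(0)), "empty")
  expect_error(classify_high_low(1:5, 0), "strictly between")
})

test_that("classification concordance measures label disagreement", {
  x <- c(1, 2, 3, 4)
  expect_equal(unname(classification_concordance(x, x, c(50, 80))), c(0, 0))
  # rank reversal at the median: all four patients flip (2 high under each,
  # disjoint pairs)
  expect_equal(unname(classification_concordance(x, rev(x), 50)), 1)
  # independent metrics at the 80th percentile: expected incongruity
  # 2 * 0.2 * 0.8 = 0.32
  set.seed(46)
  reps <- replicate(60, {
    a <- runif(200); b <- runif(200)
    classification_concordance(a, b, 80)
  })
  expect_equal(mean(reps), 0.32, tolerance = 0.03)
  expect_error(classification_concordance(1:3, 1:4), "same patients")
})

test_that("Kaplan-Meier estimates match hand-computed product-limit values", {
  # 6-patient fixture, one stratum
  rec <- data.frame(os_time = c(2, 4, 4, 6, 8, 9),
                    os_event = c(1, 1, 0, 1, 0, 1))
  fit <- fit_survival(rec, rep(FALSE, 6))
  km <- summary(fit$km, times = c(2, 4, 6, 9))
  orc <- oracle_km(rec$os_time, rec$os_event)
  expect_equal(km$surv, orc$surv)
  # at-risk count at t = 0 equals the stratum size
  expect_equal(fit$at_risk$n_risk[fit$at_risk$time == 0], 6)
  expect_true(!is.null(fit$flag))  # single stratum: HR undefined
})

test_that("Cox fit recovers a planted hazard ratio and handles edge cases", {
  set.seed(47)
  n <- 400
  high <- rep(c(TRUE, FALSE), each = n / 2)
  t_evt <- rexp(n, 0.002 * ifelse(high, 2, 1))
  cens <- runif(n, 0, 1500)
  rec <- data.frame(os_time = pmin(t_evt, cens),
                    os_event = as.integer(t_evt <= cens))
  fit <- fit_survival(rec, high)
  se <- sqrt(diag(vcov(fit$cox)))[1]
  expect_lt(abs(log(fit$hazard_ratio) - log(2)) / se, 3)

  # identical strata: HR close to 1
  rec2 <- data.frame(os_time = rexp(200, 0.01), os_event = 1)
  fit2 <- fit_survival(rec2, rep(c(TRUE, FALSE), 100))
  expect_equal(fit2$hazard_ratio, 1, tolerance = 0.5)

  # zero events in one stratum -> flagged, not an error
  rec3 <- data.frame(os_time = c(rexp(20, 0.01), runif(20, 500, 600)),
                     os_event = c(rep(1, 20), rep(0, 20)))
  fit3 <- fit_survival(rec3, rep(c(FALSE, TRUE), each = 20))
  expect_true(!is.null(fit3$flag))
  expect_true(is.na(fit3$hazard_ratio))
})

test_that("administrative censoring truncates follow-up at the horizon", {
  rec <- data.frame(os_time = c(100, 3000, 4000), os_event = c(1, 1, 0))
  fit <- fit_survival(rec, c(TRUE, FALSE, TRUE), censor_at = 2885)
  expect_equal(max(fit$km$time), 2885)
  expect_equal(fit$n_events, 1)  # late events censored away
})

test_that("threshold sweep is monotone in the high-group size", {
  set.seed(48)
  n <- 150
  burden <- rlnorm(n, 3, 1)
  rec <- data.frame(os_time = rexp(n, 0.005), os_event = rbinom(n, 1, 0.7))
  sweep <- threshold_sweep(rec, burden, percentile_grid = c(30, 50, 70, 80, 90))
  expect_true(all(diff(sweep$n_high) <= 0))
  expect_lte(sweep$n_high[sweep$percentile == 80],
             sweep$n_high[sweep$percentile == 50])
  # constant hazard: HR ~ 1 across the grid
  ok <- !is.na(sweep$hazard_ratio)
  expect_true(all(abs(log(sweep$hazard_ratio[ok])) < 1))
})
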