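## Evaluation layer: ROC/AUC, logistic response models with quartile response
## probabilities, BH correction, percentile classification and concordance,
## Cox PH / Kaplan-Meier survival, and threshold sweeps.

#' ROC curve and AUC for a burden metric as a response predictor
#'
#' Builds the ROC curve by threshold sweep and reports the area under it,
#' which equals the Mann-Whitney probability that a responder outscores a
#' non-responder (ties counted half).
#'
#' @param scores numeric predictor (higher = more likely responder).
#' @param labels binary response vector (0/1 or logical), both classes present.
#' @param metric optional metric name carried in the result.
#' @return list of class `roc_result` with `auc`, `curve` (data.frame of fpr,
#'   tpr), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, metric = NULL) {
  labels <- as.integer(labels)
  keep <- stats::complete.cases(scores, labels)
  scores <- scores[keep]; labels <- labels[keep]
  .assert(all(labels %in% 0:1), "labels must be binary")
  .assert(length(unique(labels)) == 2L,
          "ROC requires both responders and non-responders")
  r <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                 levels = c(0, 1), direction = "<")
  curve <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), , drop = FALSE]
  structure(list(metric = metric, auc = as.numeric(r$auc), curve = curve,
                 n_pos = sum(labels == 1L), n_neg = sum(labels == 0L)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC%s: AUC = %.3f (%d responders / %d non-responders)\n",
              if (is.null(x$metric)) "" else paste0(" [", x$metric, "]"),
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Logistic model of immunotherapy response on log2 burden
#'
#' Fits response ~ log2(burden + pseudocount) (+ therapy indicator when two
#' therapy arms are present, e.g. aCTLA4 vs aPD1 in melanoma) by maximum
#' likelihood, and reports the Wald p-value for the burden slope, the
#' percentage increase in the odds of response per log2 fold change
#' ((exp(beta) - 1) * 100), and fitted response probabilities at the cohort's
#' 25th and 75th burden percentiles. With a therapy covariate, quartile
#' probabilities are reported per arm as well as marginalized over the
#' observed therapy mix.
#'
#' @param burden numeric burden vector.
#' @param response binary response vector (NA allowed; such patients are
#'   excluded).
#' @param therapy optional character/factor vector of therapy arms.
#' @param log_base logarithm base for the burden transform (default 2).
#' @param pseudocount added before the log transform so zero burdens are
#'   admissible (default 1).
#' @return list of class `logistic_fit`.
#' @export
fit_response_model <- function(burden, response, therapy = NULL,
                               log_base = 2, pseudocount = 1) {
  keep <- !is.na(response) & !is.na(burden)
  if (!is.null(therapy)) keep <- keep & !is.na(therapy)
  burden <- burden[keep]; response <- as.integer(response[keep])
  therapy <- if (is.null(therapy)) NULL else as.character(therapy)[keep]
  n <- length(burden)
  .assert(n >= 10L, "need at least 10 patients with response status")
  .assert(all(burden + pseudocount > 0), "burden + pseudocount must be positive")
  x <- log(burden + pseudocount, base = log_base)
  use_therapy <- !is.null(therapy) && length(unique(therapy)) >= 2L
  df <- data.frame(response = response, x = x)
  if (use_therapy) df$therapy <- factor(therapy)
  fml <- if (use_therapy) response ~ x + therapy else response ~ x
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  separation <- warned || any(abs(cf) > 15)
  slope <- unname(cf["x"])
  se <- sqrt(diag(stats::vcov(fit)))["x"]
  p <- 2 * stats::pnorm(-abs(slope / se))
  q <- stats::quantile(burden, c(0.25, 0.75), type = 7, names = FALSE)
  marginal_prob <- function(bq) {
    nd <- df
    nd$x <- log(bq + pseudocount, base = log_base)
    mean(stats::predict(fit, newdata = nd, type = "response"))
  }
  arm_prob <- NULL
  if (use_therapy) {
    arms <- sort(unique(therapy))
    arm_prob <- do.call(rbind, lapply(arms, function(a) {
      nd <- data.frame(x = log(q + pseudocount, base = log_base), therapy = a)
      pr <- stats::predict(fit, newdata = nd, type = "response")
      data.frame(therapy = a, n = sum(therapy == a),
                 prob_q25 = pr[1], prob_q75 = pr[2], row.names = NULL)
    }))
  }
  structure(list(
    n = n, coefficients = cf, slope = slope, se = unname(se),
    p_value = unname(p), p_adjusted = NA_real_,
    odds_increase_pct = (exp(slope * log(log_base) / log(2)) - 1) * 100,
    burden_q25 = q[1], burden_q75 = q[2],
    response_prob_q25 = marginal_prob(q[1]),
    response_prob_q75 = marginal_prob(q[2]),
    per_arm = arm_prob, separation = separation, fit = fit
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic response model (n = %d)%s\n  slope per log2: %.4f (p = %.4g); odds change: %+.1f%% per log2 fold change\n  response probability: %.3f at 25th %%ile, %.3f at 75th %%ile\n",
    x$n, if (x$separation) " [flagged: possible separation]" else "",
    x$slope, x$p_value, x$odds_increase_pct,
    x$response_prob_q25, x$response_prob_q75))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return BH step-up adjusted values.
#' @export
bh_adjust <- function(p_values) {
  .assert(is.numeric(p_values) && all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
          "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Classify patients as burden-high by strict percentile exceedance
#'
#' A patient is "high" when the burden strictly exceeds the cohort percentile
#' value (type-7 quantile, linear interpolation between order statistics).
#' With all burdens equal nothing exceeds the quantile and no one is high.
#'
#' @param burdens numeric vector (one cohort / disease at a time).
#' @param percentile percentile threshold in (0, 100), default 80.
#' @return logical vector, TRUE = high.
#' @export
classify_high_low <- function(burdens, percentile = 80) {
  .assert(length(burdens) >= 1L, "empty cohort")
  .assert(is.numeric(percentile) && percentile > 0 && percentile < 100,
          "`percentile` must lie strictly between 0 and 100")
  cut <- stats::quantile(burdens, percentile / 100, type = 7, names = FALSE,
                         na.rm = TRUE)
  burdens > cut
}

#' Fraction of patients classified discordantly by two metrics
#'
#' At each percentile threshold, classifies patients as high/low under both
#' metrics and reports the fraction whose labels disagree.
#'
#' @param metric_a,metric_b numeric vectors over the same patients.
#' @param percentile_grid percentiles to evaluate (default 80).
#' @return named numeric vector, one incongruity fraction per percentile.
#' @export
classification_concordance <- function(metric_a, metric_b,
                                       percentile_grid = 80) {
  .assert(length(metric_a) == length(metric_b),
          "metrics must cover the same patients")
  out <- vapply(percentile_grid, function(p) {
    mean(classify_high_low(metric_a, p) != classify_high_low(metric_b, p))
  }, numeric(1))
  stats::setNames(out, percentile_grid)
}

#' Cox proportional-hazards and Kaplan-Meier fit for a high/low stratifier
#'
#' Fits the hazard of death for burden-high vs burden-low patients (Efron
#' ties), honoring right-censoring, with optional administrative censoring at
#' a stated horizon. Also computes Kaplan-Meier curves and a number-at-risk
#' table.
#'
#' @param records data.frame with columns os_time (days) and os_event
#'   (TRUE/1 = death observed).
#' @param high_low logical vector, TRUE = burden-high.
#' @param censor_at optional administrative censoring horizon in days.
#' @param at_risk_times times (days) for the at-risk table; defaults to six
#'   evenly spaced points from 0 to the last follow-up.
#' @return list of class `survival_fit` with `hazard_ratio`, `ci`, `p_value`,
#'   `n`, `n_events`, `km` (survfit), `at_risk`, and `flag` (NULL, or a reason
#'   the HR is not estimable).
#' @export
fit_survival <- function(records, high_low, censor_at = NULL,
                         at_risk_times = NULL) {
  df <- data.frame(time = as.numeric(records$os_time),
                   event = as.integer(records$os_event),
                   high = as.logical(high_low))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  .assert(nrow(df) >= 2L, "need at least two patients with survival data")
  .assert(all(df$time > 0), "survival times must be positive")
  if (!is.null(censor_at)) {
    over <- df$time > censor_at
    df$event[over] <- 0L
    df$time[over] <- censor_at
  }
  km <- survival::survfit(survival::Surv(time, event) ~ high, data = df)
  if (is.null(at_risk_times)) {
    at_risk_times <- round(seq(0, max(df$time), length.out = 6))
  }
  sm <- summary(km, times = at_risk_times, extend = TRUE)
  at_risk <- data.table::data.table(
    stratum = if (is.null(sm$strata)) "all" else as.character(sm$strata),
    time = sm$time, n_risk = sm$n.risk)
  flag <- NULL
  hr <- ci <- p <- NA_real_
  cox <- NULL
  ev <- tapply(df$event, df$high, sum)
  if (length(unique(df$high)) < 2L) {
    flag <- "single stratum: hazard ratio undefined"
  } else if (any(ev == 0) || anyNA(ev)) {
    flag <- "zero events in a stratum: hazard ratio not estimable"
  } else {
    cox <- survival::coxph(survival::Surv(time, event) ~ high, data = df,
                           ties = "efron")
    sc <- summary(cox)
    hr <- unname(sc$conf.int[1, "exp(coef)"])
    ci <- unname(sc$conf.int[1, c("lower .95", "upper .95")])
    p <- unname(sc$coefficients[1, "Pr(>|z|)"])
  }
  structure(list(hazard_ratio = hr, ci = ci, p_value = p,
                 n = nrow(df), n_high = sum(df$high),
                 n_events = sum(df$event), cox = cox, km = km,
                 at_risk = at_risk, flag = flag),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  if (!is.null(x$flag)) {
    cat(sprintf("Survival fit (n = %d, %d events): %s\n", x$n, x$n_events, x$flag))
  } else {
    cat(sprintf(
      "Survival fit (n = %d, %d events): HR(high vs low) = %.3f [%.3f, %.3f], p = %.4g\n",
      x$n, x$n_events, x$hazard_ratio, x$ci[1], x$ci[2], x$p_value))
  }
  invisible(x)
}

#' Hazard-ratio sweep over classification thresholds
#'
#' Reclassifies patients as burden-high at each percentile of the grid and
#' refits the Cox model, showing how threshold choice moves the estimated
#' hazard ratio and its significance. Points where the model is not estimable
#' are flagged and the sweep continues.
#'
#' @param records data.frame with os_time and os_event columns.
#' @param burdens numeric burden vector over the same patients.
#' @param percentile_grid percentiles in (0, 100) (default seq(30, 90, 5)).
#' @param censor_at optional administrative censoring horizon.
#' @return data.table with columns percentile, hazard_ratio, p_value, n_high,
#'   flag.
#' @export
threshold_sweep <- function(records, burdens, percentile_grid = seq(30, 90, 5),
                            censor_at = NULL) {
  .assert(all(percentile_grid > 0 & percentile_grid < 100),
          "percentile grid must lie strictly between 0 and 100")
  rows <- lapply(percentile_grid, function(p) {
    hl <- classify_high_low(burdens, p)
    fit <- tryCatch(fit_survival(records, hl, censor_at = censor_at),
                    error = function(e) NULL)
    if (is.null(fit)) {
      data.table::data.table(percentile = p, hazard_ratio = NA_real_,
                             p_value = NA_real_, n_high = sum(hl),
                             flag = "fit failed")
    } else {
      data.table::data.table(percentile = p, hazard_ratio = fit$hazard_ratio,
                             p_value = fit$p_value, n_high = sum(hl),
                             flag = if (is.null(fit$flag)) NA_character_ else fit$flag)
    }
  })
  data.table::rbindlist(rows)
}
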