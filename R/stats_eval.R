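## Association, survival and prediction-performance statistics used across
## the pipeline. Standard tests are delegated to stats/survival/pROC; the
## AUC inside roc_metrics uses the Mann-Whitney rank identity directly so
## that the DeLong comparison (pROC) has an independent counterpart.

#' Pearson chi-square test on a contingency table
#'
#' Statistic sum (O - E)^2 / E with df = (r-1)(c-1). No continuity
#' correction by default (including 2x2 tables); a zero row or column total
#' is an error because expected counts are undefined.
#'
#' @param table r x c matrix of nonnegative counts.
#' @param correct apply Yates continuity correction for 2x2 tables.
#' @return list: statistic, df, p.value, expected, residuals (Pearson
#'   (O-E)/sqrt(E)), stdres (standardized residuals).
#' @export
chisq_test <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0) || any(!is.finite(table)))
    stop("counts must be nonnegative and finite", call. = FALSE)
  if (sum(table) <= 0) stop("table total must be positive", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row/column total: expected counts undefined", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, expected = ht$expected,
       residuals = ht$residuals, stdres = ht$stdres)
}

#' Logistic association with covariate adjustment
#'
#' Maximum-likelihood binomial fit of \code{y} on \code{x} plus covariates;
#' returns the odds ratio of \code{x} with Wald confidence interval and
#' p-value. Quasi-complete separation is detected (absurd coefficient or
#' standard error) and reported in the \code{flag} field rather than
#' raising an error.
#'
#' @param y binary response (factor or 0/1) with both levels present.
#' @param x predictor of interest.
#' @param covariates optional data frame of adjustment columns.
#' @return list: or, ci (2), p.value, beta, se, flag ("ok" or
#'   "separation"), kind ("univariate"/"multivariate").
#' @export
logistic_assoc <- function(y, x, covariates = NULL) {
  yf <- droplevels(as.factor(y))
  if (nlevels(yf) != 2) stop("y must have two levels", call. = FALSE)
  df <- data.frame(y = yf, x = x)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                     family = stats::binomial()))
  co <- summary(fit)$coefficients
  xr <- grep("^x", rownames(co))[1]
  beta <- co[xr, 1]; se <- co[xr, 2]; p <- co[xr, 4]
  flag <- if (abs(beta) > 15 || se > 100) "separation" else "ok"
  list(or = exp(beta), ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       p.value = p, beta = beta, se = se, flag = flag,
       kind = if (is.null(covariates)) "univariate" else "multivariate")
}

#' Kaplan-Meier curves with a log-rank test
#'
#' @param time,event right-censored outcome (times > 0, >= 1 event).
#' @param group grouping factor.
#' @return list: fit (survfit), chisq, df, p.value (log-rank).
#' @export
km_logrank <- function(time, event, group) {
  if (any(time <= 0, na.rm = TRUE)) stop("times must be > 0", call. = FALSE)
  if (sum(event, na.rm = TRUE) == 0)
    stop("no events observed: survival comparison undefined", call. = FALSE)
  df <- data.frame(time = time, event = event, group = as.factor(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- length(sd_$n) - 1
  list(fit = fit, chisq = sd_$chisq, df = dfree,
       p.value = stats::pchisq(sd_$chisq, dfree, lower.tail = FALSE))
}

#' Cox proportional-hazards association
#'
#' Partial-likelihood fit with Efron tie handling. Zero observed events are
#' an explicit error (a Cox fit on such a stratum would yield a spurious
#' hazard ratio, as happens for overall survival in young thyroid-cancer
#' cohorts with no deaths).
#'
#' @param time,event outcome.
#' @param x predictor of interest.
#' @param covariates optional adjustment data frame.
#' @param ties tie-handling method.
#' @return list: hr, ci, p.value (Wald), p.lrt (likelihood ratio), beta,
#'   se, fit.
#' @export
cox_ph <- function(time, event, x, covariates = NULL, ties = "efron") {
  if (any(time <= 0, na.rm = TRUE)) stop("times must be > 0", call. = FALSE)
  if (sum(event, na.rm = TRUE) == 0)
    stop("no events observed: Cox model not estimable", call. = FALSE)
  df <- data.frame(time = time, event = event, x = x)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  fit <- survival::coxph(survival::Surv(time, event) ~ ., data = df,
                         ties = ties)
  co <- summary(fit)$coefficients
  xr <- grep("^x", rownames(co))[1]
  beta <- co[xr, 1]; se <- co[xr, 3]; p <- co[xr, 5]
  lrt <- 2 * diff(fit$loglik)
  list(hr = exp(beta),
       ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       p.value = p,
       p.lrt = stats::pchisq(lrt, length(stats::coef(fit)),
                             lower.tail = FALSE),
       beta = beta, se = se, fit = fit)
}

## Mann-Whitney AUC: probability a random positive outscores a random
## negative (ties count 1/2).
auc_mw <- function(score, y) {
  y <- as.integer(as.factor(y)) - 1L  # second level = positive
  r <- rank(score)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics for a continuous score
#'
#' AUC by the Mann-Whitney rank identity; optimal cut-point by the Youden
#' index (sensitivity + specificity - 1) over the observed score values,
#' predicting positive when score >= cut-point; sensitivity, specificity,
#' PPV and NPV at that cut-point. The Brier score (mean squared error of
#' the predicted probability) is computed when the score lies in \[0,1\]
#' and is NA otherwise. A constant score yields AUC 0.5 and a flagged,
#' undefined cut-point.
#'
#' @param score numeric predictor (higher = more likely positive).
#' @param y binary outcome; its second factor level (or 1) is positive.
#' @param cutpoint_rule currently "youden".
#' @return list of class \code{prediction_metrics}: auc, cutpoint,
#'   sensitivity, specificity, ppv, npv, brier, flag.
#' @export
roc_metrics <- function(score, y, cutpoint_rule = c("youden")) {
  cutpoint_rule <- match.arg(cutpoint_rule)
  yf <- droplevels(as.factor(y))
  if (nlevels(yf) != 2) stop("both classes must be present", call. = FALSE)
  pos <- yf == levels(yf)[2]
  if (length(unique(score)) == 1) {
    return(structure(list(auc = 0.5, cutpoint = NA_real_,
                          sensitivity = NA_real_, specificity = NA_real_,
                          ppv = NA_real_, npv = NA_real_,
                          brier = NA_real_, flag = "constant_score"),
                     class = "prediction_metrics"))
  }
  auc <- auc_mw(score, yf)
  cuts <- sort(unique(score))
  best <- c(youden = -Inf, cut = NA, sens = NA, spec = NA)
  for (ct in cuts) {
    pred <- score >= ct
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    if (sens + spec - 1 > best["youden"])
      best <- c(youden = sens + spec - 1, cut = ct, sens = sens,
                spec = spec)
  }
  pred <- score >= best["cut"]
  ppv <- if (sum(pred)) sum(pred & pos) / sum(pred) else NA_real_
  npv <- if (sum(!pred)) sum(!pred & !pos) / sum(!pred) else NA_real_
  brier <- if (all(score >= 0 & score <= 1))
    mean((score - as.numeric(pos))^2) else NA_real_
  structure(list(auc = auc, cutpoint = unname(best["cut"]),
                 sensitivity = unname(best["sens"]),
                 specificity = unname(best["spec"]),
                 ppv = ppv, npv = npv, brier = brier, flag = "ok"),
            class = "prediction_metrics")
}

#' Harrell concordance index for a risk score
#'
#' Probability that of two comparable samples, the one with the worse
#' outcome carries the higher score.
#'
#' @param score risk score (higher = higher risk).
#' @param time,event right-censored outcome.
#' @return list: cindex, se.
#' @export
cindex <- function(score, time, event) {
  cf <- survival::concordance(survival::Surv(time, event) ~ score,
                              reverse = TRUE)
  list(cindex = unname(cf$concordance), se = sqrt(unname(cf$var)))
}

#' DeLong test for two paired AUCs
#'
#' Compares the AUCs of two scores measured on the same samples using the
#' DeLong covariance of the paired empirical AUCs and a two-sided normal
#' test. Identical scores return a zero difference with p = 1.
#'
#' @param score_a,score_b paired scores (same samples, same order).
#' @param y binary outcome (second level positive).
#' @return list: auc_a, auc_b, delta_auc, statistic, p.value.
#' @export
delong_test <- function(score_a, score_b, y) {
  if (length(score_a) != length(score_b) || length(score_a) != length(y))
    stop("scores and outcome must be paired (equal length)", call. = FALSE)
  yf <- droplevels(as.factor(y))
  lev <- levels(yf)
  ra <- pROC::roc(yf, score_a, levels = lev, direction = "<", quiet = TRUE)
  rb <- pROC::roc(yf, score_b, levels = lev, direction = "<", quiet = TRUE)
  dauc <- as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb))
  if (isTRUE(all.equal(score_a, score_b)))
    return(list(auc_a = as.numeric(pROC::auc(ra)),
                auc_b = as.numeric(pROC::auc(rb)),
                delta_auc = 0, statistic = 0, p.value = 1))
  tt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  p <- tt$p.value
  if (!is.finite(p)) p <- 1
  list(auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(rb)),
       delta_auc = dauc, statistic = unname(tt$statistic), p.value = p)
}

#' Compare two paired concordance indices
#'
#' Joint estimation of both concordances with their covariance (infinite-
#' simal jackknife, via the survival package), then a two-sided normal test
#' on the difference.
#'
#' @param score_a,score_b paired risk scores (higher = higher risk).
#' @param time,event shared outcome.
#' @return list: cindex_a, cindex_b, delta, statistic, p.value.
#' @export
compare_cindex <- function(score_a, score_b, time, event) {
  if (length(score_a) != length(score_b) || length(score_a) != length(time))
    stop("scores and outcome must be paired (equal length)", call. = FALSE)
  df <- data.frame(time = time, event = event, a = score_a, b = score_b)
  cf <- survival::concordance(survival::Surv(time, event) ~ a + b,
                              data = df, reverse = TRUE)
  d <- cf$concordance[1] - cf$concordance[2]
  v <- cf$var[1, 1] + cf$var[2, 2] - 2 * cf$var[1, 2]
  z <- if (v <= 0) 0 else d / sqrt(v)
  list(cindex_a = unname(cf$concordance[1]),
       cindex_b = unname(cf$concordance[2]),
       delta = unname(d), statistic = unname(z),
       p.value = 2 * stats::pnorm(-abs(z)))
}

#' Kruskal-Wallis rank test
#'
#' @param values numeric vector.
#' @param group grouping factor with >= 2 levels present.
#' @return list: statistic, df, p.value.
#' @export
kruskal_test <- function(values, group) {
  g <- droplevels(as.factor(group))
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  ht <- stats::kruskal.test(values, g)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Spearman rank correlation
#'
#' @param x,y paired numeric vectors with >= 3 complete pairs.
#' @return list: rho, p.value.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  ht <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ht$estimate), p.value = ht$p.value)
}
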