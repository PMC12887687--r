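# Per-window regression layer: logistic models for subtype vs matched
# control with odds ratios, Wald intervals and AUROC, optional L1/L2
# regularized fits, and Cox proportional hazards time-to-death analysis.

#' Fit a per-window logistic regression for subtype vs control
#'
#' One multivariable logistic model per window: outcome is case vs matched
#' control, predictors are the window's pre-diagnosis condition indicators
#' (typically filtered upstream to the Mann-Whitney-significant set) plus the
#' demographic covariates age, age squared, sex, and an age-by-sex
#' interaction. Per-condition odds ratios are `exp(coefficient)` with Wald
#' 95% intervals. Conditions showing complete separation are reported with
#' an unbounded-CI flag and excluded from the significant set; exactly
#' collinear condition columns abort with their names.
#'
#' @param X Binary condition matrix (participants x conditions), e.g.
#'   `presence_indicator()` of a pre-window presence matrix.
#' @param outcome Logical/0-1 vector: 1 = case.
#' @param covariates Optional `data.frame` with `age` and `sex`
#'   (`"female"`/`"male"`) per participant; `NULL` fits conditions only.
#' @param mwu_significant Optional character vector; condition columns are
#'   restricted to it and an overlap flag is recorded.
#' @param or_cap Display cap: ORs above it get `capped_gt` = TRUE (default 3).
#' @param alpha Significance level (default 0.05).
#' @return List with `results` (`data.table`: `condition`, `or`, `ci_lo`,
#'   `ci_hi`, `p`, `significant`, `separation`, `mwu_overlap`, `capped_gt`)
#'   and `fit` (the `glm` object).
#' @export
fit_window_logistic <- function(X, outcome, covariates = NULL,
                                mwu_significant = NULL, or_cap = 3,
                                alpha = 0.05) {
  outcome <- as.integer(outcome)
  stopifnot(length(outcome) == nrow(X), all(outcome %in% 0:1))
  if (!is.null(mwu_significant)) {
    X <- X[, colnames(X) %in% mwu_significant, drop = FALSE]
  }
  X <- X[, colSums(X) > 0 & colSums(X) < nrow(X), drop = FALSE]
  conds <- colnames(X)
  if (length(conds) > 1L) {
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1L) {
      drop_idx <- qrX$pivot[seq(qrX$rank + 1L, ncol(X) + 1L)] - 1L
      stop("collinear condition columns: ",
           paste(conds[drop_idx], collapse = ", "), call. = FALSE)
    }
  }
  df <- data.frame(.y = outcome, X, check.names = FALSE)
  form <- paste0("`", conds, "`", collapse = " + ")
  if (!is.null(covariates)) {
    df$age <- covariates$age
    df$sex <- factor(covariates$sex, levels = c("female", "male"))
    form <- paste(form, "+ age + I(age^2) + age:sex")
  }
  fit <- stats::glm(stats::as.formula(paste(".y ~", form)), data = df,
                    family = stats::binomial())
  sm <- summary(fit)$coefficients
  rn <- gsub("`", "", rownames(sm))
  keep <- rn %in% conds
  est <- sm[keep, "Estimate"]; se <- sm[keep, "Std. Error"]
  pv <- sm[keep, "Pr(>|z|)"]
  # complete separation: diverging estimate or exploding Wald SE
  sep <- abs(est) > 10 | se > 10
  out <- data.table::data.table(
    condition = rn[keep], or = exp(est),
    ci_lo = exp(est - 1.959964 * se), ci_hi = exp(est + 1.959964 * se),
    p = pv, separation = sep)
  out[, significant := p < alpha & !separation]
  out[, mwu_overlap := condition %in% (mwu_significant %||% character(0))]
  out[, capped_gt := or > or_cap]
  data.table::setorder(out, p)
  list(results = out[], fit = fit)
}

#' Rank-based AUROC with midrank tie handling
#'
#' Equals the Mann-Whitney U probability `U / (n1 * n0)` for the same scores.
#'
#' @param scores Numeric predicted scores.
#' @param labels 0/1 (or logical) true labels.
#' @return AUROC in `[0, 1]`.
#' @export
evaluate_auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute AUROC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUROC for a window logistic model
#'
#' Stratified k-fold cross-validation: the model of
#' [fit_window_logistic()] is refit on each training fold and scored on the
#' held-out fold; fold AUROCs are averaged.
#'
#' @inheritParams fit_window_logistic
#' @param k Number of folds (default 5).
#' @param seed Seed for the stratified fold assignment.
#' @return Mean held-out AUROC.
#' @export
cv_auroc <- function(X, outcome, covariates = NULL, k = 5L, seed = 1L) {
  outcome <- as.integer(outcome)
  set.seed(seed)
  fold <- integer(length(outcome))
  for (cl in 0:1) {
    idx <- which(outcome == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  aucs <- vapply(seq_len(k), function(f) {
    tr <- fold != f; te <- !tr
    fit <- fit_window_logistic(X[tr, , drop = FALSE], outcome[tr],
                               covariates = if (is.null(covariates)) NULL
                                            else covariates[tr, , drop = FALSE])$fit
    newdf <- data.frame(X[te, , drop = FALSE], check.names = FALSE)
    if (!is.null(covariates)) {
      newdf$age <- covariates$age[te]
      newdf$sex <- factor(covariates$sex[te], levels = c("female", "male"))
    }
    evaluate_auroc(stats::predict(fit, newdata = newdf, type = "response"),
                   outcome[te])
  }, 0)
  mean(aucs)
}

#' L1/L2-regularized window logistic fit
#'
#' Regularized comparison model over the same design (conditions +
#' covariates); coefficients are reported without confidence intervals.
#'
#' @inheritParams fit_window_logistic
#' @param penalty `"L1"` (lasso) or `"L2"` (ridge).
#' @param lambda Regularization strength (single value).
#' @return `data.table` with `term` and `coefficient`.
#' @export
fit_regularized_logistic <- function(X, outcome, covariates = NULL,
                                     penalty = c("L1", "L2"), lambda = 0.01) {
  penalty <- match.arg(penalty)
  M <- as.matrix(X)
  if (!is.null(covariates)) {
    male <- as.integer(covariates$sex == "male")
    M <- cbind(M, age = covariates$age, age2 = covariates$age^2,
               age_sex = covariates$age * male)
  }
  fit <- glmnet::glmnet(M, as.integer(outcome), family = "binomial",
                        alpha = if (penalty == "L1") 1 else 0,
                        lambda = lambda, standardize = TRUE)
  cf <- as.matrix(stats::coef(fit))
  data.table::data.table(term = rownames(cf), coefficient = cf[, 1L])
}

#' Cox proportional hazards model for time to death
#'
#' Time runs from the index date to death or administrative censoring;
#' the event is death. Hazard ratios use Breslow tie handling.
#'
#' @param assignments Cohort rows with `index_date`, `death_date` (`NA` if
#'   alive), `age_at_index`, `sex`, and a `group` column distinguishing e.g.
#'   dementia vs control.
#' @param covariates Character vector of covariate columns (default
#'   `c("group", "age_at_index", "sex")`).
#' @param censor_date Administrative censoring date (default `"2024-04-30"`,
#'   the mortality-register cutoff emulated by the generator).
#' @return `data.table`: `covariate`, `hr`, `ci_lo`, `ci_hi`, `p`,
#'   `n_events`.
#' @export
cox_time_to_death <- function(assignments,
                              covariates = c("group", "age_at_index", "sex"),
                              censor_date = as.Date("2024-04-30")) {
  a <- data.table::as.data.table(assignments)
  censor_date <- as.Date(censor_date)
  a[, event := as.integer(!is.na(death_date) & death_date <= censor_date)]
  a[, stop_date := data.table::fifelse(event == 1L, death_date, censor_date)]
  a[, time := as.numeric(stop_date - index_date) / 365.25]
  a <- a[time > 0]
  if (sum(a$event) == 0L) stop("no death events", call. = FALSE)
  if ("group" %in% covariates &&
      any(a[, sum(event) == 0L, by = group]$V1)) {
    warning("a group is fully censored", call. = FALSE)
  }
  form <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(covariates, collapse = " + ")))
  fit <- survival::coxph(form, data = a, ties = "breslow")
  sm <- summary(fit)
  co <- sm$coefficients
  data.table::data.table(
    covariate = rownames(co), hr = co[, "exp(coef)"],
    ci_lo = sm$conf.int[, "lower .95"], ci_hi = sm$conf.int[, "upper .95"],
    p = co[, "Pr(>|z|)"], n_events = sum(a$event))
}
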