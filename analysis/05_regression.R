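#!/usr/bin/env Rscript
# Stage 5: per-window logistic regression.
#
# For each pre-diagnosis window and each subtype, fits a logistic model of
# case vs matched control on the window's condition indicators (restricted
# to the Mann-Whitney-significant set) adjusted for age, age squared, sex,
# and an age-by-sex interaction. Reports odds ratios with Wald 95%
# intervals (ORs above 3 flagged for display capping) and stratified
# 5-fold cross-validated AUROC per window.

library(comorbmap)
library(data.table)

diagnoses <- read_diagnoses("results/data/diagnoses.csv")
assignments <- fread("results/assignments.csv", colClasses = list(character = "id"))
assignments[, `:=`(index_date = as.Date(index_date),
                   death_date = as.Date(death_date))]
pairs <- fread("results/matched_pairs.csv",
               colClasses = list(character = c("case_id", "control_id")))
pairs[, index_date := as.Date(index_date)]

all_index <- rbind(assignments[label %in% c("AD", "VaD"), .(id, index_date)],
                   pairs[, .(id = control_id, index_date)])
offsets <- map_event_offsets(diagnoses, all_index, drop_stems = "S72")
w <- default_windows()

or_tables <- list(); aurocs <- list()
for (g in c("AD", "VaD")) {
  sig <- fread(sprintf("results/prevalence_code_%s.csv", g))[
    significant == TRUE, condition]
  case_a <- assignments[label == g]
  ctl_ids <- pairs[cohort == g, control_id]
  ctl_a <- assignments[id %in% ctl_ids]
  ctl_a[, index_date := pairs[match(ctl_a$id, control_id), index_date]]
  ctl_a[, age_at_index := as.numeric(index_date - birth_date(birth_year)) / 365.25]
  ids <- c(case_a$id, ctl_a$id)
  y <- c(rep(1L, nrow(case_a)), rep(0L, nrow(ctl_a)))
  cov <- data.frame(age = c(case_a$age_at_index, ctl_a$age_at_index),
                    sex = c(case_a$sex, ctl_a$sex))
  for (wl in w[kind == "pre", label]) {
    X <- presence_indicator(build_presence_matrix(offsets, ids, wl))
    if (!any(colnames(X) %in% sig)) next
    fit <- tryCatch(fit_window_logistic(X, y, covariates = cov,
                                        mwu_significant = sig),
                    error = function(e) NULL)
    if (is.null(fit)) next
    or_tables[[paste(g, wl)]] <- fit$results[, `:=`(cohort = g, window = wl)]
    Xs <- X[, colnames(X) %in% sig, drop = FALSE]
    aurocs[[paste(g, wl)]] <- data.table(
      cohort = g, window = wl,
      auroc = cv_auroc(Xs, y, covariates = cov, seed = 1))
  }
}
or_tables <- rbindlist(or_tables, fill = TRUE)
aurocs <- rbindlist(aurocs)
fwrite(or_tables, "results/odds_ratios.csv")
fwrite(aurocs, "results/auroc.csv")

cat("significant per-window associations (p < 0.05, also MWU-significant):\n")
print(or_tables[significant == TRUE & mwu_overlap == TRUE,
                .(cohort, window, condition, or = round(or, 2),
                  ci = sprintf("[%.2f, %.2f]", ci_lo, ci_hi),
                  capped_gt)][order(cohort, window)])
cat("\ncross-validated AUROC by window:\n")
print(dcast(aurocs, window ~ cohort, value.var = "auroc"))
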