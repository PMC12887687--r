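#!/usr/bin/env Rscript
# Stage 6: time-to-death and polygenic-risk-score comparisons.
#
# Cox proportional hazards on time from the index date to death (censored
# April 2024), dementia vs matched controls adjusted for age at index and
# sex, with Breslow tie handling; and pairwise Mann-Whitney comparisons of
# the AD polygenic risk score between AD, VaD, and controls with
# Benjamini-Hochberg correction.

library(comorbmap)
library(data.table)

assignments <- fread("results/assignments.csv", colClasses = list(character = "id"))
assignments[, `:=`(index_date = as.Date(index_date),
                   death_date = as.Date(death_date))]
pairs <- fread("results/matched_pairs.csv",
               colClasses = list(character = c("case_id", "control_id")))
pairs[, index_date := as.Date(index_date)]

ctl <- assignments[id %in% pairs$control_id]
ctl[, index_date := pairs[match(ctl$id, control_id), index_date]]
ctl[, age_at_index := as.numeric(index_date - birth_date(birth_year)) / 365.25]
surv_data <- rbind(assignments[label %in% c("AD", "VaD")][, group := "dementia"],
                   ctl[, group := "control"], fill = TRUE)
surv <- cox_time_to_death(surv_data)
fwrite(surv, "results/survival.csv")
cat("Cox time-to-death (dementia vs matched controls):\n")
print(surv[, .(covariate, hr = round(hr, 2),
               ci = sprintf("[%.2f, %.2f]", ci_lo, ci_hi), p = signif(p, 3))])

prs <- fread("results/data/prs.csv", colClasses = list(character = "id"))
sc <- rbind(prs[id %in% assignments[label == "AD", id], .(id, prs, group = "AD")],
            prs[id %in% assignments[label == "VaD", id], .(id, prs, group = "VaD")],
            prs[id %in% pairs$control_id, .(id, prs, group = "control")])
prs_res <- compare_prs(sc)
fwrite(prs_res, "results/prs_comparisons.csv")
cat("\nPRS comparisons (BH-adjusted):\n")
print(prs_res[, .(group1, group2, p_adj = signif(p_adj, 3))])
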