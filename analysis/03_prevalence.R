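#!/usr/bin/env Rscript
# Stage 3: group-level prevalence comparison.
#
# Maps every comorbidity to a signed offset from the index date, then runs
# two-sided Mann-Whitney U tests with Bonferroni correction over the whole
# mapped horizon: dementia overall vs matched controls at individual-code
# and ICD-10-block level (binary presence and per-block sums of distinct
# codes), plus per-subtype comparisons whose significant sets feed the
# regression stage.

library(comorbmap)
library(data.table)

diagnoses <- read_diagnoses("results/data/diagnoses.csv")
assignments <- fread("results/assignments.csv", colClasses = list(character = "id"))
assignments[, index_date := as.Date(index_date)]
pairs <- fread("results/matched_pairs.csv",
               colClasses = list(character = c("case_id", "control_id")))
pairs[, index_date := as.Date(index_date)]

all_index <- rbind(assignments[label %in% c("AD", "VaD"), .(id, index_date)],
                   pairs[, .(id = control_id, index_date)])
offsets <- map_event_offsets(diagnoses, all_index, drop_stems = "S72")

full_w <- "0-10 after"  # cumulative over the whole mapped horizon
dem_ids <- assignments[label %in% c("AD", "VaD"), id]
ctl_ids <- pairs$control_id

for (lv in c("code", "block")) {
  res <- compare_prevalence(
    build_presence_matrix(offsets, dem_ids, full_w, level = lv),
    build_presence_matrix(offsets, ctl_ids, full_w, level = lv), level = lv)
  fwrite(res, sprintf("results/prevalence_%s.csv", lv))
  cat(sprintf("%s level: %d of %d tested conditions significant after Bonferroni\n",
              lv, sum(res$significant), nrow(res)))
  print(top_conditions(res, 10)[, .(condition, prev_cohort, prev_control,
                                    p_adj = signif(p_adj, 3))])
}

for (g in c("AD", "VaD")) {
  ids_g <- assignments[label == g, id]
  ctl_g <- pairs[cohort == g, control_id]
  res <- compare_prevalence(
    build_presence_matrix(offsets, ids_g, full_w),
    build_presence_matrix(offsets, ctl_g, full_w))
  fwrite(res, sprintf("results/prevalence_code_%s.csv", g))
  cat(sprintf("%s vs matched controls: significant codes: %s\n", g,
              paste(res[significant == TRUE, condition], collapse = ", ")))
}
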