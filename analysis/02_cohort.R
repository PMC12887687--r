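#!/usr/bin/env Rscript
# Stage 2: resolve diagnoses and build the matched cohorts.
#
# Applies the diagnosis-resolution workflow (majority subtype category,
# exclusions for four or more categories, unspecified/MCI/other-only
# profiles, Down syndrome codes, and missing inpatient data), matches each
# case 1:1 to an age- and sex-matched control alive on the placeholder index
# date, and builds the hip-fracture control-disease cohort with its own
# controls.

library(comorbmap)
library(data.table)

participants <- read_participants("results/data/participants.csv")
diagnoses <- read_diagnoses("results/data/diagnoses.csv")

assignments <- build_dementia_cohort(participants, diagnoses)

pool <- assignments[label == "none"]
pairs <- list()
for (g in c("AD", "VaD")) {
  pairs[[g]] <- match_controls(assignments[label == g],
                               pool[!id %in% unlist(lapply(pairs, `[[`, "control_id"))],
                               tolerance_years = 1, seed = 1)[, cohort := g]
}
pairs <- rbindlist(pairs)

cd <- build_control_disease_cohort(participants, diagnoses)
cd_pairs <- match_controls(cd, pool[!id %in% c(pairs$control_id, cd$id)],
                           tolerance_years = 1, seed = 1)

dir.create("results", showWarnings = FALSE)
fwrite(assignments, "results/assignments.csv")
fwrite(pairs, "results/matched_pairs.csv")
fwrite(cd, "results/control_disease.csv")
fwrite(cd_pairs, "results/control_disease_pairs.csv")

s <- summarize_cohort(assignments, participants, diagnoses)
for (nm in names(s)) fwrite(s[[nm]], sprintf("results/summary_%s.csv", nm))

cat(sprintf("cohorts: %d AD, %d VaD, %d matched controls, %d hip-fracture cases\n",
            sum(assignments$label == "AD"), sum(assignments$label == "VaD"),
            nrow(pairs), nrow(cd)))
cat(sprintf("deceased fraction, dementia: %.0f%%; matched controls: %.0f%%\n",
            100 * s$deceased[label %in% c("AD", "VaD"),
                             sum(deceased) / sum(n)],
            100 * assignments[id %in% pairs$control_id,
                              mean(!is.na(death_date))]))
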