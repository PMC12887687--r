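#!/usr/bin/env Rscript
# Stage 1: simulate the study population.
#
# Generates the planted synthetic cohort that stands in for first-instance
# ICD-10 inpatient extracts: 2000 AD and 1000 VaD cases with scheduled
# diagnosis dates (age ~ N(70, 4)), 6000 background participants, and 2000
# hip-fracture (control-disease) participants. Comorbidity histories follow
# age-dependent annual first-admission probabilities; a known set of planted
# window-specific odds enrichments (depressive episodes and food/fluid-intake
# symptoms before AD, cerebral infarction and type 1 diabetes before VaD,
# pressure ulcers and pneumonia after diagnosis in both) provides ground
# truth for the downstream stages.

library(comorbmap)

seed <- 1L
out <- "results/data"

fx <- make_fixture("planted-AD-VaD", seed = seed, dir = out)

cat(sprintf("wrote %s: %d participants, %d first-instance diagnoses\n",
            out, nrow(fx$participants), nrow(fx$diagnoses)))
cat("planted effects:\n")
print(fx$truth$planted)
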