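#!/usr/bin/env Rscript
# Stage 4: per-window co-occurrence networks and characteristic conditions.
#
# For every time window (seven pre-diagnosis, five cumulative post) and each
# cohort (AD, VaD, their matched controls, hip fracture and its controls),
# builds the condition co-occurrence network (nodes = conditions above a 1%
# cumulative prevalence floor; edges = co-occurrence counts above threshold),
# computes degree centrality, and extracts conditions characteristic of each
# subtype: present in the subtype's network but absent from its control
# network, validated against the hip-fracture analysis.

library(comorbmap)
library(data.table)

diagnoses <- read_diagnoses("results/data/diagnoses.csv")
assignments <- fread("results/assignments.csv", colClasses = list(character = "id"))
assignments[, index_date := as.Date(index_date)]
pairs <- fread("results/matched_pairs.csv",
               colClasses = list(character = c("case_id", "control_id")))
pairs[, index_date := as.Date(index_date)]
cd <- fread("results/control_disease.csv", colClasses = list(character = "id"))
cd[, index_date := as.Date(index_date)]
cd_pairs <- fread("results/control_disease_pairs.csv",
                  colClasses = list(character = c("case_id", "control_id")))
cd_pairs[, index_date := as.Date(index_date)]

all_index <- rbind(assignments[label %in% c("AD", "VaD"), .(id, index_date)],
                   pairs[, .(id = control_id, index_date)],
                   cd[, .(id, index_date)],
                   cd_pairs[, .(id = control_id, index_date)])
offsets <- map_event_offsets(diagnoses, all_index, drop_stems = "S72")

w <- default_windows()
groups <- list(
  AD = assignments[label == "AD", id],
  control_AD = pairs[cohort == "AD", control_id],
  VaD = assignments[label == "VaD", id],
  control_VaD = pairs[cohort == "VaD", control_id],
  hip = cd$id, control_hip = cd_pairs$control_id)

nets <- lapply(groups, function(ids) {
  setNames(lapply(w$label, function(wl) {
    build_cooccurrence_network(build_presence_matrix(offsets, ids, wl),
                               cohort = NA_character_)
  }), w$label)
})

dir.create("results/networks", showWarnings = FALSE, recursive = TRUE)
for (g in names(nets)) for (wl in names(nets[[g]])) {
  net <- nets[[g]][[wl]]
  if (nrow(net$edges)) {
    export_network(net, path_csv = sprintf("results/networks/%s_%s.csv",
                                           g, gsub("[ +]", "", wl)))
  }
}

# centrality trajectory: when do circulatory conditions become central?
for (g in c("AD", "VaD")) {
  central <- rbindlist(lapply(names(nets[[g]]), function(wl) {
    ctr <- nets[[g]][[wl]]$centrality
    if (!length(ctr)) return(NULL)
    data.table(window = wl, condition = names(ctr), centrality = ctr)
  }))
  fwrite(central, sprintf("results/centrality_%s.csv", g))
  hubs <- central[centrality >= 0.5, .N, by = window]
  cat(g, "windows with central (>= 0.5) conditions:",
      paste(hubs$window, collapse = ", "), "\n")
}

disease_set <- control_disease_characteristic_set(nets$hip, nets$control_hip)
cc <- rbindlist(lapply(c("AD", "VaD"), function(g) {
  sig <- fread(sprintf("results/prevalence_code_%s.csv", g))
  out <- characteristic_conditions(nets[[g]], nets[[paste0("control_", g)]],
                                   disease_characteristic = disease_set,
                                   mwu_significant = sig[significant == TRUE,
                                                         condition])
  if (nrow(out)) out[, cohort := g]
  out
}), fill = TRUE)
cc[, chapter := code_to_chapter(condition)]
fwrite(cc, "results/characteristic_conditions.csv")

cat(sprintf("characteristic conditions: %d (%d validated against hip fracture)\n",
            nrow(cc), sum(cc$validated)))
print(cc[status == "new", .(cohort, window, condition, chapter, validated)])
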