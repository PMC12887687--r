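#' @import data.table
NULL

.datatable.aware <- TRUE

# quiet R CMD check notes for data.table non-standard evaluation
utils::globalVariables(c(
  ".", ".N", ".SD", "id", "code", "date", "icd10_code", "index_date",
  "label", "reason", "death_date", "birth_year", "age_at_index", "offset",
  "cond", "status", "norm", "sex", "significant", "p_adj", "degenerate",
  "condition", "group", "prs", "p", "in_control_disease_net", "validated",
  "mwu_overlap", "score_delta", "from", "to", "or", "separation",
  "capped_gt", "event", "stop_date", "time", "cohort", "case_id",
  "control_id", "chapter", "window", "deceased", "span", "ncat", "multiplier",
  "start", "end", "start_key", "end_key", "V1"
))
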