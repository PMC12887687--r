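# Cohort construction: reading participant/diagnosis tables, resolving the
# overall dementia diagnosis from subtype code counts, matching age- and
# sex-matched controls with placeholder index dates, and the hip-fracture
# control-disease cohort.

#' Read a participants table
#'
#' Expected columns: `id`, `sex` (`"female"`/`"male"`), `birth_year`,
#' `death_date` (ISO-8601 or empty for alive).
#'
#' @param path CSV path.
#' @return `data.table` with typed columns; `death_date` is `Date` (`NA` for
#'   alive).
#' @export
read_participants <- function(path) {
  p <- data.table::fread(path, colClasses = list(character = "id"))
  req <- c("id", "sex", "birth_year", "death_date")
  if (!all(req %in% names(p))) {
    stop("participants table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  p[, death_date := as.Date(as.character(death_date))]
  p[, birth_year := as.integer(birth_year)]
  if (!all(p$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  if (anyDuplicated(p$id)) stop("duplicate participant ids", call. = FALSE)
  p[]
}

#' Read a diagnoses table, keeping first instances only
#'
#' Expected columns: `id`, `icd10_code`, `date`. Codes are normalized; per
#' (participant, code) only the earliest event is retained, mirroring
#' first-instance inpatient extracts. The number of later duplicates dropped
#' is reported.
#'
#' @param path CSV path.
#' @return `data.table` with `id`, `code`, `date`, sorted by id then date.
#' @export
read_diagnoses <- function(path) {
  d <- data.table::fread(path, colClasses = list(character = "id"))
  req <- c("id", "icd10_code", "date")
  if (!all(req %in% names(d))) {
    stop("diagnoses table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  d <- d[, .(id, code = parse_icd10(icd10_code), date = as.Date(as.character(date)))]
  if (anyNA(d$date)) stop("unparseable diagnosis dates", call. = FALSE)
  n0 <- nrow(d)
  d <- d[order(date), .SD[1L], by = .(id, code)]
  if (n0 > nrow(d)) {
    message(sprintf("read_diagnoses: dropped %d non-first instances", n0 - nrow(d)))
  }
  data.table::setorder(d, id, date)
  d[]
}

#' Resolve a participant's overall dementia diagnosis
#'
#' Counts first-instance events per dementia subtype category and applies the
#' resolution rules: any Down-syndrome (Q90-family) code excludes the
#' participant; four or more distinct subtype categories exclude the
#' participant; otherwise the most common category wins, ties broken by the
#' earliest-dated code among the tied categories (then by fixed precedence
#' AD > VaD > Other > Unspecified > MCI). A winner of AD or VaD yields that
#' label with index date equal to the earliest date of any code in the
#' winning category; a winner among Other/Unspecified/MCI is excluded; no
#' dementia-category codes at all yields `"none"`. Delirium (F05-family)
#' never counts as a dementia category, so it is automatically ignored as a
#' primary diagnosis while remaining available as a comorbidity.
#'
#' @param codes Character vector of ICD-10 codes (first instances).
#' @param dates `Date` vector parallel to `codes`.
#' @param map Code map from [dementia_code_map()].
#' @return List with `label` (`"AD"`, `"VaD"`, `"excluded"`, `"none"`),
#'   `reason` (for exclusions, else `NA`), `index_date` (`Date` or `NA`).
#' @export
resolve_overall_diagnosis <- function(codes, dates, map = dementia_code_map()) {
  stopifnot(length(codes) == length(dates))
  if (length(codes) == 0L) {
    return(list(label = "none", reason = NA_character_,
                index_date = as.Date(NA)))
  }
  norm <- parse_icd10(codes)
  dates <- as.Date(dates)
  if (any(startsWith(norm, "Q90"))) {
    return(list(label = "excluded", reason = "Down syndrome code",
                index_date = as.Date(NA)))
  }
  cat <- dementia_category(norm, map)
  keep <- cat != "none"
  if (!any(keep)) {
    return(list(label = "none", reason = NA_character_,
                index_date = as.Date(NA)))
  }
  cat <- cat[keep]; dt <- dates[keep]
  if (length(unique(cat)) >= 4L) {
    return(list(label = "excluded", reason = "four or more subtype categories",
                index_date = as.Date(NA)))
  }
  counts <- table(cat)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L) {
    # earliest-dated code among tied categories; date ties by precedence
    prec <- c("AD", "VaD", "Other", "Unspecified", "MCI")
    earliest <- vapply(top, function(k) min(as.numeric(dt[cat == k])), 0)
    top <- top[earliest == min(earliest)]
    top <- prec[prec %in% top][1L]
  }
  if (top %in% c("AD", "VaD")) {
    list(label = top, reason = NA_character_,
         index_date = min(dt[cat == top]))
  } else {
    only_minor <- all(unique(cat) %in% c("Other", "Unspecified", "MCI"))
    list(label = "excluded",
         reason = if (only_minor) "non-AD/VaD subtype categories only"
                  else "overall diagnosis not AD or VaD",
         index_date = as.Date(NA))
  }
}

#' Resolve diagnoses for a whole cohort
#'
#' Applies [resolve_overall_diagnosis()] to every participant and emits
#' summary counts. Participants without any inpatient events are excluded
#' (`"no inpatient data"`).
#'
#' @param participants Table from [read_participants()].
#' @param diagnoses Table from [read_diagnoses()].
#' @return `data.table` of cohort assignments: `id`, `label`, `reason`,
#'   `index_date`, `age_at_index` (years; birth assumed at mid-year since
#'   only birth year is available).
#' @export
build_dementia_cohort <- function(participants, diagnoses) {
  p <- data.table::as.data.table(participants)
  d <- .normalize_diagnoses(diagnoses)
  if (nrow(p) == 0L) stop("empty participants table", call. = FALSE)
  # fast path: participants with no dementia-category and no Q90 code are
  # "none" without running the per-participant resolver
  ucode <- unique(d$code)
  flagged <- ucode[dementia_category(ucode) != "none" | startsWith(parse_icd10(ucode), "Q90")]
  needs <- d[code %in% flagged, unique(id)]
  res_none <- data.table::data.table(
    id = setdiff(unique(d$id), needs), label = "none",
    reason = NA_character_, index_date = as.Date(NA))
  res <- d[id %in% needs][, {
    r <- resolve_overall_diagnosis(code, date)
    list(label = r$label, reason = r$reason,
         index_date = as.Date(r$index_date))
  }, by = id]
  res <- data.table::rbindlist(list(res, res_none), use.names = TRUE)
  out <- merge(p[, .(id, sex, birth_year, death_date)], res, by = "id",
               all.x = TRUE)
  out[is.na(label), `:=`(label = "excluded", reason = "no inpatient data")]
  out[, age_at_index := as.numeric(index_date - birth_date(birth_year)) / 365.25]
  counts <- out[, .N, by = .(label, reason)][order(label)]
  message("build_dementia_cohort: ",
          paste(sprintf("%s%s=%d", counts$label,
                        ifelse(is.na(counts$reason), "",
                               paste0(" (", counts$reason, ")")),
                        counts$N), collapse = ", "))
  out[]
}

# Accept either the raw schema (id, icd10_code, date) or the reader's
# (id, code, date); normalize codes and deduplicate to first instances.
.normalize_diagnoses <- function(d) {
  d <- data.table::as.data.table(d)
  if (!"code" %in% names(d) && "icd10_code" %in% names(d)) {
    d <- d[, .(id, code = icd10_code, date)]
  }
  d <- d[, .(id, code = parse_icd10(code), date = as.Date(date))]
  d[order(date), .SD[1L], by = .(id, code)][, .(id, code, date)]
}

#' Mid-year birth date from a birth year
#'
#' Only year of birth is available in the source data, so ages are computed
#' from July 1 of the birth year.
#'
#' @param birth_year Integer vector.
#' @return `Date` vector.
#' @export
birth_date <- function(birth_year) {
  as.Date(sprintf("%d-07-01", as.integer(birth_year)))
}

#' Match controls to cases by sex and age at index
#'
#' 1:1 greedy matching without replacement: cases are processed in order of
#' matching difficulty (fewest same-sex candidates within tolerance first),
#' each taking its nearest-age available candidate, with seeded random
#' tie-breaking among equally distant candidates. Each matched control
#' inherits its case's index date as a placeholder diagnosis flag date.
#'
#' @param cases Assignment rows for the cases (must have `id`, `sex`,
#'   `birth_year`, `index_date`).
#' @param pool Candidate controls (`id`, `sex`, `birth_year`, optionally
#'   `death_date`); callers must ensure these have no dementia-category codes
#'   anywhere in their records. When `death_date` is present, candidates who
#'   died before a case's index date are ineligible for that case (a control
#'   must be alive on its placeholder flag date).
#' @param tolerance_years Maximum |age difference| at index (default 1).
#' @param seed Integer seed for tie-breaking.
#' @return `data.table` of matched pairs: `case_id`, `control_id`, `sex`,
#'   `age_diff`, `index_date`. Unmatched cases are reported via warning and
#'   kept in the `unmatched` attribute.
#' @export
match_controls <- function(cases, pool, tolerance_years = 1.0, seed = 1L) {
  cs <- data.table::as.data.table(cases)
  pl <- data.table::as.data.table(pool)
  stopifnot(!any(cs$id %in% pl$id))
  set.seed(seed)
  case_age <- as.numeric(cs$index_date - birth_date(cs$birth_year)) / 365.25
  pool_age_at <- function(idx_date, rows) {
    as.numeric(idx_date - birth_date(pl$birth_year[rows])) / 365.25
  }
  pool_death <- if ("death_date" %in% names(pl)) pl$death_date
                else rep(as.Date(NA), nrow(pl))
  alive_at <- function(idx_date, rows) {
    is.na(pool_death[rows]) | pool_death[rows] >= idx_date
  }
  pairs <- vector("list", nrow(cs))
  used <- rep(FALSE, nrow(pl))
  # difficulty = candidate count within tolerance, rarest stratum first
  diff_n <- vapply(seq_len(nrow(cs)), function(i) {
    rows <- which(pl$sex == cs$sex[i])
    rows <- rows[alive_at(cs$index_date[i], rows)]
    sum(abs(pool_age_at(cs$index_date[i], rows) - case_age[i]) <= tolerance_years)
  }, 0L)
  ord <- order(diff_n, sample.int(nrow(cs)))
  for (i in ord) {
    rows <- which(pl$sex == cs$sex[i] & !used)
    rows <- rows[alive_at(cs$index_date[i], rows)]
    if (!length(rows)) next
    d <- abs(pool_age_at(cs$index_date[i], rows) - case_age[i])
    ok <- d <= tolerance_years
    if (!any(ok)) next
    rows <- rows[ok]; d <- d[ok]
    best <- rows[d == min(d)]
    pick <- if (length(best) > 1L) sample(best, 1L) else best
    used[pick] <- TRUE
    pairs[[i]] <- data.table::data.table(
      case_id = cs$id[i], control_id = pl$id[pick], sex = cs$sex[i],
      age_diff = min(d), index_date = cs$index_date[i])
  }
  out <- data.table::rbindlist(pairs)
  unmatched <- cs$id[!cs$id %in% out$case_id]
  if (length(unmatched)) {
    warning(sprintf("match_controls: %d case(s) unmatched", length(unmatched)),
            call. = FALSE)
  }
  data.table::setattr(out, "unmatched", unmatched)
  out[]
}

#' Build the hip-fracture control-disease cohort
#'
#' Participants with any S72-family (femoral fracture) code and no
#' dementia-category code anywhere are included, with index date equal to
#' their earliest fracture code date. Used to re-run the full analysis on a
#' non-dementia disease, testing specificity of dementia-associated
#' patterns.
#'
#' @param participants,diagnoses As in [build_dementia_cohort()].
#' @param fracture_stem Code family stem (default `"S72"`).
#' @return `data.table` of assignments with `label = "control_disease"`.
#' @export
build_control_disease_cohort <- function(participants, diagnoses,
                                         fracture_stem = "S72") {
  p <- data.table::as.data.table(participants)
  d <- .normalize_diagnoses(diagnoses)
  has_dementia <- d[dementia_category(code) != "none", unique(id)]
  frac <- d[startsWith(code, fracture_stem) & !id %in% has_dementia,
            .(index_date = min(date)), by = id]
  if (nrow(frac) == 0L) {
    warning("empty control-disease cohort", call. = FALSE)
  }
  out <- merge(frac, p[, .(id, sex, birth_year, death_date)], by = "id")
  out[, `:=`(label = "control_disease", reason = NA_character_,
             age_at_index = as.numeric(index_date - birth_date(birth_year)) / 365.25)]
  out[]
}
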