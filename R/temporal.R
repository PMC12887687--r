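# Temporal mapping: signed offsets from the index date, the pre/post window
# scheme, and cumulative presence matrices with "new in window" flags.

#' Default time windows relative to the index date
#'
#' Seven pre-diagnosis windows partition all time before the index date, with
#' span narrowing toward diagnosis (20+ years before down to 0-2 years
#' before), and five cumulative post-diagnosis windows anchored at the index
#' date ((0,2] through (0,10] years after). Boundary convention: a pre window
#' "a to b years before" covers offsets in `(-b, -a]`; "20+ before" covers
#' offsets `<= -20`; an offset of exactly 0 (codes recorded on the diagnosis
#' day) falls in "0-2 before", treating same-admission codes as pre-existing
#' burden. Post window "0-k after" covers `(0, k]`; offsets beyond +10 years
#' are outside every window.
#'
#' @param diagnosis_day_pre If `FALSE`, offset 0 is assigned to the post
#'   windows instead of "0-2 before".
#' @return A `data.table` with columns `label`, `lo`, `hi`, `kind`
#'   (`"pre"`/`"post_cumulative"`), in chronological order.
#' @export
default_windows <- function(diagnosis_day_pre = TRUE) {
  w <- data.table::data.table(
    label = c("20+ before", "15-20 before", "10-15 before", "7-10 before",
              "5-7 before", "2-5 before", "0-2 before",
              "0-2 after", "0-4 after", "0-6 after", "0-8 after",
              "0-10 after"),
    lo = c(-Inf, -20, -15, -10, -7, -5, -2, 0, 0, 0, 0, 0),
    hi = c(-20, -15, -10, -7, -5, -2, 0, 2, 4, 6, 8, 10),
    kind = c(rep("pre", 7L), rep("post_cumulative", 5L))
  )
  attr(w, "diagnosis_day_pre") <- diagnosis_day_pre
  w
}

#' Signed offset in years between an event and the index date
#'
#' @param event_date,index_date `Date` vectors (recycled).
#' @return Numeric years, `(event - index) / 365.25`; negative before index.
#' @examples
#' offset_years(as.Date("2000-01-01"), as.Date("2010-01-01"))
#' @export
offset_years <- function(event_date, index_date) {
  if (anyNA(event_date) || anyNA(index_date)) {
    stop("missing date in offset_years()", call. = FALSE)
  }
  as.numeric(as.Date(event_date) - as.Date(index_date)) / 365.25
}

#' Assign a signed offset to its time window(s)
#'
#' Pre-index offsets land in exactly one pre window; post-index offsets land
#' in every cumulative post window containing them; offsets beyond +10 years
#' land nowhere.
#'
#' @param offset Numeric vector of signed year offsets.
#' @param windows Window table from [default_windows()].
#' @return A list (one element per offset) of window label character vectors.
#' @examples
#' assign_window(c(-8.2, 3, -25))
#' @export
assign_window <- function(offset, windows = default_windows()) {
  day_pre <- isTRUE(attr(windows, "diagnosis_day_pre"))
  lapply(offset, function(o) {
    if (is.na(o)) return(character(0))
    pre_side <- o < 0 || (o == 0 && day_pre)
    if (pre_side) {
      hit <- windows$kind == "pre" &
        ((o > windows$lo & o <= windows$hi) | (o == 0 & windows$hi == 0))
    } else {
      hit <- windows$kind == "post_cumulative" & o > windows$lo & o <= windows$hi
      if (o == 0 && !day_pre) hit <- windows$kind == "post_cumulative"
    }
    windows$label[hit]
  })
}

#' Map diagnosis events to offsets from each participant's index date
#'
#' Joins first-instance diagnosis events to cohort index dates and computes
#' signed year offsets. Participants without an index date are dropped with a
#' warning. Dementia subtype codes themselves can be excluded so that
#' comorbidity analyses do not trivially separate cases from controls.
#'
#' @param diagnoses `data.table` with `id`, `code`, `date` (first instances).
#' @param assignments Cohort assignments with `id` and `index_date` (see
#'   [build_dementia_cohort()] and [match_controls()]).
#' @param drop_dementia_codes Drop events whose code is in any dementia
#'   subtype set (default `TRUE`): index-defining codes are not comorbidities.
#' @param drop_stems Additional code-family stems to drop, e.g. the fracture
#'   family defining a control-disease cohort.
#' @return `data.table` with `id`, `code`, `offset`.
#' @export
map_event_offsets <- function(diagnoses, assignments,
                              drop_dementia_codes = TRUE,
                              drop_stems = NULL) {
  dg <- data.table::as.data.table(diagnoses)
  as_dt <- data.table::as.data.table(assignments)[!is.na(index_date),
                                                  .(id, index_date)]
  ev <- merge(dg, as_dt, by = "id")
  ev[, code := parse_icd10(code)]
  if (drop_dementia_codes) {
    ucode <- unique(ev$code)
    drop <- ucode[dementia_category(ucode) != "none"]
    ev <- ev[!code %in% drop]
  }
  for (s in drop_stems) ev <- ev[!startsWith(code, s)]
  ev[, offset := offset_years(date, index_date)]
  ev[, .(id, code, offset)]
}

#' Build a per-window presence matrix
#'
#' For one time window, codes each (participant, condition) cell as `absent`
#' (0), `present` (1), or `new` (2). Diagnoses are treated as permanent once
#' recorded, so presence is cumulative: a condition is `present` in window
#' `w` if its first instance falls at or before the window's upper bound, and
#' `new` if the first instance falls inside the window itself (for cumulative
#' post windows, anywhere in `(0, hi]`). At block level a participant's block
#' indicator is present iff any member code is present, and the per-block sum
#' of distinct present codes is returned alongside.
#'
#' @param offsets Event offsets from [map_event_offsets()].
#' @param ids Participant ids to include as rows (all-absent rows are kept so
#'   cohort denominators are explicit).
#' @param window A single row of the window table (or its label).
#' @param level `"code"` or `"block"`.
#' @param windows Full window table (used to resolve a label).
#' @param block_table Block table for `level = "block"`.
#' @return An object of class `presence_matrix`: list with `status` (integer
#'   matrix, participants x conditions, 0/1/2), `window`, `level`, `kind`,
#'   and for block level `sums` (distinct present codes per block).
#' @export
build_presence_matrix <- function(offsets, ids, window,
                                  level = c("code", "block"),
                                  windows = default_windows(),
                                  block_table = load_block_table()) {
  level <- match.arg(level)
  if (is.character(window)) {
    window <- windows[label == window]
    if (nrow(window) != 1L) stop("unknown window label", call. = FALSE)
  }
  day_pre <- isTRUE(attr(windows, "diagnosis_day_pre"))
  ev <- data.table::as.data.table(offsets)[id %in% ids]
  if (level == "block") {
    ev <- ev[, .(id, cond = code_to_block(code, block_table), code, offset)]
  } else {
    ev <- ev[, .(id, cond = code, code, offset)]
  }

  lo <- window$lo; hi <- window$hi
  in_win <- function(o) {
    if (window$kind == "pre") {
      (o > lo & o <= hi) | (o == 0 & hi == 0 & day_pre)
    } else {
      o > lo & o <= hi
    }
  }
  # presence is cumulative up to the window's upper bound; diagnosis-day
  # events count as pre when the convention says so
  is_present <- function(o) {
    if (window$kind == "pre") o <= hi | (o == 0 & hi == 0 & day_pre) else o <= hi
  }

  # first instance per (participant, condition)
  first <- ev[, .(offset = min(offset)), by = .(id, cond)]
  first <- first[is_present(offset)]
  first[, status := ifelse(in_win(offset), 2L, 1L)]

  conds <- sort(unique(first$cond))
  mat <- matrix(0L, nrow = length(ids), ncol = length(conds),
                dimnames = list(ids, conds))
  if (nrow(first)) {
    mat[cbind(match(first$id, ids), match(first$cond, conds))] <- first$status
  }
  out <- list(status = mat, window = window$label, kind = window$kind,
              level = level, n = length(ids))
  if (level == "block") {
    firstc <- ev[, .(offset = min(offset)), by = .(id, cond, code)]
    firstc <- firstc[is_present(offset)]
    cnt <- firstc[, .N, by = .(id, cond)]
    sums <- matrix(0L, nrow = length(ids), ncol = length(conds),
                   dimnames = list(ids, conds))
    if (nrow(cnt)) {
      sums[cbind(match(cnt$id, ids), match(cnt$cond, conds))] <- cnt$N
    }
    out$sums <- sums
  }
  structure(out, class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: window '%s' (%s), level %s, %d participants x %d conditions\n",
              x$window, x$kind, x$level, nrow(x$status), ncol(x$status)))
  cat(sprintf("  present cells: %d (of which new: %d)\n",
              sum(x$status >= 1L), sum(x$status == 2L)))
  invisible(x)
}

#' Binary presence indicators from a presence matrix
#'
#' @param pm A `presence_matrix`.
#' @return Integer 0/1 matrix (present-or-new vs absent).
#' @export
presence_indicator <- function(pm) {
  (pm$status >= 1L) + 0L
}
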