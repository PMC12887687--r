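# ICD-10 code handling: normalization, block/chapter roll-up (WHO version
# 2019 block table shipped in extdata), and dementia subtype classification.

.comorbmap_env <- new.env(parent = emptyenv())

#' Parse and normalize ICD-10 codes
#'
#' Normalizes raw ICD-10 codes to the dotless uppercase form used throughout
#' the package (`"F00.1"` and `"f001"` both become `"F001"`). A valid
#' normalized code is one uppercase letter, two digits, and up to two further
#' alphanumerics. Normalization is idempotent.
#'
#' @param raw Character vector of codes, dotted or dotless, any case.
#' @return Character vector of normalized codes.
#' @examples
#' parse_icd10(c("F00.1", "g30", "I63.9"))
#' @export
parse_icd10 <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  if (!is.character(raw)) raw <- as.character(raw)
  norm <- toupper(gsub("[.[:space:]]", "", raw))
  bad <- is.na(norm) | !grepl("^[A-Z][0-9]{2}[0-9A-Z]{0,2}$", norm)
  if (any(bad)) {
    stop("malformed ICD-10 code(s): ",
         paste(unique(raw[bad]), collapse = ", "), call. = FALSE)
  }
  norm
}

#' Load the WHO ICD-10 (2019) block/chapter table
#'
#' Reads the packaged plain-text table mapping 3-character code ranges to
#' blocks (e.g. `F00-F09`) and chapters (e.g. chapter V, mental and
#' behavioural disorders). Ranges are non-overlapping; gaps in the code space
#' (ranges WHO leaves unassigned) are not covered and trigger lookup errors.
#'
#' @param path Optional path to an alternative table with the same columns
#'   (`start`, `end`, `block`, `chapter_num`, `chapter_roman`,
#'   `chapter_label`).
#' @return A `data.table` with one row per block, plus integer sort keys.
#' @export
load_block_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.comorbmap_env$block_table)) return(.comorbmap_env$block_table)
    path <- system.file("extdata", "icd10_blocks.tsv", package = "comorbmap",
                        mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("start", "end", "block", "chapter_roman", "chapter_label"),
    integer = "chapter_num"))
  tab[, `:=`(start_key = .icd10_key(start), end_key = .icd10_key(end))]
  data.table::setkey(tab, start_key)
  if (any(tab$end_key < tab$start_key)) stop("block table has inverted ranges")
  if (any(utils::head(tab$end_key, -1L) >= utils::tail(tab$start_key, -1L))) {
    stop("block table ranges overlap")
  }
  if (cache) .comorbmap_env$block_table <- tab
  tab
}

# Integer sort key for a 3-character code: letter*100 + 2-digit number.
.icd10_key <- function(code3) {
  match(substr(code3, 1L, 1L), LETTERS) * 100L +
    as.integer(substr(code3, 2L, 3L))
}

.block_row <- function(codes, table) {
  key <- .icd10_key(substr(parse_icd10(codes), 1L, 3L))
  idx <- findInterval(key, table$start_key)
  hit <- idx >= 1L & key <= table$end_key[pmax(idx, 1L)]
  if (!all(hit)) {
    stop("ICD-10 code(s) not covered by any block: ",
         paste(unique(codes[!hit]), collapse = ", "), call. = FALSE)
  }
  idx
}

#' Map ICD-10 codes to their block
#'
#' Four-character codes inherit the block of their 3-character prefix
#' (standard ICD-10 convention).
#'
#' @param codes Character vector of ICD-10 codes (dotted or dotless).
#' @param table Block table from [load_block_table()].
#' @return Character vector of block ids, e.g. `"F00-F09"`.
#' @examples
#' code_to_block(c("F001", "I63.9", "G30"))
#' @export
code_to_block <- function(codes, table = load_block_table()) {
  table$block[.block_row(codes, table)]
}

#' Map ICD-10 codes to their chapter
#'
#' @inheritParams code_to_block
#' @param value `"roman"` for the chapter numeral (`"V"`, `"XIX"`, ...),
#'   `"number"` for the integer, `"label"` for the chapter title.
#' @return Vector of chapter identifiers, one per code.
#' @examples
#' code_to_chapter(c("F001", "G30", "S720"))
#' @export
code_to_chapter <- function(codes, table = load_block_table(),
                            value = c("roman", "number", "label")) {
  value <- match.arg(value)
  row <- .block_row(codes, table)
  switch(value,
         roman = table$chapter_roman[row],
         number = table$chapter_num[row],
         label = table$chapter_label[row])
}

#' Dementia subtype code sets
#'
#' The ICD-10 code sets used to resolve an overall dementia diagnosis:
#' Alzheimer's disease (AD), vascular dementia (VaD), other dementias,
#' unspecified dementia, and mild cognitive impairment (MCI), plus the
#' primary-diagnosis exclusion families (F05 delirium, which is kept as a
#' comorbidity but never counts as a dementia diagnosis, and Q90 Down
#' syndrome, which excludes the participant outright).
#'
#' @return A list with character vectors `AD`, `VaD`, `Other`, `Unspecified`,
#'   `MCI`, and `primary_exclusion_stems`.
#' @export
dementia_code_map <- function() {
  list(
    AD = c("F00", "F001", "F002", "F009", "G30", "G301", "G308", "G309"),
    VaD = c("F01", "F011", "F012", "F013", "F018", "F019"),
    Other = c("F02", "F021", "F022", "F023", "F024", "F028", "G31"),
    Unspecified = "F03",
    MCI = "F067",
    primary_exclusion_stems = c("F05", "Q90")
  )
}

#' Classify ICD-10 codes against the dementia code sets
#'
#' Exact matches against the subtype sets are tried first; otherwise a
#' 4-character code falls back to its 3-character prefix (so `F005` counts as
#' AD via `F00`, while `F068` stays `none` because only `F067` is MCI).
#'
#' @param codes Character vector of ICD-10 codes.
#' @param map Code map from [dementia_code_map()].
#' @return Character vector over `{"AD","VaD","Other","Unspecified","MCI",
#'   "none"}`.
#' @examples
#' dementia_category(c("G301", "F013", "F067", "J189"))
#' @export
dementia_category <- function(codes, map = dementia_code_map()) {
  norm <- parse_icd10(codes)
  cats <- c("AD", "VaD", "Other", "Unspecified", "MCI")
  lookup <- unlist(lapply(cats, function(k) {
    stats::setNames(rep(k, length(map[[k]])), map[[k]])
  }))
  out <- unname(lookup[norm])
  miss <- is.na(out)
  if (any(miss)) out[miss] <- unname(lookup[substr(norm[miss], 1L, 3L)])
  out[is.na(out)] <- "none"
  out
}

#' Flag primary-diagnosis exclusion codes (F05 / Q90 families)
#'
#' Family membership means the normalized code starts with the stem, so
#' `F050`, `F059`, `Q909` are all flagged.
#'
#' @inheritParams dementia_category
#' @return Logical vector.
#' @export
is_primary_exclusion <- function(codes, map = dementia_code_map()) {
  norm <- parse_icd10(codes)
  stems <- map$primary_exclusion_stems
  Reduce(`|`, lapply(stems, function(s) startsWith(norm, s)))
}

#' Strip the "unspecified" suffix from condition names for display
#'
#' ICD-10 condition titles frequently end in ", unspecified"; for readability
#' of ranked tables the suffix is removed from the display label while the
#' code itself is untouched.
#'
#' @param names Character vector of condition names.
#' @return Character vector of display labels.
#' @export
display_label <- function(names) {
  trimws(sub(",?\\s*unspecified\\s*$", "", names, ignore.case = TRUE))
}
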