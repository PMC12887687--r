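# Synthetic first-instance ICD-10 inpatient histories with the statistical
# structure the analysis assumes: age-dependent baseline incidence in
# discrete annual steps, latent subtype groups with scheduled diagnosis
# dates, window-specific planted odds enrichment, a death model, and a
# simulated polygenic risk score. Stands in for access-restricted inpatient
# extracts; every generated case carries its ground truth.

#' Curated default condition catalog
#'
#' Roughly fifty real ICD-10 conditions spanning the chapters that dominate
#' older-adult inpatient coding (circulatory, metabolic, respiratory,
#' musculoskeletal, genitourinary, mental health, injury), each with a
#' baseline annual first-admission probability at age 60 and a log-linear
#' age slope per year. Dementia subtype codes, Q90 and S72 are deliberately
#' absent (the generator plants those itself); F05 delirium is present since
#' it is retained as a comorbidity.
#'
#' @return `data.table` with `code`, `name`, `p60`, `slope`.
#' @export
default_condition_catalog <- function() {
  data.table::rbindlist(list(
    list("I10", "Essential hypertension", 0.012, 0.050),
    list("E11", "Type 2 diabetes mellitus", 0.0060, 0.040),
    list("E10", "Type 1 diabetes mellitus", 0.0012, 0.010),
    list("F32", "Depressive episode", 0.0040, 0.015),
    list("F05", "Delirium", 0.0008, 0.120),
    list("I63", "Cerebral infarction", 0.0025, 0.080),
    list("I61", "Intracerebral haemorrhage", 0.0008, 0.070),
    list("G45", "Transient cerebral ischaemic attack", 0.0020, 0.070),
    list("I69", "Sequelae of cerebrovascular disease", 0.0010, 0.080),
    list("I20", "Angina pectoris", 0.0050, 0.050),
    list("I21", "Acute myocardial infarction", 0.0030, 0.060),
    list("I25", "Chronic ischaemic heart disease", 0.0070, 0.060),
    list("I48", "Atrial fibrillation and flutter", 0.0060, 0.080),
    list("I50", "Heart failure", 0.0040, 0.090),
    list("I73", "Peripheral vascular disease", 0.0015, 0.060),
    list("E03", "Hypothyroidism", 0.0020, 0.020),
    list("E05", "Thyrotoxicosis", 0.0010, 0.010),
    list("E87", "Disorders of fluid and electrolyte balance", 0.0020, 0.090),
    list("E78", "Disorders of lipoprotein metabolism", 0.0040, 0.040),
    list("D50", "Iron deficiency anaemia", 0.0030, 0.050),
    list("D64", "Other anaemias", 0.0010, 0.070),
    list("G40", "Epilepsy", 0.0015, 0.010),
    list("G47", "Sleep disorders", 0.0020, 0.020),
    list("J18", "Pneumonia", 0.0040, 0.090),
    list("J22", "Acute lower respiratory infection", 0.0020, 0.080),
    list("J44", "Chronic obstructive pulmonary disease", 0.0040, 0.060),
    list("J45", "Asthma", 0.0030, 0.000),
    list("K21", "Gastro-oesophageal reflux disease", 0.0050, 0.020),
    list("K29", "Gastritis and duodenitis", 0.0040, 0.020),
    list("K59", "Functional intestinal disorders", 0.0030, 0.040),
    list("K80", "Cholelithiasis", 0.0050, 0.030),
    list("K57", "Diverticular disease of intestine", 0.0040, 0.050),
    list("M06", "Rheumatoid arthritis", 0.0012, 0.020),
    list("M16", "Coxarthrosis", 0.0030, 0.050),
    list("M17", "Gonarthrosis", 0.0040, 0.040),
    list("M47", "Spondylosis", 0.0030, 0.030),
    list("M54", "Dorsalgia", 0.0060, 0.010),
    list("M81", "Osteoporosis without pathological fracture", 0.0020, 0.070),
    list("N17", "Acute renal failure", 0.0020, 0.090),
    list("N18", "Chronic kidney disease", 0.0015, 0.080),
    list("N39", "Other disorders of urinary system", 0.0060, 0.080),
    list("N20", "Calculus of kidney and ureter", 0.0030, 0.010),
    list("L89", "Decubitus ulcer", 0.0008, 0.120),
    list("L03", "Cellulitis", 0.0020, 0.050),
    list("B37", "Candidiasis", 0.0010, 0.060),
    list("A41", "Other sepsis", 0.0015, 0.100),
    list("R55", "Syncope and collapse", 0.0030, 0.050),
    list("R63", "Symptoms concerning food and fluid intake", 0.0015, 0.080),
    list("R32", "Urinary incontinence", 0.0010, 0.100),
    list("W19", "Unspecified fall", 0.0020, 0.090),
    list("S09", "Head injury", 0.0020, 0.060),
    list("S32", "Fracture of lumbar spine and pelvis", 0.0010, 0.070),
    list("H25", "Senile cataract", 0.0040, 0.060),
    list("H35", "Other retinal disorders", 0.0015, 0.050),
    list("F10", "Alcohol-related disorders", 0.0030, 0.000),
    list("F17", "Tobacco-related mental and behavioural disorders", 0.0040, 0.000),
    list("C44", "Other malignant neoplasms of skin", 0.0030, 0.050),
    list("C61", "Malignant neoplasm of prostate", 0.0020, 0.060),
    list("C50", "Malignant neoplasm of breast", 0.0020, 0.020),
    list("G20", "Parkinson disease", 0.0005, 0.100),
    list("I67", "Other cerebrovascular diseases", 0.0006, 0.090),
    list("K90", "Intestinal malabsorption", 0.0005, 0.050)
  ), use.names = FALSE)[, stats::setNames(.SD, c("code", "name", "p60", "slope"))]
}

#' Extend a condition catalog with synthetic filler codes
#'
#' Adds valid random ICD-10 3-character codes (covered by the WHO block
#' table, excluding dementia, Q90 and S72 families) with log-uniform baseline
#' probabilities, for large-catalog simulation studies.
#'
#' @param n Number of filler codes to add.
#' @param seed Seed for code and parameter draws.
#' @param base Catalog to extend (default [default_condition_catalog()]).
#' @param p60_range Baseline annual probability range (log-uniform).
#' @param slope_range Age slope range (uniform).
#' @return `data.table` catalog with `n` extra rows.
#' @export
synthetic_catalog <- function(n, seed = 1L, base = default_condition_catalog(),
                              p60_range = c(5e-4, 1e-2),
                              slope_range = c(0, 0.06)) {
  set.seed(seed)
  tab <- load_block_table()
  reserved <- c("F00", "F01", "F02", "F03", "F05", "F06", "G30", "G31",
                "Q90", "S72", base$code)
  pool <- unlist(lapply(seq_len(nrow(tab)), function(i) {
    lo <- tab$start_key[i]; hi <- tab$end_key[i]
    keys <- lo:hi
    paste0(LETTERS[keys %/% 100L], sprintf("%02d", keys %% 100L))
  }))
  pool <- setdiff(pool, reserved)
  codes <- sample(pool, n)
  extra <- data.table::data.table(
    code = codes,
    name = paste("Synthetic condition", codes),
    p60 = exp(stats::runif(n, log(p60_range[1]), log(p60_range[2]))),
    slope = stats::runif(n, slope_range[1], slope_range[2]))
  data.table::rbindlist(list(base, extra))
}

#' Synthetic population configuration
#'
#' Bundles and validates every knob of the generator. Defaults emulate an
#' older UK cohort observed through inpatient records: births 1936-1945,
#' observation from age 40 to an administrative censor date of 2024-04-30,
#' dementia diagnosis age normal(75, 5) truncated to [62, 86] (and below the
#' censor), a Gompertz-like death model (annual probability 0.004 at age 60
#' doubling every 8 years, multiplied 4-fold after the index event), and a
#' standard-normal polygenic risk score shifted by +0.5 SD in AD and
#' +0.25 SD in VaD.
#'
#' @param n_ad,n_vad,n_background,n_control_disease Group sizes (cases,
#'   background pool for controls, hip-fracture cohort).
#' @param seed Integer seed; the generator is deterministic given the config.
#' @param catalog Condition catalog (`code`, `p60`, `slope`).
#' @param planted `data.table` of planted effects with columns `cohort`
#'   (`"AD"`/`"VaD"`/`"control_disease"`), `code`, `window` (label in
#'   `windows`), `multiplier` (odds scale, per in-window year), or `NULL`.
#' @param birth_year_range Inclusive integer range.
#' @param diagnosis_age List `mean`, `sd`, `lo`, `hi` (truncated normal, in
#'   years) for the dementia diagnosis age.
#' @param fracture_age Same structure for the hip-fracture index age
#'   (fractures cluster later in life than this cohort's diagnoses).
#' @param death List `p60`, `slope`, `post_index_multiplier`, `cap`.
#' @param observation List `start_age`, `censor_date`.
#' @param prs List `shift_ad`, `shift_vad`.
#' @param windows Window table interpreting planted window labels.
#' @return Validated config (class `synthetic_config`).
#' @export
synthetic_config <- function(n_ad = 400L, n_vad = 200L, n_background = 2000L,
                             n_control_disease = 300L, seed = 1L,
                             catalog = default_condition_catalog(),
                             planted = NULL,
                             birth_year_range = c(1936L, 1945L),
                             diagnosis_age = list(mean = 75, sd = 5,
                                                  lo = 62, hi = 86),
                             fracture_age = list(mean = 77, sd = 6,
                                                 lo = 60, hi = 92),
                             death = list(p60 = 0.004, slope = log(2) / 8,
                                          post_index_multiplier = 4, cap = 0.6),
                             observation = list(start_age = 40,
                                                censor_date = as.Date("2024-04-30")),
                             prs = list(shift_ad = 0.5, shift_vad = 0.25),
                             windows = default_windows()) {
  bad <- character(0)
  if (any(c(n_ad, n_vad, n_background, n_control_disease) < 0)) bad <- c(bad, "counts")
  if (!all(catalog$p60 > 0 & catalog$p60 < 1)) bad <- c(bad, "catalog$p60")
  if (!is.null(planted)) {
    planted <- data.table::as.data.table(planted)
    req <- c("cohort", "code", "window", "multiplier")
    if (!all(req %in% names(planted))) bad <- c(bad, "planted columns")
    else {
      if (!all(planted$multiplier > 0)) bad <- c(bad, "planted$multiplier")
      if (!all(planted$window %in% windows$label)) bad <- c(bad, "planted$window")
      if (!all(planted$code %in% catalog$code)) bad <- c(bad, "planted$code")
    }
  }
  if (!(death$p60 > 0 && death$p60 < 1)) bad <- c(bad, "death$p60")
  if (length(bad)) {
    stop("invalid synthetic config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    n_ad = as.integer(n_ad), n_vad = as.integer(n_vad),
    n_background = as.integer(n_background),
    n_control_disease = as.integer(n_control_disease),
    seed = as.integer(seed), catalog = data.table::as.data.table(catalog),
    planted = planted, birth_year_range = as.integer(birth_year_range),
    diagnosis_age = diagnosis_age, fracture_age = fracture_age, death = death,
    observation = list(start_age = observation$start_age,
                       censor_date = as.Date(observation$censor_date)),
    prs = prs, windows = windows), class = "synthetic_config")
}

# Annual probability at integer-year index t (ages [a, a+1), midpoint a+0.5).
.annual_p <- function(p60, slope, age_mid, cap = 0.5) {
  pmin(cap, p60 * exp(slope * (age_mid - 60)))
}

#' Generate a synthetic population
#'
#' Simulates, per participant: sex (fair coin), birth year (uniform over the
#' configured range), for cases a scheduled diagnosis age (truncated normal,
#' kept below the censor date) with the subtype's ICD-10 codes recorded at
#' that date, a death year from the discrete-hazard death model (cases are
#' conditioned to survive to diagnosis; the post-index multiplier applies
#' after the index), and first-instance condition events: each year of
#' observation from the start age, every not-yet-diagnosed catalog condition
#' occurs with its age-dependent annual probability, odds-multiplied by any
#' planted effect whose cohort and window (relative to the scheduled
#' diagnosis) match. Only first instances are kept; no event postdates death
#' or the censor date. Hip-fracture (control-disease) participants receive an
#' S720 code at a sampled index age and no dementia codes. Occasional extra
#' dementia codes (a second code of the same subtype, or an unspecified-
#' dementia F03 after the index) exercise the diagnosis-resolution workflow
#' without changing the majority category.
#'
#' @param config A [synthetic_config()].
#' @return List with `participants`, `diagnoses` (CSV-ready `data.table`s
#'   with columns `id`, `sex`, `birth_year`, `death_date` and `id`,
#'   `icd10_code`, `date`), `prs` (`id`, `group`, `prs`), and `truth`
#'   (per-participant latent group and scheduled diagnosis date, plus the
#'   planted-effect table).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  ob <- config$observation
  n <- config$n_ad + config$n_vad + config$n_background + config$n_control_disease
  group <- rep(c("AD", "VaD", "background", "control_disease"),
               c(config$n_ad, config$n_vad, config$n_background,
                 config$n_control_disease))
  id <- sprintf("P%06d", seq_len(n))
  sex <- sample(c("female", "male"), n, replace = TRUE)
  birth_year <- sample(seq(config$birth_year_range[1], config$birth_year_range[2]),
                       n, replace = TRUE)
  bdate <- birth_date(birth_year)
  censor_age <- as.numeric(ob$censor_date - bdate) / 365.25

  # scheduled index age (dementia diagnosis or hip fracture), kept >= 1 year
  # before the censor so the index event is observable
  has_index <- group %in% c("AD", "VaD", "control_disease")
  is_frac <- group == "control_disease"
  da <- config$diagnosis_age; fa <- config$fracture_age
  mean_i <- ifelse(is_frac, fa$mean, da$mean)
  sd_i <- ifelse(is_frac, fa$sd, da$sd)
  lo_i <- ifelse(is_frac, fa$lo, da$lo)
  hi_i <- pmin(ifelse(is_frac, fa$hi, da$hi), censor_age - 1)
  index_age <- rep(NA_real_, n)
  u <- stats::runif(n, stats::pnorm(lo_i, mean_i, sd_i),
                    stats::pnorm(hi_i, mean_i, sd_i))
  index_age[has_index] <- stats::qnorm(u, mean_i, sd_i)[has_index]
  index_date <- bdate + round(index_age * 365.25)

  # common annual grid from the observation start age
  t_max <- as.integer(ceiling(max(censor_age))) - ob$start_age
  age_mid <- ob$start_age + seq_len(t_max) - 0.5

  # --- death model ---------------------------------------------------------
  dh <- .annual_p(config$death$p60, config$death$slope, age_mid,
                  cap = config$death$cap)
  H <- matrix(dh, nrow = n, ncol = t_max, byrow = TRUE)
  post <- outer(rep(1, n), age_mid)
  post <- sweep(post, 1, ifelse(has_index, index_age, Inf), `-`) > 0
  H[post] <- pmin(config$death$cap, H[post] * config$death$post_index_multiplier)
  # cases survive to their index by construction
  pre_index <- sweep(outer(rep(1, n), age_mid), 1,
                     ifelse(has_index, index_age, -Inf), `-`) < 0
  H[has_index & pre_index] <- 0
  u_death <- stats::runif(n)
  Fd <- matrix(0, n, t_max)
  ls <- rep(0, n)
  for (t in seq_len(t_max)) {
    ls <- ls + log1p(-H[, t])
    Fd[, t] <- 1 - exp(ls)
  }
  death_t <- rowSums(Fd < u_death) + 1L   # first year index with F >= u
  died <- death_t <= t_max
  death_frac <- stats::runif(n)
  death_age <- ob$start_age + death_t - 1L + death_frac
  death_date <- bdate + round(death_age * 365.25)
  death_date[has_index & died] <- pmax(death_date[has_index & died],
                                       index_date[has_index & died] + 1L)
  death_date[died & death_date > ob$censor_date] <- NA  # censored after cutoff
  death_date[!died] <- NA
  end_date <- pmin(data.table::fifelse(is.na(death_date),
                                       ob$censor_date, death_date),
                   ob$censor_date)

  # --- condition events ----------------------------------------------------
  cat_tab <- config$catalog
  planted <- config$planted
  win <- config$windows
  events <- vector("list", nrow(cat_tab))
  for (ci in seq_len(nrow(cat_tab))) {
    p_t <- .annual_p(cat_tab$p60[ci], cat_tab$slope[ci], age_mid)
    u <- stats::runif(n)
    pl <- if (is.null(planted)) NULL else planted[code == cat_tab$code[ci]]
    t_first <- rep(NA_integer_, n)
    plain <- rep(TRUE, n)
    if (!is.null(pl) && nrow(pl)) {
      for (g in unique(pl$cohort)) {
        rows <- which(group == g)
        if (!length(rows)) next
        plain[rows] <- FALSE
        M <- matrix(p_t, nrow = length(rows), ncol = t_max, byrow = TRUE)
        off <- outer(index_age[rows], age_mid, function(a, m) m - a)
        for (k in which(pl$cohort == g)) {
          wrow <- win[label == pl$window[k]]
          in_w <- off > wrow$lo & off <= wrow$hi
          odds <- M[in_w] / (1 - M[in_w]) * pl$multiplier[k]
          M[in_w] <- odds / (1 + odds)
        }
        Fw <- matrix(0, length(rows), t_max)
        ls <- rep(0, length(rows))
        for (t in seq_len(t_max)) {
          ls <- ls + log1p(-M[, t])
          Fw[, t] <- 1 - exp(ls)
        }
        tf <- rowSums(Fw < u[rows]) + 1L
        tf[tf > t_max] <- NA_integer_
        t_first[rows] <- tf
      }
    }
    if (any(plain)) {
      Fc <- 1 - exp(cumsum(log1p(-p_t)))
      tf <- findInterval(u[plain], Fc) + 1L
      tf[tf > t_max] <- NA_integer_
      t_first[plain] <- tf
    }
    hit <- which(!is.na(t_first))
    if (!length(hit)) next
    frac <- stats::runif(length(hit))
    ev_date <- bdate[hit] +
      round((ob$start_age + t_first[hit] - 1L + frac) * 365.25)
    keep <- ev_date <= end_date[hit]
    events[[ci]] <- data.table::data.table(
      id = id[hit[keep]], icd10_code = cat_tab$code[ci],
      date = ev_date[keep])
  }

  # --- index-defining codes ------------------------------------------------
  map <- dementia_code_map()
  idx_code <- rep(NA_character_, n)
  is_ad <- group == "AD"; is_vad <- group == "VaD"
  idx_code[is_ad] <- sample(map$AD, sum(is_ad), replace = TRUE)
  idx_code[is_vad] <- sample(map$VaD, sum(is_vad), replace = TRUE)
  idx_code[group == "control_disease"] <- "S720"
  dem <- data.table::data.table(id = id[has_index],
                                icd10_code = idx_code[has_index],
                                date = index_date[has_index])
  # second same-subtype code and occasional F03, after the index
  extra_p <- stats::runif(n); extra_gap <- stats::runif(n, 0.2, 1.5)
  f03_p <- stats::runif(n); f03_gap <- stats::runif(n, 0.5, 2)
  extras <- list()
  for (g in c("AD", "VaD")) {
    rows <- which(group == g & extra_p < 0.4)
    if (length(rows)) {
      codeset <- setdiff(map[[g]], idx_code[rows])
      second <- vapply(rows, function(i) {
        sample(setdiff(map[[g]], idx_code[i]), 1L)
      }, "")
      d2 <- index_date[rows] + round(extra_gap[rows] * 365.25)
      ok <- d2 <= end_date[rows]
      extras[[g]] <- data.table::data.table(id = id[rows[ok]],
                                            icd10_code = second[ok],
                                            date = d2[ok])
    }
  }
  rows <- which((is_ad | is_vad) & f03_p < 0.2)
  if (length(rows)) {
    d3 <- index_date[rows] + round(f03_gap[rows] * 365.25)
    ok <- d3 <= end_date[rows]
    extras[["F03"]] <- data.table::data.table(id = id[rows[ok]],
                                              icd10_code = "F03",
                                              date = d3[ok])
  }

  diagnoses <- data.table::rbindlist(c(events, list(dem), extras))
  data.table::setorder(diagnoses, id, date, icd10_code)

  prs_shift <- c(AD = config$prs$shift_ad, VaD = config$prs$shift_vad,
                 background = 0, control_disease = 0)[group]
  prs <- data.table::data.table(id = id, group = group,
                                prs = stats::rnorm(n) + unname(prs_shift))

  participants <- data.table::data.table(id = id, sex = sex,
                                         birth_year = birth_year,
                                         death_date = death_date)
  truth <- list(
    assignments = data.table::data.table(id = id, group = group,
                                         index_date = index_date),
    planted = planted, seed = config$seed)
  list(participants = participants, diagnoses = diagnoses, prs = prs,
       truth = truth)
}

#' Named fixture bundles
#'
#' * `tiny`: 20 hand-built participants whose expected cohort labels are
#'   documented (3 AD, 1 VaD, exclusions for four subtype categories,
#'   unspecified-only, Down syndrome and no inpatient data, 2 hip fractures,
#'   and controls), for hand-checkable end-to-end runs.
#' * `null`: a generated population with no planted effects.
#' * `planted-AD-VaD`: planted enrichment mimicking the qualitative target
#'   pattern — depressive episodes (F32) enriched 15-20 years before AD,
#'   food/fluid-intake symptoms (R63) 7-10 years before AD, cerebral
#'   infarction (I63) 15-20 years before VaD, type 1 diabetes (E10) 10-15
#'   years before VaD, and shared frailty codes (L89 decubitus ulcer, J18
#'   pneumonia) enriched after diagnosis in both subtypes.
#'
#' @param name One of `"tiny"`, `"null"`, `"planted-AD-VaD"`.
#' @param seed Seed passed to the generator (ignored for `tiny`).
#' @param dir Optional directory; when given, `participants.csv`,
#'   `diagnoses.csv`, `prs.csv` and `truth.json` are written there.
#' @param ... Overrides forwarded to [synthetic_config()] for the generated
#'   fixtures (e.g. group sizes).
#' @return As [generate_population()].
#' @export
make_fixture <- function(name = c("tiny", "null", "planted-AD-VaD"),
                         seed = 1L, dir = NULL, ...) {
  name <- match.arg(name)
  out <- switch(name,
    tiny = .tiny_fixture(),
    null = generate_population(synthetic_config(seed = seed, ...)),
    `planted-AD-VaD` = {
      # larger arms and a slightly younger diagnosis-age distribution so the
      # earliest pre-diagnosis windows fall inside the observation span and
      # planted rare conditions can clear the network node floor
      args <- utils::modifyList(list(
        seed = seed, planted = planted_effects_default(),
        n_ad = 2000L, n_vad = 1000L, n_background = 6000L,
        n_control_disease = 2000L,
        diagnosis_age = list(mean = 70, sd = 4, lo = 60, hi = 80)),
        list(...))
      generate_population(do.call(synthetic_config, args))
    }
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(out$participants, file.path(dir, "participants.csv"))
    data.table::fwrite(out$diagnoses, file.path(dir, "diagnoses.csv"))
    data.table::fwrite(out$prs, file.path(dir, "prs.csv"))
    jsonlite::write_json(
      list(assignments = out$truth$assignments, planted = out$truth$planted,
           seed = out$truth$seed),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  out
}

#' Default planted-effect table for the planted-AD-VaD fixture
#'
#' @return `data.table` with `cohort`, `code`, `window`, `multiplier`.
#' @export
planted_effects_default <- function() {
  span <- function(cohort, code, windows, mult) {
    data.table::data.table(cohort = cohort, code = code, window = windows,
                           multiplier = mult)
  }
  pre <- c("20+ before", "15-20 before", "10-15 before", "7-10 before",
           "5-7 before", "2-5 before", "0-2 before")
  data.table::rbindlist(list(
    # persistent enrichment, emerging early and carried to diagnosis
    span("AD", "F32", pre[-1], 3),           # depressive episodes, early AD
    span("AD", "R63", pre[4:7], 3),          # food/fluid intake symptoms
    span("VaD", "I63", pre, 3),              # early cerebral infarction
    span("VaD", "E10", pre[3:7], 2.5),       # type 1 diabetes
    # single-window enrichment of rare codes (window-specific recovery)
    span("AD", "K90", "10-15 before", 5),    # intestinal disorder
    span("VaD", "I67", "10-15 before", 6),   # cerebrovascular disease
    # shared post-diagnosis frailty profile
    span(c("AD", "VaD"), "L89", "0-10 after", 4),
    span(c("AD", "VaD"), "J18", "0-10 after", 3)
  ))
}

# Twenty hand-built participants with known expected labels.
.tiny_fixture <- function() {
  P <- function(id, sex, by, dd = NA) list(id = id, sex = sex, birth_year = by,
                                           death_date = dd)
  participants <- data.table::rbindlist(list(
    P("T01", "female", 1940), P("T02", "male", 1941, "2020-03-01"),
    P("T03", "female", 1942), P("T04", "male", 1940),
    P("T05", "female", 1941), P("T06", "male", 1942),
    P("T07", "female", 1940), P("T08", "male", 1941),
    P("T09", "female", 1942), P("T10", "male", 1940),
    P("T11", "female", 1941), P("T12", "male", 1942),
    P("T13", "female", 1940), P("T14", "male", 1941),
    P("T15", "female", 1942), P("T16", "male", 1940),
    P("T17", "female", 1941), P("T18", "male", 1942),
    P("T19", "female", 1940), P("T20", "male", 1941)
  ))
  participants[, birth_year := as.integer(birth_year)]
  participants[, death_date := as.Date(death_date)]
  D <- function(id, code, date) list(id = id, icd10_code = code, date = date)
  diagnoses <- data.table::rbindlist(list(
    # T01: AD by majority (2 AD codes vs 1 VaD), index 2012-05-01
    D("T01", "G30", "2012-05-01"), D("T01", "G309", "2014-02-01"),
    D("T01", "F019", "2015-06-01"), D("T01", "I10", "2002-01-10"),
    # T02: AD single code; died 2020
    D("T02", "F00", "2016-08-01"), D("T02", "J18", "2019-01-15"),
    # T03: AD vs VaD 1-1 tie, AD earlier -> AD, index 2013-03-01
    D("T03", "G301", "2013-03-01"), D("T03", "F011", "2015-09-01"),
    # T04: VaD by majority
    D("T04", "F011", "2011-01-01"), D("T04", "F019", "2012-01-01"),
    D("T04", "G30", "2013-01-01"),
    # T05: four subtype categories -> excluded
    D("T05", "F00", "2010-01-01"), D("T05", "F011", "2011-01-01"),
    D("T05", "F03", "2012-01-01"), D("T05", "F067", "2013-01-01"),
    # T06: unspecified only -> excluded
    D("T06", "F03", "2012-06-01"),
    # T07: Down syndrome code anywhere -> excluded
    D("T07", "Q900", "2005-01-01"), D("T07", "G30", "2012-01-01"),
    # T08: no events at all -> excluded (no inpatient data)
    # T09, T10: hip fracture cohort (S72 family, no dementia codes)
    D("T09", "S720", "2010-04-01"), D("T09", "I10", "2000-05-01"),
    D("T10", "S721", "2011-07-01"),
    # T11-T20: controls with scattered comorbidities
    D("T11", "I10", "2001-02-01"), D("T11", "E11", "2010-03-01"),
    D("T12", "K21", "2005-06-01"), D("T13", "M54", "2008-09-01"),
    D("T14", "I10", "2003-04-01"), D("T15", "F32", "1999-11-01"),
    D("T16", "J45", "2002-07-01"), D("T17", "I10", "2004-01-01"),
    D("T18", "E78", "2007-05-01"), D("T19", "I10", "2005-08-01"),
    D("T20", "K80", "2009-10-01")
  ))
  diagnoses[, date := as.Date(date)]
  data.table::setorder(diagnoses, id, date, icd10_code)
  truth <- list(assignments = data.table::data.table(
    id = sprintf("T%02d", 1:20),
    group = c("AD", "AD", "AD", "VaD", "excluded", "excluded", "excluded",
              "excluded", "control_disease", "control_disease",
              rep("background", 10)),
    index_date = as.Date(c("2012-05-01", "2016-08-01", "2013-03-01",
                           "2011-01-01", NA, NA, NA, NA,
                           "2010-04-01", "2011-07-01", rep(NA, 10)))),
    planted = NULL, seed = NA_integer_)
  prs <- data.table::data.table(id = participants$id,
                                group = truth$assignments$group,
                                prs = 0)
  list(participants = participants, diagnoses = diagnoses, prs = prs,
       truth = truth)
}
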