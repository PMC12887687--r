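test_that("generator is deterministic and respects first-instance structure", {
  cfg <- synthetic_config(n_ad = 80, n_vad = 40, n_background = 200,
                          n_control_disease = 30, seed = 9)
  g1 <- generate_population(cfg)
  g2 <- generate_population(cfg)
  expect_identical(g1, g2)
  # different seed changes the draw
  g3 <- generate_population(synthetic_config(n_ad = 80, n_vad = 40,
                                             n_background = 200,
                                             n_control_disease = 30, seed = 10))
  expect_false(identical(g1$diagnoses, g3$diagnoses))
  # no duplicated (participant, code); no event before the observation start,
  # after death, or after the censor date
  expect_equal(anyDuplicated(g1$diagnoses[, .(id, icd10_code)]), 0L)
  m <- merge(g1$diagnoses, g1$participants, by = "id")
  expect_true(all(m$date <= synthetic_config()$observation$censor_date))
  expect_true(all(is.na(m$death_date) | m$date <= m$death_date))
  age_at_event <- as.numeric(m$date - birth_date(m$birth_year)) / 365.25
  expect_true(all(age_at_event >= 40 - 0.01))
  # truth covers every generated case
  expect_setequal(g1$truth$assignments$id, g1$participants$id)
  expect_equal(sum(g1$truth$assignments$group == "AD"), 80)
})

test_that("cases carry their subtype codes at the scheduled index date", {
  g <- generate_population(synthetic_config(n_ad = 60, n_vad = 60,
                                            n_background = 50,
                                            n_control_disease = 40, seed = 3))
  tr <- g$truth$assignments
  dg <- g$diagnoses[, .(id, code = parse_icd10(icd10_code), date)]
  for (grp in c("AD", "VaD")) {
    ids <- tr[group == grp, id]
    first_dem <- dg[id %in% ids & dementia_category(code) == grp,
                    .(d = min(date)), by = id]
    expect_setequal(first_dem$id, ids)
    expect_true(all(first_dem$d == tr[match(first_dem$id, id), index_date]))
  }
  # hip-fracture participants get S72-family codes and no dementia codes
  hip <- tr[group == "control_disease", id]
  expect_true(all(dg[id %in% hip, sum(startsWith(code, "S72")) > 0, by = id]$V1))
  expect_equal(nrow(dg[id %in% hip & dementia_category(code) != "none"]), 0L)
  # background participants never carry dementia codes
  bg <- tr[group == "background", id]
  expect_equal(nrow(dg[id %in% bg & dementia_category(code) != "none"]), 0L)
})

test_that("with all multipliers 1 prevalence matches the configured expectation", {
  n <- 5000
  cfg <- synthetic_config(n_ad = 0, n_vad = 0, n_background = n,
                          n_control_disease = 0, seed = 13)
  g <- generate_population(cfg)
  m <- merge(g$diagnoses, g$participants, by = "id")
  # expected lifetime presence per condition from the config arithmetic,
  # integrating the annual model over each participant's observed span
  end_date <- pmin(data.table::fifelse(is.na(g$participants$death_date),
                                       cfg$observation$censor_date,
                                       g$participants$death_date),
                   cfg$observation$censor_date)
  end_age <- as.numeric(end_date - birth_date(g$participants$birth_year)) / 365.25
  checked <- 0L
  for (cd in c("I10", "F32", "J18", "M54", "E11", "K80", "G40", "L89")) {
    row <- cfg$catalog[code == cd]
    stopifnot(nrow(row) == 1L)
    p_person <- vapply(end_age, function(e) {
      if (e < 40.5) return(0)
      a <- seq(40.5, e, by = 1)
      1 - exp(sum(log1p(-pmin(0.5, row$p60 * exp(row$slope * (a - 60))))))
    }, 0)
    expected <- sum(p_person)
    observed <- length(unique(m[icd10_code == cd, id]))
    se <- sqrt(sum(p_person * (1 - p_person)))
    expect_lt(abs(observed - expected), 3.5 * se + 1)
    checked <- checked + 1L
  }
  expect_equal(checked, 8L)
})

test_that("a planted window multiplier reproduces the target odds ratio", {
  pl <- data.table::data.table(cohort = "AD", code = "F32",
                               window = "15-20 before", multiplier = 3)
  cfg <- synthetic_config(n_ad = 2000, n_vad = 0, n_background = 2000,
                          n_control_disease = 0, seed = 17, planted = pl,
                          diagnosis_age = list(mean = 70, sd = 4,
                                               lo = 60, hi = 80))
  g <- generate_population(cfg)
  tr <- g$truth$assignments
  # empirical odds of a first F32 instance inside the planted window for AD
  # cases vs the background pool evaluated at matched pseudo-index dates
  dg <- g$diagnoses[icd10_code == "F32"]
  in_window <- function(ids, idx_dates) {
    first <- dg[id %in% ids][, .(d = min(date)), by = id]
    off <- as.numeric(first$d - idx_dates[match(first$id, ids)]) / 365.25
    sum(off > -20 & off <= -15)
  }
  ad <- tr[group == "AD"]
  bg <- tr[group == "background"]
  set.seed(1)
  bg_idx <- ad$index_date[sample.int(nrow(ad), nrow(bg), replace = TRUE)]
  # background pseudo-index: borrow case diagnosis dates (placeholder logic)
  k1 <- in_window(ad$id, ad$index_date)
  k0 <- in_window(bg$id, bg_idx)
  or <- (k1 / (nrow(ad) - k1)) / (k0 / (nrow(bg) - k0))
  expect_gt(or, 2.2)
  expect_lt(or, 4.0)
})

test_that("fixtures bundle and serialize as documented", {
  tmp <- withr::local_tempdir()
  fx <- make_fixture("null", seed = 2, dir = tmp, n_ad = 30, n_vad = 20,
                     n_background = 80, n_control_disease = 10)
  expect_true(all(file.exists(file.path(tmp, c("participants.csv",
                                               "diagnoses.csv", "prs.csv",
                                               "truth.json")))))
  p <- read_participants(file.path(tmp, "participants.csv"))
  expect_equal(nrow(p), 140L)
  truth <- jsonlite::read_json(file.path(tmp, "truth.json"))
  expect_equal(length(truth$assignments), 140L)
  expect_error(make_fixture("nope"), "arg")
  # invalid config is rejected with the offending fields named
  expect_error(synthetic_config(catalog = data.frame(code = "I10", p60 = 2,
                                                     slope = 0)),
               "p60")
  expect_error(synthetic_config(planted = data.frame(cohort = "AD",
                                                     code = "I10",
                                                     window = "nope",
                                                     multiplier = 1)),
               "window")
})
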