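test_that("resolve_overall_diagnosis applies the stated resolution rules", {
  d <- function(x) as.Date(x)
  # majority: 2 AD vs 1 VaD, index = earliest AD-code date
  r <- resolve_overall_diagnosis(c("G30", "G309", "F019"),
                                 d(c("2010-01-01", "2012-01-01", "2013-01-01")))
  expect_equal(r$label, "AD")
  expect_equal(r$index_date, d("2010-01-01"))
  # four distinct categories -> excluded
  r <- resolve_overall_diagnosis(c("F00", "F011", "F03", "F067"),
                                 d(c("2010-01-01", "2011-01-01",
                                     "2012-01-01", "2013-01-01")))
  expect_equal(r$label, "excluded")
  expect_match(r$reason, "four or more")
  # unspecified only -> excluded
  r <- resolve_overall_diagnosis("F03", d("2011-01-01"))
  expect_equal(r$label, "excluded")
  # 1-1 AD/VaD tie: earliest-dated subtype code wins (VaD here)
  r <- resolve_overall_diagnosis(c("G30", "F019"),
                                 d(c("2012-01-01", "2010-01-01")))
  expect_equal(r$label, "VaD")
  expect_equal(r$index_date, d("2010-01-01"))
  # Q90 anywhere excludes regardless of dementia codes
  r <- resolve_overall_diagnosis(c("G30", "Q909"),
                                 d(c("2012-01-01", "2000-01-01")))
  expect_equal(r$label, "excluded")
  expect_match(r$reason, "Down")
  # delirium and ordinary comorbidities alone are not a case
  r <- resolve_overall_diagnosis(c("F05", "I10"),
                                 d(c("2010-01-01", "2011-01-01")))
  expect_equal(r$label, "none")
})

test_that("resolution matches the brute-force oracle on random event lists", {
  set.seed(101)
  for (i in 1:400) {
    ev <- random_event_list()
    got <- resolve_overall_diagnosis(ev$codes, ev$dates)
    want <- oracle_resolve(ev$codes, ev$dates)
    expect_equal(got$label, want$label,
                 info = paste(ev$codes, ev$dates, collapse = " "))
    if (got$label %in% c("AD", "VaD")) {
      expect_equal(got$index_date, want$index_date)
    }
  }
})

test_that("build_dementia_cohort labels the tiny fixture as documented", {
  fx <- make_fixture("tiny")
  asn <- suppressMessages(build_dementia_cohort(fx$participants, fx$diagnoses))
  lab <- setNames(asn$label, asn$id)
  expect_equal(unname(lab[c("T01", "T02", "T03")]), rep("AD", 3))
  expect_equal(unname(lab["T04"]), "VaD")
  expect_equal(unname(lab[c("T05", "T06", "T07", "T08")]), rep("excluded", 4))
  expect_equal(asn[id == "T08", reason], "no inpatient data")
  expect_equal(asn[id == "T07", reason], "Down syndrome code")
  expect_equal(asn[id == "T01", index_date], as.Date("2012-05-01"))
  # controls (pool) have no dementia-category codes
  expect_true(all(asn[id %in% sprintf("T%02d", 9:20), label] == "none"))
  expect_error(suppressMessages(build_dementia_cohort(fx$participants[0], fx$diagnoses)),
               "empty")
})

test_that("matching is 1:1, sex-exact, within tolerance and deterministic", {
  set.seed(5)
  n_case <- 60; n_pool <- 200
  cases <- data.table::data.table(
    id = paste0("C", 1:n_case),
    sex = sample(c("female", "male"), n_case, TRUE),
    birth_year = sample(1936:1945, n_case, TRUE),
    index_date = as.Date("2015-06-01"))
  pool <- data.table::data.table(
    id = paste0("P", 1:n_pool),
    sex = sample(c("female", "male"), n_pool, TRUE),
    birth_year = sample(1936:1945, n_pool, TRUE))
  pr <- match_controls(cases, pool, tolerance_years = 1, seed = 42)
  expect_lte(nrow(pr), n_case)
  expect_equal(anyDuplicated(pr$control_id), 0L)
  expect_equal(anyDuplicated(pr$case_id), 0L)
  expect_true(all(abs(pr$age_diff) <= 1))
  sex_of <- setNames(pool$sex, pool$id)
  expect_true(all(pr$sex == sex_of[pr$control_id]))
  # identical inputs + seed reproduce the same pairing
  pr2 <- match_controls(cases, pool, tolerance_years = 1, seed = 42)
  expect_identical(pr, pr2)
  # controls inherit the case's index date
  expect_true(all(pr$index_date == as.Date("2015-06-01")))
})

test_that("matching reports unmatched cases when the pool is exhausted", {
  cases <- data.table::data.table(
    id = c("C1", "C2"), sex = c("male", "male"),
    birth_year = c(1940L, 1940L), index_date = as.Date("2015-01-01"))
  pool <- data.table::data.table(id = "P1", sex = "female", birth_year = 1940L)
  expect_warning(pr <- match_controls(cases, pool), "unmatched")
  expect_equal(nrow(pr), 0L)
  expect_setequal(attr(pr, "unmatched"), c("C1", "C2"))
  # nearest-age matching: the one-birth-year gap (~1.0 y) beats the
  # ten-year gap and sits inside a 1.1-year tolerance
  cases <- data.table::data.table(id = "C1", sex = "female",
                                  birth_year = 1940L,
                                  index_date = as.Date("2015-07-01"))
  pool <- data.table::data.table(id = c("P1", "P2"), sex = "female",
                                 birth_year = c(1939L, 1930L))
  pr <- match_controls(cases, pool, tolerance_years = 1.1)
  expect_equal(pr$control_id, "P1")
  expect_equal(pr$age_diff, 1, tolerance = 0.01)
})

test_that("hip-fracture cohort takes S72-family carriers without dementia codes", {
  fx <- make_fixture("tiny")
  cd <- build_control_disease_cohort(fx$participants, fx$diagnoses)
  expect_setequal(cd$id, c("T09", "T10"))
  expect_equal(cd[id == "T09", index_date], as.Date("2010-04-01"))
  # a participant with S72 plus a dementia code is excluded
  dg <- data.table::rbindlist(list(
    fx$diagnoses,
    data.table::data.table(id = "T11", icd10_code = c("S720", "G30"),
                           date = as.Date(c("2010-01-01", "2012-01-01")))))
  cd2 <- build_control_disease_cohort(fx$participants, dg)
  expect_false("T11" %in% cd2$id)
})

test_that("readers enforce schema and first-instance deduplication", {
  tmp <- withr::local_tempdir()
  pfile <- file.path(tmp, "p.csv"); dfile <- file.path(tmp, "d.csv")
  writeLines(c("id,sex,birth_year,death_date",
               "A,female,1940,", "B,male,1941,2020-01-01"), pfile)
  writeLines(c("id,icd10_code,date",
               "A,F00.1,2010-01-01", "A,F001,2008-05-01",
               "B,I10,2005-01-01"), dfile)
  p <- read_participants(pfile)
  expect_equal(p$death_date, as.Date(c(NA, "2020-01-01")))
  d <- suppressMessages(read_diagnoses(dfile))
  # dotted and dotless dialects collapse to one first instance
  expect_equal(nrow(d[id == "A"]), 1L)
  expect_equal(d[id == "A", date], as.Date("2008-05-01"))
  writeLines(c("id,sex", "A,female"), pfile)
  expect_error(read_participants(pfile), "columns")
})
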