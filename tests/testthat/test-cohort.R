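test_that("age normalization converts every unit and rejects bad input", {
  expect_equal(normalize_age(24, "MON"), 2)
  expect_equal(normalize_age(1, "DEC"), 10)
  expect_equal(normalize_age(10, "YR"), 10)
  expect_equal(normalize_age(365.25, "DY"), 1)
  expect_equal(normalize_age(52.18, "WK"), 1)
  expect_equal(normalize_age(8766, "HR"), 1)
  # negative, missing unit, unknown unit -> missing
  expect_true(is.na(normalize_age(-3, "YR")))
  expect_true(is.na(normalize_age(5, "")))
  expect_true(is.na(normalize_age(5, "FORTNIGHT")))
  expect_true(is.na(normalize_age(NA, "YR")))
  # vectorized with mixed units
  expect_equal(normalize_age(c(24, 1, 7), c("MON", "DEC", "YR")),
               c(2, 10, 7))
})

test_that("onset time needs two full dates and a non-negative difference", {
  expect_equal(onset_days("20200110", "20200101"), 9L)
  expect_equal(onset_days("20200101", "20200101"), 0L)
  expect_true(is.na(onset_days("202001", "20200101")))   # partial event
  expect_true(is.na(onset_days("20200110", "2020")))     # partial start
  expect_true(is.na(onset_days("20200101", "20200110"))) # negative
  expect_true(is.na(onset_days("20200230", "20200101"))) # invalid date
})

test_that("onset bins are inclusive integer ranges with explicit overflow", {
  expect_equal(as.character(bin_onset(c(0, 7, 8, 60, 61, 180, 181, 360,
                                        361, 400, NA))),
               c("0-7", "0-7", "8-60", "8-60", "61-180", "61-180",
                 "181-360", "181-360", ">360", ">360", "missing"))
})

test_that("inclusion requires pediatric age, PS respiratory drug and psychiatric PT", {
  demo <- demo_rows(
    primaryid = 1:6, caseid = 1:6,
    fda_dt = rep("20200601", 6),
    age = c("10", "18", "204", "10", "10", "17.5"),
    age_cod = c("YR", "YR", "MON", "YR", "YR", "YR"))
  drug <- data.frame(
    primaryid = 1:6, caseid = 1:6, drug_seq = 1,
    role_cod = c("PS", "PS", "PS", "SS", "PS", "PS"),
    drugname = c("MONTELUKAST", "MONTELUKAST", "MONTELUKAST",
                 "MONTELUKAST", "ASPIRIN", "PROMETHAZINE"),
    route = "Oral")
  reac <- data.frame(
    primaryid = c(1, 1, 2, 3, 4, 5, 6), caseid = c(1, 1, 2, 3, 4, 5, 6),
    pt = c("Anxiety", "Depression", "Anxiety", "Anxiety", "Anxiety",
           "Anxiety", "Headache"))
  dir <- tiny_bundle(demo = demo, drug = drug, reac = reac)
  b <- read_bundle(dir)
  cases <- assemble_cases(deduplicate(b$demo), b)
  cohort <- select_cases(cases, test_vocab())

  # case 1: included, two psychiatric PTs -> one case row, two pair rows
  # case 2: aged exactly 18 -> excluded at the boundary
  # case 3: 204 months = 17 years -> included
  # case 4: respiratory drug only as secondary suspect -> excluded
  # case 5: PS drug not respiratory -> excluded
  # case 6: no psychiatric PT -> excluded
  expect_setequal(cohort$cases$primaryid, c("1", "3"))
  expect_equal(nrow(cohort$pairs), 3L)
  expect_equal(sum(cohort$pairs$primaryid == "1"), 2L)
  # attrition counts each criterion in order
  expect_equal(unname(cohort$attrition),
               c(6L, 5L, 3L, 2L))
})

test_that("seriousness and outcome fields derive from outcome codes", {
  demo <- demo_rows(primaryid = 1:2, caseid = 1:2,
                    fda_dt = rep("20200601", 2))
  drug <- data.frame(primaryid = 1:2, caseid = 1:2, drug_seq = 1,
                     role_cod = "PS", drugname = "MONTELUKAST",
                     route = "Oral")
  reac <- data.frame(primaryid = 1:2, caseid = 1:2, pt = "Anxiety")
  outc <- data.frame(primaryid = c(1, 1), caseid = c(1, 1),
                     outc_cod = c("DE", "HO"))
  dir <- tiny_bundle(demo = demo, drug = drug, reac = reac, outc = outc)
  b <- read_bundle(dir)
  cohort <- select_cases(assemble_cases(deduplicate(b$demo), b),
                         test_vocab())
  c1 <- cohort$cases[cohort$cases$primaryid == "1", ]
  c2 <- cohort$cases[cohort$cases$primaryid == "2", ]
  expect_true(c1$serious); expect_true(c1$death); expect_false(c1$life_threat)
  expect_false(c2$serious)  # no outcome rows -> non-serious
  expect_equal(sort(c1$outcome_codes[[1]]), c("DE", "HO"))
  expect_equal(c2$outcome_codes[[1]], character(0))
})

test_that("cohort invariants hold on generated data", {
  dir <- withr::local_tempdir()
  generate_bundle(synthetic_config(n_cases = 2000, seed = 21), dir)
  b <- read_bundle(dir)
  demo <- remove_deleted(deduplicate(b$demo), b$deleted_ids)
  cohort <- select_cases(assemble_cases(demo, b), read_vocab(
    file.path(dir, "vocab")))
  cs <- cohort$cases
  expect_true(all(cs$age_years >= 0 & cs$age_years < 18))
  expect_false(anyNA(cs$age_group))
  expect_true(all(cs$serious == (lengths(cs$outcome_codes) > 0)))
  # pair rows at least as many as cases; equality iff one pair per case
  expect_gte(nrow(cohort$pairs), nrow(cs))
  per_case <- table(cohort$pairs$primaryid)
  expect_equal(nrow(cohort$pairs) == nrow(cs), all(per_case == 1))
  # attrition nonincreasing
  expect_true(all(diff(unname(cohort$attrition)) <= 0))
})
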