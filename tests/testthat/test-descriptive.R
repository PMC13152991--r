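test_that("half-up rounding reproduces published percentage arithmetic", {
  expect_equal(round_half_up(49.225, 2), 49.23)  # round() would give 49.22
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(pct_of(3443, 6994), 49.23)
  expect_equal(pct_of(5776, 6994), 82.59)
  expect_equal(pct_of(6994, 6994), 100.00)
  expect_equal(pct_of(0, 53), 0)
})

test_that("frequency tables respect their denominators", {
  x <- c("a", "a", "b", NA)
  t <- freq_table(x)
  expect_equal(sum(t$count), 4L)  # single-select sums to denominator
  expect_equal(t$pct[t$category == "a"], 50)
  expect_equal(t$count[t$category == "Not specified"], 1L)
  # all in one category
  t2 <- freq_table(rep("only", 7))
  expect_equal(t2$pct, 100)
  # explicit denominator for multi-select data
  t3 <- freq_table(c("DE", "DE", "HO"), denom = 2)
  expect_equal(sum(t3$count), 3L)
  expect_gt(sum(t3$pct), 100)
})

test_that("the cohort summary emits every characteristics table", {
  dir <- withr::local_tempdir()
  generate_bundle(synthetic_config(n_cases = 3000, seed = 31), dir)
  run <- pv_run(dir)
  s <- run$summary
  expect_setequal(names(s$tables),
                  c("sex", "age_group", "reporter", "country", "route",
                    "indication", "degree", "outcomes", "onset", "year"))
  n <- s$n
  for (nm in c("sex", "age_group", "degree", "onset", "year"))
    expect_equal(sum(s$tables[[nm]]$count), n, label = nm)
  # age median/IQR are pediatric and ordered
  q <- s$age_median_iqr
  expect_true(q["q1"] <= q["median"] && q["median"] <= q["q3"])
  expect_true(q["q3"] < 18)
  # serious + non-serious partition the cohort
  deg <- s$tables$degree
  expect_setequal(deg$category, c("Serious", "Non-serious"))
})

test_that("empty cohorts summarize to empty tables, not errors", {
  demo <- demo_rows(primaryid = 1, caseid = 1, fda_dt = "20200101",
                    age = "30", age_cod = "YR")
  dir <- tiny_bundle(demo = demo)
  b <- read_bundle(dir)
  cohort <- select_cases(assemble_cases(deduplicate(b$demo), b),
                         test_vocab())
  expect_equal(nrow(cohort$cases), 0L)
  s <- summarize_cohort(cohort)
  expect_equal(s$n, 0L)
})

test_that("per-drug PT composition applies the minimum-report threshold", {
  pairs <- data.frame(
    primaryid = as.character(1:21),
    ingredient = c(rep("montelukast", 11), rep("rarerx", 10)),
    pt = c(rep("Anxiety", 7), rep("Depression", 4), rep("Anxiety", 10)),
    focus_hlgt = "Anxiety disorders and symptoms",
    death = FALSE, life_threat = FALSE,
    stringsAsFactors = FALSE)
  t <- drug_pt_composition(pairs, "montelukast")
  expect_equal(t$count[t$category == "Anxiety"], 7L)
  expect_equal(t$pct[t$category == "Anxiety"], pct_of(7, 11))
  # a drug with exactly 10 reports is excluded under the default "> 10"
  expect_equal(nrow(drug_pt_composition(pairs, "rarerx")), 0L)
  expect_equal(nrow(drug_pt_composition(pairs, "rarerx",
                                        min_reports = 0)), 1L)
  expect_equal(nrow(drug_pt_composition(pairs, "unknowndrug",
                                        min_reports = 0)), 0L)
})

test_that("HLGT rollup covers the three focus groups plus a remainder", {
  pairs <- data.frame(
    primaryid = as.character(1:4),
    ingredient = "hydroxyzine",
    pt = c("Completed suicide", "Suicide attempt", "Anxiety", "Nightmare"),
    focus_hlgt = c("Suicidal and self-injurious behaviours",
                   "Suicidal and self-injurious behaviours",
                   "Anxiety disorders and symptoms", NA),
    death = FALSE, life_threat = FALSE, stringsAsFactors = FALSE)
  t <- drug_hlgt_composition(pairs, "hydroxyzine")
  expect_equal(nrow(t), 4L)
  expect_equal(t$count[t$category ==
                         "Suicidal and self-injurious behaviours"], 2L)
  expect_equal(t$pct[t$category ==
                       "Suicidal and self-injurious behaviours"], 50)
  expect_equal(t$count[t$category ==
                         "Depressed mood disorders and disturbances"], 0L)
})

test_that("death and life-threatening rates use drug-level denominators", {
  pairs <- data.frame(
    primaryid = as.character(1:53),
    ingredient = "hydroxyzine",
    pt = "Anxiety", focus_hlgt = "Anxiety disorders and symptoms",
    death = c(rep(TRUE, 27), rep(FALSE, 26)),
    life_threat = FALSE, stringsAsFactors = FALSE)
  r <- serious_outcome_rates(pairs, "hydroxyzine")
  expect_equal(r$death_n, 27L)
  expect_equal(r$death_pct, 50.94)
  expect_equal(r$life_threat_pct, 0)
})
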