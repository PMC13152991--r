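test_that("bundle size matches the configured case count without duplication", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_cases = 100, duplicate_rate = 0,
                          deletion_rate = 0, seed = 11)
  generate_bundle(cfg, dir)
  demo <- readLines(file.path(dir, "demo.txt"))
  expect_length(demo, 101L)  # header + one row per case
  # every case id appears exactly once
  ids <- sapply(strsplit(demo[-1], "$", fixed = TRUE), `[`, 2)
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("the same configuration produces byte-identical bundles", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- synthetic_config(n_cases = 400, seed = 99,
                          signal_pairs = data.frame(drug = "montelukast",
                                                    pt = "Anxiety",
                                                    lambda = 4))
  generate_bundle(cfg, d1)
  generate_bundle(cfg, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("duplicated cases share a case id with distinct primary ids", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_cases = 500, duplicate_rate = 0.3,
                          deletion_rate = 0, seed = 5)
  generate_bundle(cfg, dir)
  demo <- read_bundle(dir)$demo
  expect_gt(nrow(demo), 500)
  expect_equal(length(unique(demo$caseid)), 500L)
  expect_equal(anyDuplicated(demo$primaryid), 0L)
  # duplicated cases: receipt dates are nondecreasing across versions
  split_fda <- split(demo$fda_dt, demo$caseid)
  multi <- split_fda[lengths(split_fda) > 1]
  expect_true(all(vapply(multi, function(z) !is.unsorted(sort(z)),
                         logical(1))))
})

test_that("the manifest records every injected signal and the deleted list", {
  dir <- withr::local_tempdir()
  sp <- data.frame(drug = c("montelukast", "hydroxyzine"),
                   pt = c("Anxiety", "Completed suicide"),
                   lambda = c(8, 2))
  cfg <- synthetic_config(n_cases = 300, deletion_rate = 0.05, seed = 2,
                          signal_pairs = sp)
  man <- generate_bundle(cfg, dir)
  expect_setequal(man$ground_truth$lambda, c(8, 2))
  expect_equal(length(man$deleted_caseids), 15L)  # 5% of 300
  # manifest file round-trips
  y <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(length(y$ground_truth), 2L)
  expect_equal(y$ground_truth[[1]]$lambda, 8)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(drugs = data.frame(
    name = "x", atc = "R00", prob = 1.2)), "sum to <= 1")
  expect_error(synthetic_config(signal_pairs = data.frame(
    drug = "montelukast", pt = "Anxiety", lambda = 0.5)), ">= 1")
  expect_error(synthetic_config(signal_pairs = data.frame(
    drug = "nosuchdrug", pt = "Anxiety", lambda = 2)), "not in")
})

test_that("the generator's closed-form population ROR matches enumeration", {
  cfg <- synthetic_config(
    n_cases = 10, seed = 1,
    signal_pairs = data.frame(drug = c("montelukast", "promethazine"),
                              pt = c("Anxiety", "Depression"),
                              lambda = c(8, 3)))
  for (k in 1:2) {
    expect_equal(
      population_ror(cfg, cfg$signal_pairs$drug[k], cfg$signal_pairs$pt[k]),
      oracle_population_ror(cfg, cfg$signal_pairs$drug[k],
                            cfg$signal_pairs$pt[k]),
      tolerance = 1e-12)
  }
  # a non-injected pair sits near independence
  expect_equal(population_ror(cfg, "ibuprofen", "Headache"), 1,
               tolerance = 0.05)
})

test_that("the mock vocabulary is complete, well-formed and round-trips", {
  cfg <- synthetic_config(n_cases = 10)
  vocab <- generate_vocab(cfg)
  # each PT appears exactly once as a hierarchy key
  expect_equal(anyDuplicated(vocab$meddra$pt_name), 0L)
  # every configured drug is mapped; respiratory ones to "R" codes
  expect_setequal(vocab$drug_dict$name, cfg$drugs$name)
  expect_equal(sum(startsWith(vocab$drug_dict$atc, "R")),
               sum(startsWith(cfg$drugs$atc, "R")))
  # psychiatric SOC present with the three focus HLGTs
  psy <- vocab$meddra[vocab$meddra$soc_code == 10037175L, ]
  expect_setequal(unique(psy$hlgt_code[psy$hlgt_code %in%
                                         c(10002861L, 10012375L,
                                           10042460L)]),
                  c(10002861L, 10012375L, 10042460L))
  dir <- withr::local_tempdir()
  write_vocab(vocab, dir)
  back <- read_vocab(dir)
  expect_equal(back$drug_dict, vocab$drug_dict)
  expect_equal(back$meddra, vocab$meddra)
})

test_that("a custom drug list flags exactly the respiratory entries", {
  drugs <- data.frame(
    name = c("a", "b", "c", "d", "e"),
    atc = c("R03DC03", "N02BA01", "R06AD02", "J01CA04", "R01AD09"),
    prob = rep(0.1, 5))
  cfg <- synthetic_config(n_cases = 10, drugs = drugs)
  vocab <- generate_vocab(cfg)
  dict <- vocab$drug_dict[vocab$drug_dict$name %in% drugs$name, ]
  expect_equal(sum(startsWith(dict$atc, "R")), 3L)
})
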