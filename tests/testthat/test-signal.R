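test_that("reporting odds ratio matches direct arithmetic", {
  r <- ror(contingency(10, 20, 30, 240))
  expect_equal(r[["est"]], 4)                 # ad/bc = 2400/600
  expect_equal(unname(r[1:3]), oracle_ror(10, 20, 30, 240),
               tolerance = 1e-12)
  # perfectly symmetric table: ROR 1, interval spans 1
  s <- ror(contingency(25, 25, 25, 25))
  expect_equal(s[["est"]], 1)
  expect_lt(s[["lo"]], 1); expect_gt(s[["hi"]], 1)
  expect_equal(ror(contingency(3, 1, 1, 3))[["est"]], 9)
  # zero cell: finite, flagged corrected
  z <- ror(contingency(3, 0, 5, 100))
  expect_true(is.finite(z[["est"]]))
  expect_equal(z[["corrected"]], 1)
})

test_that("proportional reporting ratio matches direct arithmetic", {
  p <- prr(contingency(10, 90, 10, 890))
  expect_equal(p[["est"]], 9)                 # (10/100)/(10/900)
  expect_equal(unname(p[1:3]), oracle_prr(10, 90, 10, 890),
               tolerance = 1e-12)
  # equal reporting proportions in both margins -> PRR 1
  expect_equal(prr(contingency(10, 90, 100, 900))[["est"]], 1)
  z <- prr(contingency(3, 10, 0, 100))
  expect_true(is.finite(z[["est"]]))
  expect_equal(z[["corrected"]], 1)
})

test_that("Yates chi-squared agrees with the textbook test and clamps", {
  expect_equal(yates_chi2(contingency(10, 10, 10, 10)), 0)  # independence
  expect_equal(yates_chi2(contingency(10, 20, 30, 240)),
               oracle_chi2(10, 20, 30, 240), tolerance = 1e-12)
  # |O-E| < 0.5 clamps to zero rather than going negative
  expect_equal(yates_chi2(contingency(10, 10, 10, 11)),
               oracle_chi2(10, 10, 10, 11))
  # zero margin -> undefined
  expect_true(is.na(yates_chi2(contingency(0, 0, 10, 10))))
})

test_that("the MHRA criterion combines PRR, chi-squared and report count", {
  m <- mhra(contingency(3, 997, 3, 8997))
  expect_equal(m$prr, 9, tolerance = 1e-12)
  expect_equal(m$pos, m$chi2 >= 4)  # the only binding condition here
  expect_false(mhra(contingency(10, 10, 10, 10))$pos)
  # two reports never signal regardless of strength
  expect_false(mhra(contingency(2, 1, 1, 1000))$pos)
})

test_that("the information component shrinks toward zero and is exact on examples", {
  # a equal to its expectation -> IC exactly 0: E = (40*25)/100 = 10
  expect_equal(bcpnn(contingency(10, 30, 15, 45))[["ic"]], 0)
  b <- bcpnn(contingency(10, 20, 30, 240))
  expect_equal(b[["ic"]], log2(10.5 / 4.5))  # E = 30*40/300 = 4
  expect_equal(unname(b), oracle_ic(10, 20, 30, 240), tolerance = 1e-12)
  # asymptotically, a/E fixed at 8 -> IC -> 3 bits and IC025 -> IC
  # (E = 1e6 * 1e6 / 1e8 = 1e4, a = 8e4)
  big <- bcpnn(contingency(80000, 920000, 920000, 98080000))
  expect_equal(big[["ic"]], 3, tolerance = 0.02)
  expect_equal(big[["ic025"]], big[["ic"]], tolerance = 0.02)
})

test_that("the Bate BCPNN variant tracks the closed form on large tables", {
  n <- bcpnn(contingency(500, 1500, 2000, 96000), variant = "noren")
  b <- bcpnn(contingency(500, 1500, 2000, 96000), variant = "bate")
  expect_equal(b[["ic"]], n[["ic"]], tolerance = 0.05)
  expect_lt(b[["ic025"]], b[["ic"]])
})

test_that("all four statistics match independent oracles on random tables", {
  set.seed(424242)
  for (i in 1:250) {
    a <- sample(1:200, 1); b <- sample(1:500, 1)
    c <- sample(1:500, 1); d <- sample(1:5000, 1)
    row <- evaluate_pair(contingency(a, b, c, d))
    expect_equal(c(row$ror, row$ror_lo, row$ror_hi),
                 oracle_ror(a, b, c, d), tolerance = 1e-9)
    expect_equal(c(row$prr, row$prr_lo, row$prr_hi),
                 oracle_prr(a, b, c, d), tolerance = 1e-9)
    expect_equal(row$chi2, oracle_chi2(a, b, c, d), tolerance = 1e-9)
    expect_equal(c(row$ic, row$ic025), oracle_ic(a, b, c, d),
                 tolerance = 1e-9)
  }
})

test_that("estimates are monotone in the diagonal cell with margins fixed", {
  # shifting one report from the off-cells onto the diagonal (margins
  # fixed) must not decrease ROR, PRR or IC
  a0 <- 5; b0 <- 95; c0 <- 50; d0 <- 850
  prev <- evaluate_pair(contingency(a0, b0, c0, d0))
  for (k in 1:20) {
    cur <- evaluate_pair(contingency(a0 + k, b0 - k, c0 - k, d0 + k))
    expect_gte(cur$ror, prev$ror)
    expect_gte(cur$prr, prev$prr)
    expect_gte(cur$ic, prev$ic)
    prev <- cur
  }
})

test_that("pairs below the minimum report count never signal", {
  # overwhelming disproportionality but only two reports
  row <- evaluate_pair(contingency(2, 1, 1, 10000))
  expect_false(row$composite)
  expect_false(row$ror_pos || row$prr_pos || row$mhra_pos || row$bcpnn_pos)
  # the same table with a = 3 signals
  expect_true(evaluate_pair(contingency(3, 1, 1, 10000))$composite)
})

test_that("the disprop estimator counts pairs at report level", {
  ex <- data.frame(primaryid = c("1", "1", "2", "3", "4", "4"),
                   drug = c("x", "x", "x", "y", "y", "x"))
  ev <- data.frame(primaryid = c("1", "2", "3", "4"),
                   event = c("e", "e", "e", "f"))
  fit <- disprop(ex, ev, n_total = 4)
  t <- fit$table
  # duplicated (report, drug) rows collapse: drug x on reports 1,2,4
  xe <- t[t$drug == "x" & t$event == "e", ]
  expect_equal(xe$a, 2L)   # reports 1 and 2
  expect_equal(xe$b, 1L)   # report 4 has x without e
  expect_equal(xe$c, 1L)   # report 3 has e without x
  expect_equal(xe$d, 0L)
  # methods work
  expect_s3_class(fit, "disprop")
  expect_true(is.matrix(coef(fit)))
  expect_equal(nrow(as.data.frame(fit)), nrow(t))
  expect_output(print(fit), "drug-event pairs")
  expect_output(print(summary(fit)), "Positive flags")
})

test_that("null tables rarely cross the ROR signal threshold", {
  # under independence with healthy cell counts, the lower bound of the
  # 95% interval exceeds 1 in about 2.5% of tables (one tail)
  set.seed(77)
  n_tab <- 4000
  hits <- 0L
  p_drug <- 0.1; p_ev <- 0.05; N <- 4000
  for (i in seq_len(n_tab)) {
    a <- stats::rbinom(1, N, p_drug * p_ev)
    b <- stats::rbinom(1, N, p_drug * (1 - p_ev))
    c <- stats::rbinom(1, N, (1 - p_drug) * p_ev)
    d <- N - a - b - c
    if (min(a, b, c, d) == 0) next
    r <- ror(a, b, c, d)
    if (r[["lo"]] > 1) hits <- hits + 1L
  }
  expect_lt(hits / n_tab, 0.045)
  expect_gt(hits / n_tab, 0.005)
})
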