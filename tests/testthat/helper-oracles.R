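# Independent reference implementations used to cross-check the package.
# They are deliberately naive (explicit loops, direct arithmetic) and share
# no code with the implementation paths they verify.

# Deduplication oracle: per case id, keep the version with the largest
# receipt date, ties broken by the largest (numeric) primary id.
oracle_dedup <- function(demo) {
  picked <- lapply(split(seq_len(nrow(demo)), demo$caseid), function(idx) {
    g <- demo[idx, , drop = FALSE]
    best <- g[g$fda_dt == max(g$fda_dt), , drop = FALSE]
    if (nrow(best) > 1) {
      pid <- as.numeric(best$primaryid)
      best <- best[which.max(pid), , drop = FALSE]
    }
    best
  })
  out <- do.call(rbind, picked[order(names(picked))])
  rownames(out) <- NULL
  out
}

# Direct-arithmetic disproportionality statistics on one 2x2 table.
oracle_ror <- function(a, b, c, d) {
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(est, est * exp(-1.96 * se), est * exp(1.96 * se))
}
oracle_prr <- function(a, b, c, d) {
  est <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  c(est, est * exp(-1.96 * se), est * exp(1.96 * se))
}
# Yates chi-squared through R's own contingency-table test.
oracle_chi2 <- function(a, b, c, d) {
  suppressWarnings(unname(
    stats::chisq.test(matrix(c(a, c, b, d), 2), correct = TRUE)$statistic))
}
oracle_ic <- function(a, b, c, d) {
  N <- a + b + c + d
  E <- (a + b) * (a + c) / N
  ic <- log((a + 0.5) / (E + 0.5)) / log(2)
  c(ic, ic - 3.3 / sqrt(a + 0.5) - 2 / (a + 0.5)^1.5)
}

# Population reporting odds ratio of a generator pair by explicit
# enumeration of the (drug, event) joint distribution, independent of the
# generator's own closed form.
oracle_population_ror <- function(config, drug, pt) {
  nd <- nrow(config$drugs); ne <- nrow(config$events)
  joint <- matrix(0, nd, ne)
  pf <- config$sex_ratio * (1 - config$sex_missing_rate)
  pm <- (1 - config$sex_ratio) * (1 - config$sex_missing_rate)
  pu <- config$sex_missing_rate
  for (sexw in list(c("F", pf), c("M", pm), c(NA, pu))) {
    s <- sexw[1]; w <- as.numeric(sexw[2])
    for (i in seq_len(nd)) {
      row <- config$events$prob
      sp <- config$signal_pairs
      for (k in seq_len(nrow(sp))) {
        if (sp$drug[k] == config$drugs$name[i] &&
            (is.na(sp$sex[k]) || (!is.na(s) && sp$sex[k] == s))) {
          j <- match(sp$pt[k], config$events$pt_name)
          row[j] <- row[j] * sp$lambda[k]
        }
      }
      joint[i, ] <- joint[i, ] +
        w * config$drugs$prob[i] / sum(config$drugs$prob) * row / sum(row)
    }
  }
  i <- match(drug, config$drugs$name)
  j <- match(pt, config$events$pt_name)
  a <- joint[i, j]; b <- sum(joint[i, ]) - a
  cc <- sum(joint[, j]) - a; d <- sum(joint) - a - b - cc
  (a * d) / (b * cc)
}

# ---- fixture builders ----------------------------------------------------

# Write a minimal "$"-delimited bundle from per-table data.frames; missing
# tables get header-only files. Returns the bundle directory.
tiny_bundle <- function(demo = NULL, drug = NULL, reac = NULL, outc = NULL,
                        ther = NULL, indi = NULL, deleted = character(0),
                        dir = withr::local_tempdir(.local_envir = parent.frame())) {
  headers <- list(
    demo = "primaryid$caseid$fda_dt$age$age_cod$sex$occp_cod$reporter_country$event_dt",
    drug = "primaryid$caseid$drug_seq$role_cod$drugname$route",
    reac = "primaryid$caseid$pt",
    outc = "primaryid$caseid$outc_cod",
    ther = "primaryid$caseid$dsg_drug_seq$start_dt",
    indi = "primaryid$caseid$indi_drug_seq$indi_pt"
  )
  tabs <- list(demo = demo, drug = drug, reac = reac, outc = outc,
               ther = ther, indi = indi)
  for (nm in names(headers)) {
    lines <- headers[[nm]]
    t <- tabs[[nm]]
    if (!is.null(t))
      lines <- c(lines, do.call(paste, c(as.list(t), sep = "$")))
    writeLines(lines, file.path(dir, paste0(nm, ".txt")))
  }
  writeLines(deleted, file.path(dir, "deleted_cases.txt"))
  write_vocab(test_vocab(), file.path(dir, "vocab"))
  dir
}

# A small fixed vocabulary for hand-built fixtures.
test_vocab <- function() {
  dd <- data.frame(
    name = c("montelukast", "promethazine", "aspirin", "comboprod"),
    ingredient = c("montelukast", "promethazine", "aspirin", "comboprod"),
    atc = c("R03DC03", "R06AD02", "N02BA01", "N02BA01/R05DA01"),
    stringsAsFactors = FALSE
  )
  md <- data.frame(
    pt_code = c(1L, 2L, 3L, 4L, 5L),
    pt_name = c("Anxiety", "Depression", "Suicidal ideation", "Headache",
                "Nightmare"),
    hlt = c("Anxiety symptoms", "Depressive disorders",
            "Suicidal behaviours", "Headaches NEC", "Sleep disturbances"),
    hlgt_code = c(10002861L, 10012375L, 10042460L, 90000002L, 90000010L),
    hlgt_name = c("Anxiety disorders and symptoms",
                  "Depressed mood disorders and disturbances",
                  "Suicidal and self-injurious behaviours",
                  "Headaches", "Sleep disorders and disturbances"),
    soc_code = c(10037175L, 10037175L, 10037175L, 10029205L, 10037175L),
    soc_name = c(rep("Psychiatric disorders", 3), "Nervous system disorders",
                 "Psychiatric disorders"),
    stringsAsFactors = FALSE
  )
  pv_vocab(dd, md)
}

# A demo-row data.frame in the shape deduplicate() expects.
demo_rows <- function(primaryid, caseid, fda_dt, age = "10", age_cod = "YR",
                      sex = "F", occp = "MD", country = "US",
                      event_dt = "20200101") {
  data.frame(primaryid = as.character(primaryid),
             caseid = as.character(caseid),
             fda_dt = as.character(fda_dt),
             age = age, age_cod = age_cod, sex = sex, occp_cod = occp,
             reporter_country = country, event_dt = event_dt,
             stringsAsFactors = FALSE)
}

# Random multi-version demo tables for dedup property tests.
random_demo <- function(n_cases, seed) {
  set.seed(seed)
  reps <- sample(1:4, n_cases, TRUE)
  caseid <- rep(sprintf("C%04d", seq_len(n_cases)), reps)
  n <- length(caseid)
  demo_rows(
    primaryid = sample(1:(n * 10), n),
    caseid = caseid,
    fda_dt = format(as.Date("2015-01-01") + sample(0:3000, n, TRUE),
                    "%Y%m%d")
  )
}
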