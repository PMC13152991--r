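# ---- default synthetic vocabularies -------------------------------------
# A mock drug dictionary and MedDRA-style hierarchy for the synthetic
# generator. Codes and groupings are synthetic stand-ins shaped like the
# real terminologies (respiratory drugs carry ATC codes beginning "R"; the
# psychiatric SOC holds three focus HLGTs); they are not extracts of the
# licensed dictionaries.

default_synthetic_drugs <- function() {
  data.frame(
    name = c("montelukast", "promethazine", "diphenhydramine",
             "desloratadine", "levocetirizine", "hydroxyzine",
             "terbutaline", "caffeine",
             "ibuprofen", "amoxicillin", "methylphenidate", "paracetamol"),
    atc = c("R03DC03", "R06AD02", "R06AA02",
            "R06AX27", "R06AE09", "R06AX90",
            "R03CC03", "R07AB90",
            "M01AE01", "J01CA04", "N06BA04", "N02BE01"),
    prob = c(0.15, 0.08, 0.08,
             0.05, 0.04, 0.03,
             0.02, 0.02,
             0.12, 0.10, 0.08, 0.10),
    stringsAsFactors = FALSE
  )
}

default_synthetic_events <- function() {
  soc_psy <- "Psychiatric disorders"
  hlgt_anx <- "Anxiety disorders and symptoms"
  hlgt_dep <- "Depressed mood disorders and disturbances"
  hlgt_sui <- "Suicidal and self-injurious behaviours"
  data.frame(
    pt_name = c("Anxiety", "Agitation", "Akathisia",
                "Depression", "Depressed mood",
                "Suicidal ideation", "Suicide attempt", "Completed suicide",
                "Intentional self-injury",
                "Cough", "Headache", "Nausea", "Vomiting", "Rash", "Pyrexia"),
    pt_code = c(10002855L, 10001497L, 10001540L,
                10012378L, 10012374L,
                10042458L, 10042464L, 10010144L,
                10022524L,
                10011224L, 10019211L, 10028813L, 10047700L, 10037844L,
                10037660L),
    prob = c(0.020, 0.010, 0.003,
             0.015, 0.006,
             0.012, 0.005, 0.004,
             0.004,
             0.060, 0.080, 0.080, 0.050, 0.060, 0.060),
    hlt = c("Anxiety symptoms", "Anxiety symptoms", "Anxiety symptoms",
            "Depressive disorders", "Depressive disorders",
            "Suicidal behaviours", "Suicidal behaviours",
            "Suicidal behaviours", "Self-injurious behaviours",
            "Coughing symptoms", "Headaches NEC", "Nausea symptoms",
            "Vomiting symptoms", "Rashes NEC", "Febrile disorders"),
    hlgt_code = c(10002861L, 10002861L, 10002861L,
                  10012375L, 10012375L,
                  10042460L, 10042460L, 10042460L, 10042460L,
                  90000001L, 90000002L, 90000003L, 90000003L, 90000004L,
                  90000005L),
    hlgt_name = c(hlgt_anx, hlgt_anx, hlgt_anx,
                  hlgt_dep, hlgt_dep,
                  hlgt_sui, hlgt_sui, hlgt_sui, hlgt_sui,
                  "Respiratory signs and symptoms",
                  "Headaches",
                  "Gastrointestinal signs and symptoms",
                  "Gastrointestinal signs and symptoms",
                  "Epidermal conditions",
                  "Body temperature conditions"),
    soc_code = c(rep(10037175L, 9L),
                 10038738L, 10029205L, 10017947L, 10017947L, 10040785L,
                 10018065L),
    soc_name = c(rep(soc_psy, 9L),
                 "Respiratory, thoracic and mediastinal disorders",
                 "Nervous system disorders",
                 "Gastrointestinal disorders",
                 "Gastrointestinal disorders",
                 "Skin and subcutaneous tissue disorders",
                 "General disorders and administration site conditions"),
    stringsAsFactors = FALSE
  )
}

default_age_dist <- function() {
  data.frame(
    group = c("0-4", "5-11", "12-17", "adult", "unknown"),
    prob = c(0.13, 0.35, 0.42, 0.07, 0.03),
    stringsAsFactors = FALSE
  )
}

# ---- configuration -------------------------------------------------------

#' Configuration for the synthetic report generator
#'
#' Defines the population a synthetic FAERS-style bundle is drawn from. Each
#' unique case gets one primary-suspect drug from the drug background and one
#' reaction preferred term from the event background; for pairs listed in
#' `signal_pairs` the joint probability is multiplied by the relative
#' reporting rate `lambda` and the event distribution renormalized within
#' that drug. When the event background sums to one (the remainder is always
#' assigned to an explicit filler term), the population reporting odds ratio
#' of an injected pair against the rest of the bundle equals `lambda`
#' exactly, which is what parameter-recovery checks exploit.
#'
#' Defaults emulate the reporting landscape of pediatric psychiatric adverse
#' events under respiratory drugs: a drug background dominated by a
#' leukotriene receptor antagonist and several antihistamines plus
#' non-respiratory filler drugs, psychiatric preferred terms under three
#' focus high-level group terms, age groups weighted toward adolescents with
#' mixed reporting units, roughly balanced sex, and serious-outcome
#' frequencies in line with published spontaneous-report series.
#'
#' @param n_cases number of unique cases (case ids) to generate.
#' @param drugs data.frame `name`, `atc`, `prob`; probabilities must sum to
#'   at most 1, the remainder going to an explicit filler drug.
#' @param events data.frame `pt_name`, `pt_code`, `prob` plus hierarchy
#'   columns `hlt`, `hlgt_code`, `hlgt_name`, `soc_code`, `soc_name`;
#'   probabilities sum to at most 1 with the remainder to a filler term.
#' @param signal_pairs data.frame `drug`, `pt`, `lambda` (each lambda >= 1);
#'   pairs not listed implicitly have lambda = 1. Optional column `sex`
#'   restricts the injection to one sex (`"F"` or `"M"`), for stratified
#'   checks.
#' @param age_dist data.frame `group` in `{0-4, 5-11, 12-17, adult,
#'   unknown}` and `prob` summing to 1.
#' @param sex_ratio fraction female among cases with known sex.
#' @param sex_missing_rate fraction of cases with unreported sex.
#' @param duplicate_rate fraction of cases emitted in two or more report
#'   versions (same case id, distinct primary ids).
#' @param dup_tie_rate among duplicated cases, fraction whose two latest
#'   versions share a receipt date, exercising the primary-id tie-break.
#' @param deletion_rate fraction of case ids placed on the deleted-report
#'   list.
#' @param partial_date_rate fraction of event/therapy dates truncated to
#'   year-month or year only.
#' @param multi_pt_rate fraction of cases with one extra background reaction
#'   term (default 0: one reaction per case keeps injected lambdas directly
#'   interpretable).
#' @param multi_drug_rate fraction of cases with one extra concomitant
#'   (non-primary-suspect) drug.
#' @param seed integer seed; together with the other fields it determines
#'   the emitted bundle byte-for-byte.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 5000,
                             drugs = default_synthetic_drugs(),
                             events = default_synthetic_events(),
                             signal_pairs = NULL,
                             age_dist = default_age_dist(),
                             sex_ratio = 0.50,
                             sex_missing_rate = 0.02,
                             duplicate_rate = 0.10,
                             dup_tie_rate = 0.20,
                             deletion_rate = 0.02,
                             partial_date_rate = 0.10,
                             multi_pt_rate = 0,
                             multi_drug_rate = 0.20,
                             seed = 1L) {
  stopifnot(n_cases >= 1, sex_ratio >= 0, sex_ratio <= 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            deletion_rate >= 0, deletion_rate < 1)
  if (sum(drugs$prob) > 1 + 1e-9 || any(drugs$prob < 0))
    stop("drug background probabilities must be non-negative and sum to <= 1")
  if (sum(events$prob) > 1 + 1e-9 || any(events$prob < 0))
    stop("event background probabilities must be non-negative and sum to <= 1")
  if (abs(sum(age_dist$prob) - 1) > 1e-9)
    stop("age_dist probabilities must sum to 1")
  if (is.null(signal_pairs)) {
    signal_pairs <- data.frame(drug = character(0), pt = character(0),
                               lambda = numeric(0), sex = character(0),
                               stringsAsFactors = FALSE)
  }
  if (nrow(signal_pairs)) {
    if (is.null(signal_pairs$sex)) signal_pairs$sex <- NA_character_
    if (any(signal_pairs$lambda < 1))
      stop("signal lambdas must be >= 1")
    if (!all(signal_pairs$drug %in% drugs$name))
      stop("signal pair drug not in drug background")
    if (!all(signal_pairs$pt %in% events$pt_name))
      stop("signal pair PT not in event background")
  }
  # filler categories absorb the remaining probability mass
  drugs <- rbind(drugs, data.frame(
    name = "synthetic filler drug", atc = "V03AX90",
    prob = max(0, 1 - sum(drugs$prob))))
  events <- rbind(events, data.frame(
    pt_name = "Synthetic filler event", pt_code = 99999999L,
    prob = max(0, 1 - sum(events$prob)),
    hlt = "Filler terms", hlgt_code = 90000009L,
    hlgt_name = "Synthetic filler group", soc_code = 10018065L,
    soc_name = "General disorders and administration site conditions"))
  structure(list(
    n_cases = as.integer(n_cases), drugs = drugs, events = events,
    signal_pairs = signal_pairs, age_dist = age_dist,
    sex_ratio = sex_ratio, sex_missing_rate = sex_missing_rate,
    duplicate_rate = duplicate_rate, dup_tie_rate = dup_tie_rate,
    deletion_rate = deletion_rate, partial_date_rate = partial_date_rate,
    multi_pt_rate = multi_pt_rate, multi_drug_rate = multi_drug_rate,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic bundle configuration:\n")
  cat("  cases:", x$n_cases, " seed:", x$seed, "\n")
  cat("  drugs:", nrow(x$drugs), " events:", nrow(x$events),
      " injected signal pairs:", nrow(x$signal_pairs), "\n")
  cat("  duplicate rate:", x$duplicate_rate,
      " deletion rate:", x$deletion_rate, "\n")
  invisible(x)
}

#' Mock vocabulary for a synthetic configuration
#'
#' Builds the [pv_vocab()] bundle matching a generator configuration: every
#' synthetic drug maps to an ATC code (respiratory ones to codes starting
#' "R") and every preferred term to a single HLT/HLGT/SOC path, including
#' the psychiatric SOC with its three focus high-level group terms.
#'
#' @param config a [synthetic_config()].
#' @return a [pv_vocab()] bundle.
#' @export
generate_vocab <- function(config) {
  dd <- data.frame(
    name = config$drugs$name,
    ingredient = config$drugs$name,
    atc = config$drugs$atc,
    stringsAsFactors = FALSE
  )
  md <- config$events[, c("pt_code", "pt_name", "hlt", "hlgt_code",
                          "hlgt_name", "soc_code", "soc_name")]
  pv_vocab(dd, md)
}

# Per-drug event distribution: background probabilities with injected
# lambdas multiplied in and renormalized. Rows = drugs, cols = events.
event_prob_matrix <- function(config, sex = NA_character_) {
  p <- matrix(config$events$prob, nrow = nrow(config$drugs),
              ncol = nrow(config$events), byrow = TRUE)
  sp <- config$signal_pairs
  if (nrow(sp)) {
    active <- is.na(sp$sex) | (!is.na(sex) & sp$sex == sex)
    for (k in which(active)) {
      i <- match(sp$drug[k], config$drugs$name)
      j <- match(sp$pt[k], config$events$pt_name)
      p[i, j] <- p[i, j] * sp$lambda[k]
    }
  }
  sweep(p, 1, rowSums(p), "/")
}

#' Population reporting odds ratio of a generator pair
#'
#' The closed-form reporting odds ratio implied by the generating joint
#' distribution of (primary-suspect drug, reaction term), against the
#' background of all other drugs and events. For an injected pair this is
#' the quantity a well-calibrated pipeline should recover; for non-injected
#' pairs it is close to (but, when other drugs carry injections, not exactly)
#' one.
#'
#' @param config a [synthetic_config()].
#' @param drug,pt names identifying the pair.
#' @return a single number.
#' @export
population_ror <- function(config, drug, pt) {
  i <- match(drug, config$drugs$name)
  j <- match(pt, config$events$pt_name)
  if (is.na(i) || is.na(j)) stop("unknown drug or PT")
  # mix sex-specific event matrices by the sex distribution
  pf <- config$sex_ratio * (1 - config$sex_missing_rate)
  pm <- (1 - config$sex_ratio) * (1 - config$sex_missing_rate)
  pu <- config$sex_missing_rate
  cond <- pf * event_prob_matrix(config, "F") +
    pm * event_prob_matrix(config, "M") +
    pu * event_prob_matrix(config, NA_character_)
  joint <- config$drugs$prob / sum(config$drugs$prob) * cond
  a <- joint[i, j]
  b <- sum(joint[i, -j])
  c <- sum(joint[-i, j])
  d <- sum(joint[-i, -j])
  (a * d) / (b * c)
}

# ---- sampling helpers ----------------------------------------------------

sample_ages <- function(config, n) {
  grp <- sample(config$age_dist$group, n, TRUE, prob = config$age_dist$prob)
  lo <- c(`0-4` = 0, `5-11` = 5, `12-17` = 12, adult = 18)
  hi <- c(`0-4` = 5, `5-11` = 12, `12-17` = 18, adult = 80)
  age <- rep(NA_real_, n)
  known <- grp != "unknown"
  age[known] <- stats::runif(sum(known), lo[grp[known]], hi[grp[known]])
  # reporting unit depends on age: infants in days/weeks/months, toddlers in
  # months, school age and up mostly years with occasional decades
  unit <- rep(NA_character_, n)
  value <- rep(NA_real_, n)
  u <- stats::runif(n)
  infant <- known & age < 1
  toddler <- known & age >= 1 & age < 5
  older <- known & age >= 5
  unit[infant] <- c("DY", "WK", "MON")[1 + findInterval(u[infant], c(0.3, 0.6))]
  unit[toddler] <- ifelse(u[toddler] < 0.7, "MON", "YR")
  unit[older] <- ifelse(u[older] < 0.95, "YR", "DEC")
  # floor conversions so the normalized age never crosses a bin upward
  value[unit %in% "DY"] <- floor(age[unit %in% "DY"] * 365.25)
  value[unit %in% "WK"] <- floor(age[unit %in% "WK"] * 52.18)
  value[unit %in% "MON"] <- floor(age[unit %in% "MON"] * 12)
  value[unit %in% "YR"] <- floor(age[unit %in% "YR"])
  value[unit %in% "DEC"] <- floor(age[unit %in% "DEC"] * 10) / 100
  list(group = grp, value = value, unit = unit)
}

sample_dates <- function(n) {
  # receipt years 2004..2024 with the reporting volume rising steeply in
  # the most recent period, as spontaneous-report series typically show
  yr_w <- c(rep(0.1291 / 5, 5), rep(0.1735 / 5, 5), rep(0.19 / 5, 5),
            rep(0.5074 / 6, 6))
  year <- sample(2004:2024, n, TRUE, prob = yr_w)
  month <- ifelse(year == 2024, sample(1:9, n, TRUE), sample(1:12, n, TRUE))
  day <- sample(1:28, n, TRUE)
  fda <- as.Date(sprintf("%04d-%02d-%02d", year, month, day))
  # event precedes receipt by up to ~3 months; therapy start precedes the
  # event by a bimodal onset time (early-onset spike plus long-therapy tail)
  event <- fda - sample(0:90, n, TRUE)
  bin <- sample(1:4, n, TRUE, prob = c(0.28, 0.05, 0.12, 0.55))
  onset <- integer(n)
  rng <- list(0:7, 8:60, 61:180, 181:360)
  for (b in 1:4) {
    idx <- bin == b
    onset[idx] <- sample(rng[[b]], sum(idx), TRUE)
  }
  start <- event - onset
  list(fda_dt = format(fda, "%Y%m%d"), event_dt = format(event, "%Y%m%d"),
       start_dt = format(start, "%Y%m%d"), year = year)
}

truncate_dates <- function(x, rate) {
  n <- length(x)
  u <- stats::runif(n)
  part <- u < rate
  half <- u < rate / 2
  x[part] <- substr(x[part], 1, 6)   # YYYYMM
  x[half] <- substr(x[half], 1, 4)   # YYYY
  x
}

# ---- bundle generation ---------------------------------------------------

#' Generate a FAERS-style quarterly bundle with known ground truth
#'
#' Writes "$"-delimited DEMO, DRUG, REAC, OUTC, THER and INDI tables, a
#' deleted-case-id list, the mock vocabulary, and a YAML manifest recording
#' every injected signal pair, into `out_dir`. Duplicate case versions share
#' a case id with distinct primary ids and (mostly) increasing receipt
#' dates; a configurable fraction of duplicates tie on the receipt date to
#' exercise the primary-id tie-break. The same configuration (including
#' seed) always produces byte-identical files.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, the manifest: a list with `files` (named paths),
#'   `ground_truth` (injected pairs with lambda and the population reporting
#'   odds ratio), `deleted_caseids`, and `config` scalars.
#' @export
generate_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  set.seed(config$seed)
  n <- config$n_cases
  caseid <- sprintf("%d", 10000000L + seq_len(n))

  # demographics
  sex <- ifelse(stats::runif(n) < config$sex_missing_rate, "",
                ifelse(stats::runif(n) < config$sex_ratio, "F", "M"))
  ages <- sample_ages(config, n)
  dates <- sample_dates(n)
  occp <- sample(c("CN", "MD", "OT", "PH", "", "LW"), n, TRUE,
                 prob = c(0.38, 0.27, 0.14, 0.13, 0.077, 0.003))
  country <- sample(c("US", "GB", "SE", "FR", "DE", "CA", "JP", "AU"), n,
                    TRUE, prob = c(0.55, 0.16, 0.045, 0.06, 0.05, 0.05,
                                   0.045, 0.04))

  # primary-suspect drug and reaction term: event drawn conditionally on
  # the drug so injected pairs get their joint probability multiplied by
  # lambda and renormalized (sex-restricted injections use per-sex tables)
  pdrug <- config$drugs$prob / sum(config$drugs$prob)
  di <- sample.int(nrow(config$drugs), n, TRUE, prob = pdrug)
  ei <- integer(n)
  for (s in c("F", "M", "")) {
    rows <- which(sex == s)
    if (!length(rows)) next
    pm <- event_prob_matrix(config, if (s == "") NA_character_ else s)
    for (d in unique(di[rows])) {
      idx <- rows[di[rows] == d]
      ei[idx] <- sample.int(ncol(pm), length(idx), TRUE, prob = pm[d, ])
    }
  }
  drugname <- toupper(config$drugs$name[di])
  pt <- config$events$pt_name[ei]

  route <- sample(c("Oral", "", "Subcutaneous", "Respiratory (inhalation)",
                    "Topical"), n, TRUE,
                  prob = c(0.61, 0.24, 0.08, 0.04, 0.03))
  indi <- sample(c("Asthma", "Product used for unknown indication",
                   "Dermatitis atopic", "Cystic fibrosis",
                   "Allergic rhinitis", "Urticaria", "Cough"), n, TRUE,
                 prob = c(0.28, 0.30, 0.05, 0.05, 0.15, 0.09, 0.08))

  # outcome codes: independent draws per code, frequencies shaped like
  # published pediatric spontaneous-report series; any code => serious
  oc_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
  oc_prob <- c(0.058, 0.086, 0.246, 0.093, 0.002, 0.017, 0.594)
  oc_draw <- matrix(stats::runif(n * 7) <
                      matrix(oc_prob, n, 7, byrow = TRUE), n, 7)

  # duplicate versions: chosen cases get 2 (or sometimes 3) versions with
  # increasing receipt dates; among duplicated cases a configurable
  # fraction ties the two latest receipt dates
  n_dup <- round(config$duplicate_rate * n)
  dup_cases <- if (n_dup) sort(sample.int(n, n_dup)) else integer(0)
  extra <- if (n_dup) 1L + (stats::runif(n_dup) < 0.25) else integer(0)
  n_ver <- rep(1L, n)
  n_ver[dup_cases] <- 1L + extra
  tie <- logical(n)
  tie[dup_cases] <- stats::runif(n_dup) < config$dup_tie_rate

  case_of <- rep(seq_len(n), n_ver)
  ver <- sequence(n_ver)
  primaryid <- paste0(caseid[case_of], ver)
  nv <- length(case_of)
  # receipt date per version: later versions days..months after the first;
  # tied cases repeat the previous version's date on the last version
  shift <- ifelse(ver == 1L, 0L, 0L)
  add <- integer(nv)
  later <- ver > 1L
  add[later] <- sample(1:200, sum(later), TRUE)
  fda_v <- as.Date(dates$fda_dt[case_of], "%Y%m%d")
  fda_v <- fda_v + ave(add, case_of, FUN = cumsum)
  is_last <- ver == n_ver[case_of]
  tie_last <- is_last & tie[case_of] & ver > 1L
  fda_v[tie_last] <- fda_v[which(tie_last) - 1L]
  fda_dt <- format(fda_v, "%Y%m%d")

  event_out <- truncate_dates(dates$event_dt, config$partial_date_rate)
  start_out <- truncate_dates(dates$start_dt, config$partial_date_rate)

  # ---- assemble per-version tables --------------------------------------
  fmt_age <- function(v) ifelse(is.na(v), "", format(v, trim = TRUE,
                                                     scientific = FALSE))
  demo <- paste(primaryid, caseid[case_of], fda_dt,
                fmt_age(ages$value[case_of]),
                ifelse(is.na(ages$unit[case_of]), "", ages$unit[case_of]),
                sex[case_of], occp[case_of], country[case_of],
                event_out[case_of], sep = "$")

  # drug rows: PS drug (seq 1) plus optional concomitant (seq 2)
  conc <- stats::runif(n) < config$multi_drug_rate
  ci_drug <- sample.int(nrow(config$drugs), n, TRUE, prob = pdrug)
  drug_rows <- data.frame(
    case = c(seq_len(n), which(conc)),
    seq = c(rep(1L, n), rep(2L, sum(conc))),
    role = c(rep("PS", n), rep("C", sum(conc))),
    name = c(drugname, toupper(config$drugs$name[ci_drug[conc]])),
    route = c(route, rep("", sum(conc))),
    stringsAsFactors = FALSE
  )
  drug_rows <- drug_rows[order(drug_rows$case, drug_rows$seq), ]

  # reaction rows: primary PT plus optional extra background PT
  extra_pt <- stats::runif(n) < config$multi_pt_rate
  e2 <- sample.int(nrow(config$events), n, TRUE, prob = config$events$prob)
  reac_rows <- data.frame(
    case = c(seq_len(n), which(extra_pt & e2 != ei)),
    pt = c(pt, config$events$pt_name[e2[extra_pt & e2 != ei]]),
    stringsAsFactors = FALSE
  )
  reac_rows <- reac_rows[order(reac_rows$case), ]

  outc_rows <- data.frame(
    case = rep(seq_len(n), times = rowSums(oc_draw)),
    code = oc_codes[unlist(apply(oc_draw, 1, which, simplify = FALSE))],
    stringsAsFactors = FALSE
  )

  expand <- function(df) {
    # replicate a per-case table across all report versions of each case
    reps <- n_ver[df$case]
    out <- df[rep(seq_len(nrow(df)), reps), , drop = FALSE]
    vz <- sequence(reps)
    first_pid_rows <- rep(seq_len(nrow(df)), reps)
    out$primaryid <- paste0(caseid[out$case], vz)
    out$caseid <- caseid[out$case]
    o <- order(out$case, out$primaryid)
    out[o, , drop = FALSE]
  }

  dr <- expand(drug_rows)
  rr <- expand(reac_rows)
  orow <- expand(outc_rows)
  th <- expand(data.frame(case = seq_len(n), seq = 1L,
                          start = start_out, stringsAsFactors = FALSE))
  ind <- expand(data.frame(case = seq_len(n), seq = 1L, indi = indi,
                           stringsAsFactors = FALSE))

  # deleted-case list
  n_del <- round(config$deletion_rate * n)
  del_ids <- if (n_del) sort(sample(caseid, n_del)) else character(0)

  files <- c(demo = "demo.txt", drug = "drug.txt", reac = "reac.txt",
             outc = "outc.txt", ther = "ther.txt", indi = "indi.txt",
             deleted = "deleted_cases.txt")
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)

  wl <- function(lines, path) writeLines(lines, path, useBytes = TRUE)
  wl(c("primaryid$caseid$fda_dt$age$age_cod$sex$occp_cod$reporter_country$event_dt",
       demo), paths["demo"])
  wl(c("primaryid$caseid$drug_seq$role_cod$drugname$route",
       paste(dr$primaryid, dr$caseid, dr$seq, dr$role, dr$name, dr$route,
             sep = "$")), paths["drug"])
  wl(c("primaryid$caseid$pt",
       paste(rr$primaryid, rr$caseid, rr$pt, sep = "$")), paths["reac"])
  wl(c("primaryid$caseid$outc_cod",
       paste(orow$primaryid, orow$caseid, orow$code, sep = "$")),
     paths["outc"])
  wl(c("primaryid$caseid$dsg_drug_seq$start_dt",
       paste(th$primaryid, th$caseid, th$seq, th$start, sep = "$")),
     paths["ther"])
  wl(c("primaryid$caseid$indi_drug_seq$indi_pt",
       paste(ind$primaryid, ind$caseid, ind$seq, ind$indi, sep = "$")),
     paths["indi"])
  wl(del_ids, paths["deleted"])

  vocab <- generate_vocab(config)
  vpaths <- write_vocab(vocab, file.path(out_dir, "vocab"))

  gt <- config$signal_pairs
  if (nrow(gt)) {
    gt$population_ror <- mapply(population_ror, drug = gt$drug, pt = gt$pt,
                                MoreArgs = list(config = config))
  } else {
    gt$population_ror <- numeric(0)
  }

  manifest <- list(
    files = as.list(paths),
    vocab = as.list(vpaths),
    columns = list(
      demo = "primaryid, caseid, fda_dt, age, age_cod, sex, occp_cod, reporter_country, event_dt",
      drug = "primaryid, caseid, drug_seq, role_cod, drugname, route",
      reac = "primaryid, caseid, pt",
      outc = "primaryid, caseid, outc_cod",
      ther = "primaryid, caseid, dsg_drug_seq, start_dt",
      indi = "primaryid, caseid, indi_drug_seq, indi_pt"
    ),
    n_cases = n,
    n_report_versions = nv,
    deleted_caseids = as.list(del_ids),
    ground_truth = lapply(seq_len(nrow(gt)), function(k) as.list(gt[k, ])),
    seed = config$seed
  )
  # the on-disk manifest stores paths relative to the bundle directory so
  # identical configurations yield byte-identical bundles wherever written
  man_disk <- manifest
  man_disk$files <- lapply(manifest$files, basename)
  man_disk$vocab <- lapply(manifest$vocab,
                           function(p) file.path("vocab", basename(p)))
  yaml::write_yaml(man_disk, file.path(out_dir, "manifest.yaml"))
  manifest$ground_truth <- gt
  manifest$deleted_caseids <- del_ids
  invisible(manifest)
}
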