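# Days per unit for age normalization. A week is taken as 52.18 per year
# (365.25/7) and a decade as ten years.
AGE_UNIT_DIVISOR <- c(YR = 1, MON = 12, WK = 52.18, DY = 365.25,
                      HR = 8766, DEC = 0.1)

#' Convert a reported age to years
#'
#' FAERS ages arrive as a number plus a unit code (years, months, weeks,
#' days, hours or decades). Negative values, unknown units, or a value
#' without a unit normalize to missing rather than erroring; the caller
#' counts the missings.
#'
#' @param value numeric vector of reported age values.
#' @param unit_code character vector of unit codes in
#'   `{YR, MON, WK, DY, HR, DEC}` (case-insensitive), or missing.
#' @return numeric vector of ages in years, NA where not resolvable.
#' @export
#' @examples
#' normalize_age(c(24, 1, -3), c("MON", "DEC", "YR"))  # 2, 10, NA
normalize_age <- function(value, unit_code) {
  value <- suppressWarnings(as.numeric(value))
  unit <- toupper(trimws(as.character(unit_code)))
  div <- AGE_UNIT_DIVISOR[unit]
  out <- value / div
  out[is.na(value) | is.na(div) | value < 0] <- NA_real_
  unname(out)
}

# Pediatric age groups used throughout: infants/toddlers, school age,
# adolescents. Ages outside [0, 18) get NA.
age_group_of <- function(age_years) {
  cut(age_years, breaks = c(0, 5, 12, 18), right = FALSE,
      labels = c("0-4", "5-11", "12-17"))
}

#' Days from therapy start to event onset
#'
#' Computed only when both dates resolve to a full YYYYMMDD date; partial
#' (year or year-month) dates and negative differences yield missing.
#'
#' @param event_dt,start_dt date strings, possibly partial.
#' @return integer vector of days, NA where not computable.
#' @export
#' @examples
#' onset_days("20200110", "20200101")  # 9
#' onset_days("202001", "20200101")    # NA: partial event date
onset_days <- function(event_dt, start_dt) {
  ev <- parse_full_date(event_dt)
  st <- parse_full_date(start_dt)
  d <- as.integer(ev - st)
  d[is.na(ev) | is.na(st) | d < 0] <- NA_integer_
  d
}

#' Bin onset time the way published summaries report it
#'
#' Inclusive integer bins 0-7, 8-60, 61-180 and 181-360 days; longer onsets
#' and missing values are reported as their own categories rather than
#' forced into the published bins.
#'
#' @param days integer vector of onset days (NA allowed).
#' @return factor with levels `0-7`, `8-60`, `61-180`, `181-360`, `>360`,
#'   `missing`.
#' @export
bin_onset <- function(days) {
  lev <- c("0-7", "8-60", "61-180", "181-360", ">360", "missing")
  idx <- findInterval(days, c(0, 8, 61, 181, 361))
  out <- lev[idx]
  out[is.na(days)] <- "missing"
  factor(out, levels = lev)
}

#' Apply the inclusion criteria and build case and pair tables
#'
#' A case is included when (1) its normalized age lies in `[age_min,
#' age_max)` years, (2) at least one drug with primary-suspect role maps to
#' a respiratory ATC code (starting "R"), and (3) at least one reaction
#' preferred term falls under the psychiatric-disorders SOC. The pair table
#' enumerates every (primary-suspect respiratory drug, psychiatric PT)
#' combination, so a case with one drug and two qualifying terms
#' contributes one case row and two pair rows — pairs, not patients, are the
#' unit of the drug-level composition and signal tables.
#'
#' @param cases a `pv_cases` object from [assemble_cases()].
#' @param vocab a [pv_vocab()] bundle.
#' @param age_min,age_max inclusion bounds in years (default `[0, 18)`).
#' @return an object of class `pv_cohort`: list with `cases` (one row per
#'   included case), `pairs` (one row per drug-PT pair), `attrition`
#'   (named counts after each filter), and unmapped-name counts.
#' @export
select_cases <- function(cases, vocab, age_min = 0, age_max = 18) {
  demo <- cases$demo
  n0 <- nrow(demo)

  age_years <- normalize_age(demo$age, demo$age_cod)
  in_age <- !is.na(age_years) & age_years >= age_min & age_years < age_max
  demo_a <- demo[in_age, , drop = FALSE]
  age_years <- age_years[in_age]

  # primary-suspect respiratory drugs per report
  drug <- cases$drug[cases$drug$role_cod == "PS", , drop = FALSE]
  dm <- is_respiratory(drug$drugname, vocab)
  n_unmapped_drug <- sum(!dm$mapped)
  drug_r <- drug[dm$mapped & dm$respiratory %in% TRUE, , drop = FALSE]
  drug_r$ingredient <- dm$ingredient[dm$mapped & dm$respiratory %in% TRUE]
  drug_r$atc <- dm$atc[dm$mapped & dm$respiratory %in% TRUE]

  has_rd <- demo_a$primaryid %in% drug_r$primaryid
  demo_rd <- demo_a[has_rd, , drop = FALSE]
  age_rd <- age_years[has_rd]

  # psychiatric reaction terms per report
  reac <- cases$reac
  cls <- classify_pt(reac$pt, vocab)
  n_unmapped_pt <- sum(!cls$mapped)
  reac_p <- reac[cls$mapped & cls$psychiatric %in% TRUE, , drop = FALSE]
  reac_p$focus_hlgt <- cls$focus_hlgt[cls$mapped & cls$psychiatric %in% TRUE]

  has_pae <- demo_rd$primaryid %in% reac_p$primaryid
  demo_f <- demo_rd[has_pae, , drop = FALSE]
  age_f <- age_rd[has_pae]

  # outcome codes and seriousness (any outcome code => serious)
  outc <- cases$outc
  oc_by_pid <- split(outc$outc_cod, outc$primaryid)
  oc <- oc_by_pid[demo_f$primaryid]
  oc[vapply(oc, is.null, logical(1))] <- list(character(0))
  serious <- demo_f$primaryid %in% outc$primaryid

  # per-case fields from the first qualifying PS respiratory drug
  first_rd <- drug_r[!duplicated(drug_r$primaryid), , drop = FALSE]
  i <- match(demo_f$primaryid, first_rd$primaryid)

  case_tab <- data.frame(
    primaryid = demo_f$primaryid,
    caseid = demo_f$caseid,
    age_years = age_f,
    age_group = age_group_of(age_f),
    sex = ifelse(demo_f$sex %in% c("F", "M"), demo_f$sex, NA_character_),
    reporter = ifelse(nzchar(demo_f$occp_cod), demo_f$occp_cod,
                      NA_character_),
    country = demo_f$reporter_country,
    route = ifelse(nzchar(first_rd$route[i]), first_rd$route[i],
                   NA_character_),
    indication = ifelse(nzchar(first_rd$indication[i]),
                        first_rd$indication[i], NA_character_),
    serious = serious,
    death = vapply(oc, function(z) "DE" %in% z, logical(1),
                   USE.NAMES = FALSE),
    life_threat = vapply(oc, function(z) "LT" %in% z, logical(1),
                         USE.NAMES = FALSE),
    onset_days = onset_days(demo_f$event_dt, first_rd$start_dt[i]),
    report_year = date_year(demo_f$fda_dt),
    stringsAsFactors = FALSE
  )
  rownames(case_tab) <- NULL
  case_tab$outcome_codes <- unname(oc)

  # pair table: every (PS respiratory drug, psychiatric PT) combination of
  # each included case
  dr_in <- drug_r[drug_r$primaryid %in% demo_f$primaryid,
                  c("primaryid", "ingredient", "atc"), drop = FALSE]
  dr_in <- dr_in[!duplicated(paste(dr_in$primaryid, dr_in$ingredient)), ]
  re_in <- reac_p[reac_p$primaryid %in% demo_f$primaryid,
                  c("primaryid", "pt", "focus_hlgt"), drop = FALSE]
  re_in <- re_in[!duplicated(paste(re_in$primaryid, re_in$pt)), ]
  pairs <- merge(dr_in, re_in, by = "primaryid", sort = FALSE)
  ci <- match(pairs$primaryid, case_tab$primaryid)
  pairs$sex <- case_tab$sex[ci]
  pairs$age_group <- as.character(case_tab$age_group)[ci]
  pairs$serious <- case_tab$serious[ci]
  pairs$death <- case_tab$death[ci]
  pairs$life_threat <- case_tab$life_threat[ci]
  pairs <- pairs[order(pairs$primaryid, pairs$ingredient, pairs$pt), ]
  rownames(pairs) <- NULL

  structure(list(
    cases = case_tab,
    pairs = pairs,
    attrition = c(assembled = n0,
                  age_included = nrow(demo_a),
                  ps_respiratory = nrow(demo_rd),
                  psychiatric_pt = nrow(demo_f)),
    unmapped = c(drug = n_unmapped_drug, pt = n_unmapped_pt)
  ), class = "pv_cohort")
}

#' @export
print.pv_cohort <- function(x, ...) {
  cat("Cohort:", nrow(x$cases), "included cases,",
      nrow(x$pairs), "drug-event pairs\n")
  at <- x$attrition
  cat("  attrition:", paste(names(at), at, sep = "=", collapse = " > "),
      "\n")
  invisible(x)
}
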