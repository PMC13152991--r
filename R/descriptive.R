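#' Frequency table with half-up percentages
#'
#' Counts occurrences of each category and expresses them as percentages of
#' a stated denominator, rounded half-up to two decimals — the arithmetic
#' used in published report-characteristic tables. For single-choice
#' variables the counts sum to the denominator; multi-select variables
#' (e.g. outcome codes) may exceed it.
#'
#' @param x character or factor vector of category labels (NA allowed; NAs
#'   are reported as `"Not specified"` unless `drop_na`).
#' @param denom denominator for percentages (default `length(x)`).
#' @param kind denominator description, e.g. `"patients"`, `"pairs"`,
#'   `"drug-specific reports"`.
#' @param sort_desc order rows by descending count (default TRUE; factors
#'   keep their level order when FALSE).
#' @param drop_na drop missing values instead of labelling them.
#' @return data.frame `category`, `count`, `pct` with attributes
#'   `denominator` and `denominator_kind`.
#' @export
freq_table <- function(x, denom = length(x), kind = "patients",
                       sort_desc = TRUE, drop_na = FALSE) {
  if (drop_na) x <- x[!is.na(x)]
  if (is.factor(x)) {
    lab <- as.character(x)
    lab[is.na(lab)] <- "Not specified"
    lv <- c(levels(x), if (anyNA(x)) "Not specified")
    cnt <- table(factor(lab, levels = lv))
  } else {
    lab <- as.character(x)
    lab[is.na(lab)] <- "Not specified"
    cnt <- table(lab)
  }
  out <- data.frame(category = names(cnt), count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  if (sort_desc) out <- out[order(-out$count, out$category), , drop = FALSE]
  out$pct <- pct_of(out$count, denom)
  rownames(out) <- NULL
  attr(out, "denominator") <- denom
  attr(out, "denominator_kind") <- kind
  out
}

# Reporting-year periods used in the summary.
year_period <- function(year) {
  cut(year, breaks = c(2004, 2009, 2014, 2019, 2025), right = FALSE,
      labels = c("2004-2008", "2009-2013", "2014-2018", "2019-2024"))
}

#' Descriptive summary of the included cohort
#'
#' Builds the standard characteristics tables — sex, age group, reporter
#' occupation, reporting country, administration route, indication,
#' seriousness, outcome categories (multi-select), onset-time bins and
#' reporting-year periods — with the number of included patients as the
#' denominator, plus median/IQR of age and onset time.
#'
#' @param cohort a `pv_cohort` from [select_cases()].
#' @param quantile_type quartile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return an object of class `pv_summary`: list of [freq_table()]s plus
#'   `age_median_iqr` and `onset_median_iqr`.
#' @export
summarize_cohort <- function(cohort, quantile_type = 7) {
  cs <- cohort$cases
  n <- nrow(cs)
  if (!n) {
    return(structure(list(tables = list(), n = 0L), class = "pv_summary"))
  }
  q3 <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(median = NA, q1 = NA, q3 = NA))
    q <- stats::quantile(x, c(0.5, 0.25, 0.75), type = quantile_type,
                         names = FALSE)
    c(median = q[1], q1 = q[2], q3 = q[3])
  }
  outcome_labels <- c(DE = "Death", LT = "Life-threatening",
                      HO = "Hospitalization (initial or prolonged)",
                      DS = "Disability", CA = "Congenital anomaly",
                      RI = "Required intervention", OT = "Other")
  oc <- unlist(cs$outcome_codes, use.names = FALSE)
  tables <- list(
    sex = freq_table(cs$sex, n),
    age_group = freq_table(cs$age_group, n, sort_desc = FALSE),
    reporter = freq_table(cs$reporter, n),
    country = freq_table(cs$country, n),
    route = freq_table(cs$route, n),
    indication = freq_table(cs$indication, n),
    degree = freq_table(ifelse(cs$serious, "Serious", "Non-serious"), n),
    outcomes = freq_table(
      factor(outcome_labels[oc], levels = unname(outcome_labels)), n,
      kind = "patients (multi-select)", sort_desc = FALSE),
    onset = freq_table(bin_onset(cs$onset_days), n, sort_desc = FALSE),
    year = freq_table(year_period(cs$report_year), n, sort_desc = FALSE)
  )
  structure(list(
    tables = tables,
    n = n,
    age_median_iqr = q3(cs$age_years),
    onset_median_iqr = q3(cs$onset_days)
  ), class = "pv_summary")
}

#' @export
print.pv_summary <- function(x, ...) {
  cat("Cohort summary (n =", x$n, "patients)\n")
  if (!x$n) return(invisible(x))
  cat(sprintf("  age    median %.1f (IQR %.1f-%.1f) years\n",
              x$age_median_iqr[1], x$age_median_iqr[2],
              x$age_median_iqr[3]))
  if (!is.na(x$onset_median_iqr[1]))
    cat(sprintf("  onset  median %.1f (IQR %.1f-%.1f) days\n",
                x$onset_median_iqr[1], x$onset_median_iqr[2],
                x$onset_median_iqr[3]))
  for (nm in names(x$tables)) {
    cat("\n--", nm, "--\n")
    print(utils::head(x$tables[[nm]], 8), row.names = FALSE)
  }
  invisible(x)
}

# Distinct reports carrying a given drug in the pair table (the published
# per-drug denominator).
drug_report_count <- function(pairs, drug) {
  length(unique(pairs$primaryid[pairs$ingredient == drug]))
}

#' Preferred-term composition of one drug's reports
#'
#' Counts the psychiatric preferred terms reported under a drug and
#' expresses each as a percentage of the drug's total report count. By
#' published convention, drugs with too few reports (default: 10 or fewer)
#' are excluded from the table.
#'
#' @param pairs the pair table of a `pv_cohort`.
#' @param drug canonical ingredient name.
#' @param min_reports exclude the drug entirely when its total report count
#'   does not exceed this (default 10); set to 0 to always report.
#' @return a [freq_table()] over preferred terms (empty for unknown or
#'   under-threshold drugs).
#' @export
drug_pt_composition <- function(pairs, drug, min_reports = 10) {
  sub <- pairs[pairs$ingredient == drug, , drop = FALSE]
  total <- length(unique(sub$primaryid))
  if (total <= min_reports) {
    out <- data.frame(category = character(0), count = integer(0),
                      pct = numeric(0))
    attr(out, "denominator") <- total
    attr(out, "denominator_kind") <- "drug-specific reports"
    return(out)
  }
  freq_table(sub$pt, total, kind = "drug-specific reports")
}

#' Focus high-level-group-term rollup of one drug's reports
#'
#' Rolls each psychiatric preferred term up to the three focus high-level
#' group terms (anxiety disorders and symptoms; depressed mood disorders
#' and disturbances; suicidal and self-injurious behaviours); psychiatric
#' terms outside these groups are reported as `Other psychiatric`.
#' Percentages use the drug's total report count as denominator.
#'
#' @param pairs the pair table of a `pv_cohort`.
#' @param drug canonical ingredient name.
#' @return a [freq_table()] over the three focus groups plus
#'   `Other psychiatric`.
#' @export
drug_hlgt_composition <- function(pairs, drug) {
  sub <- pairs[pairs$ingredient == drug, , drop = FALSE]
  total <- length(unique(sub$primaryid))
  focus <- ifelse(is.na(sub$focus_hlgt), "Other psychiatric",
                  sub$focus_hlgt)
  # count each report once per group
  key <- !duplicated(paste(sub$primaryid, focus))
  lv <- c("Anxiety disorders and symptoms",
          "Depressed mood disorders and disturbances",
          "Suicidal and self-injurious behaviours",
          "Other psychiatric")
  freq_table(factor(focus[key], levels = lv), total,
             kind = "drug-specific reports", sort_desc = FALSE)
}

#' Death and life-threatening outcome rates per drug
#'
#' Among a drug's reports, the number and percentage with a death (DE)
#' outcome code and with a life-threatening (LT) code; denominators are the
#' drug's total report count.
#'
#' @param pairs the pair table of a `pv_cohort`.
#' @param drug canonical ingredient name; when NULL (default), all drugs in
#'   the pair table.
#' @return data.frame `drug`, `n_reports`, `death_n`, `death_pct`,
#'   `life_threat_n`, `life_threat_pct`.
#' @export
serious_outcome_rates <- function(pairs, drug = NULL) {
  drugs <- if (is.null(drug)) sort(unique(pairs$ingredient)) else drug
  rows <- lapply(drugs, function(dg) {
    sub <- pairs[pairs$ingredient == dg, , drop = FALSE]
    sub <- sub[!duplicated(sub$primaryid), , drop = FALSE]
    n <- nrow(sub)
    de <- sum(sub$death)
    lt <- sum(sub$life_threat)
    data.frame(drug = dg, n_reports = n,
               death_n = de, death_pct = pct_of(de, n),
               life_threat_n = lt, life_threat_pct = pct_of(lt, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
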