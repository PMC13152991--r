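# Build the report-level inputs for disproportionality fitting from
# assembled cases: the pediatric background demo rows, primary-suspect drug
# exposures (canonical ingredient where the dictionary maps the name), and
# events at the requested rollup level.
signal_inputs <- function(cases, vocab, level = c("pt", "hlgt", "soc"),
                          age_min = 0, age_max = 18) {
  level <- match.arg(level)
  demo <- cases$demo
  age <- normalize_age(demo$age, demo$age_cod)
  keep <- !is.na(age) & age >= age_min & age < age_max
  demo <- demo[keep, , drop = FALSE]
  demo$age_years <- age[keep]
  demo$age_group <- as.character(age_group_of(demo$age_years))
  demo$sex_k <- ifelse(demo$sex %in% c("F", "M"), demo$sex, NA_character_)

  drug <- cases$drug[cases$drug$role_cod == "PS" &
                       cases$drug$primaryid %in% demo$primaryid, ,
                     drop = FALSE]
  dm <- is_respiratory(drug$drugname, vocab)
  exposure <- data.frame(
    primaryid = drug$primaryid,
    drug = ifelse(dm$mapped, dm$ingredient,
                  normalize_drug_name(drug$drugname)),
    respiratory = dm$respiratory %in% TRUE,
    stringsAsFactors = FALSE
  )

  reac <- cases$reac[cases$reac$primaryid %in% demo$primaryid, ,
                     drop = FALSE]
  cls <- classify_pt(reac$pt, vocab)
  event <- switch(level,
    pt = reac$pt,
    hlgt = ifelse(cls$mapped, cls$hlgt_name, "Unmapped"),
    soc = ifelse(cls$mapped, cls$soc_name, "Unmapped"))
  events <- data.frame(primaryid = reac$primaryid, event = event,
                       stringsAsFactors = FALSE)
  list(demo = demo, exposure = exposure, events = events,
       n_total = nrow(demo), level = level)
}

#' Stratified disproportionality analysis
#'
#' Recomputes the four disproportionality statistics within age-group or
#' sex strata. The comparator of each stratum is restricted to reports in
#' that stratum (same-stratum non-cases), so a stratum's contingency table
#' is fully self-contained; the same composite rule applies. Drugs with
#' fewer reports than the minimum in a stratum are emitted with suppressed
#' flags; drugs with no reports in a stratum are absent, and empty strata
#' yield no rows.
#'
#' @param cases a `pv_cases` object (deduplicated, deletion-filtered).
#' @param vocab a [pv_vocab()] bundle.
#' @param axis `"age_group"` (levels 0-4, 5-11, 12-17) or `"sex"` (F, M;
#'   unknown-sex reports are excluded from sex strata).
#' @param level event rollup: `"soc"` (default, drug-level signals against
#'   the psychiatric SOC), `"hlgt"` or `"pt"`.
#' @param event event label to keep (default the psychiatric SOC); NULL
#'   keeps every event.
#' @param respiratory_only keep respiratory drugs only (default TRUE).
#' @param age_min,age_max background age bounds in years.
#' @param min_reports,bcpnn_variant passed to [disprop()].
#' @return data.frame: one row per (drug, event, stratum) with the full
#'   signal-table columns plus `axis` and `stratum`.
#' @export
stratified_signals <- function(cases, vocab, axis = c("age_group", "sex"),
                               level = "soc",
                               event = "Psychiatric disorders",
                               respiratory_only = TRUE,
                               age_min = 0, age_max = 18,
                               min_reports = 3, bcpnn_variant = "noren") {
  axis <- match.arg(axis)
  si <- signal_inputs(cases, vocab, level, age_min, age_max)
  strata <- if (axis == "age_group") c("0-4", "5-11", "12-17")
            else c("F", "M")
  key <- if (axis == "age_group") si$demo$age_group else si$demo$sex_k

  out <- list()
  for (s in strata) {
    ids <- si$demo$primaryid[!is.na(key) & key == s]
    if (!length(ids)) next
    ex <- si$exposure[si$exposure$primaryid %in% ids, , drop = FALSE]
    ev <- si$events[si$events$primaryid %in% ids, , drop = FALSE]
    fit <- disprop(ex[, c("primaryid", "drug")], ev, length(ids),
                   min_reports = min_reports,
                   bcpnn_variant = bcpnn_variant)
    t <- fit$table
    if (respiratory_only) {
      resp <- unique(ex$drug[ex$respiratory])
      t <- t[t$drug %in% resp, , drop = FALSE]
    }
    if (!is.null(event)) t <- t[t$event %in% event, , drop = FALSE]
    if (!nrow(t)) next
    t$axis <- axis
    t$stratum <- s
    out[[s]] <- t
  }
  res <- if (length(out)) do.call(rbind, out) else {
    cbind(dispro_stats(integer(0), integer(0), integer(0), integer(0)),
          drug = character(0), event = character(0),
          axis = character(0), stratum = character(0))
  }
  rownames(res) <- NULL
  res
}

#' Export signal tables in forest-plot-ready form
#'
#' One row per (drug, event, stratum) with the reporting-odds-ratio point
#' estimate and confidence bounds, ordered by drug then stratum; strata
#' without a row stay absent rather than being filled with NA.
#'
#' @param signals a data.frame from [stratified_signals()], or a list of
#'   them (e.g. the age and sex axes together).
#' @param path optional CSV output path.
#' @return the export data.frame, invisibly when `path` is given.
#' @export
forest_export <- function(signals, path = NULL) {
  if (is.data.frame(signals)) signals <- list(signals)
  tab <- do.call(rbind, signals)
  cols <- c("drug", "event", "axis", "stratum", "a", "ror", "ror_lo",
            "ror_hi", "composite")
  out <- tab[, cols, drop = FALSE]
  names(out)[names(out) == "ror"] <- "estimate"
  names(out)[names(out) == "ror_lo"] <- "lo"
  names(out)[names(out) == "ror_hi"] <- "hi"
  out <- out[order(out$drug, out$axis, out$stratum), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
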