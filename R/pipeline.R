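#' Run configuration
#'
#' Collects the tunable settings of the pipeline. The defaults reproduce
#' the study design this pipeline implements: pediatric ages `[0, 18)`
#' years, the psychiatric-disorders SOC with its three focus high-level
#' group terms, a pediatric-only comparator background, the closed-form
#' BCPNN variant, a minimum of three reports for any signal flag, and a
#' more-than-ten-reports threshold for per-drug composition tables.
#'
#' @param age_min,age_max cohort age bounds in years.
#' @param background `"pediatric"` (comparator = deduplicated reports
#'   within the age bounds) or `"all"` (every deduplicated report).
#' @param bcpnn_variant `"noren"` or `"bate"`.
#' @param min_reports minimum a-cell count for signal flags.
#' @param pt_table_min per-drug composition tables require strictly more
#'   reports than this.
#' @param quantile_type quartile convention for median/IQR summaries.
#' @param seed seed used by the `simulate` stage.
#' @return a named list of class `pv_config`.
#' @export
pv_config <- function(age_min = 0, age_max = 18,
                      background = c("pediatric", "all"),
                      bcpnn_variant = c("noren", "bate"),
                      min_reports = 3, pt_table_min = 10,
                      quantile_type = 7, seed = 1L) {
  structure(list(
    age_min = age_min, age_max = age_max,
    background = match.arg(background),
    bcpnn_variant = match.arg(bcpnn_variant),
    min_reports = min_reports, pt_table_min = pt_table_min,
    quantile_type = quantile_type, seed = as.integer(seed),
    soc_code = PSYCHIATRIC_SOC_CODE,
    focus_hlgt_codes = unname(FOCUS_HLGT_CODES)
  ), class = "pv_config")
}

#' Signal table at one event rollup level
#'
#' Fits the disproportionality estimator over the configured background
#' and returns the rows of interest: respiratory drugs crossed with
#' psychiatric events — the psychiatric SOC at `level = "soc"`, the three
#' focus high-level group terms at `"hlgt"`, or the psychiatric preferred
#' terms at `"pt"`.
#'
#' @param cases a `pv_cases` object (deduplicated, deletion-filtered).
#' @param vocab a [pv_vocab()] bundle.
#' @param level `"pt"`, `"hlgt"` or `"soc"`.
#' @param config a [pv_config()].
#' @return the signal table: one row per pair, ordered by descending
#'   report count, with cells, statistics, flags and composite decision.
#' @export
pv_signals <- function(cases, vocab, level = c("pt", "hlgt", "soc"),
                       config = pv_config()) {
  level <- match.arg(level)
  fit_level(cases, vocab, level, config)$table
}

# Fit disproportionality at one rollup level and keep the rows of
# interest: respiratory drugs crossed with psychiatric events.
fit_level <- function(cases, vocab, level, config) {
  bg_min <- if (config$background == "pediatric") config$age_min else 0
  bg_max <- if (config$background == "pediatric") config$age_max else Inf
  si <- signal_inputs(cases, vocab, level, bg_min, bg_max)
  fit <- disprop(si$exposure[, c("primaryid", "drug")], si$events,
                 si$n_total, min_reports = config$min_reports,
                 bcpnn_variant = config$bcpnn_variant)
  t <- fit$table
  resp <- unique(si$exposure$drug[si$exposure$respiratory])
  t <- t[t$drug %in% resp, , drop = FALSE]
  keep_ev <- switch(level,
    soc = "Psychiatric disorders",
    hlgt = unique(vocab$meddra$hlgt_name[vocab$meddra$hlgt_code %in%
                                           config$focus_hlgt_codes]),
    pt = unique(vocab$meddra$pt_name[vocab$meddra$soc_code ==
                                       config$soc_code]))
  t <- t[t$event %in% keep_ev, , drop = FALSE]
  t <- cbind(level = level, t)
  t <- t[order(-t$a), , drop = FALSE]
  rownames(t) <- NULL
  list(fit = fit, table = t, n_total = si$n_total)
}

#' Run the full pharmacovigilance pipeline on a bundle
#'
#' Orchestrates every stage: read the quarterly-style bundle, deduplicate
#' case versions, remove deleted cases, assemble per-case records, apply
#' the pediatric/respiratory-drug/psychiatric-event inclusion criteria,
#' and compute the descriptive summary, per-drug compositions,
#' disproportionality signal tables at SOC, HLGT and PT level, and
#' age/sex-stratified signals. An attrition record counts reports after
#' every filter step.
#'
#' @param bundle a bundle directory or [generate_bundle()] manifest.
#' @param vocab a [pv_vocab()] bundle; by default read from the `vocab/`
#'   subdirectory of the bundle.
#' @param config a [pv_config()].
#' @param out_dir optional directory; when given, every table is written
#'   as CSV along with the attrition record and the resolved
#'   configuration.
#' @return an object of class `pv_run`: list with `cohort`, `summary`,
#'   `signals` (SOC/HLGT/PT tables), `stratified`, `outcome_rates`,
#'   `attrition`, and the resolved `config`.
#' @export
pv_run <- function(bundle, vocab = NULL, config = pv_config(),
                   out_dir = NULL) {
  raw <- read_bundle(bundle)
  if (is.null(vocab)) {
    vdir <- if (is.character(bundle)) file.path(bundle, "vocab")
            else file.path(dirname(bundle$files$demo), "vocab")
    vocab <- read_vocab(vdir)
  }

  demo_d <- deduplicate(raw$demo)
  demo_f <- remove_deleted(demo_d, raw$deleted_ids)
  cases <- assemble_cases(demo_f, raw)
  cohort <- select_cases(cases, vocab, config$age_min, config$age_max)

  attrition <- c(
    raw_report_versions = nrow(raw$demo),
    deduplicated = nrow(demo_d),
    deletion_filtered = nrow(demo_f),
    age_included = unname(cohort$attrition["age_included"]),
    ps_respiratory = unname(cohort$attrition["ps_respiratory"]),
    psychiatric_pt = unname(cohort$attrition["psychiatric_pt"])
  )

  summ <- summarize_cohort(cohort, quantile_type = config$quantile_type)

  sig_soc <- fit_level(cases, vocab, "soc", config)
  sig_hlgt <- fit_level(cases, vocab, "hlgt", config)
  sig_pt <- fit_level(cases, vocab, "pt", config)

  strat_age <- stratified_signals(
    cases, vocab, "age_group", level = "soc",
    age_min = config$age_min, age_max = config$age_max,
    min_reports = config$min_reports,
    bcpnn_variant = config$bcpnn_variant)
  strat_sex <- stratified_signals(
    cases, vocab, "sex", level = "soc",
    age_min = config$age_min, age_max = config$age_max,
    min_reports = config$min_reports,
    bcpnn_variant = config$bcpnn_variant)

  rates <- serious_outcome_rates(cohort$pairs)

  run <- structure(list(
    cohort = cohort, summary = summ,
    signals = list(soc = sig_soc$table, hlgt = sig_hlgt$table,
                   pt = sig_pt$table),
    fits = list(soc = sig_soc$fit, hlgt = sig_hlgt$fit, pt = sig_pt$fit),
    stratified = rbind(strat_age, strat_sex),
    outcome_rates = rates,
    attrition = attrition,
    malformed = raw$malformed,
    config = config
  ), class = "pv_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

SIGNAL_COLS <- c("level", "drug", "event", "a", "b", "c", "d",
                 "ror", "ror_lo", "ror_hi", "prr", "prr_lo", "prr_hi",
                 "chi2", "ic", "ic025", "ror_pos", "prr_pos", "mhra_pos",
                 "bcpnn_pos", "composite", "corrected")

#' Write the artifacts of a pipeline run
#'
#' Emits one CSV per table (cohort cases and pairs, descriptive frequency
#' tables, signal tables at each level, stratified signals, outcome
#' rates), the attrition record, and the resolved configuration as YAML.
#'
#' @param run a `pv_run` object.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the vector of written paths.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  paths <- character(0)
  cases_flat <- run$cohort$cases
  cases_flat$outcome_codes <- vapply(cases_flat$outcome_codes, paste,
                                     character(1), collapse = ";")
  paths <- c(paths, w(cases_flat, "cohort_cases"))
  paths <- c(paths, w(run$cohort$pairs, "cohort_pairs"))
  for (nm in names(run$summary$tables))
    paths <- c(paths, w(run$summary$tables[[nm]],
                        paste0("descriptive_", nm)))
  for (nm in names(run$signals)) {
    t <- run$signals[[nm]]
    paths <- c(paths, w(t[, intersect(SIGNAL_COLS, names(t))],
                        paste0("signals_", nm)))
  }
  paths <- c(paths, w(run$stratified, "signals_stratified"))
  paths <- c(paths, w(forest_export(run$stratified), "forest_stratified"))
  paths <- c(paths, w(run$outcome_rates, "outcome_rates"))
  paths <- c(paths, w(data.frame(step = names(run$attrition),
                                 n = unname(run$attrition)), "attrition"))
  cfg <- unclass(run$config)
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yaml"))
  invisible(c(paths, file.path(out_dir, "config_resolved.yaml")))
}

#' @export
print.pv_run <- function(x, ...) {
  cat("Pharmacovigilance pipeline run\n")
  cat("  attrition:",
      paste(names(x$attrition), x$attrition, sep = "=", collapse = " > "),
      "\n")
  cat("  included patients:", nrow(x$cohort$cases),
      " drug-event pairs:", nrow(x$cohort$pairs), "\n")
  cat("  composite drug-level signals:",
      sum(x$signals$soc$composite), "\n")
  invisible(x)
}
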