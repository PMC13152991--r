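# Expected header fields for each bundle table. Only the columns the
# pipeline consumes are required; files are "$"-delimited with a header
# line, as in FAERS quarterly ASCII distributions.
BUNDLE_SCHEMAS <- list(
  demo = c("primaryid", "caseid", "fda_dt", "age", "age_cod", "sex",
           "occp_cod", "reporter_country", "event_dt"),
  drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname",
           "route"),
  reac = c("primaryid", "caseid", "pt"),
  outc = c("primaryid", "caseid", "outc_cod"),
  ther = c("primaryid", "caseid", "dsg_drug_seq", "start_dt"),
  indi = c("primaryid", "caseid", "indi_drug_seq", "indi_pt")
)

read_dollar_table <- function(path, table) {
  if (!file.exists(path)) stop("missing bundle file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("unparseable header in ", path, ": empty file")
  hdr <- tolower(strsplit(lines[1], "$", fixed = TRUE)[[1]])
  want <- BUNDLE_SCHEMAS[[table]]
  if (!all(want %in% hdr))
    stop("unparseable header in ", path, ": need fields ",
         paste(setdiff(want, hdr), collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(body)]
  sp <- split_dollar(body, length(hdr))
  df <- as.data.frame(sp$fields, stringsAsFactors = FALSE)
  names(df) <- hdr
  df <- df[, want, drop = FALSE]
  attr(df, "n_malformed") <- length(sp$malformed)
  attr(df, "quarantine") <- body[sp$malformed]
  df
}

#' Read a FAERS-style quarterly bundle
#'
#' Reads the six "$"-delimited tables (DEMO, DRUG, REAC, OUTC, THER, INDI)
#' and any deleted-case-id lists into typed collections. THER start dates
#' and INDI indications are joined onto the drug rows by report id and drug
#' sequence. Malformed lines (wrong field count) are counted per table and
#' reported in the result, never silently dropped.
#'
#' @param x either a bundle directory containing `demo.txt`, `drug.txt`,
#'   `reac.txt`, `outc.txt`, `ther.txt`, `indi.txt` and optional
#'   `deleted*.txt`, or a manifest list (as returned by
#'   [generate_bundle()]) with `files` paths.
#' @return an object of class `pv_bundle`: list with data.frames `demo`,
#'   `drug`, `reac`, `outc`, the `deleted_ids` character vector, a
#'   `malformed` named count vector, and `quarantine`, the verbatim
#'   malformed lines per table (for audit side files).
#' @export
read_bundle <- function(x) {
  if (is.character(x) && length(x) == 1 && dir.exists(x)) {
    paths <- file.path(x, paste0(names(BUNDLE_SCHEMAS), ".txt"))
    names(paths) <- names(BUNDLE_SCHEMAS)
    del_paths <- list.files(x, pattern = "^deleted.*\\.txt$",
                            full.names = TRUE)
  } else if (is.list(x) && !is.null(x$files)) {
    paths <- unlist(x$files)
    del_paths <- paths[names(paths) == "deleted"]
    paths <- paths[names(paths) != "deleted"]
  } else {
    stop("x must be a bundle directory or a manifest list")
  }

  tabs <- lapply(names(BUNDLE_SCHEMAS), function(tb)
    read_dollar_table(paths[[tb]], tb))
  names(tabs) <- names(BUNDLE_SCHEMAS)
  malformed <- vapply(tabs, function(t) attr(t, "n_malformed") %||% 0L,
                      integer(1))

  # join therapy start date and indication onto drug rows by
  # (primaryid, drug_seq)
  drug <- tabs$drug
  key <- paste(drug$primaryid, drug$drug_seq)
  th <- tabs$ther
  drug$start_dt <- th$start_dt[match(key, paste(th$primaryid,
                                                th$dsg_drug_seq))]
  ind <- tabs$indi
  drug$indication <- ind$indi_pt[match(key, paste(ind$primaryid,
                                                  ind$indi_drug_seq))]
  drug$start_dt[is.na(drug$start_dt)] <- ""
  drug$indication[is.na(drug$indication)] <- ""

  deleted <- character(0)
  for (p in del_paths) {
    dl <- readLines(p, warn = FALSE)
    deleted <- c(deleted, trimws(dl[nzchar(trimws(dl))]))
  }

  quarantine <- lapply(tabs, function(t) attr(t, "quarantine") %||%
                         character(0))
  structure(list(
    demo = tabs$demo, drug = drug, reac = tabs$reac, outc = tabs$outc,
    deleted_ids = unique(deleted), malformed = malformed,
    quarantine = quarantine
  ), class = "pv_bundle")
}

#' @export
print.pv_bundle <- function(x, ...) {
  cat("FAERS-style bundle:\n")
  cat(sprintf("  %-6s %8d rows\n", c("DEMO", "DRUG", "REAC", "OUTC"),
              c(nrow(x$demo), nrow(x$drug), nrow(x$reac), nrow(x$outc))),
      sep = "")
  cat("  deleted ids:", length(x$deleted_ids), "\n")
  if (any(x$malformed > 0))
    cat("  malformed lines:",
        paste(names(x$malformed)[x$malformed > 0],
              x$malformed[x$malformed > 0], collapse = ", "), "\n")
  invisible(x)
}

#' Deduplicate report versions to one row per case
#'
#' FAERS distributes every revision of a case as a separate report version.
#' Rows are sorted by case id, receipt date (`fda_dt`) and primary id, and
#' the last version per case is retained: the most recent receipt date wins,
#' with receipt-date ties broken by the highest primary id. Primary ids are
#' compared numerically when all parse as numbers, lexicographically
#' otherwise. Output rows are ordered by case id; the number of versions
#' removed is recorded in attribute `n_removed`.
#'
#' @param demo data.frame of demographic rows with columns `caseid`,
#'   `fda_dt`, `primaryid`.
#' @return the deduplicated data.frame (one row per `caseid`).
#' @export
deduplicate <- function(demo) {
  if (!nrow(demo)) {
    attr(demo, "n_removed") <- 0L
    return(demo)
  }
  o <- order(demo$caseid, demo$fda_dt, primaryid_order_key(demo$primaryid))
  sorted <- demo[o, , drop = FALSE]
  keep <- !duplicated(sorted$caseid, fromLast = TRUE)
  out <- sorted[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- nrow(demo) - nrow(out)
  out
}

#' Remove reports whose case id is on a deleted list
#'
#' Quarterly packages ship lists of case ids withdrawn from the system;
#' these are applied after deduplication, so a deleted case disappears
#' entirely. Deleted ids not present in the data are counted but harmless.
#'
#' @param demo deduplicated demographic rows.
#' @param deleted_ids character vector of case ids to drop.
#' @return filtered data.frame; attributes `n_deleted` (rows removed) and
#'   `n_unmatched` (listed ids not present).
#' @export
remove_deleted <- function(demo, deleted_ids) {
  deleted_ids <- unique(as.character(deleted_ids))
  hit <- demo$caseid %in% deleted_ids
  out <- demo[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_deleted") <- sum(hit)
  attr(out, "n_unmatched") <- sum(!(deleted_ids %in% demo$caseid))
  out
}

#' Assemble per-case records from the bundle tables
#'
#' Joins drug, reaction and outcome rows onto the surviving (deduplicated,
#' deletion-filtered) demographic rows by primary id. Rows in DRUG/REAC/OUTC
#' belonging to removed report versions are dropped and counted as orphans.
#'
#' @param demo deduplicated, deletion-filtered demographic rows.
#' @param bundle a `pv_bundle` (supplies drug/reac/outc tables).
#' @return an object of class `pv_cases`: list with `demo` and the filtered
#'   `drug`, `reac`, `outc` tables plus orphan counts.
#' @export
assemble_cases <- function(demo, bundle) {
  keep <- demo$primaryid
  f <- function(tab) {
    hit <- tab$primaryid %in% keep
    out <- tab[hit, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_orphan") <- sum(!hit)
    out
  }
  drug <- f(bundle$drug)
  reac <- f(bundle$reac)
  outc <- f(bundle$outc)
  structure(list(
    demo = demo, drug = drug, reac = reac, outc = outc,
    orphans = c(drug = attr(drug, "n_orphan"),
                reac = attr(reac, "n_orphan"),
                outc = attr(outc, "n_orphan"))
  ), class = "pv_cases")
}

#' @export
print.pv_cases <- function(x, ...) {
  cat("Assembled cases:", nrow(x$demo), "reports;",
      nrow(x$drug), "drug rows;", nrow(x$reac), "reaction rows;",
      nrow(x$outc), "outcome rows\n")
  invisible(x)
}
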