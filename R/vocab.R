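# MedDRA-style codes for the psychiatric focus of the pipeline. The SOC and
# the three focus high-level group terms (anxiety; depressed mood; suicidal
# and self-injurious behaviour) are addressed by code so that a user-supplied
# hierarchy with different labels still classifies correctly.
PSYCHIATRIC_SOC_CODE <- 10037175L
FOCUS_HLGT_CODES <- c(
  anxiety    = 10002861L,
  depression = 10012375L,
  suicidal   = 10042460L
)

#' Assemble a vocabulary bundle
#'
#' Bundles a drug dictionary (verbatim name to canonical ingredient and WHO
#' ATC code) with a MedDRA-style hierarchy (preferred term to HLT, HLGT and
#' SOC along a single primary path). MedDRA itself is licensed and is never
#' bundled: callers supply their own tables, or use the mock vocabulary
#' produced by [generate_vocab()] for synthetic data.
#'
#' @param drug_dict data.frame with columns `name`, `ingredient`, `atc`.
#' @param meddra data.frame with columns `pt_code`, `pt_name`, `hlt`,
#'   `hlgt_code`, `hlgt_name`, `soc_code`, `soc_name`.
#' @return an object of class `pv_vocab`.
#' @export
pv_vocab <- function(drug_dict, meddra) {
  need_d <- c("name", "ingredient", "atc")
  need_m <- c("pt_code", "pt_name", "hlt", "hlgt_code", "hlgt_name",
              "soc_code", "soc_name")
  if (!all(need_d %in% names(drug_dict)))
    stop("drug_dict must have columns: ", paste(need_d, collapse = ", "))
  if (!all(need_m %in% names(meddra)))
    stop("meddra must have columns: ", paste(need_m, collapse = ", "))
  drug_dict$name <- normalize_drug_name(drug_dict$name)
  if (anyDuplicated(drug_dict$name))
    stop("duplicate drug names after normalization")
  # single-parent property: each PT reaches exactly one SOC
  if (anyDuplicated(meddra$pt_name))
    stop("each preferred term must appear exactly once in the hierarchy")
  # acyclicity across levels: a label may not recur at a different level
  lv <- list(pt = unique(meddra$pt_name), hlt = unique(meddra$hlt),
             hlgt = unique(meddra$hlgt_name), soc = unique(meddra$soc_name))
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (i < j && length(intersect(lv[[i]], lv[[j]])))
      stop("hierarchy label reused across levels: ",
           paste(intersect(lv[[i]], lv[[j]]), collapse = ", "))
  }
  structure(list(drug_dict = drug_dict, meddra = meddra),
            class = "pv_vocab")
}

#' @export
print.pv_vocab <- function(x, ...) {
  cat("Vocabulary bundle:\n")
  cat("  drug dictionary:", nrow(x$drug_dict), "entries (",
      sum(startsWith(x$drug_dict$atc, "R")), "respiratory )\n")
  cat("  hierarchy:      ", nrow(x$meddra), "preferred terms,",
      length(unique(x$meddra$soc_name)), "SOCs\n")
  invisible(x)
}

#' Classify a drug name as respiratory or not
#'
#' A drug is respiratory when its mapped ATC code begins with "R"
#' (respiratory system: nasal and throat preparations, drugs for obstructive
#' airway disease, cough and cold preparations, systemic antihistamines, and
#' other respiratory products). Combination products are respiratory if any
#' component ATC code begins with "R"; component codes are separated by "/"
#' in the dictionary. Names absent from the dictionary return an explicit
#' unmapped status, never a silent FALSE.
#'
#' @param drugname character vector of verbatim drug names.
#' @param vocab a [pv_vocab()] bundle.
#' @return data.frame with columns `drugname`, `ingredient`, `atc`,
#'   `respiratory` (logical, NA when unmapped) and `mapped` (logical).
#' @export
is_respiratory <- function(drugname, vocab) {
  key <- normalize_drug_name(drugname)
  i <- match(key, vocab$drug_dict$name)
  atc <- vocab$drug_dict$atc[i]
  resp <- vapply(atc, function(code) {
    if (is.na(code)) return(NA)
    any(startsWith(strsplit(code, "/", fixed = TRUE)[[1]], "R"))
  }, logical(1), USE.NAMES = FALSE)
  data.frame(
    drugname = as.character(drugname),
    ingredient = vocab$drug_dict$ingredient[i],
    atc = atc,
    respiratory = resp,
    mapped = !is.na(i),
    stringsAsFactors = FALSE
  )
}

#' Classify a preferred term within the hierarchy
#'
#' Returns, per PT, its SOC and — when it lies under one of the three focus
#' psychiatric high-level group terms — that HLGT label; PTs under the
#' psychiatric SOC but outside the focus groups get `focus_hlgt = NA` with
#' `psychiatric = TRUE`. Unknown PTs are flagged unmapped and counted by the
#' caller, never dropped silently.
#'
#' @param pt_name character vector of preferred-term names.
#' @param vocab a [pv_vocab()] bundle.
#' @return data.frame with columns `pt_name`, `soc_code`, `soc_name`,
#'   `hlgt_code`, `hlgt_name`, `psychiatric`, `focus_hlgt`, `mapped`.
#' @export
classify_pt <- function(pt_name, vocab) {
  m <- vocab$meddra
  i <- match(as.character(pt_name), m$pt_name)
  psy <- m$soc_code[i] == PSYCHIATRIC_SOC_CODE
  focus <- ifelse(!is.na(i) & m$hlgt_code[i] %in% FOCUS_HLGT_CODES,
                  m$hlgt_name[i], NA_character_)
  data.frame(
    pt_name = as.character(pt_name),
    soc_code = m$soc_code[i],
    soc_name = m$soc_name[i],
    hlgt_code = m$hlgt_code[i],
    hlgt_name = m$hlgt_name[i],
    psychiatric = psy,
    focus_hlgt = focus,
    mapped = !is.na(i),
    stringsAsFactors = FALSE
  )
}

#' Write a vocabulary bundle to tab-delimited files
#'
#' @param vocab a [pv_vocab()] bundle.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths (`drug_dict.tsv`, `meddra.tsv`).
#' @export
write_vocab <- function(vocab, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dd <- file.path(dir, "drug_dict.tsv")
  md <- file.path(dir, "meddra.tsv")
  utils::write.table(vocab$drug_dict, dd, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(vocab$meddra, md, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(drug_dict = dd, meddra = md))
}

#' Read a vocabulary bundle from tab-delimited files
#'
#' @param dir directory containing `drug_dict.tsv` and `meddra.tsv` as
#'   written by [write_vocab()] (or supplied by the user in that layout).
#' @return a [pv_vocab()] bundle.
#' @export
read_vocab <- function(dir) {
  dd <- utils::read.delim(file.path(dir, "drug_dict.tsv"),
                          colClasses = "character")
  md <- utils::read.delim(file.path(dir, "meddra.tsv"), colClasses = c(
    pt_code = "integer", hlgt_code = "integer", soc_code = "integer"))
  pv_vocab(dd, md)
}
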