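#' Normalize a drug name for dictionary lookup
#'
#' Case-folds, trims leading/trailing whitespace, and collapses internal
#' whitespace runs to a single space. Dictionary matching is exact after
#' this normalization; no fuzzy matching is attempted.
#'
#' @param x character vector of verbatim drug names.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_drug_name("  Montelukast   SODIUM ")
normalize_drug_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Round half-up to a fixed number of decimals
#'
#' Commercial rounding: ties go away from zero (for the non-negative
#' quantities used here, upward). This is the convention that reproduces
#' published count/percentage tables, unlike [base::round()]'s
#' round-half-even. A small epsilon guards against binary floating-point
#' representations of exact halves.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(49.225, 2)  # 49.23, where round() would give 49.22
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage of a denominator, rounded half-up to two decimals
#'
#' @param count numeric numerator(s).
#' @param denom single numeric denominator.
#' @param digits decimal places (default 2, matching published tables).
#' @return numeric vector of percentages.
#' @export
#' @examples
#' pct_of(3443, 6994)  # 49.23
pct_of <- function(count, denom, digits = 2) {
  if (denom <= 0) return(rep(NA_real_, length(count)))
  round_half_up(100 * count / denom, digits)
}

# Parse YYYYMMDD-style integers that may be truncated to YYYYMM or YYYY.
# Returns a Date for fully-resolved values, NA otherwise. Never errors on
# malformed input; callers count the NAs.
parse_full_date <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  full <- !is.na(x) & grepl("^[0-9]{8}$", x)
  if (any(full)) {
    d <- as.Date(x[full], format = "%Y%m%d")
    out[full] <- d
  }
  out
}

# TRUE where a date string resolves to a full valid YYYYMMDD date.
is_full_date <- function(x) !is.na(parse_full_date(x))

# Extract the 4-digit year from a possibly partial YYYY/YYYYMM/YYYYMMDD
# value; NA where absent or unparseable.
date_year <- function(x) {
  x <- trimws(as.character(x))
  y <- rep(NA_integer_, length(x))
  ok <- !is.na(x) & grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", x)
  y[ok] <- as.integer(substr(x[ok], 1, 4))
  y
}

# Split "$"-delimited lines, tolerating ragged rows. Returns a list with
# a character matrix of conforming rows and the indices of malformed ones.
split_dollar <- function(lines, nfields) {
  parts <- strsplit(lines, "$", fixed = TRUE)
  # trailing empty field is dropped by strsplit; pad rows one short whose
  # line ends in the delimiter
  len <- lengths(parts)
  ends <- endsWith(lines, "$")
  pad <- which(len == nfields - 1L & ends)
  if (length(pad)) {
    parts[pad] <- lapply(parts[pad], function(p) c(p, ""))
    len[pad] <- nfields
  }
  ok <- len == nfields
  mat <- if (any(ok)) {
    matrix(unlist(parts[ok], use.names = FALSE), ncol = nfields, byrow = TRUE)
  } else {
    matrix(character(0), ncol = nfields)
  }
  list(fields = mat, malformed = which(!ok))
}

# Numeric-aware comparison key for report identifiers: FAERS primaryids are
# numeric but stored as strings. When every id parses as a number the
# numeric value is used for ordering; otherwise ids order lexicographically.
primaryid_order_key <- function(id) {
  num <- suppressWarnings(as.numeric(id))
  if (!anyNA(num)) num else as.character(id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
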