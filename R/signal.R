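# ---- 2x2 contingency machinery ------------------------------------------

#' Build a 2x2 contingency table for a drug-event pair
#'
#' Cell a counts reports with the target drug and target event, b the
#' target drug with other events, c other drugs with the target event, d
#' everything else. Counts are at report level against a defined background
#' of N reports.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return an object of class `contingency_2x2`.
#' @export
contingency <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cells must be non-negative integers")
  if (sum(cells) <= 0) stop("empty table")
  structure(as.list(cells), N = sum(cells), class = "contingency_2x2")
}

cells_of <- function(ct) {
  if (inherits(ct, "contingency_2x2")) unlist(ct[c("a", "b", "c", "d")])
  else stop("not a contingency_2x2")
}

#' Reporting odds ratio with Wald 95% confidence interval
#'
#' ROR = ad/bc; the interval is exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c +
#' 1/d)). When any cell is zero the Haldane-Anscombe correction (0.5 added
#' to all four cells) is applied and the result marked corrected.
#'
#' @param ct a [contingency()] table, or the `a` cell with `b`, `c`, `d`
#'   supplied as further arguments.
#' @param b,c,d remaining cells when `ct` is given as a count.
#' @return named numeric vector `est`, `lo`, `hi`, `corrected` (0/1).
#' @export
#' @examples
#' ror(contingency(10, 20, 30, 240))  # est 4.0
ror <- function(ct, b = NULL, c = NULL, d = NULL) {
  x <- if (inherits(ct, "contingency_2x2")) cells_of(ct) else c(ct, b, c, d)
  corrected <- any(x == 0)
  if (corrected) x <- x + 0.5
  est <- (x[1] * x[4]) / (x[2] * x[3])
  se <- sqrt(sum(1 / x))
  c(est = unname(est), lo = unname(est * exp(-1.96 * se)),
    hi = unname(est * exp(1.96 * se)), corrected = as.numeric(corrected))
}

#' Proportional reporting ratio with 95% confidence interval
#'
#' PRR = (a/(a+b)) / (c/(c+d)); the interval is exp(log PRR +/- 1.96
#' sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))). Zero cells trigger the same
#' continuity correction as [ror()].
#'
#' @inheritParams ror
#' @return named numeric vector `est`, `lo`, `hi`, `corrected`.
#' @export
#' @examples
#' prr(contingency(10, 90, 10, 890))  # est 9.0
prr <- function(ct, b = NULL, c = NULL, d = NULL) {
  x <- if (inherits(ct, "contingency_2x2")) cells_of(ct) else c(ct, b, c, d)
  corrected <- any(x == 0)
  if (corrected) x <- x + 0.5
  est <- (x[1] / (x[1] + x[2])) / (x[3] / (x[3] + x[4]))
  se <- sqrt(1 / x[1] - 1 / (x[1] + x[2]) + 1 / x[3] - 1 / (x[3] + x[4]))
  c(est = unname(est), lo = unname(est * exp(-1.96 * se)),
    hi = unname(est * exp(1.96 * se)), corrected = as.numeric(corrected))
}

#' Yates-corrected chi-squared statistic of a 2x2 table
#'
#' Sum over the four cells of (|O - E| - 0.5)^2 / E with expected counts
#' from the margins, clamped to zero when |O - E| < 0.5 (the correction may
#' not exceed the deviation itself). A zero margin leaves the statistic
#' undefined (NA).
#'
#' @inheritParams ror
#' @return single numeric value (NA when degenerate).
#' @export
yates_chi2 <- function(ct, b = NULL, c = NULL, d = NULL) {
  x <- if (inherits(ct, "contingency_2x2")) cells_of(ct) else c(ct, b, c, d)
  N <- sum(x)
  r1 <- x[1] + x[2]; r2 <- x[3] + x[4]
  c1 <- x[1] + x[3]; c2 <- x[2] + x[4]
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(NA_real_)
  E <- c(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / N
  dev <- abs(x - E)
  if (dev[1] < 0.5) return(0)
  unname(sum((dev - 0.5)^2 / E))
}

#' MHRA signal criterion
#'
#' The UK MHRA variation of the proportional reporting ratio: a pair
#' signals when PRR >= 2, the Yates-corrected chi-squared >= 4, and at
#' least 3 reports carry the pair.
#'
#' @inheritParams ror
#' @param min_reports minimum a-cell count (default 3).
#' @return list with `prr`, `chi2`, `pos`.
#' @export
mhra <- function(ct, b = NULL, c = NULL, d = NULL, min_reports = 3) {
  x <- if (inherits(ct, "contingency_2x2")) cells_of(ct) else c(ct, b, c, d)
  p <- prr(x[1], x[2], x[3], x[4])
  chi2 <- yates_chi2(x[1], x[2], x[3], x[4])
  pos <- !is.na(chi2) && p[["est"]] >= 2 && chi2 >= 4 && x[1] >= min_reports
  list(prr = p[["est"]], chi2 = chi2, pos = pos)
}

#' BCPNN information component
#'
#' The Bayesian confidence propagation neural network measure: a shrunk
#' log2 observed-to-expected reporting ratio. Two variants are available.
#' `"noren"` (default) uses the closed-form approximation IC =
#' log2((a + 0.5) / (E + 0.5)) with E = (a+b)(a+c)/N and lower bound
#' IC025 = IC - 3.3 (a + 0.5)^-1/2 - 2 (a + 0.5)^-3/2. `"bate"` uses the
#' original beta/Dirichlet moment approximation with a normal lower bound
#' E(IC) - 1.96 sd(IC). Shrinkage keeps every cell configuration finite.
#'
#' @inheritParams ror
#' @param variant `"noren"` or `"bate"`.
#' @return named numeric vector `ic`, `ic025` (bits).
#' @export
#' @examples
#' bcpnn(contingency(10, 20, 30, 240))  # IC = log2(10.5/4.5)
bcpnn <- function(ct, b = NULL, c = NULL, d = NULL,
                  variant = c("noren", "bate")) {
  variant <- match.arg(variant)
  x <- if (inherits(ct, "contingency_2x2")) cells_of(ct) else c(ct, b, c, d)
  a <- x[1]; N <- sum(x)
  n1 <- x[1] + x[2]   # drug margin
  m1 <- x[1] + x[3]   # event margin
  if (variant == "noren") {
    E <- n1 * m1 / N
    ic <- log2((a + 0.5) / (E + 0.5))
    ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  } else {
    # Bate et al. moment approximation with priors gamma11 = alpha1 =
    # beta1 = 1, alpha = beta = 2
    g11 <- 1; a1 <- 1; b1 <- 1; al <- 2; be <- 2
    gam <- g11 * (N + al) * (N + be) / ((n1 + a1) * (m1 + b1))
    ic <- log2((a + g11) * (N + al) * (N + be) /
                 ((N + gam) * (n1 + a1) * (m1 + b1)))
    v <- (1 / log(2))^2 * (
      (N - a + gam - g11) / ((a + g11) * (1 + N + gam)) +
        (N - n1 + al - a1) / ((n1 + a1) * (1 + N + al)) +
        (N - m1 + be - b1) / ((m1 + b1) * (1 + N + be)))
    ic025 <- ic - 1.96 * sqrt(v)
  }
  c(ic = unname(ic), ic025 = unname(ic025))
}

# Vectorized computation of all four statistics over parallel cell-count
# vectors. Returns a data.frame; this is the engine behind disprop().
dispro_stats <- function(a, b, c, d, min_reports = 3,
                         bcpnn_variant = "noren") {
  # double arithmetic throughout: margin products overflow 32-bit integers
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  a2 <- a + 0.5 * corrected; b2 <- b + 0.5 * corrected
  c2 <- c + 0.5 * corrected; d2 <- d + 0.5 * corrected

  ror_est <- (a2 * d2) / (b2 * c2)
  ror_se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  ror_lo <- ror_est * exp(-1.96 * ror_se)
  ror_hi <- ror_est * exp(1.96 * ror_se)

  prr_est <- (a2 / (a2 + b2)) / (c2 / (c2 + d2))
  prr_se <- sqrt(1 / a2 - 1 / (a2 + b2) + 1 / c2 - 1 / (c2 + d2))
  prr_lo <- prr_est * exp(-1.96 * prr_se)
  prr_hi <- prr_est * exp(1.96 * prr_se)

  N <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2m <- b + d
  E11 <- r1 * c1 / N
  dev <- abs(a - E11)
  # Yates statistic: in a 2x2 all four |O-E| are equal
  chi2 <- (dev - 0.5)^2 * (1 / E11 + 1 / (r1 * c2m / N) +
                             1 / (r2 * c1 / N) + 1 / (r2 * c2m / N))
  chi2[dev < 0.5] <- 0
  chi2[r1 == 0 | r2 == 0 | c1 == 0 | c2m == 0] <- NA_real_

  if (bcpnn_variant == "noren") {
    Eb <- r1 * c1 / N
    ic <- log2((a + 0.5) / (Eb + 0.5))
    ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  } else {
    g11 <- 1; a1 <- 1; b1 <- 1; al <- 2; be <- 2
    gam <- g11 * (N + al) * (N + be) / ((r1 + a1) * (c1 + b1))
    ic <- log2((a + g11) * (N + al) * (N + be) /
                 ((N + gam) * (r1 + a1) * (c1 + b1)))
    v <- (1 / log(2))^2 * (
      (N - a + gam - g11) / ((a + g11) * (1 + N + gam)) +
        (N - r1 + al - a1) / ((r1 + a1) * (1 + N + al)) +
        (N - c1 + be - b1) / ((c1 + b1) * (1 + N + be)))
    ic025 <- ic - 1.96 * sqrt(v)
  }

  enough <- a >= min_reports
  ror_pos <- enough & ror_lo > 1
  prr_pos <- enough & prr_lo > 1
  mhra_pos <- enough & !is.na(chi2) & prr_est >= 2 & chi2 >= 4
  bcpnn_pos <- enough & ic025 > 0
  composite <- ror_pos & prr_pos & mhra_pos & bcpnn_pos

  data.frame(
    a = a, b = b, c = c, d = d, n_reports = a,
    ror = ror_est, ror_lo = ror_lo, ror_hi = ror_hi,
    prr = prr_est, prr_lo = prr_lo, prr_hi = prr_hi,
    chi2 = chi2, ic = ic, ic025 = ic025,
    ror_pos = ror_pos, prr_pos = prr_pos, mhra_pos = mhra_pos,
    bcpnn_pos = bcpnn_pos, composite = composite,
    corrected = corrected
  )
}

#' Evaluate a single drug-event pair
#'
#' Runs all four disproportionality algorithms on one contingency table and
#' applies the composite rule: a signal is valid only when the ROR, PRR,
#' MHRA and BCPNN criteria are all met simultaneously and the pair carries
#' at least `min_reports` reports. Below that threshold the estimates are
#' still reported but every flag is suppressed.
#'
#' @param ct a [contingency()] table.
#' @param min_reports minimum a-cell count for any flag (default 3).
#' @param bcpnn_variant `"noren"` or `"bate"`.
#' @return one-row data.frame of estimates, intervals, flags and the
#'   composite decision.
#' @export
evaluate_pair <- function(ct, min_reports = 3, bcpnn_variant = "noren") {
  x <- cells_of(ct)
  dispro_stats(x[1], x[2], x[3], x[4], min_reports = min_reports,
               bcpnn_variant = bcpnn_variant)
}

# ---- report-level pair counting -----------------------------------------

# Count contingency cells for every (drug, event) pair observed together at
# least once. exposure: data.frame(primaryid, drug); events:
# data.frame(primaryid, event); n_total: number of reports in the
# background. Duplicated (primaryid, drug) or (primaryid, event) rows are
# collapsed so counts are per report.
count_pairs <- function(exposure, events, n_total) {
  exposure <- exposure[!duplicated(paste(exposure$primaryid,
                                         exposure$drug)), , drop = FALSE]
  events <- events[!duplicated(paste(events$primaryid, events$event)), ,
                   drop = FALSE]
  drug_tot <- table(exposure$drug)
  event_tot <- table(events$event)
  j <- merge(exposure, events, by = "primaryid")
  if (!nrow(j)) {
    return(data.frame(drug = character(0), event = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0)))
  }
  at <- as.data.frame(table(drug = j$drug, event = j$event),
                      stringsAsFactors = FALSE)
  at <- at[at$Freq > 0, , drop = FALSE]
  a <- at$Freq
  b <- as.integer(drug_tot[at$drug]) - a
  cc <- as.integer(event_tot[at$event]) - a
  d <- n_total - a - b - cc
  out <- data.frame(drug = at$drug, event = at$event, a = a, b = b, c = cc,
                    d = d, stringsAsFactors = FALSE)
  out[order(out$drug, out$event), , drop = FALSE]
}

# ---- the disprop estimator ----------------------------------------------

#' Fit disproportionality statistics over a report background
#'
#' The central estimator: given per-report drug exposures and per-report
#' events, forms the 2x2 contingency table of every observed (drug, event)
#' pair against the background of `n_total` reports and computes the
#' reporting odds ratio, proportional reporting ratio, Yates chi-squared
#' (MHRA criterion) and BCPNN information component, each with its signal
#' flag, plus the conservative all-four composite flag.
#'
#' @param exposure data.frame with columns `primaryid`, `drug`: one row per
#'   report-drug exposure (typically primary-suspect drugs only).
#' @param events data.frame with columns `primaryid`, `event`: one row per
#'   report-event occurrence. The event may be any rollup level — preferred
#'   term, high-level group term, or system organ class.
#' @param n_total number of reports in the background population.
#' @param min_reports minimum a-cell count for signal flags (default 3).
#' @param bcpnn_variant `"noren"` (closed-form approximation, default) or
#'   `"bate"` (original moment approximation).
#' @return an object of class `disprop`: the signal table with one row per
#'   pair, plus the call and settings. Methods: [print.disprop()],
#'   [summary.disprop()], [coef.disprop()], [as.data.frame.disprop()],
#'   [plot.disprop()].
#' @export
#' @examples
#' ex <- data.frame(primaryid = c("1", "2", "3", "4"),
#'                  drug = c("x", "x", "y", "y"))
#' ev <- data.frame(primaryid = c("1", "2", "3", "4"),
#'                  event = c("e", "e", "e", "f"))
#' disprop(ex, ev, n_total = 4)
disprop <- function(exposure, events, n_total, min_reports = 3,
                    bcpnn_variant = c("noren", "bate")) {
  bcpnn_variant <- match.arg(bcpnn_variant)
  counts <- count_pairs(exposure, events, n_total)
  stats <- if (nrow(counts)) {
    cbind(counts[, c("drug", "event")],
          dispro_stats(counts$a, counts$b, counts$c, counts$d,
                       min_reports = min_reports,
                       bcpnn_variant = bcpnn_variant))
  } else {
    cbind(counts[, c("drug", "event")],
          dispro_stats(integer(0), integer(0), integer(0), integer(0)))
  }
  rownames(stats) <- NULL
  structure(list(
    table = stats, n_total = n_total, min_reports = min_reports,
    bcpnn_variant = bcpnn_variant, call = match.call()
  ), class = "disprop")
}

#' @export
print.disprop <- function(x, ...) {
  cat("Disproportionality analysis (", nrow(x$table), " drug-event pairs, ",
      "N = ", x$n_total, " reports)\n", sep = "")
  cat("Composite signals (all four algorithms, >= ", x$min_reports,
      " reports): ", sum(x$table$composite), "\n\n", sep = "")
  sig <- x$table[x$table$composite, , drop = FALSE]
  if (nrow(sig)) {
    show <- sig[order(-sig$ror),
                c("drug", "event", "a", "ror", "ror_lo", "ror_hi",
                  "prr", "chi2", "ic", "ic025")]
    show[, -(1:3)] <- lapply(show[, -(1:3)], round, 2)
    print(utils::head(show, 20), row.names = FALSE)
    if (nrow(show) > 20) cat("... and", nrow(show) - 20, "more\n")
  }
  invisible(x)
}

#' Summary of a disproportionality fit
#'
#' @param object a [disprop()] fit.
#' @param ... unused.
#' @return a list of class `summary.disprop` with pair counts, flag counts
#'   per algorithm, and the composite-signal table.
#' @export
summary.disprop <- function(object, ...) {
  t <- object$table
  structure(list(
    n_pairs = nrow(t),
    n_evaluable = sum(t$a >= object$min_reports),
    flags = c(ror = sum(t$ror_pos), prr = sum(t$prr_pos),
              mhra = sum(t$mhra_pos), bcpnn = sum(t$bcpnn_pos),
              composite = sum(t$composite)),
    signals = t[t$composite, , drop = FALSE],
    n_total = object$n_total
  ), class = "summary.disprop")
}

#' @export
print.summary.disprop <- function(x, ...) {
  cat("Pairs:", x$n_pairs, " evaluable (>= min reports):", x$n_evaluable,
      "\n")
  cat("Positive flags: ROR", x$flags["ror"], "| PRR", x$flags["prr"],
      "| MHRA", x$flags["mhra"], "| BCPNN", x$flags["bcpnn"],
      "| composite", x$flags["composite"], "\n")
  invisible(x)
}

#' Point estimates of a disproportionality fit
#'
#' @param object a [disprop()] fit.
#' @param ... unused.
#' @return numeric matrix (one row per pair) of ROR, PRR, chi-squared and
#'   IC point estimates, row-named `drug:event`.
#' @export
coef.disprop <- function(object, ...) {
  t <- object$table
  m <- as.matrix(t[, c("ror", "prr", "chi2", "ic")])
  rownames(m) <- paste(t$drug, t$event, sep = ":")
  m
}

#' @export
as.data.frame.disprop <- function(x, ...) x$table

#' Forest-style plot of reporting odds ratios
#'
#' Draws the ROR point estimates and 95% confidence intervals of the
#' fitted pairs on a log axis, composite signals highlighted.
#'
#' @param x a [disprop()] fit.
#' @param top plot at most this many pairs, by descending ROR (default 30).
#' @param ... passed to [graphics::plot()].
#' @export
plot.disprop <- function(x, top = 30, ...) {
  t <- x$table[x$table$a >= x$min_reports, , drop = FALSE]
  if (!nrow(t)) {
    warning("nothing to plot: no pair reaches the minimum report count")
    return(invisible(x))
  }
  t <- utils::head(t[order(-t$ror), ], top)
  k <- nrow(t)
  y <- rev(seq_len(k))
  graphics::plot(t$ror, y, log = "x", pch = 19,
                 col = ifelse(t$composite, "firebrick", "grey40"),
                 xlim = range(c(t$ror_lo, t$ror_hi, 1), finite = TRUE),
                 yaxt = "n", xlab = "Reporting odds ratio (95% CI)",
                 ylab = "", ...)
  graphics::segments(t$ror_lo, y, t$ror_hi, y,
                     col = ifelse(t$composite, "firebrick", "grey40"))
  graphics::abline(v = 1, lty = 2)
  graphics::axis(2, at = y, labels = paste(t$drug, t$event, sep = ": "),
                 las = 2, cex.axis = 0.7)
  invisible(x)
}
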