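---
title: "Methods: disproportionality signal detection on spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection on spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous-reporting systems such as FAERS collect individual case
safety reports without denominators: we observe how often a drug–event
combination is *reported*, never how often it *occurs* per exposed
patient. Disproportionality analysis works around this by asking whether
a pair is reported more often than the background reporting pattern
predicts. `pvsignal` applies this machinery to a focused question:
psychiatric adverse events (pAEs) in pediatric patients (0–17 years)
whose primary-suspect drug is a respiratory drug — WHO ATC category "R":
drugs for obstructive airway disease, nasal and throat preparations,
cough and cold preparations, systemic antihistamines, and other
respiratory products.

Because spontaneous data are noisy in characteristic ways — one case
submitted as several report versions, withdrawn cases, ages reported in
five different units, partial dates — the package treats the cleaning
pipeline as part of the method and tests it with the same rigor as the
statistics.

## Pipeline and assumptions

1. **Ingestion.** Quarterly-style `$`-delimited tables (DEMO, DRUG,
   REAC, OUTC, THER, INDI) are read with a tolerant parser: lines with
   the wrong field count are counted and quarantined, never silently
   dropped, and a missing file or unparseable header is a hard error.
2. **Deduplication.** Reports are sorted by `CASEID`, `FDA_DT`,
   `PRIMARYID` and the last version per case is kept: the most recent
   receipt date wins, ties go to the highest primary id (numerically
   compared when ids parse as numbers, since the files store them as
   strings). This is idempotent and is verified against a brute-force
   group-by-maximum oracle.
3. **Deleted reports.** Withdrawn case ids are removed *after*
   deduplication, and any quarter's list applies globally. We treat case
   ids as globally unique across quarters.
4. **Cohort selection.** A case is included iff (i) its normalized age
   lies in `[0, 18)` years, (ii) at least one primary-suspect drug maps
   to an ATC code starting with "R" (combination products qualify when
   any component does), and (iii) at least one reaction preferred term
   lies under the psychiatric-disorders SOC. The half-open age interval
   keeps 17-year-olds with fractional ages; exact 18.0 is excluded.
   Drug-name matching is exact after normalization (case-fold, trim,
   collapse whitespace) — no fuzzy matching, because silent approximate
   matches are unreproducible; unmapped names are counted and reported
   for curation.
5. **Units of analysis.** Patients and drug–event *pairs* are distinct
   units: one case with one respiratory drug and two psychiatric
   preferred terms contributes one patient and two pair rows. Drug-level
   denominators (composition tables, death and life-threatening rates)
   use the drug's distinct report count.
6. **Statistics.** Every observed pair gets the four-algorithm panel
   (ROR, PRR, MHRA χ², BCPNN IC) on its 2×2 table, and the composite
   flag requires all four criteria plus at least three reports.

The interpretation caveat is inherited from the design: a composite
signal is a reporting disproportion, not an incidence estimate and not
causality.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `age_min`, `age_max` | 0, 18 | cohort bounds in years, half-open interval |
| `background` | `"pediatric"` | comparator population for the 2×2 tables: reports within the age bounds, or `"all"` reports in the bundle |
| `min_reports` | 3 | minimum a-cell count for any signal flag; below it, estimates are reported with flags suppressed |
| `pt_table_min` | 10 | per-drug composition tables require strictly more reports than this |
| `bcpnn_variant` | `"noren"` | closed-form IC approximation; `"bate"` switches to the original moment approximation with a normal lower bound |
| `quantile_type` | 7 | quartile convention for median/IQR (linear interpolation); conventions differ across software, so it is explicit and configurable |

The comparator population deserves emphasis: published signal tables
rarely state whether their non-cases are age-restricted, and the choice
moves every b, c, d cell. We default to the pediatric-only background —
the question being asked is "is this pair over-reported *among pediatric
reports*" — and expose `"all"` for sensitivity analysis. In stratified
analyses the comparator is the same-stratum non-cases, which is what
"stratified disproportionality" means operationally; a pooled-background
alternative would answer a different question.

## Numerical choices

- **Zero cells.** ROR and PRR get the Haldane–Anscombe correction (0.5
  added to all four cells) only when a zero cell occurs, and such rows
  are flagged `corrected`; nonzero tables are never perturbed. The χ²
  statistic is undefined (NA, flag false) on a zero margin. The IC needs
  no correction: shrinkage keeps it finite everywhere.
- **Yates clamping.** The continuity correction is not allowed to exceed
  the deviation itself: when |O − E| < 0.5 the statistic is exactly 0.
- **Percent arithmetic.** Table percentages round half-up to two
  decimals (3443/6994 → 49.23); `round()`'s round-half-even would
  disagree with published tables on exact halves. An epsilon guards
  against binary floating-point representations of halves.
- **Cell arithmetic** is done in doubles throughout: margin products of
  realistic bundles overflow 32-bit integers.
- **Dates.** Onset time = event date − therapy start date, computed only
  when both resolve to full `YYYYMMDD` dates; partial dates and negative
  differences become missing rather than guesses. Onset bins (0–7, 8–60,
  61–180, 181–360 days) are reported together with explicit `>360` and
  `missing` categories instead of forcing every case into the published
  bins.
- **Age units.** Years, months (/12), weeks (/52.18), days (/365.25),
  hours (/8766) and decades (×10); negative values and unit-less values
  normalize to missing and are counted.

## The synthetic generator

`synthetic_config()` + `generate_bundle()` emit a complete bundle with
known ground truth. Each unique case draws one primary-suspect drug from
a background distribution and one reaction term conditionally on the
drug: for injected pairs the joint probability is multiplied by the
relative reporting rate λ and renormalized within the drug. Because the
event background always sums to one (an explicit filler term absorbs the
remainder), the population reporting odds ratio of an injected pair
equals λ exactly — this is what makes λ a recoverable target rather than
a loose effect-size knob. `population_ror()` exposes the closed form,
including the small cross-pair coupling that appears when several drugs
carry injections (each injection slightly deflates its drug's other
event rates, so non-injected pairs sit near, not exactly at, 1).

The generator deliberately reproduces the failure modes the pipeline
must handle: duplicate report versions with increasing receipt dates
(default 10% of cases) including a configurable fraction of receipt-date
ties to exercise the primary-id tie-break (20% of duplicates);
deleted-case lists (2%); dates truncated to year-month or year (10%);
ages emitted in mixed units by age (days/weeks/months for infants,
months for toddlers, years with occasional decades above five); an adult
and an unknown-age share (7% and 3%) so the age filter has work to do;
unknown sex (2%); and concomitant non-suspect drugs (20%). Age-group
weights (13/35/42 for 0–4/5–11/12–17), sex balance, reporter, country,
route, indication and outcome-code frequencies are chosen to resemble
published pediatric spontaneous-report series; receipt years 2004–2024
rise steeply in the most recent period. One reaction term per case is
the default so that injected λ values stay directly interpretable;
multi-term and multi-drug modes exist for stress tests.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: verbatim drug-name chaos (misspellings,
salts, brand names) that a real dictionary mapping must absorb; duplicate
versions with *changed* content between revisions; reporting waves after
regulatory actions; correlated multi-drug, multi-event reports; and any
real dose/indication structure. Recovery of λ on synthetic bundles shows
the estimator and plumbing are correct, not that any particular real
signal is true.

## Validation design

The test suite and `scripts/acceptance.R` check five properties, at
problem sizes chosen to keep the full run in the minutes range on one
CPU: (1) published count/percentage pairs reproduce exactly to two
decimals; (2) deduplication matches a brute-force oracle on 1,000
random multi-version case sets; (3) all four statistics match
independent direct-arithmetic oracles (and R's own Yates-corrected
`chisq.test`) to 1e-9 relative tolerance on 1,000 random tables;
(4) twenty 50,000-case bundles with λ ∈ {2, 4, 8} injections yield 95%
CIs that cover λ in at least 90% of replicates and composite detection
of every λ = 8 pair; (5) with no injections, the composite rule flags at
most 5% of pairs with a ≥ 3 across twenty 20,000-case bundles (in
practice well under 1% — the all-four conjunction is much more
conservative than any single criterion).

One published-table quirk forced a choice: the reporting-year rows of
the characteristics table we mirror print percentages inconsistent with
their own counts and stated denominator (and the onset-bin distribution
is inconsistent with the printed onset median), so year-bin and
onset-median values are *not* used as exact-reproduction targets; the
package reports its own internally consistent arithmetic instead.

## Known limitations

- Exact-match drug dictionaries under-map real verbatim names; the
  unmapped counter is the honest signal of that loss.
- The Wald intervals for ROR/PRR are asymptotic; at a-cells near the
  minimum of 3 their coverage is approximate, which is one reason the
  composite rule, not any single interval, gates a signal.
- No multiplicity adjustment is applied — the design is exploratory, and
  the composite rule is the conservatism mechanism.
- Legacy pre-2012Q4 ISR-format files and the XML dialect are out of
  scope, as are empirical-Bayes shrinkage estimators (EBGM/MGPS).
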