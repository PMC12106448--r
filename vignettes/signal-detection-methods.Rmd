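---
title: "Methods: disproportionality signal detection for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Spontaneous-report databases such as FAERS collect voluntarily submitted
suspicions that a drug caused an adverse event. They have no denominator —
no count of exposed, unaffected patients — so absolute risks cannot be
estimated. Disproportionality analysis works around this by asking whether a
drug–event pair is reported *more often than expected* given the rest of the
database: a 2×2 contingency table compares the event's share among the
target drug's reports with its share among all other reports. A pair whose
statistics exceed pre-set thresholds is a *signal*: a prompt for clinical
review, never proof of causation.

`pvsignal` implements this analysis for cohorts selected by a target-drug
lexicon (its motivating application: probiotic preparations, a product
family reported under many free-text names) against a large background, at
two levels of the MedDRA-style hierarchy: preferred terms (PT) and system
organ classes (SOC).

# The counting unit

Every statistic is computed from cells

* `a` — (report, term) units with the target drug and the term,
* `b` — units with the target drug and any other term,
* `c`, `d` — the same for background reports.

The unit is the (report, term) *pair*, not the report: a report carries
several PTs and therefore contributes to several terms; within one term
(and, at SOC level, within one SOC, however many of the report's PTs map
there) it counts once. This is the only convention under which a small
cohort's SOC counts can exceed its report count, as published scans of this
kind routinely show. `b` and `d` are completed from the level-specific pair
totals, so `a + b` is always the target cohort's pair total at that level.

Unmapped PTs never silently join an SOC: at SOC level they are excluded
from the pair universe and tallied (`n_unmapped_pairs` in `glance()`); in
the yearly gastrointestinal split they count under "other" with a separate
`unmapped` tally.

# The three statistics

With `N = a + b + c + d`:

* **ROR** `= ad/bc`, 95% CI `exp(ln ROR ± 1.96 √(1/a+1/b+1/c+1/d))` (Woolf).
* **PRR** `= [a/(a+b)] / [c/(c+d)]`, with the uncorrected Pearson
  `χ² = N(ad−bc)² / ((a+b)(c+d)(a+c)(b+d))`, and a log-scale delta-method CI
  with standard error `√(1/a − 1/(a+b) + 1/c − 1/(c+d))`.
* **EBGM**, implemented as the relative reporting ratio
  `aN/((a+b)(a+c))` — observed over expected under independence — with a
  lognormal 95% interval sharing the Woolf standard error; `EBGM05` is its
  lower bound. The full MGPS gamma-Poisson shrinkage that the name EBGM
  often denotes is deliberately out of scope: for the rare-exposure regimes
  this package targets (a ≪ c, (a+b) ≪ N) the relative reporting ratio and
  PRR agree within 2%, which is exactly the two-decimal PRR/EBGM agreement
  visible in published tables of this kind, and the unshrunk estimator is
  transparent and exactly testable. Consequently EBGM05 here is a sampling
  bound, not a shrinkage bound, and is anti-conservative for very small `a`
  relative to MGPS.

**Undefined marking.** When a required cell or margin is zero a statistic is
`NA`, never a fabricated number: no Haldane–Anscombe 0.5 correction is
applied by default (available via `haldane = TRUE` on the ROR). Since the
joint criteria gate on `N ≥ 3`, the choice does not affect flagging;
undefined statistics never fire a flag.

**Joint criteria.** ROR: `N ≥ 3` and CI lower bound ≥ 1 — the boundary is
inclusive by default (`ror_boundary = "strict"` switches to `> 1`); PRR:
`N ≥ 3`, `PRR ≥ 2`, `χ² ≥ 4`; EBGM: `EBGM05 > 2`; `flag_all` is their
conjunction. `evaluate_signal()` applies the criteria to any statistics
table, so published statistics can be re-flagged without the underlying
margins.

# Reading, deduplication, partition

The FAERS dialect is dollar-delimited text with one header row per table.
The parser counts and excludes rows with a wrong field count rather than
repairing or dropping them silently — in a data-quality-sensitive domain the
parse summary is part of the result. Ages are converted to years from the
public codebook's unit codes (`DEC`×10, `YR`, `MON`/12, `WK`·7/365.25,
`DY`/365.25, `HR`/8766); implausible ages over 120 years become unknown.
Routes collapse to oral/other (the two levels descriptive tables of this
kind report), taking the primary-suspect drug row's route.

Cases arrive in multiple versions; `deduplicate()` keeps, per case, the
highest version, breaking ties by latest receipt date then highest report
id — standard practice, and fully deterministic. The pipeline always
collapses versions before any counting.

A report belongs to the target cohort iff *any* of its primary-suspect
drugs matches the lexicon (the unit of analysis is the report, and
restricting to the PS role keeps concomitant mentions out). Matching is by
normalized substring — uppercase, whitespace-collapsed,
punctuation-stripped — because product families appear under many verbatim
spellings; the bundled probiotic lexicon is deliberately conservative, and
false-positive fragments are the user's responsibility.

# Descriptives, trends, subgroups

`describe_cohort()` tabulates sex, age band (`<20`, decade bands, `>80`,
unknown), reporter, country, outcomes and route, with percentages rounded
half-up to two decimals, matching published table rendering. Unknown
categories are always reported. The outcome block's denominator is the
number of reports with at least one serious outcome code, each code counted
once — published tables of this layout are sometimes internally
inconsistent here, so the convention is fixed and documented rather than
fitted to any one table. Trend years come from the receipt date (event
dates in spontaneous reports are too incomplete).

Subgroups: sex (male/female; unknown excluded) and age at an 18-year
cut-off with 18 itself in the minor group (`≤18` vs `>18`); unknown ages
belong to neither stratum. `subgroup_scan()` restricts *both* cohort and
background to the stratum before building tables — the stratum-matched
comparator is the epidemiologically defensible default, because it cancels
stratum-specific reporting propensities; `comparator = "all"` keeps the full
background instead for comparison with analyses that do not say which
convention they used.

# The synthetic generator

`generate_reports()` emulates the structure the analysis consumes, with
defaults calibrated to the marginal composition of a published 74-report
probiotic cohort: sex 17/41/16 (male/female/unknown), age-band masses with
40.5% unknown, reporters two-thirds consumers, countries two-thirds United
States, outcomes 38% non-serious, routes 51/49 oral/other, and reporting
years uniform over 2005–2023. The events-per-report count is truncated
geometric on 1..10 with mean 285/74 ≈ 3.85 — the published cohort fixes
only the mean (285 PT pairs over 74 reports), so the distribution family is
a modeling choice, chosen for its monotone-decreasing shape typical of
per-report event counts, and is configurable. The duplicate rate defaults
to 10% — spontaneous-report databases carry a substantial version-duplicate
load, and no published figure pins it down; duplicates perturb only mutable
fields (receipt date, reporter), so deduplication correctness is checkable
against demographics.

Planted signals multiply the chosen PT's background weight by the
configured relative risk inside target-drug reports, then renormalize. The
realized reporting-rate ratio therefore approaches the configured relative
risk only when the planted weight is small; recovery studies use a planted
background weight of 0.02 for this reason. A planted signal may optionally
be restricted to one sex, which is how subgroup recovery is exercised.
Event sets are drawn without replacement via the Gumbel top-k race, so a
report never repeats a PT.

What the generator does *not* emulate: correlated event co-occurrence,
drug–drug interactions and concomitant-medication effects, reporting-rate
secular trends, country–reporter dependence, and free-text drug-name noise
beyond casing/synonym variation. Passing recovery tests therefore show the
pipeline's statistical machinery works under a clean generative model; they
do not certify performance on real FAERS data, whose biases (under- and
stimulated reporting, duplicates that differ in demographics, coding drift)
are outside the model.

# Validation design and problem sizes

The test suite checks each statistic against an independently coded
brute-force oracle on 1,000 random tables (agreement to 1e−12 relative
error), the algebraic identity ROR ≥ PRR ⇔ ad ≥ bc, strict monotonicity in
the a-cell, the rare-exposure PRR/EBGM limit, and null CI calibration
(93–97% coverage of 1 over 2,000 multinomial tables under independence,
with expected a-cell 125). The end-to-end study generates 100 datasets of
20,000 cases (5% target share, one PT planted at relative risk 10 over
background weight 0.02), runs the full pipeline, and requires the planted
PT flagged by all three algorithms in at least 95 of 100 seeds with a mean
false-positive rate over unplanted PTs below 5%; a male-only planted signal
must surface in the male subgroup scan and not in the female one (10
seeds). These sizes put the planted PT's expected a-cell in the hundreds —
comfortably identifiable — while keeping a full run to a few minutes on one
CPU; they are the package's standing benchmark configuration.

Published point values of ROR/PRR/EBGM from real-database scans are *not*
reproduction targets: they depend on the full database's background
margins, which a desk analysis cannot reconstruct. What is reproduced
exactly is everything margin-free: descriptive percentages from printed
counts, and the joint-flag pattern of printed statistics tables
(`evaluate_signal()` on the bundled fixtures).

# Known limitations

* EBGM is unshrunk; small-count EBGM05 values are anti-conservative
  relative to MGPS.
* No multiple-testing correction is applied, matching standard practice for
  hypothesis-generating scans; users scanning thousands of terms should
  treat isolated flags accordingly.
* The PRR CI uses the delta method; exact intervals are not offered.
* Dose, therapy duration, indication and free-text drug coding are out of
  scope; REAC input is assumed PT-coded.
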