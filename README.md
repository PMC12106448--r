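# pvsignal

Disproportionality signal detection for spontaneous adverse-event reports.

`pvsignal` is an R toolkit for pharmacovigilance mining of spontaneous-report
databases distributed in the FAERS quarterly ASCII dialect (dollar-delimited
DEMO/DRUG/REAC/OUTC tables). It was built around a concrete use case —
scanning a small cohort of probiotic-preparation reports against a
multi-million-report background — but every step is generic: any
target-drug lexicon, any PT→SOC term dictionary, any FAERS-dialect extract.

The package covers the full analysis chain:

* **Reading and assembly** — `read_quarter()`, `assemble_cases()`: parse the
  four quarterly tables (malformed rows counted, never silently dropped),
  join them into one record per report instance, convert age unit codes
  (DEC/YR/MON/WK/DY/HR) to years, and decode sex/reporter/outcome/route.
* **Deduplication** — `deduplicate()`: one record per case, keeping the
  highest version, then the latest receipt date, then the highest report id.
* **Target partition** — `flag_target_reports()` with a `drug_lexicon()`:
  a report is a target report iff a primary-suspect (PS) drug matches a
  normalized name fragment.
* **Signal scan** — `scan_signals()` at PT or SOC level. For each term the
  2×2 table (a, b, c, d) counts (report, term) pairs, and three statistics
  are computed:

  * reporting odds ratio, ROR = ad/bc, with the Woolf 95% CI
    exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d));
  * proportional reporting ratio, PRR = [a/(a+b)]/[c/(c+d)], with the
    uncorrected χ² = N(ad − bc)²/((a+b)(c+d)(a+c)(b+d));
  * EBGM, here the relative reporting ratio aN/((a+b)(a+c)), with a
    lognormal interval whose lower bound is EBGM05.

  Joint criteria flag a signal: ROR (N ≥ 3, CI lower bound ≥ 1),
  PRR (N ≥ 3, PRR ≥ 2, χ² ≥ 4), EBGM (EBGM05 > 2), and their conjunction.
* **Descriptives and subgroups** — `describe_cohort()`, `annual_counts()`,
  `gi_split_counts()`, `country_counts()`, `stratify()` (sex; age with an
  18-year cut-off), and `subgroup_scan()` with a stratum-matched comparator.
* **Synthetic benchmark** — `synthetic_config()` / `generate_reports()`:
  a spontaneous-report simulator with multi-version duplicates, realistic
  missingness, and planted drug–event associations of configurable strength,
  plus `write_faers_dialect()` so the whole pipeline can be exercised
  end-to-end with known ground truth.
* **Orchestration** — `run_pipeline()` (and a thin CLI at
  `inst/cli/pvsignal.R`) runs generate/read → dedup → partition → scans →
  subgroups → descriptives and writes CSV tables plus a run manifest.

## Worked example

```r
library(pvsignal)

cfg <- synthetic_config(
  n_cases = 5000, p_target = 0.05, seed = 42,
  planted_signals = tibble::tibble(pt = "flatulence", relative_risk = 10)
)
sim   <- generate_reports(cfg)
lex   <- load_drug_lexicon(pvsignal_example("probiotic_lexicon.txt"))
dict  <- load_term_dictionary(pvsignal_example("synthetic_pt_vocabulary.tsv"))
cases <- flag_target_reports(deduplicate(sim$cases), lex)
scan  <- scan_signals(cases, level = "pt", dict = dict)
scan
#> # Disproportionality scan (PT level): 47 terms, 1 meeting all three criteria
#> # target reports: 256; background reports: 4744
dplyr::select(tidy(scan), term, n, ror, ror_lo, prr, chi2, ebgm05, flag_all)[1:3, ]
#> # A tibble: 3 × 8
#>   term                      n   ror ror_lo   prr   chi2 ebgm05 flag_all
#>   <chr>                 <int> <dbl>  <dbl> <dbl>  <dbl>  <dbl> <lgl>
#> 1 FLATULENCE              133  6.35  5.16   5.69 398.    3.68  TRUE
#> 2 ANAPHYLACTIC REACTION    28  1.25  0.846  1.24   1.25  0.831 FALSE
#> 3 INSOMNIA                 29  1.25  0.852  1.24   1.29  0.836 FALSE
glance(scan)
```

The planted term tops the scan: 133 of the 256 target reports carry it, its
reporting odds are ~6× the background (ROR 6.35, CI lower bound 5.16 — below
the planted relative risk of 10 because the planted weight here is not
small), and all three algorithms flag it (`flag_all = TRUE`); the unplanted
terms sit near ROR 1 and stay unflagged. `autoplot(scan)` draws the corresponding
volcano plot, and `describe_cohort(dplyr::filter(cases, is_target))` gives
the characteristics table.

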