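# Frozen expected values below were computed by independent hand evaluation
# of the standard formulas (see helper oracle): for (a,b,c,d) = (10,90,100,9900)
# ROR = 11.0 with CI (5.5595, 21.7645), PRR = 10.0 with chi2 = 74.4472,
# EBGM = 9.1818 with EBGM05 = 4.6406.

test_that("reporting odds ratio and Woolf interval match hand-computed values", {
  r <- ror_with_ci(10, 90, 100, 9900)
  expect_equal(r$ror, 11.0)
  expect_equal(r$ror_lo, 5.559515, tolerance = 0.005)
  expect_equal(r$ror_hi, 21.76449, tolerance = 0.005)
  # symmetric table: exactly 1, interval straddles it symmetrically on log scale
  s <- ror_with_ci(5, 5, 5, 5)
  expect_identical(s$ror, 1)
  expect_equal(log(s$ror_hi), -log(s$ror_lo))
  # zero cell: undefined-marked, not zero and not an error
  z <- ror_with_ci(0, 10, 10, 100)
  expect_true(is.na(z$ror) && is.na(z$ror_lo))
  # Haldane switch substitutes the 0.5-corrected value instead
  h <- ror_with_ci(0, 10, 10, 100, haldane = TRUE)
  expect_equal(h$ror, (0.5 * 100.5) / (10.5 * 10.5))
})

test_that("PRR and chi-squared match hand-computed values and the null table", {
  p <- prr_with_chi2(10, 90, 100, 9900)
  expect_equal(p$prr, 10.0)
  expect_equal(p$chi2, 74.44717, tolerance = 0.005)
  s <- prr_with_chi2(5, 5, 5, 5)
  expect_identical(s$prr, 1)
  expect_identical(s$chi2, 0)
  # a = 0: PRR is 0 so no flag can fire; its CI is undefined
  z <- prr_with_chi2(0, 100, 100, 9800)
  expect_identical(z$prr, 0)
  expect_true(is.na(z$prr_lo))
  # c = 0: undefined-marked
  expect_true(is.na(prr_with_chi2(5, 5, 0, 10)$prr))
})

test_that("chi-squared equals the uncorrected Pearson statistic", {
  tabs <- random_tables(25, seed = 42, max_cell = 500)
  ours <- prr_with_chi2(tabs$a, tabs$b, tabs$c, tabs$d)$chi2
  ref <- mapply(function(a, b, c, d) {
    suppressWarnings(stats::chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                                       correct = FALSE)$statistic)
  }, tabs$a, tabs$b, tabs$c, tabs$d)
  expect_equal(ours, unname(ref), tolerance = 1e-10)
})

test_that("EBGM (relative reporting ratio) matches hand-computed values", {
  e <- ebgm_with_ci(10, 90, 100, 9900)
  expect_equal(e$ebgm, 9.181818, tolerance = 0.005)
  expect_equal(e$ebgm05, 4.640587, tolerance = 0.005)
  expect_identical(ebgm_with_ci(5, 5, 5, 5)$ebgm, 1)
  # degenerate table with empty margins is undefined-marked
  expect_true(is.na(ebgm_with_ci(3, 0, 0, 0)$ebgm))
})

test_that("all three statistics agree with the brute-force oracle", {
  tabs <- random_tables(1000, seed = 1)
  got <- dplyr::bind_cols(
    ror_with_ci(tabs$a, tabs$b, tabs$c, tabs$d),
    prr_with_chi2(tabs$a, tabs$b, tabs$c, tabs$d),
    ebgm_with_ci(tabs$a, tabs$b, tabs$c, tabs$d)
  )
  for (i in seq_len(nrow(tabs))) {
    o <- oracle_stats(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    for (f in names(o)) {
      expect_lt(rel_err(got[[f]][i], o[[f]]), 1e-12)
    }
  }
})

test_that("ror >= prr exactly when ad >= bc, and shifting b to a raises all three", {
  tabs <- random_tables(400, seed = 2, max_cell = 1000)
  ror <- ror_with_ci(tabs$a, tabs$b, tabs$c, tabs$d)$ror
  prr <- prr_with_chi2(tabs$a, tabs$b, tabs$c, tabs$d)$prr
  expect_identical(ror >= prr, tabs$a * tabs$d >= tabs$b * tabs$c)

  shift <- dplyr::filter(tabs, b >= 2)[1:100, ]
  before <- list(ror = ror_with_ci(shift$a, shift$b, shift$c, shift$d)$ror,
                 prr = prr_with_chi2(shift$a, shift$b, shift$c, shift$d)$prr,
                 ebgm = ebgm_with_ci(shift$a, shift$b, shift$c, shift$d)$ebgm)
  after <- list(ror = ror_with_ci(shift$a + 1, shift$b - 1, shift$c, shift$d)$ror,
                prr = prr_with_chi2(shift$a + 1, shift$b - 1, shift$c, shift$d)$prr,
                ebgm = ebgm_with_ci(shift$a + 1, shift$b - 1, shift$c, shift$d)$ebgm)
  expect_true(all(after$ror > before$ror))
  expect_true(all(after$prr > before$prr))
  expect_true(all(after$ebgm > before$ebgm))
})

test_that("PRR and EBGM agree within 2% in the rare-exposure limit", {
  # a << c and (a+b) << N: the two-decimal PRR/EBGM agreement seen in
  # published scans of a tiny cohort against a huge background
  tabs <- withr::with_seed(3, tibble::tibble(
    a = sample(1:20, 200, replace = TRUE),
    b = sample(30:300, 200, replace = TRUE),
    c0 = sample(2000:50000, 200, replace = TRUE)
  ))
  tabs$c <- pmax(tabs$c0, 100 * tabs$a)
  tabs$d <- pmax(1000 * (tabs$a + tabs$b), 20 * tabs$c) - tabs$c
  stopifnot(all(tabs$a <= 0.01 * tabs$c),
            all((tabs$a + tabs$b) <= 0.001 * (tabs$a + tabs$b + tabs$c + tabs$d)))
  prr <- prr_with_chi2(tabs$a, tabs$b, tabs$c, tabs$d)$prr
  ebgm <- ebgm_with_ci(tabs$a, tabs$b, tabs$c, tabs$d)$ebgm
  expect_lt(max(abs(prr - ebgm) / prr), 0.02)
})

test_that("contingency tables count (report, term) pairs once per report", {
  cases <- cases_tbl(
    mk_case(1, events = "pt x", is_target = TRUE),
    mk_case(2, events = "pt y", is_target = TRUE),
    mk_case(3, events = "pt x", is_target = FALSE),
    mk_case(4, events = "pt y", is_target = FALSE),
    mk_case(5, events = "pt y", is_target = FALSE)
  )
  expect_identical(unlist(build_contingency(cases, "pt x", "pt")),
                   c(a = 1L, b = 1L, c = 1L, d = 2L))
  expect_identical(unlist(build_contingency(cases, "pt y", "pt")),
                   c(a = 1L, b = 1L, c = 2L, d = 1L))

  # two PTs of one report mapping to the same SOC contribute one unit
  dict <- term_dictionary(pt = c("pt x", "pt x2", "pt y"),
                          soc = c("soc s", "soc s", "soc other"))
  soc_cases <- cases_tbl(
    mk_case(1, events = c("pt x", "pt x2"), is_target = TRUE),
    mk_case(2, events = "pt y", is_target = FALSE)
  )
  tab <- build_contingency(soc_cases, "soc s", "soc", dict = dict)
  expect_identical(tab$a, 1L)
  # repeated PT strings on a report also count once
  dup <- cases_tbl(mk_case(1, events = c("pt x", "PT X"), is_target = TRUE),
                   mk_case(2, events = "pt y", is_target = FALSE))
  expect_identical(build_contingency(dup, "pt x", "pt")$a, 1L)
  expect_error(build_contingency(soc_cases, "no such soc", "soc", dict = dict),
               "not in the dictionary")
})

test_that("joint criteria reproduce the published flag pattern", {
  # rows shaped like a published SOC scan: immune-system row meets ROR and
  # PRR but not EBGM05 > 2; gastrointestinal and hepatobiliary meet all three
  ref <- readr::read_tsv(pvsignal_example("reference_soc_stats.tsv"),
                         col_types = readr::cols(soc = "c", .default = "d"))
  flags <- evaluate_signal(ref)
  immune <- flags[flags$soc == "immune system disorders", ]
  expect_true(immune$flag_ror && immune$flag_prr && !immune$flag_ebgm)
  expect_false(immune$flag_all)
  expect_identical(flags$soc[flags$flag_all],
                   c("gastrointestinal disorders", "hepatobiliary disorders"))
})

test_that("flags respect the N >= 3 gate and undefined statistics", {
  gated <- evaluate_signal(tibble::tibble(n = 2, ror_lo = 50, prr = 60,
                                          chi2 = 100, ebgm05 = 40))
  expect_false(gated$flag_ror)
  undef <- evaluate_signal(tibble::tibble(n = 10, ror_lo = NA_real_,
                                          prr = NA_real_, chi2 = NA_real_,
                                          ebgm05 = NA_real_))
  expect_false(any(undef$flag_ror, undef$flag_prr, undef$flag_ebgm, undef$flag_all))
  # boundary: lower bound exactly 1 flags inclusively, not strictly
  edge <- tibble::tibble(n = 5, ror_lo = 1, prr = 3, chi2 = 10, ebgm05 = 3)
  expect_true(evaluate_signal(edge)$flag_ror)
  expect_false(evaluate_signal(edge, ror_boundary = "strict")$flag_ror)
})

test_that("scans emit one sorted row per target-observed term", {
  cases <- cases_tbl(
    mk_case(1, events = c("pt x", "pt y"), is_target = TRUE),
    mk_case(2, events = "pt z", is_target = TRUE),
    mk_case(3, events = c("pt x", "pt w"), is_target = FALSE),
    mk_case(4, events = "pt y", is_target = FALSE)
  )
  sc <- scan_signals(cases, "pt")
  expect_identical(nrow(sc), 3L)               # pt w unseen among targets
  expect_setequal(sc$term, c("PT X", "PT Y", "PT Z"))
  ror <- sc$ror
  expect_true(!is.unsorted(rev(ror[!is.na(ror)])))
  expect_identical(nrow(scan_signals(cases[cases$is_target == FALSE, ], "pt")), 0L)
  # tidy/glance interface
  expect_s3_class(tidy(sc), "tbl_df")
  g <- glance(sc)
  expect_identical(g$n_terms, 3L)
  expect_identical(g$n_target_reports, 2L)
})
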