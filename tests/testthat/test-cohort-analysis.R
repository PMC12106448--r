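ref_counts <- function() {
  readr::read_tsv(pvsignal_example("reference_cohort_counts.tsv"),
                  col_types = "cci", progress = FALSE)
}

test_that("descriptive table reproduces published percentages from counts", {
  tab <- describe_cohort(cohort_from_counts(ref_counts()))
  get <- function(ch, cat) tab$pct[tab$characteristic == ch & tab$category == cat]
  expect_identical(get("reporter", "consumer"), 67.57)
  expect_identical(get("route", "oral"), 51.35)
  expect_identical(get("age", "70~79"), 14.86)
  expect_identical(get("country", "united states"), 67.57)
  expect_identical(get("sex", "female"), 55.41)
  # the over-50 aggregate
  over50 <- sum(tab$n[tab$characteristic == "age" &
                        tab$category %in% c("50~59", "60~69", "70~79", ">80")])
  expect_identical(pvsignal:::round_half_up(over50 / 74 * 100, 2), 39.19)
})

test_that("descriptive blocks report unknowns and sum to 100 percent", {
  tab <- describe_cohort(cohort_from_counts(ref_counts()))
  for (ch in c("sex", "age", "reporter", "country", "route")) {
    expect_equal(sum(tab$pct[tab$characteristic == ch]), 100, tolerance = 0.02)
  }
  expect_identical(tab$n[tab$characteristic == "age" & tab$category == "unknown"], 30L)

  lone <- mk_case(1, sex = "unknown", age = NA, reporter = "unknown",
                  country = "unknown")
  lt <- describe_cohort(dplyr::select(lone, -is_target))
  expect_identical(lt$pct[lt$characteristic == "sex" & lt$category == "unknown"], 100)
  expect_identical(lt$pct[lt$characteristic == "age" & lt$category == "unknown"], 100)

  none <- describe_cohort(lone[0, ])
  expect_true(all(is.na(none$pct)))
  expect_true(all(none$n == 0L))
})

test_that("annual counts cover the span with explicit zeros and conserve totals", {
  cases <- cases_tbl(
    mk_case(1, date = "2022-03-01"), mk_case(2, date = "2022-07-01"),
    mk_case(3, date = "2022-11-01"), mk_case(4, date = "2019-05-05")
  )
  ann <- annual_counts(cases)
  expect_identical(ann$year, 2019:2022)
  expect_identical(ann$n, c(1L, 0L, 0L, 3L))
  expect_identical(sum(ann$n), nrow(cases))
  expect_identical(nrow(annual_counts(cases[0, ])), 0L)

  # uniform dates: yearly counts within 3 sigma of n/19
  sim <- generate_reports(synthetic_config(n_cases = 5000, seed = 31,
                                           duplicate_rate = 0))
  ann2 <- annual_counts(sim$cases, years = 2005:2023)
  p <- 1 / 19
  sigma <- sqrt(5000 * p * (1 - p))
  expect_true(all(abs(ann2$n - 5000 * p) < 3 * sigma))
  expect_identical(sum(ann2$n), 5000L)
})

test_that("the gastro/other split classifies pairs and conserves totals", {
  dict <- mini_dict()
  cases <- cases_tbl(
    mk_case(1, date = "2019-02-02", events = c("vomiting", "anxiety")),
    mk_case(2, date = "2021-08-08", events = c("mystery term", "flatulence"))
  )
  split <- gi_split_counts(cases, dict)
  r2019 <- split[split$year == 2019, ]
  expect_identical(c(r2019$gi, r2019$other, r2019$total), c(1L, 1L, 2L))
  r2021 <- split[split$year == 2021, ]
  expect_identical(r2021$unmapped, 1L)   # unmapped counts under other, tallied
  expect_identical(r2021$other, 1L)
  expect_true(all(split$gi + split$other == split$total))
})

test_that("strata split at 18 years and exclude unknowns", {
  cases <- cases_tbl(
    mk_case(1, sex = "male", age = 17),
    mk_case(2, sex = "female", age = 18),
    mk_case(3, sex = "unknown", age = 19),
    mk_case(4, sex = "female", age = NA)
  )
  expect_identical(stratify(cases, "sex", "male")$primary_id, 1L)
  expect_identical(stratify(cases, "age", "minor")$primary_id, c(1L, 2L))
  expect_identical(stratify(cases, "age", "adult")$primary_id, 3L)
  # sex strata plus unknown partition the cohort
  expect_identical(nrow(stratify(cases, "sex", "male")) +
                     nrow(stratify(cases, "sex", "female")) +
                     sum(cases$sex == "unknown"), nrow(cases))
  expect_error(stratify(cases, "sex", "adult"), "male")
})

test_that("subgroup scans use a stratum-matched comparator and stay subset-bounded", {
  withr::with_seed(77, {
    n <- 400
    cases <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      mk_case(i, sex = sample(c("male", "female"), 1),
              age = sample(c(NA, 5:80), 1),
              events = sample(c("pt x", "pt y", "pt z"), sample(1:2, 1)),
              is_target = i <= 60)
    }))
  })
  overall <- scan_signals(cases, "pt")
  for (v in c("male", "female")) {
    sub <- subgroup_scan(cases, "sex", v, level = "pt")
    m <- dplyr::left_join(tibble::as_tibble(sub)[c("term", "a")],
                          tibble::as_tibble(overall)[c("term", "a")],
                          by = "term", suffix = c("_sub", "_all"))
    expect_true(all(m$a_sub <= m$a_all))
  }
  # complementary strata plus unknown-attribute cells recompose the overall a
  a_of <- function(sc, term) {
    v <- sc$a[sc$term == term]
    if (length(v) == 0) 0L else v
  }
  unknown_sex <- cases[cases$sex == "unknown" & cases$is_target, ]
  for (term in overall$term) {
    a_m <- a_of(subgroup_scan(cases, "sex", "male", level = "pt"), term)
    a_f <- a_of(subgroup_scan(cases, "sex", "female", level = "pt"), term)
    a_u <- sum(vapply(unknown_sex$events,
                      function(e) term %in% toupper(e), logical(1)))
    expect_identical(a_m + a_f + a_u, a_of(overall, term))
  }
  # an empty stratum yields an empty result with a warning
  kids <- cases[!is.na(cases$age_years) & cases$age_years <= 18 & !cases$is_target, ]
  expect_warning(empty <- subgroup_scan(kids, "age", "minor", level = "pt"),
                 "no target reports")
  expect_identical(nrow(empty), 0L)
})
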