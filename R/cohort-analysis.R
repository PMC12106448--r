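# Descriptive and stratified views of a deduplicated target cohort.

AGE_BAND_BREAKS <- c(-Inf, 20, 30, 40, 50, 60, 70, 80, Inf)
AGE_BAND_LABELS <- c("<20", "20~29", "30~39", "40~49", "50~59", "60~69",
                     "70~79", ">80")

age_band <- function(age_years) {
  band <- cut(age_years, breaks = AGE_BAND_BREAKS, labels = AGE_BAND_LABELS,
              right = FALSE)
  out <- as.character(band)
  out[is.na(age_years)] <- "unknown"
  out
}

count_block <- function(values, levels, denom) {
  n <- as.integer(table(factor(values, levels = levels)))
  tibble::tibble(category = levels, n = n,
                 pct = if (denom > 0) round_half_up(n / denom * 100, 2) else NA_real_)
}

#' Descriptive characteristics of a cohort
#'
#' Tabulates sex, age band, reporter, country, outcome and administration
#' route with counts and percentages, the layout of a clinical
#' characteristics table. Unknown categories are reported, never dropped.
#' Percentages are count/denominator x 100, rounded half-up to two decimals.
#' The denominator is the cohort size for every block except outcomes, where
#' it is the number of reports with at least one serious outcome (a report
#' with several outcome codes counts once per code).
#'
#' @param cases A deduplicated case tibble.
#' @return A tibble with columns `characteristic`, `category`, `n`, `pct`.
#' @export
#' @examples
#' counts <- readr::read_tsv(pvsignal_example("reference_cohort_counts.tsv"),
#'                           col_types = "cci")
#' describe_cohort(cohort_from_counts(counts))
describe_cohort <- function(cases) {
  n_total <- nrow(cases)
  outc_long <- unlist(cases$outcomes, use.names = FALSE)
  n_serious <- if (n_total > 0) sum(lengths(cases$outcomes) > 0) else 0L

  country_levels <- if (n_total > 0) {
    c(sort(setdiff(unique(cases$country), "unknown")),
      intersect("unknown", unique(cases$country)))
  } else character(0)

  blocks <- list(
    sex = count_block(cases$sex, c("male", "female", "unknown"), n_total),
    age = count_block(age_band(cases$age_years),
                      c(AGE_BAND_LABELS, "unknown"), n_total),
    reporter = count_block(cases$reporter,
                           c("consumer", "physician", "pharmacist", "other",
                             "unknown"), n_total),
    country = count_block(cases$country, country_levels, n_total),
    outcome = count_block(outc_long,
                          c("hospitalization", "life_threatening", "disability",
                            "death", "other_serious"), n_serious),
    route = count_block(cases$route, c("oral", "other"), n_total)
  )
  dplyr::bind_rows(blocks, .id = "characteristic")
}

#' Expand a characteristic count table into a case set
#'
#' Builds a cohort whose descriptive marginals equal the given counts, with
#' characteristics assigned independently (row order within each
#' characteristic is deterministic). Useful for reproducing a published
#' descriptive table from its printed counts.
#'
#' @param counts A tibble with columns `characteristic` (one of `sex`, `age`,
#'   `reporter`, `country`, `outcome`, `route`), `category`, `n`. All blocks
#'   except `outcome` must sum to the same cohort size; `outcome` counts are
#'   assigned one code per case from the first case on.
#' @param year Receipt year given to every case.
#' @return A case tibble of the common cohort size.
#' @export
cohort_from_counts <- function(counts, year = 2020) {
  blk <- function(ch) dplyr::filter(counts, .data$characteristic == ch)
  expand <- function(ch, size) {
    b <- blk(ch)
    v <- rep(b$category, b$n)
    if (length(v) > size) abort(paste0("Block '", ch, "' exceeds the cohort size."))
    c(v, rep(NA_character_, size - length(v)))
  }
  sizes <- vapply(c("sex", "age", "reporter", "country", "route"),
                  function(ch) sum(blk(ch)$n), double(1))
  if (length(unique(sizes)) != 1) {
    abort("sex/age/reporter/country/route blocks must sum to a common cohort size.")
  }
  size <- as.integer(sizes[[1]])
  age_rep <- c("<20" = 10, "20~29" = 25, "30~39" = 35, "40~49" = 45,
               "50~59" = 55, "60~69" = 65, "70~79" = 75, ">80" = 85)
  ages <- unname(age_rep[expand("age", size)])
  outc <- expand("outcome", size)
  tibble::tibble(
    primary_id = seq_len(size),
    case_id = seq_len(size),
    case_version = 1L,
    received_date = as.Date(paste0(year, "-06-30")),
    sex = expand("sex", size),
    age_years = as.double(ages),
    reporter = expand("reporter", size),
    country = expand("country", size),
    route = expand("route", size),
    outcomes = lapply(outc, function(o) if (is.na(o)) character(0) else o),
    drugs = rep(list(tibble::tibble(name_raw = "TARGET PRODUCT", role = "PS")), size),
    events = rep(list("adverse event"), size),
    is_target = TRUE
  )
}

#' Annual report counts
#'
#' @param cases A deduplicated case tibble.
#' @param years Integer vector of years to report; defaults to the full span
#'   observed in the data. Years without reports appear explicitly with 0.
#' @return A tibble with columns `year`, `n`.
#' @export
annual_counts <- function(cases, years = NULL) {
  yr <- as.integer(format(cases$received_date, "%Y"))
  if (is.null(years)) {
    years <- if (length(yr) == 0) integer(0) else seq(min(yr), max(yr))
  }
  tibble::tibble(year = as.integer(years),
                 n = as.integer(table(factor(yr, levels = years))))
}

#' Yearly gastrointestinal versus other event split
#'
#' Classifies each (report, PT) pair by whether its PT maps to the
#' gastrointestinal SOC, per receipt year. Unmapped PTs count under `other`
#' and are additionally tallied in `unmapped`.
#'
#' @param cases A deduplicated case tibble.
#' @param dict A `term_dictionary`.
#' @param years As in [annual_counts()].
#' @param gi_soc SOC name treated as gastrointestinal.
#' @return A tibble with columns `year`, `gi`, `other`, `total`, `unmapped`;
#'   `gi + other = total` in every row.
#' @export
gi_split_counts <- function(cases, dict, years = NULL,
                            gi_soc = "gastrointestinal disorders") {
  yr_case <- as.integer(format(cases$received_date, "%Y"))
  if (is.null(years)) {
    years <- if (length(yr_case) == 0) integer(0) else seq(min(yr_case), max(yr_case))
  }
  ne <- lengths(cases$events)
  pairs <- tibble::tibble(
    primary_id = rep(cases$primary_id, ne),
    year = rep(yr_case, ne),
    pt = norm_term(unlist(cases$events, use.names = FALSE))
  )
  pairs <- dplyr::distinct(pairs)
  soc <- map_pt_to_soc(dict, pairs$pt)
  pairs$gi <- !is.na(soc) & soc == norm_term(gi_soc)
  pairs$unmapped <- is.na(soc)
  fy <- factor(pairs$year, levels = years)
  tibble::tibble(
    year = as.integer(years),
    gi = as.integer(table(fy[pairs$gi])),
    other = as.integer(table(fy[!pairs$gi])),
    unmapped = as.integer(table(fy[pairs$unmapped]))
  ) |>
    dplyr::mutate(total = .data$gi + .data$other) |>
    dplyr::select("year", "gi", "other", "total", "unmapped")
}

#' Per-country report counts
#'
#' @param cases A deduplicated case tibble.
#' @return A tibble `country`, `n` sorted by descending count (the CSV behind
#'   a reporting-geography map).
#' @export
country_counts <- function(cases) {
  dplyr::arrange(dplyr::count(cases, .data$country), dplyr::desc(.data$n),
                 .data$country)
}

#' Restrict cases to a sex or age stratum
#'
#' Sex strata keep only the named sex; age strata split at 18 years with
#' `minor` meaning 18 or younger and `adult` strictly older. Reports with the
#' stratifying attribute unknown belong to no stratum.
#'
#' @param cases A case tibble.
#' @param axis `"sex"` or `"age"`.
#' @param value For sex: `"male"` or `"female"`; for age: `"adult"` or
#'   `"minor"`.
#' @return The subset of `cases` in the stratum.
#' @export
stratify <- function(cases, axis = c("sex", "age"), value) {
  axis <- match.arg(axis)
  if (axis == "sex") {
    if (!value %in% c("male", "female")) abort("Sex stratum must be 'male' or 'female'.")
    cases[cases$sex == value, ]
  } else {
    if (!value %in% c("adult", "minor")) abort("Age stratum must be 'adult' or 'minor'.")
    known <- !is.na(cases$age_years)
    if (value == "minor") cases[known & cases$age_years <= 18, ]
    else cases[known & cases$age_years > 18, ]
  }
}

#' Subgroup disproportionality scan
#'
#' Restricts both the target and the background reports to the stratum
#' (a stratum-matched comparator) and then runs [scan_signals()] unchanged.
#' With `comparator = "all"` the background stays unrestricted.
#'
#' @inheritParams scan_signals
#' @param axis,value Stratum, as in [stratify()].
#' @param comparator `"stratum"` (default) or `"all"`.
#' @return A `pv_scan` (empty, with a warning, if the stratum holds no
#'   target reports).
#' @export
subgroup_scan <- function(cases, axis, value, level = c("pt", "soc"),
                          dict = NULL, comparator = c("stratum", "all"),
                          ror_boundary = c("inclusive", "strict"),
                          haldane = FALSE) {
  comparator <- match.arg(comparator)
  require_is_target(cases)
  stratum <- stratify(cases, axis, value)
  sub <- if (comparator == "stratum") stratum else
    dplyr::bind_rows(dplyr::filter(stratum, .data$is_target),
                     dplyr::filter(cases, !.data$is_target))
  if (sum(sub$is_target) == 0) {
    warn(paste0("Stratum ", axis, "=", value, " holds no target reports."))
  }
  scan_signals(sub, level = level, dict = dict, ror_boundary = ror_boundary,
               haldane = haldane)
}

#' Line plot of annual report counts
#'
#' @param annual Output of [annual_counts()].
#' @return A ggplot object.
#' @export
plot_annual_counts <- function(annual) {
  ggplot2::ggplot(annual, ggplot2::aes(.data$year, .data$n)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "year", y = "case reports",
                  title = "Annual adverse event case reports") +
    ggplot2::theme_minimal()
}

#' Stacked bar plot of the gastrointestinal split
#'
#' @param split Output of [gi_split_counts()].
#' @return A ggplot object.
#' @export
plot_gi_split <- function(split) {
  long <- tidyr::pivot_longer(split, c("gi", "other"), names_to = "class",
                              values_to = "n")
  long$class <- c(gi = "gastrointestinal disorders",
                  other = "other adverse events")[long$class]
  ggplot2::ggplot(long, ggplot2::aes(.data$year, .data$n, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "year", y = "(report, PT) pairs", fill = NULL,
                  title = "Gastrointestinal versus other adverse events by year") +
    ggplot2::theme_minimal()
}
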