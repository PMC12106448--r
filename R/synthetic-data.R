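# Synthetic spontaneous-report generator with planted drug-event signals.
#
# Emulates the structure of a FAERS-style cohort: multi-version duplicate
# cases, one primary-suspect drug per report, 1-N event PTs drawn from a
# weighted vocabulary, demographic attributes with realistic missingness,
# and configurable planted associations whose recovery can be scored against
# the generated ground truth.

default_pt_vocabulary <- function() {
  path <- system.file("extdata", "synthetic_pt_vocabulary.tsv", package = "pvsignal")
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}

TARGET_DRUG_NAMES <- c("PROBIOTIC BLEND", "LACTOBACILLUS RHAMNOSUS GG",
                       "BIFIDOBACTERIUM LONGUM CAPSULE",
                       "SACCHAROMYCES BOULARDII", "Lactobacillus acidophilus tablet")
BACKGROUND_DRUG_NAMES <- c("ASPIRIN", "METFORMIN", "LISINOPRIL", "ATORVASTATIN",
                           "OMEPRAZOLE", "AMOXICILLIN", "IBUPROFEN",
                           "LEVOTHYROXINE", "LACTULOSE", "SERTRALINE")

# Mean of the geometric distribution truncated to {1, ..., max}.
truncated_geometric_mean <- function(p, max) {
  k <- seq_len(max)
  pmf <- p * (1 - p)^(k - 1)
  sum(k * pmf) / sum(pmf)
}

solve_truncgeom_p <- function(mean, max) {
  if (mean <= 1 || mean >= (max + 1) / 2) {
    abort("`events_per_report_dist` mean must lie in (1, (max+1)/2).")
  }
  uniroot(function(p) truncated_geometric_mean(p, max) - mean,
          c(1e-6, 1 - 1e-6), tol = 1e-12)$root
}

#' Configure the synthetic report generator
#'
#' Defaults reproduce the marginal structure of a published 74-report
#' probiotic cohort: sex 23%/55%/22% (male/female/unknown), 40.5% unknown
#' age with mass concentrated over 50, two thirds consumer-reported, two
#' thirds from the United States, a 51/49 oral/other route split, 38%
#' non-serious outcomes, and a truncated-geometric events-per-report count
#' on 1..10 with mean 3.85 (285 distinct PTs over 74 reports).
#'
#' @param n_cases Number of unique cases to generate.
#' @param p_target Probability that a case's primary-suspect drug is the
#'   target product.
#' @param pt_vocabulary Tibble with columns `pt`, `soc`.
#' @param background_pt_weights Non-negative weights over the vocabulary
#'   rows (default uniform); relative scale only.
#' @param events_per_report_dist Either
#'   `list(name = "truncated_geometric", mean =, max =)` (or `p =` in place
#'   of `mean`) or `list(name = "fixed", k =)`.
#' @param planted_signals Tibble with columns `pt`, `relative_risk`
#'   (multiplies the PT's background weight in target-drug reports before
#'   renormalization) and optionally `sex` (`NA` = applies to all target
#'   reports; `"male"`/`"female"` restricts the planting to that stratum).
#' @param sex_dist,reporter_dist,country_dist,outcome_dist,route_dist Named
#'   probability vectors (must sum to 1). `outcome_dist` is over
#'   `none`/`death`/`life_threatening`/`hospitalization`/`disability`/
#'   `other_serious`; each report receives at most one outcome code.
#' @param age_dist Tibble with columns `lo`, `hi`, `prob`; a row with `NA`
#'   bounds carries the unknown-age mass. Ages are integer-uniform within
#'   the sampled band.
#' @param duplicate_rate Probability that a case receives two or more
#'   versions (later versions perturb only date and reporter).
#' @param date_range Integer vector `c(start_year, end_year)`; receipt dates
#'   are uniform over the span.
#' @param seed Integer seed; generation is a pure function of
#'   (config, seed).
#' @return A validated `synthetic_config` list.
#' @export
#' @examples
#' cfg <- synthetic_config(n_cases = 500, seed = 7,
#'   planted_signals = tibble::tibble(pt = "flatulence", relative_risk = 10))
#' sim <- generate_reports(cfg)
#' sim$truth$realized_counts
synthetic_config <- function(n_cases,
                             p_target = 0.05,
                             pt_vocabulary = default_pt_vocabulary(),
                             background_pt_weights = NULL,
                             events_per_report_dist = list(name = "truncated_geometric",
                                                           mean = 285 / 74, max = 10),
                             planted_signals = tibble::tibble(pt = character(),
                                                              relative_risk = double()),
                             sex_dist = c(male = 17, female = 41, unknown = 16) / 74,
                             age_dist = tibble::tibble(
                               lo = c(0, 20, 30, 40, 50, 60, 70, 80, NA),
                               hi = c(19, 29, 39, 49, 59, 69, 79, 100, NA),
                               prob = c(11, 0, 1, 3, 6, 9, 11, 3, 30) / 74),
                             reporter_dist = c(consumer = 50, physician = 7,
                                               pharmacist = 7, other = 2, unknown = 8) / 74,
                             country_dist = c(united_states = 50, canada = 6,
                                              germany = 5, russia = 4, turkey = 3,
                                              south_korea = 3, algeria = 3) / 74,
                             outcome_dist = c(none = 28, hospitalization = 16,
                                              life_threatening = 3, disability = 2,
                                              death = 1, other_serious = 24) / 74,
                             route_dist = c(oral = 38, other = 36) / 74,
                             duplicate_rate = 0.10,
                             date_range = c(2005, 2023),
                             seed = 1L) {
  if (!is.numeric(n_cases) || n_cases < 1) abort("`n_cases` must be a positive integer.")
  if (p_target < 0 || p_target > 1) abort("`p_target` must lie in [0, 1].")
  if (duplicate_rate < 0 || duplicate_rate > 1) abort("`duplicate_rate` must lie in [0, 1].")
  if (!all(c("pt", "soc") %in% names(pt_vocabulary))) {
    abort("`pt_vocabulary` must have columns `pt` and `soc`.")
  }
  pt_vocabulary <- tibble::as_tibble(pt_vocabulary)
  if (is.null(background_pt_weights)) {
    background_pt_weights <- rep(1, nrow(pt_vocabulary))
  }
  if (length(background_pt_weights) != nrow(pt_vocabulary) ||
      any(background_pt_weights < 0) || sum(background_pt_weights) <= 0) {
    abort("`background_pt_weights` must be non-negative, not all zero, and match the vocabulary length.")
  }
  check_prob_vector(sex_dist, "sex_dist")
  check_prob_vector(reporter_dist, "reporter_dist")
  check_prob_vector(country_dist, "country_dist")
  check_prob_vector(outcome_dist, "outcome_dist")
  check_prob_vector(route_dist, "route_dist")
  if (any(age_dist$prob < 0) || abs(sum(age_dist$prob) - 1) > 1e-9) {
    abort("`age_dist` probabilities must be non-negative and sum to 1.")
  }
  planted_signals <- tibble::as_tibble(planted_signals)
  if (!"sex" %in% names(planted_signals)) {
    planted_signals$sex <- rep(NA_character_, nrow(planted_signals))
  }
  if (nrow(planted_signals) > 0) {
    if (any(!planted_signals$pt %in% pt_vocabulary$pt)) {
      abort("`planted_signals` contains PT(s) absent from `pt_vocabulary`.")
    }
    if (any(planted_signals$relative_risk < 0)) {
      abort("`planted_signals` relative_risk must be >= 0.")
    }
    bad_sex <- !is.na(planted_signals$sex) &
      !planted_signals$sex %in% c("male", "female")
    if (any(bad_sex)) abort("`planted_signals` sex must be NA, 'male' or 'female'.")
  }
  dist <- events_per_report_dist
  if (identical(dist$name, "truncated_geometric")) {
    if (is.null(dist$max)) abort("`events_per_report_dist` needs a `max`.")
    if (is.null(dist$p)) {
      if (is.null(dist$mean)) abort("`events_per_report_dist` needs `p` or `mean`.")
      dist$p <- solve_truncgeom_p(dist$mean, dist$max)
    }
  } else if (identical(dist$name, "fixed")) {
    if (is.null(dist$k) || dist$k < 1) abort("`events_per_report_dist` fixed spec needs `k` >= 1.")
  } else {
    abort("`events_per_report_dist` name must be 'truncated_geometric' or 'fixed'.")
  }
  if (length(date_range) != 2 || date_range[1] > date_range[2]) {
    abort("`date_range` must be c(start_year, end_year) with start <= end.")
  }
  structure(list(
    n_cases = as.integer(n_cases), p_target = p_target,
    pt_vocabulary = pt_vocabulary,
    background_pt_weights = background_pt_weights,
    events_per_report_dist = dist,
    planted_signals = planted_signals,
    sex_dist = sex_dist, age_dist = age_dist, reporter_dist = reporter_dist,
    country_dist = country_dist, outcome_dist = outcome_dist,
    route_dist = route_dist, duplicate_rate = duplicate_rate,
    date_range = as.integer(date_range), seed = as.integer(seed)
  ), class = "synthetic_config")
}

sample_events_k <- function(dist, n) {
  if (dist$name == "fixed") return(rep(as.integer(dist$k), n))
  k <- seq_len(dist$max)
  pmf <- dist$p * (1 - dist$p)^(k - 1)
  sample(k, n, replace = TRUE, prob = pmf)
}

# Weighted sampling without replacement via the Gumbel-top-k race, vectorized
# over all reports in a group sharing one weight vector.
sample_pt_sets <- function(pt_names, w, k) {
  m <- length(k)
  V <- length(pt_names)
  if (m == 0) return(list())
  k <- pmin(k, sum(w > 0))
  key <- matrix(-log(-log(runif(m * V))), m, V)
  key <- sweep(key, 2, log(w), `+`)
  row <- rep(seq_len(m), times = V)
  vidx <- rep(seq_len(V), each = m)
  ord <- order(row, -as.vector(key))
  sel <- rep(seq_len(V), m) <= k[rep(seq_len(m), each = V)]
  split(pt_names[vidx[ord][sel]], factor(row[ord][sel], levels = seq_len(m)))
}

sample_ages <- function(age_dist, n) {
  band <- sample.int(nrow(age_dist), n, replace = TRUE, prob = age_dist$prob)
  lo <- age_dist$lo[band]
  hi <- age_dist$hi[band]
  age <- lo + floor(runif(n) * (hi - lo + 1))
  age[is.na(lo)] <- NA_real_
  as.double(age)
}

#' Generate a synthetic case set with known ground truth
#'
#' Draws `n_cases` unique cases from the configured marginals. Target-drug
#' reports draw their events from the background PT weights with each
#' planted PT's weight multiplied by its relative risk (then renormalized);
#' background reports use the unmodified weights. A configurable fraction of
#' cases receives additional versions that perturb only the receipt date and
#' reporter, so deduplication correctness is checkable. Identical config and
#' seed yield identical output.
#'
#' @param config A `synthetic_config`.
#' @return A list with `cases` (the case tibble, including duplicate
#'   versions, in the schema of [assemble_cases()]) and `truth` (class
#'   `pv_truth`: the planted signals, per-(drug class, PT) realized pair
#'   counts over unique cases, and the seed).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_reports_impl(config))
}

generate_reports_impl <- function(config) {
  n <- config$n_cases
  vocab <- config$pt_vocabulary
  is_target <- runif(n) < config$p_target
  sex <- sample_cat(config$sex_dist, n)
  age <- sample_ages(config$age_dist, n)
  reporter <- sample_cat(config$reporter_dist, n)
  country <- sample_cat(config$country_dist, n)
  outcome <- sample_cat(config$outcome_dist, n)
  route <- sample_cat(config$route_dist, n)
  start <- as.Date(paste0(config$date_range[1], "-01-01"))
  end <- as.Date(paste0(config$date_range[2], "-12-31"))
  received <- start + floor(runif(n) * (as.integer(end - start) + 1))
  k <- sample_events_k(config$events_per_report_dist, n)

  # event sets: one weight vector per (target status x applicable plantings)
  w0 <- config$background_pt_weights
  planted <- config$planted_signals
  events <- vector("list", n)
  grp_key <- ifelse(is_target,
                    paste0("t:", ifelse(sex %in% planted$sex[!is.na(planted$sex)], sex, "")),
                    "bg")
  for (key in unique(grp_key)) {
    idx <- which(grp_key == key)
    w <- w0
    if (key != "bg") {
      gsex <- sub("^t:", "", key)
      rows <- which(is.na(planted$sex) | (nzchar(gsex) & planted$sex == gsex))
      for (r in rows) {
        w[vocab$pt == planted$pt[r]] <- w[vocab$pt == planted$pt[r]] * planted$relative_risk[r]
      }
    }
    events[idx] <- sample_pt_sets(vocab$pt, w, k[idx])
  }

  # drugs: one PS row, plus an occasional concomitant
  ps_name <- ifelse(is_target,
                    sample(TARGET_DRUG_NAMES, n, replace = TRUE),
                    sample(BACKGROUND_DRUG_NAMES, n, replace = TRUE))
  has_conc <- runif(n) < 0.3
  conc_name <- sample(BACKGROUND_DRUG_NAMES, n, replace = TRUE)
  drug_long <- tibble::tibble(
    case = c(seq_len(n), which(has_conc)),
    name_raw = c(ps_name, conc_name[has_conc]),
    role = c(rep("PS", n), rep("C", sum(has_conc)))
  )
  drug_long <- drug_long[order(drug_long$case, drug_long$role != "PS"), ]
  drugs <- unname(split(drug_long[c("name_raw", "role")],
                        factor(drug_long$case, levels = seq_len(n))))

  cases <- tibble::tibble(
    primary_id = NA_integer_,
    case_id = seq_len(n),
    case_version = 1L,
    received_date = received,
    sex = sex,
    age_years = age,
    reporter = reporter,
    country = country,
    route = route,
    outcomes = lapply(outcome, function(o) if (o == "none") character(0) else o),
    drugs = drugs,
    events = events
  )

  # duplicate versions: same case_id, higher version, later date, new reporter
  dup <- runif(n) < config$duplicate_rate
  if (any(dup)) {
    n_extra <- 1L + (runif(sum(dup)) < 0.25)
    src <- rep(which(dup), n_extra)
    ver <- unlist(lapply(n_extra, function(e) seq_len(e) + 1L), use.names = FALSE)
    extra <- cases[src, ]
    extra$case_version <- ver
    inc <- sample(30:400, length(src), replace = TRUE)
    extra$received_date <- extra$received_date +
      stats::ave(inc, src, FUN = cumsum)  # dates increase with version
    extra$reporter <- sample_cat(config$reporter_dist, length(src))
    cases <- dplyr::bind_rows(cases, extra)
  }
  cases <- dplyr::arrange(cases, .data$case_id, .data$case_version)
  cases$primary_id <- seq_len(nrow(cases))
  cases$is_target_truth <- rep(is_target, times = tabulate(cases$case_id, n))

  # ground truth: (drug class, pt) pair counts over unique cases
  realized <- tibble::tibble(
    drug_class = ifelse(rep(is_target, k), "target", "background"),
    pt = unlist(events, use.names = FALSE)
  )
  realized <- dplyr::count(realized, .data$drug_class, .data$pt, name = "n")
  realized <- tidyr::complete(realized,
                              drug_class = c("target", "background"),
                              pt = vocab$pt, fill = list(n = 0L))
  truth <- structure(list(planted_signals = planted,
                          realized_counts = realized,
                          seed = config$seed),
                     class = "pv_truth")
  list(cases = cases, truth = truth)
}

#' @export
print.pv_truth <- function(x, ...) {
  cat("<pv_truth> seed ", x$seed, "; ", nrow(x$planted_signals),
      " planted signal(s)\n", sep = "")
  if (nrow(x$planted_signals) > 0) print(x$planted_signals)
  invisible(x)
}

REV_SEX <- c(male = "M", female = "F", unknown = "")
REV_OCCP <- c(consumer = "CN", physician = "MD", pharmacist = "PH",
              other = "OT", unknown = "")
REV_OUTC <- c(death = "DE", life_threatening = "LT", hospitalization = "HO",
              disability = "DS", other_serious = "OT")

#' Write a case set as FAERS-dialect quarterly files
#'
#' Emits dollar-delimited DEMO/DRUG/REAC/OUTC text files with header rows.
#' Reading them back through [read_quarter()] and [assemble_cases()]
#' reproduces the case set field for field.
#'
#' @param cases A case tibble (every report must carry at least one event).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_faers_dialect <- function(cases, dir) {
  if (nrow(cases) == 0) abort("Refusing to write an empty case set.")
  if (any(lengths(cases$events) == 0)) {
    abort("Case set contains report(s) with no events; these are invalid.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("Cannot create directory ", dir))
  fmt_age <- function(x) ifelse(is.na(x), "", format(x, digits = 15, trim = TRUE))

  demo <- paste(cases$primary_id, cases$case_id, cases$case_version,
                format(cases$received_date, "%Y%m%d"),
                fmt_age(cases$age_years),
                ifelse(is.na(cases$age_years), "", "YR"),
                unname(REV_SEX[cases$sex]),
                unname(REV_OCCP[cases$reporter]),
                ifelse(cases$country == "unknown", "", cases$country),
                sep = "$")

  nd <- vapply(cases$drugs, nrow, integer(1))
  d_pid <- rep(cases$primary_id, nd)
  d_cid <- rep(cases$case_id, nd)
  d_route <- rep(toupper(cases$route), nd)
  d_name <- unlist(lapply(cases$drugs, `[[`, "name_raw"), use.names = FALSE)
  d_role <- unlist(lapply(cases$drugs, `[[`, "role"), use.names = FALSE)
  d_seq <- sequence(nd)
  drug <- paste(d_pid, d_cid, d_seq, d_role, d_name,
                ifelse(d_role == "PS", d_route, ""), sep = "$")

  ne <- lengths(cases$events)
  reac <- paste(rep(cases$primary_id, ne), rep(cases$case_id, ne),
                unlist(cases$events, use.names = FALSE), sep = "$")

  no <- lengths(cases$outcomes)
  outc <- paste(rep(cases$primary_id, no), rep(cases$case_id, no),
                unname(REV_OUTC[unlist(cases$outcomes, use.names = FALSE)]),
                sep = "$")

  paths <- c(demo = file.path(dir, "DEMO.txt"), drug = file.path(dir, "DRUG.txt"),
             reac = file.path(dir, "REAC.txt"), outc = file.path(dir, "OUTC.txt"))
  readr::write_lines(c(paste(DEMO_COLS, collapse = "$"), demo), paths[["demo"]])
  readr::write_lines(c(paste(DRUG_COLS, collapse = "$"), drug), paths[["drug"]])
  readr::write_lines(c(paste(REAC_COLS, collapse = "$"), reac), paths[["reac"]])
  readr::write_lines(c(paste(OUTC_COLS, collapse = "$"), outc), paths[["outc"]])
  invisible(paths)
}
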