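# Shared fixtures: a minimal case-row builder and an independently coded
# scalar oracle for the three disproportionality statistics.

mk_case <- function(primary_id, case_id = primary_id, version = 1L,
                    date = "2020-01-01", sex = "unknown", age = NA_real_,
                    reporter = "unknown", country = "unknown", route = "other",
                    outcomes = character(0),
                    drugs = tibble::tibble(name_raw = "DRUG X", role = "PS"),
                    events = "headache", is_target = NA) {
  tibble::tibble(
    primary_id = as.integer(primary_id), case_id = as.integer(case_id),
    case_version = as.integer(version), received_date = as.Date(date),
    sex = sex, age_years = as.double(age), reporter = reporter,
    country = country, route = route,
    outcomes = list(outcomes), drugs = list(drugs), events = list(events),
    is_target = is_target
  )
}

cases_tbl <- function(...) dplyr::bind_rows(...)

target_drug <- function() tibble::tibble(name_raw = "PROBIOTIC BLEND", role = "PS")
other_drug <- function() tibble::tibble(name_raw = "ASPIRIN", role = "PS")

mini_dict <- function() load_term_dictionary(pvsignal_example("meddra_mini.tsv"))
vocab_dict <- function() load_term_dictionary(pvsignal_example("synthetic_pt_vocabulary.tsv"))
probiotic_lex <- function() load_drug_lexicon(pvsignal_example("probiotic_lexicon.txt"))

# Scalar, loop-free-of-the-package transcription of the three formulas: the
# brute-force oracle the vectorized implementation is checked against.
oracle_stats <- function(a, b, c, d) {
  # doubles throughout: the chi-squared denominator overflows 32-bit integers
  a <- as.double(a); b <- as.double(b); c <- as.double(c); d <- as.double(d)
  N <- a + b + c + d
  z <- qnorm(0.975)
  ror <- (a * d) / (b * c)
  se_ror <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  prr <- (a / (a + b)) / (c / (c + d))
  se_prr <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  chi2 <- N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  ebgm <- a * N / ((a + b) * (a + c))
  list(ror = ror,
       ror_lo = exp(log(ror) - z * se_ror), ror_hi = exp(log(ror) + z * se_ror),
       prr = prr,
       prr_lo = exp(log(prr) - z * se_prr), prr_hi = exp(log(prr) + z * se_prr),
       chi2 = chi2,
       ebgm = ebgm, ebgm05 = exp(log(ebgm) - z * se_ror))
}

random_tables <- function(n, seed, max_cell = 1e4) {
  withr::with_seed(seed, tibble::tibble(
    a = sample.int(max_cell, n, replace = TRUE),
    b = sample.int(max_cell, n, replace = TRUE),
    c = sample.int(max_cell, n, replace = TRUE),
    d = sample.int(max_cell, n, replace = TRUE)
  ))
}

rel_err <- function(x, y) abs(x - y) / pmax(abs(y), .Machine$double.eps)

# Generator settings used by the recovery studies: one PT planted at a given
# relative risk over a background weight of 0.02, everything else uniform.
recovery_config <- function(seed, n_cases = 20000, p_target = 0.05,
                            planted_pt = "flatulence", relative_risk = 10,
                            planted_weight = 0.02, sex = NA_character_) {
  vocab <- readr::read_tsv(pvsignal_example("synthetic_pt_vocabulary.tsv"),
                           col_types = "cc", progress = FALSE)
  w <- rep((1 - planted_weight) / (nrow(vocab) - 1), nrow(vocab))
  w[vocab$pt == planted_pt] <- planted_weight
  synthetic_config(
    n_cases = n_cases, p_target = p_target, seed = seed,
    pt_vocabulary = vocab, background_pt_weights = w,
    planted_signals = tibble::tibble(pt = planted_pt,
                                     relative_risk = relative_risk,
                                     sex = sex)
  )
}
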