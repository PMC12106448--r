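# Disproportionality statistics on the 2x2 contingency table
#
#   a : (report, term) units with the target drug and the term of interest
#   b : units with the target drug and any other term
#   c : units with background drugs and the term
#   d : units with background drugs and other terms
#
# The counting unit is the (report, term) pair: one report contributes each
# of its distinct PTs once, and at SOC level each distinct SOC once, however
# many of its PTs map there. All three statistics return NA ("undefined") --
# never a fabricated zero -- when a required cell is empty; signal flags
# treat undefined statistics as negative.

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ROR = (a d) / (b c)` with the 95% interval
#' `exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. All four cells must be
#' positive for a defined value; with `haldane = TRUE` a 0.5 continuity
#' correction is added to every cell of tables containing a zero.
#'
#' @param a,b,c,d Integer vectors (recycled to a common length): the 2x2 cells.
#' @param conf_level Confidence level for the interval.
#' @param haldane Apply the Haldane-Anscombe 0.5 correction to zero-cell
#'   tables instead of returning `NA`.
#' @return A tibble with columns `ror`, `ror_lo`, `ror_hi` (`NA` when
#'   undefined).
#' @export
#' @examples
#' ror_with_ci(10, 90, 100, 9900)
ror_with_ci <- function(a, b, c, d, conf_level = 0.95, haldane = FALSE) {
  n <- max(length(a), length(b), length(c), length(d))
  cells <- vctrs_recycle(a, b, c, d, n = n)
  a <- cells[[1]]; b <- cells[[2]]; c <- cells[[3]]; d <- cells[[4]]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (haldane) {
    a <- a + 0.5 * zero; b <- b + 0.5 * zero; c <- c + 0.5 * zero; d <- d + 0.5 * zero
    ok <- rep(TRUE, n)
  } else {
    ok <- !zero
  }
  ror <- ifelse(ok, (a * d) / (b * c), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tibble::tibble(ror = ror,
                 ror_lo = exp(log(ror) - z * se),
                 ror_hi = exp(log(ror) + z * se))
}

#' Proportional reporting ratio with chi-squared statistic
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`, the chi-squared (1 df, no continuity
#' correction) `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with `N = a+b+c+d`,
#' and a log-scale interval with delta-method standard error
#' `sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`. `PRR` is `NA` when `c = 0` or a
#' margin is empty; it is 0 (with `NA` interval) when `a = 0`.
#'
#' @inheritParams ror_with_ci
#' @return A tibble with columns `prr`, `prr_lo`, `prr_hi`, `chi2`.
#' @export
#' @examples
#' prr_with_chi2(10, 90, 100, 9900)
prr_with_chi2 <- function(a, b, c, d, conf_level = 0.95) {
  n <- max(length(a), length(b), length(c), length(d))
  cells <- vctrs_recycle(a, b, c, d, n = n)
  a <- cells[[1]]; b <- cells[[2]]; c <- cells[[3]]; d <- cells[[4]]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  N <- a + b + c + d
  ok <- (a + b) > 0 & c > 0 & (c + d) > 0
  prr <- ifelse(ok, (a / (a + b)) / (c / (c + d)), NA_real_)
  ci_ok <- ok & a > 0
  se <- ifelse(ci_ok, sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)), NA_real_)
  chi_ok <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  chi2 <- ifelse(chi_ok,
                 N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d)),
                 NA_real_)
  tibble::tibble(prr = prr,
                 prr_lo = ifelse(ci_ok, exp(log(prr) - z * se), NA_real_),
                 prr_hi = ifelse(ci_ok, exp(log(prr) + z * se), NA_real_),
                 chi2 = chi2)
}

#' Relative reporting ratio (EBGM) with lognormal lower bound
#'
#' The observed-to-expected reporting ratio `EBGM = a N / ((a+b)(a+c))` with
#' `N = a+b+c+d`, and the 95% interval
#' `exp(log EBGM +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`; `EBGM05` is the
#' lower bound used by the signal criterion. This is the unshrunk
#' relative reporting ratio; the full gamma-Poisson shrinkage of MGPS is
#' deliberately not implemented (see the methods vignette).
#'
#' @inheritParams ror_with_ci
#' @return A tibble with columns `ebgm`, `ebgm05`, `ebgm95`.
#' @export
#' @examples
#' ebgm_with_ci(10, 90, 100, 9900)
ebgm_with_ci <- function(a, b, c, d, conf_level = 0.95) {
  n <- max(length(a), length(b), length(c), length(d))
  cells <- vctrs_recycle(a, b, c, d, n = n)
  a <- cells[[1]]; b <- cells[[2]]; c <- cells[[3]]; d <- cells[[4]]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  N <- a + b + c + d
  ok <- (a + b) > 0 & (a + c) > 0 & (c + d) > 0 & (b + d) > 0
  ebgm <- ifelse(ok, a * N / ((a + b) * (a + c)), NA_real_)
  ci_ok <- ok & a > 0 & b > 0 & c > 0 & d > 0
  se <- ifelse(ci_ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tibble::tibble(ebgm = ebgm,
                 ebgm05 = ifelse(ci_ok, exp(log(ebgm) - z * se), NA_real_),
                 ebgm95 = ifelse(ci_ok, exp(log(ebgm) + z * se), NA_real_))
}

# recycle scalars against vectors
vctrs_recycle <- function(..., n) {
  lapply(list(...), function(x) {
    if (length(x) == n) as.double(x)
    else if (length(x) == 1) rep(as.double(x), n)
    else abort("Cell vectors must have length 1 or a common length.")
  })
}

#' Evaluate joint signal criteria
#'
#' Applies the three per-algorithm positive-signal criteria and their
#' conjunction to a table of computed statistics:
#' * ROR: `n >= 3` and lower CI bound `>= 1` (boundary inclusive by default,
#'   settable to strict `> 1`);
#' * PRR: `n >= 3`, `PRR >= 2` and `chi2 >= 4`;
#' * EBGM: `EBGM05 > 2`.
#'
#' Undefined (`NA`) statistics never fire a flag.
#'
#' @param stats A data frame with columns `n` (the a-cell count), `ror_lo`,
#'   `prr`, `chi2`, `ebgm05`.
#' @param ror_boundary `"inclusive"` (`ror_lo >= 1`) or `"strict"`
#'   (`ror_lo > 1`).
#' @return The input tibble with logical columns `flag_ror`, `flag_prr`,
#'   `flag_ebgm` and their conjunction `flag_all` appended.
#' @export
#' @examples
#' evaluate_signal(tibble::tibble(
#'   n = c(7, 97), ror_lo = c(1.21, 4.15), prr = c(2.11, 3.84),
#'   chi2 = c(4.15, 223.12), ebgm05 = c(1.13, 3.12)))
evaluate_signal <- function(stats, ror_boundary = c("inclusive", "strict")) {
  ror_boundary <- match.arg(ror_boundary)
  need <- c("n", "ror_lo", "prr", "chi2", "ebgm05")
  missing <- setdiff(need, names(stats))
  if (length(missing) > 0) {
    abort(paste0("`stats` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  stats <- tibble::as_tibble(stats)
  ror_ok <- if (ror_boundary == "inclusive") stats$ror_lo >= 1 else stats$ror_lo > 1
  flag_ror <- !is.na(stats$ror_lo) & stats$n >= 3 & ror_ok
  flag_prr <- !is.na(stats$prr) & !is.na(stats$chi2) &
    stats$n >= 3 & stats$prr >= 2 & stats$chi2 >= 4
  flag_ebgm <- !is.na(stats$ebgm05) & stats$ebgm05 > 2
  dplyr::mutate(stats,
                flag_ror = flag_ror,
                flag_prr = flag_prr,
                flag_ebgm = flag_ebgm,
                flag_all = flag_ror & flag_prr & flag_ebgm)
}

# Long (report, term) pair table at the requested level. One row per distinct
# (report, term); unmapped PTs are dropped at SOC level and tallied in the
# "n_unmapped_pairs" attribute.
term_pairs <- function(cases, dict = NULL, level = c("pt", "soc")) {
  level <- match.arg(level)
  pairs <- tibble::tibble(
    primary_id = rep(cases$primary_id, lengths(cases$events)),
    is_target = rep(cases$is_target, lengths(cases$events)),
    term = norm_term(unlist(cases$events, use.names = FALSE))
  )
  n_unmapped <- 0L
  if (level == "soc") {
    if (is.null(dict)) abort("A term dictionary is required at SOC level.")
    pairs$term <- map_pt_to_soc(dict, pairs$term)
    n_unmapped <- sum(is.na(pairs$term))
    pairs <- dplyr::filter(pairs, !is.na(.data$term))
  }
  pairs <- dplyr::distinct(pairs, .data$primary_id, .data$is_target, .data$term)
  attr(pairs, "n_unmapped_pairs") <- n_unmapped
  pairs
}

require_is_target <- function(cases) {
  if (!"is_target" %in% names(cases)) {
    abort("`cases` must carry an `is_target` column; run flag_target_reports() first.")
  }
  invisible(cases)
}

#' Build a 2x2 contingency table for one term
#'
#' Counts (report, term) units among target and background reports for a
#' single PT or SOC. Each report contributes each of its distinct PTs once;
#' at SOC level each distinct mapped SOC once, regardless of how many of the
#' report's PTs map there.
#'
#' @param cases A deduplicated case tibble carrying `is_target` (see
#'   [flag_target_reports()]).
#' @param term The PT or SOC of interest (case/whitespace-insensitive).
#' @param level `"pt"` or `"soc"`.
#' @param dict A `term_dictionary`; required at SOC level.
#' @return A one-row tibble with columns `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(cases, term, level = c("pt", "soc"), dict = NULL) {
  level <- match.arg(level)
  require_is_target(cases)
  term <- norm_term(term)
  if (level == "soc" && !is.null(dict) && !(term %in% dict$pt_to_soc)) {
    abort(paste0("SOC '", term, "' is not in the dictionary's SOC set."))
  }
  pairs <- term_pairs(cases, dict, level)
  tot <- table(factor(pairs$is_target, levels = c(FALSE, TRUE)))
  hit <- pairs$term == term
  a <- sum(hit & pairs$is_target)
  c <- sum(hit & !pairs$is_target)
  tibble::tibble(a = a, b = as.integer(tot[["TRUE"]]) - a,
                 c = c, d = as.integer(tot[["FALSE"]]) - c)
}

#' Scan all terms for disproportionate reporting
#'
#' Builds the 2x2 table for every term observed among target reports at the
#' requested level and computes ROR, PRR with chi-squared, and EBGM with
#' their intervals and signal flags. Rows are sorted by descending ROR
#' (undefined last), ties and undefined rows alphabetically by term.
#'
#' @inheritParams build_contingency
#' @param ror_boundary Passed to [evaluate_signal()].
#' @param haldane Passed to [ror_with_ci()].
#' @return A `pv_scan` tibble: one row per term with columns `term`, `level`,
#'   `n` (= a), `a`, `b`, `c`, `d`, the three statistics blocks and the four
#'   flags. Metadata (level, report totals, unmapped-pair tally) is attached
#'   as attributes and surfaced by [glance.pv_scan()].
#' @seealso [evaluate_signal()], [subgroup_scan()], [autoplot.pv_scan()]
#' @export
scan_signals <- function(cases, level = c("pt", "soc"), dict = NULL,
                         ror_boundary = c("inclusive", "strict"),
                         haldane = FALSE) {
  level <- match.arg(level)
  require_is_target(cases)
  pairs <- term_pairs(cases, dict, level)
  tgt <- dplyr::count(dplyr::filter(pairs, .data$is_target), .data$term, name = "a")
  if (nrow(tgt) == 0) {
    out <- empty_scan(level)
  } else {
    bg <- dplyr::count(dplyr::filter(pairs, !.data$is_target), .data$term, name = "c")
    tot_t <- sum(tgt$a)
    tot_b <- sum(bg$c)
    tab <- dplyr::left_join(tgt, bg, by = "term")
    tab$c[is.na(tab$c)] <- 0L
    tab <- dplyr::mutate(tab, b = tot_t - .data$a, d = tot_b - .data$c)
    out <- dplyr::bind_cols(
      tibble::tibble(term = tab$term, level = toupper(level), n = tab$a,
                     a = tab$a, b = tab$b, c = tab$c, d = tab$d),
      ror_with_ci(tab$a, tab$b, tab$c, tab$d, haldane = haldane),
      prr_with_chi2(tab$a, tab$b, tab$c, tab$d),
      ebgm_with_ci(tab$a, tab$b, tab$c, tab$d)
    )
    out <- evaluate_signal(out, ror_boundary = ror_boundary)
    out <- dplyr::arrange(out, is.na(.data$ror), dplyr::desc(.data$ror), .data$term)
  }
  n_case <- if (nrow(cases) > 0) c(sum(cases$is_target), sum(!cases$is_target)) else c(0L, 0L)
  structure(out,
            class = c("pv_scan", class(out)),
            level = toupper(level),
            n_target_reports = n_case[1],
            n_background_reports = n_case[2],
            n_unmapped_pairs = attr(pairs, "n_unmapped_pairs"),
            ror_boundary = match.arg(ror_boundary))
}

empty_scan <- function(level) {
  tibble::tibble(term = character(), level = character(), n = integer(),
                 a = integer(), b = integer(), c = integer(), d = integer(),
                 ror = double(), ror_lo = double(), ror_hi = double(),
                 prr = double(), prr_lo = double(), prr_hi = double(),
                 chi2 = double(),
                 ebgm = double(), ebgm05 = double(), ebgm95 = double(),
                 flag_ror = logical(), flag_prr = logical(),
                 flag_ebgm = logical(), flag_all = logical())
}

#' @export
print.pv_scan <- function(x, ...) {
  cat("# Disproportionality scan (", attr(x, "level"), " level): ",
      nrow(x), " terms, ", sum(x$flag_all), " meeting all three criteria\n",
      "# target reports: ", attr(x, "n_target_reports"),
      "; background reports: ", attr(x, "n_background_reports"), "\n", sep = "")
  NextMethod()
}

#' Tidy a disproportionality scan
#'
#' @param x A `pv_scan`.
#' @param ... Unused.
#' @return The scan as a plain tibble (one row per term).
#' @importFrom generics tidy
#' @export
tidy.pv_scan <- function(x, ...) {
  tibble::as_tibble(unclass_scan(x))
}

#' One-row summary of a disproportionality scan
#'
#' @param x A `pv_scan`.
#' @param ... Unused.
#' @return A one-row tibble: level, term and report totals, pair counts, the
#'   number of terms flagged by each algorithm and by all three jointly.
#' @importFrom generics glance
#' @export
glance.pv_scan <- function(x, ...) {
  tibble::tibble(
    level = attr(x, "level"),
    n_terms = nrow(x),
    n_target_reports = attr(x, "n_target_reports"),
    n_background_reports = attr(x, "n_background_reports"),
    n_target_pairs = if (nrow(x) > 0) x$a[1] + x$b[1] else 0L,
    n_unmapped_pairs = attr(x, "n_unmapped_pairs"),
    n_flag_ror = sum(x$flag_ror),
    n_flag_prr = sum(x$flag_prr),
    n_flag_ebgm = sum(x$flag_ebgm),
    n_flag_all = sum(x$flag_all)
  )
}

unclass_scan <- function(x) {
  class(x) <- setdiff(class(x), "pv_scan")
  attr(x, "level") <- NULL
  attr(x, "n_target_reports") <- NULL
  attr(x, "n_background_reports") <- NULL
  attr(x, "n_unmapped_pairs") <- NULL
  attr(x, "ror_boundary") <- NULL
  x
}

#' Volcano-style coordinates for a scan
#'
#' @param scan A `pv_scan`.
#' @return A tibble with `term`, `log2_ror`, `neg_log10_p` (upper-tail
#'   probability of the chi-squared statistic, 1 df) and `flag_all`, suitable
#'   for a volcano plot or CSV export.
#' @export
volcano_table <- function(scan) {
  tibble::tibble(
    term = scan$term,
    log2_ror = log2(scan$ror),
    neg_log10_p = -log10(pchisq(scan$chi2, df = 1, lower.tail = FALSE)),
    flag_all = scan$flag_all
  )
}

#' Volcano plot of a disproportionality scan
#'
#' @param object A `pv_scan`.
#' @param label_flagged Label the terms meeting all three criteria.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.pv_scan <- function(object, label_flagged = TRUE, ...) {
  df <- dplyr::filter(volcano_table(object), is.finite(.data$log2_ror),
                      is.finite(.data$neg_log10_p))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$log2_ror, .data$neg_log10_p,
                                        colour = .data$flag_all)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick"),
                                 name = "all criteria") +
    ggplot2::labs(x = "log2 reporting odds ratio",
                  y = "-log10 p (chi-squared)",
                  title = paste0("Disproportionality scan (",
                                 attr(object, "level"), " level)")) +
    ggplot2::theme_minimal()
  if (label_flagged && any(df$flag_all)) {
    p <- p + ggplot2::geom_text(
      data = dplyr::filter(df, .data$flag_all),
      ggplot2::aes(label = .data$term),
      vjust = -0.7, size = 3, show.legend = FALSE)
  }
  p
}

#' Render a scan for export
#'
#' Two-decimal presentation columns alongside the full-precision values, in
#' the column layout of published disproportionality tables.
#'
#' @param scan A `pv_scan`.
#' @return A tibble with rendered `*_2dp` companion columns.
#' @export
format_scan <- function(scan) {
  num <- c("ror", "ror_lo", "ror_hi", "prr", "prr_lo", "prr_hi",
           "chi2", "ebgm", "ebgm05")
  out <- tibble::as_tibble(unclass_scan(scan))
  for (col in num) out[[paste0(col, "_2dp")]] <- round_half_up(out[[col]], 2)
  out
}
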