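# End-to-end orchestration: generate/read -> assemble -> deduplicate ->
# partition -> scan -> subgroups -> descriptives, with a run manifest.

#' Assemble a pipeline run configuration
#'
#' @param input `"synthetic"` or `"faers_dir"` (exactly one input mode).
#' @param faers_dir Directory of dollar-delimited quarterly files
#'   (`input = "faers_dir"`).
#' @param synthetic A `synthetic_config` (`input = "synthetic"`).
#' @param dictionary,lexicon Paths to the term dictionary and target-drug
#'   lexicon files.
#' @param levels Analysis levels, a subset of `c("pt", "soc")`.
#' @param subgroup_axes Subset of `c("sex", "age")`.
#' @param out_dir Output directory for tables and the manifest.
#' @param seed Optional integer overriding the synthetic config's seed
#'   (required in synthetic mode if the synthetic config carries none).
#' @param ror_boundary,haldane,comparator Criteria switches passed through to
#'   [scan_signals()] and [subgroup_scan()].
#' @return A `run_config` list.
#' @export
pipeline_config <- function(input = c("synthetic", "faers_dir"),
                            faers_dir = NULL, synthetic = NULL,
                            dictionary, lexicon,
                            levels = c("pt", "soc"),
                            subgroup_axes = c("sex", "age"),
                            out_dir, seed = NULL,
                            ror_boundary = "inclusive", haldane = FALSE,
                            comparator = "stratum") {
  input <- match.arg(input)
  if (input == "faers_dir" && is.null(faers_dir)) {
    abort("`faers_dir` is required when input = 'faers_dir'.")
  }
  if (input == "synthetic") {
    if (is.null(synthetic)) abort("`synthetic` config is required when input = 'synthetic'.")
    if (!is.null(seed)) synthetic$seed <- as.integer(seed)
    if (is.null(synthetic$seed)) abort("A seed is required in synthetic mode.")
  }
  levels <- match.arg(levels, several.ok = TRUE)
  if (length(subgroup_axes) > 0) {
    subgroup_axes <- match.arg(subgroup_axes, c("sex", "age"), several.ok = TRUE)
  }
  structure(list(input = input, faers_dir = faers_dir, synthetic = synthetic,
                 dictionary = dictionary, lexicon = lexicon, levels = levels,
                 subgroup_axes = subgroup_axes, out_dir = out_dir,
                 ror_boundary = ror_boundary, haldane = haldane,
                 comparator = comparator),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes all requested stages in order and writes every output table as
#' CSV under `out_dir`, plus `manifest.json` recording the configuration,
#' seed, stage row counts (read, parsed, deduplicated, target, background)
#' and package version. Identical configuration and seed yield identical
#' outputs.
#'
#' @param config A `run_config` from [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dict <- stage("load_dictionary", load_term_dictionary(config$dictionary))
  lex <- stage("load_lexicon", load_drug_lexicon(config$lexicon))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  truth <- NULL
  if (config$input == "synthetic") {
    sim <- stage("generate", generate_reports(config$synthetic))
    truth <- sim$truth
    faers_dir <- out("faers")
    stage("write_dialect", write_faers_dialect(sim$cases, faers_dir))
  } else {
    faers_dir <- config$faers_dir
  }

  raw <- stage("read_quarter", read_quarter(faers_dir))
  cases <- stage("assemble", assemble_cases(raw))
  n_read <- sum(raw$parse_summary$rows)
  n_parsed <- nrow(cases)
  dedup <- stage("deduplicate", deduplicate(cases))
  dedup <- stage("flag_target", flag_target_reports(dedup, lex))
  target <- dplyr::filter(dedup, .data$is_target)

  readr::write_csv(flatten_cases(dedup), out("cases.csv"), progress = FALSE)
  readr::write_csv(describe_cohort(target), out("describe.csv"), progress = FALSE)
  readr::write_csv(annual_counts(target), out("annual.csv"), progress = FALSE)
  readr::write_csv(gi_split_counts(target, dict), out("gi_split.csv"), progress = FALSE)
  readr::write_csv(country_counts(target), out("country_counts.csv"), progress = FALSE)

  scans <- list()
  for (lv in config$levels) {
    sc <- stage(paste0("scan_", lv),
                scan_signals(dedup, level = lv, dict = dict,
                             ror_boundary = config$ror_boundary,
                             haldane = config$haldane))
    scans[[lv]] <- sc
    readr::write_csv(format_scan(sc), out(paste0("scan_", lv, ".csv")),
                     progress = FALSE)
    for (axis in config$subgroup_axes) {
      values <- if (axis == "sex") c("male", "female") else c("adult", "minor")
      for (v in values) {
        ssc <- stage(paste0("subgroup_", lv, "_", axis, "_", v),
                     suppressWarnings(subgroup_scan(
                       dedup, axis, v, level = lv, dict = dict,
                       comparator = config$comparator,
                       ror_boundary = config$ror_boundary,
                       haldane = config$haldane)))
        readr::write_csv(format_scan(ssc),
                         out(paste0("scan_", lv, "_", axis, "_", v, ".csv")),
                         progress = FALSE)
      }
    }
  }
  if ("pt" %in% names(scans)) {
    readr::write_csv(volcano_table(scans$pt), out("volcano.csv"), progress = FALSE)
  }
  if (!is.null(truth)) {
    readr::write_csv(truth$realized_counts, out("truth_realized_counts.csv"),
                     progress = FALSE)
    readr::write_csv(truth$planted_signals, out("truth_planted_signals.csv"),
                     progress = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pvsignal")),
    input = config$input,
    seed = if (config$input == "synthetic") config$synthetic$seed else NULL,
    levels = config$levels,
    subgroup_axes = config$subgroup_axes,
    criteria = list(ror_boundary = config$ror_boundary,
                    haldane = config$haldane, comparator = config$comparator),
    counts = list(rows_read = n_read,
                  rows_malformed = sum(raw$parse_summary$rows_malformed),
                  reports_parsed = n_parsed,
                  reports_deduplicated = nrow(dedup),
                  reports_target = nrow(target),
                  reports_background = nrow(dedup) - nrow(target)),
    complete = TRUE
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

# One row per report with list-columns serialized for delimited output.
flatten_cases <- function(cases) {
  dplyr::mutate(cases,
    outcomes = vapply(.data$outcomes, paste, character(1), collapse = ";"),
    drugs = vapply(.data$drugs,
                   function(d) paste(d$role, d$name_raw, sep = ":", collapse = ";"),
                   character(1)),
    events = vapply(.data$events, paste, character(1), collapse = ";"))
}

#' Build a synthetic config from a plain list
#'
#' Converts a declarative configuration document (for example parsed YAML)
#' into a [synthetic_config()], resolving `pt_vocabulary` given as a file
#' path and `planted_signals` given as a list of records.
#'
#' @param lst Named list of `synthetic_config()` arguments.
#' @return A `synthetic_config`.
#' @export
synthetic_config_from_list <- function(lst) {
  if (!is.null(lst$pt_vocabulary) && is.character(lst$pt_vocabulary)) {
    lst$pt_vocabulary <- readr::read_tsv(lst$pt_vocabulary, col_types = "cc",
                                         progress = FALSE)
  }
  if (!is.null(lst$planted_signals) && !is.data.frame(lst$planted_signals)) {
    lst$planted_signals <- dplyr::bind_rows(lapply(lst$planted_signals, function(s) {
      tibble::tibble(pt = s$pt, relative_risk = s$relative_risk,
                     sex = s$sex %||% NA_character_)
    }))
  }
  for (nm in c("sex_dist", "reporter_dist", "country_dist", "outcome_dist",
               "route_dist")) {
    if (!is.null(lst[[nm]])) lst[[nm]] <- unlist(lst[[nm]])
  }
  if (!is.null(lst$age_dist) && !is.data.frame(lst$age_dist)) {
    lst$age_dist <- dplyr::bind_rows(lapply(lst$age_dist, tibble::as_tibble))
  }
  do.call(synthetic_config, lst)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
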