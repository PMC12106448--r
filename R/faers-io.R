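# Reading FAERS-dialect quarterly extracts and assembling case reports.
#
# The dialect: plain-text tables, one header row, fields separated by `$`,
# one file per role (DEMO = demographics, DRUG = drug rows with roles,
# REAC = reaction PTs, OUTC = outcome codes). Reports are keyed by
# `primaryid`; `caseid`/`caseversion` tie multiple versions of one case
# together.

DEMO_COLS <- c("primaryid", "caseid", "caseversion", "rept_dt", "age",
               "age_cod", "sex", "occp_cod", "occr_country")
DRUG_COLS <- c("primaryid", "caseid", "drug_seq", "role_cod", "drugname", "route")
REAC_COLS <- c("primaryid", "caseid", "pt")
OUTC_COLS <- c("primaryid", "caseid", "outc_cod")

# Split dollar-delimited lines, padding trailing empty fields (strsplit drops
# them). Lines whose field count differs from the header are excluded and
# tallied, never silently dropped.
parse_dollar_file <- function(path, required_cols) {
  lines <- readr::read_lines(path, progress = FALSE)
  if (length(lines) == 0) abort(paste0("File ", path, " is empty."))
  header <- strsplit(lines[[1]], "$", fixed = TRUE)[[1]]
  header <- stringr::str_squish(stringr::str_to_lower(header))
  missing <- setdiff(required_cols, header)
  if (length(missing) > 0) {
    abort(paste0("File ", path, " lacks mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  nfield <- stringr::str_count(body, stringr::fixed("$")) + 1L
  ok <- nfield == length(header)
  n_malformed <- sum(!ok)
  if (n_malformed > 0) {
    warn(paste0(basename(path), ": ", n_malformed,
                " malformed row(s) excluded (wrong field count)."))
  }
  parts <- strsplit(body[ok], "$", fixed = TRUE)
  mat <- matrix("", nrow = length(parts), ncol = length(header))
  if (length(parts) > 0) {
    flat <- unlist(parts, use.names = FALSE)
    idx <- sequence(lengths(parts))
    mat[cbind(rep(seq_along(parts), lengths(parts)), idx)] <- flat
  }
  out <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                           .name_repair = "minimal")
  names(out) <- header
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Read a FAERS-dialect quarterly extract
#'
#' Reads the DEMO/DRUG/REAC/OUTC tables of a dollar-delimited quarterly
#' extract. File roles are detected from file names (case-insensitive
#' `demo`/`drug`/`reac`/`outc` substrings) unless `paths` is a named vector.
#' Rows with the wrong field count are excluded and counted in the parse
#' summary, never silently dropped.
#'
#' @param paths Either a directory containing the four files, or a character
#'   vector of file paths (optionally named `demo`, `drug`, `reac`, `outc`).
#' @return A list of class `faers_raw` with tibbles `demo`, `drug`, `reac`,
#'   `outc` (all columns character) and a `parse_summary` tibble
#'   (`file`, `rows`, `rows_malformed`).
#' @export
read_quarter <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- dir(paths, full.names = TRUE)
  }
  roles <- c("demo", "drug", "reac", "outc")
  if (is.null(names(paths)) || !all(roles %in% names(paths))) {
    nm <- stringr::str_to_lower(basename(paths))
    assign_role <- function(role) {
      hit <- paths[stringr::str_detect(nm, role)]
      if (length(hit) != 1) {
        abort(paste0("Expected exactly one file matching '", role, "', found ",
                     length(hit), "."))
      }
      hit
    }
    paths <- setNames(vapply(roles, assign_role, character(1)), roles)
  }
  cols <- list(demo = DEMO_COLS, drug = DRUG_COLS, reac = REAC_COLS, outc = OUTC_COLS)
  tables <- lapply(roles, function(r) parse_dollar_file(paths[[r]], cols[[r]]))
  names(tables) <- roles
  tables$parse_summary <- tibble::tibble(
    file = basename(unname(paths[roles])),
    role = roles,
    rows = vapply(tables[roles], nrow, integer(1)),
    rows_malformed = vapply(tables[roles], function(t) attr(t, "n_malformed"), integer(1))
  )
  structure(tables, class = "faers_raw")
}

# Age unit codes of the public FAERS codebook, converted to years.
AGE_FACTORS <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 7 / 365.25,
                 DY = 1 / 365.25, HR = 1 / 8766)

convert_age_years <- function(age, age_cod) {
  val <- suppressWarnings(as.numeric(age))
  cod <- stringr::str_to_upper(stringr::str_squish(age_cod))
  cod[!nzchar(cod)] <- "YR"
  fac <- unname(AGE_FACTORS[cod])
  yrs <- val * fac
  yrs[is.na(fac) | is.na(val) | yrs < 0 | yrs > 120] <- NA_real_
  yrs
}

SEX_CODES <- c(M = "male", F = "female")
OCCP_CODES <- c(CN = "consumer", MD = "physician", PH = "pharmacist", OT = "other")
OUTC_CODES <- c(DE = "death", LT = "life_threatening", HO = "hospitalization",
                DS = "disability", OT = "other_serious")

decode <- function(x, codes, default) {
  out <- unname(codes[stringr::str_to_upper(stringr::str_squish(x))])
  out[is.na(out)] <- default
  out
}

#' Assemble case reports from raw quarterly tables
#'
#' Joins the four tables into one row per report instance (`primaryid`),
#' normalizing demographics: ages are converted to years from the FAERS unit
#' codes (DEC, YR, MON, WK, DY, HR; implausible ages over 120 become
#' unknown), sex/reporter/outcome codes are decoded, and routes are collapsed
#' to `oral`/`other` (the route of the primary-suspect drug row; missing or
#' non-oral routes count as other). Reaction, drug and outcome rows whose key
#' matches no demographic row are excluded as orphans and tallied; reports
#' with no reaction rows are dropped and tallied (a case report must carry at
#' least one event).
#'
#' @param raw A `faers_raw` list from [read_quarter()].
#' @return A case tibble, one row per report instance, with columns
#'   `primary_id`, `case_id`, `case_version`, `received_date`, `sex`,
#'   `age_years`, `reporter`, `country`, `route`, and list-columns `outcomes`
#'   (character, empty = non-serious), `drugs` (tibbles with `name_raw`,
#'   `role`), `events` (character PTs). An `assembly_summary` attribute
#'   tallies orphans and event-less reports.
#' @export
assemble_cases <- function(raw) {
  stopifnot(inherits(raw, "faers_raw"))
  demo <- raw$demo
  keys <- demo$primaryid
  orphan <- function(tab) sum(!tab$primaryid %in% keys)
  orphans <- c(drug = orphan(raw$drug), reac = orphan(raw$reac),
               outc = orphan(raw$outc))

  drug <- dplyr::filter(raw$drug, .data$primaryid %in% keys)
  reac <- dplyr::filter(raw$reac, .data$primaryid %in% keys)
  outc <- dplyr::filter(raw$outc, .data$primaryid %in% keys)

  drug <- dplyr::arrange(drug, .data$primaryid,
                         suppressWarnings(as.integer(.data$drug_seq)))
  drugs_by <- split(
    tibble::tibble(name_raw = drug$drugname,
                   role = stringr::str_to_upper(stringr::str_squish(drug$role_cod))),
    factor(drug$primaryid, levels = keys)
  )
  events_by <- split(reac$pt, factor(reac$primaryid, levels = keys))
  outc_by <- split(decode(outc$outc_cod, OUTC_CODES, "other_serious"),
                   factor(outc$primaryid, levels = keys))

  route_raw <- stringr::str_to_upper(stringr::str_squish(drug$route))
  ps_rows <- drug[stringr::str_to_upper(stringr::str_squish(drug$role_cod)) == "PS", ]
  ps_route <- setNames(
    ifelse(stringr::str_to_upper(stringr::str_squish(ps_rows$route)) == "ORAL",
           "oral", "other"),
    ps_rows$primaryid)
  ps_route <- ps_route[!duplicated(names(ps_route))]

  cases <- tibble::tibble(
    primary_id = suppressWarnings(as.integer(demo$primaryid)),
    case_id = suppressWarnings(as.integer(demo$caseid)),
    case_version = suppressWarnings(as.integer(demo$caseversion)),
    received_date = as.Date(demo$rept_dt, format = "%Y%m%d"),
    sex = decode(demo$sex, SEX_CODES, "unknown"),
    age_years = convert_age_years(demo$age, demo$age_cod),
    reporter = decode(demo$occp_cod, OCCP_CODES, "unknown"),
    country = ifelse(nzchar(stringr::str_squish(demo$occr_country)),
                     stringr::str_squish(demo$occr_country), "unknown"),
    route = ifelse(demo$primaryid %in% names(ps_route),
                   unname(ps_route[demo$primaryid]), "other"),
    outcomes = unname(lapply(outc_by, as.character)),
    drugs = unname(drugs_by),
    events = unname(lapply(events_by, as.character))
  )
  no_events <- lengths(cases$events) == 0
  if (any(no_events)) {
    warn(paste0(sum(no_events), " report(s) without reaction rows dropped."))
  }
  cases <- cases[!no_events, ]
  cases <- dplyr::arrange(cases, .data$primary_id)
  attr(cases, "assembly_summary") <- tibble::tibble(
    orphan_drug_rows = orphans[["drug"]],
    orphan_reac_rows = orphans[["reac"]],
    orphan_outc_rows = orphans[["outc"]],
    reports_without_events = sum(no_events)
  )
  cases
}

#' Collapse multi-version cases to one record per case
#'
#' For each `case_id` keeps the record with the highest `case_version`, ties
#' broken by latest `received_date`, then highest `primary_id` — the standard
#' precedence for spontaneous-report deduplication, fully deterministic.
#' Output is sorted by `case_id`. Idempotent, and never invents records:
#' every output row is an input row.
#'
#' @param cases A case tibble (see [assemble_cases()]).
#' @return The deduplicated case tibble, one row per `case_id`.
#' @export
deduplicate <- function(cases) {
  if (nrow(cases) == 0) return(cases)
  ord <- order(cases$case_id, -cases$case_version,
               -as.integer(cases$received_date), -cases$primary_id)
  out <- cases[ord, ]
  out <- out[!duplicated(out$case_id), ]
  dplyr::arrange(out, .data$case_id)
}

#' Partition reports into target and background
#'
#' A report is a target report when at least one of its drugs with the
#' primary-suspect (PS) role matches the lexicon; all other reports form the
#' background. The partition is exhaustive and disjoint.
#'
#' @param cases A case tibble.
#' @param lexicon A `drug_lexicon`.
#' @return The case tibble with a logical `is_target` column appended.
#' @export
flag_target_reports <- function(cases, lexicon) {
  if (nrow(cases) == 0) {
    return(dplyr::mutate(cases, is_target = logical(0)))
  }
  long <- tibble::tibble(
    primary_id = rep(cases$primary_id, vapply(cases$drugs, nrow, integer(1))),
    name_raw = unlist(lapply(cases$drugs, `[[`, "name_raw"), use.names = FALSE),
    role = unlist(lapply(cases$drugs, `[[`, "role"), use.names = FALSE)
  )
  hit_ids <- unique(long$primary_id[long$role == "PS" &
                                      match_drug(lexicon, long$name_raw)])
  dplyr::mutate(cases, is_target = .data$primary_id %in% hit_ids)
}
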