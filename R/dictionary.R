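#' Load a preferred-term dictionary
#'
#' Reads a tab-delimited term dictionary mapping MedDRA-style preferred terms
#' (PT) to system organ classes (SOC), with an optional lowest-level-term
#' (LLT) column giving alternate forms that recode to the row's PT. Lookups
#' are case-insensitive and whitespace-normalized. The full licensed MedDRA
#' hierarchy is not required: any two-column table suffices, and the package
#' bundles a miniature dictionary plus a synthetic extended vocabulary under
#' `inst/extdata` (see [pvsignal_example()]).
#'
#' @param path Path to a UTF-8, tab-delimited file with a header row and
#'   columns `pt` and `soc`, optionally `llt`.
#' @return An object of class `term_dictionary`: a list with `pt_to_soc`
#'   (named character vector keyed by normalized PT) and `llt_to_pt` (named
#'   character vector, possibly empty).
#' @details A PT must map to exactly one SOC; rows repeating a PT with a
#'   conflicting SOC raise an error naming the term. LLT forms always recode
#'   to a PT present in the dictionary, so composing the two maps never
#'   dangles.
#' @export
#' @examples
#' dict <- load_term_dictionary(pvsignal_example("meddra_mini.tsv"))
#' map_pt_to_soc(dict, c("Vomiting", "  flatulence "))
load_term_dictionary <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("pt", "soc")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Dictionary file ", path, " lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  pt <- norm_term(raw$pt)
  soc <- norm_term(raw$soc)
  tab <- dplyr::distinct(tibble::tibble(pt = pt, soc = soc))
  dup <- tab$pt[duplicated(tab$pt)]
  if (length(dup) > 0) {
    abort(paste0("Conflicting SOC assignments for PT(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  pt_to_soc <- setNames(tab$soc, tab$pt)

  llt_to_pt <- setNames(character(0), character(0))
  if ("llt" %in% names(raw)) {
    keep <- !is.na(raw$llt) & nzchar(stringr::str_squish(raw$llt))
    if (any(keep)) {
      ltab <- dplyr::distinct(tibble::tibble(llt = norm_term(raw$llt[keep]),
                                             pt = pt[keep]))
      ldup <- ltab$llt[duplicated(ltab$llt)]
      if (length(ldup) > 0) {
        abort(paste0("Conflicting PT assignments for LLT(s): ",
                     paste(unique(ldup), collapse = ", ")))
      }
      llt_to_pt <- setNames(ltab$pt, ltab$llt)
    }
  }
  structure(list(pt_to_soc = pt_to_soc, llt_to_pt = llt_to_pt),
            class = "term_dictionary")
}

#' Construct a term dictionary from vectors
#'
#' Programmatic counterpart of [load_term_dictionary()], convenient for tests
#' and simulated vocabularies.
#'
#' @param pt,soc Character vectors of equal length.
#' @param llt Optional character vector of alternate forms (same length),
#'   `NA` where a row has none.
#' @return A `term_dictionary`.
#' @export
term_dictionary <- function(pt, soc, llt = NULL) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp), add = TRUE)
  df <- tibble::tibble(pt = pt, soc = soc)
  if (!is.null(llt)) df$llt <- llt
  readr::write_tsv(df, tmp, progress = FALSE)
  load_term_dictionary(tmp)
}

#' Map preferred terms to system organ classes
#'
#' Total on its input: every PT yields either its SOC or the distinguished
#' unmapped value `NA_character_`; unmapped terms never silently join an SOC.
#' If the dictionary carries LLT forms, terms are first recoded LLT to PT.
#'
#' @param dict A `term_dictionary`.
#' @param pt Character vector of preferred terms (any case/whitespace).
#' @return Character vector of SOC names, `NA` where unmapped.
#' @export
map_pt_to_soc <- function(dict, pt) {
  stopifnot(inherits(dict, "term_dictionary"))
  key <- norm_term(pt)
  recoded <- unname(dict$llt_to_pt[key])
  key <- ifelse(!is.na(recoded), recoded, key)
  unname(dict$pt_to_soc[key])
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat("<term_dictionary> ", length(x$pt_to_soc), " PTs, ",
      length(unique(x$pt_to_soc)), " SOCs, ",
      length(x$llt_to_pt), " LLT forms\n", sep = "")
  invisible(x)
}

#' Load a target-drug lexicon
#'
#' A lexicon is a list of normalized name fragments identifying the target
#' product family among free-text drug names: one fragment per line, UTF-8,
#' lines starting with `#` ignored. Normalization uppercases, trims,
#' collapses internal whitespace and strips punctuation.
#'
#' @param path Path to the fragment file.
#' @return An object of class `drug_lexicon` (a character vector of
#'   normalized fragments).
#' @export
#' @examples
#' lex <- load_drug_lexicon(pvsignal_example("probiotic_lexicon.txt"))
#' match_drug(lex, c("Lactobacillus rhamnosus GG capsule", "LACTULOSE"))
load_drug_lexicon <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!stringr::str_starts(lines, "#")]
  frags <- norm_drug(lines)
  frags <- unique(frags[nzchar(frags)])
  if (length(frags) == 0) abort(paste0("Lexicon file ", path, " contains no fragments."))
  drug_lexicon(frags)
}

#' @rdname load_drug_lexicon
#' @param fragments Character vector of fragments (normalized on construction).
#' @export
drug_lexicon <- function(fragments) {
  frags <- unique(norm_drug(fragments))
  frags <- frags[nzchar(frags)]
  structure(frags, class = "drug_lexicon")
}

#' Match raw drug names against a lexicon
#'
#' A name matches when any lexicon fragment occurs as a substring of the
#' normalized name. Substring (rather than exact) matching reflects the
#' free-text nature of spontaneous-report drug fields, where one product
#' family appears under many verbatim spellings.
#'
#' @param lexicon A `drug_lexicon` (an empty lexicon matches nothing).
#' @param raw_name Character vector of verbatim drug names.
#' @return Logical vector, `TRUE` where the name matches.
#' @export
match_drug <- function(lexicon, raw_name) {
  nm <- norm_drug(raw_name)
  out <- rep(FALSE, length(nm))
  ok <- !is.na(nm) & nzchar(nm)
  for (frag in lexicon) {
    out[ok] <- out[ok] | stringr::str_detect(nm[ok], stringr::fixed(frag))
  }
  out
}

#' Paths to bundled example files
#'
#' @param file Name of a file under the package's `extdata` directory; `NULL`
#'   lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
pvsignal_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "pvsignal"))
  } else {
    path <- system.file("extdata", file, package = "pvsignal")
    if (!nzchar(path)) abort(paste0("No bundled file named ", file))
    path
  }
}
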