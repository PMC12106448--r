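# Internal helpers shared across modules.

#' @importFrom rlang .data abort warn .env
#' @importFrom stats runif setNames pchisq uniroot rmultinom
NULL

# Round half away from zero (the convention used for rendered percentages);
# base round() is round-half-even.
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Uppercase, trim, collapse internal whitespace. Term keys and drug names are
# always compared in this normal form.
norm_term <- function(x) {
  stringr::str_squish(stringr::str_to_upper(x))
}

# Drug-name normal form additionally strips punctuation.
norm_drug <- function(x) {
  x <- stringr::str_replace_all(stringr::str_to_upper(x), "[[:punct:]]", " ")
  stringr::str_squish(x)
}

# Validate a named categorical probability vector.
check_prob_vector <- function(p, field) {
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    abort(paste0("`", field, "` must be a named probability vector."))
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort(paste0("`", field, "` must be non-negative and sum to 1 (got sum ",
                 format(sum(p)), ")."))
  }
  invisible(p)
}

sample_cat <- function(p, n) {
  sample(names(p), n, replace = TRUE, prob = p)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
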