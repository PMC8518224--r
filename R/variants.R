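# Amino-acid variant nomenclature.
#
# Amino-acid-level protein variants are the unit of record throughout the
# package. A variant token is "<wt><pos><mut>" where <wt>/<mut> are one- or
# three-letter amino-acid codes (stop: "*" or "Ter") and <pos> is the 1-based
# protein coordinate (Met1 is position 1).

AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln", E = "Glu",
  G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys", M = "Met", F = "Phe",
  P = "Pro", S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val", `*` = "Ter"
)
AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

.aa_from_code <- function(code) {
  out <- rep(NA_character_, length(code))
  three <- nchar(code) == 3L
  # three-letter, case-insensitive ("ARG" == "Arg"); "Ter" is the stop code
  cap <- paste0(toupper(substr(code, 1, 1)), tolower(substr(code, 2, 3)))
  out[three] <- unname(AA_ONE[cap[three]])
  one <- nchar(code) == 1L
  up <- toupper(code)
  ok1 <- one & (up %in% names(AA_THREE))
  out[ok1] <- up[ok1]
  out
}

#' Parse amino-acid variant tokens
#'
#' Accepts one-letter (`"C124S"`), three-letter (`"Cys124Ser"`), and mixed
#' notation; stop gains may be written `"*"` or `"Ter"` (`"R130*"`,
#' `"Arg130Ter"`). The consequence is derived from the codes: `synonymous`
#' when the two amino acids are identical, `nonsense` when the substitution
#' introduces a stop, `missense` otherwise.
#'
#' @param tokens Character vector of variant tokens.
#' @return A tibble with one row per token and columns `variant` (canonical
#'   one-letter token), `wt_aa`, `position`, `mut_aa`, `consequence`.
#' @examples
#' parse_variant(c("Arg130Pro", "C124S", "R130*", "A5A"))
#' @export
parse_variant <- function(tokens) {
  stopifnot(is.character(tokens), length(tokens) >= 1L)
  if (any(is.na(tokens) | !nzchar(tokens))) {
    stop("variant tokens must be non-empty strings", call. = FALSE)
  }
  m <- stringr::str_match(
    tokens,
    "^([A-Za-z]{3}|[A-Za-z*])([0-9]+)([A-Za-z]{3}|[A-Za-z*])$"
  )
  bad <- is.na(m[, 1])
  wt <- .aa_from_code(m[, 2])
  mut <- .aa_from_code(m[, 4])
  pos <- suppressWarnings(as.integer(m[, 3]))
  bad <- bad | is.na(wt) | is.na(mut) | is.na(pos) | pos < 1L
  if (any(bad)) {
    stop(
      "malformed variant token(s): ",
      paste(utils::head(tokens[bad], 5L), collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    variant = paste0(wt, pos, mut),
    wt_aa = wt,
    position = pos,
    mut_aa = mut,
    consequence = variant_consequence(wt, mut)
  )
}

#' @rdname parse_variant
#' @param wt_aa,mut_aa One-letter amino-acid codes (`"*"` for stop).
#' @return `variant_consequence()`: character vector in
#'   `c("synonymous", "nonsense", "missense")`.
#' @export
variant_consequence <- function(wt_aa, mut_aa) {
  dplyr::case_when(
    wt_aa == mut_aa ~ "synonymous",
    mut_aa == "*" & wt_aa != "*" ~ "nonsense",
    TRUE ~ "missense"
  )
}

#' Format variants as tokens
#'
#' Inverse of [parse_variant()]: `parse_variant(format_variant(v))` returns
#' the same variant. Stops are written `"*"` in one-letter style and `"Ter"`
#' in three-letter style.
#'
#' @param wt_aa,mut_aa One-letter codes (`"*"` for stop); or pass a tibble
#'   from [parse_variant()] as the first argument.
#' @param position 1-based protein position.
#' @param style `"one"` (default) or `"three"`.
#' @return Character vector of tokens.
#' @export
format_variant <- function(wt_aa, position = NULL, mut_aa = NULL,
                           style = c("one", "three")) {
  style <- match.arg(style)
  if (is.data.frame(wt_aa)) {
    df <- wt_aa
    wt_aa <- df$wt_aa
    position <- df$position
    mut_aa <- df$mut_aa
  }
  stopifnot(length(wt_aa) == length(position), length(wt_aa) == length(mut_aa))
  if (!all(wt_aa %in% names(AA_THREE)) || !all(mut_aa %in% names(AA_THREE))) {
    stop("unknown one-letter amino-acid code", call. = FALSE)
  }
  if (style == "one") {
    paste0(wt_aa, position, mut_aa)
  } else {
    paste0(AA_THREE[wt_aa], position, AA_THREE[mut_aa])
  }
}

#' Known dominant-negative PTEN variants
#'
#' The four catalytic-pocket substitutions established as dominant negatives
#' in the PTEN literature, used as the default `known` set when partitioning
#' loss-of-activity-only variants.
#'
#' @return Character vector of one-letter variant tokens.
#' @export
pten_known_dn <- function() c("C124S", "G129E", "R130G", "R130Q")
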