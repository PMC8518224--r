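# Readers and writers for the external tables the pipeline touches:
# FASTA coding sequences, replicate/composite score TSVs, activity TSVs,
# and clinical/somatic variant catalogs.

new_cds_sequence <- function(name, sequence, codon_table = NULL) {
  if (is.null(codon_table)) codon_table <- Biostrings::GENETIC_CODE
  sequence <- chartr("u", "t", sequence)
  sequence <- toupper(chartr("U", "T", sequence))
  if (!grepl("^[ACGT]*$", sequence)) {
    stop("CDS contains characters outside {A,C,G,T}", call. = FALSE)
  }
  n <- nchar(sequence)
  if (n == 0L || n %% 3L != 0L) {
    stop("CDS length (", n, ") is not a positive multiple of 3", call. = FALSE)
  }
  codons <- substring(sequence, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  protein <- unname(codon_table[codons])
  internal_stop <- which(protein == "*")
  internal_stop <- internal_stop[internal_stop < length(codons)]
  if (length(internal_stop) > 0L) {
    stop("internal stop codon at codon index ",
         paste(internal_stop, collapse = ", "), call. = FALSE)
  }
  structure(
    list(name = name, sequence = sequence, codons = codons,
         protein = protein, codon_table = codon_table),
    class = "cds_sequence"
  )
}

#' @export
print.cds_sequence <- function(x, ...) {
  cat("<cds_sequence> ", x$name, ": ", length(x$codons), " codons",
      if (x$protein[length(x$protein)] == "*") " (incl. terminal stop)",
      "\n", sep = "")
  invisible(x)
}

#' Read a coding sequence from FASTA
#'
#' Reads the first record of a FASTA file, uppercases it, normalizes U to T,
#' and validates it as a coding sequence (length divisible by three, no
#' internal stop codon).
#'
#' @param path Path to a FASTA file with at least one record.
#' @param codon_table Named character vector mapping codons to one-letter
#'   amino acids; defaults to the standard genetic code.
#' @return A `cds_sequence` object: name, nucleotide string, codon vector and
#'   translation.
#' @export
read_cds_fasta <- function(path, codon_table = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  new_cds_sequence(names(seqs)[1], as.character(seqs[[1]]), codon_table)
}

#' Write a coding sequence to FASTA
#'
#' @param cds A `cds_sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  writeLines(c(paste0(">", cds$name), cds$sequence), path)
  invisible(path)
}

.check_variant_col <- function(df, variant_col, path) {
  if (!variant_col %in% names(df)) {
    stop("column '", variant_col, "' not found in ", path, call. = FALSE)
  }
  ok <- !is.na(df[[variant_col]]) & nzchar(df[[variant_col]])
  if (!all(ok)) {
    stop("empty variant token at line ", which(!ok)[1] + 1L, " of ", path,
         call. = FALSE)
  }
  parsed <- tryCatch(parse_variant(df[[variant_col]]), error = function(e) e)
  if (inherits(parsed, "error")) {
    bad <- which(is.na(stringr::str_match(
      df[[variant_col]],
      "^([A-Za-z]{3}|[A-Za-z*])([0-9]+)([A-Za-z]{3}|[A-Za-z*])$")[, 1]))
    stop("unparseable variant token '", df[[variant_col]][bad[1]],
         "' at line ", bad[1] + 1L, " of ", path, call. = FALSE)
  }
  parsed
}

#' Read a variant score table
#'
#' Reads a TSV with a header whose rows are variants and whose remaining
#' numeric columns are per-replicate (or composite) scores. Variant tokens
#' are canonicalized through [parse_variant()]; missing cells stay missing.
#' The column holding the variant token is configurable so externally
#' published score tables with other layouts can be consumed.
#'
#' @param path TSV path.
#' @param variant_col Name of the variant-token column (default `"variant"`).
#' @return A tibble with `variant`, `consequence`, and the table's numeric
#'   score columns, one row per variant.
#' @export
read_score_table <- function(path, variant_col = "variant") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  parsed <- .check_variant_col(df, variant_col, path)
  if (anyDuplicated(parsed$variant)) {
    dup <- parsed$variant[duplicated(parsed$variant)][1]
    stop("duplicate variant row '", dup, "' in ", path, call. = FALSE)
  }
  score_cols <- setdiff(names(df), c(variant_col, "consequence"))
  out <- dplyr::bind_cols(
    parsed[, c("variant", "consequence")],
    df[, score_cols, drop = FALSE]
  )
  tibble::as_tibble(out)
}

#' Write a score table (and other pipeline tibbles) as TSV
#'
#' Numeric values are written with shortest round-trip precision so a
#' write/read cycle reproduces every value exactly.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a clinical/somatic variant catalog
#'
#' A catalog is a TSV of variant observations grouped into categories (cancer
#' types, clinical assertion groups, ...). Rows sharing a (variant, category)
#' pair are aggregated by summing their counts; a missing count column means
#' one observation per row.
#'
#' @param path TSV path.
#' @param variant_col,category_col,count_col Column names; `count_col` may be
#'   absent from the file.
#' @return A tibble with `variant`, `consequence`, `category`, `n_obs`
#'   (unique (variant, category) rows, `n_obs >= 1`).
#' @export
read_cancer_catalog <- function(path, variant_col = "variant",
                                category_col = "category",
                                count_col = "count") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  parsed <- .check_variant_col(df, variant_col, path)
  if (!category_col %in% names(df)) {
    stop("column '", category_col, "' not found in ", path, call. = FALSE)
  }
  n_obs <- if (count_col %in% names(df)) as.numeric(df[[count_col]]) else 1
  if (any(is.na(n_obs) | n_obs < 1)) {
    stop("observation counts must be >= 1 in ", path, call. = FALSE)
  }
  tibble::tibble(
    variant = parsed$variant,
    consequence = parsed$consequence,
    category = as.character(df[[category_col]]),
    n_obs = n_obs
  ) |>
    dplyr::group_by(.data$variant, .data$consequence, .data$category) |>
    dplyr::summarise(n_obs = sum(.data$n_obs), .groups = "drop")
}

#' Read an activity score table
#'
#' Reads a two-column (configurable) TSV of raw enzymatic activity scores in
#' the style of the yeast phosphatase rescue dataset. A row whose token is
#' `"WT"` (case-insensitive) is kept as the designated wild-type anchor.
#'
#' @param path TSV path.
#' @param variant_col,score_col Column names.
#' @return Tibble with `variant`, `consequence` (`NA` for the WT row) and
#'   `activity` (raw scale).
#' @export
read_activity_scores <- function(path, variant_col = "variant",
                                 score_col = "activity") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c(variant_col, score_col)) {
    if (!col %in% names(df)) {
      stop("column '", col, "' not found in ", path, call. = FALSE)
    }
  }
  tok <- as.character(df[[variant_col]])
  is_wt <- toupper(tok) == "WT"
  cons <- rep(NA_character_, length(tok))
  canon <- tok
  if (any(!is_wt)) {
    parsed <- parse_variant(tok[!is_wt])
    canon[!is_wt] <- parsed$variant
    cons[!is_wt] <- parsed$consequence
  }
  canon[is_wt] <- "WT"
  tibble::tibble(
    variant = canon,
    consequence = cons,
    activity = as.numeric(df[[score_col]])
  )
}
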