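# Codon-degeneracy SNV null model.
#
# Every nucleotide of a coding sequence is substituted to every other
# nucleotide (9 events per codon); events are translated and collapsed to
# unique protein variants carrying a degeneracy frequency (the number of
# distinct SNV events producing the variant). The degeneracy-weighted class
# fractions over these variants are the All-SNV baseline expected in the
# absence of selection. Transition/transversion weighting is deliberately
# uniform by default; a rate hook is provided for sensitivity analyses.

NUCS <- c("A", "C", "G", "T")

#' Enumerate all single-nucleotide variants of a CDS
#'
#' The initiator codon and the terminal stop codon are excluded by default,
#' so a CDS of `n` codons ending in a stop yields exactly `9 * (n - 2)`
#' events.
#'
#' @param cds A `cds_sequence` (see [read_cds_fasta()]).
#' @param include_start Include codon 1.
#' @param include_stop Include the terminal stop codon (if present).
#' @return Tibble of SNV events: `nt_position` (1-based in the CDS),
#'   `ref_nt`, `alt_nt`, `codon_index`, `ref_codon`, `alt_codon`,
#'   `variant`, `wt_aa`, `position`, `mut_aa`, `consequence`.
#' @export
enumerate_snvs <- function(cds, include_start = FALSE,
                           include_stop = FALSE) {
  stopifnot(inherits(cds, "cds_sequence"))
  n <- length(cds$codons)
  idx <- seq_len(n)
  if (!include_start) idx <- setdiff(idx, 1L)
  if (!include_stop && cds$protein[n] == "*") idx <- setdiff(idx, n)
  if (length(idx) == 0L) {
    stop("no codons left to enumerate", call. = FALSE)
  }
  code <- cds$codon_table
  # 9 events per codon: 3 positions x 3 alternative nucleotides
  events <- tidyr::expand_grid(
    codon_index = idx,
    offset = 1:3,
    alt_rank = 1:3
  )
  ref_codon <- cds$codons[events$codon_index]
  ref_nt <- substr(ref_codon, events$offset, events$offset)
  alt_nt <- vapply(seq_len(nrow(events)), function(i) {
    setdiff(NUCS, ref_nt[i])[events$alt_rank[i]]
  }, "")
  alt_codon <- ref_codon
  substr(alt_codon, events$offset, events$offset) <- alt_nt
  wt_aa <- unname(code[ref_codon])
  mut_aa <- unname(code[alt_codon])
  tibble::tibble(
    nt_position = (events$codon_index - 1L) * 3L + events$offset,
    ref_nt = ref_nt,
    alt_nt = alt_nt,
    codon_index = events$codon_index,
    ref_codon = ref_codon,
    alt_codon = alt_codon,
    variant = paste0(wt_aa, events$codon_index, mut_aa),
    wt_aa = wt_aa,
    position = events$codon_index,
    mut_aa = mut_aa,
    consequence = variant_consequence(wt_aa, mut_aa)
  ) |>
    dplyr::arrange(.data$nt_position, .data$alt_nt)
}

#' Degeneracy-weighted null spectrum of protein variants
#'
#' Drops synonymous SNV events and collapses the rest to unique protein
#' variants; each variant's `frequency` is the number of distinct SNV
#' events producing it. When a class map is supplied it is joined on, and
#' a warning reports classification coverage if it falls below
#' `min_coverage`.
#'
#' @inheritParams enumerate_snvs
#' @param class_map Optional tibble mapping `variant` to `class` (or
#'   `joint_class`).
#' @param min_coverage Warn when the degeneracy-weighted fraction of
#'   spectrum variants with a class falls below this value.
#' @return Tibble: `variant`, `wt_aa`, `position`, `mut_aa`, `consequence`,
#'   `frequency`, and `class` when a map is given. Frequencies sum to the
#'   number of non-synonymous SNV events.
#' @export
null_spectrum <- function(cds, class_map = NULL, include_start = FALSE,
                          include_stop = FALSE, min_coverage = 0.25) {
  spec <- enumerate_snvs(cds, include_start, include_stop) |>
    dplyr::filter(.data$consequence != "synonymous") |>
    dplyr::group_by(.data$variant, .data$wt_aa, .data$position,
                    .data$mut_aa, .data$consequence) |>
    dplyr::summarise(frequency = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$position, .data$mut_aa)
  if (!is.null(class_map)) {
    class_col <- if ("joint_class" %in% names(class_map)) "joint_class"
                 else "class"
    spec <- dplyr::left_join(
      spec,
      dplyr::select(class_map, "variant",
                    class = dplyr::all_of(class_col)),
      by = "variant"
    )
    coverage <- sum(spec$frequency[!is.na(spec$class)]) /
      sum(spec$frequency)
    if (coverage < min_coverage) {
      warning(sprintf(
        "only %.1f%% of the null spectrum (degeneracy-weighted) carries a ",
        100 * coverage), "class label", call. = FALSE)
    }
    attr(spec, "class_coverage") <- coverage
  }
  spec
}

#' Expected class fractions under the null spectrum
#'
#' Degeneracy-weighted class fractions over the classified portion of the
#' spectrum: the expected class composition of observed variants in the
#' absence of selection.
#'
#' @param spectrum A classified spectrum from [null_spectrum()].
#' @return Tibble `class`, `weight`, `fraction` (fractions sum to 1).
#' @export
expected_class_fractions <- function(spectrum) {
  if (!"class" %in% names(spectrum)) {
    stop("spectrum carries no class labels; pass class_map to ",
         "null_spectrum()", call. = FALSE)
  }
  spectrum |>
    dplyr::filter(!is.na(.data$class)) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(weight = sum(.data$frequency), .groups = "drop") |>
    dplyr::mutate(fraction = .data$weight / sum(.data$weight))
}

#' Observed class fractions of a variant catalog
#'
#' @param catalog Catalog tibble (`variant`, `n_obs`, optionally
#'   `category`); fractions are computed over all rows passed, so filter by
#'   category first for per-category fractions.
#' @param class_map Tibble mapping `variant` to `class`/`joint_class`.
#' @param mode `"per_observation"` or `"unique_variant"`.
#' @return Tibble `class`, `n`, `fraction` (fractions sum to 1 over
#'   classified observations; unmapped variants are excluded from the
#'   denominator).
#' @export
observed_class_fractions <- function(catalog, class_map,
                                     mode = c("per_observation",
                                              "unique_variant")) {
  mode <- match.arg(mode)
  class_col <- if ("joint_class" %in% names(class_map)) "joint_class"
               else "class"
  four <- c("wt_like", "loss_abundance_only", "loss_activity_only",
            "loss_both")
  mapped <- catalog |>
    dplyr::inner_join(
      dplyr::select(class_map, "variant",
                    class = dplyr::all_of(class_col)),
      by = "variant") |>
    dplyr::filter(!is.na(.data$class), .data$class %in% four)
  if (nrow(mapped) == 0L) {
    stop("no catalog observations could be classified", call. = FALSE)
  }
  if (mode == "unique_variant") {
    mapped <- dplyr::distinct(mapped, .data$variant, .data$class) |>
      dplyr::mutate(n_obs = 1)
  }
  mapped |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = sum(.data$n_obs), .groups = "drop") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
}

#' Fold enrichment of observed over expected class fractions
#'
#' @param observed Tibble `class`, `fraction` (e.g.
#'   [observed_class_fractions()]).
#' @param expected Tibble `class`, `fraction` (e.g.
#'   [expected_class_fractions()]); fractions must sum to 1.
#' @return Tibble `class`, `observed`, `expected`, `fold`.
#' @export
fold_enrichment <- function(observed, expected) {
  if (abs(sum(expected$fraction) - 1) > 1e-8) {
    stop("expected fractions must sum to 1", call. = FALSE)
  }
  out <- dplyr::full_join(
    dplyr::select(observed, "class", observed = "fraction"),
    dplyr::select(expected, "class", expected = "fraction"),
    by = "class"
  ) |>
    dplyr::mutate(
      observed = dplyr::coalesce(.data$observed, 0),
      fold = dplyr::case_when(
        .data$expected > 0 ~ .data$observed / .data$expected,
        .data$observed > 0 ~ Inf,
        TRUE ~ NaN
      )
    )
  if (any(is.infinite(out$fold))) {
    warning("class observed but expected fraction is zero; fold is Inf",
            call. = FALSE)
  }
  out
}
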