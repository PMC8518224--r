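# Per-replicate abundance scoring.
#
# A variant's reads are depth-normalized per bin, renormalized to a
# frequency distribution over the four bins, and collapsed to a raw score by
# a bin-weighted average with weights (0, 1/3, 2/3, 1) (low to high
# fluorescence). Raw scores are then anchored so that the replicate's
# nonsense-control median maps to 0 and its synonymous-control median to 1.

#' Scoring configuration
#'
#' @param bin_weights Strictly increasing weights over the four bins.
#' @param min_reads_per_variant Variants with fewer total reads in a
#'   replicate are flagged unscored (missing), not zero.
#' @param anchor `"median"` (default) or `"mean"` of the control score
#'   distributions used for normalization.
#' @param min_controls Minimum number of scored synonymous and of nonsense
#'   controls required to normalize a replicate.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(bin_weights = c(0, 1/3, 2/3, 1),
                           min_reads_per_variant = 5,
                           anchor = c("median", "mean"),
                           min_controls = 5L) {
  stopifnot(length(bin_weights) == 4, all(diff(bin_weights) > 0))
  anchor <- match.arg(anchor)
  structure(
    list(bin_weights = bin_weights,
         min_reads_per_variant = min_reads_per_variant,
         anchor = anchor,
         min_controls = as.integer(min_controls)),
    class = "scoring_config"
  )
}

#' Depth-normalized bin frequencies for one variant
#'
#' `f_b = (c_b / N_b) / sum_b'(c_b' / N_b')`: the variant's read count in
#' each bin is divided by that bin's total depth, then renormalized to sum
#' to one. Scores are therefore invariant to rescaling all depths by a
#' constant.
#'
#' @param counts Integer vector of length 4, reads per bin.
#' @param depths Positive vector of length 4, total reads per bin.
#' @return Numeric vector of length 4 summing to 1.
#' @export
bin_frequencies <- function(counts, depths) {
  stopifnot(length(counts) == 4, length(depths) == 4)
  if (any(depths <= 0)) stop("all bin depths must be positive", call. = FALSE)
  if (any(counts < 0)) stop("negative bin count", call. = FALSE)
  if (sum(counts) == 0) stop("variant has zero reads", call. = FALSE)
  r <- counts / depths
  r / sum(r)
}

#' Bin-weighted average raw score
#'
#' @param f Bin frequencies from [bin_frequencies()].
#' @param config A [scoring_config()].
#' @return Raw score in `[0, 1]` (for the default weights).
#' @export
weighted_average_score <- function(f, config = scoring_config()) {
  sum(config$bin_weights * f)
}

#' Anchor raw scores to control medians
#'
#' `s' = (s - anchor_nonsense) / (anchor_synonymous - anchor_nonsense)`.
#' Values outside `[0, 1]` are possible and preserved.
#'
#' @param raw Numeric raw scores (may contain `NA`).
#' @param synonymous_scores,nonsense_scores Raw scores of the scored control
#'   variants in the same replicate.
#' @param config A [scoring_config()].
#' @return Normalized scores, same length as `raw`.
#' @export
normalize_scores <- function(raw, synonymous_scores, nonsense_scores,
                             config = scoring_config()) {
  syn <- synonymous_scores[!is.na(synonymous_scores)]
  non <- nonsense_scores[!is.na(nonsense_scores)]
  if (length(syn) < config$min_controls || length(non) < config$min_controls) {
    stop("need at least ", config$min_controls,
         " scored synonymous and nonsense controls", call. = FALSE)
  }
  anchor <- if (config$anchor == "median") stats::median else mean
  a_syn <- anchor(syn)
  a_non <- anchor(non)
  if (a_syn <= a_non) {
    stop("replicate failed separation: synonymous anchor (",
         signif(a_syn, 4), ") <= nonsense anchor (", signif(a_non, 4), ")",
         call. = FALSE)
  }
  (raw - a_non) / (a_syn - a_non)
}

#' Score one replicate's bin counts
#'
#' Computes per-variant raw bin-weighted scores, flags variants below the
#' read filter as missing, averages codon-level entries encoding the same
#' amino-acid change (when a `codon_variant` column is present), and anchors
#' the replicate on its synonymous and nonsense controls.
#'
#' @param counts Tibble `variant`, `consequence`, `bin`, `count` (one
#'   replicate; see [simulate_sort_replicate()]). An optional
#'   `codon_variant` column identifies codon-level entries to be averaged
#'   per amino-acid variant before normalization.
#' @param config A [scoring_config()].
#' @return Tibble `variant`, `consequence`, `total_reads`, `raw_score`,
#'   `score` (normalized; `NA` where unscored).
#' @export
score_replicate <- function(counts, config = scoring_config()) {
  stopifnot(all(c("variant", "consequence", "bin", "count") %in%
                  names(counts)))
  depths <- counts |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(depth = sum(.data$count), .groups = "drop")
  if (any(depths$depth <= 0) || nrow(depths) != 4) {
    stop("each of the four bins needs positive total depth", call. = FALSE)
  }
  w <- config$bin_weights
  unit <- if ("codon_variant" %in% names(counts)) "codon_variant" else
    "variant"
  per <- counts |>
    dplyr::left_join(depths, by = "bin") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      unique(c(unit, "variant", "consequence"))))) |>
    dplyr::arrange(.data$bin, .by_group = TRUE) |>
    dplyr::summarise(
      total_reads = sum(.data$count),
      raw_score = {
        r <- .data$count / .data$depth
        if (sum(.data$count) == 0) NA_real_ else sum(w * r / sum(r))
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(raw_score = dplyr::if_else(
      .data$total_reads < config$min_reads_per_variant,
      NA_real_, .data$raw_score))
  # codon-level entries encoding the same amino-acid change: unweighted mean
  per <- per |>
    dplyr::group_by(.data$variant, .data$consequence) |>
    dplyr::summarise(
      total_reads = sum(.data$total_reads),
      raw_score = if (all(is.na(.data$raw_score))) NA_real_ else
        mean(.data$raw_score, na.rm = TRUE),
      .groups = "drop"
    )
  per$score <- normalize_scores(
    per$raw_score,
    per$raw_score[per$consequence == "synonymous"],
    per$raw_score[per$consequence == "nonsense"],
    config
  )
  per
}

#' Score a multi-replicate experiment
#'
#' @param counts Long tibble with a `replicate` column over
#'   [score_replicate()]-style bin counts.
#' @param config A [scoring_config()].
#' @return Long tidy score table: `variant`, `consequence`, `replicate`,
#'   `total_reads`, `raw_score`, `score`.
#' @export
score_experiment <- function(counts, config = scoring_config()) {
  stopifnot("replicate" %in% names(counts))
  counts |>
    dplyr::group_split(.data$replicate) |>
    purrr::map_dfr(function(d) {
      r <- d$replicate[1]
      dplyr::mutate(
        score_replicate(dplyr::select(d, -"replicate"), config),
        replicate = r, .after = "consequence")
    })
}

#' Pivot a long replicate score table to the wide on-disk layout
#'
#' @param scores Long table from [score_experiment()].
#' @return Wide tibble: `variant`, `consequence`, one `rep_<i>` column per
#'   replicate.
#' @export
scores_to_wide <- function(scores) {
  scores |>
    dplyr::select("variant", "consequence", "replicate", "score") |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "score",
                       names_prefix = "rep_")
}

#' Pivot a wide score table (e.g. from [read_score_table()]) to long
#'
#' @param wide Wide tibble whose replicate columns are named `rep_<i>` (or
#'   any non-reserved numeric columns).
#' @return Long tibble `variant`, `consequence`, `replicate`, `score`.
#' @export
scores_to_long <- function(wide) {
  score_cols <- setdiff(names(wide), c("variant", "consequence"))
  wide |>
    tidyr::pivot_longer(dplyr::all_of(score_cols),
                        names_to = "replicate", values_to = "score") |>
    dplyr::mutate(replicate = as.integer(
      stringr::str_remove(.data$replicate, "^rep_")))
}
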