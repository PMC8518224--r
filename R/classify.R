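# Abundance x activity integration and four-way functional classification.
#
# Activity cutoffs are applied on the raw activity scale: wild-type-like
# above 10^-1.11 (lower 95th percentile of synonymous activity in the source
# dataset), loss below 10^-2.13 (upper 95th percentile of nonsense activity).
# Rescaling to a 0..1 reporting scale (mean nonsense -> 0, WT -> 1) happens
# after classification and is used for plotting only.

#' Classification configuration
#'
#' @param activity_wt_cutoff Raw activity above which a variant is
#'   wild-type-like (default `10^-1.11`).
#' @param activity_loss_cutoff Raw activity below which a variant is loss of
#'   activity (default `10^-2.13`).
#' @param wt_anchor `"auto"` (designated WT row if present, else mean of
#'   synonymous variants), `"wt_row"`, or `"synonymous_mean"`.
#' @return A `classification_config` list.
#' @export
classification_config <- function(activity_wt_cutoff = 10^-1.11,
                                  activity_loss_cutoff = 10^-2.13,
                                  wt_anchor = c("auto", "wt_row",
                                                "synonymous_mean")) {
  stopifnot(activity_loss_cutoff < activity_wt_cutoff)
  structure(
    list(activity_wt_cutoff = activity_wt_cutoff,
         activity_loss_cutoff = activity_loss_cutoff,
         wt_anchor = match.arg(wt_anchor)),
    class = "classification_config"
  )
}

#' Classify raw activity scores
#'
#' @param raw Positive raw activity scores.
#' @param config A [classification_config()].
#' @return Character vector in `c("wt_like", "loss", "indeterminate")`.
#' @export
classify_activity <- function(raw, config = classification_config()) {
  if (any(!is.na(raw) & raw <= 0)) {
    stop("raw activity scores must be positive", call. = FALSE)
  }
  dplyr::case_when(
    is.na(raw) ~ NA_character_,
    raw > config$activity_wt_cutoff ~ "wt_like",
    raw < config$activity_loss_cutoff ~ "loss",
    TRUE ~ "indeterminate"
  )
}

#' Rescale raw activity for reporting
#'
#' `scaled = (raw - mean_nonsense) / (wt_score - mean_nonsense)`, so the
#' mean nonsense activity maps to 0 and the wild-type anchor to 1.
#'
#' @param raw Raw activity scores.
#' @param nonsense_scores Raw activities of the nonsense variants.
#' @param wt_score Raw activity of the wild-type anchor.
#' @return Rescaled scores.
#' @export
rescale_activity <- function(raw, nonsense_scores, wt_score) {
  m_non <- mean(nonsense_scores, na.rm = TRUE)
  if (!is.finite(m_non) || wt_score <= m_non) {
    stop("wild-type activity anchor must exceed the mean nonsense activity",
         call. = FALSE)
  }
  (raw - m_non) / (wt_score - m_non)
}

#' Combine abundance and activity classes
#'
#' @param abundance_class In `c("wt_like", "low", "unclassified")`.
#' @param activity_class In `c("wt_like", "loss", "indeterminate")`.
#' @return Joint class in `c("wt_like", "loss_abundance_only",
#'   "loss_activity_only", "loss_both", "unclassified")`.
#' @export
four_way_classify <- function(abundance_class, activity_class) {
  dplyr::case_when(
    is.na(abundance_class) | is.na(activity_class) ~ "unclassified",
    abundance_class == "unclassified" |
      activity_class == "indeterminate" ~ "unclassified",
    abundance_class == "wt_like" & activity_class == "wt_like" ~ "wt_like",
    abundance_class == "low" & activity_class == "wt_like" ~
      "loss_abundance_only",
    abundance_class == "wt_like" & activity_class == "loss" ~
      "loss_activity_only",
    abundance_class == "low" & activity_class == "loss" ~ "loss_both",
    TRUE ~ "unclassified"
  )
}

#' Integrate composite abundance and activity scores
#'
#' Joins composite abundance records (with `abundance_class`, see
#' [classify_abundance_confidence()]) to an activity table, classifies
#' activity on the raw scale, forms the four-way joint class, and attaches
#' the rescaled activity. Variants present in only one assay are kept with
#' joint class `unclassified` and an explanatory `unclassified_reason`
#' (`missing_abundance` / `missing_activity` are counted separately from
#' `indeterminate` calls).
#'
#' @param records Composite abundance records with `abundance_class`.
#' @param activity Activity table from [read_activity_scores()] or
#'   [generate_activity_scores()] (optionally containing a `"WT"` row).
#' @param config A [classification_config()].
#' @return Tibble of functional class records: `variant`, `consequence`,
#'   `score` (abundance), `abundance_class`, `activity`, `activity_class`,
#'   `scaled_activity`, `joint_class`, `unclassified_reason`.
#' @export
classify_variants <- function(records, activity,
                              config = classification_config()) {
  stopifnot("abundance_class" %in% names(records))
  wt_row <- activity[activity$variant == "WT", ]
  act <- activity[activity$variant != "WT", ]
  syn_mean <- mean(act$activity[act$consequence == "synonymous"],
                   na.rm = TRUE)
  wt_score <- switch(config$wt_anchor,
    wt_row = if (nrow(wt_row)) wt_row$activity[1] else
      stop("no designated WT row in activity table", call. = FALSE),
    synonymous_mean = syn_mean,
    auto = if (nrow(wt_row)) wt_row$activity[1] else syn_mean
  )
  if (!is.finite(wt_score)) {
    stop("no usable wild-type activity anchor (no WT row and no synonymous ",
         "variants)", call. = FALSE)
  }
  non_act <- act$activity[act$consequence == "nonsense"]
  joined <- dplyr::full_join(
    dplyr::select(records, "variant", "consequence", "score", "se",
                  "abundance_class"),
    dplyr::select(act, "variant", act_consequence = "consequence",
                  "activity"),
    by = "variant"
  ) |>
    dplyr::mutate(
      consequence = dplyr::coalesce(.data$consequence,
                                    .data$act_consequence),
      activity_class = classify_activity(.data$activity, config),
      scaled_activity = if (length(non_act) > 0) {
        rescale_activity(.data$activity, non_act, wt_score)
      } else NA_real_,
      joint_class = four_way_classify(.data$abundance_class,
                                      .data$activity_class),
      unclassified_reason = dplyr::case_when(
        .data$joint_class != "unclassified" ~ NA_character_,
        is.na(.data$abundance_class) ~ "missing_abundance",
        is.na(.data$activity_class) ~ "missing_activity",
        .data$abundance_class == "unclassified" &
          .data$activity_class == "indeterminate" ~ "both_indeterminate",
        .data$abundance_class == "unclassified" ~
          "indeterminate_abundance",
        TRUE ~ "indeterminate_activity"
      )
    ) |>
    dplyr::select(-"act_consequence")
  joined
}

#' Per-category class fold enrichment
#'
#' For every catalog category, the fraction of observations (or unique
#' variants) in each functional class is divided by that class's baseline
#' fraction (e.g. the degeneracy-weighted All-SNV null). Fractions are
#' computed over classified variants only, so within every category
#' `sum(fold * baseline)` is exactly 1.
#'
#' @param catalog Catalog tibble (`variant`, `category`, `n_obs`).
#' @param classes Class map: tibble with `variant` and `joint_class` (or
#'   `class`).
#' @param baseline Tibble with `class`, `fraction` summing to 1 over the
#'   four classes (see [expected_class_fractions()]).
#' @param mode `"per_observation"` (weight by `n_obs`, default for somatic
#'   catalogs) or `"unique_variant"` (each variant counts once, for
#'   clinical categories without frequencies).
#' @return Tibble `category`, `class`, `n`, `fraction`,
#'   `baseline_fraction`, `fold`.
#' @export
category_enrichment <- function(catalog, classes, baseline,
                                mode = c("per_observation",
                                         "unique_variant")) {
  mode <- match.arg(mode)
  if (abs(sum(baseline$fraction) - 1) > 1e-8) {
    stop("baseline fractions must sum to 1", call. = FALSE)
  }
  class_col <- if ("joint_class" %in% names(classes)) "joint_class" else
    "class"
  four <- c("wt_like", "loss_abundance_only", "loss_activity_only",
            "loss_both")
  mapped <- catalog |>
    dplyr::inner_join(
      dplyr::select(classes, "variant", class = dplyr::all_of(class_col)),
      by = "variant") |>
    dplyr::filter(.data$class %in% four)
  if (nrow(mapped) == 0L) {
    stop("no catalog variants with a four-way classification", call. = FALSE)
  }
  weight <- if (mode == "per_observation") mapped$n_obs else 1
  mapped |>
    dplyr::mutate(w = weight) |>
    dplyr::group_by(.data$category, .data$class) |>
    dplyr::summarise(n = sum(.data$w), .groups = "drop") |>
    tidyr::complete(category = unique(mapped$category),
                    class = four, fill = list(n = 0)) |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::left_join(
      dplyr::select(baseline, "class", baseline_fraction = "fraction"),
      by = "class") |>
    dplyr::mutate(fold = dplyr::case_when(
      .data$baseline_fraction > 0 ~ .data$fraction /
        .data$baseline_fraction,
      .data$fraction > 0 ~ Inf,
      TRUE ~ NaN
    )) |>
    (\(d) {
      if (any(is.infinite(d$fold))) {
        warning("class with zero baseline fraction observed in catalog; ",
                "fold reported as Inf", call. = FALSE)
      }
      d
    })()
}

#' Partition loss-of-activity-only variants by dominant-negative status
#'
#' Splits the loss-of-activity-only variants into the known
#' dominant-negative set and novel candidates. When a catalog is supplied,
#' the known set's contribution share (fraction of loss-of-activity-only
#' observations carried by known dominant negatives) is reported per
#' category.
#'
#' @param classes Functional class records (tibble with `variant`,
#'   `joint_class`).
#' @param known Known dominant-negative variant tokens (default
#'   [pten_known_dn()]).
#' @param catalog Optional catalog for contribution shares.
#' @return List with `known`, `novel_candidates` (tibbles of
#'   loss-of-activity-only records) and `category_share` (tibble
#'   `category`, `n_known`, `n_total`, `share`, or `NULL`).
#' @export
split_dominant_negative_candidates <- function(classes,
                                               known = pten_known_dn(),
                                               catalog = NULL) {
  known <- parse_variant(known)$variant
  lao <- dplyr::filter(classes, .data$joint_class == "loss_activity_only")
  out <- list(
    known = dplyr::filter(lao, .data$variant %in% known),
    novel_candidates = dplyr::filter(lao, !.data$variant %in% known),
    category_share = NULL
  )
  if (!is.null(catalog)) {
    out$category_share <- catalog |>
      dplyr::filter(.data$variant %in% lao$variant) |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(
        n_known = sum(.data$n_obs[.data$variant %in% known]),
        n_total = sum(.data$n_obs),
        share = .data$n_known / .data$n_total,
        .groups = "drop"
      )
  }
  out
}
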