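# Replicate-count filtering and composite score aggregation.
#
# A variant must be scored in at least k* replicates to enter the composite
# dataset. k* is chosen by a bootstrap test on the control variants: at a
# candidate k, the filtered data "separates" when the upper bound of the 95%
# confidence interval of the mean nonsense composite score lies below the
# 5th percentile of synonymous composite scores. The decision pass fraction
# comes from an ordinary paired bootstrap of control variants (each control
# keeps its replicate count); a label-permuted variant of the same procedure
# (replicate counts shuffled across the pooled controls) is available as the
# explicit null control for calibrating the test.

#' Replicate-filter configuration
#'
#' @param k_range Candidate replicate-filter values (default `0:15`).
#' @param n_boot Bootstrap resamples per candidate k (default 100).
#' @param ci_level Confidence level of the nonsense-mean interval.
#' @param syn_tail Synonymous lower-tail quantile defining the separation
#'   target (default 0.05, i.e. the lowest 5% of synonymous scores).
#' @param pass_fraction Minimum bootstrap pass fraction for a k to qualify.
#' @param ci `"normal"` (mean +/- z * se across control variants, default)
#'   or `"percentile"` (bootstrap percentile interval of the mean).
#' @param seed Integer seed for the bootstrap.
#' @return A `filter_config` list.
#' @export
filter_config <- function(k_range = 0:15, n_boot = 100, ci_level = 0.95,
                          syn_tail = 0.05, pass_fraction = 0.95,
                          ci = c("normal", "percentile"), seed = 1L) {
  stopifnot(n_boot >= 1, syn_tail >= 0, syn_tail < 0.5,
            ci_level > 0, ci_level < 1, pass_fraction > 0, pass_fraction <= 1)
  structure(
    list(k_range = sort(unique(as.integer(k_range))),
         n_boot = as.integer(n_boot), ci_level = ci_level,
         syn_tail = syn_tail, pass_fraction = pass_fraction,
         ci = match.arg(ci), seed = as.integer(seed)),
    class = "filter_config"
  )
}

# controls: tibble(score, n_reps, consequence) with one row per control
# variant (composite over all its scored replicates).
.control_table <- function(scores) {
  scores |>
    dplyr::filter(.data$consequence %in% c("synonymous", "nonsense"),
                  !is.na(.data$score)) |>
    dplyr::group_by(.data$variant, .data$consequence) |>
    dplyr::summarise(n_reps = dplyr::n(), score = mean(.data$score),
                     .groups = "drop")
}

.separation_pass <- function(syn, non, config) {
  if (length(syn) < 5L || length(non) < 5L) return(NA)
  z <- stats::qnorm(1 - (1 - config$ci_level) / 2)
  upper <- mean(non) + z * stats::sd(non) / sqrt(length(non))
  upper < stats::quantile(syn, config$syn_tail, names = FALSE)
}

#' Evaluate one replicate-filter value
#'
#' Filters the control variants to those scored in at least `k` replicates
#' and asks, over bootstrap resamples, how often the upper bound of the 95%
#' CI of the mean nonsense composite score falls below the lowest
#' `syn_tail` quantile of synonymous composite scores. With
#' `permute_null = TRUE` the replicate-count labels are shuffled across the
#' pooled controls in every resample, destroying any true association
#' between score quality and replicate count — the calibration null.
#'
#' @param scores Long replicate score table (see [score_experiment()]); only
#'   control variants are used.
#' @param k Candidate filter value.
#' @param config A [filter_config()].
#' @param permute_null Run the label-permutation null instead of the paired
#'   bootstrap.
#' @return A `filter_evaluation` list: `k`, `pass_fraction`,
#'   `observed_pass`, `n_syn`, `n_non` (controls surviving k in the observed
#'   data), `n_boot`, `status` (`"ok"` or `"insufficient controls"`).
#' @export
evaluate_filter_value <- function(scores, k, config = filter_config(),
                                  permute_null = FALSE) {
  ctrl <- .control_table(scores)
  syn <- ctrl[ctrl$consequence == "synonymous", ]
  non <- ctrl[ctrl$consequence == "nonsense", ]
  obs_syn <- syn$score[syn$n_reps >= k]
  obs_non <- non$score[non$n_reps >= k]
  observed <- .separation_pass(obs_syn, obs_non, config)
  if (is.na(observed)) {
    return(structure(
      list(k = k, pass_fraction = 0, observed_pass = FALSE,
           n_syn = length(obs_syn), n_non = length(obs_non),
           n_boot = config$n_boot, status = "insufficient controls"),
      class = "filter_evaluation"))
  }
  pass <- logical(config$n_boot)
  .with_seed(.child_seed(config$seed, paste0("filter_k", k, permute_null)), {
    for (b in seq_len(config$n_boot)) {
      bs <- syn[sample(nrow(syn), replace = TRUE), ]
      bn <- non[sample(nrow(non), replace = TRUE), ]
      if (permute_null) {
        pooled <- c(bs$n_reps, bn$n_reps)
        pooled <- sample(pooled)
        bs$n_reps <- pooled[seq_len(nrow(bs))]
        bn$n_reps <- pooled[-seq_len(nrow(bs))]
      }
      p <- .separation_pass(bs$score[bs$n_reps >= k],
                            bn$score[bn$n_reps >= k], config)
      pass[b] <- isTRUE(p)
    }
  })
  structure(
    list(k = k, pass_fraction = mean(pass), observed_pass = observed,
         n_syn = length(obs_syn), n_non = length(obs_non),
         n_boot = config$n_boot, status = "ok"),
    class = "filter_evaluation"
  )
}

#' @export
print.filter_evaluation <- function(x, ...) {
  cat("<filter_evaluation> k =", x$k,
      "| pass fraction", format(x$pass_fraction),
      "| observed", if (isTRUE(x$observed_pass)) "pass" else "fail",
      "|", x$n_syn, "syn /", x$n_non, "non controls",
      if (x$status != "ok") paste0(" [", x$status, "]"), "\n")
  invisible(x)
}

#' Select the minimal replicate filter
#'
#' Evaluates every k in `k_range` and returns the smallest k whose bootstrap
#' pass fraction reaches `pass_fraction`.
#'
#' @inheritParams evaluate_filter_value
#' @return A `replicate_filter` object: `k_star` plus a per-k report
#'   (accessible via [tidy()]); errors listing the pass fractions when no k
#'   qualifies.
#' @export
select_replicate_filter <- function(scores, config = filter_config()) {
  evals <- purrr::map(config$k_range, function(k) {
    evaluate_filter_value(scores, k, config)
  })
  report <- purrr::map_dfr(evals, function(e) {
    tibble::tibble(k = e$k, pass_fraction = e$pass_fraction,
                   observed_pass = e$observed_pass,
                   n_syn = e$n_syn, n_non = e$n_non, status = e$status)
  })
  ok <- report$k[report$pass_fraction >= config$pass_fraction]
  if (length(ok) == 0L) {
    stop("no replicate filter value reached a pass fraction of ",
         config$pass_fraction, "; fractions were: ",
         paste(sprintf("k=%d:%.2f", report$k, report$pass_fraction),
               collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(k_star = min(ok), report = report, config = config),
    class = "replicate_filter"
  )
}

#' @export
print.replicate_filter <- function(x, ...) {
  cat("<replicate_filter> selected k* =", x$k_star, "over k in [",
      min(x$report$k), ",", max(x$report$k), "] with",
      x$config$n_boot, "bootstraps\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.replicate_filter <- function(x, ...) x$report

#' @export
glance.replicate_filter <- function(x, ...) {
  tibble::tibble(k_star = x$k_star, n_boot = x$config$n_boot,
                 pass_fraction_threshold = x$config$pass_fraction,
                 n_candidates = nrow(x$report))
}

#' Aggregate replicate scores into composite scores
#'
#' The composite score is the mean of a variant's per-replicate normalized
#' scores; variants scored in fewer than `min_replicates` replicates are
#' excluded. The coefficient of variation is reported only for composite
#' scores above 0.05 (it diverges near the nonsense anchor).
#'
#' @param scores Long replicate score table.
#' @param min_replicates The selected replicate filter k* (or an override).
#' @return Tibble of composite records: `variant`, `consequence`, `n_reps`,
#'   `score`, `sd`, `se`, `cv`, `cv_undefined`.
#' @export
aggregate_composite <- function(scores, min_replicates = 0L) {
  if (inherits(min_replicates, "replicate_filter")) {
    min_replicates <- min_replicates$k_star
  }
  scores |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::group_by(.data$variant, .data$consequence) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      sd = stats::sd(.data$score),
      score = mean(.data$score),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_reps >= min_replicates) |>
    dplyr::mutate(
      se = .data$sd / sqrt(.data$n_reps),
      cv_undefined = .data$score <= 0.05,
      cv = dplyr::if_else(.data$cv_undefined, NA_real_,
                          .data$sd / .data$score)
    )
}

#' Assign abundance confidence classes
#'
#' Thresholds come from the composite control distributions: `q_syn` is the
#' 5th percentile of synonymous composite scores, `q_non` the 95th
#' percentile of nonsense composite scores. A variant is confidently
#' `wt_like` when `score - 2*se > q_non` and `score + 2*se >= q_syn`;
#' confidently `low` when `score + 2*se < q_syn` and `score - 2*se <=
#' q_non`; otherwise `unclassified`. Variants without a standard error
#' (single replicate) are unclassified.
#'
#' @param records Composite records from [aggregate_composite()].
#' @param syn_tail,non_tail Control quantiles defining the thresholds.
#' @return `records` with an `abundance_class` column.
#' @export
classify_abundance_confidence <- function(records, syn_tail = 0.05,
                                          non_tail = 0.95) {
  syn <- records$score[records$consequence == "synonymous"]
  non <- records$score[records$consequence == "nonsense"]
  if (length(syn) == 0L || length(non) == 0L) {
    stop("composite records must include synonymous and nonsense controls",
         call. = FALSE)
  }
  q_syn <- stats::quantile(syn, syn_tail, names = FALSE)
  q_non <- stats::quantile(non, non_tail, names = FALSE)
  if (q_syn <= q_non) {
    stop("control distributions do not separate: 5th pct synonymous (",
         signif(q_syn, 4), ") <= 95th pct nonsense (", signif(q_non, 4), ")",
         call. = FALSE)
  }
  records |>
    dplyr::mutate(abundance_class = dplyr::case_when(
      is.na(.data$se) ~ "unclassified",
      .data$score - 2 * .data$se > q_non &
        .data$score + 2 * .data$se >= q_syn ~ "wt_like",
      .data$score + 2 * .data$se < q_syn &
        .data$score - 2 * .data$se <= q_non ~ "low",
      TRUE ~ "unclassified"
    ))
}

#' Compare two score sets over their shared variants
#'
#' Ordinary least squares of `b` on `a` over the overlapping variants, with
#' Pearson and Spearman correlations over the same pairs. Used to decide
#' whether two independently scored libraries can be combined without
#' further normalization (|slope - 1| and |intercept| within tolerance).
#'
#' @param a,b Tibbles with `variant` and a score column.
#' @param score_col Score column name (default `"score"`).
#' @return A `score_set_comparison` object with [tidy()] and [glance()]
#'   methods; `glance()` reports `n_overlap`, `slope`, `intercept`,
#'   `pearson_r2`, `spearman_rho2`.
#' @export
compare_score_sets <- function(a, b, score_col = "score") {
  shared <- dplyr::inner_join(
    dplyr::select(a, "variant", a_score = dplyr::all_of(score_col)),
    dplyr::select(b, "variant", b_score = dplyr::all_of(score_col)),
    by = "variant"
  ) |>
    dplyr::filter(!is.na(.data$a_score), !is.na(.data$b_score))
  if (nrow(shared) < 3L) {
    stop("need at least 3 overlapping scored variants, got ", nrow(shared),
         call. = FALSE)
  }
  fit <- stats::lm(b_score ~ a_score, data = shared)
  structure(
    list(
      fit = fit,
      data = shared,
      n_overlap = nrow(shared),
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      pearson_r2 = stats::cor(shared$a_score, shared$b_score)^2,
      spearman_rho2 = stats::cor(shared$a_score, shared$b_score,
                                 method = "spearman")^2
    ),
    class = "score_set_comparison"
  )
}

#' @export
print.score_set_comparison <- function(x, ...) {
  cat("<score_set_comparison>", x$n_overlap, "overlapping variants\n",
      " slope", signif(x$slope, 3), "intercept", signif(x$intercept, 3),
      "| Pearson r^2", signif(x$pearson_r2, 3),
      "| Spearman rho^2", signif(x$spearman_rho2, 3), "\n")
  invisible(x)
}

#' @export
tidy.score_set_comparison <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4])
  )
}

#' @export
glance.score_set_comparison <- function(x, ...) {
  tibble::tibble(n_overlap = x$n_overlap, slope = x$slope,
                 intercept = x$intercept, pearson_r2 = x$pearson_r2,
                 spearman_rho2 = x$spearman_rho2)
}

#' Gate for combining two score sets
#'
#' @param comparison A [compare_score_sets()] result.
#' @param slope_tol,intercept_tol Tolerances on |slope - 1| and |intercept|.
#' @return `TRUE`/`FALSE`.
#' @export
score_sets_combinable <- function(comparison, slope_tol = 0.15,
                                  intercept_tol = 0.15) {
  abs(comparison$slope - 1) <= slope_tol &&
    abs(comparison$intercept) <= intercept_tol
}
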