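# ggplot2 views of the pipeline's result types.

JOINT_CLASS_COLORS <- c(
  wt_like = "#2ca02c", loss_abundance_only = "#17becf",
  loss_activity_only = "#ff7f0e", loss_both = "#9467bd",
  unclassified = "grey70"
)

#' Replicate-filter pass fractions per candidate k
#'
#' @param x A `replicate_filter` from [select_replicate_filter()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.replicate_filter <- function(x, ...) {
  ggplot2::ggplot(x$report, ggplot2::aes(x = .data$k,
                                         y = .data$pass_fraction)) +
    ggplot2::geom_hline(yintercept = x$config$pass_fraction,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = x$k_star, colour = "#d62728",
                        alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "replicate filter k",
                  y = "bootstrap pass fraction",
                  title = paste0("Replicate filter selection (k* = ",
                                 x$k_star, ")")) +
    ggplot2::theme_minimal()
}

#' Scatter of two score sets with the fitted line
#'
#' @param x A `score_set_comparison` from [compare_score_sets()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.score_set_comparison <- function(x, ...) {
  ggplot2::ggplot(x$data, ggplot2::aes(x = .data$a_score,
                                       y = .data$b_score)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = x$slope, intercept = x$intercept,
                         colour = "#9467bd") +
    ggplot2::labs(
      x = "score, set A", y = "score, set B",
      title = sprintf("n = %d, slope %.2f, intercept %.2f, r² %.2f",
                      x$n_overlap, x$slope, x$intercept, x$pearson_r2)) +
    ggplot2::theme_minimal()
}

#' Composite abundance score distributions by consequence
#'
#' @param records Composite records from [aggregate_composite()].
#' @return A ggplot.
#' @export
plot_score_distribution <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$score,
                                        fill = .data$consequence)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.7,
                            position = "identity") +
    ggplot2::labs(x = "composite abundance score", y = "variants") +
    ggplot2::theme_minimal()
}

#' Abundance vs activity scatter colored by joint class
#'
#' @param classes Functional class records from [classify_variants()].
#' @return A ggplot.
#' @export
plot_abundance_activity <- function(classes) {
  d <- dplyr::filter(classes, !is.na(.data$score), !is.na(.data$activity))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score,
                                  y = .data$scaled_activity,
                                  colour = .data$joint_class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::scale_colour_manual(values = JOINT_CLASS_COLORS) +
    ggplot2::labs(x = "composite abundance score",
                  y = "rescaled activity score",
                  colour = "joint class") +
    ggplot2::theme_minimal()
}

#' Fold enrichment per category and class
#'
#' @param enrichment Output of [category_enrichment()].
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data$class, y = .data$fold,
                               colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_manual(values = JOINT_CLASS_COLORS,
                                 guide = "none") +
    ggplot2::facet_wrap(~category) +
    ggplot2::labs(x = NULL, y = "fold enrichment vs All-SNV baseline") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Mutational tolerance heatmap
#'
#' Positions are ordered by the clustering when one is supplied, otherwise
#' by coordinate; unscored substitutions are grey.
#'
#' @param profiles Output of [tolerance_profiles()].
#' @param clustering Optional [cluster_positions()] result.
#' @return A ggplot.
#' @export
plot_tolerance_heatmap <- function(profiles, clustering = NULL) {
  long <- profiles |>
    dplyr::mutate(scores = purrr::map(.data$scores, function(v) {
      tibble::tibble(mut_aa = names(v), score = unname(v))
    })) |>
    tidyr::unnest("scores")
  ord <- if (is.null(clustering)) sort(unique(long$position)) else
    clustering$order
  long <- dplyr::filter(long, .data$position %in% ord)
  long$position <- factor(long$position, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$mut_aa,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#d62728", mid = "white",
                                  high = "#1f77b4", midpoint = 0.5,
                                  na.value = "grey80") +
    ggplot2::labs(x = "position", y = "substitution",
                  fill = "abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 6))
}
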