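# Per-position mutational tolerance profiles and clustering.
#
# A position's tolerance profile is the vector of composite abundance scores
# of its scored missense substitutions. High-coverage positions (>= 17
# scored missense variants by default) are compared with a
# pairwise-complete Euclidean distance rescaled by sqrt(19 / n_shared) and
# clustered agglomeratively.

#' Build per-position tolerance profiles
#'
#' @param records Composite score records (tibble with `variant`, `score`).
#' @param exclude_stop Drop nonsense substitutions from profiles (default).
#' @return A tibble with `position`, `n_scored` (scored missense entries),
#'   `positional_median`, and a `scores` list-column of named score vectors
#'   (names are mutant amino acids).
#' @export
tolerance_profiles <- function(records, exclude_stop = TRUE) {
  parsed <- parse_variant(records$variant)
  d <- dplyr::bind_cols(parsed[, c("position", "mut_aa")],
                        score = records$score) |>
    dplyr::filter(!is.na(.data$score))
  d <- dplyr::semi_join(
    d, dplyr::filter(parsed, .data$consequence == "missense" |
                       (!exclude_stop & .data$consequence == "nonsense")),
    by = c("position", "mut_aa"))
  if (exclude_stop) d <- dplyr::filter(d, .data$mut_aa != "*")
  d |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(
      n_scored = dplyr::n(),
      positional_median = stats::median(.data$score),
      scores = list(stats::setNames(.data$score, .data$mut_aa)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$position)
}

#' Select high-coverage positions
#'
#' @param profiles Output of [tolerance_profiles()] (or composite records,
#'   which are profiled first).
#' @param min_missense Minimum scored missense variants per position
#'   (default 17).
#' @return Integer vector of positions.
#' @export
select_high_coverage_positions <- function(profiles, min_missense = 17) {
  if (!"n_scored" %in% names(profiles)) {
    profiles <- tolerance_profiles(profiles)
  }
  profiles$position[profiles$n_scored >= min_missense]
}

.profile_matrix <- function(profiles) {
  aas <- setdiff(names(AA_THREE), "*")
  m <- matrix(NA_real_, nrow(profiles), length(aas),
              dimnames = list(profiles$position, aas))
  for (i in seq_len(nrow(profiles))) {
    v <- profiles$scores[[i]]
    m[i, intersect(names(v), aas)] <- v[intersect(names(v), aas)]
  }
  m
}

# pairwise-complete Euclidean distance, rescaled by sqrt(19 / n_shared) so
# sparse overlaps are comparable with complete ones
.profile_dist <- function(m, min_shared = 5L) {
  n <- nrow(m)
  d <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      shared <- !is.na(m[i, ]) & !is.na(m[j, ])
      ns <- sum(shared)
      if (ns >= min_shared) {
        d[i, j] <- d[j, i] <-
          sqrt(sum((m[i, shared] - m[j, shared])^2) * 19 / ns)
      }
    }
  }
  diag(d) <- 0
  d
}

#' Cluster positions by tolerance pattern
#'
#' Agglomerative clustering (average linkage by default) of high-coverage
#' position profiles. Positions sharing fewer than `min_shared` scored
#' amino acids with every other position are excluded with a warning; any
#' remaining incomparable pair is assigned the maximum observed distance.
#' Input rows are ordered by position before clustering so the result is
#' invariant to row permutation.
#'
#' @param profiles Output of [tolerance_profiles()].
#' @param k Number of flat groups to cut the dendrogram into.
#' @param linkage `stats::hclust` method (default `"average"`).
#' @param min_shared Minimum shared scored amino acids per pair.
#' @return A `position_clustering` object: `hclust`, `order` (positions in
#'   dendrogram order), `groups` (tibble `position`, `cluster`),
#'   `excluded` (positions dropped for insufficient overlap).
#' @export
cluster_positions <- function(profiles, k = 3, linkage = "average",
                              min_shared = 5L) {
  stopifnot(nrow(profiles) >= 2)
  profiles <- dplyr::arrange(profiles, .data$position)
  m <- .profile_matrix(profiles)
  d <- .profile_dist(m, min_shared)
  isolated <- which(vapply(seq_len(nrow(d)), function(i) {
    all(is.na(d[i, -i]))
  }, TRUE))
  excluded <- as.integer(rownames(d)[isolated])
  if (length(isolated) > 0L) {
    warning(length(isolated), " position(s) share < ", min_shared,
            " scored amino acids with every other position; excluded",
            call. = FALSE)
    d <- d[-isolated, -isolated, drop = FALSE]
  }
  if (nrow(d) < 2L) stop("fewer than 2 comparable positions", call. = FALSE)
  if (anyNA(d)) d[is.na(d)] <- max(d, na.rm = TRUE)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  groups <- stats::cutree(hc, k = min(k, nrow(d)))
  structure(
    list(
      hclust = hc,
      order = as.integer(rownames(d)[hc$order]),
      groups = tibble::tibble(position = as.integer(names(groups)),
                              cluster = unname(groups)),
      excluded = excluded
    ),
    class = "position_clustering"
  )
}

#' @export
print.position_clustering <- function(x, ...) {
  cat("<position_clustering>", length(x$order), "positions,",
      max(x$groups$cluster), "groups",
      if (length(x$excluded)) paste0(" (", length(x$excluded),
                                     " excluded)"), "\n")
  invisible(x)
}

#' Export a position dendrogram as Newick text
#'
#' @param clustering A [cluster_positions()] result.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(clustering, path = NULL) {
  phy <- ape::as.phylo(clustering$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Assign tolerance groups from positional medians
#'
#' A position is `tolerant` when its positional median composite score is at
#' least `tolerant_min`, `intolerant` when at most `intolerant_max`, and
#' `partial` otherwise; positions below the coverage threshold stay `NA`.
#' The default boundaries (0.75 / 0.35) are package defaults on the
#' nonsense-0 / synonymous-1 composite scale, exposed as arguments.
#'
#' @param profiles Output of [tolerance_profiles()].
#' @param tolerant_min,intolerant_max Median thresholds.
#' @param min_missense Coverage threshold for assignment.
#' @return `profiles` with a `group` column.
#' @export
tolerance_group <- function(profiles, tolerant_min = 0.75,
                            intolerant_max = 0.35, min_missense = 17) {
  stopifnot(intolerant_max < tolerant_min)
  profiles |>
    dplyr::mutate(group = dplyr::case_when(
      .data$n_scored < min_missense ~ NA_character_,
      .data$positional_median >= tolerant_min ~ "tolerant",
      .data$positional_median <= intolerant_max ~ "intolerant",
      TRUE ~ "partial"
    ))
}
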