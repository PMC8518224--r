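# Synthetic sort-seq data generator.
#
# Emulates a VAMP-seq style experiment: a variant library with known true
# abundances and activities, FACS sorting of a fluorescent-fusion cell pool
# into four equally populated bins, multinomial read sampling per bin, and
# per-variant per-replicate dropout. Every generator is a pure function of
# (config, seed) so downstream stages are testable without external data.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.child_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1e6
  as.integer((seed * 1009 + h) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults describe a desk-scale sort-seq experiment: 500 variants scored in
#' 8 replicate sorts at 50,000 reads per bin, with Gaussian cell-level
#' fluorescence noise (sd 0.10 on the unit abundance scale) and 15%
#' variant-per-replicate dropout emulating library sparseness.
#'
#' @param n_variants Library size (including controls).
#' @param n_replicates Number of replicate sort experiments.
#' @param reads_per_bin Sequencing depth per fluorescence bin.
#' @param cells_per_variant Sorted cells per (present) variant per replicate.
#' @param fluorescence_noise_sd Cell-level Gaussian noise sd on the unit
#'   abundance scale.
#' @param dropout_rate Probability a variant is absent from a replicate.
#' @param class_mix Named proportions over the four true functional classes;
#'   must sum to 1.
#' @param n_synonymous,n_nonsense Number of designated control variants.
#' @param activity_noise_sd Log10-scale lognormal noise sd for simulated
#'   activity scores.
#' @param seed Integer seed; all generators derive their randomness from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_variants = 500,
                       n_replicates = 8,
                       reads_per_bin = 50000,
                       cells_per_variant = 1000,
                       fluorescence_noise_sd = 0.10,
                       dropout_rate = 0.15,
                       class_mix = c(wt_like = 0.5,
                                     loss_abundance_only = 0.2,
                                     loss_activity_only = 0.1,
                                     loss_both = 0.2),
                       n_synonymous = 20,
                       n_nonsense = 20,
                       activity_noise_sd = 0.1,
                       seed = 1L) {
  stopifnot(
    n_variants >= 1, n_replicates >= 1, reads_per_bin >= 1,
    cells_per_variant >= 1, fluorescence_noise_sd >= 0,
    dropout_rate >= 0, dropout_rate < 1,
    abs(sum(class_mix) - 1) < 1e-8,
    setequal(names(class_mix),
             c("wt_like", "loss_abundance_only",
               "loss_activity_only", "loss_both"))
  )
  structure(
    list(n_variants = as.integer(n_variants),
         n_replicates = as.integer(n_replicates),
         reads_per_bin = as.integer(reads_per_bin),
         cells_per_variant = as.integer(cells_per_variant),
         fluorescence_noise_sd = fluorescence_noise_sd,
         dropout_rate = dropout_rate,
         class_mix = class_mix,
         n_synonymous = as.integer(n_synonymous),
         n_nonsense = as.integer(n_nonsense),
         activity_noise_sd = activity_noise_sd,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Abundance and activity priors per true class. Abundant classes sit in
# [0.7, 1], destabilized classes in [0, 0.3]; activity (raw, log10 scale)
# stays clear of the classification cutoffs (10^-1.11 / 10^-2.13) so that a
# lognormal noise sd of ~0.1 log10 misclassifies < 5% of variants.
.draw_abundance <- function(class, n) {
  switch(class,
    wt_like = ,
    loss_activity_only = stats::runif(n, 0.7, 1.0),
    loss_abundance_only = ,
    loss_both = stats::runif(n, 0.0, 0.3),
    synonymous = stats::runif(n, 0.9, 1.0),
    nonsense = stats::runif(n, 0.0, 0.05)
  )
}

.draw_activity <- function(class, n) {
  lost <- class %in% c("loss_activity_only", "loss_both", "nonsense")
  if (lost) 10^stats::runif(n, -2.5, -2.35) else 10^stats::runif(n, -0.9, 0)
}

#' Generate a true variant library
#'
#' Draws a library of amino-acid variants with known ("true") abundances,
#' raw activities, functional classes, and per-replicate presence flags.
#' Designated synonymous and nonsense control sets are always included; the
#' remaining variants are missense, drawn from `class_mix`.
#'
#' @param config A [sim_config()].
#' @param variants Optional tibble of candidate missense variants (columns
#'   `variant`, `consequence`) to draw identities from, e.g. the
#'   SNV-reachable variants of a CDS; by default identities are synthesized
#'   site-saturation style (any substitution) over `positions`.
#' @param positions Protein positions over which synthesized missense
#'   identities are drawn (default `2:402`); concentrating them raises
#'   per-position coverage.
#' @param wildtype Optional `cds_sequence` (or character vector of
#'   one-letter residues indexed by position) supplying the wild-type
#'   residue at each position, so synthesized variant tokens are consistent
#'   with a reference sequence; random residues are used when `NULL`.
#' @return Tibble: `variant`, `consequence`, `true_class`, `true_abundance`,
#'   `true_activity_raw`, and a `present` list-column of per-replicate
#'   logical flags.
#' @export
generate_library <- function(config = sim_config(), variants = NULL,
                             positions = 2:402, wildtype = NULL) {
  n_ctrl <- config$n_synonymous + config$n_nonsense
  if (config$n_variants <= n_ctrl) {
    stop("n_variants (", config$n_variants,
         ") must exceed the number of control variants (", n_ctrl, ")",
         call. = FALSE)
  }
  .with_seed(.child_seed(config$seed, "library"), {
    n_mis <- config$n_variants - n_ctrl
    classes <- sample(names(config$class_mix), n_mis,
                      replace = TRUE, prob = config$class_mix)
    aas <- setdiff(names(AA_THREE), "*")
    if (is.null(variants)) {
      # site-saturation style: one fixed wild-type residue per position,
      # substitutions drawn without replacement within a position
      wt_by_pos <- if (is.null(wildtype)) {
        stats::setNames(sample(aas, length(positions), replace = TRUE),
                        positions)
      } else {
        prot <- if (inherits(wildtype, "cds_sequence")) wildtype$protein
                else wildtype
        stopifnot(max(positions) <= length(prot),
                  all(prot[positions] %in% aas))
        stats::setNames(prot[positions], positions)
      }
      all_ids <- tidyr::expand_grid(position = positions, mut = aas) |>
        dplyr::mutate(wt = wt_by_pos[as.character(.data$position)]) |>
        dplyr::filter(.data$mut != .data$wt)
      if (nrow(all_ids) < n_mis) {
        stop("position range too small for requested missense count",
             call. = FALSE)
      }
      pick <- all_ids[sample(nrow(all_ids), n_mis), ]
      mis_id <- paste0(pick$wt, pick$position, pick$mut)
    } else {
      pool <- dplyr::filter(variants, .data$consequence == "missense")
      if (nrow(pool) < n_mis) {
        stop("variant pool smaller than requested missense count",
             call. = FALSE)
      }
      mis_id <- sample(pool$variant, n_mis)
    }
    syn_aa <- sample(aas, config$n_synonymous, replace = TRUE)
    syn_id <- paste0(syn_aa, seq_len(config$n_synonymous) + 500L, syn_aa)
    non_id <- paste0(sample(aas, config$n_nonsense, replace = TRUE),
                     seq_len(config$n_nonsense) + 600L, "*")
    lib <- tibble::tibble(
      variant = c(syn_id, non_id, mis_id),
      consequence = c(rep("synonymous", config$n_synonymous),
                      rep("nonsense", config$n_nonsense),
                      rep("missense", n_mis)),
      true_class = c(rep("wt_like", config$n_synonymous),
                     rep("loss_both", config$n_nonsense),
                     classes)
    )
    draw_class <- c(rep("synonymous", config$n_synonymous),
                    rep("nonsense", config$n_nonsense), classes)
    lib$true_abundance <- vapply(
      draw_class, function(cl) .draw_abundance(cl, 1L), 0)
    lib$true_activity_raw <- vapply(
      draw_class, function(cl) .draw_activity(cl, 1L), 0)
    lib$present <- lapply(seq_len(nrow(lib)), function(i) {
      stats::runif(config$n_replicates) >= config$dropout_rate
    })
    lib
  })
}

#' Simulate one replicate sort
#'
#' For each variant present in the replicate, `cells_per_variant` cells are
#' given a fluorescence value `true_abundance + N(0, noise_sd)`; quartile
#' gates are drawn at the 25/50/75th percentiles of the pooled cell
#' population; reads are then drawn multinomially within each bin to a depth
#' of `reads_per_bin`.
#'
#' @param library Output of [generate_library()].
#' @param config The [sim_config()].
#' @param replicate_index Integer in `1:n_replicates`.
#' @return Tibble of bin counts: `variant`, `consequence`, `bin` (1..4, low
#'   to high fluorescence), `count`. Column sums per bin equal
#'   `reads_per_bin` exactly.
#' @export
simulate_sort_replicate <- function(library, config, replicate_index) {
  stopifnot(nrow(library) > 0,
            replicate_index >= 1, replicate_index <= config$n_replicates)
  if (config$reads_per_bin < 1) stop("reads_per_bin must be >= 1")
  .with_seed(.child_seed(config$seed, paste0("sort", replicate_index)), {
    present <- vapply(library$present, `[[`, TRUE, replicate_index)
    idx <- which(present)
    if (length(idx) == 0L) stop("no variants present in replicate")
    ncell <- config$cells_per_variant
    fl <- rep(library$true_abundance[idx], each = ncell) +
      stats::rnorm(length(idx) * ncell, 0, config$fluorescence_noise_sd)
    vid <- rep(idx, each = ncell)
    gates <- stats::quantile(fl, c(0.25, 0.5, 0.75), names = FALSE)
    bin <- findInterval(fl, gates) + 1L
    cellcounts <- matrix(0, nrow(library), 4)
    tab <- table(factor(vid, levels = seq_len(nrow(library))),
                 factor(bin, levels = 1:4))
    cellcounts[] <- as.numeric(tab)
    counts <- matrix(0, nrow(library), 4)
    for (b in 1:4) {
      if (sum(cellcounts[, b]) > 0) {
        counts[, b] <- stats::rmultinom(1, config$reads_per_bin,
                                        cellcounts[, b])
      }
    }
    tibble::tibble(
      variant = rep(library$variant, 4L),
      consequence = rep(library$consequence, 4L),
      bin = rep(1:4, each = nrow(library)),
      count = as.integer(counts)
    ) |>
      dplyr::filter(rep(present, 4L))
  })
}

#' Simulate a full multi-replicate sort experiment
#'
#' @inheritParams simulate_sort_replicate
#' @return Long tibble with a `replicate` column stacked over
#'   [simulate_sort_replicate()] outputs.
#' @export
simulate_sort_experiment <- function(library, config) {
  purrr::map_dfr(seq_len(config$n_replicates), function(r) {
    dplyr::mutate(simulate_sort_replicate(library, config, r),
                  replicate = r, .before = 1)
  })
}

#' Generate raw activity scores for a library
#'
#' Raw activity is the library's true activity multiplied by lognormal noise
#' (`activity_noise_sd` on the log10 scale). On the raw scale, wild-type-like
#' classes lie above the upper classification cutoff and loss classes below
#' the lower cutoff before noise.
#'
#' @param library Output of [generate_library()].
#' @param config The [sim_config()].
#' @return Tibble `variant`, `consequence`, `activity` (raw scale).
#' @export
generate_activity_scores <- function(library, config) {
  .with_seed(.child_seed(config$seed, "activity"), {
    tibble::tibble(
      variant = library$variant,
      consequence = library$consequence,
      activity = library$true_activity_raw *
        10^stats::rnorm(nrow(library), 0, config$activity_noise_sd)
    )
  })
}

#' Generate a synthetic variant catalog from a null spectrum
#'
#' Emulates a somatic/clinical variant catalog: observations are allocated to
#' the four functional classes according to target fold enrichments over the
#' spectrum's degeneracy-weighted baseline, then variant identities within
#' each class are sampled with probability proportional to SNV degeneracy.
#'
#' Classes with a fold target different from 1 receive exactly
#' `fold * baseline` of the observations (largest-remainder rounding);
#' classes with fold 1 share the remaining probability proportionally to
#' their baseline, so the realized composition always sums to one. When all
#' folds differ from 1 the weights are renormalized globally instead.
#'
#' @param spectrum A classified null spectrum: tibble with `variant`,
#'   `frequency`, and `class` (see [null_spectrum()]); rows with `NA` class
#'   are ignored.
#' @param fold_enrichments Named numeric over the four classes.
#' @param n_observations Total observations to draw; 0 gives an empty
#'   catalog.
#' @param seed Integer seed.
#' @param category Category label for the emitted catalog.
#' @return Catalog tibble: `variant`, `consequence`, `category`, `n_obs`.
#' @export
generate_cancer_catalog <- function(spectrum, fold_enrichments,
                                    n_observations, seed = 1L,
                                    category = "synthetic") {
  classes <- names(fold_enrichments)
  stopifnot(length(classes) > 0)
  spec <- dplyr::filter(spectrum, !is.na(.data$class),
                        .data$class %in% classes)
  if (nrow(spec) == 0L) stop("spectrum has no classified variants")
  if (all(fold_enrichments <= 0)) stop("all-zero fold enrichments")
  if (n_observations == 0) {
    return(tibble::tibble(variant = character(), consequence = character(),
                          category = character(), n_obs = numeric()))
  }
  base <- spec |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(w = sum(.data$frequency), .groups = "drop") |>
    dplyr::mutate(frac = .data$w / sum(.data$w))
  base <- base[match(classes, base$class), ]
  base$frac[is.na(base$frac)] <- 0
  targeted <- fold_enrichments != 1
  q <- fold_enrichments * base$frac
  if (any(!targeted) && sum(q[targeted]) < 1) {
    q[!targeted] <- base$frac[!targeted] *
      (1 - sum(q[targeted])) / sum(base$frac[!targeted])
  } else {
    q <- q / sum(q)
  }
  # largest-remainder allocation of observations to classes
  raw_n <- n_observations * q
  n_class <- floor(raw_n)
  rem <- n_observations - sum(n_class)
  if (rem > 0) {
    ord <- order(raw_n - n_class, decreasing = TRUE)
    n_class[ord[seq_len(rem)]] <- n_class[ord[seq_len(rem)]] + 1
  }
  .with_seed(seed, {
    draws <- purrr::map_dfr(seq_along(classes), function(i) {
      if (n_class[i] == 0) return(NULL)
      pool <- dplyr::filter(spec, .data$class == classes[i])
      if (nrow(pool) == 0L) {
        stop("no spectrum variants in class ", classes[i], call. = FALSE)
      }
      picked <- sample(nrow(pool), n_class[i], replace = TRUE,
                       prob = pool$frequency)
      tibble::tibble(variant = pool$variant[picked])
    })
    draws |>
      dplyr::count(.data$variant, name = "n_obs") |>
      dplyr::left_join(
        dplyr::distinct(spec, .data$variant, .data$consequence),
        by = "variant") |>
      dplyr::transmute(.data$variant, .data$consequence,
                       category = category, n_obs = as.numeric(.data$n_obs))
  })
}

#' Generate a toy coding sequence
#'
#' Starts with ATG, ends with a stop codon, and contains no internal stops.
#'
#' @param n_codons Total codons including start and stop (`>= 2`).
#' @param seed Integer seed.
#' @return A `cds_sequence`.
#' @export
generate_toy_cds <- function(n_codons, seed = 1L) {
  stopifnot(n_codons >= 2)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  stops <- names(code)[code == "*"]
  .with_seed(seed, {
    mid <- if (n_codons > 2) sample(sense, n_codons - 2L, replace = TRUE)
           else character()
    new_cds_sequence(
      paste0("toy_cds_", n_codons, "c_seed", seed),
      paste0(c("ATG", mid, sample(stops, 1L)), collapse = "")
    )
  })
}
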