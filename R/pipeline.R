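# End-to-end pipeline orchestration.
#
# run_pipeline() chains simulate -> score -> composite -> classify ->
# nullmodel -> enrich -> cluster from a single config (R list or YAML file)
# with one global seed. Each stage derives a child seed by hashing its name,
# so inserting a stage does not perturb the randomness of the others. Every
# emitted file is recorded in a manifest with its MD5 checksum; rerunning
# with the same config and seed reproduces identical checksums.

#' Default pipeline configuration
#'
#' @param seed Global seed.
#' @param outdir Output directory.
#' @param simulate List of [sim_config()] overrides, or `FALSE` to consume
#'   files instead (`scores_path`, `activity_path`, `catalog_path`).
#' @param cds_path FASTA path of the CDS for the null model; default is the
#'   packaged synthetic PTEN-like CDS.
#' @param scoring,filter,classification Config overrides for
#'   [scoring_config()], [filter_config()], [classification_config()].
#' @param enrichment List: `fold_enrichments`, `n_observations`, `mode`.
#' @param clustering List: `min_missense`, `k`, or `FALSE` to skip.
#' @param max_positions Restrict simulated missense variants to CDS
#'   positions `2..max_positions` (`NULL` for no restriction); concentrating
#'   the library raises per-position coverage so the clustering stage has
#'   high-coverage positions to work with at desk scale.
#' @return A nested config list.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("mave_run_"),
                            simulate = list(), cds_path = NULL,
                            scoring = list(), filter = list(),
                            classification = list(),
                            enrichment = list(
                              fold_enrichments = c(
                                wt_like = 1, loss_abundance_only = 1,
                                loss_activity_only = 1, loss_both = 3),
                              n_observations = 5000,
                              mode = "per_observation"),
                            clustering = list(min_missense = 17, k = 3),
                            max_positions = NULL) {
  list(seed = as.integer(seed), outdir = outdir, simulate = simulate,
       cds_path = cds_path, scoring = scoring, filter = filter,
       classification = classification, enrichment = enrichment,
       clustering = clustering, max_positions = max_positions)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys override [pipeline_config()]
#'   defaults.
#' @return A config list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  if (!is.null(cfg$enrichment$fold_enrichments)) {
    cfg$enrichment$fold_enrichments <-
      unlist(cfg$enrichment$fold_enrichments)
  }
  cfg
}

#' Packaged synthetic PTEN-like coding sequence
#'
#' A synthetic 403-residue CDS (404 codons including the terminal stop,
#' i.e. 402 non-initiator sense codons) shipped with the package as a
#' stand-in for the PTEN reference cDNA, for use by the null model at desk
#' scale. It is NOT the biological PTEN sequence:
#' only its length and the codons at the dominant-negative-relevant
#' positions (Cys124 = TGT, Gly129 = GGA, Arg130 = CGA) match the
#' reference; all other codons are deterministic filler. SNV event counts
#' that depend only on codon count and on those codons (e.g. the total
#' event count and the known-dominant-negative degeneracy) are faithful.
#'
#' @return A `cds_sequence`.
#' @export
pten_synthetic_cds <- function() {
  read_cds_fasta(system.file("extdata", "pten_cds_synthetic.fa",
                             package = "maveintegrate", mustWork = TRUE))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()] list or the path to a YAML file.
#' @return A manifest tibble (`stage`, `file`, `md5`, `bytes`), invisibly
#'   carrying the in-memory results as attribute `"results"`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  emitted <- list()
  emit <- function(stage, file, writer) {
    path <- file.path(outdir, file)
    writer(path)
    emitted[[length(emitted) + 1L]] <<- tibble::tibble(
      stage = stage, file = file)
    path
  }

  cds <- .stage("nullmodel", {
    if (is.null(config$cds_path)) pten_synthetic_cds()
    else read_cds_fasta(config$cds_path)
  })
  max_pos <- config$max_positions
  lib_positions <- 2:(if (is.null(max_pos)) length(cds$codons) - 2L
                      else max_pos)

  scfg <- .stage("scoring", do.call(scoring_config, config$scoring))
  ccfg <- .stage("classify",
                 do.call(classification_config, config$classification))

  if (!identical(config$simulate, FALSE)) {
    sim_args <- config$simulate
    sim_args$seed <- .child_seed(config$seed, "simulate")
    simc <- .stage("simulate", do.call(sim_config, sim_args))
    library <- .stage("simulate",
                      generate_library(simc, positions = lib_positions,
                                       wildtype = cds))
    emit("simulate", "library.tsv", function(p) {
      write_score_table(dplyr::select(library, -"present"), p)
    })
    counts <- .stage("simulate", simulate_sort_experiment(library, simc))
    for (r in seq_len(simc$n_replicates)) {
      emit("simulate", sprintf("counts_rep%d.tsv", r), function(p) {
        write_score_table(
          dplyr::filter(counts, .data$replicate == r) |>
            dplyr::select(-"replicate"), p)
      })
    }
    activity <- .stage("simulate", generate_activity_scores(library, simc))
    emit("simulate", "activity.tsv",
         function(p) write_score_table(activity, p))
    scores <- .stage("score", score_experiment(counts, scfg))
  } else {
    for (need in c("scores_path", "activity_path")) {
      if (is.null(config[[need]])) {
        stop("pipeline stage 'classify' needs input '", need,
             "' when simulation is disabled", call. = FALSE)
      }
    }
    scores <- .stage("score",
                     scores_to_long(read_score_table(config$scores_path)))
    scores$total_reads <- NA_real_
    activity <- .stage("classify",
                       read_activity_scores(config$activity_path))
  }
  emit("score", "replicate_scores.tsv",
       function(p) write_score_table(scores_to_wide(scores), p))

  fcfg_args <- config$filter
  fcfg_args$seed <- .child_seed(config$seed, "filter")
  fcfg <- do.call(filter_config, fcfg_args)
  filt <- .stage("composite", select_replicate_filter(scores, fcfg))
  emit("composite", "filter_report.tsv",
       function(p) write_score_table(tidy(filt), p))
  composite <- .stage("composite", {
    aggregate_composite(scores, filt) |> classify_abundance_confidence()
  })
  emit("composite", "composite.tsv",
       function(p) write_score_table(composite, p))

  classes <- .stage("classify", classify_variants(composite, activity, ccfg))
  emit("classify", "classes.tsv", function(p) write_score_table(classes, p))

  four <- c("wt_like", "loss_abundance_only", "loss_activity_only",
            "loss_both")
  class_map <- dplyr::filter(classes, .data$joint_class %in% four) |>
    dplyr::select("variant", class = "joint_class")
  spectrum <- .stage("nullmodel", {
    s <- null_spectrum(cds)
    if (!is.null(max_pos)) {
      s <- dplyr::filter(s, .data$position <= max_pos)
    }
    dplyr::left_join(s, class_map, by = "variant")
  })
  emit("nullmodel", "null_spectrum.tsv",
       function(p) write_score_table(spectrum, p))
  baseline <- .stage("nullmodel", expected_class_fractions(spectrum))
  emit("nullmodel", "class_fractions.tsv",
       function(p) write_score_table(baseline, p))

  ecfg <- config$enrichment
  catalog <- .stage("enrich", generate_cancer_catalog(
    spectrum, ecfg$fold_enrichments, ecfg$n_observations,
    seed = .child_seed(config$seed, "enrich")))
  emit("enrich", "catalog.tsv", function(p) write_score_table(catalog, p))
  enrichment <- .stage("enrich", category_enrichment(
    catalog, classes, baseline, mode = ecfg$mode))
  emit("enrich", "enrichment.tsv",
       function(p) write_score_table(enrichment, p))

  clustering <- NULL
  profiles <- .stage("cluster", tolerance_profiles(composite))
  if (!identical(config$clustering, FALSE)) {
    kcfg <- config$clustering
    hi <- profiles[profiles$n_scored >= kcfg$min_missense, ]
    profiles_out <- tolerance_group(profiles,
                                    min_missense = kcfg$min_missense)
    emit("cluster", "profiles.tsv", function(p) {
      write_score_table(dplyr::select(profiles_out, -"scores"), p)
    })
    if (nrow(hi) >= 2L) {
      clustering <- .stage("cluster",
                           cluster_positions(hi, k = kcfg$k))
      emit("cluster", "groups.tsv",
           function(p) write_score_table(clustering$groups, p))
      emit("cluster", "dendrogram.nwk",
           function(p) dendrogram_newick(clustering, p))
    }
  }

  manifest <- dplyr::bind_rows(emitted)
  manifest$md5 <- unname(tools::md5sum(file.path(outdir, manifest$file)))
  manifest$bytes <- file.size(file.path(outdir, manifest$file))
  write_score_table(manifest, file.path(outdir, "manifest.tsv"))
  attr(manifest, "results") <- list(
    scores = scores, filter = filt, composite = composite,
    classes = classes, spectrum = spectrum, baseline = baseline,
    catalog = catalog, enrichment = enrichment, profiles = profiles,
    clustering = clustering
  )
  invisible(manifest)
}

#' One-command synthetic demonstration run
#'
#' Runs the whole pipeline on a position-concentrated synthetic library so
#' every stage, including tolerance clustering, has data to work on.
#'
#' @param outdir Output directory.
#' @param seed Global seed.
#' @return The run manifest (see [run_pipeline()]).
#' @export
run_demo <- function(outdir = tempfile("mave_demo_"), seed = 1L) {
  cfg <- pipeline_config(
    seed = seed, outdir = outdir,
    simulate = list(n_variants = 460, n_replicates = 8,
                    reads_per_bin = 20000),
    clustering = list(min_missense = 10, k = 3),
    max_positions = 26
  )
  run_pipeline(cfg)
}
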