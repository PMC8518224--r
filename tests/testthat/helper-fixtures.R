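# Shared fixtures, generated in code. Heavy simulations are memoised so the
# default-scale experiment is run once per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Default-scale simulated experiment: 500 variants, 8 replicates,
# 50k reads/bin, noise sd 0.10 (the generator defaults).
default_sim <- function(seed = 101L) {
  memo(paste0("default_sim_", seed), {
    cfg <- sim_config(seed = seed)
    lib <- generate_library(cfg)
    scores <- score_experiment(simulate_sort_experiment(lib, cfg))
    list(config = cfg, library = lib, scores = scores)
  })
}

# Well-separated control scores: all variants in 8 replicates, synonymous
# and nonsense separated by ~50 control sds.
separated_control_scores <- function(n_per_group = 40, seed = 11L,
                                     sd = 0.02) {
  set.seed(seed)
  make <- function(prefix, cons, center) {
    do.call(rbind, lapply(seq_len(n_per_group), function(i) {
      data.frame(variant = paste0(prefix, i),
                 consequence = cons, replicate = 1:8,
                 score = rnorm(8, center, sd))
    }))
  }
  tibble::as_tibble(rbind(make("S", "synonymous", 1),
                          make("N", "nonsense", 0)))
}

# Null-calibration controls: synonymous and nonsense scores drawn from the
# same distribution, replicate counts 1..8.
identical_control_scores <- function(n_per_group = 40, seed = 12L) {
  set.seed(seed)
  make <- function(prefix, cons) {
    do.call(rbind, lapply(seq_len(n_per_group), function(i) {
      k <- sample(1:8, 1)
      data.frame(variant = paste0(prefix, i), consequence = cons,
                 replicate = seq_len(k), score = rnorm(k, 0.5, 0.1))
    }))
  }
  tibble::as_tibble(rbind(make("S", "synonymous"),
                          make("N", "nonsense")))
}

# Adversarial fixture: variants observed in <= 2 replicates carry
# pure-noise scores; variants with more replicates are cleanly separated.
adversarial_control_scores <- function(n_per_group = 60, seed = 13L) {
  set.seed(seed)
  make <- function(prefix, cons, center) {
    do.call(rbind, lapply(seq_len(n_per_group), function(i) {
      k <- sample(1:8, 1, prob = c(0.25, 0.25, rep(0.5 / 6, 6)))
      # low-replicate variants carry a pure-noise score (one bad draw,
      # repeated over their few replicates)
      score <- if (k <= 2) rep(runif(1), k) else rnorm(k, center, 0.03)
      data.frame(variant = paste0(prefix, i), consequence = cons,
                 replicate = seq_len(k), score = score)
    }))
  }
  tibble::as_tibble(rbind(make("S", "synonymous", 1),
                          make("N", "nonsense", 0)))
}

# A tiny library built by hand (explicit true abundances).
manual_library <- function(abundances, consequences = NULL,
                           n_replicates = 1L) {
  n <- length(abundances)
  if (is.null(consequences)) consequences <- rep("missense", n)
  tibble::tibble(
    variant = paste0("A", seq_len(n) + 1L, "V"),
    consequence = consequences,
    true_class = "wt_like",
    true_abundance = abundances,
    true_activity_raw = 0.5,
    present = replicate(n, rep(TRUE, n_replicates), simplify = FALSE)
  )
}
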