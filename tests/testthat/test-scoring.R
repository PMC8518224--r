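test_that("bin frequencies implement depth normalization", {
  expect_equal(bin_frequencies(c(10, 10, 10, 10), rep(100, 4)),
               rep(0.25, 4))
  expect_equal(bin_frequencies(c(0, 0, 0, 40), rep(100, 4)),
               c(0, 0, 0, 1))
  # depth-weighted case, hand arithmetic on the formula
  expect_equal(bin_frequencies(c(10, 0, 0, 10), c(100, 100, 100, 400)),
               c(0.8, 0, 0, 0.2))
  expect_error(bin_frequencies(c(1, 1, 1, 1), c(100, 0, 100, 100)),
               "positive")
  expect_error(bin_frequencies(c(0, 0, 0, 0), rep(100, 4)), "zero reads")
})

test_that("weighted average score maps bin mass to the 0-1 scale", {
  expect_equal(weighted_average_score(c(1, 0, 0, 0)), 0)
  expect_equal(weighted_average_score(c(0, 0, 0, 1)), 1)
  expect_equal(weighted_average_score(rep(0.25, 4)), 0.5)
})

test_that("raw scores match a hand-computed spreadsheet oracle", {
  # two variants, tiny counts, unequal depths; frozen by hand:
  # v1: r = (0.1, 0, 0, 0.025), f = (0.8, 0, 0, 0.2), score = 0.2
  # v2: r = (.05,.05,.05,.0125), f = (4,4,4,1)/13, score = 5/13
  depths <- c(100, 100, 100, 400)
  f1 <- bin_frequencies(c(10, 0, 0, 10), depths)
  f2 <- bin_frequencies(c(5, 5, 5, 5), depths)
  expect_equal(weighted_average_score(f1), 0.2, tolerance = 1e-12)
  expect_equal(weighted_average_score(f2), 5 / 13, tolerance = 1e-12)
})

test_that("moving a read to a higher bin never decreases the score", {
  set.seed(42)
  for (i in 1:50) {
    counts <- rpois(4, 20)
    counts[1] <- counts[1] + 1  # ensure a movable read
    depths <- sample(1000:5000, 4)
    base <- weighted_average_score(bin_frequencies(counts, depths))
    b <- sample(1:3, 1)
    if (counts[b] == 0) next
    shifted <- counts
    shifted[b] <- shifted[b] - 1
    shifted[b + 1] <- shifted[b + 1] + 1
    expect_gte(weighted_average_score(bin_frequencies(shifted, depths)),
               base - 1e-12)
  }
})

test_that("scores are invariant to rescaling all depths", {
  counts <- c(7, 3, 11, 19)
  depths <- c(1000, 2000, 1500, 3000)
  expect_equal(
    weighted_average_score(bin_frequencies(counts, depths)),
    weighted_average_score(bin_frequencies(counts, depths * 17))
  )
})

test_that("normalization anchors controls at 0 and 1", {
  syn <- rep(0.8, 6)
  non <- rep(0.2, 6)
  expect_equal(normalize_scores(0.2, syn, non), 0)
  expect_equal(normalize_scores(0.8, syn, non), 1)
  expect_equal(normalize_scores(0.5, syn, non), 0.5)
  expect_equal(normalize_scores(0.95, syn, non), 1.25)  # may exceed 1
  expect_error(normalize_scores(0.5, non, syn), "failed separation")
  expect_error(normalize_scores(0.5, syn[1:3], non), "at least 5")
})

test_that("replicate scoring filters low-read variants and recovers ranks", {
  cfg <- sim_config(n_variants = 300, n_replicates = 1,
                    reads_per_bin = 30000, cells_per_variant = 500,
                    fluorescence_noise_sd = 0.05, dropout_rate = 0,
                    seed = 14)
  lib <- generate_library(cfg)
  counts <- simulate_sort_replicate(lib, cfg, 1)
  scored <- score_replicate(counts)
  j <- match(scored$variant, lib$variant)
  expect_gt(cor(lib$true_abundance[j], scored$score,
                method = "spearman", use = "complete.obs"), 0.95)
  expect_equal(median(scored$score[scored$consequence == "nonsense"],
                      na.rm = TRUE), 0, tolerance = 0.05)
  expect_equal(median(scored$score[scored$consequence == "synonymous"],
                      na.rm = TRUE), 1, tolerance = 0.05)

  # a variant under the read filter is missing, not zero
  low <- counts
  v1 <- low$variant[1]
  low$count[low$variant == v1] <- c(1, 1, 1, 0)
  scored_low <- score_replicate(low)
  expect_true(is.na(scored_low$score[scored_low$variant == v1]))
})

test_that("codon-level entries are averaged per amino-acid variant", {
  counts <- tibble::tibble(
    variant = rep(c(rep("K5N", 2), paste0("S", 10:21, "A"),
                    paste0("L", 30:41, "*")), each = 4),
    codon_variant = rep(c("K5N.aac", "K5N.aat", paste0("syn", 10:21),
                          paste0("non", 30:41)), each = 4),
    consequence = rep(c("missense", "missense", rep("synonymous", 12),
                        rep("nonsense", 12)), each = 4),
    bin = rep(1:4, 26),
    count = c(c(0, 0, 0, 100), c(0, 0, 100, 0),
              rep(c(0, 0, 0, 100), 11), c(0, 0, 100, 0),
              rep(c(100, 0, 0, 0), 11), c(0, 100, 0, 0))
  )
  scored <- score_replicate(counts)
  # raw codon scores 1 and 2/3 average to 5/6 before anchoring
  k5n <- scored[scored$variant == "K5N", ]
  expect_equal(nrow(k5n), 1)
  expect_equal(k5n$raw_score, 5 / 6, tolerance = 1e-12)
})
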