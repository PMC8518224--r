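test_that("library generation is deterministic and respects the class mixture", {
  cfg <- sim_config(n_variants = 1000, seed = 7)
  lib1 <- generate_library(cfg)
  lib2 <- generate_library(cfg)
  expect_identical(lib1, lib2)
  expect_equal(nrow(lib1), 1000)
  expect_false(anyDuplicated(lib1$variant) > 0)

  # designated control sets
  expect_equal(sum(lib1$consequence == "synonymous"), 20)
  expect_equal(sum(lib1$consequence == "nonsense"), 20)
  expect_true(all(lib1$true_abundance[lib1$consequence == "synonymous"] >= 0.9))
  expect_true(all(lib1$true_abundance[lib1$consequence == "nonsense"] <= 0.05))

  # class counts within binomial 99% bounds of expectation (n = 960 missense)
  mix <- c(wt_like = 0.5, loss_abundance_only = 0.2,
           loss_activity_only = 0.1, loss_both = 0.2)
  mis <- lib1[lib1$consequence == "missense", ]
  for (cl in names(mix)) {
    n_cl <- sum(mis$true_class == cl)
    expect_gte(n_cl, qbinom(0.005, nrow(mis), mix[[cl]]))
    expect_lte(n_cl, qbinom(0.995, nrow(mis), mix[[cl]]))
  }

  # degenerate mixture: every missense variant wt-like and abundant
  cfg1 <- sim_config(n_variants = 100, seed = 3,
                     class_mix = c(wt_like = 1, loss_abundance_only = 0,
                                   loss_activity_only = 0, loss_both = 0))
  lib_wt <- generate_library(cfg1)
  mis_wt <- lib_wt[lib_wt$consequence == "missense", ]
  expect_true(all(mis_wt$true_class == "wt_like"))
  expect_true(all(mis_wt$true_abundance >= 0.7))

  expect_error(generate_library(sim_config(n_variants = 30)), "exceed")
})

test_that("sort simulation conserves reads and populates quartile gates", {
  cfg <- sim_config(n_variants = 200, n_replicates = 2,
                    reads_per_bin = 10000, cells_per_variant = 200,
                    seed = 5)
  lib <- generate_library(cfg)
  counts <- simulate_sort_replicate(lib, cfg, 1)
  # conservation: each bin sequenced to depth reads_per_bin exactly
  depth <- as.vector(tapply(counts$count, counts$bin, sum))
  expect_equal(depth, rep(10000, 4))
  # determinism
  expect_identical(counts, simulate_sort_replicate(lib, cfg, 1))
  expect_false(identical(counts, simulate_sort_replicate(lib, cfg, 2)))
  expect_error(simulate_sort_replicate(lib, sim_config(reads_per_bin = 0)))
})

test_that("a high-abundance variant concentrates in the top bin at zero noise", {
  lib <- manual_library(c(1.0, seq(0, 1, length.out = 99)))
  cfg <- sim_config(n_variants = 100, n_replicates = 1,
                    reads_per_bin = 20000, cells_per_variant = 500,
                    fluorescence_noise_sd = 1e-6, dropout_rate = 0, seed = 2)
  counts <- simulate_sort_replicate(lib, cfg, 1)
  top <- counts[counts$variant == lib$variant[1], ]
  expect_gt(top$count[top$bin == 4] / sum(top$count), 0.99)
})

test_that("true abundance orders mean bin index (monotone readout)", {
  cfg <- sim_config(n_variants = 1000, n_replicates = 1,
                    reads_per_bin = 50000, cells_per_variant = 300,
                    fluorescence_noise_sd = 0.15, dropout_rate = 0,
                    seed = 9)
  lib <- generate_library(cfg)
  counts <- simulate_sort_replicate(lib, cfg, 1)
  mean_bin <- counts |>
    dplyr::group_by(variant) |>
    dplyr::summarise(mb = sum(bin * count) / sum(count))
  j <- match(mean_bin$variant, lib$variant)
  expect_gt(cor(lib$true_abundance[j], mean_bin$mb, method = "spearman"),
            0.95)
})

test_that("simulated activity scores respect the cutoffs before noise", {
  cfg <- sim_config(n_variants = 500, seed = 21, activity_noise_sd = 0)
  lib <- generate_library(cfg)
  act <- generate_activity_scores(lib, cfg)
  lost <- lib$true_class %in% c("loss_activity_only", "loss_both")
  expect_true(all(act$activity[lost & lib$consequence == "missense"] <
                    10^-2.13))
  expect_true(all(act$activity[!lost & lib$consequence == "missense"] >
                    10^-1.11))

  # at noise sd 0.1 (log10), misclassification against truth stays < 5%
  cfg2 <- sim_config(n_variants = 500, seed = 22, activity_noise_sd = 0.1)
  act2 <- generate_activity_scores(lib, cfg2)
  called <- classify_activity(act2$activity)
  truth <- ifelse(lost, "loss", "wt_like")
  expect_lt(mean(called != truth), 0.05)
})

test_that("toy CDS generation yields valid deterministic ORFs", {
  cds <- generate_toy_cds(30, seed = 4)
  expect_equal(length(cds$codons), 30)
  expect_equal(cds$codons[1], "ATG")
  expect_equal(cds$protein[30], "*")
  expect_false("*" %in% cds$protein[-30])
  expect_identical(cds$sequence, generate_toy_cds(30, seed = 4)$sequence)
})

test_that("catalog generation matches the null in the all-ones case", {
  cds <- generate_toy_cds(60, seed = 6)
  spec <- null_spectrum(cds)
  set.seed(31)
  spec$class <- sample(c("wt_like", "loss_abundance_only",
                         "loss_activity_only", "loss_both"),
                       nrow(spec), replace = TRUE,
                       prob = c(0.4, 0.25, 0.2, 0.15))
  folds1 <- c(wt_like = 1, loss_abundance_only = 1,
              loss_activity_only = 1, loss_both = 1)
  cat_tbl <- generate_cancer_catalog(spec, folds1, 4000, seed = 8)
  expect_equal(sum(cat_tbl$n_obs), 4000)
  obs <- observed_class_fractions(cat_tbl, spec)
  base <- expected_class_fractions(spec)
  fe <- fold_enrichment(obs, base)
  expect_true(all(abs(fe$fold - 1) < 0.1))

  expect_equal(nrow(generate_cancer_catalog(spec, folds1, 0)), 0)
  expect_error(generate_cancer_catalog(
    spec, 0 * folds1, 100), "zero")
})
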