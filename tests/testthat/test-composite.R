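test_that("perfectly separated controls pass at every k; small k is selected", {
  scores <- separated_control_scores()
  cfg <- filter_config(k_range = 0:8, n_boot = 50, seed = 2)
  ev <- evaluate_filter_value(scores, 0, cfg)
  expect_equal(ev$pass_fraction, 1.0)
  expect_true(ev$observed_pass)
  filt <- select_replicate_filter(scores, cfg)
  expect_equal(filt$k_star, 0)
  # determinism
  expect_equal(select_replicate_filter(scores, cfg)$k_star, filt$k_star)
})

test_that("identically distributed controls essentially never pass", {
  scores <- identical_control_scores()
  cfg <- filter_config(n_boot = 200, seed = 3)
  ev <- evaluate_filter_value(scores, 0, cfg)
  mc_sd <- sqrt(0.05 * 0.95 / 200)
  expect_lte(ev$pass_fraction, 0.05 + 2 * mc_sd)
  expect_error(select_replicate_filter(
    scores, filter_config(k_range = 0:2, n_boot = 50, seed = 3)),
    "pass fraction")
})

test_that("a filter larger than every replicate count reports insufficient controls", {
  scores <- separated_control_scores()  # all variants in 8 replicates
  ev <- evaluate_filter_value(scores, 9, filter_config(seed = 1))
  expect_equal(ev$status, "insufficient controls")
  expect_equal(ev$pass_fraction, 0)
})

test_that("noise confined to low-replicate variants defeats permissive filters", {
  scores <- adversarial_control_scores(seed = 17)
  cfg <- filter_config(k_range = 0:8, n_boot = 100, seed = 4)
  filt <- select_replicate_filter(scores, cfg)
  rep_tbl <- tidy(filt)
  # contaminated filters (k <= 1 keeps the pure-noise variants) fail...
  expect_true(all(
    rep_tbl$pass_fraction[rep_tbl$k <= 1] < cfg$pass_fraction))
  # ...while k = 3 removes every noise variant and always separates
  expect_equal(rep_tbl$pass_fraction[rep_tbl$k == 3], 1.0)
  expect_gte(filt$k_star, 2)
  expect_equal(glance(filt)$k_star, filt$k_star)
})

test_that("the permutation null control destroys the filter's advantage", {
  scores <- adversarial_control_scores(seed = 19)
  cfg <- filter_config(n_boot = 100, seed = 5)
  paired <- evaluate_filter_value(scores, 3, cfg)
  permuted <- evaluate_filter_value(scores, 3, cfg, permute_null = TRUE)
  expect_gte(paired$pass_fraction, 0.95)
  expect_lt(permuted$pass_fraction, paired$pass_fraction)
})

test_that("composite aggregation computes mean/sd/se/cv over present replicates", {
  scores <- tibble::tibble(
    variant = c(rep("A2V", 3), rep("C3W", 3), rep("D4E", 2)),
    consequence = "missense",
    replicate = c(1:3, 1:3, 1:2),
    score = c(1, 1, 1, 0.2, 0.4, 0.6, 0.4, 0.6)
  )
  rec <- aggregate_composite(scores, 0)
  a <- rec[rec$variant == "A2V", ]
  expect_equal(a$score, 1)
  expect_equal(a$sd, 0)
  expect_equal(a$cv, 0)
  b <- rec[rec$variant == "C3W", ]
  expect_equal(b$score, 0.4)
  expect_equal(b$sd, 0.2)
  expect_equal(b$se, 0.2 / sqrt(3), tolerance = 1e-6)
  # filter rule: n_reps < k excludes
  rec3 <- aggregate_composite(scores, 3)
  expect_false("D4E" %in% rec3$variant)
  # replicate order invariance; appending the mean shrinks se
  shuffled <- scores[sample(nrow(scores)), ]
  expect_equal(dplyr::arrange(aggregate_composite(shuffled, 0), variant),
               dplyr::arrange(rec, variant))
  extra <- dplyr::bind_rows(scores, tibble::tibble(
    variant = "C3W", consequence = "missense", replicate = 4L, score = 0.4))
  b2 <- aggregate_composite(extra, 0)
  b2 <- b2[b2$variant == "C3W", ]
  expect_equal(b2$score, 0.4)
  expect_lt(b2$se, b$se)
})

test_that("cv is withheld near the nonsense anchor", {
  scores <- tibble::tibble(
    variant = rep(c("A2V", "C3W"), each = 2), consequence = "missense",
    replicate = rep(1:2, 2), score = c(0.01, 0.03, 0.5, 0.7))
  rec <- aggregate_composite(scores, 0)
  expect_true(rec$cv_undefined[rec$variant == "A2V"])
  expect_true(is.na(rec$cv[rec$variant == "A2V"]))
  expect_false(rec$cv_undefined[rec$variant == "C3W"])
})

test_that("abundance confidence classes follow the two-sided rule", {
  mk <- function(score, se) tibble::tibble(
    variant = "A2V", consequence = "missense", n_reps = 4L,
    score = score, sd = se * 2, se = se)
  ctrl <- tibble::tibble(
    variant = c(paste0("S", 1:10, "S"), paste0("N", 1:10, "N")),
    consequence = rep(c("synonymous", "nonsense"), each = 10),
    n_reps = 4L, score = c(rep(c(0.8, 1.0), 5), rep(c(0.0, 0.2), 5)),
    sd = 0.02, se = 0.01)
  cls <- function(score, se) {
    classify_abundance_confidence(dplyr::bind_rows(mk(score, se), ctrl))
  }
  expect_equal(cls(1.0, 0.01)$abundance_class[1], "wt_like")
  expect_equal(cls(0.0, 0.01)$abundance_class[1], "low")
  expect_equal(cls(0.5, 0.01)$abundance_class[1], "unclassified")
  # degenerate controls: no separation is an error
  bad <- ctrl
  bad$score <- 0.5
  expect_error(classify_abundance_confidence(bad), "separate")
})

test_that("score set comparison recovers affine relationships", {
  a <- tibble::tibble(variant = paste0("A", 2:31, "V"),
                      score = seq(0, 1, length.out = 30))
  ident <- compare_score_sets(a, a)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)
  expect_equal(ident$pearson_r2, 1)

  b <- dplyr::mutate(a, score = 2 * score + 1)
  aff <- compare_score_sets(a, b)
  expect_equal(aff$slope, 2)
  expect_equal(aff$intercept, 1)
  expect_equal(aff$spearman_rho2, 1)
  expect_true(score_sets_combinable(ident))
  expect_false(score_sets_combinable(aff))

  # three collinear points: verified against lm() directly
  a3 <- tibble::tibble(variant = c("A2V", "A3V", "A4V"),
                       score = c(0, 0.5, 1))
  b3 <- tibble::tibble(variant = a3$variant, score = c(0.1, 0.5, 0.9))
  cmp <- compare_score_sets(a3, b3)
  oracle <- lm(b3$score ~ a3$score)
  expect_equal(cmp$slope, unname(coef(oracle)[2]))  # 0.8
  expect_equal(cmp$intercept, unname(coef(oracle)[1]))  # 0.1
  # the three points are exactly collinear, so r^2 is exactly 1
  expect_equal(cmp$pearson_r2,
               suppressWarnings(summary(oracle)$r.squared))
  expect_equal(cmp$slope, 0.8)
  expect_equal(cmp$intercept, 0.1)

  expect_error(compare_score_sets(a3[1:2, ], b3[1:2, ]), "3 overlapping")
  expect_equal(glance(cmp)$n_overlap, 3)
  expect_equal(nrow(suppressWarnings(tidy(cmp))), 2)
})
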