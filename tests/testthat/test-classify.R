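test_that("activity rescaling maps mean-nonsense to 0 and WT to 1", {
  non <- c(0.004, 0.005, 0.006)
  expect_equal(rescale_activity(0.005, non, 1.0), 0)
  expect_equal(rescale_activity(1.0, non, 1.0), 1)
  expect_equal(rescale_activity(0.5025, non, 1.0), 0.5)
  expect_error(rescale_activity(0.5, c(1, 1), 0.5), "exceed")
})

test_that("raw activity cutoffs split wt-like / indeterminate / loss", {
  expect_equal(classify_activity(10^-1.0), "wt_like")
  expect_equal(classify_activity(10^-2.5), "loss")
  expect_equal(classify_activity(10^-1.5), "indeterminate")
  expect_error(classify_activity(-1), "positive")
})

test_that("the four-way classification covers all combinations", {
  expect_equal(four_way_classify("wt_like", "wt_like"), "wt_like")
  expect_equal(four_way_classify("low", "wt_like"), "loss_abundance_only")
  # Asp92His-style: abundant but catalytically dead
  expect_equal(four_way_classify("wt_like", "loss"), "loss_activity_only")
  expect_equal(four_way_classify("low", "loss"), "loss_both")
  expect_equal(four_way_classify("unclassified", "wt_like"), "unclassified")
  expect_equal(four_way_classify("wt_like", "indeterminate"),
               "unclassified")
  expect_equal(four_way_classify(NA, "loss"), "unclassified")
})

test_that("classify_variants joins assays and explains unclassified calls", {
  records <- tibble::tibble(
    variant = c("A2V", "C3W", "D4E", paste0("S", 1:5, "S"),
                paste0("N", 1:5, "N")),
    consequence = c(rep("missense", 3), rep("synonymous", 5),
                    rep("nonsense", 5)),
    n_reps = 4L, score = c(1, 0.05, 1, rep(1, 5), rep(0, 5)),
    sd = 0.02, se = 0.01,
    abundance_class = c("wt_like", "low", "wt_like", rep("wt_like", 5),
                        rep("low", 5))
  )
  activity <- tibble::tibble(
    variant = c("A2V", "C3W", "E5K", paste0("S", 1:5, "S"),
                paste0("N", 1:5, "N")),
    consequence = c("missense", "missense", "missense",
                    rep("synonymous", 5), rep("nonsense", 5)),
    activity = c(10^-0.5, 10^-2.5, 10^-0.2, rep(10^-0.3, 5),
                 rep(10^-2.4, 5))
  )
  cls <- classify_variants(records, activity)
  expect_equal(cls$joint_class[cls$variant == "A2V"], "wt_like")
  expect_equal(cls$joint_class[cls$variant == "C3W"], "loss_both")
  # missing assay rows are unclassified with a stated reason
  expect_equal(cls$joint_class[cls$variant == "D4E"], "unclassified")
  expect_equal(cls$unclassified_reason[cls$variant == "D4E"],
               "missing_activity")
  expect_equal(cls$unclassified_reason[cls$variant == "E5K"],
               "missing_abundance")
  # rescaled activity: mean nonsense -> 0, synonymous-mean anchor -> 1
  expect_equal(cls$scaled_activity[cls$variant == "N1N"], 0,
               tolerance = 0.02)
})

test_that("category enrichment satisfies the fold-baseline identity", {
  baseline <- tibble::tibble(
    class = c("wt_like", "loss_abundance_only", "loss_activity_only",
              "loss_both"),
    fraction = c(0.4, 0.25, 0.1, 0.25))
  classes <- tibble::tibble(
    variant = paste0("A", 2:41, "V"),
    joint_class = rep(baseline$class, each = 10))
  # one category matching baseline, one all-loss_both
  catalog <- dplyr::bind_rows(
    tibble::tibble(variant = c("A2V", "A3V", "A12V", "A22V", "A32V"),
                   category = "match",
                   n_obs = c(20, 20, 25, 10, 25)),
    tibble::tibble(variant = paste0("A", 32:41, "V"),
                   category = "pure_lb", n_obs = 1))
  enr <- category_enrichment(catalog, classes, baseline)
  m <- enr[enr$category == "match", ]
  expect_equal(m$fold[m$class == "wt_like"], 1)
  expect_equal(sort(m$fold), rep(1, 4))
  p <- enr[enr$category == "pure_lb", ]
  expect_equal(p$fold[p$class == "loss_both"], 4)  # 1.0 / 0.25
  expect_equal(p$fold[p$class == "wt_like"], 0)
  # identity: sum(fold * baseline) == 1 within each category
  ident <- enr |>
    dplyr::group_by(category) |>
    dplyr::summarise(s = sum(fold * baseline_fraction))
  expect_equal(ident$s, rep(1, 2), tolerance = 1e-12)

  # unique-variant mode ignores observation counts
  enr_u <- category_enrichment(catalog, classes, baseline,
                               mode = "unique_variant")
  mu <- enr_u[enr_u$category == "match", ]
  expect_equal(mu$fraction[mu$class == "wt_like"], 0.4)

  # zero-baseline class observed -> Inf with warning
  base0 <- baseline
  base0$fraction <- c(0.5, 0.25, 0, 0.25)
  expect_warning(enr0 <- category_enrichment(catalog, classes, base0),
                 "Inf")
  expect_true(is.infinite(
    enr0$fold[enr0$category == "match" &
                enr0$class == "loss_activity_only"]))
})

test_that("known dominant negatives are partitioned from novel candidates", {
  classes <- tibble::tibble(
    variant = c("C124S", "D92H", "R130Q", "A2V"),
    joint_class = c("loss_activity_only", "loss_activity_only",
                    "loss_activity_only", "wt_like"))
  split <- split_dominant_negative_candidates(classes)
  expect_setequal(split$known$variant, c("C124S", "R130Q"))
  expect_equal(split$novel_candidates$variant, "D92H")

  # contribution share: 87 of 100 loss-of-activity observations are known
  catalog <- tibble::tibble(
    variant = c("C124S", "R130Q", "D92H"),
    category = "uterine", n_obs = c(50, 37, 13))
  split2 <- split_dominant_negative_candidates(classes, catalog = catalog)
  expect_equal(split2$category_share$share, 0.87)

  empty <- split_dominant_negative_candidates(
    tibble::tibble(variant = "A2V", joint_class = "wt_like"))
  expect_equal(nrow(empty$known), 0)
  expect_equal(nrow(empty$novel_candidates), 0)
})
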