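test_that("relative deviation is the signed percent difference", {
  expect_equal(relative_deviation(100, 100), 0)
  expect_equal(relative_deviation(110, 100), 10)
  expect_equal(relative_deviation(95, 100), -5)
  expect_equal(relative_deviation(c(110, 95), c(100, 100)), c(10, -5))
  expect_error(relative_deviation(10, 0), "undefined")
})

test_that("agreement categories fold the sign and use half-open intervals", {
  expect_equal(as.character(agreement_category(3)), "very_good")
  expect_equal(as.character(agreement_category(-3)), "very_good")
  expect_equal(as.character(agreement_category(7)), "good")
  expect_equal(as.character(agreement_category(25)), "poor")
  ## boundaries assigned upward
  expect_equal(
    as.character(agreement_category(c(5, 10, 20))),
    c("good", "fair", "poor")
  )
  expect_error(agreement_category(NA_real_), "defined")
})

test_that("IoU counts overlap over union on rasters", {
  a <- matrix(FALSE, 10, 10)
  a[1:4, 1:4] <- TRUE
  expect_equal(iou(a, a), 1)
  b <- matrix(FALSE, 10, 10)
  b[6:9, 6:9] <- TRUE
  expect_equal(iou(a, b), 0)
  ## half-overlapping equal squares: intersection n/2, union 3n/2 -> 1/3
  c1 <- matrix(FALSE, 10, 10)
  c1[1:4, 1:4] <- TRUE
  c2 <- matrix(FALSE, 10, 10)
  c2[1:4, 3:6] <- TRUE
  expect_equal(iou(c1, c2), 1 / 3)
  expect_equal(iou(c1, c2), iou(c2, c1)) # symmetry
  expect_error(iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "undefined")
})

test_that("IoU interpretation uses strict thresholds", {
  expect_equal(as.character(interpret_iou(0.92)), "near_perfect")
  expect_equal(as.character(interpret_iou(0.60)), "acceptable")
  expect_equal(as.character(interpret_iou(0.50)), "below_acceptable")
  expect_equal(
    as.character(interpret_iou(c(0.75, 0.751, 0.90, 0.901))),
    c("acceptable", "good", "good", "near_perfect")
  )
  expect_error(interpret_iou(1.2), "\\[0, 1\\]")
})

test_that("Pearson correlation matches the closed form and is labelled", {
  expect_equal(pearson(1:5, 1:5)$r, 1)
  expect_equal(pearson(1:5, -(1:5))$r, -1)
  p <- pearson(c(1, 2, 3), c(1, 2, 4))
  expect_equal(p$r, 1.5 / sqrt(7 / 3), tolerance = 1e-12) # hand-computed closed form
  expect_equal(round(p$r, 3), 0.982)
  expect_equal(as.character(p$interpretation), "very_strong")
  expect_equal(as.character(pearson(1:10, 1:10)$interpretation), "very_strong")
  expect_error(pearson(1:2, 1:2), "n >= 3")
  expect_error(pearson(c(1, 1, 1), 1:3), "zero variance")
})

test_that("summaries pool records, count categories and respect the schema", {
  rec <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    age_group = c(4, 4, 4, 67, 67, 67),
    step = 1L, model_design = "ad_hoc", target = "tissue",
    a_manual_um2 = c(100, 110, 120, 200, 210, 220) * 1e4,
    a_model_um2 = c(101, 112, 126, 208, 232, 272) * 1e4
  )
  rec$rd <- relative_deviation(rec$a_model_um2, rec$a_manual_um2)
  rec$category <- agreement_category(rec$rd)
  rec$iou <- c(0.95, 0.93, 0.91, 0.92, 0.88, 0.80)
  s <- summarize_performance(rec)
  expect_true(all(c(
    "rd_mean", "rd_sd", "pcc", "pcc_interpretation", "iou_mean", "iou_sd",
    "n_very_good", "n_good", "n_fair", "n_poor"
  ) %in% names(s)))
  all_row <- dplyr::filter(s, age_group == "All")
  expect_equal(all_row$n, 6L)
  expect_equal(all_row$rd_mean, mean(rec$rd)) # pooled, not group-averaged
  ## category counts partition each group
  grp <- dplyr::filter(s, age_group != "All")
  expect_equal(grp$n_very_good + grp$n_good + grp$n_fair + grp$n_poor, grp$n)

  ## identical records: zero deviation, all very good
  same <- rec[c(1, 1, 1), ]
  same$a_model_um2 <- same$a_manual_um2
  same$rd <- 0
  same$category <- agreement_category(same$rd)
  s2 <- summarize_performance(same)
  all2 <- dplyr::filter(s2, age_group == "All")
  expect_equal(all2$rd_mean, 0)
  expect_equal(all2$rd_sd, 0)
  expect_equal(all2$n_very_good, 3L)
  ## zero model-area variance: correlation not computable, rest still emitted
  expect_true(is.na(all2$pcc))
  expect_equal(as.character(all2$pcc_interpretation), "not_computable")
})

test_that("groups smaller than three get no correlation", {
  rec <- tibble::tibble(
    sample_id = c("a", "b"), age_group = 14, step = 2L,
    model_design = "ad_hoc", target = "mucosa",
    a_manual_um2 = c(1e5, 2e5), a_model_um2 = c(1.1e5, 1.9e5),
    rd = c(10, -5), category = agreement_category(c(10, -5)),
    iou = c(0.8, 0.9)
  )
  s <- summarize_performance(rec)
  expect_true(all(is.na(s$pcc)))
  expect_equal(unique(as.character(s$pcc_interpretation)), "not_computable")
  expect_equal(dplyr::filter(s, age_group == "14")$rd_mean, 2.5)
})

test_that("Bland-Altman data and plots are generated from records", {
  rec <- tibble::tibble(
    sample_id = sprintf("s%d", 1:4), age_group = c(4, 14, 49, 67),
    step = 1L, model_design = "ad_hoc", target = "tissue",
    a_manual_um2 = 1e5 * 1:4, a_model_um2 = 1e5 * c(1.05, 2.2, 2.9, 4.1),
    rd = c(5, 10, -3.3, 2.5), category = agreement_category(c(5, 10, -3.3, 2.5)),
    iou = c(0.9, 0.8, 0.95, 0.92)
  )
  class(rec) <- c("eval_records", class(rec))
  ba <- bland_altman_data(rec)
  expect_named(ba, c("sample_id", "age_group", "step", "model_design", "rd", "category"))
  expect_s3_class(plot_bland_altman(rec), "ggplot")
  expect_s3_class(plot_area_correlation(rec), "ggplot")
  expect_s3_class(ggplot2::autoplot(rec), "ggplot")
  expect_s3_class(ggplot2::autoplot(summarize_performance(rec)), "ggplot")
})
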