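test_that("OKS analytic values", {
  gt <- rbind(c(10, 10), c(30, 40))
  expect_equal(oks(gt, gt, bbox_area = 2500, sigmas = 0.05), 1)

  # single keypoint with d^2 = 2 * area * sigma^2: exponent is exactly -1
  area <- 400
  sigma <- 0.1
  d <- sqrt(2 * area * sigma^2)
  expect_equal(oks(rbind(c(d, 0)), rbind(c(0, 0)), bbox_area = area,
                   sigmas = sigma),
               exp(-1), tolerance = 1e-9)

  # one exact keypoint, one infinitely far: mean of 1 and 0
  pred <- rbind(c(10, 10), c(Inf, Inf))
  expect_equal(oks(pred, gt, bbox_area = 2500, sigmas = 0.05), 0.5)

  # a missing prediction for a visible keypoint also contributes 0
  pred_na <- rbind(c(10, 10), c(NA, NA))
  expect_equal(oks(pred_na, gt, bbox_area = 2500, sigmas = 0.05), 0.5)

  # invisible keypoints are excluded from the mean
  expect_equal(oks(pred, gt, bbox_area = 2500, sigmas = 0.05,
                   visibility = c(2, 0)), 1)
  expect_error(oks(pred, gt, bbox_area = 2500, sigmas = 0.05,
                   visibility = c(0, 0)), "visible")
})

test_that("OKS is bounded, maximal only at exact match, decreasing in error", {
  set.seed(21)
  for (rep in 1:25) {
    k <- sample(1:5, 1)
    gt <- matrix(runif(2 * k, 0, 100), ncol = 2)
    pred <- gt + matrix(rnorm(2 * k, sd = 5), ncol = 2)
    v <- oks(pred, gt, bbox_area = 900, sigmas = 0.08)
    expect_gte(v, 0)
    expect_lte(v, 1)
    if (!isTRUE(all.equal(pred, gt))) expect_lt(v, 1)
    # pushing one keypoint further from its ground truth strictly lowers OKS
    e <- pred[1, ] - gt[1, ]
    u <- if (all(e == 0)) c(1, 0) else e / sqrt(sum(e^2))
    worse <- pred
    worse[1, ] <- pred[1, ] + 10 * u
    expect_lt(oks(worse, gt, bbox_area = 900, sigmas = 0.08), v)
  }
})

test_that("the strict exponent variant squares the area term", {
  d <- 10
  area <- 50
  sigma <- 0.2
  default <- oks(rbind(c(d, 0)), rbind(c(0, 0)), area, sigma)
  strict <- oks(rbind(c(d, 0)), rbind(c(0, 0)), area, sigma,
                strict_as_printed = TRUE)
  expect_equal(default, exp(-d^2 / (2 * area * sigma^2)))
  expect_equal(strict, exp(-d^2 / (2 * area^2 * sigma^2)))
})

test_that("average precision in both modes, with monotonicity in T", {
  expect_equal(average_precision(c(0.9, 0.8), 0.5), 1)
  expect_equal(average_precision(c(0.3, 0.2), 0.5), 0)
  expect_equal(average_precision(c(0.3, 0.2), 0.5, mode = "as_printed"), 0)
  expect_equal(average_precision(c(0.9, 0.3), 0.5, mode = "as_printed"), 0.45)
  expect_error(average_precision(numeric(0), 0.5), "empty")

  set.seed(31)
  for (rep in 1:20) {
    vals <- runif(sample(1:40, 1))
    for (mode in c("indicator", "as_printed")) {
      ap <- vapply(seq(0, 0.95, by = 0.05), average_precision,
                   numeric(1), oks_values = vals, mode = mode)
      expect_true(all(diff(ap) <= 0))
    }
  }
})

test_that("mean AP and precision/recall arithmetic", {
  expect_equal(mean_ap(c(1, 1)), 1)
  expect_equal(mean_ap(c(0, 1)), 0.5)
  expect_equal(mean_ap(0.7), 0.7)
  expect_error(mean_ap(numeric(0)), "empty")

  pr <- precision_recall(9, 1, 3)
  expect_equal(pr$precision, 0.9)
  expect_equal(pr$recall, 0.75)
  pr0 <- precision_recall(0, 0, 5)
  expect_true(is.na(pr0$precision))
  expect_equal(pr0$recall, 0)
  prn <- precision_recall(7, 0, 0)
  expect_equal(prn$precision, 1)
  expect_equal(prn$recall, 1)
  expect_error(precision_recall(-1, 0, 0), "non-negative")
})

test_that("relative error supports both denominator conventions", {
  expect_equal(round(relative_error(83, 79), 2), 4.82)
  expect_equal(round(relative_error(83, 79, denominator = "measured"), 2),
               5.06)
  expect_equal(relative_error(120, 120), 0)
  # swapping arguments and the denominator together leaves the error fixed
  expect_equal(relative_error(83, 79, "assessed"),
               relative_error(79, 83, "measured"))
  expect_error(relative_error(0, 5), "positive")
})

test_that("error summary uses the population standard deviation", {
  s <- error_summary(c(4, 4))
  expect_equal(s$mean_pct, 4)
  expect_equal(s$sd_pct, 0)
  s2 <- error_summary(c(0, 10))
  expect_equal(s2$mean_pct, 5)
  expect_equal(s2$sd_pct, 5)
  set.seed(41)
  x <- runif(17, 0, 10)
  expect_equal(error_summary(x)$sd_pct, pop_sd_ref(x))
  expect_error(error_summary(numeric(0)), "empty")
})

test_that("evaluate_counts produces the per-video report with summary row", {
  counts <- data.frame(video_id = c("a", "b"), assessed = c(100, 200),
                       measured = c(90, 210))
  res <- evaluate_counts(counts)
  expect_equal(res$table$relative_error_pct, c(10, 5))
  expect_equal(res$mean_pct, 7.5)
  expect_equal(res$sd_pct, 2.5)
  expect_equal(res$accuracy_pct, 92.5)
  expect_error(evaluate_counts(data.frame(assessed = numeric(0),
                                          measured = numeric(0))), "rows")
  expect_error(evaluate_counts(data.frame(x = 1)), "assessed")
})

test_that("keypoint evaluation on COCO-style JSON: perfect and degraded", {
  gt_xy <- list(rbind(c(20, 20), c(25, 40)), rbind(c(60, 60), c(66, 80)))
  gt_file <- withr::local_tempfile(fileext = ".json")
  write_coco_json(gt_file, list(coco_ann(1, gt_xy[[1]]),
                                coco_ann(1, gt_xy[[2]])))

  # perfect predictions
  pred_file <- withr::local_tempfile(fileext = ".json")
  write_coco_json(pred_file, list(coco_ann(1, gt_xy[[1]]),
                                  coco_ann(1, gt_xy[[2]])))
  res <- evaluate_keypoints(gt_file, pred_file, sigmas = 0.05)
  expect_equal(res$oks_values, c(1, 1))
  expect_equal(res$map_50, 1)
  expect_equal(res$map_50_95, 1)
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)

  # one prediction badly off, one instance unmatched in a second image
  pred2 <- withr::local_tempfile(fileext = ".json")
  write_coco_json(pred2, list(coco_ann(1, gt_xy[[1]]),
                              coco_ann(1, gt_xy[[2]] + 500),
                              coco_ann(2, rbind(c(0, 0), c(5, 5)))))
  res2 <- evaluate_keypoints(gt_file, pred2, sigmas = 0.05)
  expect_equal(sort(round(res2$oks_values, 6)), c(0, 1))
  expect_equal(res2$tp, 1)
  expect_equal(res2$fp, 2)        # the far-off match and the extra image
  expect_equal(res2$fn, 0)
  expect_equal(res2$precision, 1 / 3)
  expect_equal(res2$recall, 1)
  expect_equal(res2$map_50, 0.5)

  # missing predictions count as false negatives with OKS 0
  pred3 <- withr::local_tempfile(fileext = ".json")
  write_coco_json(pred3, list(coco_ann(1, gt_xy[[1]])))
  res3 <- evaluate_keypoints(gt_file, pred3, sigmas = 0.05)
  expect_equal(res3$fn, 1)
  expect_equal(res3$recall, 0.5)
})
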