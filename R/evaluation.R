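#' Object keypoint similarity (OKS)
#'
#' Gaussian-kernel similarity between a predicted and a ground-truth keypoint
#' set, scaled by object size and per-keypoint spread constants: the mean
#' over visible ground-truth keypoints of `exp(-d_i^2 / (2 * s * sigma_i^2))`
#' where `d_i` is the prediction error of keypoint `i` in pixels and `s` is
#' the bounding-box area in square pixels (the COCO object-scale convention
#' `s = sqrt(area)^2`). An exact match scores 1; errors large relative to the
#' object score near 0.
#'
#' @param pred,gt Numeric matrices with one row per keypoint and columns
#'   x, y (rows aligned by keypoint identity). A missing (`NA`) prediction
#'   for a visible keypoint contributes similarity 0.
#' @param bbox_area Ground-truth bounding-box area in square pixels (> 0).
#' @param sigmas Per-keypoint spread constants (> 0), length 1 or
#'   `nrow(gt)`.
#' @param visibility Optional numeric/logical flags, one per keypoint; a
#'   keypoint enters the mean iff its flag is > 0. Defaults to all visible.
#' @param strict_as_printed If `TRUE`, use `2 * area^2 * sigma^2` in the
#'   exponent denominator (the object scale squared again) instead of the
#'   default `2 * area * sigma^2`.
#' @return OKS in `[0, 1]`.
#' @examples
#' gt <- rbind(c(10, 10), c(20, 20))
#' oks(gt, gt, bbox_area = 100, sigmas = 0.05) # 1
#' @export
oks <- function(pred, gt, bbox_area, sigmas, visibility = NULL,
                strict_as_printed = FALSE) {
  pred <- rbind(pred)
  gt <- rbind(gt)
  if (nrow(pred) != nrow(gt)) {
    stop("`pred` and `gt` must have the same number of keypoints",
         call. = FALSE)
  }
  if (!is.numeric(bbox_area) || is.na(bbox_area) || bbox_area <= 0) {
    stop("`bbox_area` must be positive", call. = FALSE)
  }
  k <- nrow(gt)
  sigmas <- rep_len(sigmas, k)
  if (any(sigmas <= 0)) stop("`sigmas` must be positive", call. = FALSE)
  if (is.null(visibility)) visibility <- rep(1, k)
  vis <- as.numeric(visibility) > 0
  if (!any(vis)) {
    stop("OKS undefined: no visible ground-truth keypoints", call. = FALSE)
  }
  d2 <- (pred[, 1] - gt[, 1])^2 + (pred[, 2] - gt[, 2])^2
  d2[is.na(d2)] <- Inf
  scale2 <- if (strict_as_printed) bbox_area^2 else bbox_area
  sim <- exp(-d2 / (2 * scale2 * sigmas^2))
  mean(sim[vis])
}

#' Average precision over per-instance OKS scores
#'
#' A detection is successful when its OKS exceeds the threshold `T`. In
#' `"indicator"` mode (default) AP is the fraction of instances exceeding the
#' threshold. `"as_printed"` mode instead averages the piecewise value
#' `OKS if OKS > T else 0`, crediting each success with its similarity rather
#' than with 1.
#'
#' @param oks_values Numeric vector of per-instance OKS scores in `[0, 1]`.
#' @param threshold OKS threshold `T` in `[0, 1]`.
#' @param mode `"indicator"` or `"as_printed"`.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(oks_values, threshold,
                              mode = c("indicator", "as_printed")) {
  mode <- match.arg(mode)
  if (length(oks_values) == 0) {
    stop("`oks_values` is empty", call. = FALSE)
  }
  if (any(oks_values < 0 | oks_values > 1, na.rm = TRUE)) {
    stop("OKS values must lie in [0, 1]", call. = FALSE)
  }
  if (mode == "indicator") {
    mean(oks_values > threshold)
  } else {
    mean(ifelse(oks_values > threshold, oks_values, 0))
  }
}

#' Mean average precision
#'
#' Arithmetic mean of AP values (over categories, or over OKS thresholds as
#' in AP@0.5:0.95).
#'
#' @param ap_values Non-empty numeric vector of AP values in `[0, 1]`.
#' @return The mean.
#' @export
mean_ap <- function(ap_values) {
  if (length(ap_values) == 0) stop("`ap_values` is empty", call. = FALSE)
  mean(ap_values)
}

#' Precision and recall from match counts
#'
#' `precision = TP / (TP + FP)` (proportion of predictions that are correct)
#' and `recall = TP / (TP + FN)` (proportion of ground truths recovered).
#'
#' @param tp,fp,fn Non-negative counts.
#' @return A list with `precision` and `recall`; a zero denominator yields
#'   `NA_real_` for that component.
#' @export
precision_recall <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  list(precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
}

#' Relative chew-count error
#'
#' Percent disagreement between the method's chew count (`assessed`) and the
#' manual observer's count (`measured`):
#' `100 * |assessed - measured| / denominator`. The denominator defaults to
#' the assessed count, the convention of the published per-video validation
#' table; `"measured"` divides by the manual count instead.
#'
#' @param assessed Method chew count(s).
#' @param measured Manual chew count(s).
#' @param denominator `"assessed"` (default) or `"measured"`.
#' @return Relative error(s) in percent (vectorized).
#' @examples
#' relative_error(83, 79) # 4.82 to 2 dp
#' @export
relative_error <- function(assessed, measured,
                           denominator = c("assessed", "measured")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "assessed") assessed else measured
  if (any(den <= 0)) {
    stop("relative error undefined: `", denominator, "` must be positive",
         call. = FALSE)
  }
  100 * abs(assessed - measured) / den
}

# Population standard deviation (divisor n, not n - 1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Summary statistics of relative errors
#'
#' @param errors Non-empty numeric vector of relative errors in percent.
#' @return A list with `mean_pct` and `sd_pct`, the population standard
#'   deviation (divisor `n`).
#' @export
error_summary <- function(errors) {
  if (length(errors) == 0) stop("`errors` is empty", call. = FALSE)
  list(mean_pct = mean(errors), sd_pct = pop_sd(errors))
}

#' Evaluate chew counts against manual observation
#'
#' Computes the per-video relative error and the summary row (mean,
#' population standard deviation, and derived accuracy `100 - mean`) for a
#' manual-count table such as the one read by [read_manual_counts()].
#'
#' @param counts Data frame with columns `assessed` and `measured`
#'   (optionally `video_id`, `duration_s`).
#' @param denominator Passed to [relative_error()].
#' @return An object of class `"count_eval"`: list with `table` (the input
#'   plus `relative_error_pct`), `mean_pct`, `sd_pct`, `accuracy_pct`, and
#'   `denominator`.
#' @export
evaluate_counts <- function(counts,
                            denominator = c("assessed", "measured")) {
  denominator <- match.arg(denominator)
  if (!all(c("assessed", "measured") %in% names(counts))) {
    stop("`counts` needs `assessed` and `measured` columns", call. = FALSE)
  }
  if (nrow(counts) == 0) stop("`counts` has no rows", call. = FALSE)
  tab <- as.data.frame(counts)
  tab$relative_error_pct <- relative_error(tab$assessed, tab$measured,
                                           denominator)
  s <- error_summary(tab$relative_error_pct)
  structure(list(table = tab,
                 mean_pct = s$mean_pct,
                 sd_pct = s$sd_pct,
                 accuracy_pct = 100 - s$mean_pct,
                 denominator = denominator),
            class = "count_eval")
}

#' @export
print.count_eval <- function(x, ...) {
  tab <- x$table
  tab$relative_error_pct <- round(tab$relative_error_pct, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("Mean relative error: %.2f %%\n", x$mean_pct))
  cat(sprintf("Standard error (population): %.2f %%\n", x$sd_pct))
  cat(sprintf("Accuracy: %.1f %%\n", x$accuracy_pct))
  invisible(x)
}

#' Read COCO-style keypoint annotations
#'
#' Parses a COCO keypoint JSON (objects `images` and `annotations`, each
#' annotation carrying `image_id`, a flat `keypoints` array of
#' `[x, y, v]` triples, and optionally `bbox = [x, y, w, h]`).
#'
#' @param path Path to the JSON file.
#' @return A list of instances, each a list with `image_id`, `keypoints`
#'   (matrix with columns x, y), `visibility`, and `bbox_area` (`NA` when no
#'   bbox is given).
#' @export
read_coco_keypoints <- function(path) {
  if (!file.exists(path)) stop("keypoint JSON not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  anns <- doc$annotations
  if (is.null(anns)) stop("keypoint JSON lacks `annotations`", call. = FALSE)
  lapply(anns, function(a) {
    kp <- as.numeric(unlist(a$keypoints))
    if (length(kp) %% 3 != 0) {
      stop("`keypoints` length must be a multiple of 3", call. = FALSE)
    }
    m <- matrix(kp, ncol = 3, byrow = TRUE)
    area <- NA_real_
    if (!is.null(a$bbox)) {
      bb <- as.numeric(unlist(a$bbox))
      area <- bb[3] * bb[4]
    }
    xy <- m[, 1:2, drop = FALSE]
    zerofill <- m[, 3] == 0 & xy[, 1] == 0 & xy[, 2] == 0  # COCO convention
    xy[zerofill, ] <- NA
    list(image_id = a$image_id, keypoints = xy, visibility = m[, 3],
         bbox_area = area)
  })
}

#' Evaluate keypoint predictions against ground truth
#'
#' Matches predictions to ground-truth instances within each image by greedy
#' descending OKS, then reports the OKS-based metrics: AP at each threshold,
#' AP@0.5, mean AP over thresholds 0.50-0.95, and precision/recall at the
#' match threshold. A prediction is a true positive when it is matched with
#' OKS above `match_threshold`; other predictions are false positives and
#' unmatched ground truths are false negatives. Unmatched ground truths enter
#' the AP pool with OKS 0.
#'
#' @param gt,pred Instance lists as returned by [read_coco_keypoints()], or
#'   paths to COCO keypoint JSON files.
#' @param sigmas Per-keypoint spread constants for [oks()].
#' @param thresholds OKS thresholds for the AP sweep (default
#'   `seq(0.5, 0.95, by = 0.05)`).
#' @param match_threshold OKS threshold for the TP/FP decision (default 0.5).
#' @param ap_mode Passed to [average_precision()].
#' @param strict_as_printed Passed to [oks()].
#' @return An object of class `"keypoint_eval"`: list with `oks_values`
#'   (per ground-truth instance), `ap_by_threshold`, `map_50`, `map_50_95`,
#'   `precision`, `recall`, and the match counts `tp`, `fp`, `fn`.
#' @export
evaluate_keypoints <- function(gt, pred, sigmas,
                               thresholds = seq(0.5, 0.95, by = 0.05),
                               match_threshold = 0.5,
                               ap_mode = c("indicator", "as_printed"),
                               strict_as_printed = FALSE) {
  ap_mode <- match.arg(ap_mode)
  if (is.character(gt)) gt <- read_coco_keypoints(gt)
  if (is.character(pred)) pred <- read_coco_keypoints(pred)
  img_ids <- unique(vapply(gt, function(a) as.character(a$image_id),
                           character(1)))
  oks_values <- numeric(0)
  tp <- 0L; fp <- 0L; fn <- 0L
  pred_ids <- vapply(pred, function(a) as.character(a$image_id), character(1))
  for (img in img_ids) {
    g <- gt[vapply(gt, function(a) as.character(a$image_id) == img,
                   logical(1))]
    p <- pred[pred_ids == img]
    if (length(p) == 0) {
      fn <- fn + length(g)
      oks_values <- c(oks_values, rep(0, length(g)))
      next
    }
    sim <- matrix(0, nrow = length(p), ncol = length(g))
    for (i in seq_along(p)) {
      for (j in seq_along(g)) {
        sim[i, j] <- oks(p[[i]]$keypoints, g[[j]]$keypoints,
                         bbox_area = g[[j]]$bbox_area,
                         sigmas = sigmas,
                         visibility = g[[j]]$visibility,
                         strict_as_printed = strict_as_printed)
      }
    }
    matched_oks <- rep(0, length(g))
    used_p <- rep(FALSE, length(p))
    used_g <- rep(FALSE, length(g))
    ord <- order(sim, decreasing = TRUE)
    for (o in ord) {
      i <- (o - 1L) %% length(p) + 1L
      j <- (o - 1L) %/% length(p) + 1L
      if (used_p[i] || used_g[j]) next
      used_p[i] <- TRUE
      used_g[j] <- TRUE
      matched_oks[j] <- sim[i, j]
      if (sim[i, j] > match_threshold) tp <- tp + 1L else fp <- fp + 1L
    }
    fp <- fp + sum(!used_p)
    fn <- fn + sum(!used_g)
    oks_values <- c(oks_values, matched_oks)
  }
  # predictions for images absent from the ground truth are false positives
  fp <- fp + sum(!pred_ids %in% img_ids)
  ap <- vapply(thresholds, function(tt) {
    average_precision(oks_values, tt, mode = ap_mode)
  }, numeric(1))
  names(ap) <- sprintf("%.2f", thresholds)
  pr <- precision_recall(tp, fp, fn)
  structure(list(oks_values = oks_values,
                 ap_by_threshold = ap,
                 map_50 = if ("0.50" %in% names(ap)) ap[["0.50"]] else
                   average_precision(oks_values, 0.5, mode = ap_mode),
                 map_50_95 = mean_ap(ap),
                 precision = pr$precision,
                 recall = pr$recall,
                 tp = tp, fp = fp, fn = fn),
            class = "keypoint_eval")
}

#' @export
print.keypoint_eval <- function(x, ...) {
  cat("<keypoint_eval>\n")
  cat(sprintf("  instances: %d   AP@0.5: %.3f   AP@0.5:0.95: %.3f\n",
              length(x$oks_values), x$map_50, x$map_50_95))
  cat(sprintf("  precision: %s   recall: %s  (TP %d, FP %d, FN %d)\n",
              format(round(x$precision, 3)), format(round(x$recall, 3)),
              x$tp, x$fp, x$fn))
  invisible(x)
}
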