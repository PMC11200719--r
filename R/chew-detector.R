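#' Detector configuration for chew counting
#'
#' Chews are counted as local maxima of the (filtered) motion curve that
#' clear a threshold and are separated by more than a minimum number of
#' frames. The default threshold is the median of the distance series -- a
#' dynamic, scale-free cutoff chosen because rest-period wobble stays below
#' the median while true chew crests rise above it, and because the median is
#' robust to outliers. The default spacing is 20 frames at 30 fps (one chew
#' lasts roughly that long), rescaled by `fps / 30` for other frame rates, and
#' guards against double counts from head shaking.
#'
#' @param min_spacing_frames Minimum frame gap: consecutive accepted peaks
#'   must differ by strictly more than this many frames. `NULL` (default)
#'   means `round(20 * fps / 30)`, resolved when the detector runs.
#' @param threshold_mode `"median"` (default; the median of the whole series),
#'   `"fixed"` (a user-supplied cutoff in pixels), or `"rolling_median"` (a
#'   sliding-window median, for long heterogeneous recordings).
#' @param fixed_threshold Cutoff in pixels, required for `"fixed"` mode.
#' @param rolling_window_s Window in seconds for `"rolling_median"` mode
#'   (default 30).
#' @param plateau_policy `"strict"` (default): all comparisons are strict, so
#'   a flat-topped plateau is not a peak. `"midpoint"`: a maximal flat run
#'   flanked by ascent and descent counts as one peak at its center (useful
#'   for unfiltered integer-valued signals).
#' @return A list of class `"detector_config"`.
#' @export
detector_config <- function(min_spacing_frames = NULL,
                            threshold_mode = c("median", "fixed",
                                               "rolling_median"),
                            fixed_threshold = NULL,
                            rolling_window_s = 30,
                            plateau_policy = c("strict", "midpoint")) {
  threshold_mode <- match.arg(threshold_mode)
  plateau_policy <- match.arg(plateau_policy)
  if (!is.null(min_spacing_frames)) {
    if (!is.numeric(min_spacing_frames) || min_spacing_frames < 0) {
      stop("`min_spacing_frames` must be >= 0", call. = FALSE)
    }
  }
  if (threshold_mode == "fixed") {
    if (is.null(fixed_threshold) || !is.numeric(fixed_threshold) ||
        fixed_threshold < 0) {
      stop("`fixed` threshold mode requires `fixed_threshold` >= 0",
           call. = FALSE)
    }
  }
  if (threshold_mode == "rolling_median" &&
      (!is.numeric(rolling_window_s) || rolling_window_s <= 0)) {
    stop("`rolling_window_s` must be positive", call. = FALSE)
  }
  structure(list(min_spacing_frames = min_spacing_frames,
                 threshold_mode = threshold_mode,
                 fixed_threshold = fixed_threshold,
                 rolling_window_s = rolling_window_s,
                 plateau_policy = plateau_policy),
            class = "detector_config")
}

#' Dynamic chew-detection threshold
#'
#' The median of the distance series (midpoint of the two central order
#' statistics for even length). Rest-period fluctuations of the nose-mouth
#' distance stay below this value, while chew crests exceed it, which is what
#' makes the median a usable scene-independent cutoff.
#'
#' @param series A `"distance_series"` or a numeric vector.
#' @return The threshold in pixels.
#' @examples
#' dynamic_threshold(c(1, 2, 3, 4, 100)) # 3
#' @export
dynamic_threshold <- function(series) {
  v <- if (inherits(series, "distance_series")) series$values else
    as.numeric(series)
  if (length(v) == 0) stop("cannot take the median of an empty series",
                           call. = FALSE)
  stats::median(v)
}

rolling_median_threshold <- function(x, window) {
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

# Candidate summits of one segment: maximal runs of equal values whose left
# and right neighbours are strictly lower. Runs touching a segment end are
# discarded (endpoints are never peaks). Returns run centers for length-1
# runs; longer runs are resolved by `plateau_policy`.
find_summits <- function(x, plateau_policy) {
  n <- length(x)
  if (n < 3) {
    return(list(candidates = integer(0), plateaus_rejected = 0L))
  }
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  cand <- integer(0)
  plateaus_rejected <- 0L
  if (m >= 3) {
    for (k in 2:(m - 1)) {
      if (r$values[k] > r$values[k - 1] && r$values[k] > r$values[k + 1]) {
        if (r$lengths[k] == 1L) {
          cand <- c(cand, starts[k])
        } else if (plateau_policy == "midpoint") {
          cand <- c(cand, (starts[k] + ends[k]) %/% 2L)
        } else {
          plateaus_rejected <- plateaus_rejected + 1L
        }
      }
    }
  }
  list(candidates = cand, plateaus_rejected = plateaus_rejected)
}

#' Detect chew peaks in a distance series
#'
#' Multi-condition threshold peak detection: scanning left to right within
#' each segment, a sample is accepted as a chew iff it is a strict local
#' maximum (`d[i] > d[i-1]` and `d[i] > d[i+1]`), its value exceeds the
#' threshold, and its frame index exceeds the previously accepted peak's by
#' strictly more than `min_spacing_frames`. The first acceptance in each
#' segment carries no spacing constraint, and the spacing counter never
#' crosses a segment boundary. Segment endpoints are never peaks.
#'
#' @param series A `"distance_series"`, normally low-pass filtered first.
#' @param cfg A [detector_config()].
#' @param threshold Optional externally supplied threshold in pixels (e.g.,
#'   the median of the unfiltered series); overrides `cfg$threshold_mode`.
#' @return An object of class `"chew_peaks"`: list with `peak_frames`
#'   (accepted chew frame indices, strictly increasing), `peak_values`,
#'   `threshold_used` (scalar, or per-sample vector for rolling mode),
#'   `min_spacing_frames`, `fps`, `n_chews`, and `rejected`, a named count of
#'   candidates discarded by reason (`below_threshold`, `too_close`,
#'   `not_local_max` -- flat-topped plateaus under the strict policy).
#' @export
detect_chew_peaks <- function(series, cfg = detector_config(),
                              threshold = NULL) {
  stopifnot(inherits(series, "distance_series"),
            inherits(cfg, "detector_config"))
  v <- series$values
  fr <- series$frame_indices
  spacing <- cfg$min_spacing_frames
  if (is.null(spacing)) spacing <- round(20 * series$fps / 30)

  if (!is.null(threshold)) {
    thr <- rep(threshold, length(v))
    thr_used <- threshold
  } else if (cfg$threshold_mode == "median") {
    thr_used <- dynamic_threshold(series)
    thr <- rep(thr_used, length(v))
  } else if (cfg$threshold_mode == "fixed") {
    thr_used <- cfg$fixed_threshold
    thr <- rep(thr_used, length(v))
  } else { # rolling_median
    win <- as.integer(round(cfg$rolling_window_s * series$fps))
    if (win %% 2L == 0L) win <- win + 1L
    thr <- numeric(length(v))
    for (k in seq_len(nrow(series$segments))) {
      idx <- series$segments[k, "start"]:series$segments[k, "end"]
      thr[idx] <- rolling_median_threshold(v[idx], win)
    }
    thr_used <- thr
  }

  accepted <- integer(0)
  rejected <- c(below_threshold = 0L, too_close = 0L, not_local_max = 0L)
  for (k in seq_len(nrow(series$segments))) {
    s <- series$segments[k, "start"]
    e <- series$segments[k, "end"]
    seg <- v[s:e]
    summ <- find_summits(seg, cfg$plateau_policy)
    rejected["not_local_max"] <- rejected["not_local_max"] +
      summ$plateaus_rejected
    last_frame <- NA_integer_
    for (i in summ$candidates) {
      gi <- s + i - 1L
      if (!(v[gi] > thr[gi])) {
        rejected["below_threshold"] <- rejected["below_threshold"] + 1L
      } else if (!is.na(last_frame) && !(fr[gi] - last_frame > spacing)) {
        rejected["too_close"] <- rejected["too_close"] + 1L
      } else {
        accepted <- c(accepted, gi)
        last_frame <- fr[gi]
      }
    }
  }
  structure(list(peak_frames = fr[accepted],
                 peak_values = v[accepted],
                 threshold_used = thr_used,
                 min_spacing_frames = spacing,
                 fps = series$fps,
                 n_chews = length(accepted),
                 rejected = as.list(rejected)),
            class = "chew_peaks")
}

#' @export
print.chew_peaks <- function(x, ...) {
  thr <- if (length(x$threshold_used) == 1) sprintf("%.2f px", x$threshold_used)
         else "rolling median"
  cat(sprintf("<chew_peaks> %d chews (threshold %s, spacing > %d frames)\n",
              x$n_chews, thr, x$min_spacing_frames))
  rej <- unlist(x$rejected)
  if (sum(rej) > 0) {
    cat("  rejected:", paste(names(rej), rej, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Count chews in a keypoint trajectory
#'
#' The full counting pipeline: build the nose-mouth distance series (bridging
#' short detector dropouts, splitting at long ones), denoise it, compute the
#' dynamic median threshold, and run the multi-condition peak detector.
#'
#' @param traj A [trajectory()] object.
#' @param filter_cfg A [filter_config()]; default zero-phase Butterworth,
#'   3 Hz cutoff, order 4.
#' @param det_cfg A [detector_config()].
#' @param max_gap_frames Dropout-bridging limit passed to
#'   [build_distance_series()].
#' @param threshold_on For median threshold mode: compute the median on the
#'   `"filtered"` series the detector sees (default) or on the `"raw"`
#'   unfiltered distances.
#' @return A `"chew_peaks"` object (see [detect_chew_peaks()]).
#' @examples
#' sim <- generate_chew_trajectory(chew_signal_config(n_chews = 10, seed = 1))
#' count_chews(sim$trajectory)$n_chews
#' @export
count_chews <- function(traj, filter_cfg = filter_config(),
                        det_cfg = detector_config(),
                        max_gap_frames = 10,
                        threshold_on = c("filtered", "raw")) {
  threshold_on <- match.arg(threshold_on)
  series <- build_distance_series(traj, max_gap_frames = max_gap_frames)
  filtered <- apply_filter(series, filter_cfg)
  thr <- NULL
  if (det_cfg$threshold_mode == "median" && threshold_on == "raw") {
    thr <- dynamic_threshold(series)
  }
  detect_chew_peaks(filtered, det_cfg, threshold = thr)
}
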