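#' Rumination duration with long rests excluded
#'
#' Chew events are grouped into bouts: consecutive chews whose inter-chew gap
#' is at most `rest_gap_s` belong to the same bout; any gap strictly
#' exceeding `rest_gap_s` (default 3 s) is treated as a rest and excluded
#' from the rumination duration. A bout's duration is the time from its first
#' to its last chew, so a single isolated chew forms a zero-length bout.
#' The identity `duration + sum(excluded gaps) == last - first chew time`
#' holds exactly.
#'
#' @param chew_times Chew event times in seconds, sorted ascending.
#' @param rest_gap_s Rest threshold in seconds (strict `>`; a gap of exactly
#'   `rest_gap_s` still counts as rumination). Default 3.
#' @return A list with `duration_s`, `bouts` (data frame with `start_s`,
#'   `end_s`, `n_chews`), and `excluded_rest_s` (total rest time removed).
#' @examples
#' rumination_duration(c(0, 1, 2, 7, 8))
#' @export
rumination_duration <- function(chew_times, rest_gap_s = 3) {
  if (!is.numeric(rest_gap_s) || rest_gap_s <= 0) {
    stop("`rest_gap_s` must be positive", call. = FALSE)
  }
  chew_times <- as.numeric(chew_times)
  if (anyNA(chew_times)) stop("chew times contain NA", call. = FALSE)
  if (is.unsorted(chew_times)) {
    stop("`chew_times` must be sorted ascending", call. = FALSE)
  }
  n <- length(chew_times)
  if (n == 0) {
    return(list(duration_s = 0,
                bouts = data.frame(start_s = numeric(0), end_s = numeric(0),
                                   n_chews = integer(0)),
                excluded_rest_s = 0))
  }
  gaps <- diff(chew_times)
  is_rest <- gaps > rest_gap_s
  bout_id <- cumsum(c(0L, as.integer(is_rest)))
  starts <- tapply(chew_times, bout_id, min)
  ends <- tapply(chew_times, bout_id, max)
  counts <- tapply(chew_times, bout_id, length)
  bouts <- data.frame(start_s = as.numeric(starts),
                      end_s = as.numeric(ends),
                      n_chews = as.integer(counts))
  list(duration_s = sum(bouts$end_s - bouts$start_s),
       bouts = bouts,
       excluded_rest_s = sum(gaps[is_rest]))
}

#' Chewing frequency
#'
#' The ratio of chew count to rumination duration, in chews per second.
#'
#' @param chew_count Number of chews (non-negative).
#' @param duration_s Rumination duration in seconds (non-negative).
#' @return Chews per second, or `NA_real_` when `duration_s` is zero (a
#'   degenerate session has no defined frequency).
#' @examples
#' chewing_frequency(90, 60) # 1.5 Hz = 90 chews per minute
#' @export
chewing_frequency <- function(chew_count, duration_s) {
  if (!is.numeric(chew_count) || chew_count < 0 ||
      !is.numeric(duration_s) || duration_s < 0) {
    stop("`chew_count` and `duration_s` must be non-negative", call. = FALSE)
  }
  if (duration_s == 0) return(NA_real_)
  chew_count / duration_s
}

#' Summarize a rumination session
#'
#' Runs the full pipeline ([count_chews()]), converts accepted peak frames to
#' seconds via the trajectory's frame rate, and reports the three session
#' indicators: chew count, rumination duration (rests over `rest_gap_s`
#' excluded), and chewing frequency.
#'
#' @inheritParams count_chews
#' @param rest_gap_s Rest-exclusion threshold in seconds (default 3).
#' @return An object of class `"session_summary"`: list with `chew_count`,
#'   `rumination_duration_s`, `chew_frequency_hz`, `bouts`,
#'   `excluded_rest_s`, `peak_times_s`, `threshold_used`, and `fps`.
#' @export
summarize_session <- function(traj, filter_cfg = filter_config(),
                              det_cfg = detector_config(),
                              rest_gap_s = 3, max_gap_frames = 10,
                              threshold_on = c("filtered", "raw")) {
  peaks <- count_chews(traj, filter_cfg, det_cfg,
                       max_gap_frames = max_gap_frames,
                       threshold_on = threshold_on)
  times <- peaks$peak_frames / peaks$fps
  dur <- rumination_duration(times, rest_gap_s = rest_gap_s)
  structure(list(chew_count = peaks$n_chews,
                 rumination_duration_s = dur$duration_s,
                 chew_frequency_hz = chewing_frequency(peaks$n_chews,
                                                       dur$duration_s),
                 bouts = dur$bouts,
                 excluded_rest_s = dur$excluded_rest_s,
                 peak_times_s = times,
                 threshold_used = peaks$threshold_used,
                 fps = peaks$fps),
            class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat("<session_summary>\n")
  cat(sprintf("  chews:               %d\n", x$chew_count))
  cat(sprintf("  rumination duration: %.2f s (%.2f s rest excluded)\n",
              x$rumination_duration_s, x$excluded_rest_s))
  cat(sprintf("  chewing frequency:   %s\n",
              if (is.na(x$chew_frequency_hz)) "undefined"
              else sprintf("%.3f chews/s", x$chew_frequency_hz)))
  cat(sprintf("  bouts:               %d\n", nrow(x$bouts)))
  invisible(x)
}

#' Real-time chewing frequency series
#'
#' Sliding-window chewing frequency for display alongside the session totals:
#' at each step the number of chews inside a centered window is divided by
#' the window length.
#'
#' @param chew_times Chew event times in seconds, sorted ascending.
#' @param window_s Window length in seconds (default 10).
#' @param step_s Step between window centers in seconds (default 1).
#' @param span Optional `c(start, end)` time range; defaults to the chew-time
#'   range.
#' @return A data frame with `time_s` (window center) and `frequency_hz`.
#' @export
chew_frequency_series <- function(chew_times, window_s = 10, step_s = 1,
                                  span = NULL) {
  if (window_s <= 0 || step_s <= 0) {
    stop("`window_s` and `step_s` must be positive", call. = FALSE)
  }
  chew_times <- as.numeric(chew_times)
  if (is.unsorted(chew_times)) {
    stop("`chew_times` must be sorted ascending", call. = FALSE)
  }
  if (is.null(span)) {
    if (length(chew_times) == 0) {
      return(data.frame(time_s = numeric(0), frequency_hz = numeric(0)))
    }
    span <- range(chew_times)
  }
  centers <- seq(span[1], span[2], by = step_s)
  h <- window_s / 2
  freq <- vapply(centers, function(tc) {
    sum(chew_times >= tc - h & chew_times <= tc + h) / window_s
  }, numeric(1))
  data.frame(time_s = centers, frequency_hz = freq)
}
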