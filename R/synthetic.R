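#' Configuration for the synthetic chew-trajectory generator
#'
#' The generator emulates the output of a facial keypoint detector watching a
#' ruminating cow: a quasi-periodic nose-mouth distance oscillation in which
#' every cycle's period and amplitude vary, overlaid with Gaussian keypoint
#' jitter, optionally interrupted by low-amplitude rest bouts and by
#' missing-detection gaps (the animal turning its head away).
#'
#' Defaults describe a typical session: 30 fps video, a mean chew period of
#' 25 frames (1.2 Hz, the rate implied by published per-video chew counts),
#' a closed-mouth nose-mouth distance of 30 px with 15 px of mouth opening,
#' and 1 px of keypoint jitter. Rest wobble is a small fraction of the chew
#' amplitude so that rest-period fluctuation stays below the series median,
#' the property the median threshold relies on.
#'
#' @param n_chews Number of chew cycles (>= 0).
#' @param fps Frames per second (default 30).
#' @param period_frames_mean Mean chew period in frames (default 25).
#' @param period_jitter_frac Per-cycle period variation: each period is drawn
#'   uniformly in `mean * (1 +/- frac)` and rounded (default 0.1).
#' @param amplitude_mean Mean mouth-opening amplitude in pixels (default 15).
#' @param amplitude_jitter_frac Per-cycle amplitude variation (default 0.15).
#' @param baseline_px Closed-mouth nose-mouth distance in pixels (default 30).
#' @param noise_std_px Gaussian jitter (per coordinate) of the mouth keypoint
#'   in pixels (default 1).
#' @param rest_bouts List of `c(after_chew, duration_s)` pairs: a rest of
#'   `duration_s` seconds is inserted after chew number `after_chew`
#'   (0 inserts it before the first chew). Must be in strictly increasing
#'   order of `after_chew` with no repeats.
#' @param rest_wobble_frac Rest-period wobble amplitude as a fraction of
#'   `amplitude_mean` (default 0.1; keep well below 0.5 so rest fluctuation
#'   stays under the median).
#' @param dropout_prob Per-frame probability of a missing detection
#'   (default 0).
#' @param seed Integer seed; identical configs generate identical output.
#' @return A list of class `"chew_signal_config"`.
#' @export
chew_signal_config <- function(n_chews = 50, fps = 30,
                               period_frames_mean = 25,
                               period_jitter_frac = 0.1,
                               amplitude_mean = 15,
                               amplitude_jitter_frac = 0.15,
                               baseline_px = 30, noise_std_px = 1,
                               rest_bouts = list(),
                               rest_wobble_frac = 0.1,
                               dropout_prob = 0, seed = 1) {
  if (!is.numeric(fps) || fps <= 0) stop("`fps` must be positive", call. = FALSE)
  if (!is.numeric(n_chews) || n_chews < 0 || n_chews != floor(n_chews)) {
    stop("`n_chews` must be a non-negative integer", call. = FALSE)
  }
  if (amplitude_mean <= 0) stop("`amplitude_mean` must be positive", call. = FALSE)
  if (period_frames_mean < 3) stop("`period_frames_mean` too short", call. = FALSE)
  for (f in c(period_jitter_frac, amplitude_jitter_frac, rest_wobble_frac,
              dropout_prob)) {
    if (!is.numeric(f) || f < 0 || f >= 1) {
      stop("fractions must lie in [0, 1)", call. = FALSE)
    }
  }
  if (noise_std_px < 0) stop("`noise_std_px` must be >= 0", call. = FALSE)
  if (length(rest_bouts) > 0) {
    rb <- do.call(rbind, lapply(rest_bouts, function(x) as.numeric(x[1:2])))
    if (anyNA(rb) || any(rb[, 1] < 0) || any(rb[, 1] > n_chews) ||
        any(rb[, 1] != floor(rb[, 1])) || any(rb[, 2] <= 0)) {
      stop("each rest bout must be c(after_chew in 0..n_chews, duration_s > 0)",
           call. = FALSE)
    }
    if (is.unsorted(rb[, 1], strictly = TRUE)) {
      stop("rest bouts must have strictly increasing, non-overlapping positions",
           call. = FALSE)
    }
  }
  structure(list(n_chews = as.integer(n_chews), fps = fps,
                 period_frames_mean = period_frames_mean,
                 period_jitter_frac = period_jitter_frac,
                 amplitude_mean = amplitude_mean,
                 amplitude_jitter_frac = amplitude_jitter_frac,
                 baseline_px = baseline_px, noise_std_px = noise_std_px,
                 rest_bouts = rest_bouts,
                 rest_wobble_frac = rest_wobble_frac,
                 dropout_prob = dropout_prob,
                 seed = as.integer(seed)),
            class = "chew_signal_config")
}

# Draw under a dedicated sub-stream seed so that toggling one randomness
# source (noise, dropout, ...) leaves the draws of the others unchanged.
with_substream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((seed %% 1000000000L) + offset)
  force(expr)
}

#' Generate a synthetic chew trajectory with known ground truth
#'
#' The nose keypoint is anchored at a fixed position; the mouth keypoint is
#' placed below it so that the nose-mouth distance follows `baseline` plus
#' one raised half-sine pulse per chew (mouth closed, open, closed again),
#' with per-cycle period and amplitude jitter. The half-sine is sampled with
#' a quarter-sample phase offset so that no two samples of a cycle are
#' exactly equal and every cycle has a unique, strict crest. Rest bouts
#' insert low-amplitude wobble around the baseline; dropout marks frames
#' undetected.
#'
#' @param cfg A [chew_signal_config()].
#' @return A list with `trajectory` (a [trajectory()] object) and
#'   `ground_truth`: list with `true_chew_count`, `true_peak_frames`
#'   (0-based frames of the chew crests), `rest_intervals_s`, and
#'   `dropped_frames`.
#' @examples
#' sim <- generate_chew_trajectory(chew_signal_config(n_chews = 5, seed = 7))
#' sim$ground_truth$true_chew_count
#' @export
generate_chew_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "chew_signal_config"))
  n <- cfg$n_chews
  periods <- if (n > 0) {
    with_substream(cfg$seed, 101L, {
      pmax(3L, as.integer(round(cfg$period_frames_mean *
        (1 + cfg$period_jitter_frac * stats::runif(n, -1, 1)))))
    })
  } else integer(0)
  amps <- if (n > 0) {
    with_substream(cfg$seed, 202L, {
      cfg$amplitude_mean *
        (1 + cfg$amplitude_jitter_frac * stats::runif(n, -1, 1))
    })
  } else numeric(0)

  rest_after <- vapply(cfg$rest_bouts, function(x) as.integer(x[1]), integer(1))
  rest_dur <- vapply(cfg$rest_bouts, function(x) as.numeric(x[2]), numeric(1))

  d <- numeric(0)
  true_peaks <- integer(0)
  rest_intervals <- matrix(numeric(0), ncol = 2)
  wobble_amp <- cfg$rest_wobble_frac * cfg$amplitude_mean

  append_rest <- function(dur_s) {
    len <- max(1L, as.integer(round(dur_s * cfg$fps)))
    tt <- seq_len(len) - 0.75                 # offset avoids exact ties
    start_frame <- length(d)
    d <<- c(d, cfg$baseline_px +
              wobble_amp * sin(2 * pi * 0.5 * tt / cfg$fps))
    rest_intervals <<- rbind(rest_intervals,
                             c(start_frame / cfg$fps,
                               (start_frame + len) / cfg$fps))
  }

  for (r in which(rest_after == 0L)) append_rest(rest_dur[r])
  for (k in seq_len(n)) {
    p <- periods[k]
    j <- 0:(p - 1)
    pulse <- cfg$baseline_px + amps[k] * sin(pi * (j + 0.25) / p)
    true_peaks <- c(true_peaks, length(d) + which.max(pulse) - 1L)
    d <- c(d, pulse)
    for (r in which(rest_after == k)) append_rest(rest_dur[r])
  }
  if (length(d) == 0) {
    d <- rep(cfg$baseline_px, as.integer(round(5 * cfg$fps)))
  }

  total <- length(d)
  noise_x <- numeric(total)
  noise_y <- numeric(total)
  if (cfg$noise_std_px > 0) {
    nz <- with_substream(cfg$seed, 303L,
                         stats::rnorm(2L * total, sd = cfg$noise_std_px))
    noise_x <- nz[seq_len(total)]
    noise_y <- nz[total + seq_len(total)]
  }
  dropped <- logical(total)
  if (cfg$dropout_prob > 0) {
    dropped <- with_substream(cfg$seed, 404L,
                              stats::runif(total) < cfg$dropout_prob)
  }

  nose_x <- rep(100, total)
  nose_y <- rep(100, total)
  mouth_x <- nose_x + noise_x
  mouth_y <- nose_y + d + noise_y
  nose_x[dropped] <- NA
  nose_y[dropped] <- NA
  mouth_x[dropped] <- NA
  mouth_y[dropped] <- NA

  traj <- trajectory(
    data.frame(frame = 0:(total - 1L),
               nose_x = nose_x, nose_y = nose_y,
               mouth_x = mouth_x, mouth_y = mouth_y),
    fps = cfg$fps,
    source_id = sprintf("synthetic(seed=%d)", cfg$seed))
  list(trajectory = traj,
       ground_truth = list(true_chew_count = length(true_peaks),
                           true_peak_frames = true_peaks,
                           rest_intervals_s = rest_intervals,
                           dropped_frames = which(dropped) - 1L))
}

#' Pipeline counting error across noise levels
#'
#' Validation harness: for each keypoint-jitter level, generates fresh seeded
#' trajectories, runs the full counting pipeline, and reports the mean
#' absolute relative count error.
#'
#' @param cfg_base A [chew_signal_config()] supplying everything except the
#'   noise level; replicate `r` at any level uses seed
#'   `cfg_base$seed + 1000 * r`.
#' @param noise_levels Numeric vector of `noise_std_px` values.
#' @param replicates Trajectories per level (default 1).
#' @param filter_cfg,det_cfg Pipeline configuration (defaults as in
#'   [count_chews()]).
#' @return A data frame with `noise_std_px` and `mean_abs_count_error_pct`
#'   (relative to the pipeline's assessed count).
#' @export
generate_noise_sweep <- function(cfg_base, noise_levels, replicates = 1,
                                 filter_cfg = filter_config(),
                                 det_cfg = detector_config()) {
  stopifnot(inherits(cfg_base, "chew_signal_config"), replicates >= 1)
  rows <- lapply(noise_levels, function(ns) {
    errs <- vapply(seq_len(replicates), function(r) {
      cfg <- cfg_base
      cfg$noise_std_px <- ns
      cfg$seed <- cfg_base$seed + 1000L * r
      sim <- generate_chew_trajectory(cfg)
      peaks <- count_chews(sim$trajectory, filter_cfg, det_cfg)
      truth <- sim$ground_truth$true_chew_count
      if (peaks$n_chews == 0) {
        if (truth == 0) 0 else 100
      } else {
        relative_error(peaks$n_chews, truth, denominator = "assessed")
      }
    }, numeric(1))
    data.frame(noise_std_px = ns, mean_abs_count_error_pct = mean(errs))
  })
  do.call(rbind, rows)
}
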