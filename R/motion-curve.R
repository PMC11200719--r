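#' Euclidean distance between two keypoints
#'
#' The chewing motion curve is built from this primitive: as the mouth opens
#' the nose-mouth distance grows, and one open-close jaw cycle traces one
#' oscillation of the curve.
#'
#' @param a,b Keypoints: numeric vectors `c(x, y)` (extra elements ignored) or
#'   lists with `x` and `y` components.
#' @return The distance in pixels (a single non-negative number).
#' @examples
#' keypoint_distance(c(0, 0), c(3, 4)) # 5
#' @export
keypoint_distance <- function(a, b) {
  a <- as_xy(a)
  b <- as_xy(b)
  sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2)
}

as_xy <- function(p) {
  if (is.list(p)) p <- c(p$x, p$y)
  p <- as.numeric(p)
  if (length(p) < 2 || anyNA(p[1:2])) {
    stop("keypoint must supply finite x and y coordinates", call. = FALSE)
  }
  p[1:2]
}

new_distance_series <- function(values, frame_indices, fps, segments) {
  stopifnot(length(values) == length(frame_indices))
  structure(list(values = as.numeric(values),
                 frame_indices = as.integer(frame_indices),
                 fps = fps,
                 segments = segments),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %d samples in %d segment(s) @ %g fps\n",
              length(x$values), nrow(x$segments), x$fps))
  invisible(x)
}

#' Build the rumination motion curve from a trajectory
#'
#' Computes the per-frame nose-mouth distance for every detected frame. Runs
#' of up to `max_gap_frames` consecutive undetected frames (brief detector
#' dropouts) are bridged by linear interpolation of the distance; longer runs
#' -- typically the animal turning its head away -- split the series into
#' separate segments so that no synthetic motion is fabricated across them.
#' Leading and trailing undetected frames are dropped.
#'
#' @param traj A [trajectory()] object with at least one detected frame.
#' @param max_gap_frames Longest dropout (in frames) to interpolate across
#'   (default 10).
#' @return A `"distance_series"`: list with `values` (pixels), `frame_indices`
#'   (matching frame numbers), `fps`, and `segments`, a two-column integer
#'   matrix of `[start, end]` positions (1-based, inclusive, into `values`)
#'   that partitions the series.
#' @export
build_distance_series <- function(traj, max_gap_frames = 10) {
  stopifnot(inherits(traj, "trajectory"))
  fr <- traj$frames[traj$frames$detected, , drop = FALSE]
  if (nrow(fr) == 0) {
    stop("trajectory has no detected frames", call. = FALSE)
  }
  d <- sqrt((fr$nose_x - fr$mouth_x)^2 + (fr$nose_y - fr$mouth_y)^2)
  f <- as.integer(fr$frame)

  gaps <- diff(f) - 1L                       # undetected frames between
  split_after <- which(gaps > max_gap_frames)

  values <- list()
  frames <- list()
  seg_start <- integer(0)
  seg_end <- integer(0)
  pos <- 0L
  run_starts <- c(1L, split_after + 1L)
  run_ends <- c(split_after, length(f))
  for (k in seq_along(run_starts)) {
    idx <- run_starts[k]:run_ends[k]
    ff <- f[idx]
    dd <- d[idx]
    full_f <- ff[1]:ff[length(ff)]
    if (length(full_f) > length(ff)) {
      dd <- stats::approx(ff, dd, xout = full_f, method = "linear")$y
    }
    values[[k]] <- dd
    frames[[k]] <- full_f
    seg_start <- c(seg_start, pos + 1L)
    pos <- pos + length(full_f)
    seg_end <- c(seg_end, pos)
  }
  new_distance_series(unlist(values), unlist(frames), traj$fps,
                      cbind(start = seg_start, end = seg_end))
}

#' Filter configuration for the motion curve
#'
#' @param kind `"lowpass"` (zero-phase Butterworth, the default), `"median"`
#'   (sliding-window median, provided for comparison), or `"none"`.
#' @param cutoff_hz Low-pass cutoff in Hz (default 3). The chew fundamental is
#'   about 1.2 Hz, so 3 Hz preserves the chewing band while rejecting
#'   keypoint jitter. Must satisfy `0 < cutoff_hz < fps / 2`.
#' @param order Butterworth order (default 4).
#' @param window Median-filter window in frames; odd (default 5).
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(kind = c("lowpass", "median", "none"),
                          cutoff_hz = 3, order = 4, window = 5) {
  kind <- match.arg(kind)
  if (kind == "lowpass") {
    if (!is.numeric(cutoff_hz) || cutoff_hz <= 0) {
      stop("`cutoff_hz` must be positive", call. = FALSE)
    }
    if (!is.numeric(order) || order < 1 || order != floor(order)) {
      stop("`order` must be a positive integer", call. = FALSE)
    }
  }
  if (kind == "median") {
    if (!is.numeric(window) || window < 1 || window != floor(window) ||
        window %% 2 == 0) {
      stop("`window` must be an odd positive integer", call. = FALSE)
    }
  }
  structure(list(kind = kind, cutoff_hz = cutoff_hz, order = order,
                 window = window),
            class = "filter_config")
}

# Steady-state initial filter state for a step input of unit height
# (direct-form II transposed), so that constant signals pass untouched.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]
  a <- a / a[1]
  if (n == 1) return(numeric(0))
  IminusA <- diag(n - 1)
  IminusA[, 1] <- IminusA[, 1] + a[-1]
  IminusA[-(n - 1), -1] <- IminusA[-(n - 1), -1] - diag(n - 2)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

# Direct-form II transposed IIR filter with explicit initial state.
df2t_filter <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]
  a <- a / a[1]
  y <- numeric(length(x))
  z <- c(zi, 0)
  for (t in seq_along(x)) {
    xt <- x[t]
    yt <- b[1] * xt + z[1]
    for (k in seq_len(n - 1)) {
      z[k] <- b[k + 1] * xt + z[k + 1] - a[k + 1] * yt
    }
    y[t] <- yt
  }
  y
}

# Zero-phase forward-backward filtering with odd-reflection padding and
# steady-state initial conditions, so edges are transient-free and constant
# input is reproduced to rounding error.
filtfilt_padded <- function(b, a, x) {
  n <- length(x)
  padlen <- 3L * (max(length(a), length(b)) - 1L)
  if (n <= padlen) {
    stop(sprintf("segment of length %d too short for the filter (needs > %d)",
                 n, padlen), call. = FALSE)
  }
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  y <- df2t_filter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- df2t_filter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

#' Low-pass filter a distance series
#'
#' Zero-phase Butterworth smoothing of the motion curve: the filter is run
#' forward and backward (with odd-reflection padding and steady-state initial
#' conditions), so peak positions are not shifted -- a property the chew
#' counter depends on. Each segment is filtered separately; detection gaps
#' carry no signal and are never filtered across.
#'
#' @param series A `"distance_series"`.
#' @param cfg A [filter_config()] with `kind = "lowpass"`.
#' @return A filtered `"distance_series"` with identical length, frame
#'   indices, and segmentation.
#' @export
lowpass_filter <- function(series, cfg = filter_config("lowpass")) {
  stopifnot(inherits(series, "distance_series"))
  if (cfg$kind != "lowpass") stop("`cfg$kind` must be \"lowpass\"", call. = FALSE)
  nyq <- series$fps / 2
  if (cfg$cutoff_hz >= nyq) {
    stop(sprintf("cutoff %g Hz must be below the Nyquist rate %g Hz",
                 cfg$cutoff_hz, nyq), call. = FALSE)
  }
  bf <- signal::butter(cfg$order, cfg$cutoff_hz / nyq, type = "low")
  padlen <- 3L * (max(length(bf$a), length(bf$b)) - 1L)
  seg_len <- series$segments[, "end"] - series$segments[, "start"] + 1L
  short <- which(seg_len <= padlen)
  if (length(short) > 0) {
    stop(sprintf("segment(s) %s too short for order-%d low-pass filtering (need > %d samples)",
                 paste(short, collapse = ", "), cfg$order, padlen),
         call. = FALSE)
  }
  out <- series$values
  for (k in seq_len(nrow(series$segments))) {
    idx <- series$segments[k, "start"]:series$segments[k, "end"]
    out[idx] <- filtfilt_padded(bf$b, bf$a, series$values[idx])
  }
  new_distance_series(out, series$frame_indices, series$fps, series$segments)
}

#' Median filter a distance series
#'
#' Sliding-window median per segment, with the window shrinking at segment
#' edges (the first and last samples keep progressively smaller symmetric
#' windows). Provided for comparison with the low-pass filter.
#'
#' @param series A `"distance_series"`.
#' @param cfg A [filter_config()] with `kind = "median"` and an odd `window`.
#' @return A filtered `"distance_series"` of identical length.
#' @export
median_filter <- function(series, cfg = filter_config("median")) {
  stopifnot(inherits(series, "distance_series"))
  if (cfg$kind != "median") stop("`cfg$kind` must be \"median\"", call. = FALSE)
  if (cfg$window %% 2 == 0) stop("median window must be odd", call. = FALSE)
  h <- (cfg$window - 1L) %/% 2L
  out <- series$values
  if (h > 0) {
    for (k in seq_len(nrow(series$segments))) {
      idx <- series$segments[k, "start"]:series$segments[k, "end"]
      x <- series$values[idx]
      n <- length(x)
      y <- vapply(seq_len(n), function(i) {
        lo <- max(1L, i - h)
        hi <- min(n, i + h)
        stats::median(x[lo:hi])
      }, numeric(1))
      out[idx] <- y
    }
  }
  new_distance_series(out, series$frame_indices, series$fps, series$segments)
}

#' Apply a filter configuration to a distance series
#'
#' Dispatches to [lowpass_filter()], [median_filter()], or the identity for
#' `kind = "none"`.
#'
#' @inheritParams lowpass_filter
#' @param cfg A [filter_config()].
#' @export
apply_filter <- function(series, cfg = filter_config()) {
  switch(cfg$kind,
         lowpass = lowpass_filter(series, cfg),
         median = median_filter(series, cfg),
         none = series)
}
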