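test_that("dynamic threshold is the median, robust to outliers", {
  expect_equal(dynamic_threshold(c(1, 2, 3, 4, 100)), 3)
  expect_equal(dynamic_threshold(c(1, 2, 3, 4)), 2.5)
  expect_equal(dynamic_threshold(7), 7)
  expect_equal(dynamic_threshold(make_series(c(1, 2, 3, 4, 100))), 3)
  expect_error(dynamic_threshold(numeric(0)), "empty")
})

test_that("triangle wave yields one accepted peak per cycle", {
  # 5 cycles of period 30: trough 0, crest 10, median 5; crests 30 apart
  cycle <- c(seq(0, 10, length.out = 16), seq(10, 0, length.out = 16)[-c(1, 16)])
  v <- rep(cycle, 5)
  s <- make_series(v)
  p <- detect_chew_peaks(s, detector_config())
  expect_equal(p$n_chews, 5)
  expect_equal(p$threshold_used, stats::median(v))
  expect_equal(p$peak_frames,
               brute_force_peaks(s$values, s$frame_indices, s$segments,
                                 stats::median(v), p$min_spacing_frames))
})

test_that("constant series has no peaks; endpoints are never peaks", {
  s <- make_series(rep(5, 50))
  expect_equal(detect_chew_peaks(s, detector_config())$n_chews, 0)
  ramp <- make_series(c(1, 2, 3, 4, 5))     # maximum at the boundary
  expect_equal(detect_chew_peaks(ramp,
                                 detector_config(threshold_mode = "fixed",
                                                 fixed_threshold = 0))$n_chews,
               0)
})

test_that("spacing condition is applied greedily left to right", {
  # two strict local maxima above threshold, 10 frames apart
  v <- rep(1, 40)
  v[c(10, 20)] <- c(8, 9)
  s <- make_series(v)
  cfg <- detector_config(min_spacing_frames = 20, threshold_mode = "fixed",
                         fixed_threshold = 2)
  p <- detect_chew_peaks(s, cfg)
  expect_equal(p$peak_frames, 9)            # earlier peak wins (0-based frames)
  expect_equal(p$rejected$too_close, 1)

  # a gap of exactly min_spacing frames is still too close (strict >)
  v2 <- rep(1, 60)
  v2[c(11, 31)] <- 8
  p2 <- detect_chew_peaks(make_series(v2), cfg)
  expect_equal(p2$n_chews, 1)
  v3 <- rep(1, 60)
  v3[c(11, 32)] <- 8
  p3 <- detect_chew_peaks(make_series(v3), cfg)
  expect_equal(p3$n_chews, 2)
})

test_that("local maxima below the threshold are rejected and tallied", {
  v <- c(rep(10, 20), 10, 11, 10, rep(10, 7), 2, 3, 2, rep(10, 10))
  s <- make_series(v)
  p <- detect_chew_peaks(s, detector_config())   # median is 10
  expect_equal(p$n_chews, 1)
  expect_equal(p$rejected$below_threshold, 1)
})

test_that("flat-topped plateaus follow the plateau policy", {
  v <- c(1, 2, 5, 5, 5, 2, 1)
  s <- make_series(v)
  strict <- detect_chew_peaks(s, detector_config(threshold_mode = "fixed",
                                                 fixed_threshold = 2))
  expect_equal(strict$n_chews, 0)
  expect_equal(strict$rejected$not_local_max, 1)
  mid <- detect_chew_peaks(s, detector_config(threshold_mode = "fixed",
                                              fixed_threshold = 2,
                                              plateau_policy = "midpoint"))
  expect_equal(mid$peak_frames, 3)          # center of the run, 0-based
})

test_that("accepted peaks match the brute-force rule on random series", {
  set.seed(101)
  for (rep in 1:120) {
    n <- sample(5:200, 1)
    v <- abs(cumsum(rnorm(n, sd = 2))) + runif(n)
    n_seg <- sample(1:3, 1)
    frames <- if (n_seg == 1) seq_len(n) - 1 else {
      breaks <- sort(sample(seq_len(n - 1), n_seg - 1))
      offs <- cumsum(c(0, rep(100, n_seg - 1)))
      seg_id <- findInterval(seq_len(n) - 1, breaks) + 1
      seq_len(n) - 1 + offs[seg_id]
    }
    s <- make_series(v, frame_indices = frames, max_gap_frames = 0)
    spacing <- sample(0:25, 1)
    cfg <- detector_config(min_spacing_frames = spacing)
    p <- detect_chew_peaks(s, cfg)
    expect_identical(p$peak_frames,
                     brute_force_peaks(s$values, s$frame_indices, s$segments,
                                       p$threshold_used, spacing))
    # spacing soundness, directly on the output
    if (p$n_chews > 1) expect_true(all(diff(p$peak_frames) > spacing))
  }
})

test_that("peak set is invariant under scaling of the distances", {
  set.seed(7)
  t <- (0:599) / 30
  v <- 30 + 10 * sin(2 * pi * 1.2 * t) + rnorm(600, sd = 0.5)
  v <- pmax(v, 0)
  base <- detect_chew_peaks(make_series(v), detector_config())
  for (c0 in c(0.01, 0.5, 3, 250)) {
    scaled <- detect_chew_peaks(make_series(v * c0), detector_config())
    expect_identical(scaled$peak_frames, base$peak_frames)
  }
})

test_that("raising a fixed threshold never increases the peak count", {
  set.seed(8)
  v <- abs(cumsum(rnorm(300))) + 5
  s <- make_series(v)
  counts <- vapply(seq(0, max(v), length.out = 12), function(thr) {
    detect_chew_peaks(s, detector_config(threshold_mode = "fixed",
                                         fixed_threshold = thr))$n_chews
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("default spacing rescales with the frame rate", {
  v <- rep(1, 10)
  expect_equal(detect_chew_peaks(make_series(v, fps = 30),
                                 detector_config())$min_spacing_frames, 20)
  expect_equal(detect_chew_peaks(make_series(v, fps = 60),
                                 detector_config())$min_spacing_frames, 40)
  expect_equal(detect_chew_peaks(make_series(v, fps = 15),
                                 detector_config())$min_spacing_frames, 10)
})

test_that("count_chews composes the pipeline and propagates emptiness", {
  sim <- generate_chew_trajectory(
    chew_signal_config(n_chews = 50, noise_std_px = 0, seed = 5))
  p <- count_chews(sim$trajectory)
  expect_equal(p$n_chews, 50)

  # rest-period wobble stays below the median: rests add no peaks
  simr <- generate_chew_trajectory(
    chew_signal_config(n_chews = 40, noise_std_px = 0,
                       rest_bouts = list(c(20, 4)), seed = 5))
  expect_equal(count_chews(simr$trajectory)$n_chews, 40)

  empty <- trajectory(data.frame(frame = 0:4, nose_x = NA, nose_y = NA,
                                 mouth_x = NA, mouth_y = NA))
  expect_error(count_chews(empty), "no detected frames")
})

test_that("threshold can be computed on the raw series instead", {
  sim <- generate_chew_trajectory(chew_signal_config(n_chews = 30, seed = 9))
  raw <- count_chews(sim$trajectory, threshold_on = "raw")
  filt <- count_chews(sim$trajectory, threshold_on = "filtered")
  expect_equal(raw$threshold_used,
               dynamic_threshold(build_distance_series(sim$trajectory)))
  expect_equal(raw$n_chews, 30)
  expect_equal(filt$n_chews, 30)
})

test_that("detector_config validates its arguments", {
  expect_error(detector_config(threshold_mode = "fixed"), "fixed_threshold")
  expect_error(detector_config(min_spacing_frames = -1), ">= 0")
  expect_error(detector_config(threshold_mode = "rolling_median",
                               rolling_window_s = 0), "positive")
})
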