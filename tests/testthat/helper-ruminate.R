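# Shared fixtures and independent oracles, built in code at test time.

# Build a distance series through the public API: nose at the origin, mouth
# at (0, v) so the nose-mouth distance equals v exactly. Gaps in
# `frame_indices` larger than `max_gap_frames` split the series.
make_series <- function(values, fps = 30,
                        frame_indices = seq_along(values) - 1,
                        max_gap_frames = 0) {
  stopifnot(all(values >= 0))
  tr <- trajectory(data.frame(frame = frame_indices,
                              nose_x = 0, nose_y = 0,
                              mouth_x = 0, mouth_y = values),
                   fps = fps)
  build_distance_series(tr, max_gap_frames = max_gap_frames)
}

# Independent reference for the multi-condition peak rule: a literal
# left-to-right scan checking, at every interior index of every segment,
# strict rise, strict fall, threshold exceedance, and the greedy spacing
# constraint on frame indices. Deliberately naive; kept free of any code
# shared with detect_chew_peaks().
brute_force_peaks <- function(values, frame_indices, segments, threshold,
                              spacing) {
  acc <- integer(0)
  for (k in seq_len(nrow(segments))) {
    s <- segments[k, "start"]
    e <- segments[k, "end"]
    if (e - s + 1 < 3) next
    last <- NA_integer_
    for (i in (s + 1):(e - 1)) {
      if (values[i] - values[i - 1] > 0 &&
          values[i] - values[i + 1] > 0 &&
          values[i] > threshold &&
          (is.na(last) || frame_indices[i] - last > spacing)) {
        acc <- c(acc, frame_indices[i])
        last <- frame_indices[i]
      }
    }
  }
  acc
}

# Random piecewise-smooth trajectory: the mouth oscillates below the nose
# with drifting amplitude, plus jitter on both keypoints. Coordinates are
# quantized to 1/1024 px (sub-pixel detector precision); on that dyadic grid
# translation by another grid value is exact in floating point, so the
# translation-invariance checks can demand bit identity.
random_trajectory <- function(n_frames = 300, fps = 30) {
  q <- function(x) round(x * 1024) / 1024
  t <- (seq_len(n_frames) - 1) / fps
  dist <- 40 + 12 * sin(2 * pi * 1.2 * t) * (1 + 0.2 * sin(2 * pi * 0.07 * t)) +
    rnorm(n_frames, sd = 0.8)
  nose_x <- 150 + rnorm(n_frames, sd = 0.5)
  nose_y <- 80 + rnorm(n_frames, sd = 0.5)
  trajectory(data.frame(frame = seq_len(n_frames) - 1,
                        nose_x = q(nose_x), nose_y = q(nose_y),
                        mouth_x = q(nose_x + rnorm(n_frames, sd = 0.5)),
                        mouth_y = q(nose_y + dist)),
             fps = fps)
}

dyadic <- function(x) round(x * 1024) / 1024

pop_sd_ref <- function(x) sqrt(sum((x - mean(x))^2) / length(x))

# Minimal COCO-style keypoint JSON writer for evaluation fixtures.
write_coco_json <- function(path, annotations) {
  jsonlite::write_json(
    list(images = lapply(unique(vapply(annotations, `[[`, numeric(1),
                                       "image_id")),
                         function(i) list(id = i)),
         annotations = annotations),
    path, auto_unbox = TRUE, digits = NA)
  path
}

coco_ann <- function(image_id, xy, vis = rep(2, nrow(xy)),
                     bbox = c(0, 0, 50, 50)) {
  list(image_id = image_id,
       keypoints = as.vector(t(cbind(xy, vis))),
       bbox = bbox)
}
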