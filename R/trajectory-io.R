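#' Construct a keypoint trajectory
#'
#' A trajectory holds the per-frame output of a facial keypoint detector for
#' one animal: the nose and mouth pixel coordinates, optional detector
#' confidences, and timing metadata. Frames where either keypoint is missing
#' are kept but flagged `detected = FALSE`; downstream code decides whether to
#' interpolate across or split at such gaps.
#'
#' Coordinates are image pixels with the origin at the top-left corner, x
#' increasing rightward and y downward; frame indices are 0-based. `time_s` is
#' derived as `frame / fps` unless the input supplies an explicit time column,
#' which then wins (dropped frames in a nominally fixed-rate video are thereby
#' representable).
#'
#' @param frames A data frame with columns `frame`, `nose_x`, `nose_y`,
#'   `mouth_x`, `mouth_y`; optionally `time_s`, `nose_conf`, `mouth_conf`.
#' @param fps Frames per second of the source video (default 30).
#' @param source_id Free-text label for the source recording.
#' @return An object of class `"trajectory"`: a list with elements `frames`
#'   (the validated, frame-sorted data frame with a logical `detected`
#'   column), `fps`, and `source_id`.
#' @examples
#' tr <- trajectory(data.frame(
#'   frame = 0:2, nose_x = 100, nose_y = 100,
#'   mouth_x = 100, mouth_y = c(130, 145, 130)))
#' tr$frames$detected
#' @export
trajectory <- function(frames, fps = 30, source_id = NA_character_) {
  if (!is.data.frame(frames)) {
    stop("`frames` must be a data frame", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1 || is.na(fps) || fps <= 0) {
    stop("`fps` must be a single positive number", call. = FALSE)
  }
  required <- c("frame", "nose_x", "nose_y", "mouth_x", "mouth_y")
  missing_cols <- setdiff(required, names(frames))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(frames) > 0) {
    if (anyNA(frames$frame)) {
      stop("`frame` column contains missing values", call. = FALSE)
    }
    if (any(frames$frame < 0) || any(frames$frame != floor(frames$frame))) {
      stop("`frame` must hold non-negative integers", call. = FALSE)
    }
    if (anyDuplicated(frames$frame)) {
      dup <- frames$frame[duplicated(frames$frame)][1]
      stop("duplicate frame_index ", dup, call. = FALSE)
    }
  }
  frames <- frames[order(frames$frame), , drop = FALSE]
  rownames(frames) <- NULL

  for (cc in c("nose_conf", "mouth_conf")) {
    if (is.null(frames[[cc]])) frames[[cc]] <- rep(1, nrow(frames))
    frames[[cc]][is.na(frames[[cc]])] <- 1
    if (nrow(frames) > 0 && any(frames[[cc]] < 0 | frames[[cc]] > 1)) {
      stop("`", cc, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (is.null(frames[["time_s"]])) {
    frames$time_s <- frames$frame / fps
  } else {
    # explicit time column wins; fill any holes from fps
    miss <- is.na(frames$time_s)
    frames$time_s[miss] <- frames$frame[miss] / fps
  }
  frames$detected <- !(is.na(frames$nose_x) | is.na(frames$nose_y) |
                         is.na(frames$mouth_x) | is.na(frames$mouth_y))
  col_order <- c("frame", "time_s", "nose_x", "nose_y", "nose_conf",
                 "mouth_x", "mouth_y", "mouth_conf", "detected")
  frames <- frames[, col_order]
  structure(list(frames = frames, fps = fps, source_id = source_id),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$frames)
  nd <- sum(x$frames$detected)
  cat(sprintf("<trajectory> %d frames (%d detected) @ %g fps", n, nd, x$fps))
  if (!is.na(x$source_id)) cat(" [", x$source_id, "]", sep = "")
  cat("\n")
  invisible(x)
}

# Parse one CSV column to numeric, reporting the first offending data row.
parse_numeric_column <- function(x, col) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop(sprintf("column '%s': cannot parse value '%s' at data row %d",
                 col, x[bad[1]], bad[1]), call. = FALSE)
  }
  out
}

#' Read a keypoint trajectory from CSV
#'
#' The expected dialect is comma-separated UTF-8 with a header row and "."
#' decimals: columns `frame`, `nose_x`, `nose_y`, `mouth_x`, `mouth_y`, and
#' optionally `time_s`, `nose_conf`, `mouth_conf`. Empty cells denote missing
#' detections; a row with any missing keypoint coordinate becomes
#' `detected = FALSE`. Missing confidences default to 1. Rows are returned
#' sorted by frame index; duplicate frame indices are an error.
#'
#' @param path Path to the CSV file.
#' @param fps_override Frames per second; overrides the default of 30. The
#'   file itself carries no rate metadata.
#' @param source_id Optional label; defaults to the file name.
#' @return A [trajectory()] object.
#' @export
read_trajectory <- function(path, fps_override = NULL, source_id = NULL) {
  if (!file.exists(path)) {
    stop("trajectory file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, fileEncoding = "UTF-8")
  required <- c("frame", "nose_x", "nose_y", "mouth_x", "mouth_y")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("trajectory CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- intersect(
    c("frame", "time_s", "nose_x", "nose_y", "nose_conf",
      "mouth_x", "mouth_y", "mouth_conf"), names(raw))
  parsed <- as.data.frame(
    lapply(stats::setNames(numeric_cols, numeric_cols),
           function(cc) parse_numeric_column(raw[[cc]], cc)),
    optional = TRUE)
  if (nrow(raw) == 0) {
    parsed <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(numeric_cols)), numeric_cols))
  }
  trajectory(parsed,
             fps = if (is.null(fps_override)) 30 else fps_override,
             source_id = if (is.null(source_id)) basename(path) else source_id)
}

#' Write a keypoint trajectory to CSV
#'
#' Inverse of [read_trajectory()]: missing coordinates are written as empty
#' cells, so `read_trajectory(write_trajectory(tr, f))` reproduces `tr`
#' field-for-field (coordinates are serialized with up to 15 significant
#' digits). An empty trajectory yields a header-only file.
#'
#' @param traj A [trajectory()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  out <- traj$frames[, c("frame", "time_s", "nose_x", "nose_y", "nose_conf",
                         "mouth_x", "mouth_y", "mouth_conf")]
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8", quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write trajectory to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Read a manual chew-count table
#'
#' Reads the per-video validation table used for chew-count evaluation:
#' columns `video_id`, `duration_s`, `assessed` (the method's count) and
#' `measured` (the manual observer's count).
#'
#' @param path Path to the CSV file.
#' @return A data frame with the four columns above.
#' @export
read_manual_counts <- function(path) {
  if (!file.exists(path)) {
    stop("count file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  required <- c("assessed", "measured")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("count CSV lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    video_id = if (is.null(raw$video_id)) as.character(seq_len(nrow(raw)))
               else raw$video_id,
    duration_s = if (is.null(raw$duration_s)) rep(NA_real_, nrow(raw))
                 else parse_numeric_column(raw$duration_s, "duration_s"),
    assessed = parse_numeric_column(raw$assessed, "assessed"),
    measured = parse_numeric_column(raw$measured, "measured"),
    stringsAsFactors = FALSE)
  if (nrow(out) == 0) stop("count CSV has no data rows", call. = FALSE)
  out
}
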