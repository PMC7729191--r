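# Reading, validating and writing landmark time series and rating tables.

#' Construct a clip track
#'
#' A clip track is the atom of the pipeline: an ordered sequence of landmark
#' configurations (frames) for one video clip, stored as a `T x N x 2` array,
#' plus clip/actor/emotion metadata and optional per-frame tracker confidence.
#'
#' @param coords numeric array of dimension `T x N x 2` (frames x landmarks x
#'   x/y). All values must be finite.
#' @param clip_id character scalar identifying the clip.
#' @param actor_id character scalar identifying the actor (optional).
#' @param emotion character scalar emotion category (optional).
#' @param frame_index integer vector of original frame indices (optional;
#'   defaults to `0:(T-1)`). Stored as metadata; internally frames are always
#'   0-based and ordered.
#' @param confidence optional numeric vector in `[0, 1]`, one value per frame.
#' @return an object of class `clip_track`.
#' @export
clip_track <- function(coords, clip_id, actor_id = NA_character_,
                       emotion = NA_character_, frame_index = NULL,
                       confidence = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 2L) {
    stop_facekin("coords must be a T x N x 2 array")
  }
  if (!all(is.finite(coords))) stop_facekin("clip '%s': non-finite coordinates", clip_id)
  n_frames <- dim(coords)[1]
  if (n_frames < 1L) stop_facekin("clip '%s': needs at least one frame", clip_id)
  if (is.null(frame_index)) frame_index <- seq_len(n_frames) - 1L
  stopifnot(length(frame_index) == n_frames)
  if (!is.null(confidence)) {
    stopifnot(length(confidence) == n_frames, all(confidence >= 0 & confidence <= 1))
  }
  structure(
    list(coords = coords, clip_id = as.character(clip_id),
         actor_id = as.character(actor_id), emotion = as.character(emotion),
         frame_index = as.integer(round(frame_index)), confidence = confidence),
    class = "clip_track"
  )
}

#' @export
print.clip_track <- function(x, ...) {
  cat(sprintf("<clip_track '%s'> %d frames, %d landmarks (actor %s, emotion %s)\n",
              x$clip_id, n_frames(x), n_landmarks(x), x$actor_id, x$emotion))
  invisible(x)
}

#' Number of frames / landmarks in a clip track
#' @param track a [clip_track()].
#' @return integer scalar.
#' @export
n_frames <- function(track) dim(track$coords)[1]

#' @rdname n_frames
#' @export
n_landmarks <- function(track) dim(track$coords)[2]

#' Extract one frame of a track as an N x 2 landmark matrix
#' @param track a [clip_track()].
#' @param f 1-based frame position.
#' @return `N x 2` numeric matrix.
#' @export
track_frame <- function(track, f) {
  track$coords[f, , , drop = TRUE]
}

#' IO configuration for landmark tables
#'
#' @param confidence_threshold frames with tracker confidence strictly below
#'   this value are flagged (default 0: keep and flag nothing). Flagged frames
#'   are never dropped on read; dropping is a pipeline decision.
#' @param drop_low_confidence if `TRUE`, pipeline stages remove flagged frames.
#' @return a list of class `io_config`.
#' @export
io_config <- function(confidence_threshold = 0, drop_low_confidence = FALSE) {
  stopifnot(confidence_threshold >= 0, confidence_threshold <= 1)
  structure(list(confidence_threshold = confidence_threshold,
                 drop_low_confidence = drop_low_confidence),
            class = "io_config")
}

#' Read an OpenFace-style landmark CSV
#'
#' Expects a header with a `frame` column and coordinate columns
#' `x_0..x_{N-1}`, `y_0..y_{N-1}` (leading/trailing whitespace in header names
#' is tolerated, as OpenFace versions differ). Optional `timestamp`,
#' `confidence` and `success` columns are captured when present. N is inferred
#' from the header. Frames are reordered by frame index; original indices are
#' kept as metadata.
#'
#' @param path path to the CSV file.
#' @param clip_id clip identifier; defaults to the file name without extension.
#' @param actor_id,emotion optional metadata.
#' @param config an [io_config()].
#' @return a [clip_track()]; attribute `"flagged_frames"` holds 1-based
#'   positions of frames whose confidence fell below the configured threshold.
#' @export
read_openface_csv <- function(path, clip_id = NULL, actor_id = NA_character_,
                              emotion = NA_character_, config = io_config()) {
  if (!file.exists(path)) stop_facekin("file not found: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  names(raw) <- trimws(names(raw))
  if (!"frame" %in% names(raw)) stop_facekin("%s: missing required column 'frame'", path)

  xcols <- grep("^x_[0-9]+$", names(raw), value = TRUE)
  n <- length(xcols)
  if (n == 0L) stop_facekin("%s: no landmark coordinate columns (x_0 ...)", path)
  wanted_x <- paste0("x_", seq_len(n) - 1L)
  wanted_y <- paste0("y_", seq_len(n) - 1L)
  missing <- setdiff(c(wanted_x, wanted_y), names(raw))
  if (length(missing) > 0L) {
    stop_facekin("%s: missing coordinate column '%s'", path, missing[1])
  }

  to_num <- function(col, label) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      stop_facekin("%s: non-numeric value in column '%s' at data row %d",
                   path, label, bad[1])
    }
    v
  }

  frame_idx <- to_num("frame", "frame")
  t_len <- nrow(raw)
  coords <- array(NA_real_, dim = c(t_len, n, 2))
  for (p in seq_len(n)) {
    coords[, p, 1] <- to_num(wanted_x[p], wanted_x[p])
    coords[, p, 2] <- to_num(wanted_y[p], wanted_y[p])
  }
  confidence <- if ("confidence" %in% names(raw)) to_num("confidence", "confidence") else NULL

  ord <- order(frame_idx)
  coords <- coords[ord, , , drop = FALSE]
  frame_idx <- frame_idx[ord]
  if (!is.null(confidence)) confidence <- confidence[ord]

  if (is.null(clip_id)) clip_id <- sub("\\.[^.]*$", "", basename(path))
  track <- clip_track(coords, clip_id = clip_id, actor_id = actor_id,
                      emotion = emotion, frame_index = frame_idx,
                      confidence = confidence)
  flagged <- integer(0)
  if (!is.null(confidence) && config$confidence_threshold > 0) {
    flagged <- which(confidence < config$confidence_threshold)
  }
  attr(track, "flagged_frames") <- flagged
  track
}

#' Write a clip track as an OpenFace-style CSV
#'
#' Inverse of [read_openface_csv()]: writing then reading reproduces the track
#' up to floating-point formatting precision (about 1e-15 relative).
#'
#' @param track a [clip_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_openface_csv <- function(track, path) {
  n <- n_landmarks(track)
  df <- data.frame(frame = track$frame_index)
  if (!is.null(track$confidence)) df$confidence <- track$confidence
  for (p in seq_len(n)) df[[paste0("x_", p - 1L)]] <- track$coords[, p, 1]
  for (p in seq_len(n)) df[[paste0("y_", p - 1L)]] <- track$coords[, p, 2]
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a ratings table
#'
#' Expects columns `rater_id, group, clip_id, arousal, valence`. Arousal and
#' valence are visual-analog-scale integers in `[1, 101]`; any out-of-range
#' value is a validation error listing the offending rows. Group labels are
#' normalized to upper case (`NT`, `ASD`, `HAT`, ...).
#'
#' @param path path to the ratings CSV.
#' @return a data.frame with one validated record per (rater, clip).
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop_facekin("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- trimws(names(df))
  needed <- c("rater_id", "group", "clip_id", "arousal", "valence")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) stop_facekin("%s: missing column '%s'", path, missing[1])
  df <- df[needed]
  validate_ratings(df)
}

#' Validate an in-memory ratings table
#' @param df data.frame with columns `rater_id, group, clip_id, arousal, valence`.
#' @return the validated data.frame, group labels upper-cased.
#' @export
validate_ratings <- function(df) {
  for (col in c("arousal", "valence")) {
    v <- df[[col]]
    if (!is.numeric(v)) stop_facekin("column '%s' must be numeric", col)
    bad <- which(!is.finite(v) | v < 1 | v > 101)
    if (length(bad) > 0L) {
      stop_facekin("%s out of range [1, 101] at row(s): %s", col,
                   paste(utils::head(bad, 10L), collapse = ", "))
    }
  }
  df$group <- toupper(trimws(as.character(df$group)))
  df$rater_id <- as.character(df$rater_id)
  df$clip_id <- as.character(df$clip_id)
  dup <- duplicated(df[c("rater_id", "clip_id")])
  if (any(dup)) {
    stop_facekin("duplicate (rater, clip) record(s) at row(s): %s",
                 paste(utils::head(which(dup), 10L), collapse = ", "))
  }
  df
}

#' Read a clip metadata table
#' @param path CSV with columns `clip_id, actor_id, emotion_category`.
#' @return data.frame.
#' @export
read_clip_metadata <- function(path) {
  if (!file.exists(path)) stop_facekin("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- trimws(names(df))
  needed <- c("clip_id", "actor_id", "emotion_category")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) stop_facekin("%s: missing column '%s'", path, missing[1])
  df[needed]
}

#' Canonical names of the eight kinematic measures
#'
#' `{dist_neutral, dist_mean, speed, accel}` aggregated by `{mean, max}`, in
#' the fixed column order used by all feature tables.
#' @return character vector of length 8.
#' @export
measure_names <- function() {
  c("dist_neutral_mean", "dist_neutral_max",
    "dist_mean_mean", "dist_mean_max",
    "speed_mean", "speed_max",
    "accel_mean", "accel_max")
}

#' Write a per-clip feature table
#'
#' One row per clip: `clip_id` plus the eight measures in canonical order.
#' Values round-trip through [read_feature_table()] to better than 1e-12.
#'
#' @param features data.frame with `clip_id` and the [measure_names()] columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  if (is.null(features) || nrow(features) == 0L) {
    stop_facekin("feature table is empty")
  }
  missing <- setdiff(c("clip_id", measure_names()), names(features))
  if (length(missing) > 0L) stop_facekin("feature table missing column '%s'", missing[1])
  if (anyDuplicated(features$clip_id)) {
    stop_facekin("duplicate clip_id in feature table: %s",
                 features$clip_id[duplicated(features$clip_id)][1])
  }
  out <- features[c("clip_id", measure_names())]
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_facekin("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(c("clip_id", measure_names()), names(df))
  if (length(missing) > 0L) stop_facekin("%s: missing column '%s'", path, missing[1])
  df$clip_id <- as.character(df$clip_id)
  for (m in measure_names()) df[[m]] <- as.numeric(df[[m]])
  df
}
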