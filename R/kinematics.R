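# Baseline faces and the frame-wise distance / speed / acceleration series,
# aggregated into the eight per-clip measures.
#
# All of these assume normalized (Procrustes-aligned) tracks; coordinates are
# dimensionless and time is measured in frames.

#' Euclidean distance between two landmark positions
#' @param p_a,p_b numeric length-2 vectors `(x, y)`.
#' @return non-negative scalar.
#' @export
point_distance <- function(p_a, p_b) {
  stopifnot(length(p_a) == 2L, length(p_b) == 2L,
            all(is.finite(p_a)), all(is.finite(p_b)))
  sqrt(sum((p_b - p_a)^2))
}

#' Root-mean-square deviation between two landmark configurations
#'
#' `sqrt(mean_p d(p_a, p_b)^2)`: the per-landmark Euclidean displacements are
#' squared before averaging, so motions of different landmarks in opposite
#' directions accumulate rather than cancel. This is the distance measure
#' underlying all kinematic series.
#'
#' @param shape_a,shape_b `N x 2` matrices with equal `N`.
#' @return non-negative scalar; 0 iff the shapes are identical.
#' @export
rmsd <- function(shape_a, shape_b) {
  shape_a <- as.matrix(shape_a); shape_b <- as.matrix(shape_b)
  if (nrow(shape_a) != nrow(shape_b)) {
    stop_facekin("landmark count mismatch: %d vs %d", nrow(shape_a), nrow(shape_b))
  }
  sqrt(mean(rowSums((shape_a - shape_b)^2)))
}

#' Baseline faces
#'
#' `clip_neutral_face()` takes the first frame of a (normalized) clip as that
#' clip's neutral baseline. `actor_mean_face()` averages every coordinate of
#' every landmark over all frames of all supplied clips of one actor; clips
#' contribute in proportion to their frame counts.
#'
#' @param track a normalized [clip_track()].
#' @return a list of class `baseline_face` with fields `shape` (`N x 2`),
#'   `kind` (`"clip_neutral"` or `"actor_mean"`) and `provenance`.
#' @export
clip_neutral_face <- function(track) {
  if (n_frames(track) < 1L) stop_facekin("empty track")
  structure(list(shape = track_frame(track, 1L), kind = "clip_neutral",
                 provenance = track$clip_id),
            class = "baseline_face")
}

#' @rdname clip_neutral_face
#' @param tracks list of normalized [clip_track()]s, all from the same actor.
#' @export
actor_mean_face <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  actors <- unique(vapply(tracks, function(t) t$actor_id, character(1)))
  if (length(actors) > 1L) {
    stop_facekin("actor_mean_face: mixed actors (%s)", paste(actors, collapse = ", "))
  }
  n <- n_landmarks(tracks[[1]])
  acc <- matrix(0, n, 2)
  total <- 0L
  for (tr in tracks) {
    if (n_landmarks(tr) != n) stop_facekin("clip '%s': landmark count differs", tr$clip_id)
    acc <- acc + cbind(colSums(tr$coords[, , 1, drop = FALSE]),
                       colSums(tr$coords[, , 2, drop = FALSE]))
    total <- total + n_frames(tr)
  }
  structure(list(shape = acc / total, kind = "actor_mean", provenance = actors),
            class = "baseline_face")
}

# internal constructor for a measure series
measure_series <- function(clip_id, measure, values) {
  structure(list(clip_id = clip_id, measure = measure, values = values),
            class = "measure_series")
}

#' Frame-wise RMSD of a clip to a baseline face
#'
#' @param track normalized [clip_track()] with `T` frames.
#' @param baseline a `baseline_face` (or `N x 2` matrix) with matching `N`.
#' @return a `measure_series` with `T` non-negative values; `values[f]` is the
#'   RMSD of frame `f` to the baseline.
#' @export
distance_series <- function(track, baseline) {
  shape <- if (inherits(baseline, "baseline_face")) baseline$shape else as.matrix(baseline)
  if (nrow(shape) != n_landmarks(track)) {
    stop_facekin("baseline landmark count differs from track")
  }
  t_len <- n_frames(track)
  dx <- track$coords[, , 1] - rep(shape[, 1], each = t_len)
  dy <- track$coords[, , 2] - rep(shape[, 2], each = t_len)
  if (is.null(dim(dx))) { dx <- matrix(dx, nrow = t_len); dy <- matrix(dy, nrow = t_len) }
  kind <- if (inherits(baseline, "baseline_face") && baseline$kind == "actor_mean")
    "dist_mean" else "dist_neutral"
  measure_series(track$clip_id, kind, sqrt(rowMeans(dx^2 + dy^2)))
}

#' Frame-to-frame RMS speed series of a clip
#'
#' The velocity of a landmark over one inter-frame interval is its coordinate
#' difference (time unit = frame), so the RMS speed between consecutive frames
#' is the RMSD of the two frames.
#'
#' @param track normalized [clip_track()] with `T >= 2` frames.
#' @return a `measure_series` with `T - 1` values.
#' @export
speed_series <- function(track) {
  t_len <- n_frames(track)
  if (t_len < 2L) stop_facekin("speed needs at least 2 frames")
  dx <- diff_frames(track$coords[, , 1, drop = FALSE])
  dy <- diff_frames(track$coords[, , 2, drop = FALSE])
  measure_series(track$clip_id, "speed", sqrt(rowMeans(dx^2 + dy^2)))
}

#' RMS acceleration-magnitude series of a clip
#'
#' Per-landmark acceleration over the window `f .. f+2` is the difference of
#' the two inter-frame velocity vectors divided by `accel_denominator` frames
#' (default 2, the length of the window; set 1 to take the raw velocity
#' difference). The series value is the RMS of the per-landmark acceleration
#' magnitudes. Constant-velocity clips give exact zeros.
#'
#' @param track normalized [clip_track()] with `T >= 3` frames.
#' @param accel_denominator 2 (default) or 1.
#' @return a `measure_series` with `T - 2` values.
#' @export
acceleration_series <- function(track, accel_denominator = 2) {
  t_len <- n_frames(track)
  if (t_len < 3L) stop_facekin("acceleration needs at least 3 frames")
  stopifnot(accel_denominator %in% c(1, 2))
  vx <- diff_frames(track$coords[, , 1, drop = FALSE])
  vy <- diff_frames(track$coords[, , 2, drop = FALSE])
  ax <- diff_mat(vx) / accel_denominator
  ay <- diff_mat(vy) / accel_denominator
  measure_series(track$clip_id, "accel", sqrt(rowMeans(ax^2 + ay^2)))
}

# first difference along the frame dimension of a T x N (x 1) array/matrix
diff_frames <- function(arr) {
  m <- arr[, , 1]
  if (is.null(dim(m))) m <- matrix(m, nrow = dim(arr)[1])
  diff_mat(m)
}

diff_mat <- function(m) {
  m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
}

#' Aggregate a measure series to a scalar
#' @param series a `measure_series` (or bare numeric vector), non-empty.
#' @param how `"mean"` or `"max"`; each series is aggregated over its own
#'   support (lengths `T`, `T-1`, `T-2` for distance, speed, acceleration).
#' @return scalar.
#' @export
aggregate_series <- function(series, how = c("mean", "max")) {
  how <- match.arg(how)
  values <- if (inherits(series, "measure_series")) series$values else series
  if (length(values) == 0L) stop_facekin("cannot aggregate an empty series")
  if (how == "mean") mean(values) else max(values)
}

#' The eight kinematic measures of one clip
#'
#' `{mean, max}` of the distance-to-clip-neutral, distance-to-actor-mean,
#' speed and acceleration-magnitude series.
#'
#' @param track normalized [clip_track()] with `T >= 3` frames.
#' @param clip_neutral baseline from [clip_neutral_face()].
#' @param actor_mean baseline from [actor_mean_face()].
#' @param accel_denominator see [acceleration_series()].
#' @return one-row data.frame: `clip_id` plus the [measure_names()] columns.
#' @export
compute_clip_features <- function(track, clip_neutral, actor_mean,
                                  accel_denominator = 2) {
  dn <- distance_series(track, clip_neutral)
  dm <- distance_series(track, actor_mean)
  sp <- speed_series(track)
  ac <- acceleration_series(track, accel_denominator)
  out <- data.frame(
    clip_id = track$clip_id,
    dist_neutral_mean = aggregate_series(dn, "mean"),
    dist_neutral_max = aggregate_series(dn, "max"),
    dist_mean_mean = aggregate_series(dm, "mean"),
    dist_mean_max = aggregate_series(dm, "max"),
    speed_mean = aggregate_series(sp, "mean"),
    speed_max = aggregate_series(sp, "max"),
    accel_mean = aggregate_series(ac, "mean"),
    accel_max = aggregate_series(ac, "max"),
    stringsAsFactors = FALSE
  )
  out
}

#' Feature table for a whole normalized study
#'
#' Computes clip-neutral and per-actor mean baselines from the aligned tracks
#' and assembles the eight measures for every clip.
#'
#' @param aligned an `aligned_study` from [normalize_study()], or a plain list
#'   of normalized [clip_track()]s.
#' @param accel_denominator see [acceleration_series()].
#' @return data.frame, one row per clip, columns `clip_id` + [measure_names()].
#' @export
compute_feature_table <- function(aligned, accel_denominator = 2) {
  tracks <- if (inherits(aligned, "aligned_study")) aligned$tracks else aligned
  stopifnot(length(tracks) >= 1L)
  actor_of <- vapply(tracks, function(t) t$actor_id, character(1))
  # clips without an actor id are treated as single-clip actors
  missing_actor <- is.na(actor_of) | actor_of == "NA" | actor_of == ""
  actor_of[missing_actor] <- paste0("clip:", vapply(tracks[missing_actor],
                                                    function(t) t$clip_id, character(1)))
  mean_faces <- lapply(split(tracks, actor_of), function(grp) {
    # groups are homogeneous by construction here; pool frames directly
    n <- n_landmarks(grp[[1]])
    acc <- matrix(0, n, 2); total <- 0L
    for (tr in grp) {
      acc <- acc + cbind(colSums(tr$coords[, , 1, drop = FALSE]),
                         colSums(tr$coords[, , 2, drop = FALSE]))
      total <- total + n_frames(tr)
    }
    structure(list(shape = acc / total, kind = "actor_mean",
                   provenance = grp[[1]]$actor_id),
              class = "baseline_face")
  })
  rows <- lapply(seq_along(tracks), function(i) {
    compute_clip_features(tracks[[i]], clip_neutral_face(tracks[[i]]),
                          mean_faces[[actor_of[i]]],
                          accel_denominator = accel_denominator)
  })
  do.call(rbind, rows)
}
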