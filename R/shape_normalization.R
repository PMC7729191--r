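# Generalized Procrustes superimposition of landmark configurations.
#
# All shapes are N x 2 matrices. A study's frames are pooled into one
# superimposition so that baselines taken from different clips live in the
# same coordinate frame.

#' Normalization configuration
#'
#' @param include_rotation remove rotation as well as translation and scale
#'   (default `TRUE`).
#' @param allow_reflection permit improper (determinant -1) alignments
#'   (default `FALSE`; faces have handedness).
#' @param tolerance relative change in the consensus below which iteration
#'   stops (default `1e-8`).
#' @param max_iterations iteration cap (default 100). Non-convergence is
#'   recorded as a warning flag on the result, not an error.
#' @return a list of class `normalization_config`.
#' @export
normalization_config <- function(include_rotation = TRUE,
                                 allow_reflection = FALSE,
                                 tolerance = 1e-8,
                                 max_iterations = 100L) {
  stopifnot(tolerance > 0, max_iterations >= 1L)
  structure(list(include_rotation = include_rotation,
                 allow_reflection = allow_reflection,
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "normalization_config")
}

#' Center a landmark configuration and scale it to unit centroid size
#'
#' Translates the centroid to the origin and divides by centroid size (the
#' root summed squared distance of landmarks from the centroid), removing
#' position-on-frame and face-size differences.
#'
#' @param shape `N x 2` numeric matrix, `N >= 2`, not all points identical.
#' @return `N x 2` matrix with centroid exactly 0 and centroid size exactly 1.
#' @export
center_scale <- function(shape) {
  shape <- as.matrix(shape)
  stopifnot(ncol(shape) == 2L, nrow(shape) >= 2L, all(is.finite(shape)))
  centered <- sweep(shape, 2, colMeans(shape))
  size <- sqrt(sum(centered^2))
  if (size == 0) stop_facekin("degenerate shape: all landmarks identical")
  centered / size
}

#' Centroid size of a configuration
#' @param shape `N x 2` matrix.
#' @return root summed squared centered coordinates.
#' @export
centroid_size <- function(shape) {
  centered <- sweep(as.matrix(shape), 2, colMeans(shape))
  sqrt(sum(centered^2))
}

# Optimal 2-D rotation angle taking `shape` onto `reference` in the
# least-squares sense; both are assumed centered. Closed form:
# theta = atan2(sum(x*y' - y*x'), sum(x*x' + y*y')).
rotation_angle <- function(shape, reference) {
  a <- sum(shape * reference)
  b <- sum(shape[, 1] * reference[, 2] - shape[, 2] * reference[, 1])
  atan2(b, a)
}

rotate_shape <- function(shape, theta) {
  ct <- cos(theta); st <- sin(theta)
  cbind(shape[, 1] * ct - shape[, 2] * st,
        shape[, 1] * st + shape[, 2] * ct)
}

#' Rotate a configuration into least-squares alignment with a reference
#'
#' Finds the orthogonal transform (determinant +1 unless `allow_reflection`)
#' minimizing the summed squared distance to the reference. Both shapes should
#' already be centered (and typically unit-size).
#'
#' @param shape,reference `N x 2` matrices with equal `N`.
#' @param allow_reflection if `TRUE`, an improper transform is used whenever
#'   it fits better.
#' @return the aligned `N x 2` matrix.
#' @export
optimal_rotation <- function(shape, reference, allow_reflection = FALSE) {
  shape <- as.matrix(shape); reference <- as.matrix(reference)
  if (nrow(shape) != nrow(reference)) {
    stop_facekin("landmark count mismatch: %d vs %d", nrow(shape), nrow(reference))
  }
  rotated <- rotate_shape(shape, rotation_angle(shape, reference))
  if (allow_reflection) {
    mirrored <- shape %*% diag(c(1, -1))
    refl <- rotate_shape(mirrored, rotation_angle(mirrored, reference))
    if (sum((refl - reference)^2) < sum((rotated - reference)^2)) {
      rotated <- refl
    }
  }
  rotated
}

# Rotate every slice of a T x N x 2 array onto `reference` (vectorized
# closed-form angles). Returns the rotated array.
rotate_all_to <- function(coords, reference) {
  x <- coords[, , 1]; y <- coords[, , 2]
  rx <- rep(reference[, 1], each = nrow(x)); ry <- rep(reference[, 2], each = nrow(x))
  dot <- rowSums(x * rx + y * ry)
  crs <- rowSums(x * ry - y * rx)
  theta <- atan2(crs, dot)
  ct <- cos(theta); st <- sin(theta)
  out <- coords
  out[, , 1] <- x * ct - y * st
  out[, , 2] <- x * st + y * ct
  out
}

#' Generalized Procrustes Analysis of a set of configurations
#'
#' Iteratively centers and scales every configuration to unit centroid size,
#' rotates each onto the current consensus, and re-estimates the consensus as
#' the per-coordinate mean, until the consensus changes by less than
#' `config$tolerance` (relative) or `config$max_iterations` is reached. The
#' final consensus is canonicalized by aligning its principal axis with +x so
#' that repeated runs and permuted inputs give identical output frames.
#'
#' @param shapes a `T x N x 2` array or a list of `N x 2` matrices, `T >= 2`.
#' @param config a [normalization_config()].
#' @return a list of class `aligned_set`: `coords` (`T x N x 2` aligned
#'   array), `consensus` (`N x 2`), `iterations`, `converged`,
#'   `residual_trace` (total Procrustes residual after each iteration) and
#'   `residual` (final value).
#' @export
gpa <- function(shapes, config = normalization_config()) {
  if (is.list(shapes)) {
    t_len <- length(shapes)
    stopifnot(t_len >= 2L)
    n <- nrow(shapes[[1]])
    coords <- array(NA_real_, c(t_len, n, 2))
    for (i in seq_len(t_len)) {
      m <- as.matrix(shapes[[i]])
      if (nrow(m) != n) stop_facekin("shape %d has %d landmarks, expected %d", i, nrow(m), n)
      coords[i, , ] <- m
    }
  } else {
    coords <- shapes
    stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 2L, dim(coords)[1] >= 2L)
  }
  t_len <- dim(coords)[1]

  # center and scale every configuration
  for (k in 1:2) {
    mu <- rowMeans(coords[, , k, drop = FALSE], dims = 1)
    coords[, , k] <- coords[, , k] - mu
  }
  sizes <- sqrt(rowSums(coords[, , 1]^2) + rowSums(coords[, , 2]^2))
  if (any(sizes == 0)) stop_facekin("degenerate configuration (zero centroid size)")
  coords[, , 1] <- coords[, , 1] / sizes
  coords[, , 2] <- coords[, , 2] / sizes

  consensus <- coords[1, , ]
  residual_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    if (config$include_rotation) {
      coords <- rotate_all_to(coords, consensus)
      if (config$allow_reflection) {
        # try the mirrored version of each configuration as well
        mirrored <- coords
        mirrored[, , 2] <- -mirrored[, , 2]
        mirrored <- rotate_all_to(mirrored, consensus)
        res_o <- rowSums((coords[, , 1] - rep(consensus[, 1], each = t_len))^2 +
                         (coords[, , 2] - rep(consensus[, 2], each = t_len))^2)
        res_m <- rowSums((mirrored[, , 1] - rep(consensus[, 1], each = t_len))^2 +
                         (mirrored[, , 2] - rep(consensus[, 2], each = t_len))^2)
        take <- res_m < res_o
        if (any(take)) {
          coords[take, , ] <- mirrored[take, , ]
        }
      }
    }
    new_consensus <- cbind(colMeans(coords[, , 1]), colMeans(coords[, , 2]))
    new_consensus <- center_scale(new_consensus)
    resid <- sum((coords[, , 1] - rep(new_consensus[, 1], each = t_len))^2 +
                 (coords[, , 2] - rep(new_consensus[, 2], each = t_len))^2)
    residual_trace <- c(residual_trace, resid)
    if (config$include_rotation) {
      # fix the rotational gauge: align the updated consensus with the
      # previous one, so that a pure rotation of the whole constellation does
      # not masquerade as a consensus change (the per-shape rotations in the
      # next sweep absorb the gauge, leaving the residual unchanged)
      new_consensus <- optimal_rotation(new_consensus, consensus,
                                        config$allow_reflection)
    }
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < config$tolerance) {
      converged <- TRUE
      break
    }
    if (!config$include_rotation) {
      # without rotation a single consensus update is exact
      converged <- TRUE
      break
    }
  }

  # canonical orientation: principal axis of the consensus along +x
  if (config$include_rotation) {
    rot <- principal_axis_rotation(consensus)
    consensus <- consensus %*% rot
    x <- coords[, , 1]; y <- coords[, , 2]
    coords[, , 1] <- x * rot[1, 1] + y * rot[2, 1]
    coords[, , 2] <- x * rot[1, 2] + y * rot[2, 2]
  }

  structure(
    list(coords = coords, consensus = consensus, iterations = iter,
         converged = converged, residual_trace = residual_trace,
         residual = residual_trace[length(residual_trace)]),
    class = "aligned_set"
  )
}

# Deterministic 2x2 rotation (det +1) taking the principal axis of a centered
# shape onto +x. The 180-degree ambiguity (both the axis sign and a half-turn
# are rotations) is resolved by the sign of the third moment along the new
# axes, which is rotation-equivariant and generically nonzero.
principal_axis_rotation <- function(shape) {
  cv <- crossprod(shape)  # 2 x 2
  ev <- eigen(cv, symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  v2 <- c(-v1[2], v1[1])  # v1 rotated by 90 degrees -> det(+1) basis
  rot <- cbind(v1, v2)
  proj <- shape %*% rot
  skew <- sum(proj[, 1]^3)
  if (abs(skew) < 1e-12) skew <- sum(proj[, 2]^3)
  if (skew < 0) rot <- -rot  # half-turn, still det +1
  dimnames(rot) <- NULL
  rot
}

#' Normalize every frame of every clip of a study into one common frame
#'
#' Pools all frames of all supplied clip tracks into a single Generalized
#' Procrustes superimposition (one study, one frame of reference), then splits
#' the aligned frames back into their clips. After this, coordinates are
#' dimensionless and baselines from different clips are directly comparable.
#'
#' @param tracks list of [clip_track()] objects sharing a landmark count.
#' @param config a [normalization_config()].
#' @return a list of class `aligned_study`: `tracks` (aligned clip tracks),
#'   `consensus`, `iterations`, `converged`, `residual`.
#' @export
normalize_study <- function(tracks, config = normalization_config()) {
  stopifnot(length(tracks) >= 1L)
  n <- n_landmarks(tracks[[1]])
  lens <- vapply(tracks, n_frames, integer(1))
  for (tr in tracks) {
    if (n_landmarks(tr) != n) stop_facekin("clip '%s': landmark count differs", tr$clip_id)
  }
  total <- sum(lens)
  pooled <- array(NA_real_, c(total, n, 2))
  offset <- 0L
  for (tr in tracks) {
    pooled[offset + seq_len(n_frames(tr)), , ] <- tr$coords
    offset <- offset + n_frames(tr)
  }
  fit <- gpa(pooled, config)
  if (!fit$converged) {
    warning(sprintf("GPA did not converge in %d iterations (final residual %.3g)",
                    fit$iterations, fit$residual), call. = FALSE)
  }
  out <- tracks
  offset <- 0L
  for (i in seq_along(tracks)) {
    idx <- offset + seq_len(lens[i])
    out[[i]]$coords <- fit$coords[idx, , , drop = FALSE]
    offset <- offset + lens[i]
  }
  structure(list(tracks = out, consensus = fit$consensus,
                 iterations = fit$iterations, converged = fit$converged,
                 residual = fit$residual),
            class = "aligned_study")
}
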