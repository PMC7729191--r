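# Independent brute-force oracles (naive per-point loops, no vectorization)
# and small fixture builders used across the suite.

naive_point_distance <- function(a, b) {
  sqrt((b[1] - a[1])^2 + (b[2] - a[2])^2)
}

naive_rmsd <- function(shape_a, shape_b) {
  n <- nrow(shape_a)
  acc <- 0
  for (p in seq_len(n)) {
    acc <- acc + naive_point_distance(shape_a[p, ], shape_b[p, ])^2
  }
  sqrt(acc / n)
}

naive_distance_series <- function(coords, baseline) {
  vapply(seq_len(dim(coords)[1]), function(f) {
    naive_rmsd(coords[f, , , drop = TRUE], baseline)
  }, numeric(1))
}

naive_speed_series <- function(coords) {
  t_len <- dim(coords)[1]
  vapply(seq_len(t_len - 1L), function(f) {
    naive_rmsd(coords[f, , , drop = TRUE], coords[f + 1L, , , drop = TRUE])
  }, numeric(1))
}

naive_accel_series <- function(coords, denominator = 2) {
  t_len <- dim(coords)[1]
  n <- dim(coords)[2]
  vapply(seq_len(t_len - 2L), function(f) {
    acc <- 0
    for (p in seq_len(n)) {
      v1 <- coords[f + 1L, p, ] - coords[f, p, ]
      v2 <- coords[f + 2L, p, ] - coords[f + 1L, p, ]
      a <- (v2 - v1) / denominator
      acc <- acc + sum(a^2)
    }
    sqrt(acc / n)
  }, numeric(1))
}

# normal-equations OLS: coefficients of y ~ 1 + X
naive_ols <- function(x, y) {
  xm <- cbind(1, as.matrix(x))
  solve(t(xm) %*% xm, t(xm) %*% y)[, 1]
}

random_shape <- function(n_points = 5L) {
  matrix(stats::rnorm(2 * n_points), ncol = 2)
}

random_track <- function(n_frames = 10L, n_points = 5L, clip_id = "rnd",
                         actor_id = "a1") {
  coords <- array(stats::rnorm(n_frames * n_points * 2), c(n_frames, n_points, 2))
  clip_track(coords, clip_id = clip_id, actor_id = actor_id)
}

# apply a similarity transform (rotation theta, scale s, translation tr)
similarity_transform <- function(shape, theta = 0, s = 1, tr = c(0, 0)) {
  r <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  out <- s * (shape %*% r)
  sweep(out, 2, tr, `+`)
}

# write an OpenFace-style landmark CSV with the given coordinate array
write_openface_fixture <- function(path, coords, frame = NULL,
                                   confidence = NULL, header_space = FALSE,
                                   drop_column = NULL, corrupt_cell = NULL) {
  t_len <- dim(coords)[1]; n <- dim(coords)[2]
  df <- data.frame(frame = frame %||% (seq_len(t_len) - 1L))
  if (!is.null(confidence)) df$confidence <- confidence
  for (p in seq_len(n)) df[[paste0("x_", p - 1L)]] <- coords[, p, 1]
  for (p in seq_len(n)) df[[paste0("y_", p - 1L)]] <- coords[, p, 2]
  if (!is.null(drop_column)) df[[drop_column]] <- NULL
  mat <- rbind(names(df), apply(df, 2, as.character))
  if (!is.null(corrupt_cell)) {
    mat[corrupt_cell[1] + 1L, corrupt_cell[2]] <- "oops"
  }
  if (header_space) mat[1, -1] <- paste0(" ", mat[1, -1])
  writeLines(apply(mat, 1, paste, collapse = ","), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
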