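test_that("point distance and RMSD match hand-computed values", {
  expect_equal(point_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(point_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(point_distance(c(1, 2), c(-4, 7)), point_distance(c(-4, 7), c(1, 2)))

  shp <- matrix(c(0, 1, 0, 1), ncol = 2)
  expect_equal(rmsd(shp, shp), 0)
  # two landmarks, displacements (3,4) and (0,0): sqrt((25 + 0)/2)
  moved <- shp + rbind(c(3, 4), c(0, 0))
  expect_equal(rmsd(shp, moved), sqrt(12.5))
  # uniform translation by (1, 0) gives exactly 1
  expect_equal(rmsd(shp, sweep(shp, 2, c(1, 0), `+`)), 1)
  expect_error(rmsd(shp, matrix(0, 3, 2)), "mismatch")
})

test_that("rmsd behaves as a metric on random shapes", {
  set.seed(31)
  for (i in 1:20) {
    a <- random_shape(6); b <- random_shape(6); c <- random_shape(6)
    expect_equal(rmsd(a, b), rmsd(b, a), tolerance = 1e-14)
    expect_lte(rmsd(a, c), rmsd(a, b) + rmsd(b, c) + 1e-12)
    expect_equal(rmsd(a, a), 0)
  }
})

test_that("baseline faces follow their definitions", {
  set.seed(32)
  tr <- random_track(3, 5, clip_id = "c1", actor_id = "a1")
  expect_equal(clip_neutral_face(tr)$shape, track_frame(tr, 1))

  # actor mean averages each coordinate over all pooled frames
  tr2 <- random_track(4, 5, clip_id = "c2", actor_id = "a1")
  mf <- actor_mean_face(list(tr, tr2))
  manual <- (apply(tr$coords, c(2, 3), sum) + apply(tr2$coords, c(2, 3), sum)) / 7
  expect_equal(mf$shape, manual, tolerance = 1e-14)

  # single 1-frame track: baseline equals that frame
  one <- clip_track(tr$coords[1, , , drop = FALSE], "c3", actor_id = "a1")
  expect_equal(actor_mean_face(list(one))$shape, track_frame(one, 1),
               ignore_attr = TRUE)

  trb <- random_track(3, 5, clip_id = "c4", actor_id = "b9")
  expect_error(actor_mean_face(list(tr, trb)), "mixed actors")
})

test_that("distance, speed and acceleration series have the stated supports and zeros", {
  n <- 6
  const <- clip_track(array(rep(rnorm(n * 2), each = 5), c(5, n, 2)), "const")
  expect_equal(distance_series(const, clip_neutral_face(const))$values, rep(0, 5))
  expect_equal(speed_series(const)$values, rep(0, 4))
  expect_equal(acceleration_series(const)$values, rep(0, 3))

  # whole face translating 2 units per frame: speed exactly 2, accel 0
  base <- matrix(rnorm(n * 2), ncol = 2)
  coords <- array(NA_real_, c(5, n, 2))
  for (f in 1:5) coords[f, , ] <- base + (f - 1) * matrix(c(2, 0), n, 2, byrow = TRUE)
  gliding <- clip_track(coords, "glide")
  expect_equal(speed_series(gliding)$values, rep(2, 4))
  expect_equal(acceleration_series(gliding)$values, rep(0, 3))

  # two landmarks, one moving (3,4) per frame: sqrt(25/2) per interval
  coords2 <- array(0, c(3, 2, 2))
  for (f in 1:3) coords2[f, 1, ] <- (f - 1) * c(3, 4)
  expect_equal(speed_series(clip_track(coords2, "x"))$values, rep(sqrt(12.5), 2))

  expect_error(speed_series(clip_track(coords2[1, , , drop = FALSE], "s")), "2 frames")
  expect_error(acceleration_series(clip_track(coords2[1:2, , , drop = FALSE], "s")),
               "3 frames")
})

test_that("acceleration divides the velocity difference by the window length", {
  # one landmark: velocities (0,0) then (2,0) -> |(2,0) - (0,0)| / 2 = 1
  coords <- array(0, c(3, 1, 2))
  coords[3, 1, 1] <- 2
  tr <- clip_track(coords, "a")
  expect_equal(acceleration_series(tr)$values, 1)
  expect_equal(acceleration_series(tr, accel_denominator = 1)$values, 2)
})

test_that("series match brute-force per-point oracles to 1e-12", {
  set.seed(33)
  for (i in 1:10) {
    tr <- random_track(10, 5)
    baseline <- random_shape(5)
    expect_equal(distance_series(tr, baseline)$values,
                 naive_distance_series(tr$coords, baseline), tolerance = 1e-12)
    expect_equal(speed_series(tr)$values, naive_speed_series(tr$coords),
                 tolerance = 1e-12)
    expect_equal(acceleration_series(tr)$values, naive_accel_series(tr$coords, 2),
                 tolerance = 1e-12)
    expect_equal(acceleration_series(tr, 1)$values, naive_accel_series(tr$coords, 1),
                 tolerance = 1e-12)
  }
})

test_that("speed and acceleration are invariant to a constant offset of the clip", {
  set.seed(34)
  tr <- random_track(8, 6)
  shifted <- tr
  shifted$coords[, , 1] <- shifted$coords[, , 1] + 3.7
  shifted$coords[, , 2] <- shifted$coords[, , 2] - 1.2
  expect_equal(speed_series(shifted)$values, speed_series(tr)$values,
               tolerance = 1e-12)
  expect_equal(acceleration_series(shifted)$values, acceleration_series(tr)$values,
               tolerance = 1e-12)

  # time reversal leaves the multiset of speed values unchanged
  reversed <- tr
  reversed$coords <- tr$coords[rev(seq_len(n_frames(tr))), , , drop = FALSE]
  expect_equal(sort(speed_series(reversed)$values), sort(speed_series(tr)$values),
               tolerance = 1e-12)
})

test_that("aggregation works over each series' own support", {
  expect_equal(aggregate_series(c(1, 2, 3), "mean"), 2)
  expect_equal(aggregate_series(c(1, 2, 3), "max"), 3)
  expect_equal(aggregate_series(rep(4, 7), "mean"), aggregate_series(rep(4, 7), "max"))
  expect_error(aggregate_series(numeric(0)), "empty")
})

test_that("the eight clip features respect mean <= max and closed forms", {
  set.seed(35)
  tr <- random_track(12, 6, actor_id = "a1")
  feats <- compute_clip_features(tr, clip_neutral_face(tr), actor_mean_face(list(tr)))
  expect_named(feats, c("clip_id", measure_names()))
  for (m in c("dist_neutral", "dist_mean", "speed", "accel")) {
    expect_lte(feats[[paste0(m, "_mean")]], feats[[paste0(m, "_max")]])
  }
  expect_true(all(feats[measure_names()] >= 0))

  # synthetic clip with known envelope: mean dist_neutral = A * mean(g) exactly
  tmpl <- make_template_face(7)
  a <- 0.8
  clip <- make_expression_clip(tmpl, expression_params(amplitude = a, n_frames = 40),
                               seed = 9, clip_id = "env", actor_id = "a1")
  g <- expression_envelope(40)
  f2 <- compute_clip_features(clip, clip_neutral_face(clip),
                              actor_mean_face(list(clip)))
  expect_equal(f2$dist_neutral_mean, a * mean(g), tolerance = 1e-10)
  expect_equal(f2$dist_neutral_max, a * max(g), tolerance = 1e-10)
})
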