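test_that("template faces are deterministic, distinct across seeds, and normalized", {
  t1 <- make_template_face(1)
  t2 <- make_template_face(1)
  t3 <- make_template_face(2)
  expect_identical(t1, t2)
  expect_gt(rmsd(t1, t3), 0)
  expect_equal(nrow(t1), 68L)
  expect_equal(colMeans(t1), c(0, 0), tolerance = 1e-12)
  expect_equal(centroid_size(t1), 1, tolerance = 1e-12)
  expect_true(all(is.finite(t1)))
})

test_that("expression envelopes start and end at the neutral face", {
  for (t_len in c(10, 47, 100)) {
    g <- expression_envelope(t_len)
    expect_equal(g[1], 0)
    expect_equal(g[t_len], 0)
    expect_true(all(g >= 0 & g <= 1))
  }
  g2 <- expression_envelope(100, active_frames = 30)
  expect_equal(sum(g2 > 0), 28L)  # 30 active frames, two of them exactly zero
})

test_that("noiseless clips realize the envelope closed form exactly", {
  tmpl <- make_template_face(5)
  clip0 <- make_expression_clip(tmpl, expression_params(amplitude = 0), seed = 1)
  expect_equal(max(speed_series(clip0)$values), 0)
  expect_equal(max(distance_series(clip0, clip_neutral_face(clip0))$values), 0)

  p <- expression_params(amplitude = 1, n_frames = 100)
  clip1 <- make_expression_clip(tmpl, p, seed = 2, clip_id = "c1")
  g <- expression_envelope(100)
  expect_equal(distance_series(clip1, clip_neutral_face(clip1))$values, g,
               tolerance = 1e-10)
  # the discrete raised cosine sums to (T-1)/2 over its T samples, so the
  # mean is (T-1)/(2T): 0.495 at T = 100
  expect_equal(mean(g), (100 - 1) / 200, tolerance = 1e-12)

  clip2 <- make_expression_clip(tmpl, expression_params(amplitude = 2), seed = 2)
  expect_equal(distance_series(clip2, clip_neutral_face(clip2))$values, 2 * g,
               tolerance = 1e-10)

  expect_error(expression_params(amplitude = -1), "amplitude")
})

test_that("clip sets are reproducible and hit the target feature correlation", {
  a <- generate_clip_set(10, seed = 3, make_tracks = TRUE)
  b <- generate_clip_set(10, seed = 3, make_tracks = TRUE)
  expect_identical(a$params, b$params)
  expect_identical(lapply(a$tracks, `[[`, "coords"),
                   lapply(b$tracks, `[[`, "coords"))

  big <- generate_clip_set(500, seed = 4, target_r = 0.51, make_tracks = FALSE)
  expect_lt(abs(big$realized_r - 0.51), 0.1)
  null <- generate_clip_set(500, seed = 4, target_r = 0, make_tracks = FALSE)
  expect_lt(abs(null$realized_r), 0.15)
  expect_error(generate_clip_set(10, seed = 1, target_r = 1), "infeasible")
})

test_that("measured features of noiseless clips match the closed-form truth", {
  cs <- generate_clip_set(8, seed = 6, make_tracks = TRUE)
  feats <- compute_feature_table(cs$tracks)
  for (m in c("dist_neutral_mean", "dist_neutral_max", "speed_mean", "speed_max",
              "accel_mean", "accel_max")) {
    expect_equal(feats[[m]], cs$true_features[[m]], tolerance = 1e-8)
  }
})

test_that("Procrustes normalization recovers measures from nuisance-jittered clips", {
  clean <- generate_clip_set(6, seed = 8, make_tracks = TRUE)
  jittered <- generate_clip_set(6, seed = 8, make_tracks = TRUE,
                                translation_range = 0.2, scale_range = 0.1,
                                rotation_range = 0.1)
  feats <- compute_feature_table(normalize_study(jittered$tracks))
  # amplitudes are ~2% of face size, so the unit-size renormalization biases
  # measures by order amplitude; allow a few percent
  expect_equal(feats$dist_neutral_mean, clean$true_features$dist_neutral_mean,
               tolerance = 0.05)
  expect_equal(feats$speed_mean, clean$true_features$speed_mean, tolerance = 0.05)
})

test_that("rating panels follow the generative linear model and MCAR assignment", {
  feats <- data.frame(clip_id = sprintf("c%02d", 1:20),
                      dist_neutral_mean = rnorm(20), speed_mean = rnorm(20))
  flat <- panel_config("NT", n_raters = 10, clips_per_rater = 4,
                       beta0 = 47.6, beta_distance = 0, beta_speed = 0,
                       noise_sd = 0)
  recs <- generate_ratings(feats, flat, seed = 9)
  expect_true(all(recs$arousal == 48))
  expect_equal(nrow(recs), 40L)

  # truncation to the scale bounds
  high <- panel_config("NT", 5, 3, beta0 = 200, beta_distance = 0,
                       beta_speed = 0, noise_sd = 0)
  expect_true(all(generate_ratings(feats, high, seed = 10)$arousal == 101))

  # ASD-style panel density: 19 raters x 14 clips over 80 clips
  feats80 <- data.frame(clip_id = sprintf("c%02d", 1:80),
                        dist_neutral_mean = rnorm(80), speed_mean = rnorm(80))
  asd <- generate_ratings(feats80, panel_config("ASD", 19, 14), seed = 11)
  expect_equal(nrow(asd) / 80, 3.325)

  expect_error(generate_ratings(feats, panel_config("NT", 3, 25), seed = 1),
               "pool")

  # assignment marginals: each clip's average rater count over replicates
  # approaches n_raters * clips_per_rater / n_clips
  counts <- rowMeans(vapply(1:40, function(i) {
    r <- generate_ratings(feats, flat, seed = 100 + i)
    tabulate(match(r$clip_id, feats$clip_id), 20)
  }, numeric(20)))
  expect_equal(mean(counts), 10 * 4 / 20, tolerance = 1e-12)
  expect_lt(max(abs(counts - 2)), 1)
})

test_that("full studies are reproducible and carry their truth tables", {
  cfg <- study_config(n_clips = 12, nt = panel_config("NT", 30, 1:3, pool_clips = 18),
                      asd = panel_config("ASD", 8, 5))
  s1 <- make_study(cfg, seed = 12, make_tracks = FALSE)
  s2 <- make_study(cfg, seed = 12, make_tracks = FALSE)
  expect_identical(s1$ratings, s2$ratings)
  expect_identical(s1$clip_set$true_features, s2$clip_set$true_features)
  expect_equal(s1$truth$asd[["beta0"]], s1$truth$nt[["beta0"]] - 4.29)
  expect_setequal(unique(s1$ratings$group), c("NT", "ASD"))
})
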