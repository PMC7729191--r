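test_that("rating summaries average per clip within one group", {
  recs <- data.frame(
    rater_id = c("r1", "r2", "r3", "r4"),
    group = c("NT", "NT", "NT", "ASD"),
    clip_id = c("c1", "c1", "c2", "c3"),
    arousal = c(40, 60, 70, 30),
    valence = c(10, 20, 30, 40)
  )
  s <- summarize_ratings(recs, "NT")
  expect_equal(s$mean_arousal[s$clip_id == "c1"], 50)
  expect_equal(s$n_raters[s$clip_id == "c1"], 2L)
  expect_equal(s$mean_arousal[s$clip_id == "c2"], 70)  # single rating
  expect_false("c3" %in% s$clip_id)                    # unrated in group: omitted
  expect_error(summarize_ratings(recs, "HAT"), "no ratings")
})

test_that("zscore standardizes with the sample SD and ignores affine changes", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(51)
  v <- rnorm(40)
  expect_equal(mean(zscore(v)), 0, tolerance = 1e-12)
  expect_equal(sd(zscore(v)), 1, tolerance = 1e-12)
  expect_equal(zscore(100 + 3 * v), zscore(v), tolerance = 1e-12)
  expect_error(zscore(rep(2, 5)), "zero variance")
  expect_error(zscore(1), "at least 2")
})

make_group_data <- function(n = 40, seed = 52, noise_sd = 0, b0 = 10,
                            b1 = 2, b2 = 0) {
  set.seed(seed)
  feats <- data.frame(clip_id = sprintf("c%02d", 1:n),
                      dist_neutral_mean = rnorm(n), speed_mean = rnorm(n))
  y <- b0 + b1 * zscore(feats$dist_neutral_mean) +
    b2 * zscore(feats$speed_mean) + rnorm(n, sd = noise_sd)
  summaries <- data.frame(clip_id = feats$clip_id, group = "NT",
                          mean_arousal = y, mean_valence = 50 + rnorm(n),
                          n_raters = 5L)
  list(features = feats, summaries = summaries)
}

test_that("within-group fits recover noiseless coefficients exactly", {
  d <- make_group_data(b0 = 10, b1 = 2)
  fit <- suppressWarnings(  # noiseless by construction: perfect fit
    fit_single_predictor(d$features, d$summaries, "dist_neutral_mean"))
  co <- fit$coefficients
  expect_equal(co$estimate, c(10, 2), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # the intercept of the z-scored-predictor model equals the mean response
  d2 <- make_group_data(noise_sd = 3, seed = 53)
  fit2 <- fit_within_group(d2$features, d2$summaries)
  expect_equal(fit2$coefficients$estimate[1], mean(d2$summaries$mean_arousal),
               tolerance = 1e-10)

  # standardized slope of a simple regression equals the Pearson correlation
  fit3 <- fit_single_predictor(d2$features, d2$summaries, "dist_neutral_mean")
  r <- cor(d2$features$dist_neutral_mean, d2$summaries$mean_arousal)
  expect_equal(fit3$coefficients$std_estimate[2], r, tolerance = 1e-10)
  expect_equal(fit3$r_squared, r^2, tolerance = 1e-10)

  # rank-deficient design is refused
  d3 <- d2
  d3$features$speed_mean <- d3$features$dist_neutral_mean
  expect_error(fit_within_group(d3$features, d3$summaries))
})

test_that("OLS coefficients match a normal-equations oracle on random designs", {
  set.seed(54)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    d <- make_group_data(n = n, seed = 54 + i, noise_sd = 2, b1 = 1.5, b2 = -0.7)
    fit <- fit_within_group(d$features, d$summaries)
    x <- cbind(zscore(d$features$dist_neutral_mean), zscore(d$features$speed_mean))
    expect_equal(fit$coefficients$estimate,
                 unname(naive_ols(x, d$summaries$mean_arousal)), tolerance = 1e-10)
  }
})

test_that("constructed standardized designs reproduce reported R-squared values", {
  # two predictors correlated 0.51 with standardized coefficients (0.28, 0.12)
  d <- synthetic_standardized_fit(c(0.28, 0.12), r = 0.51)
  expect_equal(cor(d$features$dist_neutral_mean, d$features$speed_mean), 0.51,
               tolerance = 1e-12)
  fit <- fit_within_group(d$features, d$summaries)
  expect_equal(fit$coefficients$std_estimate[2:3], c(0.28, 0.12), tolerance = 1e-10)
  expect_equal(fit$r_squared, d$analytic_r_squared, tolerance = 1e-10)
  expect_equal(round(fit$r_squared, 2), 0.13)

  d2 <- synthetic_standardized_fit(c(0.27, 0.17), r = 0.51)
  expect_equal(round(fit_within_group(d2$features, d2$summaries)$r_squared, 2), 0.15)
})

test_that("between-group models recover a pure intercept offset exactly", {
  d <- make_group_data(n = 30, seed = 55, noise_sd = 5)
  s_nt <- d$summaries
  s_asd <- d$summaries
  s_asd$group <- "ASD"
  fit0 <- suppressWarnings(fit_between_group(d$features, s_nt, s_asd))
  expect_equal(fit0$coefficients$estimate, rep(0, 3), tolerance = 1e-12)

  s_asd$mean_arousal <- s_nt$mean_arousal - 4.29
  fit <- suppressWarnings(fit_between_group(d$features, s_nt, s_asd))
  expect_equal(fit$coefficients$estimate[1], 4.29, tolerance = 1e-10)
  expect_equal(fit$coefficients$estimate[2:3], c(0, 0), tolerance = 1e-10)

  expect_error(fit_between_group(d$features, s_nt[1:2, ], s_asd[3:4, ]), "clips")
})

test_that("hat values follow the projection-matrix identities", {
  d <- make_group_data(n = 80, seed = 56, noise_sd = 4, b2 = 1)
  fit <- fit_within_group(d$features, d$summaries)
  h <- hat_values(fit)
  expect_equal(mean(h), 3 / 80, tolerance = 1e-12)
  expect_equal(sum(h), 3, tolerance = 1e-12)
  expect_true(all(h > 0 & h <= 1))
  expect_equal(format(round(mean(h), 3)), "0.038")

  # intercept-only model: every hat value is 1/n
  n <- 10
  s <- data.frame(clip_id = sprintf("c%d", 1:n), group = "NT",
                  mean_arousal = rnorm(n), mean_valence = 50, n_raters = 1L)
  f <- data.frame(clip_id = s$clip_id, dist_neutral_mean = rnorm(n))
  fit1 <- fit_single_predictor(f, s, "dist_neutral_mean")
  expect_equal(mean(hat_values(fit1)), 2 / n, tolerance = 1e-12)
})

test_that("leave-one-out z-distance flags isolated clips only", {
  set.seed(57)
  feats <- data.frame(clip_id = sprintf("c%02d", 1:30),
                      dist_neutral_mean = rnorm(30))
  expect_length(flag_outliers(feats, threshold = 4)$flagged, 0L)

  feats$dist_neutral_mean[30] <- mean(feats$dist_neutral_mean[1:29]) +
    12 * sd(feats$dist_neutral_mean[1:29])
  rep_ <- flag_outliers(feats, threshold = 4)
  expect_equal(rep_$flagged, "c30")
  expect_gt(rep_$loo_z[["c30"]], 4)
  expect_length(flag_outliers(feats, threshold = Inf)$flagged, 0L)
})

test_that("re-fits without flagged clips change the slope in the expected direction", {
  # high-leverage point below the trend pulls the slope down; removing it
  # makes the slope more extreme
  set.seed(58)
  n <- 25
  x <- c(rnorm(n - 1), 8)
  y <- 10 + 2 * x + c(rnorm(n - 1, sd = 0.5), 0)
  y[n] <- 10 + 2 * 0  # far below the trend at x = 8
  feats <- data.frame(clip_id = sprintf("c%02d", 1:n), dist_neutral_mean = x)
  summ <- data.frame(clip_id = feats$clip_id, group = "NT", mean_arousal = y,
                     mean_valence = 50, n_raters = 1L)
  fit <- fit_single_predictor(feats, summ, "dist_neutral_mean")
  rep_ <- flag_outliers(feats, threshold = 4, fit = fit)
  expect_equal(rep_$flagged, sprintf("c%02d", n))
  ref <- refit_excluding(fit, rep_)
  expect_gt(ref$refit$coefficients$estimate[2], fit$coefficients$estimate[2])
  expect_equal(ref$refit$df_residual, n - 1 - 2)

  # empty flag set: identical fit
  ref0 <- refit_excluding(fit, character(0))
  expect_equal(ref0$refit$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-12)
})

test_that("added-variable slopes obey the Frisch-Waugh identity", {
  set.seed(59)
  for (r in c(0, 0.51)) {
    d <- synthetic_standardized_fit(c(0.3, 0.2), r = max(r, 1e-9))
    noisy <- d$summaries
    noisy$mean_arousal <- noisy$mean_arousal + rnorm(nrow(noisy), sd = 5)
    fit <- fit_within_group(d$features, noisy)
    for (p in fit$predictors) {
      av <- added_variable_data(fit, p)
      expect_equal(attr(av, "slope"),
                   fit$coefficients$estimate[match(p, fit$coefficients$term)],
                   tolerance = 1e-10)
    }
  }
  d1 <- synthetic_standardized_fit(0.3)
  fit1 <- fit_single_predictor(d1$features, d1$summaries, "dist_neutral_mean")
  expect_error(added_variable_data(fit1, "dist_neutral_mean"), "at least 2")
})

test_that("valence copies of arousal give identical fits; empty summaries fail", {
  d <- make_group_data(n = 30, seed = 60, noise_sd = 5)
  s_nt <- d$summaries
  s_nt$mean_valence <- s_nt$mean_arousal
  s_asd <- s_nt; s_asd$group <- "ASD"
  spec <- specificity_models(d$features, s_nt, s_asd)
  fit_a <- fit_within_group(d$features, s_nt)
  expect_equal(spec$within_a$coefficients$estimate, fit_a$coefficients$estimate,
               tolerance = 1e-12)
  expect_error(specificity_models(d$features, s_nt[0, ], s_asd), "empty")
})

test_that("confidence intervals are calibrated over generative replicates", {
  # features-level simulation of the full study design: 100 replicates of
  # n = 80 clips, NT and ASD panels, betas recovered by the pipeline's fits
  bench <- run_benchmark(replicates = 100, seed = 71)
  expect_gte(sum(bench$per_replicate$beta1_covered), 88)
  expect_gte(sum(bench$per_replicate$beta2_covered), 88)
  # difference-model slopes truly zero: their CIs cover 0 in >= 90 replicates
  expect_gte(sum(bench$per_replicate$diff_slope_dist_covers0), 90)
  # valence generated independently of the predictors
  expect_gte(sum(bench$per_replicate$valence_slope_dist_covers0), 90)
  # group offset estimated within 2 SEs in the vast majority of replicates
  expect_gte(sum(bench$per_replicate$offset_within_2se), 90)
})
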