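# Synthetic study generator: face-like landmark templates, expression
# trajectories with a neutral -> peak -> neutral envelope, and rater panels
# whose arousal ratings follow the within-group linear model. Every stage of
# the analysis pipeline can be exercised against known ground truth.

#' Deterministic face-like landmark template
#'
#' Builds a 68-landmark configuration in the standard layout (17 jaw, 2 x 5
#' brow, 9 nose, 2 x 6 eye, 20 mouth points), perturbs it with seeded
#' identity jitter, and center-scales it (centroid 0, centroid size 1).
#'
#' @param seed integer seed; the same seed always returns the same face.
#' @param jitter_sd identity jitter standard deviation in pre-normalization
#'   units (default 0.02).
#' @return `68 x 2` matrix.
#' @export
make_template_face <- function(seed, jitter_sd = 0.02) {
  base <- face_layout()
  with_seed(seed, {
    shape <- base + matrix(stats::rnorm(length(base), sd = jitter_sd), ncol = 2)
    center_scale(shape)
  })
}

# canonical 68-point layout (x right, y up), pre-normalization units
face_layout <- function() {
  jaw_t <- seq(-1, 1, length.out = 17)
  jaw <- cbind(jaw_t * 0.85, -0.55 - 0.45 * (1 - jaw_t^2))
  brow_x <- seq(0.2, 0.6, length.out = 5)
  brow <- function(sgn) cbind(sgn * brow_x, 0.42 + 0.08 * sin(seq(0, pi, length.out = 5)))
  nose_bridge <- cbind(rep(0, 4), seq(0.32, 0.05, length.out = 4))
  nose_base <- cbind(seq(-0.12, 0.12, length.out = 5),
                     c(-0.05, -0.08, -0.09, -0.08, -0.05))
  eye <- function(cx) {
    ang <- seq(0, 2 * pi, length.out = 7)[-7]
    cbind(cx + 0.13 * cos(ang), 0.28 + 0.055 * sin(ang))
  }
  mouth_outer_ang <- seq(0, 2 * pi, length.out = 13)[-13]
  mouth_outer <- cbind(0.28 * cos(mouth_outer_ang), -0.45 + 0.12 * sin(mouth_outer_ang))
  mouth_inner_ang <- seq(0, 2 * pi, length.out = 9)[-9]
  mouth_inner <- cbind(0.18 * cos(mouth_inner_ang), -0.45 + 0.05 * sin(mouth_inner_ang))
  rbind(jaw, brow(-1), brow(1), nose_bridge, nose_base,
        eye(-0.35), eye(0.35), mouth_outer, mouth_inner)
}

#' Expression trajectory parameters
#'
#' The expression follows a raised-cosine envelope
#' `g(k) = (1 - cos(2*pi*k/(D-1))) / 2` over `active_frames = D` frames,
#' centered in the clip and zero outside, so every clip starts and ends at the
#' neutral face. The displacement field is a per-landmark direction pattern
#' with unit root-mean-square length, orthogonal to the rigid motions
#' (translation, scaling, rotation of the template), so that `amplitude` is
#' exactly the peak RMSD from the neutral face and is not absorbed by the
#' Procrustes normalization.
#'
#' @param amplitude peak RMSD from the neutral face, in normalized coordinate
#'   units (consensus faces have centroid size 1; default 0.02).
#' @param n_frames clip length `T` (default 100).
#' @param active_frames frames spanned by the expression, `3 <= D <= T`
#'   (default `T`).
#' @param noise_sd per-coordinate tracking-noise SD (default 0).
#' @param translation_range,scale_range,rotation_range half-widths of the
#'   uniform per-frame nuisance jitter: translation in coordinate units,
#'   scale as a relative factor, rotation in radians (defaults 0).
#' @return list of class `expression_params`.
#' @export
expression_params <- function(amplitude = 0.02, n_frames = 100L,
                              active_frames = n_frames, noise_sd = 0,
                              translation_range = 0, scale_range = 0,
                              rotation_range = 0) {
  if (amplitude < 0) stop_facekin("amplitude must be >= 0")
  stopifnot(n_frames >= 3L, active_frames >= 3L, active_frames <= n_frames,
            noise_sd >= 0, translation_range >= 0, scale_range >= 0,
            rotation_range >= 0)
  structure(list(amplitude = amplitude, n_frames = as.integer(n_frames),
                 active_frames = as.integer(active_frames), noise_sd = noise_sd,
                 translation_range = translation_range,
                 scale_range = scale_range, rotation_range = rotation_range),
            class = "expression_params")
}

#' Raised-cosine expression envelope
#' @param n_frames clip length `T`.
#' @param active_frames expression duration `D` (centered in the clip).
#' @return numeric vector of length `T` with `g[1] = g[T] = 0` and peak near 1.
#' @export
expression_envelope <- function(n_frames, active_frames = n_frames) {
  stopifnot(active_frames >= 3L, active_frames <= n_frames)
  g <- numeric(n_frames)
  start <- floor((n_frames - active_frames) / 2)
  k <- seq_len(active_frames) - 1L
  g[start + k + 1L] <- (1 - cos(2 * pi * k / (active_frames - 1))) / 2
  g
}

# unit-RMS displacement field orthogonal to translation, scaling and rotation
# of the (centered, unit-size) template
displacement_field <- function(template, seed) {
  n <- nrow(template)
  with_seed(seed, {
    d <- matrix(stats::rnorm(2 * n), ncol = 2)
    basis <- list(
      cbind(rep(1 / sqrt(n), n), 0),
      cbind(0, rep(1 / sqrt(n), n)),
      template,                                # scaling direction, |.| = 1
      cbind(-template[, 2], template[, 1])     # infinitesimal rotation, |.| = 1
    )
    for (b in basis) d <- d - sum(d * b) * b
    d / sqrt(mean(rowSums(d^2)))
  })
}

#' Generate one synthetic expression clip
#'
#' Frame `f` is `template + amplitude * g(f) * field`, plus optional
#' per-coordinate tracking noise, then an optional per-frame nuisance
#' similarity transform (translation/scale/rotation jitter emulating face
#' position in the camera frame). With zero noise and zero nuisance ranges,
#' the distance-to-clip-neutral series equals `amplitude * g(f)` exactly.
#'
#' @param template `68 x 2` template from [make_template_face()] (any centered
#'   unit-size shape works).
#' @param params an [expression_params()].
#' @param seed integer seed (drives field, noise and nuisance draws).
#' @param clip_id,actor_id,emotion metadata for the resulting track.
#' @return a [clip_track()].
#' @export
make_expression_clip <- function(template, params, seed, clip_id = "clip",
                                 actor_id = NA_character_,
                                 emotion = NA_character_) {
  stopifnot(inherits(params, "expression_params"))
  t_len <- params$n_frames
  n <- nrow(template)
  g <- expression_envelope(t_len, params$active_frames)
  field <- displacement_field(template, child_seed(seed, 1))
  coords <- array(NA_real_, c(t_len, n, 2))
  with_seed(child_seed(seed, 2), {
    for (f in seq_len(t_len)) {
      frame <- template + params$amplitude * g[f] * field
      if (params$noise_sd > 0) {
        frame <- frame + matrix(stats::rnorm(2 * n, sd = params$noise_sd), ncol = 2)
      }
      if (params$rotation_range > 0 || params$scale_range > 0 ||
          params$translation_range > 0) {
        theta <- stats::runif(1, -params$rotation_range, params$rotation_range)
        s <- 1 + stats::runif(1, -params$scale_range, params$scale_range)
        tr <- stats::runif(2, -params$translation_range, params$translation_range)
        frame <- s * rotate_shape(frame, theta)
        frame <- sweep(frame, 2, tr, `+`)
      }
      coords[f, , ] <- frame
    }
  })
  clip_track(coords, clip_id = clip_id, actor_id = actor_id, emotion = emotion)
}

# Solve for the latent log-scale correlation rho such that
# cor(logA + logD, logA) = target, given spreads sa (amplitude) and sd_
# (duration). Distance scales with A * mass(D) and speed with A, so this
# controls the realized distance-speed feature correlation.
solve_latent_rho <- function(target, sa, sd_) {
  f <- function(rho) {
    (sa + rho * sd_) / sqrt(sa^2 + sd_^2 + 2 * rho * sa * sd_) - target
  }
  stats::uniroot(f, c(-0.9999, 0.9999), tol = 1e-12)$root
}

#' Generate a set of synthetic expression clips
#'
#' Per-clip amplitude `A` and expression duration `D` are drawn jointly
#' log-normal, with their latent correlation solved so that the realized
#' Pearson correlation between the mean distance-to-neutral feature (which
#' scales with `A` times the envelope mass of `D`) and the mean speed feature
#' (which scales with `A`) approximates `target_r`. Clips are distributed
#' round-robin over `n_actors` seeded templates.
#'
#' @param n_clips number of clips, `>= 3`.
#' @param seed integer seed; the full set is reproducible from it.
#' @param target_r target distance-speed feature correlation, `|r| < 1`
#'   (default 0.51).
#' @param n_frames clip length (default 100).
#' @param n_actors number of actor templates (default 12).
#' @param amplitude_meanlog,amplitude_sdlog log-normal amplitude parameters
#'   (default `log(0.02)`, 0.30).
#' @param duration_meanlog,duration_sdlog log-normal duration parameters in
#'   frames (default `log(60)`, 0.45); durations are rounded and clamped to
#'   `[10, n_frames]`.
#' @param noise_sd,translation_range,scale_range,rotation_range forwarded to
#'   [expression_params()] for every clip.
#' @param make_tracks if `FALSE`, only parameters and closed-form true
#'   features are generated (fast mode for simulation studies).
#' @return list of class `synthetic_clip_set`: `tracks` (list or `NULL`),
#'   `params` (per-clip data.frame with `clip_id, actor_id, emotion,
#'   amplitude, duration`), `true_features` (closed-form noiseless features),
#'   `realized_r`, `seed`.
#' @export
generate_clip_set <- function(n_clips, seed, target_r = 0.51, n_frames = 100L,
                              n_actors = 12L,
                              amplitude_meanlog = log(0.02),
                              amplitude_sdlog = 0.30,
                              duration_meanlog = log(60),
                              duration_sdlog = 0.45,
                              noise_sd = 0, translation_range = 0,
                              scale_range = 0, rotation_range = 0,
                              make_tracks = TRUE) {
  stopifnot(n_clips >= 3L)
  if (abs(target_r) >= 1) stop_facekin("infeasible target correlation %g", target_r)
  rho <- solve_latent_rho(target_r, amplitude_sdlog, duration_sdlog)
  draws <- with_seed(child_seed(seed, 1), {
    u1 <- stats::rnorm(n_clips)
    u2 <- stats::rnorm(n_clips)
    list(u1 = u1, u2 = u2)
  })
  amplitude <- exp(amplitude_meanlog + amplitude_sdlog * draws$u1)
  log_d <- duration_meanlog + duration_sdlog * (rho * draws$u1 +
                                                  sqrt(1 - rho^2) * draws$u2)
  duration <- pmin(pmax(round(exp(log_d)), 10L), n_frames)

  clip_id <- sprintf("clip%03d", seq_len(n_clips))
  actor_id <- sprintf("actor%02d", (seq_len(n_clips) - 1L) %% n_actors + 1L)
  emotion <- sprintf("category%02d", (seq_len(n_clips) - 1L) %% 21L + 1L)
  params <- data.frame(clip_id = clip_id, actor_id = actor_id,
                       emotion = emotion, amplitude = amplitude,
                       duration = as.integer(duration), stringsAsFactors = FALSE)

  true_features <- do.call(rbind, lapply(seq_len(n_clips), function(i) {
    g <- expression_envelope(n_frames, duration[i])
    a <- amplitude[i]
    sp <- a * abs(diff(g))
    ac <- a * abs(diff(diff(g))) / 2
    data.frame(clip_id = clip_id[i],
               dist_neutral_mean = a * mean(g), dist_neutral_max = a * max(g),
               speed_mean = mean(sp), speed_max = max(sp),
               accel_mean = mean(ac), accel_max = max(ac),
               stringsAsFactors = FALSE)
  }))
  realized_r <- stats::cor(true_features$dist_neutral_mean, true_features$speed_mean)

  tracks <- NULL
  if (make_tracks) {
    templates <- lapply(seq_len(n_actors), function(a) {
      make_template_face(child_seed(seed, 100 + a))
    })
    tracks <- lapply(seq_len(n_clips), function(i) {
      p <- expression_params(amplitude = amplitude[i], n_frames = n_frames,
                             active_frames = duration[i], noise_sd = noise_sd,
                             translation_range = translation_range,
                             scale_range = scale_range,
                             rotation_range = rotation_range)
      make_expression_clip(templates[[(i - 1L) %% n_actors + 1L]], p,
                           seed = child_seed(seed, 1000 + i),
                           clip_id = clip_id[i], actor_id = actor_id[i],
                           emotion = emotion[i])
    })
  }
  structure(list(tracks = tracks, params = params, true_features = true_features,
                 realized_r = realized_r, target_r = target_r, seed = seed),
            class = "synthetic_clip_set")
}

#' Rater-panel configuration
#'
#' @param group group label (`"NT"`, `"ASD"`, `"HAT"`, ...).
#' @param n_raters number of raters in the panel.
#' @param clips_per_rater integer vector; each rater's clip count is drawn
#'   uniformly from it (a scalar gives every rater the same count).
#' @param beta0,beta_distance,beta_speed generative coefficients of the
#'   arousal model on z-scored distance and speed features (arousal-scale
#'   points per SD).
#' @param noise_sd rater-level arousal noise SD (rating points).
#' @param pool_clips size of the stimulus pool raters draw from; when larger
#'   than the analysed clip set, draws falling outside the set are discarded
#'   (emulating panels rated on a wider video pool). `NULL` = the clip set.
#' @param valence_beta0 mean valence; valence is generated independently of
#'   the kinematic features (the generator's default truth is that the
#'   predictors are arousal-specific).
#' @param valence_noise_sd rater-level valence noise SD.
#' @param bounds rating-scale bounds (default `c(1, 101)`).
#' @return list of class `panel_config`.
#' @export
panel_config <- function(group, n_raters, clips_per_rater,
                         beta0 = 47.60, beta_distance = 5.93,
                         beta_speed = 2.53, noise_sd = 25,
                         pool_clips = NULL, valence_beta0 = 51,
                         valence_noise_sd = 25, bounds = c(1, 101)) {
  stopifnot(n_raters >= 1L, all(clips_per_rater >= 1L),
            noise_sd >= 0, valence_noise_sd >= 0, length(bounds) == 2L)
  structure(list(group = toupper(group), n_raters = as.integer(n_raters),
                 clips_per_rater = as.integer(clips_per_rater),
                 beta0 = beta0, beta_distance = beta_distance,
                 beta_speed = beta_speed, noise_sd = noise_sd,
                 pool_clips = pool_clips, valence_beta0 = valence_beta0,
                 valence_noise_sd = valence_noise_sd, bounds = bounds),
            class = "panel_config")
}

#' Generate rating records for one panel
#'
#' Each rater is assigned `clips_per_rater` clips uniformly without
#' replacement from the stimulus pool (missing-completely-at-random design);
#' each assigned clip in the analysis set yields one arousal and one valence
#' rating. Arousal follows the linear model
#' `beta0 + beta_distance * z(dist) + beta_speed * z(speed) + clip effect +
#' noise`, rounded to integers and truncated to the rating scale; valence is
#' independent of the features.
#'
#' @param features per-clip feature table with `clip_id` and the predictor
#'   columns.
#' @param panel a [panel_config()].
#' @param seed integer seed.
#' @param clip_offsets per-clip arousal offsets shared by all raters (length 1
#'   or `n_clips`); clip-level random effects live here.
#' @param valence_clip_offsets per-clip valence offsets.
#' @param predictors feature columns entering the generative model.
#' @return data.frame of rating records
#'   (`rater_id, group, clip_id, arousal, valence`).
#' @export
generate_ratings <- function(features, panel, seed, clip_offsets = 0,
                             valence_clip_offsets = 0,
                             predictors = c("dist_neutral_mean", "speed_mean")) {
  stopifnot(inherits(panel, "panel_config"))
  n_clips <- nrow(features)
  pool_n <- panel$pool_clips %||% n_clips
  if (pool_n < n_clips) stop_facekin("pool_clips smaller than the clip set")
  if (max(panel$clips_per_rater) > pool_n) {
    stop_facekin("clips_per_rater exceeds the stimulus pool size")
  }
  z1 <- zscore(features[[predictors[1]]])
  z2 <- if (length(predictors) > 1L) zscore(features[[predictors[2]]]) else 0
  expected <- panel$beta0 + panel$beta_distance * z1 + panel$beta_speed * z2 +
    clip_offsets
  expected_val <- panel$valence_beta0 + valence_clip_offsets + 0 * z1
  lo <- panel$bounds[1]; hi <- panel$bounds[2]

  with_seed(seed, {
    recs <- vector("list", panel$n_raters)
    for (r in seq_len(panel$n_raters)) {
      k <- if (length(panel$clips_per_rater) == 1L) panel$clips_per_rater else
        sample(panel$clips_per_rater, 1L)
      assigned <- sample.int(pool_n, k)
      assigned <- assigned[assigned <= n_clips]
      if (length(assigned) == 0L) next
      arousal <- round(expected[assigned] +
                         stats::rnorm(length(assigned), sd = panel$noise_sd))
      valence <- round(expected_val[assigned] +
                         stats::rnorm(length(assigned), sd = panel$valence_noise_sd))
      recs[[r]] <- data.frame(
        rater_id = sprintf("%s_r%04d", tolower(panel$group), r),
        group = panel$group,
        clip_id = features$clip_id[assigned],
        arousal = pmin(pmax(arousal, lo), hi),
        valence = pmin(pmax(valence, lo), hi),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

#' Study-level generator configuration
#'
#' Defaults encode the study conditions the pipeline is designed for: 80
#' four-second clips of 100 frames and 68 landmarks from 12 actors; a
#' distance-speed feature correlation of 0.51; an NT panel of 401 raters
#' rating 1-6 clips each from a wider stimulus pool (about 11.2 raters per
#' analysed clip) and an ASD panel of 19 raters rating 14 clips each (3.325
#' raters per clip); generative arousal coefficients (47.60, 5.93, 2.53) with
#' the ASD intercept lower by `group_offset = 4.29` rating points; shared
#' clip-level rating effects (SD 18) plus rater-level noise (SD 25); valence
#' independent of the kinematic features.
#'
#' @param n_clips,n_frames,n_actors,target_r clip-set parameters.
#' @param amplitude_meanlog,amplitude_sdlog,duration_meanlog,duration_sdlog
#'   per-clip amplitude/duration distributions (see [generate_clip_set()]).
#' @param noise_sd tracking-noise SD per coordinate.
#' @param translation_range,scale_range,rotation_range per-frame nuisance
#'   jitter half-widths (coordinate units / relative factor / radians).
#' @param nt,asd [panel_config()]s for the two panels.
#' @param group_offset ASD intercept deficit in rating points; the ASD
#'   panel's `beta0` is `nt$beta0 - group_offset`.
#' @param clip_effect_sd SD of the clip-level arousal effect shared by both
#'   panels (rating points).
#' @param valence_clip_sd SD of the clip-level valence effect.
#' @return list of class `study_config`.
#' @export
study_config <- function(n_clips = 80L, n_frames = 100L, n_actors = 12L,
                         target_r = 0.51,
                         amplitude_meanlog = log(0.02), amplitude_sdlog = 0.30,
                         duration_meanlog = log(60), duration_sdlog = 0.45,
                         noise_sd = 1e-4, translation_range = 0.05,
                         scale_range = 0.05, rotation_range = 0.05,
                         nt = panel_config("NT", n_raters = 401L,
                                           clips_per_rater = 1:6,
                                           pool_clips = 125L),
                         asd = panel_config("ASD", n_raters = 19L,
                                            clips_per_rater = 14L),
                         group_offset = 4.29,
                         clip_effect_sd = 18, valence_clip_sd = 12) {
  asd$beta0 <- nt$beta0 - group_offset
  asd$beta_distance <- nt$beta_distance
  asd$beta_speed <- nt$beta_speed
  structure(list(n_clips = as.integer(n_clips), n_frames = as.integer(n_frames),
                 n_actors = as.integer(n_actors), target_r = target_r,
                 amplitude_meanlog = amplitude_meanlog,
                 amplitude_sdlog = amplitude_sdlog,
                 duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog,
                 noise_sd = noise_sd, translation_range = translation_range,
                 scale_range = scale_range, rotation_range = rotation_range,
                 nt = nt, asd = asd, group_offset = group_offset,
                 clip_effect_sd = clip_effect_sd,
                 valence_clip_sd = valence_clip_sd),
            class = "study_config")
}

#' Generate a full synthetic study
#'
#' Clips (optionally with landmark tracks), true per-clip parameters and
#' features, and NT + ASD rating panels generated from the within-group
#' linear model with a group intercept offset. Fully reproducible from
#' `(config, seed)`.
#'
#' @param config a [study_config()].
#' @param seed integer seed.
#' @param make_tracks generate landmark tracks (`TRUE`) or only features and
#'   ratings (fast mode for simulation studies).
#' @return list of class `synthetic_study`: `clip_set`, `ratings` (combined
#'   data.frame), `truth` (list with the generative coefficients and offsets),
#'   `config`, `seed`.
#' @export
make_study <- function(config = study_config(), seed = 1L, make_tracks = TRUE) {
  stopifnot(inherits(config, "study_config"))
  clip_set <- generate_clip_set(
    n_clips = config$n_clips, seed = child_seed(seed, 1),
    target_r = config$target_r, n_frames = config$n_frames,
    n_actors = config$n_actors,
    amplitude_meanlog = config$amplitude_meanlog,
    amplitude_sdlog = config$amplitude_sdlog,
    duration_meanlog = config$duration_meanlog,
    duration_sdlog = config$duration_sdlog,
    noise_sd = config$noise_sd, translation_range = config$translation_range,
    scale_range = config$scale_range, rotation_range = config$rotation_range,
    make_tracks = make_tracks
  )
  offsets <- with_seed(child_seed(seed, 2), {
    list(arousal = stats::rnorm(config$n_clips, sd = config$clip_effect_sd),
         valence = stats::rnorm(config$n_clips, sd = config$valence_clip_sd))
  })
  feats <- clip_set$true_features
  ratings_nt <- generate_ratings(feats, config$nt, seed = child_seed(seed, 3),
                                 clip_offsets = offsets$arousal,
                                 valence_clip_offsets = offsets$valence)
  ratings_asd <- generate_ratings(feats, config$asd, seed = child_seed(seed, 4),
                                  clip_offsets = offsets$arousal,
                                  valence_clip_offsets = offsets$valence)
  ratings <- rbind(ratings_nt, ratings_asd)
  truth <- list(
    nt = c(beta0 = config$nt$beta0, beta_distance = config$nt$beta_distance,
           beta_speed = config$nt$beta_speed),
    asd = c(beta0 = config$asd$beta0, beta_distance = config$asd$beta_distance,
            beta_speed = config$asd$beta_speed),
    group_offset = config$group_offset,
    clip_offsets = offsets$arousal, valence_clip_offsets = offsets$valence
  )
  structure(list(clip_set = clip_set, ratings = ratings, truth = truth,
                 config = config, seed = seed),
            class = "synthetic_study")
}
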