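# Orchestration: exploratory measure-selection run, confirmatory rating-model
# run, synthetic-study export and the parameter-recovery benchmark. Each run
# function works on in-memory objects and optionally writes its artifacts
# (CSV/JSON stamped with a config hash) to an output directory.

pipeline_log <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Exploratory measure-selection analysis
#'
#' Normalizes all clips into one Procrustes frame, computes the eight
#' kinematic measures per clip, their Pearson correlation matrix and block
#' structure, and selects one distance and one speed predictor.
#'
#' @param tracks list of [clip_track()]s (e.g. read with
#'   [read_openface_csv()] or generated by [generate_clip_set()]).
#' @param output_dir optional directory for artifacts (`features.csv`,
#'   `correlation_matrix.csv`, `study1_report.json`).
#' @param norm_config a [normalization_config()].
#' @param block_threshold absolute-correlation threshold for
#'   [correlation_blocks()].
#' @param aggregation predictor-selection policy, `"mean"` or `"max"`.
#' @param accel_denominator see [acceleration_series()].
#' @param verbose log progress messages.
#' @return list of class `study1_result`: `features`, `correlation`, `blocks`,
#'   `predictors`, `alignment` (consensus/iterations/residual), `config_hash`.
#' @export
run_study1 <- function(tracks, output_dir = NULL,
                       norm_config = normalization_config(),
                       block_threshold = 0.5, aggregation = "mean",
                       accel_denominator = 2, verbose = FALSE) {
  if (length(tracks) == 0L) stop_facekin("no tracks supplied")
  cfg <- list(norm = norm_config, block_threshold = block_threshold,
              aggregation = aggregation, accel_denominator = accel_denominator)
  hash <- config_hash(cfg)
  pipeline_log(verbose, "study1 [%s]: normalizing %d clips", hash, length(tracks))
  aligned <- normalize_study(tracks, norm_config)
  features <- compute_feature_table(aligned, accel_denominator)
  correlation <- pearson_matrix(features)
  blocks <- correlation_blocks(correlation, block_threshold)
  predictors <- tryCatch(select_predictors(blocks, aggregation),
                         error = function(e) {
                           warning(conditionMessage(e), call. = FALSE)
                           NULL
                         })
  pipeline_log(verbose, "study1 [%s]: %d blocks, predictors: %s", hash,
               length(blocks), paste(predictors, collapse = ", "))
  result <- structure(
    list(features = features, correlation = correlation, blocks = blocks,
         predictors = predictors,
         alignment = list(iterations = aligned$iterations,
                          converged = aligned$converged,
                          residual = aligned$residual),
         config_hash = hash),
    class = "study1_result"
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(features, file.path(output_dir, "features.csv"))
    write_correlation_matrix(correlation, file.path(output_dir, "correlation_matrix.csv"))
    write_json_report(list(config_hash = hash, predictors = predictors,
                           blocks = blocks,
                           alignment = result$alignment),
                      file.path(output_dir, "study1_report.json"))
  }
  result
}

#' Confirmatory rating-model analysis
#'
#' Summarizes ratings per clip and group, fits the within-group arousal
#' models, the between-group difference model, single-predictor models,
#' valence-specificity models, and produces the outlier report with re-fits
#' and added-variable data. Any additional group labels present in the
#' ratings (e.g. a high-autistic-traits replication panel) are fitted with
#' identical machinery and, paired with the first group, get their own
#' difference model.
#'
#' @param features per-clip feature table.
#' @param ratings validated rating records with at least 2 groups.
#' @param groups the two primary group labels (default `c("NT", "ASD")`).
#' @param predictors predictor columns (default mean distance + mean speed).
#' @param output_dir optional artifact directory.
#' @param outlier_threshold leave-one-out z threshold for [flag_outliers()].
#' @param ci_level confidence level.
#' @param verbose log progress messages.
#' @return list of class `study2_result` with `summaries`, `fits` (named list
#'   of `rating_fit`s), `outliers`, `refits`, `added_variable`, `config_hash`.
#' @export
run_study2 <- function(features, ratings, groups = c("NT", "ASD"),
                       predictors = c("dist_neutral_mean", "speed_mean"),
                       output_dir = NULL, outlier_threshold = 4,
                       ci_level = 0.95, verbose = FALSE) {
  if (is.null(ratings) || nrow(ratings) == 0L) stop_facekin("empty ratings")
  present <- unique(ratings$group)
  for (g in groups) {
    if (!g %in% present) stop_facekin("group '%s' absent from ratings", g)
  }
  cfg <- list(groups = groups, predictors = predictors,
              outlier_threshold = outlier_threshold, ci_level = ci_level)
  hash <- config_hash(cfg)
  extra_groups <- setdiff(present, groups)

  summaries <- lapply(stats::setNames(nm = c(groups, extra_groups)),
                      function(g) summarize_ratings(ratings, g))
  fits <- list()
  for (g in c(groups, extra_groups)) {
    fits[[paste0("arousal_", g)]] <-
      fit_within_group(features, summaries[[g]], predictors, ci_level = ci_level)
    for (p in predictors) {
      fits[[paste0("arousal_", g, "_", p)]] <-
        fit_single_predictor(features, summaries[[g]], p, ci_level = ci_level)
    }
  }
  fits[["arousal_difference"]] <-
    fit_between_group(features, summaries[[groups[1]]], summaries[[groups[2]]],
                      predictors, ci_level = ci_level)
  for (g in extra_groups) {
    fits[[paste0("arousal_difference_", groups[1], "_", g)]] <-
      fit_between_group(features, summaries[[groups[1]]], summaries[[g]],
                        predictors, ci_level = ci_level)
  }
  spec <- specificity_models(features, summaries[[groups[1]]],
                             summaries[[groups[2]]], predictors,
                             ci_level = ci_level)
  fits[[paste0("valence_", groups[1])]] <- spec$within_a
  fits[[paste0("valence_", groups[2])]] <- spec$within_b
  fits[["valence_difference"]] <- spec$between

  primary <- fits[[paste0("arousal_", groups[1])]]
  analysis_features <- features[match(primary$clip_id, features$clip_id), ]
  outliers <- flag_outliers(analysis_features, predictors[1],
                            threshold = outlier_threshold, fit = primary)
  refits <- list()
  avd <- list()
  for (g in groups) {
    f <- fits[[paste0("arousal_", g)]]
    refits[[g]] <- refit_excluding(f, outliers)
    if (length(predictors) >= 2L) {
      avd[[g]] <- lapply(stats::setNames(nm = predictors),
                         function(p) added_variable_data(f, p))
    }
  }
  pipeline_log(verbose, "study2 [%s]: %d models, %d outliers flagged", hash,
               length(fits), length(outliers$flagged))

  result <- structure(
    list(summaries = summaries, fits = fits, outliers = outliers,
         refits = refits, added_variable = avd, config_hash = hash),
    class = "study2_result"
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fits_to_table(fits),
                     file.path(output_dir, "model_coefficients.csv"),
                     row.names = FALSE)
    write_json_report(
      list(config_hash = hash,
           outliers = list(flagged = outliers$flagged,
                           loo_z = as.list(outliers$loo_z[outliers$flagged]),
                           hat = as.list(outliers$hat %||% list())),
           refit_distance_slopes = lapply(refits, function(r) {
             stats::setNames(as.list(r$comparison$estimate_refit), r$comparison$term)
           })),
      file.path(output_dir, "study2_report.json"))
    for (g in names(avd)) {
      for (p in names(avd[[g]])) {
        utils::write.csv(avd[[g]][[p]],
                         file.path(output_dir, sprintf("added_variable_%s_%s.csv", g, p)),
                         row.names = FALSE)
      }
    }
  }
  result
}

#' Generate and export a synthetic study
#'
#' Runs [make_study()] and (optionally) writes the artifacts the IO module
#' reads back: one OpenFace-style CSV per clip, `ratings.csv`,
#' `clip_metadata.csv` and `study_manifest.json`.
#'
#' @param config a [study_config()].
#' @param seed integer seed.
#' @param output_dir optional export directory.
#' @param verbose log progress messages.
#' @return the `synthetic_study`, invisibly when writing.
#' @export
simulate_study <- function(config = study_config(), seed = 1L,
                           output_dir = NULL, verbose = FALSE) {
  study <- make_study(config, seed, make_tracks = TRUE)
  pipeline_log(verbose, "simulate [%s]: %d clips, %d ratings",
               config_hash(config), config$n_clips, nrow(study$ratings))
  if (!is.null(output_dir)) {
    dir.create(file.path(output_dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
    for (tr in study$clip_set$tracks) {
      write_openface_csv(tr, file.path(output_dir, "tracks",
                                       paste0(tr$clip_id, ".csv")))
    }
    utils::write.csv(study$ratings, file.path(output_dir, "ratings.csv"),
                     row.names = FALSE)
    meta <- study$clip_set$params[c("clip_id", "actor_id", "emotion")]
    names(meta) <- c("clip_id", "actor_id", "emotion_category")
    utils::write.csv(meta, file.path(output_dir, "clip_metadata.csv"),
                     row.names = FALSE)
    write_json_report(list(seed = seed, config_hash = config_hash(config),
                           n_clips = config$n_clips,
                           realized_feature_correlation = study$clip_set$realized_r),
                      file.path(output_dir, "study_manifest.json"))
    return(invisible(study))
  }
  study
}

#' Parameter-recovery benchmark
#'
#' Repeatedly generates a synthetic study, fits the within-group and
#' between-group models, and summarizes how often the 95% confidence
#' intervals cover the generative truth and how far the recovered group
#' offset lies from its generating value.
#'
#' @param replicates number of replicates, `>= 2`.
#' @param config a [study_config()].
#' @param seed integer seed; replicate `i` uses a derived child seed.
#' @param full_pipeline if `TRUE`, every replicate generates landmark tracks,
#'   normalizes them and measures features; if `FALSE` (default), the
#'   closed-form true features are used, benchmarking the rating-model stage.
#' @param verbose log progress messages.
#' @return list of class `benchmark_result`: `per_replicate` (data.frame),
#'   `coverage` (named coverage proportions), `replicates`, `seed`.
#' @export
run_benchmark <- function(replicates = 100L, config = study_config(),
                          seed = 1L, full_pipeline = FALSE, verbose = FALSE) {
  if (replicates < 2L) stop_facekin("need at least 2 replicates")
  rows <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    study <- make_study(config, seed = child_seed(seed, i),
                        make_tracks = full_pipeline)
    feats <- if (full_pipeline) {
      compute_feature_table(normalize_study(study$clip_set$tracks))
    } else {
      study$clip_set$true_features
    }
    s_nt <- summarize_ratings(study$ratings, "NT")
    s_asd <- summarize_ratings(study$ratings, "ASD")
    fit_nt <- fit_within_group(feats, s_nt)
    fit_diff <- fit_between_group(feats, s_nt, s_asd)
    spec_nt <- fit_within_group(feats, s_nt, response = "mean_valence")
    co <- fit_nt$coefficients
    cd <- fit_diff$coefficients
    cv <- spec_nt$coefficients
    truth <- study$truth$nt
    offset_se <- (cd$ci_high[1] - cd$ci_low[1]) / (2 * stats::qt(0.975, fit_diff$df_residual))
    rows[[i]] <- data.frame(
      replicate = i,
      beta1_hat = co$estimate[2],
      beta1_covered = co$ci_low[2] <= truth["beta_distance"] &
        truth["beta_distance"] <= co$ci_high[2],
      beta2_covered = co$ci_low[3] <= truth["beta_speed"] &
        truth["beta_speed"] <= co$ci_high[3],
      offset_hat = cd$estimate[1],
      offset_covered = cd$ci_low[1] <= study$truth$group_offset &
        study$truth$group_offset <= cd$ci_high[1],
      offset_within_2se = abs(cd$estimate[1] - study$truth$group_offset) <= 2 * offset_se,
      diff_slope_dist_covers0 = cd$ci_low[2] <= 0 & 0 <= cd$ci_high[2],
      valence_slope_dist_covers0 = cv$ci_low[2] <= 0 & 0 <= cv$ci_high[2],
      realized_r = study$clip_set$realized_r
    )
    pipeline_log(verbose, "benchmark replicate %d/%d done", i, replicates)
  }
  per_replicate <- do.call(rbind, rows)
  coverage <- colMeans(per_replicate[c("beta1_covered", "beta2_covered",
                                       "offset_covered", "offset_within_2se",
                                       "diff_slope_dist_covers0",
                                       "valence_slope_dist_covers0")])
  structure(list(per_replicate = per_replicate, coverage = coverage,
                 replicates = replicates, seed = seed),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Parameter-recovery benchmark: %d replicates\n", x$replicates))
  print(round(x$coverage, 3))
  invisible(x)
}
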