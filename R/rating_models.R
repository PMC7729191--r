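# Study-2 machinery: rating summarization, within-group and between-group OLS
# models of arousal on z-scored kinematic predictors, leverage diagnostics,
# added-variable data, outlier re-fits and valence-specificity models.

#' Per-clip, per-group rating summaries
#'
#' Averages arousal and valence over raters, per clip, within one group.
#' Clips with no ratings in the group are omitted; because raters are assigned
#' to clips completely at random, the omission and the unequal rater counts
#' induce no bias in the per-clip means.
#'
#' @param ratings data.frame of validated rating records
#'   (see [read_ratings()]).
#' @param group group label (`"NT"`, `"ASD"`, `"HAT"`, ...).
#' @return data.frame `clip_id, group, mean_arousal, mean_valence, n_raters`.
#' @export
summarize_ratings <- function(ratings, group) {
  stopifnot(nrow(ratings) > 0L)
  group <- toupper(group)
  sub <- ratings[ratings$group == group, , drop = FALSE]
  if (nrow(sub) == 0L) stop_facekin("no ratings for group '%s'", group)
  agg <- do.call(rbind, lapply(split(sub, sub$clip_id), function(d) {
    data.frame(clip_id = d$clip_id[1], group = group,
               mean_arousal = mean(d$arousal), mean_valence = mean(d$valence),
               n_raters = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$clip_id), , drop = FALSE]
}

#' Z-score a numeric vector
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (denominator
#' `n - 1`).
#'
#' @param values numeric vector, length >= 2, nonzero variance.
#' @return z-scored vector.
#' @export
zscore <- function(values) {
  if (length(values) < 2L) stop_facekin("zscore needs at least 2 values")
  s <- stats::sd(values)
  if (s == 0) stop_facekin("zscore: zero variance")
  (values - mean(values)) / s
}

# Core fit: OLS of `response_values` on z-scored predictor columns of `data`,
# plus the fully standardized variant (response z-scored too). Predictors are
# z-scored over exactly the analysis rows supplied.
fit_rating_core <- function(data, predictors, response_values, label,
                            ci_level = 0.95) {
  n <- nrow(data)
  k <- length(predictors) + 1L
  if (n < k + 1L) stop_facekin("model '%s': %d observations for %d coefficients", label, n, k)
  design <- data.frame(.y = response_values)
  for (p in predictors) design[[p]] <- zscore(data[[p]])
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", predictors), collapse = " + ")))
  fit <- stats::lm(fml, data = design)
  if (fit$rank < k) stop_facekin("model '%s': rank-deficient design", label)
  # the standardized variant is undefined for a constant response (e.g. the
  # difference model on identical summaries); report NA there
  has_std <- stats::sd(response_values) > 0
  design_std <- design
  design_std$.y <- if (has_std) zscore(response_values) else response_values * NA_real_
  fit_std <- if (has_std) stats::lm(fml, data = design_std) else fit

  smry <- summary(fit)
  smry_std <- summary(fit_std)
  ci <- stats::confint(fit, level = ci_level)
  ci_std <- stats::confint(fit_std, level = ci_level)
  if (!has_std) ci_std <- ci * NA_real_
  coefs <- data.frame(
    term = c("(Intercept)", predictors),
    estimate = unname(stats::coef(fit)),
    ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
    p_value = unname(smry$coefficients[, 4]),
    std_estimate = if (has_std) unname(stats::coef(fit_std)) else rep(NA_real_, k),
    std_ci_low = unname(ci_std[, 1]), std_ci_high = unname(ci_std[, 2]),
    std_p_value = if (has_std) unname(smry_std$coefficients[, 4]) else rep(NA_real_, k),
    stringsAsFactors = FALSE
  )
  fstat <- if (is.null(smry$fstatistic)) c(NA_real_, NA_real_, NA_real_) else smry$fstatistic
  structure(
    list(label = label, n = n, predictors = predictors, response = response_values,
         coefficients = coefs,
         r_squared = smry$r.squared, adj_r_squared = smry$adj.r.squared,
         sigma = smry$sigma,
         sigma_std = if (has_std) smry_std$sigma else NA_real_,
         df_residual = fit$df.residual,
         f_statistic = unname(fstat[1]), f_df = unname(fstat[2:3]),
         residuals = stats::resid(fit), hat = unname(stats::hatvalues(fit)),
         ci_level = ci_level, clip_id = data$clip_id,
         model = fit, model_std = fit_std, data = data),
    class = "rating_fit"
  )
}

#' @export
print.rating_fit <- function(x, digits = 2, ...) {
  cat(sprintf("Linear model: %s  (n = %d)\n", x$label, x$n))
  co <- x$coefficients
  tab <- data.frame(
    term = co$term,
    estimate = round(co$estimate, digits),
    `95% CI` = sprintf("[%.*f, %.*f]", digits, co$ci_low, digits, co$ci_high),
    p = signif(co$p_value, 3),
    std = round(co$std_estimate, digits),
    `std 95% CI` = sprintf("[%.*f, %.*f]", digits, co$std_ci_low, digits, co$std_ci_high),
    check.names = FALSE
  )
  print(tab, row.names = FALSE)
  cat(sprintf("R2 = %.*f, adj. R2 = %.*f, residual SE = %.*f (df = %d), F = %.*f (df = %d; %d)\n",
              digits, x$r_squared, digits, x$adj_r_squared, digits, x$sigma,
              x$df_residual, digits, x$f_statistic, x$f_df[1], x$f_df[2]))
  invisible(x)
}

# Merge a feature table and a summary table on clip_id, keeping common clips.
merge_features_summaries <- function(features, summaries) {
  merged <- merge(features, summaries, by = "clip_id", sort = TRUE)
  if (nrow(merged) == 0L) stop_facekin("no clips shared between features and summaries")
  merged
}

#' Within-group arousal model
#'
#' OLS of the group's per-clip mean arousal on z-scored distance and speed
#' predictors: `Arousal_G = b0 + b1 * Distance + b2 * Speed + e`. Predictors
#' are z-scored over exactly the analysis clips, so the intercept equals the
#' group's mean rating. The returned fit also carries the fully standardized
#' variant (response z-scored as well).
#'
#' @param features per-clip feature table (`clip_id` + measure columns).
#' @param summaries output of [summarize_ratings()] for one group.
#' @param predictors character vector of feature-column names; default the
#'   confirmatory pair (mean distance to clip-neutral, mean speed).
#' @param response `"mean_arousal"` (default) or `"mean_valence"`.
#' @param ci_level confidence level for t-based intervals (default 0.95).
#' @return a `rating_fit`.
#' @export
fit_within_group <- function(features, summaries,
                             predictors = c("dist_neutral_mean", "speed_mean"),
                             response = "mean_arousal", ci_level = 0.95) {
  merged <- merge_features_summaries(features, summaries)
  label <- sprintf("%s ~ %s (%s)", response, paste(predictors, collapse = " + "),
                   merged$group[1] %||% "group")
  fit_rating_core(merged, predictors, merged[[response]], label, ci_level)
}

#' Between-group difference model
#'
#' OLS of the per-clip difference of group mean ratings (first minus second
#' group) on the z-scored predictors. A nonzero intercept indicates a mean
#' rating offset between the groups; nonzero slopes would indicate
#' group-dependent use of the kinematic cues.
#'
#' @param features per-clip feature table.
#' @param summaries_a,summaries_b [summarize_ratings()] outputs for the two
#'   groups (e.g. NT and ASD); only clips rated in both groups enter.
#' @inheritParams fit_within_group
#' @return a `rating_fit`.
#' @export
fit_between_group <- function(features, summaries_a, summaries_b,
                              predictors = c("dist_neutral_mean", "speed_mean"),
                              response = "mean_arousal", ci_level = 0.95) {
  common <- intersect(summaries_a$clip_id, summaries_b$clip_id)
  if (length(common) < length(predictors) + 2L) {
    stop_facekin("only %d clips rated in both groups; need at least %d",
                 length(common), length(predictors) + 2L)
  }
  a <- summaries_a[match(common, summaries_a$clip_id), ]
  b <- summaries_b[match(common, summaries_b$clip_id), ]
  diff_df <- data.frame(clip_id = common, stringsAsFactors = FALSE)
  diff_df$.diff <- a[[response]] - b[[response]]
  merged <- merge_features_summaries(features, diff_df)
  label <- sprintf("%s difference (%s - %s) ~ %s", response,
                   a$group[1], b$group[1], paste(predictors, collapse = " + "))
  fit_rating_core(merged, predictors, merged$.diff, label, ci_level)
}

#' Single-predictor model
#'
#' As [fit_within_group()] but with one predictor; in the standardized variant
#' the slope equals the Pearson correlation of predictor and response and the
#' model's R-squared equals its square.
#'
#' @inheritParams fit_within_group
#' @param predictor one feature-column name.
#' @return a `rating_fit`.
#' @export
fit_single_predictor <- function(features, summaries, predictor,
                                 response = "mean_arousal", ci_level = 0.95) {
  fit_within_group(features, summaries, predictors = predictor,
                   response = response, ci_level = ci_level)
}

#' Leverage (hat) values of a fit
#'
#' Diagonal of the projection matrix; each value in `(0, 1]`, summing to the
#' number of coefficients, so the mean is `k / n`.
#'
#' @param fit a `rating_fit`.
#' @return numeric vector, one value per observation.
#' @export
hat_values <- function(fit) {
  stopifnot(inherits(fit, "rating_fit"))
  fit$hat
}

#' Flag extreme clips on a predictor by leave-one-out z-distance
#'
#' Observation `i` is flagged when `|x_i - mean(x[-i])| / sd(x[-i])` exceeds
#' `threshold` (default 4). This formalizes the visual identification of
#' separated points in an added-variable plot; the threshold is configurable
#' because any such rule is an approximation of visual judgment.
#'
#' @param features feature table (or any data.frame with `clip_id` and the
#'   predictor column); at least 4 rows.
#' @param predictor feature column to screen.
#' @param threshold leave-one-out z-distance above which a clip is flagged;
#'   `Inf` flags nothing.
#' @param fit optional `rating_fit` on the same clips; if given, its hat
#'   values are attached to the report.
#' @return list of class `outlier_report`: `flagged` (clip ids), `loo_z`
#'   (named vector), `threshold`, `predictor`, `hat`.
#' @export
flag_outliers <- function(features, predictor = "dist_neutral_mean",
                          threshold = 4, fit = NULL) {
  x <- features[[predictor]]
  if (is.null(x)) stop_facekin("no column '%s' in features", predictor)
  n <- length(x)
  if (n < 4L) stop_facekin("outlier screening needs at least 4 observations")
  loo_z <- vapply(seq_len(n), function(i) {
    m <- mean(x[-i]); s <- stats::sd(x[-i])
    if (s == 0) return(Inf * (x[i] != m))
    abs(x[i] - m) / s
  }, numeric(1))
  names(loo_z) <- features$clip_id
  flagged <- features$clip_id[loo_z > threshold]
  hat <- NULL
  if (!is.null(fit)) {
    hat <- stats::setNames(fit$hat, fit$clip_id)[as.character(flagged)]
  }
  structure(list(flagged = as.character(flagged), loo_z = loo_z,
                 threshold = threshold, predictor = predictor, hat = hat),
            class = "outlier_report")
}

#' Re-fit a model excluding flagged clips
#'
#' Repeats the fit on the remaining clips (predictors re-z-scored over the
#' retained set, consistent with z-scoring over the analysis clips) and pairs
#' the original and re-fit coefficients.
#'
#' @param fit a `rating_fit`.
#' @param report an `outlier_report` (or character vector of clip ids).
#' @return list of class `refit_report`: `original` and `refit` (both
#'   `rating_fit`), `excluded`, `comparison` (data.frame of paired
#'   coefficients).
#' @export
refit_excluding <- function(fit, report) {
  stopifnot(inherits(fit, "rating_fit"))
  excluded <- if (inherits(report, "outlier_report")) report$flagged else as.character(report)
  keep <- !(fit$clip_id %in% excluded)
  k <- length(fit$predictors) + 1L
  if (sum(keep) < k + 1L) stop_facekin("too few observations left after exclusion")
  data2 <- fit$data[keep, , drop = FALSE]
  refit <- fit_rating_core(data2, fit$predictors, fit$response[keep],
                           paste0(fit$label, " [outliers excluded]"), fit$ci_level)
  comparison <- data.frame(term = fit$coefficients$term,
                           estimate = fit$coefficients$estimate,
                           estimate_refit = refit$coefficients$estimate,
                           stringsAsFactors = FALSE)
  structure(list(original = fit, refit = refit, excluded = excluded,
                 comparison = comparison),
            class = "refit_report")
}

#' Added-variable (partial regression) data for one predictor
#'
#' Residuals of the response regressed on the other predictors, paired with
#' residuals of the chosen predictor regressed on the other predictors. The
#' OLS slope through these pairs equals the predictor's coefficient in the
#' full model (Frisch-Waugh-Lovell).
#'
#' @param fit a `rating_fit` with at least 2 predictors.
#' @param predictor which predictor to isolate.
#' @return data.frame `clip_id, x_partial, y_partial`, with attribute
#'   `"slope"` (the partial slope).
#' @export
added_variable_data <- function(fit, predictor) {
  stopifnot(inherits(fit, "rating_fit"))
  if (length(fit$predictors) < 2L) {
    stop_facekin("added-variable data needs at least 2 predictors")
  }
  if (!predictor %in% fit$predictors) stop_facekin("'%s' is not in the model", predictor)
  others <- setdiff(fit$predictors, predictor)
  design <- fit$model$model  # contains .y and z-scored predictors
  fml_o <- stats::as.formula(paste("`", predictor, "` ~ ",
                                   paste(sprintf("`%s`", others), collapse = " + "),
                                   sep = ""))
  fml_y <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", others), collapse = " + ")))
  x_partial <- stats::resid(stats::lm(fml_o, data = design))
  y_partial <- stats::resid(stats::lm(fml_y, data = design))
  out <- data.frame(clip_id = fit$clip_id, x_partial = unname(x_partial),
                    y_partial = unname(y_partial), stringsAsFactors = FALSE)
  attr(out, "slope") <- unname(stats::coef(stats::lm(y_partial ~ x_partial))[2])
  out
}

#' Valence-specificity models
#'
#' Repeats the two within-group models and the between-group difference model
#' with mean valence as the response, probing whether the kinematic predictors
#' are arousal-specific.
#'
#' @param features per-clip feature table.
#' @param summaries_a,summaries_b group summaries (e.g. NT and ASD).
#' @inheritParams fit_within_group
#' @return named list of `rating_fit`s: `within_a`, `within_b`, `between`.
#' @export
specificity_models <- function(features, summaries_a, summaries_b,
                               predictors = c("dist_neutral_mean", "speed_mean"),
                               ci_level = 0.95) {
  if (nrow(summaries_a) == 0L || nrow(summaries_b) == 0L) {
    stop_facekin("empty group summaries")
  }
  list(
    within_a = fit_within_group(features, summaries_a, predictors,
                                response = "mean_valence", ci_level = ci_level),
    within_b = fit_within_group(features, summaries_b, predictors,
                                response = "mean_valence", ci_level = ci_level),
    between = fit_between_group(features, summaries_a, summaries_b, predictors,
                                response = "mean_valence", ci_level = ci_level)
  )
}

#' Deterministic dataset with prescribed standardized coefficients
#'
#' Constructs a clip-level dataset (features plus rating summaries) whose
#' standardized OLS fit has *exactly* the requested standardized coefficients
#' and predictor correlation, by Gram-Schmidt construction: two unit-variance
#' predictors with sample correlation `r`, a response assembled from the
#' prescribed signal plus an orthogonal residual scaled so the response has
#' unit sample variance. The fit's R-squared then equals the analytic value
#' `b1^2 + b2^2 + 2*b1*b2*r` (or `b^2` with a single predictor), which makes
#' the function a worked-example generator for validating reported
#' explained-variance figures.
#'
#' @param std_betas standardized coefficients: length 2 (distance, speed) or
#'   length 1 (single predictor).
#' @param r predictor sample correlation (ignored for a single predictor).
#' @param n number of clips (default 80).
#' @param response_center,response_scale affine map from the unit-variance
#'   response to the rating scale (defaults 47.6 and 20).
#' @return list: `features`, `summaries`, `predictors`, `analytic_r_squared`.
#' @export
synthetic_standardized_fit <- function(std_betas, r = 0.51, n = 80L,
                                       response_center = 47.6,
                                       response_scale = 20) {
  k <- length(std_betas)
  stopifnot(k %in% c(1L, 2L), n >= k + 3L)
  if (k == 2L && abs(r) >= 1) stop_facekin("need |r| < 1")
  raw <- cbind(seq_len(n), sin(seq_len(n)), cos(sqrt(2) * seq_len(n)))
  u <- matrix(0, n, 3)
  for (j in 1:3) {
    v <- raw[, j] - mean(raw[, j])
    if (j > 1L) for (i in seq_len(j - 1L)) v <- v - sum(v * u[, i]) / sum(u[, i]^2) * u[, i]
    u[, j] <- v / stats::sd(v)
  }
  if (k == 2L) {
    x1 <- u[, 1]
    x2 <- r * u[, 1] + sqrt(1 - r^2) * u[, 2]
    signal <- std_betas[1] * x1 + std_betas[2] * x2
    r2 <- std_betas[1]^2 + std_betas[2]^2 + 2 * std_betas[1] * std_betas[2] * r
    resid <- u[, 3] * sqrt(1 - r2)
    predictors <- c("dist_neutral_mean", "speed_mean")
    feats <- data.frame(clip_id = sprintf("clip%03d", seq_len(n)),
                        dist_neutral_mean = x1, speed_mean = x2,
                        stringsAsFactors = FALSE)
  } else {
    x1 <- u[, 1]
    signal <- std_betas[1] * x1
    r2 <- std_betas[1]^2
    resid <- u[, 2] * sqrt(1 - r2)
    predictors <- "dist_neutral_mean"
    feats <- data.frame(clip_id = sprintf("clip%03d", seq_len(n)),
                        dist_neutral_mean = x1, stringsAsFactors = FALSE)
  }
  if (r2 >= 1) stop_facekin("standardized coefficients imply R-squared >= 1")
  y <- signal + resid
  summaries <- data.frame(clip_id = feats$clip_id, group = "NT",
                          mean_arousal = response_center + response_scale * y,
                          mean_valence = 51, n_raters = 11L,
                          stringsAsFactors = FALSE)
  list(features = feats, summaries = summaries, predictors = predictors,
       analytic_r_squared = r2)
}

#' Export a set of fits as a tidy coefficient table
#' @param fits named list of `rating_fit`s.
#' @return data.frame with one row per (model, term).
#' @export
fits_to_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    cbind(model = nm, f$coefficients,
          r_squared = f$r_squared, adj_r_squared = f$adj_r_squared,
          sigma = f$sigma, df = f$df_residual, f_statistic = f$f_statistic,
          n = f$n, stringsAsFactors = FALSE)
  }))
}
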