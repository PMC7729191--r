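# Exploratory structure of the eight candidate measures: the Pearson
# correlation matrix, its block structure, and predictor selection.

#' Pearson correlation matrix of the candidate measures
#'
#' @param table feature table: data.frame with the [measure_names()] columns
#'   (a `clip_id` column is ignored); at least 3 rows, every measure with
#'   nonzero variance.
#' @return symmetric `8 x 8` matrix with unit diagonal, rows/columns labelled
#'   by measure.
#' @export
pearson_matrix <- function(table) {
  cols <- intersect(measure_names(), names(table))
  if (length(cols) < 2L) stop_facekin("feature table lacks measure columns")
  m <- as.matrix(table[cols])
  if (nrow(m) < 3L) stop_facekin("need at least 3 clips for a correlation matrix")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop_facekin("measure '%s' has zero variance", cols[which(sds == 0)[1]])
  }
  r <- stats::cor(m)
  diag(r) <- 1
  r
}

#' Correlation blocks of measures
#'
#' Connected components of the graph whose vertices are the measures and whose
#' edges join pairs with `|r| >= threshold`. With the paper-typical structure
#' this splits the eight measures into a distance block and a speed /
#' acceleration block.
#'
#' @param matrix symmetric correlation matrix with labelled dimnames.
#' @param threshold absolute-correlation edge threshold, in `(0, 1)`;
#'   default 0.5 ("moderate to strong").
#' @return list of character vectors (the blocks), each sorted in canonical
#'   measure order; blocks ordered by their first member.
#' @export
correlation_blocks <- function(matrix, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  labels <- colnames(matrix)
  stopifnot(!is.null(labels), isTRUE(all.equal(matrix, t(matrix), tolerance = 1e-8)))
  k <- ncol(matrix)
  adj <- abs(matrix) >= threshold
  diag(adj) <- TRUE
  comp <- rep(NA_integer_, k)
  cid <- 0L
  for (s in seq_len(k)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  canon <- intersect(measure_names(), labels)
  canon <- c(canon, setdiff(labels, canon))
  blocks <- lapply(split(labels, comp), function(b) canon[canon %in% b])
  blocks[order(vapply(blocks, function(b) match(b[1], canon), integer(1)))]
}

#' Select one predictor per correlation block
#'
#' The default policy mirrors the confirmatory analysis: take the
#' mean-aggregated distance-to-clip-neutral measure from the distance block
#' and the mean-aggregated speed measure from the dynamics block. The
#' `aggregation` policy switch selects the max-aggregated variants instead.
#'
#' @param blocks list of measure-name blocks from [correlation_blocks()];
#'   at least 2 blocks.
#' @param aggregation `"mean"` (default) or `"max"`.
#' @return character vector of length 2: the distance predictor and the speed
#'   predictor.
#' @export
select_predictors <- function(blocks, aggregation = c("mean", "max")) {
  aggregation <- match.arg(aggregation)
  if (length(blocks) < 2L) {
    stop_facekin("predictor selection needs at least 2 correlation blocks, got %d",
                 length(blocks))
  }
  dist_name <- paste0("dist_neutral_", aggregation)
  speed_name <- paste0("speed_", aggregation)
  in_block <- function(name) {
    hit <- which(vapply(blocks, function(b) name %in% b, logical(1)))
    if (length(hit) != 1L) stop_facekin("measure '%s' not found in exactly one block", name)
    hit
  }
  bd <- in_block(dist_name)
  bs <- in_block(speed_name)
  if (bd == bs) {
    stop_facekin("'%s' and '%s' fall in the same correlation block; cannot select one per block",
                 dist_name, speed_name)
  }
  c(dist_name, speed_name)
}

#' Write a correlation matrix as CSV
#' @param matrix labelled correlation matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(matrix, path) {
  df <- data.frame(measure = rownames(matrix), matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
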