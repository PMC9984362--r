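# CSV materialization of per-feature score records (the score-plot data).

#' Write feature scores to CSV
#'
#' One row per feature with columns `feature_id`, `dp0`, `dpmod`, `sens`,
#' `auc0`, `aucmod`, `p_value`, `category`. Numeric columns are written with
#' 15 significant digits so a read-back is lossless at double precision.
#'
#' @param scores a `feature_scores` data.frame (see [score_features()]),
#'   or a `selection_result` whose scores will be written.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  if (inherits(scores, "selection_result")) scores <- scores$scores
  stopifnot(is.data.frame(scores), nrow(scores) >= 1L)
  out <- scores
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.15g", x))
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write scores to '%s'", path), call. = FALSE)
  invisible(path)
}

#' Read feature scores from CSV
#'
#' @param path CSV written by [write_scores()].
#' @return a `feature_scores` data.frame.
#' @export
read_scores <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("feature_scores", "data.frame")
  df
}

#' Write a feature matrix to CSV
#'
#' Header row carries the feature names; the first column (`sample_id`) the
#' sample ids.
#'
#' @param fm a [feature_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(sample_id = rownames(fm), as.data.frame(unclass(fm)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path CSV written by [write_feature_matrix()].
#' @return a [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  feature_matrix(m, colnames(m), df[[1]])
}
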