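# Core method: per-feature discriminant power before/after perturbation,
# sensitivity to the perturbation, and multi-threshold selection.

#' Area under the ROC curve of one feature
#'
#' `AUC = P(X2 > X1) + 0.5 * P(X2 = X1)` for values `x1` of class 1 and `x2`
#' of class 2, computed through the midrank Mann-Whitney U statistic
#' (`U / (n1 * n2)`); ties contribute half weight, no continuity correction.
#'
#' @param x1 feature values for class 1 (label 0).
#' @param x2 feature values for class 2 (label 1).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 1L || n2 < 1L) stop("both classes must be non-empty", call. = FALSE)
  if (anyNA(x1) || anyNA(x2) || any(!is.finite(c(x1, x2)))) {
    stop("feature values must be finite", call. = FALSE)
  }
  r <- rank(c(x1, x2), ties.method = "average")
  u <- sum(r[(n1 + 1L):(n1 + n2)]) - n2 * (n2 + 1) / 2
  u / (n1 * n2)
}

#' Discriminant power of one feature
#'
#' `DP = max(AUC, 1 - AUC)`, in `[0.5, 1]`. DP is rank-based, hence invariant
#' under any strictly increasing transform of the feature and under swapping
#' the class labels; high DP means high discriminant capability regardless of
#' the direction of the feature-to-label relationship.
#'
#' @param values feature values across all samples.
#' @param labels binary labels (0 / 1) aligned with `values`.
#' @return list with elements `dp` and `auc`.
#' @export
discriminant_power <- function(values, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) != 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  a <- auc(values[labels == 0L], values[labels == 1L])
  list(dp = max(a, 1 - a), auc = a)
}

#' Sensitivity of a feature to a perturbation
#'
#' Relative change in discriminant power caused by the artifact injection:
#' `SENS = |DPmod - DP0| / DP0`. A robust feature has low SENS; the selection
#' threshold `th_sens` is typically in `[0.05, 0.1]`.
#'
#' @param dp0 DP on the original images, in `[0.5, 1]`.
#' @param dpmod DP on the perturbed images.
#' @return non-negative sensitivity value.
#' @export
sensitivity <- function(dp0, dpmod) {
  if (any(dp0 < 0.5 | dp0 > 1)) {
    stop("dp0 must lie in [0.5, 1]", call. = FALSE)
  }
  abs(dpmod - dp0) / dp0
}

#' Score every feature before and after perturbation
#'
#' For each feature column, computes the discriminant power on the original
#' matrix (`dp0`), on the perturbed matrix (`dpmod`, rows are the perturbed
#' counterparts of the same samples), the sensitivity `sens`, the underlying
#' AUC values, and a pooled two-sample t-test p-value on the original values
#' (reported for reference only; it never participates in selection).
#'
#' @param F0 [feature_matrix()] on the original images.
#' @param Fmod [feature_matrix()] on the perturbed images; must share feature
#'   names and sample alignment with `F0`.
#' @param labels binary labels (0 / 1) aligned with the rows.
#' @return a `feature_scores` data.frame with one row per feature.
#' @export
score_features <- function(F0, Fmod, labels) {
  if (!identical(dim(F0), dim(Fmod)) ||
      !identical(colnames(F0), colnames(Fmod))) {
    stop("F0 and Fmod must share shape and feature names", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(F0)) {
    stop("labels must align with feature matrix rows", call. = FALSE)
  }
  if (length(unique(labels)) != 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  i1 <- labels == 0L; i2 <- labels == 1L
  scores <- lapply(seq_len(ncol(F0)), function(j) {
    a0 <- auc(F0[i1, j], F0[i2, j])
    am <- auc(Fmod[i1, j], Fmod[i2, j])
    dp0 <- max(a0, 1 - a0); dpm <- max(am, 1 - am)
    pv <- if (sd(F0[i1, j]) == 0 && sd(F0[i2, j]) == 0) 1 else
      t.test(F0[i1, j], F0[i2, j], var.equal = TRUE)$p.value
    data.frame(feature_id = colnames(F0)[j], auc0 = a0, aucmod = am,
               dp0 = dp0, dpmod = dpm, sens = sensitivity(dp0, dpm),
               p_value = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, scores)
  class(out) <- c("feature_scores", "data.frame")
  out
}

#' Select features by joint DP / sensitivity thresholds
#'
#' A feature is `selected` when its discriminant power reaches `th_dp` and
#' its sensitivity stays at or below `th_sens`; otherwise it is categorized
#' `high_sens` (too sensitive to the artifact) or `low_dp` (not discriminant
#' enough). Which DP the threshold tests is controlled by `dp_rule`:
#' `"both"` (default) requires `min(dp0, dpmod) >= th_dp`, `"pre"` tests
#' `dp0` only, `"post"` tests `dpmod` only. An empty selection triggers a
#' warning advising different threshold values.
#'
#' @param scores a `feature_scores` data.frame from [score_features()].
#' @param th_dp discriminant-power threshold in `[0.5, 1]` (admissible
#'   working range is about 0.6-0.8).
#' @param th_sens sensitivity threshold, `>= 0` (typically 0.05-0.1).
#' @param dp_rule which DP the `th_dp` test uses, see above.
#' @return a `selection_result`: list with `scores` (with a `category`
#'   column), `th_dp`, `th_sens`, `dp_rule`, `selected_ids`, `n_sel` and
#'   `empty_alert`.
#' @export
select_features <- function(scores, th_dp = 0.6, th_sens = 0.1,
                            dp_rule = c("both", "pre", "post")) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1L)
  dp_rule <- match.arg(dp_rule)
  if (th_dp < 0.5 || th_dp > 1) stop("th_dp must lie in [0.5, 1]", call. = FALSE)
  if (th_sens < 0) stop("th_sens must be >= 0", call. = FALSE)
  dp_test <- switch(dp_rule,
                    both = pmin(scores$dp0, scores$dpmod),
                    pre = scores$dp0,
                    post = scores$dpmod)
  category <- ifelse(dp_test >= th_dp & scores$sens <= th_sens, "selected",
                     ifelse(scores$sens > th_sens, "high_sens", "low_dp"))
  scores$category <- category
  selected_ids <- scores$feature_id[category == "selected"]
  empty <- length(selected_ids) == 0L
  if (empty) {
    warning("empty selection: no feature satisfies the thresholds; ",
            "consider different th_dp / th_sens values", call. = FALSE)
  }
  structure(
    list(scores = scores, th_dp = th_dp, th_sens = th_sens, dp_rule = dp_rule,
         selected_ids = selected_ids, n_sel = length(selected_ids),
         empty_alert = empty),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  tab <- table(factor(x$scores$category,
                      levels = c("selected", "high_sens", "low_dp")))
  cat(sprintf("<selection_result> th_dp %.3g, th_sens %.3g (%s): %d selected, %d high_sens, %d low_dp\n",
              x$th_dp, x$th_sens, x$dp_rule, tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Run the full selection over all tests of a modality
#'
#' Extracts features on the original set once, then for each of the
#' modality's three artifact tests: perturbs the set, extracts features on
#' the perturbed images, scores, and selects. The per-test selections are the
#' primary output; the intersection of the three selected sets is reported as
#' the overall robust set.
#'
#' @param set an [image_set()].
#' @param settings a `robusel_settings` object.
#' @param extractor function mapping an `image_set` to a [feature_matrix()];
#'   defaults to [extract_handcrafted()] with intensity and Haralick
#'   features (or to the configured deep backend when
#'   `settings$feature_mode == "deep"`).
#' @param test_ids which tests to run (default all three).
#' @return a `modality_result`: list with `per_test` (named list of
#'   `selection_result`s), `intersection` (character vector of feature ids
#'   selected in every test), `draw_logs`, and `F0`.
#' @export
run_modality <- function(set, settings, extractor = NULL, test_ids = 1:3) {
  stopifnot(inherits(set, "image_set"))
  settings <- validate_settings(settings)
  if (is.null(extractor)) {
    extractor <- if (identical(settings$feature_mode, "deep")) {
      backend <- get_backend(settings$network_name, settings$layer_name)
      function(s) extract_deep(s, backend)
    } else {
      function(s) extract_handcrafted(s)
    }
  }
  F0 <- extractor(set)
  per_test <- list(); draw_logs <- list()
  for (tid in test_ids) {
    pert <- perturb_dataset(set, settings, tid)
    Fmod <- extractor(pert$set)
    sc <- score_features(F0, Fmod, set$labels)
    per_test[[paste0("test", tid)]] <-
      select_features(sc, settings$th_dp, settings$th_sens, settings$dp_rule)
    draw_logs[[paste0("test", tid)]] <- pert$draw_log
  }
  intersection <- Reduce(intersect, lapply(per_test, `[[`, "selected_ids"))
  structure(
    list(per_test = per_test, intersection = intersection,
         draw_logs = draw_logs, F0 = F0, labels = set$labels,
         settings = settings),
    class = "modality_result"
  )
}

#' @export
print.modality_result <- function(x, ...) {
  ns <- vapply(x$per_test, `[[`, 0L, "n_sel")
  cat(sprintf("<modality_result> %s: n_sel per test [%s], intersection %d\n",
              x$settings$modality, paste(ns, collapse = ", "),
              length(x$intersection)))
  invisible(x)
}
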