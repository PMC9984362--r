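# Classical feature-ranking baselines and the comparison protocol: rank by a
# class-separability criterion on the ORIGINAL images, keep the top N_sel
# (N_sel taken from the robust selection), then measure how those features
# behave on the perturbed images.

ranking_methods <- c("ttest", "entropy", "bhattacharyya", "wilcoxon", "roc")

# Class-conditional moments with a variance floor for degenerate features.
class_moments <- function(x, i1, i2, eps = 1e-12) {
  list(m1 = mean(x[i1]), m2 = mean(x[i2]),
       v1 = max(var(x[i1]), eps), v2 = max(var(x[i2]), eps))
}

#' Rank features by a classical separability criterion
#'
#' Implements the five ranking criteria used as comparison baselines:
#' * `ttest` - absolute two-sample t statistic with pooled variance;
#' * `entropy` - symmetrized Kullback-Leibler divergence between the
#'   class-conditional Gaussian fits;
#' * `bhattacharyya` - Gaussian Bhattacharyya distance (Chernoff-bound
#'   family), `(m1 - m2)^2 / (4 (v1 + v2)) + log((v1 + v2) / (2 sqrt(v1 v2))) / 2`;
#' * `wilcoxon` - absolute standardized Mann-Whitney U statistic;
#' * `roc` - area between the empirical ROC curve and the chance diagonal,
#'   `|AUC - 0.5|`.
#'
#' Gaussian criteria use sample means/variances with a variance floor of
#' `1e-12` for degenerate (constant) features. Features are sorted by
#' decreasing criterion; ties are broken by feature index.
#'
#' @param F a [feature_matrix()].
#' @param labels binary labels (0 / 1) aligned with rows.
#' @param method one of `"ttest"`, `"entropy"`, `"bhattacharyya"`,
#'   `"wilcoxon"`, `"roc"`.
#' @return a `ranking_result`: list with `method`, `ranked_ids` (all feature
#'   ids, best first) and `criterion_values` (named, in feature order).
#' @export
rank_features <- function(F, labels, method = ranking_methods) {
  method <- match.arg(method)
  labels <- as.integer(labels)
  if (length(unique(labels)) != 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  i1 <- labels == 0L; i2 <- labels == 1L
  n1 <- sum(i1); n2 <- sum(i2)
  crit <- vapply(seq_len(ncol(F)), function(j) {
    x <- F[, j]
    switch(method,
      ttest = {
        mo <- class_moments(x, i1, i2)
        sp2 <- ((n1 - 1) * mo$v1 + (n2 - 1) * mo$v2) / (n1 + n2 - 2)
        abs(mo$m1 - mo$m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
      },
      entropy = {
        mo <- class_moments(x, i1, i2)
        d2 <- (mo$m1 - mo$m2)^2
        0.5 * (mo$v1 / mo$v2 + mo$v2 / mo$v1 - 2 +
                 d2 * (1 / mo$v1 + 1 / mo$v2))
      },
      bhattacharyya = {
        mo <- class_moments(x, i1, i2)
        vb <- (mo$v1 + mo$v2) / 2
        (mo$m1 - mo$m2)^2 / (8 * vb) + 0.5 * log(vb / sqrt(mo$v1 * mo$v2))
      },
      wilcoxon = {
        a <- auc(x[i1], x[i2])
        u <- a * n1 * n2
        abs(u - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
      },
      roc = abs(auc(x[i1], x[i2]) - 0.5)
    )
  }, 0)
  names(crit) <- colnames(F)
  ord <- order(-crit, seq_along(crit))
  structure(list(method = method, ranked_ids = colnames(F)[ord],
                 selected_ids = NULL, criterion_values = crit),
            class = "ranking_result")
}

#' Forward-backward stepwise linear regression selection
#'
#' Fits a linear regression of the 0/1 label on the features by classical
#' stepwise selection: at each iteration the candidate with the smallest
#' partial-F p-value below `p_enter` is added, then any included feature
#' whose p-value rises above `p_remove` is removed; iteration stops at a
#' fixpoint. Deterministic given the column order; may return an empty set.
#'
#' @param F a [feature_matrix()].
#' @param labels binary labels (0 / 1).
#' @param p_enter entry p-value threshold (default 0.05).
#' @param p_remove removal p-value threshold (default 0.10).
#' @param max_steps safety cap on iterations.
#' @return a `ranking_result` with `selected_ids` (in inclusion order) and
#'   `ranked_ids = selected_ids`.
#' @export
stepwise_select <- function(F, labels, p_enter = 0.05, p_remove = 0.10,
                            max_steps = 200L) {
  y <- as.numeric(labels)
  n <- nrow(F)
  if (n <= 2L) stop("need more than 2 samples", call. = FALSE)
  X <- unclass(F)
  included <- character()
  rss_of <- function(vars) {
    if (length(vars) == 0L) return(list(rss = sum((y - mean(y))^2), df = n - 1L))
    fit <- stats::lm.fit(cbind(1, X[, vars, drop = FALSE]), y)
    list(rss = sum(fit$residuals^2), df = n - fit$rank)
  }
  partial_f_p <- function(rss_small, df_small, rss_big, df_big) {
    ddf <- df_small - df_big
    if (ddf <= 0 || rss_big <= 0) return(1)
    f <- ((rss_small - rss_big) / ddf) / (rss_big / df_big)
    pf(f, ddf, df_big, lower.tail = FALSE)
  }
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    base <- rss_of(included)
    # forward: best candidate below p_enter
    cand <- setdiff(colnames(X), included)
    if (length(cand) > 0L && base$df > 1L) {
      pvals <- vapply(cand, function(v) {
        fit <- rss_of(c(included, v))
        partial_f_p(base$rss, base$df, fit$rss, fit$df)
      }, 0)
      best <- which.min(pvals)
      if (pvals[best] < p_enter) {
        included <- c(included, cand[best])
        changed <- TRUE
      }
    }
    # backward: drop any included feature above p_remove
    if (length(included) > 0L) {
      full <- rss_of(included)
      pdrop <- vapply(included, function(v) {
        fit <- rss_of(setdiff(included, v))
        partial_f_p(fit$rss, fit$df, full$rss, full$df)
      }, 0)
      worst <- which.max(pdrop)
      if (pdrop[worst] > p_remove) {
        included <- setdiff(included, included[worst])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(list(method = "stepwise", ranked_ids = included,
                 selected_ids = included, criterion_values = NULL),
            class = "ranking_result")
}

#' Evaluate a baseline ranking under the comparison protocol
#'
#' Keeps the ranking's first `n_sel` features (for stepwise, its own selected
#' set), scores them on the original/perturbed pair with [score_features()],
#' and summarizes the sensitivity and post-perturbation DP of the kept
#' features (the mean and standard deviation reported in the comparison
#' tables).
#'
#' @param F0,Fmod original and perturbed [feature_matrix()]s.
#' @param labels binary labels (0 / 1).
#' @param ranking a `ranking_result`.
#' @param n_sel number of features to keep (the robust selection's `n_sel`).
#' @return list with `kept_ids`, `scores`, `mean_sens`, `sd_sens`,
#'   `mean_dpmod`, `sd_dpmod`.
#' @export
evaluate_ranking <- function(F0, Fmod, labels, ranking, n_sel) {
  stopifnot(inherits(ranking, "ranking_result"))
  if (identical(ranking$method, "stepwise")) {
    kept <- ranking$selected_ids
  } else {
    if (n_sel < 1L) stop("n_sel must be >= 1", call. = FALSE)
    if (n_sel > length(ranking$ranked_ids)) {
      stop("n_sel exceeds the number of ranked features", call. = FALSE)
    }
    kept <- ranking$ranked_ids[seq_len(n_sel)]
  }
  if (length(kept) == 0L) stop("empty feature set to evaluate", call. = FALSE)
  sc <- score_features(F0[, kept, drop = FALSE], Fmod[, kept, drop = FALSE],
                       labels)
  list(kept_ids = kept, scores = sc,
       mean_sens = mean(sc$sens), sd_sens = sd(sc$sens),
       mean_dpmod = mean(sc$dpmod), sd_dpmod = sd(sc$dpmod))
}
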