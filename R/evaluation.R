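# Downstream classification harness: linear SVM on selected features,
# discriminancy-threshold sweep, repeated stratified hold-out.

f1_score <- function(truth, pred) {
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  if (tp + fp + fn == 0L) return(1)   # no positives anywhere: vacuously perfect
  if (tp == 0L) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Train and evaluate a linear SVM on one split
#'
#' Features are standardized by the training-set mean and standard deviation
#' (unit-variance floor for constant columns), then fed to a linear-kernel
#' maximum-margin classifier with fixed regularization `C = 1`. Reports
#' accuracy, F1 on the positive class (label 1), and the AUC of the decision
#' scores on the test split.
#'
#' @param Ftrain,Ftest feature matrices; `Ftest` columns must contain the
#'   training feature names (extra columns are dropped, order is aligned).
#' @param ytrain,ytest binary labels (0 / 1).
#' @param cost SVM regularization constant (default 1).
#' @return list with `acc`, `f1`, `auc`.
#' @export
train_eval <- function(Ftrain, ytrain, Ftest, ytest, cost = 1) {
  ytrain <- as.integer(ytrain); ytest <- as.integer(ytest)
  if (length(unique(ytrain)) != 2L) {
    stop("both classes must be present in the training labels", call. = FALSE)
  }
  if (!all(colnames(Ftrain) %in% colnames(Ftest))) {
    stop("test features must contain the training feature names", call. = FALSE)
  }
  Ftest <- Ftest[, colnames(Ftrain), drop = FALSE]
  mu <- colMeans(Ftrain)
  sg <- apply(Ftrain, 2, sd)
  sg[sg == 0] <- 1
  Ztr <- sweep(sweep(unclass(Ftrain), 2, mu), 2, sg, "/")
  Zte <- sweep(sweep(unclass(Ftest), 2, mu), 2, sg, "/")
  fit <- e1071::svm(Ztr, factor(ytrain, levels = c(0L, 1L)),
                    kernel = "linear", cost = cost, scale = FALSE)
  pred <- predict(fit, Zte, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # orient decision scores so that larger means class "1"
  score <- if (colnames(dv)[1] == "0/1") -dv[, 1] else dv[, 1]
  acc <- mean(as.integer(as.character(pred)) == ytest)
  f1 <- f1_score(ytest, as.integer(as.character(pred)))
  a <- if (length(unique(ytest)) == 2L)
    auc(score[ytest == 0L], score[ytest == 1L]) else NA_real_
  list(acc = acc, f1 = f1, auc = a)
}

# One end-to-end run: robust selection on the training set for one artifact
# test, SVM on the selected features, evaluation on a (perturbed) test set;
# plus the no-selection baseline on all features.
run_selected_eval <- function(train_set, test_set, settings, test_id,
                              th_dp = settings$th_dp, extractor = NULL,
                              perturb_test = TRUE, test_seed = NULL) {
  if (is.null(extractor)) extractor <- function(s) extract_handcrafted(s)
  F0 <- extractor(train_set)
  pert_tr <- perturb_dataset(train_set, settings, test_id)
  Fmod <- extractor(pert_tr$set)
  sc <- score_features(F0, Fmod, train_set$labels)
  sel <- withCallingHandlers(
    select_features(sc, th_dp, settings$th_sens, settings$dp_rule),
    warning = function(w) invokeRestart("muffleWarning"))

  test_eval_set <- if (perturb_test) {
    perturb_dataset(test_set, settings, test_id,
                    seed = if (is.null(test_seed))
                      derive_seed(settings$seed, test_id, salt = 1L)
                    else test_seed)$set
  } else test_set
  Fte <- extractor(test_eval_set)

  baseline <- train_eval(F0, train_set$labels, Fte, test_set$labels)
  selected <- if (sel$n_sel > 0L) {
    train_eval(F0[, sel$selected_ids, drop = FALSE], train_set$labels,
               Fte, test_set$labels)
  } else list(acc = NA_real_, f1 = NA_real_, auc = NA_real_)
  list(selection = sel, selected = selected, baseline = baseline)
}

#' Sweep the discriminancy threshold and evaluate downstream classification
#'
#' For each `th_dp` in the grid: run the robust selection on the training set
#' (one artifact test), train a linear SVM on the selected features of the
#' original training images, and evaluate on the independent test set
#' perturbed by the same artifact test (drawn from an independent seed
#' stream). The no-selection baseline (all features) is evaluated alongside.
#' An empty selection at some grid point is flagged; the baseline is still
#' computed there.
#'
#' @param train_set,test_set [image_set()]s.
#' @param settings a `robusel_settings` object.
#' @param grid `th_dp` grid; default `seq(0.5, 0.7, by = 0.05)` (5 points).
#' @param test_id which artifact test to use (default 1).
#' @param extractor optional feature extractor, as in [run_modality()].
#' @return data.frame with one row per grid point: `th_dp`, `n_sel`,
#'   `empty`, train/test metrics for the selected features and the
#'   no-selection baseline.
#' @export
threshold_sweep <- function(train_set, test_set, settings,
                            grid = seq(0.5, 0.7, by = 0.05), test_id = 1L,
                            extractor = NULL) {
  if (length(grid) == 0L || any(grid < 0.5 | grid > 1)) {
    stop("grid must be non-empty within [0.5, 1]", call. = FALSE)
  }
  rows <- lapply(grid, function(th) {
    r <- run_selected_eval(train_set, test_set, settings, test_id, th_dp = th,
                           extractor = extractor)
    data.frame(th_dp = th, n_sel = r$selection$n_sel,
               empty = r$selection$empty_alert,
               acc = r$selected$acc, f1 = r$selected$f1, auc = r$selected$auc,
               acc_nosel = r$baseline$acc, f1_nosel = r$baseline$f1,
               auc_nosel = r$baseline$auc)
  })
  do.call(rbind, rows)
}

#' Repeated stratified hold-out evaluation
#'
#' Splits the set into stratified random train/test partitions `n_rep` times;
#' on each repetition runs the robust selection on the training split, trains
#' the linear SVM on the selected features, perturbs the test split with an
#' independent seed stream, and reports ACC / F1 / AUC for the selected
#' features and for the no-selection baseline. Fully reproducible from
#' `seed`.
#'
#' @param set an [image_set()].
#' @param settings a `robusel_settings` object.
#' @param test_id which artifact test to use.
#' @param n_rep number of repetitions (default 10).
#' @param train_frac training fraction in (0, 1) (default 0.7).
#' @param seed seed for the split and perturbation streams; defaults to
#'   `settings$seed`.
#' @param extractor optional feature extractor.
#' @return a `classifier_report`: list with `per_rep` (data.frame, one row
#'   per repetition) and `summary` (means and standard deviations).
#' @export
holdout_repeats <- function(set, settings, test_id = 1L, n_rep = 10L,
                            train_frac = 0.7, seed = NULL, extractor = NULL) {
  stopifnot(inherits(set, "image_set"))
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must be strictly between 0 and 1", call. = FALSE)
  }
  if (min(table(set$labels)) < 2L) {
    stop("each class needs at least 2 samples for a stratified split",
         call. = FALSE)
  }
  if (is.null(seed)) seed <- settings$seed
  idx1 <- which(set$labels == 0L); idx2 <- which(set$labels == 1L)
  n1_tr <- max(1L, round(train_frac * length(idx1)))
  n2_tr <- max(1L, round(train_frac * length(idx2)))
  if (n1_tr >= length(idx1) || n2_tr >= length(idx2)) {
    stop("train_frac leaves an empty test split", call. = FALSE)
  }
  rows <- lapply(seq_len(n_rep), function(rep) {
    split <- with_local_seed(derive_seed(seed, test_id, salt = rep), {
      list(tr = c(sample(idx1, n1_tr), sample(idx2, n2_tr)))
    })
    tr <- sort(split$tr)
    te <- setdiff(seq_along(set$labels), tr)
    r <- run_selected_eval(set[tr], set[te], settings, test_id,
                           extractor = extractor,
                           test_seed = derive_seed(seed, test_id,
                                                   salt = 1000L + rep))
    data.frame(rep = rep, n_sel = r$selection$n_sel,
               acc = r$selected$acc, f1 = r$selected$f1, auc = r$selected$auc,
               acc_nosel = r$baseline$acc, f1_nosel = r$baseline$f1,
               auc_nosel = r$baseline$auc)
  })
  per_rep <- do.call(rbind, rows)
  summ <- c(colMeans(per_rep[, -1], na.rm = TRUE),
            stats::setNames(apply(per_rep[, -1], 2, sd, na.rm = TRUE),
                            paste0("sd_", colnames(per_rep)[-1])))
  structure(list(per_rep = per_rep, summary = as.list(summ),
                 n_rep = n_rep, train_frac = train_frac, test_id = test_id),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %d reps | mean test AUC %.3f (selected) vs %.3f (no selection)\n",
              x$n_rep, x$summary$auc, x$summary$auc_nosel))
  invisible(x)
}
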