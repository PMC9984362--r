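make_planted_matrix <- function(n_per_class = 30, n_noise = 5, seed = 21) {
  set.seed(seed)
  labels <- rep(0:1, each = n_per_class)
  X <- matrix(rnorm(2 * n_per_class * (n_noise + 1)), 2 * n_per_class)
  X[, 1] <- labels + rnorm(2 * n_per_class, sd = 0.05)   # near-perfect signal
  colnames(X) <- c("signal", sprintf("noise%d", seq_len(n_noise)))
  list(F = feature_matrix(X, sample_ids = sprintf("s%03d", seq_len(nrow(X)))),
       labels = labels)
}

test_that("a label-equal feature ranks first under every criterion", {
  d <- make_planted_matrix()
  for (m in c("ttest", "entropy", "bhattacharyya", "wilcoxon", "roc")) {
    rk <- rank_features(d$F, d$labels, m)
    expect_identical(rk$ranked_ids[1], "signal", label = m)
    expect_setequal(rk$ranked_ids, colnames(d$F))
  }
})

test_that("pooled t statistic matches the hand formula on a worked 6-sample array", {
  x <- c(1, 2, 3); y <- c(2, 4, 6)
  F <- feature_matrix(cbind(f = c(x, y)), sample_ids = letters[1:6])
  labels <- rep(0:1, each = 3)
  sp2 <- ((3 - 1) * var(x) + (3 - 1) * var(y)) / (6 - 2)
  t_manual <- abs(mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  rk <- rank_features(F, labels, "ttest")
  expect_equal(unname(rk$criterion_values["f"]), t_manual, tolerance = 1e-12)
  expect_equal(t_manual, abs(unname(t.test(x, y, var.equal = TRUE)$statistic)),
               tolerance = 1e-12)
})

test_that("gaussian bhattacharyya matches its equal-variance closed form", {
  set.seed(22)
  n <- 50
  base <- rnorm(n)
  # class 2 = class 1 + delta: sample variances are exactly equal
  for (delta in c(1, 3)) {
    F <- feature_matrix(cbind(f = c(base, base + delta)),
                        sample_ids = sprintf("s%02d", 1:(2 * n)))
    rk <- rank_features(F, rep(0:1, each = n), "bhattacharyya")
    expect_equal(unname(rk$criterion_values["f"]), delta^2 / (8 * var(base)),
                 tolerance = 1e-12)
  }
})

test_that("wilcoxon criterion equals the standardized U from pair counting", {
  set.seed(23)
  x1 <- sample(1:10, 12, TRUE); x2 <- sample(1:10, 15, TRUE)
  F <- feature_matrix(cbind(f = c(x1, x2)), sample_ids = sprintf("s%02d", 1:27))
  rk <- rank_features(F, rep(0:1, c(12, 15)), "wilcoxon")
  u <- sum(outer(x1, x2, function(a, b) (b > a) + 0.5 * (b == a)))
  z <- abs(u - 12 * 15 / 2) / sqrt(12 * 15 * (12 + 15 + 1) / 12)
  expect_equal(unname(rk$criterion_values["f"]), z, tolerance = 1e-12)
})

test_that("roc ranking order equals ordering by dp0", {
  set.seed(24)
  n <- 20
  labels <- rep(0:1, each = n)
  X <- matrix(rnorm(2 * n * 6), 2 * n)
  X <- X + outer(labels, seq(0, 1, length.out = 6))
  colnames(X) <- sprintf("f%d", 1:6)
  F <- feature_matrix(X, sample_ids = sprintf("s%02d", 1:(2 * n)))
  rk <- rank_features(F, labels, "roc")
  sc <- score_features(F, F, labels)
  expect_equal(unname(rk$criterion_values), sc$dp0 - 0.5, tolerance = 1e-12)
  expect_identical(rk$ranked_ids,
                   sc$feature_id[order(-(sc$dp0), seq_len(6))])
})

test_that("monotone transforms preserve rank-based but not gaussian criteria", {
  d <- make_planted_matrix(seed = 25)
  Fexp <- feature_matrix(exp(unclass(d$F)), sample_ids = rownames(d$F))
  for (m in c("wilcoxon", "roc")) {
    expect_equal(rank_features(Fexp, d$labels, m)$criterion_values,
                 rank_features(d$F, d$labels, m)$criterion_values,
                 tolerance = 1e-12, label = m)
  }
  expect_false(isTRUE(all.equal(
    rank_features(Fexp, d$labels, "ttest")$criterion_values,
    rank_features(d$F, d$labels, "ttest")$criterion_values)))
})

test_that("stepwise recovers a planted linear signal and prunes duplicates", {
  set.seed(26)
  n <- 100
  X <- matrix(rnorm(n * 6), n)
  colnames(X) <- sprintf("f%d", 1:6)
  y <- as.integer(X[, 3] + rnorm(n, sd = 0.3) > 0)
  F <- feature_matrix(X, sample_ids = sprintf("s%03d", 1:n))
  rk <- stepwise_select(F, y)
  expect_true("f3" %in% rk$selected_ids)

  # duplicated copy of the informative feature: at most one of the pair kept
  Xd <- cbind(X, f3copy = X[, 3])
  Fd <- feature_matrix(Xd, sample_ids = sprintf("s%03d", 1:n))
  rkd <- stepwise_select(Fd, y)
  expect_lte(sum(c("f3", "f3copy") %in% rkd$selected_ids), 1L)
})

test_that("stepwise on pure noise stays (near) empty", {
  count <- vapply(1:10, function(i) {
    set.seed(100 + i)
    X <- matrix(rnorm(100 * 8), 100)
    colnames(X) <- sprintf("f%d", 1:8)
    F <- feature_matrix(X, sample_ids = sprintf("s%03d", 1:100))
    length(stepwise_select(F, rep(0:1, each = 50))$selected_ids)
  }, 0L)
  expect_lte(mean(count), 1)
})

test_that("the comparison protocol reproduces the selection's own summary", {
  set.seed(27)
  n <- 30
  labels <- rep(0:1, each = n)
  X <- matrix(rnorm(2 * n * 5), 2 * n) + outer(labels, c(2, 1.5, 1, 0.5, 0))
  colnames(X) <- sprintf("f%d", 1:5)
  F0 <- feature_matrix(X, sample_ids = sprintf("s%02d", 1:(2 * n)))
  Fmod <- feature_matrix(X + matrix(rnorm(2 * n * 5, sd = 0.5), 2 * n),
                         sample_ids = rownames(F0))
  sc <- score_features(F0, Fmod, labels)
  sel <- suppressWarnings(select_features(sc, 0.6, 0.5))
  own_rank <- structure(list(method = "own", ranked_ids = sel$selected_ids,
                            selected_ids = sel$selected_ids),
                       class = "ranking_result")
  ev <- evaluate_ranking(F0, Fmod, labels, own_rank, sel$n_sel)
  own <- sc[sc$feature_id %in% sel$selected_ids, ]
  expect_equal(ev$mean_sens, mean(own$sens), tolerance = 1e-12)
  expect_equal(ev$mean_dpmod, mean(own$dpmod), tolerance = 1e-12)

  # n_sel = all features: grand means over every score
  rk <- rank_features(F0, labels, "roc")
  ev_all <- evaluate_ranking(F0, Fmod, labels, rk, 5L)
  expect_equal(ev_all$mean_dpmod, mean(sc$dpmod), tolerance = 1e-12)
  expect_error(evaluate_ranking(F0, Fmod, labels, rk, 0L), "n_sel")
})
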