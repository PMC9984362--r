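test_that("every operator is the exact identity at its identity parameters", {
  img <- fixture_image(15, 13)
  expect_identical(apply_brightness(img, 1, 0, 0), img)
  expect_identical(apply_stage_shift(img, 0, 0), img)
  expect_identical(apply_defocus(img, 0), img)
  expect_identical(apply_local_defocus(img, radius = 0, sigma = 2), img)
  expect_identical(apply_local_defocus(img, radius = 5, sigma = 0), img)
  expect_identical(apply_gel_texture(img, amplitude = 0), img)
  expect_identical(apply_autofluorescence(img, amplitude = 0), img)
  expect_identical(apply_photobleach(img, 1), img)
  expect_identical(apply_saturate(img, 1), img)
})

test_that("outputs stay in [0, 1] and inputs are untouched", {
  img <- fixture_image(20, 20)
  orig <- img + 0
  ops <- list(
    function(x) apply_brightness(x, 1.4, 0.2, 0.3),
    function(x) apply_stage_shift(x, 4, -3),
    function(x) apply_defocus(x, 2.5),
    function(x) apply_local_defocus(x, c(10, 10), 6, 2),
    function(x) apply_gel_texture(x, 0.08, 3, seed = 1),
    function(x) apply_autofluorescence(x, 0.3, 5, seed = 2),
    function(x) apply_photobleach(x, 0.5),
    function(x) apply_saturate(x, 1.8)
  )
  for (f in ops) {
    out <- f(img)
    expect_identical(dim(out), dim(img))
    expect_true(min(out) >= 0 && max(out) <= 1)
    expect_identical(img, orig)
  }
})

test_that("brightness acts affinely: constants map exactly, means transform", {
  out <- apply_brightness(matrix(0.4, 5, 5), gain = 1.5, offset = 0.05)
  expect_equal(out, matrix(0.65, 5, 5), tolerance = 1e-12)
  # no clipping, no gradient: mean(out) = gain * mean(in) + offset
  img <- fixture_image() * 0.4 + 0.2
  out2 <- apply_brightness(img, 1.2, 0.05)
  expect_equal(mean(out2), 1.2 * mean(img) + 0.05, tolerance = 1e-12)
  # lateral gradient: leftmost column darker than rightmost for positive slope
  out3 <- apply_brightness(matrix(0.5, 8, 8), gradient_slope = 0.4)
  expect_lt(mean(out3[, 1]), mean(out3[, 8]))
  expect_error(apply_brightness(img, gain = 0), "gain")
  expect_error(apply_brightness(img, gain = NA), "finite")
})

test_that("stage shift translates content and preserves the interior histogram", {
  z <- matrix(0, 11, 11); z[6, 6] <- 1
  expect_equal(apply_stage_shift(z, 2, 3)[8, 9], 1)
  img <- fixture_image(30, 30)
  sh <- apply_stage_shift(img, 3, -2)
  # interior of the shifted image is a copy of the source sub-window
  expect_identical(sh[4:30, 1:28], img[1:27, 3:30])
})

test_that("defocus preserves blob mass and never increases variance", {
  blob <- matrix(0, 41, 41); blob[17:25, 17:25] <- 0.6
  out <- apply_defocus(blob, 2)
  expect_lt(abs(sum(out) - sum(blob)) / sum(blob), 0.001)
  img <- fixture_image(32, 32)
  v <- vapply(c(0, 1, 2, 4), function(s) var(as.vector(apply_defocus(img, s))), 0)
  expect_true(all(diff(v) <= 1e-12))
})

test_that("local defocus only touches the masked disk", {
  img <- fixture_image(40, 40)
  out <- apply_local_defocus(img, center = c(20, 20), radius = 6, sigma = 2)
  rr <- matrix(seq_len(40), 40, 40)
  cc <- t(rr)
  far <- sqrt((rr - 20)^2 + (cc - 20)^2) > 1.5 * 6
  expect_identical(out[far], img[far])
  inside <- sqrt((rr - 20)^2 + (cc - 20)^2) <= 6
  expect_lte(var(out[inside]), var(img[inside]))
})

test_that("gel texture adds a zero-mean field of the requested amplitude", {
  img <- matrix(0.5, 64, 64)
  out <- apply_gel_texture(img, amplitude = 0.03, correlation_length = 3, seed = 9)
  added <- out - img
  expect_lt(abs(mean(added)), 3 * 0.03 / sqrt(length(img)) + 1e-6)
  expect_equal(sd(as.vector(added)), 0.03, tolerance = 1e-6)
  # longer correlation length -> wider spatial autocorrelation of the field
  acor_width <- function(len) {
    f <- apply_gel_texture(img, 0.03, len, seed = 11) - img
    cor(as.vector(f[, -1]), as.vector(f[, -64]))
  }
  expect_gt(acor_width(8), acor_width(1))
})

test_that("autofluorescence adds a non-negative background peaking at amplitude", {
  out0 <- apply_autofluorescence(matrix(0, 48, 48), 0.07, scale = 8, seed = 3)
  expect_equal(max(out0), 0.07, tolerance = 1e-12)
  expect_true(min(out0) >= 0)
  img <- fixture_image(48, 48) * 0.5
  out <- apply_autofluorescence(img, 0.07, scale = 8, seed = 3)
  expect_true(min(out) >= min(img))
  expect_gte(quantile(out, 0.25), quantile(img, 0.25))
  # RGB input: only the green plane changes
  rgb <- array(0.2, c(16, 16, 3))
  outc <- apply_autofluorescence(rgb, 0.1, scale = 4, seed = 5)
  expect_identical(outc[, , 1], rgb[, , 1])
  expect_identical(outc[, , 3], rgb[, , 3])
  expect_gt(mean(outc[, , 2]), 0.2)
})

test_that("photobleach scales every statistic exactly by the factor", {
  img <- matrix(c(0.1, 0.3, 0.5, 0.7, 0.9, 0.2, 0.4, 0.6, 0.8,
                  0.15, 0.25, 0.35, 0.45, 0.55, 0.65, 0.75, 0.85, 0.95,
                  0.05, 0.12, 0.22, 0.32, 0.42, 0.52, 0.62), 5, 5)
  out <- apply_photobleach(img, 0.7)
  expect_equal(mean(out), 0.7 * mean(img), tolerance = 1e-12)
  expect_equal(sum(out), 0.7 * sum(img), tolerance = 1e-12)
  for (p in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    expect_equal(quantile(out, p, names = FALSE),
                 0.7 * quantile(img, p, names = FALSE), tolerance = 1e-12)
  }
  expect_true(all(apply_photobleach(img, 0) == 0))
})

test_that("saturation clips exactly the pixels above 1/gain and is monotone", {
  img <- fixture_image(25, 25)
  out <- apply_saturate(img, 1.4)
  expect_equal(mean(out == 1), mean(img >= 1 / 1.4), tolerance = 1e-12)
  out_small <- pmin(pmax(1.2 * img, 0), 1)
  expect_true(all(out >= out_small))
})

test_that("dataset perturbation is seeded, label-preserving and replayable", {
  set <- fixture_set(n_per_class = 5)
  s <- default_settings("IM-ACQ-1", seed = 11L)
  r1 <- perturb_dataset(set, s, 1)
  r2 <- perturb_dataset(set, s, 1)
  expect_identical(r1$set$images, r2$set$images)
  expect_identical(r1$draw_log, r2$draw_log)
  expect_identical(r1$set$labels, set$labels)
  expect_identical(r1$set$ids, set$ids)
  expect_length(r1$set$images, 10L)
  expect_equal(nrow(r1$draw_log), 10L)
  # different seed, different draws
  r3 <- perturb_dataset(set, default_settings("IM-ACQ-1", seed = 12L), 1)
  expect_false(identical(r1$set$images, r3$set$images))
  # invalid pairing
  expect_error(perturb_dataset(set, s, 4), "test_id")
})

test_that("degenerate identity ranges reproduce the input for every test", {
  for (modality in names(modality_tests)) {
    set <- fixture_set(n_per_class = 2, modality_hint = modality)
    s <- identity_settings(modality)
    for (tid in 1:3) {
      expect_identical(perturb_dataset(set, s, tid)$set$images, set$images,
                       label = paste(modality, "test", tid))
    }
  }
})

test_that("rank-preserving operators leave the DP of monotone intensity features unchanged", {
  set <- fixture_set(n_per_class = 8)
  s <- default_settings("IM-ACQ-3",
                        photobleach.factor = c(0.6, 0.6))
  F0 <- extract_handcrafted(set, include = "intensity")
  pert <- perturb_dataset(set, s, 2)  # photobleach
  Fmod <- extract_handcrafted(pert$set, include = "intensity")
  sc <- score_features(F0, Fmod, set$labels)
  mono <- c("int.mean", "int.median", "int.min", "int.p10", "int.p25",
            "int.p75", "int.p90", "int.max", "int.total")
  expect_equal(sc$dpmod[match(mono, sc$feature_id)],
               sc$dp0[match(mono, sc$feature_id)], tolerance = 1e-12)
})
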