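# Synthetic two-class microscopy-like crops with a planted robust signal
# (blob size and internal texture) and a planted fragile confound
# (class-correlated global brightness), plus ground-truth scoring of
# selection quality.

#' Generate a synthetic two-class image set with a planted confound
#'
#' Each crop is a dark background plus one centered soft-edged elliptical
#' blob. The class signal is planted twice over:
#' * robust: class 2 blobs are larger by `robust_effect` (relative radius)
#'   and carry stronger internal texture by `texture_effect` (relative
#'   amplitude of a band-limited pattern inside the blob);
#' * fragile: class 2 images are additionally brightened globally by
#'   `confound_effect` - a class-correlated acquisition confound that
#'   inflates the apparent discriminancy of global intensity features but
#'   does not survive brightness perturbations.
#'
#' Gaussian pixel noise of standard deviation `noise_std` is added, and the
#' result clipped to `[0, 1]`; configurations that would clip more than 1%
#' of pixels are rejected. The set is fully determined by `seed`.
#'
#' The accompanying ground truth lists the handcrafted features expected to
#' discriminate through shape/texture as `robust_feature_ids`: the
#' co-occurrence statistics that are monotone in the local gray-level
#' dispersion and invariant to affine brightness changes by construction
#' (contrast, correlation, difference variance, difference entropy, given the
#' range-based gray-level quantization of [haralick_features()]). The global
#' intensity statistics that ride on the brightness confound are listed as
#' `fragile_feature_ids`; quantiles whose order straddles the two classes'
#' blob-area fractions (the 90th percentile at the default geometry) mix
#' object-size signal with the confound and belong to neither set.
#'
#' @param n_per_class images per class (default 200).
#' @param image_size square crop side in pixels (default 96).
#' @param robust_effect relative blob-radius difference between classes
#'   (default 0.25).
#' @param texture_effect relative intra-blob texture-amplitude difference
#'   (default 0.3).
#' @param confound_effect class-correlated global brightness offset in
#'   intensity units (default 0.06).
#' @param noise_std pixel noise standard deviation (default 0.02).
#' @param fluorescence_mode if `TRUE`, tag the set `IM-ACQ-3` (fluorescence
#'   battery; handcrafted features then read the green plane of RGB input;
#'   the generated images are grayscale so only the modality tag changes).
#' @param seed integer seed (default 0).
#' @return list with `set` (an [image_set()]) and `truth` (a
#'   `synthetic_truth`: list of `robust_feature_ids`, `fragile_feature_ids`).
#' @export
generate_two_class_set <- function(n_per_class = 200L, image_size = 96L,
                                   robust_effect = 0.25, texture_effect = 0.3,
                                   confound_effect = 0.06, noise_std = 0.02,
                                   fluorescence_mode = FALSE, seed = 0L) {
  if (n_per_class < 2L) stop("n_per_class must be >= 2", call. = FALSE)
  if (any(c(robust_effect, texture_effect, confound_effect, noise_std) < 0)) {
    stop("effect sizes and noise must be >= 0", call. = FALSE)
  }
  n <- image_size
  base_radius <- 0.19 * n          # class-1 blob radius in pixels
  background <- 0.20
  blob_amp <- 0.30                 # blob plateau height above background
  tex_amp <- 0.08                  # class-1 granular texture amplitude
  edge_w <- 2                      # sigmoid edge softness in pixels

  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)

  make_image <- function(label, img_seed) {
    with_local_seed(img_seed, {
      cy <- (n + 1) / 2 + runif(1, -3, 3)
      cx <- (n + 1) / 2 + runif(1, -3, 3)
      r <- base_radius * (1 + robust_effect * label)
      ecc <- runif(1, 0.85, 1.18)        # axis ratio; area kept constant
      th <- runif(1, 0, pi)
      xr <- (cc - cx) * cos(th) + (rr - cy) * sin(th)
      yr <- -(cc - cx) * sin(th) + (rr - cy) * cos(th)
      d <- sqrt((xr / ecc)^2 + (yr * ecc)^2)
      mask <- 1 / (1 + exp((d - r) / edge_w))
      # granular (pixel-scale) intra-blob texture, e.g. chromatin/organelle
      # grain below the optical blur scale
      texture <- matrix(rnorm(n * n), n, n)
      a_tex <- tex_amp * (1 + texture_effect * label)
      img <- background + blob_amp * mask + a_tex * texture * mask +
        confound_effect * label + rnorm(n * n, sd = noise_std)
      over <- mean(img < 0 | img > 1)
      if (over > 0.01) {
        stop("effect sizes push more than 1% of pixels outside [0, 1]",
             call. = FALSE)
      }
      clip01(img)
    })
  }

  labels <- rep(c(0L, 1L), each = n_per_class)
  images <- lapply(seq_along(labels), function(i) {
    make_image(labels[i], derive_seed(seed, i, salt = 17L))
  })
  ids <- sprintf("syn_%s_%04d", ifelse(labels == 0L, "c1", "c2"),
                 seq_along(labels))
  set <- image_set(images, labels, ids,
                   modality_hint = if (fluorescence_mode) "IM-ACQ-3" else "IM-ACQ-1")
  truth <- structure(
    list(
      robust_feature_ids = c("har.contrast", "har.correlation",
                             "har.diff_variance", "har.diff_entropy"),
      fragile_feature_ids = c("int.mean", "int.median", "int.p10", "int.p25",
                              "int.p75", "int.total")
    ),
    class = "synthetic_truth"
  )
  list(set = set, truth = truth)
}

#' Precision and recall of robust-feature recovery
#'
#' Scores a selection against the generator's ground truth: precision is the
#' fraction of truth-covered selected features that are truly robust,
#' `|selected ∩ robust| / |selected ∩ (robust ∪ fragile)|`; recall is
#' `|selected ∩ robust| / |robust|`. Features outside both truth sets are
#' ignored. An empty denominator yields `NA` (undefined), not 0.
#'
#' @param result a `selection_result` covering the handcrafted feature set.
#' @param truth a `synthetic_truth` from [generate_two_class_set()].
#' @return list with `precision`, `recall`, and the intersecting id sets.
#' @export
ground_truth_eval <- function(result, truth) {
  stopifnot(inherits(result, "selection_result"),
            inherits(truth, "synthetic_truth"))
  sel <- result$selected_ids
  rob <- intersect(sel, truth$robust_feature_ids)
  fra <- intersect(sel, truth$fragile_feature_ids)
  covered <- length(rob) + length(fra)
  precision <- if (covered == 0L) NA_real_ else length(rob) / covered
  recall <- if (length(truth$robust_feature_ids) == 0L) NA_real_ else
    length(rob) / length(truth$robust_feature_ids)
  list(precision = precision, recall = recall,
       selected_robust = rob, selected_fragile = fra)
}
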