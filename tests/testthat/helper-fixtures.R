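# Shared fixtures: tiny deterministic images and sets, and brute-force
# oracles kept independent of the package's own implementations.

fixture_image <- function(nr = 12, nc = 12, seed = 42) {
  set.seed(seed)
  matrix(runif(nr * nc), nr, nc)
}

fixture_set <- function(n_per_class = 4, nr = 16, nc = 16, seed = 7,
                        modality_hint = NULL) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), each = n_per_class)
  images <- lapply(labels, function(l) {
    # class 2 slightly brighter so features carry some signal
    m <- matrix(runif(nr * nc, 0.2, 0.6), nr, nc) + 0.1 * l
    pmin(m, 1)
  })
  image_set(images, labels, modality_hint = modality_hint)
}

# exhaustive pairwise AUC: P(x2 > x1) + 0.5 P(x2 = x1)
brute_auc <- function(x1, x2) {
  mean(outer(x1, x2, function(a, b) (b > a) + 0.5 * (b == a)))
}

# sort-and-interpolate percentile (R type-7 definition, written out)
brute_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# settings whose ranges are degenerate at every operator's identity point
identity_settings <- function(modality = "IM-ACQ-1") {
  default_settings(
    modality,
    brightness.gain = c(1, 1), brightness.offset = c(0, 0),
    brightness.slope = c(0, 0),
    stage_shift.dy = c(0, 0), stage_shift.dx = c(0, 0),
    defocus.sigma = c(0, 0),
    local_defocus.radius = c(0, 0), local_defocus.sigma = c(0, 0),
    gel_texture.amplitude = c(0, 0), gel_texture.length = c(2, 2),
    autofluorescence.amplitude = c(0, 0), autofluorescence.scale = c(8, 8),
    photobleach.factor = c(1, 1),
    saturate.gain = c(1, 1)
  )
}
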