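# Handcrafted descriptors: intensity statistics, Haralick GLCM statistics and
# histogram-of-oriented-gradients, computed on a single grayscale image and
# batched into a feature matrix.

intensity_names <- c("int.mean", "int.median", "int.std", "int.min", "int.p10",
                     "int.p25", "int.p75", "int.p90", "int.max", "int.entropy",
                     "int.total")

haralick_names <- c("har.asm", "har.contrast", "har.correlation",
                    "har.variance", "har.idm", "har.sum_average",
                    "har.sum_variance", "har.sum_entropy", "har.entropy",
                    "har.diff_variance", "har.diff_entropy", "har.imc1",
                    "har.imc2")

#' Intensity descriptors of one image
#'
#' Returns the ordered 11-vector of global intensity statistics: mean, median,
#' population standard deviation, minimum, 10th / 25th / 75th / 90th
#' percentile, maximum, Shannon entropy, and total intensity. Percentiles use
#' linear interpolation of the sorted values; entropy is computed in bits
#' from the 256-bin histogram of `[0, 1]` with the convention
#' `0 * log2(0) = 0`.
#'
#' @param image 2D numeric matrix with values in `[0, 1]`.
#' @return named numeric vector of length 11.
#' @export
intensity_features <- function(image) {
  if (is.null(dim(image)) || length(image) == 0L) {
    stop("image must be a non-empty 2D matrix", call. = FALSE)
  }
  x <- as.vector(image)
  n <- length(x)
  q <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  p <- tabulate(pmin(floor(x * 256) + 1L, 256L), 256L) / n
  p <- p[p > 0]
  out <- c(mean(x), stats::median(x), sqrt(sum((x - mean(x))^2) / n), min(x),
           q[1], q[2], q[3], q[4], max(x), -sum(p * log2(p)), sum(x))
  names(out) <- intensity_names
  out
}

# Quantize intensities to 1..levels gray levels. By default the bins span the
# image's own min..max range (the convention of MATLAB's graycomatrix), which
# makes the co-occurrence statistics invariant to affine brightness changes;
# rescale = "none" uses fixed equal-width bins on [0, 1].
quantize_levels <- function(image, levels, rescale = c("image", "none")) {
  rescale <- match.arg(rescale)
  if (rescale == "image") {
    rng <- range(image)
    if (diff(rng) == 0) return(matrix(1L, nrow(image), ncol(image)))
    image <- (image - rng[1]) / diff(rng)
  }
  pmin(floor(image * levels) + 1L, levels)
}

# Symmetric normalized GLCM for one displacement (dr, dc).
glcm_one <- function(q, levels, dr, dc) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- seq_len(nr - abs(dr)); c1 <- seq_len(nc - abs(dc))
  rows_a <- if (dr >= 0) r1 else r1 + abs(dr)
  cols_a <- if (dc >= 0) c1 else c1 + abs(dc)
  a <- q[rows_a, cols_a, drop = FALSE]
  b <- q[rows_a + dr, cols_a + dc, drop = FALSE]
  counts <- tabulate((a - 1L) * levels + b, levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  P <- P + t(P)
  P / sum(P)
}

haralick_stats <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P)                       # symmetric: px == py
  mu <- sum(seq_len(L) * px)
  sigma <- sqrt(sum((seq_len(L) - mu)^2 * px))
  plog <- function(p) ifelse(p > 0, log2(p), 0)

  # sum (i+j) and difference |i-j| distributions
  k_sum <- 2:(2 * L)
  p_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), 0)
  k_dif <- 0:(L - 1)
  p_dif <- vapply(k_dif, function(k) sum(P[abs(i - j) == k]), 0)

  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sigma == 0) 0 else
    (sum(i * j * P) - mu^2) / sigma^2
  variance <- sum((i - mu)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sum_avg <- sum(k_sum * p_sum)
  sum_var <- sum((k_sum - sum_avg)^2 * p_sum)
  sum_ent <- -sum(p_sum * plog(p_sum))
  entropy <- -sum(P * plog(P))
  dif_avg <- sum(k_dif * p_dif)
  dif_var <- sum((k_dif - dif_avg)^2 * p_dif)
  dif_ent <- -sum(p_dif * plog(p_dif))

  hx <- -sum(px * plog(px))
  pxy <- outer(px, px)
  hxy1 <- -sum(P * plog(pxy))
  hxy2 <- -sum(pxy * plog(pxy))
  imc1 <- if (hx == 0) 0 else (entropy - hxy1) / hx
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))

  c(asm, contrast, correlation, variance, idm, sum_avg, sum_var, sum_ent,
    entropy, dif_var, dif_ent, imc1, imc2)
}

#' Haralick texture descriptors of one image
#'
#' Quantizes the image to `levels` gray levels (bins spanning the image's own
#' intensity range by default, so the statistics are invariant to affine
#' brightness changes), accumulates the symmetric
#' normalized gray-level co-occurrence matrix at distance 1 for the four
#' standard angles (0, 45, 90, 135 degrees) and returns the 13 Haralick
#' statistics averaged over angles: angular second moment, contrast,
#' correlation, variance (sum of squares), inverse difference moment, sum
#' average, sum variance, sum entropy, entropy, difference variance,
#' difference entropy, and the two information measures of correlation.
#' Correlation is defined as 0 when the marginal standard deviation vanishes
#' (constant image). Entropies are in bits.
#'
#' @param image 2D numeric matrix with values in `[0, 1]`.
#' @param levels number of gray levels for quantization (default 32).
#' @param rescale `"image"` (bins span the image's min..max, default) or
#'   `"none"` (fixed bins on `[0, 1]`).
#' @return named numeric vector of length 13.
#' @export
haralick_features <- function(image, levels = 32L, rescale = c("image", "none")) {
  if (is.null(dim(image)) || length(image) == 0L) {
    stop("image must be a non-empty 2D matrix", call. = FALSE)
  }
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  q <- quantize_levels(image, levels, match.arg(rescale))
  # angles 0, 45, 90, 135 degrees at distance 1 (origin top-left, row-major);
  # angles with no admissible pixel pair (degenerate geometry) are skipped
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  ok <- vapply(offsets, function(o) {
    nrow(q) > abs(o[1]) && ncol(q) > abs(o[2])
  }, TRUE)
  if (!any(ok)) stop("image too small for co-occurrence pairs", call. = FALSE)
  stats4 <- vapply(offsets[ok], function(o) {
    haralick_stats(glcm_one(q, levels, o[1], o[2]))
  }, numeric(13L))
  out <- rowMeans(stats4)
  names(out) <- haralick_names
  out
}

resize_bilinear <- function(image, h, w) {
  a <- EBImage::imageData(EBImage::resize(EBImage::Image(t(image)), w = w,
                                          h = h, filter = "bilinear"))
  t(a)
}

#' Histogram-of-oriented-gradients descriptor
#'
#' Resizes the image (bilinear) to `resize_to` so the descriptor length is
#' constant, computes centered gradients, accumulates 9 unsigned orientation
#' bins per 8 x 8 cell (linear vote splitting between neighboring bins), and
#' normalizes 2 x 2-cell blocks with L2-hys (clip at 0.2, renormalize). For a
#' 64 x 64 geometry this yields `(8 - 1)^2 * 4 * 9 = 1764` values. A constant
#' image gives the all-zero vector.
#'
#' @param image 2D numeric matrix with values in `[0, 1]`.
#' @param resize_to target square side in pixels (default 64).
#' @param orientations number of unsigned orientation bins (default 9).
#' @param cell cell side in pixels (default 8).
#' @param block block side in cells (default 2).
#' @return named numeric vector (`hog.0001` ...), length 1764 at defaults.
#' @export
hog_features <- function(image, resize_to = 64L, orientations = 9L,
                         cell = 8L, block = 2L) {
  if (is.null(dim(image)) || length(image) == 0L) {
    stop("image must be a non-empty 2D matrix", call. = FALSE)
  }
  m <- resize_bilinear(image, resize_to, resize_to)
  n <- resize_to
  # centered differences, replicated edges
  gx <- m[, c(2:n, n)] - m[, c(1, 1:(n - 1))]
  gy <- m[c(2:n, n), ] - m[c(1, 1:(n - 1)), ]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi          # (-180, 180]
  ang <- ang %% 180                        # unsigned orientation [0, 180)

  ncell <- n %/% cell
  bin_w <- 180 / orientations
  # linear interpolation of each vote between the two neighboring bins
  pos <- ang / bin_w - 0.5
  lo <- floor(pos)
  frac <- pos - lo
  lo_bin <- (as.integer(lo) %% orientations) + 1L
  hi_bin <- (lo_bin %% orientations) + 1L
  cell_r <- (slice.index(m, 1) - 1L) %/% cell + 1L
  cell_c <- (slice.index(m, 2) - 1L) %/% cell + 1L
  idx_lo <- cell_r + ncell * (cell_c - 1L) + ncell * ncell * (lo_bin - 1L)
  idx_hi <- cell_r + ncell * (cell_c - 1L) + ncell * ncell * (hi_bin - 1L)
  hist <- array(0, c(ncell, ncell, orientations))
  acc <- tapply(c(mag * (1 - frac), mag * frac), c(idx_lo, idx_hi), sum)
  hist[as.integer(names(acc))] <- acc

  nb <- ncell - block + 1L
  eps <- 1e-6
  out <- numeric(nb * nb * block * block * orientations)
  k <- 1L
  span <- block * block * orientations
  for (bc in seq_len(nb)) {
    for (br in seq_len(nb)) {
      v <- as.vector(hist[br:(br + block - 1L), bc:(bc + block - 1L), ])
      v <- v / sqrt(sum(v^2) + eps^2)
      v <- pmin(v, 0.2)
      nrm <- sqrt(sum(v^2))
      if (nrm > eps) v <- v / nrm else v[] <- 0
      out[k:(k + span - 1L)] <- v
      k <- k + span
    }
  }
  names(out) <- sprintf("hog.%04d", seq_along(out))
  out
}

#' Feature matrices
#'
#' A `feature_matrix` is a samples x features numeric matrix with unique
#' feature names as column names and sample ids as row names, free of
#' non-finite values.
#'
#' @param values numeric matrix (samples x features).
#' @param feature_names unique feature names (defaults to column names).
#' @param sample_ids sample ids aligned with rows (defaults to row names).
#' @return a `feature_matrix` (numeric matrix subclass).
#' @export
feature_matrix <- function(values, feature_names = colnames(values),
                           sample_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(feature_names) || anyDuplicated(feature_names)) {
    stop("feature names must be present and unique", call. = FALSE)
  }
  if (is.null(sample_ids) || length(sample_ids) != nrow(values)) {
    stop("sample ids must align with rows", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("feature matrix contains non-finite values", call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, feature_names)
  class(values) <- c("feature_matrix", class(values))
  values
}

#' Extract handcrafted features for a whole image set
#'
#' Computes the selected descriptor families on every image and concatenates
#' them into a [feature_matrix()] with deterministic column order (intensity,
#' then Haralick, then HoG). RGB images are converted to luminance, except
#' under the fluorescence modality (`IM-ACQ-3`) where the green plane is read
#' directly.
#'
#' @param set an [image_set()].
#' @param include subset of `c("intensity", "haralick", "hog")`.
#' @return a `feature_matrix` of size `n_samples` x `n_features`.
#' @export
extract_handcrafted <- function(set, include = c("intensity", "haralick")) {
  stopifnot(inherits(set, "image_set"))
  if (length(include) == 0L) stop("include must be non-empty", call. = FALSE)
  include <- match.arg(include, c("intensity", "haralick", "hog"),
                       several.ok = TRUE)
  channel <- gray_channel_for(set)
  rows <- lapply(set$images, function(img) {
    g <- as_gray(img, channel)
    unlist(c(
      if ("intensity" %in% include) list(intensity_features(g)),
      if ("haralick" %in% include) list(haralick_features(g)),
      if ("hog" %in% include) list(hog_features(g))
    ))
  })
  feature_matrix(do.call(rbind, rows), sample_ids = set$ids)
}
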