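# Artifact operators. All operators take intensities in [0, 1], return an
# array of the same shape clipped to [0, 1], and are the exact identity at
# their identity parameters. Randomness enters only through explicit seeds so
# that a logged draw replays bit-exactly.

clip01 <- function(x) pmin(pmax(x, 0), 1)

check_image01 <- function(image) {
  if (!is.numeric(image) || !(length(dim(image)) %in% c(2L, 3L))) {
    stop("image must be a 2D matrix or H x W x 3 array", call. = FALSE)
  }
  if (anyNA(image) || min(image) < 0 || max(image) > 1) {
    stop("image intensities must be finite and in [0, 1]", call. = FALSE)
  }
  invisible(image)
}

check_finite <- function(...) {
  vals <- c(...)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("perturbation parameters must be finite", call. = FALSE)
  }
}

# Apply a plane-wise operator to 2D or 3-plane input.
per_plane <- function(image, f) {
  if (length(dim(image)) == 2L) return(f(image))
  out <- image
  for (p in 1:3) out[, , p] <- f(image[, , p])
  out
}

#' Brightness artifact
#'
#' Affine intensity drift with an optional lateral illumination gradient:
#' `out = clip(gain * in + offset + gradient_slope * u, 0, 1)` where `u` is
#' the horizontal pixel coordinate normalized to `[-0.5, 0.5]`. Identity at
#' `gain = 1, offset = 0, gradient_slope = 0`.
#'
#' @param image numeric array with values in `[0, 1]`.
#' @param gain multiplicative factor, `> 0`.
#' @param offset additive offset.
#' @param gradient_slope intensity change per normalized horizontal span.
#' @return perturbed image, same shape, clipped to `[0, 1]`.
#' @export
apply_brightness <- function(image, gain = 1, offset = 0, gradient_slope = 0) {
  check_image01(image); check_finite(gain, offset, gradient_slope)
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  per_plane(image, function(m) {
    w <- ncol(m)
    u <- if (w == 1L) 0 else (seq_len(w) - 1) / (w - 1) - 0.5
    clip01(gain * m + offset + matrix(gradient_slope * u, nrow(m), w, byrow = TRUE))
  })
}

# Reflect (mirror, edge not repeated) index lookup for out-of-range indices.
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  k <- (idx - 1L) %% period
  k <- ifelse(k < 0, k + period, k)
  as.integer(ifelse(k >= n, period - k, k) + 1L)
}

#' Stage multi-positioning artifact
#'
#' Translates the crop content by whole pixels, emulating misregistration of
#' the acquisition stage between frames; the vacated border is filled by
#' reflect padding. Identity at `dy = dx = 0`.
#'
#' @param image numeric array with values in `[0, 1]`.
#' @param dy,dx integer translation in pixels (positive = down / right).
#' @param pad border policy; only `"reflect"` is implemented.
#' @return translated image, same shape.
#' @export
apply_stage_shift <- function(image, dy = 0, dx = 0, pad = "reflect") {
  check_image01(image); check_finite(dy, dx)
  pad <- match.arg(pad, "reflect")
  dy <- as.integer(round(dy)); dx <- as.integer(round(dx))
  per_plane(image, function(m) {
    rows <- reflect_index(seq_len(nrow(m)) - dy, nrow(m))
    cols <- reflect_index(seq_len(ncol(m)) - dx, ncol(m))
    m[rows, cols, drop = FALSE]
  })
}

# Separable Gaussian convolution, kernel truncated at 4*sigma, reflect
# boundary. sigma = 0 is the identity.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(mat, along_rows) {
    n <- if (along_rows) nrow(mat) else ncol(mat)
    acc <- 0
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- reflect_index(seq_len(n) + off, n)
      acc <- acc + k[j] * (if (along_rows) mat[idx, , drop = FALSE]
                           else mat[, idx, drop = FALSE])
    }
    acc
  }
  conv1(conv1(m, TRUE), FALSE)
}

#' Out-of-focus artifact
#'
#' Convolution with a normalized isotropic Gaussian kernel (truncated at four
#' standard deviations) using reflect boundary handling. Identity at
#' `sigma = 0`.
#'
#' @param image numeric array with values in `[0, 1]`.
#' @param sigma blur standard deviation in pixels, `>= 0`.
#' @return blurred image, same shape.
#' @export
apply_defocus <- function(image, sigma = 0) {
  check_image01(image); check_finite(sigma)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  per_plane(image, function(m) clip01(gaussian_blur(m, sigma)))
}

#' Local out-of-focus artifact
#'
#' Blurs only a disk-shaped region: `out = m * blur + (1 - m) * in` where `m`
#' is 1 inside `radius`, falls off as a raised cosine over `radius / 2`, and
#' is 0 beyond `1.5 * radius`. Identity at `sigma = 0` or `radius = 0`.
#'
#' @param image numeric array with values in `[0, 1]`.
#' @param center `(row, col)` of the blurred region (1-based); defaults to
#'   the image center.
#' @param radius region radius in pixels, `>= 0`.
#' @param sigma blur standard deviation in pixels, `>= 0`.
#' @return partially blurred image, same shape.
#' @export
apply_local_defocus <- function(image, center = NULL, radius = 0, sigma = 0) {
  check_image01(image); check_finite(radius, sigma)
  if (radius < 0 || sigma < 0) stop("radius and sigma must be >= 0", call. = FALSE)
  if (radius == 0 || sigma == 0) return(image)
  d2 <- dim(image)[1:2]
  if (is.null(center)) center <- (d2 + 1) / 2
  rr <- matrix(seq_len(d2[1]), d2[1], d2[2])
  cc <- matrix(seq_len(d2[2]), d2[1], d2[2], byrow = TRUE)
  dist <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  mask <- ifelse(dist <= radius, 1,
                 ifelse(dist >= 1.5 * radius, 0,
                        0.5 * (1 + cos(pi * (dist - radius) / (radius / 2)))))
  per_plane(image, function(m) {
    clip01(mask * gaussian_blur(m, sigma) + (1 - mask) * m)
  })
}

# Smooth standard-normal random field: white noise blurred at `scale`,
# restandardized to zero mean / unit sd. Deterministic given `seed`.
smooth_field <- function(nr, nc, scale, seed) {
  noise <- with_local_seed(seed, matrix(rnorm(nr * nc), nr, nc))
  f <- gaussian_blur(noise, scale)
  s <- stats::sd(as.vector(f))
  if (s == 0) return(matrix(0, nr, nc))
  (f - mean(f)) / s
}

#' Gel texture variation artifact
#'
#' Adds a zero-mean spatially correlated random field (white noise smoothed
#' with a Gaussian of scale `correlation_length`, rescaled to standard
#' deviation `amplitude`), emulating appearance changes of the culture gel.
#' Identity at `amplitude = 0`.
#'
#' @param image numeric array with values in `[0, 1]`.
#' @param amplitude field standard deviation in intensity units, `>= 0`.
#' @param correlation_length smoothing scale in pixels, `> 0`.
#' @param seed integer seed for the random field.
#' @return perturbed image, same shape, clipped to `[0, 1]`.
#' @export
apply_gel_texture <- function(image, amplitude = 0, correlation_length = 4,
                              seed = 0L) {
  check_image01(image); check_finite(amplitude, correlation_length)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (amplitude == 0) return(image)
  d2 <- dim(image)[1:2]
  field <- amplitude * smooth_field(d2[1], d2[2], correlation_length, seed)
  per_plane(image, function(m) clip01(m + field))
}

#' Culture-medium autofluorescence artifact
#'
#' Adds a non-negative, spatially smooth background emission with maximum
#' `amplitude` (a smoothed random field shifted and rescaled to
#' `[0, amplitude]`). On RGB input only the green plane is affected, matching
#' GFP-channel acquisition. Identity at `amplitude = 0`.
#'
#' @param image numeric array with values in `[0, 1]`.
#' @param amplitude background peak intensity, `>= 0`.
#' @param scale smoothing scale of the background in pixels, `> 0`.
#' @param seed integer seed for the random field.
#' @return perturbed image, same shape, clipped to `[0, 1]`.
#' @export
apply_autofluorescence <- function(image, amplitude = 0, scale = 16, seed = 0L) {
  check_image01(image); check_finite(amplitude, scale)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (amplitude == 0) return(image)
  d2 <- dim(image)[1:2]
  f <- smooth_field(d2[1], d2[2], scale, seed)
  rng <- range(f)
  bg <- if (diff(rng) == 0) matrix(amplitude, d2[1], d2[2]) else
    amplitude * (f - rng[1]) / diff(rng)
  if (length(dim(image)) == 2L) return(clip01(image + bg))
  out <- image
  out[, , 2L] <- clip01(image[, , 2L] + bg)
  out
}

#' Photobleaching artifact
#'
#' Multiplicative loss of fluorophore emission: `out = factor * in`.
#' Identity at `factor = 1`.
#'
#' @param image numeric array with values in `[0, 1]`.
#' @param factor remaining emission fraction in `[0, 1]`.
#' @return attenuated image, same shape.
#' @export
apply_photobleach <- function(image, factor = 1) {
  check_image01(image); check_finite(factor)
  if (factor < 0 || factor > 1) stop("factor must be in [0, 1]", call. = FALSE)
  factor * image
}

#' Fluorescence saturation artifact
#'
#' Sensor clipping of high intensities: `out = clip(gain * in, 0, 1)`.
#' Identity at `gain = 1`.
#'
#' @param image numeric array with values in `[0, 1]`.
#' @param gain emission gain, `>= 1`.
#' @return saturated image, same shape.
#' @export
apply_saturate <- function(image, gain = 1) {
  check_image01(image); check_finite(gain)
  if (gain < 1) stop("gain must be >= 1", call. = FALSE)
  clip01(gain * image)
}

# Dispatch one artifact kind with a named parameter list.
apply_artifact <- function(image, kind, params) {
  switch(kind,
    brightness = apply_brightness(image, params$gain, params$offset, params$slope),
    stage_shift = apply_stage_shift(image, params$dy, params$dx),
    defocus = apply_defocus(image, params$sigma),
    local_defocus = apply_local_defocus(image, radius = params$radius,
                                        sigma = params$sigma),
    gel_texture = apply_gel_texture(image, params$amplitude, params$length,
                                    params$seed),
    autofluorescence = apply_autofluorescence(image, params$amplitude,
                                              params$scale, params$seed),
    photobleach = apply_photobleach(image, params$factor),
    saturate = apply_saturate(image, params$gain),
    stop(sprintf("unknown artifact kind '%s'", kind), call. = FALSE)
  )
}

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Small deterministic seed derivation so that test streams are independent.
derive_seed <- function(seed, test_id, salt = 0L) {
  (as.integer(seed) * 7919L + as.integer(test_id) * 104729L +
     as.integer(salt) * 31L) %% 2147483629L
}

#' Perturb a labeled image set with one artifact test
#'
#' Applies the `test_id`-th artifact of the settings' modality to every image
#' of the set. Per-image parameters are drawn uniformly from the SETTING
#' ranges with a seeded RNG (integer parameters from the integer grid), so
#' the same seed reproduces the output bit-exactly. Labels and ids are
#' carried over unchanged.
#'
#' @param set an [image_set()].
#' @param settings a `robusel_settings` object.
#' @param test_id which of the modality's three tests to apply (1, 2 or 3).
#' @param seed optional seed overriding `settings$seed` (used e.g. for an
#'   independent test-set perturbation stream).
#' @return a list with elements `set` (the perturbed `image_set`) and
#'   `draw_log` (a data.frame of the per-image parameter draws, one row per
#'   image, for exact replay).
#' @export
perturb_dataset <- function(set, settings, test_id, seed = NULL) {
  stopifnot(inherits(set, "image_set"))
  settings <- validate_settings(settings)
  test_id <- as.integer(test_id)
  kinds <- modality_tests[[settings$modality]]
  if (is.na(test_id) || test_id < 1L || test_id > length(kinds)) {
    stop(sprintf("test_id must be 1..%d for modality %s", length(kinds),
                 settings$modality), call. = FALSE)
  }
  kind <- kinds[test_id]
  base_seed <- derive_seed(if (is.null(seed)) settings$seed else seed, test_id)
  pnames <- kind_params[[kind]]
  integer_params <- c("dy", "dx")
  needs_field_seed <- kind %in% c("gel_texture", "autofluorescence")

  n <- length(set$images)
  draws <- with_local_seed(base_seed, {
    lapply(seq_len(n), function(i) {
      ps <- lapply(pnames, function(p) {
        rg <- settings$ranges[[paste0(kind, ".", p)]]
        if (p %in% integer_params) {
          lo <- as.integer(ceiling(rg[1])); hi <- as.integer(floor(rg[2]))
          if (hi < lo) stop(sprintf("empty integer range for %s.%s", kind, p),
                            call. = FALSE)
          sample(seq(lo, hi), 1L)
        } else {
          runif(1, rg[1], rg[2])
        }
      })
      names(ps) <- pnames
      if (needs_field_seed) {
        ps$seed <- sample.int(2147483629L, 1L)
      }
      ps
    })
  })

  images <- vector("list", n)
  for (i in seq_len(n)) {
    images[[i]] <- apply_artifact(set$images[[i]], kind, draws[[i]])
  }
  log_df <- do.call(rbind, lapply(seq_len(n), function(i) {
    as.data.frame(draws[[i]])
  }))
  log_df <- cbind(data.frame(id = set$ids, test_id = test_id, kind = kind,
                             stringsAsFactors = FALSE), log_df)
  list(set = image_set(images, set$labels, set$ids, set$modality_hint),
       draw_log = log_df)
}
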