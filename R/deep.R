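# Deep transfer-learning features: pooled activations from reference CNN
# topologies (ResNet101, VGG19, NASNet-A Large, DenseNet201) run by the
# package's own inference engine (src/convops.cpp). Weights are drawn at
# instantiation time from a seeded He-scaled normal ("random" weights); this
# realizes the architecture contract (layer geometry, pooled feature
# dimensionality) without any model download. Loading published pretrained
# weights is not supported by this engine; descriptors requesting
# `weights = "pretrained"` raise a capability error advising handcrafted
# mode.

# ---- weight cache -----------------------------------------------------------

new_weight_cache <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed); e$i <- 0L; e$params <- list()
  e
}

reset_cache <- function(pe) { pe$i <- 0L; invisible(pe) }

next_weights <- function(pe, n, sd) {
  pe$i <- pe$i + 1L
  if (length(pe$params) >= pe$i && !is.null(pe$params[[pe$i]])) {
    return(pe$params[[pe$i]])
  }
  w <- with_local_seed(derive_seed(pe$seed, pe$i, salt = 3L),
                       rnorm(n, sd = sd))
  pe$params[[pe$i]] <- w
  w
}

# ---- layer primitives -------------------------------------------------------

same_pads <- function(n, k, s) {
  total <- max((ceiling(n / s) - 1) * s + k - n, 0)
  c(floor(total / 2), total - floor(total / 2))
}

conv2d <- function(x, pe, filters, k, stride = 1L, padding = "same",
                   act = "relu") {
  d <- dim(x)
  pads <- if (padding == "same") {
    c(same_pads(d[1], k, stride), same_pads(d[2], k, stride))
  } else c(0L, 0L, 0L, 0L)
  cin <- d[3]
  w <- matrix(next_weights(pe, k * k * cin * filters, sqrt(2 / (k * k * cin))),
              k * k * cin, filters)
  cpp_conv2d(x, w, k, k, stride, stride, pads[1], pads[2], pads[3], pads[4],
             identical(act, "relu"))
}

dwconv2d <- function(x, pe, k, stride = 1L) {
  d <- dim(x)
  pads <- c(same_pads(d[1], k, stride), same_pads(d[2], k, stride))
  w <- matrix(next_weights(pe, k * k * d[3], sqrt(2 / (k * k))), k * k, d[3])
  cpp_dwconv2d(x, w, k, k, stride, stride, pads[1], pads[2], pads[3], pads[4],
               FALSE)
}

pool2d <- function(x, k, stride, type = c("max", "avg"), padding = "same") {
  type <- match.arg(type)
  d <- dim(x)
  pads <- if (padding == "same") {
    c(same_pads(d[1], k, stride), same_pads(d[2], k, stride))
  } else c(0L, 0L, 0L, 0L)
  cpp_pool2d(x, k, k, stride, stride, pads[1], pads[2], pads[3], pads[4],
             type == "max")
}

relu_act <- function(x) { x[x < 0] <- 0; x }

gap2d <- function(x) {
  d <- dim(x)
  colMeans(matrix(x, d[1] * d[2], d[3]))
}

concat_ch <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  array(unlist(xs, use.names = FALSE),
        c(d[1], d[2], sum(vapply(xs, function(a) dim(a)[3], 0L))))
}

# ---- backbones --------------------------------------------------------------

vgg19_forward <- function(x, pe, layer = "max-pool5") {
  stage <- as.integer(sub("max-pool", "", layer))
  blocks <- list(c(64, 2), c(128, 2), c(256, 4), c(512, 4), c(512, 4))
  for (b in seq_along(blocks)) {
    for (i in seq_len(blocks[[b]][2])) {
      x <- conv2d(x, pe, blocks[[b]][1], 3L)
    }
    x <- pool2d(x, 2L, 2L, "max", padding = "valid")
    if (b == stage) return(as.vector(x))
  }
  as.vector(x)
}

resnet101_forward <- function(x, pe, layer = "average-pool5") {
  bottleneck <- function(x, mid, out, stride) {
    cin <- dim(x)[3]
    shortcut <- if (cin != out || stride > 1L)
      conv2d(x, pe, out, 1L, stride, act = "linear") else x
    y <- conv2d(x, pe, mid, 1L, stride)
    y <- conv2d(y, pe, mid, 3L)
    y <- conv2d(y, pe, out, 1L, act = "linear")
    relu_act(y + shortcut)
  }
  x <- conv2d(x, pe, 64L, 7L, 2L)
  x <- pool2d(x, 3L, 2L, "max")
  widths <- c(256L, 512L, 1024L, 2048L)
  reps <- c(3L, 4L, 23L, 3L)
  for (s in 1:4) {
    for (i in seq_len(reps[s])) {
      x <- bottleneck(x, widths[s] / 4L, widths[s],
                      stride = if (i == 1L && s > 1L) 2L else 1L)
    }
  }
  gap2d(x)
}

densenet201_forward <- function(x, pe, layer = "average_pool5") {
  dense_layer <- function(x, growth) {
    y <- conv2d(relu_act(x), pe, 4L * growth, 1L, act = "linear")
    y <- conv2d(relu_act(y), pe, growth, 3L, act = "linear")
    concat_ch(x, y)
  }
  transition <- function(x) {
    y <- conv2d(relu_act(x), pe, dim(x)[3] %/% 2L, 1L, act = "linear")
    pool2d(y, 2L, 2L, "avg", padding = "valid")
  }
  x <- conv2d(x, pe, 64L, 7L, 2L)
  x <- pool2d(x, 3L, 2L, "max")
  reps <- c(6L, 12L, 48L, 32L)
  for (b in 1:4) {
    for (i in seq_len(reps[b])) x <- dense_layer(x, 32L)
    if (b < 4L) x <- transition(x)
  }
  gap2d(relu_act(x))
}

nasnetlarge_forward <- function(x, pe, layer = "global_average_pool5") {
  squeeze <- function(x, f) conv2d(relu_act(x), pe, f, 1L, act = "linear")
  sep <- function(x, k, stride, f) {
    y <- dwconv2d(relu_act(x), pe, k, stride)
    conv2d(y, pe, f, 1L, act = "linear")
  }
  adjust <- function(p, h, f) {
    if (is.null(p)) p <- h
    if (dim(p)[1] != dim(h)[1]) {
      p <- pool2d(relu_act(p), 3L, 2L, "avg")
      p <- conv2d(p, pe, f, 1L, act = "linear")
    } else if (dim(p)[3] != f) {
      p <- squeeze(p, f)
    }
    p
  }
  normal_cell <- function(h, p, f) {
    p <- adjust(p, h, f)
    hq <- squeeze(h, f)
    b1 <- sep(hq, 5L, 1L, f) + sep(p, 3L, 1L, f)
    b2 <- sep(p, 5L, 1L, f) + sep(p, 3L, 1L, f)
    b3 <- pool2d(hq, 3L, 1L, "avg") + p
    b4 <- pool2d(p, 3L, 1L, "avg") + pool2d(p, 3L, 1L, "avg")
    b5 <- sep(hq, 3L, 1L, f) + hq
    list(x = concat_ch(p, b1, b2, b3, b4, b5), p = h)
  }
  reduction_cell <- function(h, p, f) {
    p <- adjust(p, h, f)
    hq <- squeeze(h, f)
    x1 <- sep(hq, 5L, 2L, f) + sep(p, 7L, 2L, f)
    x2 <- pool2d(hq, 3L, 2L, "max") + sep(p, 7L, 2L, f)
    x3 <- pool2d(hq, 3L, 2L, "avg") + sep(p, 5L, 2L, f)
    x4 <- pool2d(x1, 3L, 1L, "avg") + x2
    x5 <- sep(x1, 3L, 1L, f) + pool2d(hq, 3L, 2L, "max")
    list(x = concat_ch(x2, x3, x4, x5), p = h)
  }
  f <- 168L
  x <- conv2d(x, pe, 96L, 3L, 2L, padding = "valid")
  cell <- reduction_cell(x, NULL, f %/% 4L)
  cell <- reduction_cell(cell$x, cell$p, f %/% 2L)
  for (stage in 1:3) {
    fs <- f * 2L^(stage - 1L)
    for (i in 1:6) cell <- normal_cell(cell$x, cell$p, fs)
    if (stage < 3L) cell <- reduction_cell(cell$x, cell$p, fs * 2L)
  }
  gap2d(relu_act(cell$x))
}

# ---- registry and extraction ------------------------------------------------

backend_registry <- function() {
  data.frame(
    network_name = c("ResNET101", "VGG19", "NasNETLarge", "DenseNET201"),
    layer_name = c("average-pool5", "max-pool5", "global_average_pool5",
                   "average_pool5"),
    input_h = c(224L, 224L, 331L, 224L),
    input_w = c(224L, 224L, 331L, 224L),
    feature_dim = c(2048L, 25088L, 4032L, 1920L),
    stringsAsFactors = FALSE
  )
}

#' List the registered CNN feature backends
#'
#' The registry mirrors the pooled-layer transfer-learning configurations
#' used for validation: ResNet101 `average-pool5` (2048 features, 224 x 224 x
#' 3 input), VGG19 `max-pool5` (25088, 224 x 224 x 3), NASNet-A Large
#' `global_average_pool5` (4032, 331 x 331 x 3) and DenseNet201
#' `average_pool5` (1920, 224 x 224 x 3). VGG19 additionally accepts
#' `max-pool1` ... `max-pool4`, with the feature dimension derived from the
#' architecture.
#'
#' @return data.frame of backend descriptors.
#' @export
list_backends <- function() backend_registry()

vgg_pool_dim <- function(stage) {
  side <- 224L %/% as.integer(2^stage)
  ch <- c(64L, 128L, 256L, 512L, 512L)[stage]
  as.integer(side * side * ch)
}

#' Resolve a backend descriptor
#'
#' @param network_name registered network name (case-insensitive).
#' @param layer_name pooling layer name; defaults to the registered layer.
#' @param weights `"random"` (seeded He-initialized instantiation, the
#'   default) or `"pretrained"` (not available in this engine; raises a
#'   capability error advising handcrafted mode).
#' @param seed seed for the random weight draw.
#' @return a `backend_descriptor` list with fields `network_name`,
#'   `layer_name`, `input_size`, `feature_dim`, `weights`, `seed`.
#' @export
get_backend <- function(network_name, layer_name = NULL, weights = "random",
                        seed = 0L) {
  reg <- backend_registry()
  row <- match(tolower(network_name), tolower(reg$network_name))
  if (is.na(row)) {
    stop(sprintf("unknown network '%s'; see list_backends()", network_name),
         call. = FALSE)
  }
  if (is.null(layer_name)) layer_name <- reg$layer_name[row]
  feature_dim <- reg$feature_dim[row]
  if (reg$network_name[row] == "VGG19") {
    if (!grepl("^max-pool[1-5]$", layer_name)) {
      stop(sprintf("unknown layer '%s' for VGG19", layer_name), call. = FALSE)
    }
    feature_dim <- vgg_pool_dim(as.integer(sub("max-pool", "", layer_name)))
  } else if (layer_name != reg$layer_name[row]) {
    stop(sprintf("unknown layer '%s' for %s", layer_name,
                 reg$network_name[row]), call. = FALSE)
  }
  weights <- match.arg(weights, c("random", "pretrained"))
  if (weights == "pretrained") {
    stop("pretrained weights are not available in this engine; ",
         "use weights = \"random\" for architecture contracts or the ",
         "handcrafted feature mode", call. = FALSE)
  }
  structure(
    list(network_name = reg$network_name[row], layer_name = layer_name,
         input_size = c(reg$input_h[row], reg$input_w[row], 3L),
         feature_dim = feature_dim, weights = weights, seed = as.integer(seed)),
    class = "backend_descriptor"
  )
}

#' Standardize one image for a CNN backend
#'
#' Bilinear resize to the backend input size, replication of grayscale input
#' to three planes, and per-plane standardization with mean 0.5 / sd 0.5
#' (the convention for randomly initialized weights; published per-network
#' constants would apply to pretrained weights).
#'
#' @param image 2D matrix or H x W x 3 array with values in `[0, 1]`.
#' @param backend a `backend_descriptor`.
#' @return standardized array of the backend's input size.
#' @export
prepare_input <- function(image, backend) {
  check_image01(image)
  h <- backend$input_size[1]; w <- backend$input_size[2]
  if (length(dim(image)) == 2L) {
    g <- resize_bilinear(image, h, w)
    x <- array(g, c(h, w, 3L))
  } else {
    x <- array(0, c(h, w, 3L))
    for (p in 1:3) x[, , p] <- resize_bilinear(image[, , p], h, w)
  }
  (x - 0.5) / 0.5
}

backend_forward <- function(x, backend, pe) {
  switch(backend$network_name,
         ResNET101 = resnet101_forward(x, pe, backend$layer_name),
         VGG19 = vgg19_forward(x, pe, backend$layer_name),
         NasNETLarge = nasnetlarge_forward(x, pe, backend$layer_name),
         DenseNET201 = densenet201_forward(x, pe, backend$layer_name))
}

#' Extract pooled CNN activations for a whole image set
#'
#' Runs every image through the backend at its native input size and returns
#' the flattened activations of the configured pooling layer as a
#' [feature_matrix()] (`deep.00001`-style column names). Extraction is
#' deterministic: the weight draw is fixed by the backend seed and shared
#' across images.
#'
#' @param set an [image_set()].
#' @param backend a `backend_descriptor` from [get_backend()].
#' @return `feature_matrix` of size `n_samples` x `feature_dim`.
#' @export
extract_deep <- function(set, backend) {
  stopifnot(inherits(set, "image_set"), inherits(backend, "backend_descriptor"))
  pe <- new_weight_cache(backend$seed)
  rows <- lapply(set$images, function(img) {
    reset_cache(pe)
    v <- backend_forward(prepare_input(img, backend), backend, pe)
    if (length(v) != backend$feature_dim) {
      stop(sprintf("backend produced %d features, registry says %d",
                   length(v), backend$feature_dim), call. = FALSE)
    }
    v
  })
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("deep.%05d", seq_len(ncol(m)))
  feature_matrix(m, sample_ids = set$ids)
}
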