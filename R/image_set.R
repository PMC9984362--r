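#' Labeled image sets
#'
#' An `image_set` bundles a list of intensity arrays with binary class labels
#' and stable sample ids. Images are either 2D matrices (grayscale) or
#' H x W x 3 arrays (RGB), with all intensities in `[0, 1]`. Arrays are
#' row-major in the imaging sense: dimension 1 is the image row (y, top to
#' bottom), dimension 2 the column (x, left to right).
#'
#' @param images list of numeric matrices or H x W x 3 arrays with values in
#'   `[0, 1]`.
#' @param labels integer vector of 0 (class 1) and 1 (class 2), one per image.
#' @param ids character vector of unique sample ids; defaults to
#'   `"img_0001"`-style ids.
#' @param modality_hint optional imaging modality, one of `"IM-ACQ-1"`
#'   (2D transmission light), `"IM-ACQ-2"` (3D phase contrast) or
#'   `"IM-ACQ-3"` (3D fluorescence time-lapse). Used to pick the artifact
#'   battery and the grayscale conversion (fluorescence reads the green
#'   plane).
#' @return an object of class `image_set`.
#' @seealso [load_image_set()], [generate_two_class_set()]
#' @export
image_set <- function(images, labels, ids = NULL, modality_hint = NULL) {
  stopifnot(is.list(images), length(images) >= 1L)
  labels <- as.integer(labels)
  if (length(labels) != length(images)) {
    stop("`images` and `labels` must have the same length", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("`labels` must be binary (0 = class 1, 1 = class 2)", call. = FALSE)
  }
  if (is.null(ids)) ids <- sprintf("img_%04d", seq_along(images))
  ids <- as.character(ids)
  if (length(ids) != length(images) || anyDuplicated(ids)) {
    stop("`ids` must be unique and aligned with `images`", call. = FALSE)
  }
  if (!is.null(modality_hint)) {
    modality_hint <- match.arg(modality_hint, c("IM-ACQ-1", "IM-ACQ-2", "IM-ACQ-3"))
  }
  for (k in seq_along(images)) {
    img <- images[[k]]
    if (!is.numeric(img) || !(length(dim(img)) %in% c(2L, 3L))) {
      stop(sprintf("image '%s' is not a 2D or 3-plane numeric array", ids[k]),
           call. = FALSE)
    }
    if (length(dim(img)) == 3L && dim(img)[3] != 3L) {
      stop(sprintf("image '%s' must have exactly 3 planes when 3D", ids[k]),
           call. = FALSE)
    }
    if (anyNA(img) || any(!is.finite(img))) {
      stop(sprintf("image '%s' contains non-finite values", ids[k]), call. = FALSE)
    }
    if (min(img) < 0 || max(img) > 1) {
      stop(sprintf("image '%s' has intensities outside [0, 1]", ids[k]),
           call. = FALSE)
    }
  }
  structure(
    list(images = images, labels = labels, ids = ids,
         modality_hint = modality_hint),
    class = "image_set"
  )
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<image_set> %d images (%d / %d per class), first image %s%s\n",
              length(x$images), sum(x$labels == 0L), sum(x$labels == 1L),
              paste(d, collapse = "x"),
              if (is.null(x$modality_hint)) "" else
                paste0(", modality ", x$modality_hint)))
  invisible(x)
}

#' @export
length.image_set <- function(x) length(x$images)

#' Subset an image set by index
#'
#' @param x an `image_set`.
#' @param i integer or logical index over samples.
#' @param ... unused.
#' @return an `image_set` with the selected samples.
#' @export
`[.image_set` <- function(x, i, ...) {
  image_set(x$images[i], x$labels[i], x$ids[i], x$modality_hint)
}

#' Load a two-class image set from a class-per-directory tree
#'
#' Reads all images under `root_path/class_dirs[1]` (label 0) and
#' `root_path/class_dirs[2]` (label 1). TIFF (8/16-bit), PNG and JPEG are
#' supported; intensities are scaled by bit depth into `[0, 1]`. Files are
#' read in lexicographic order within each class so that two loads of the same
#' tree produce identical sets.
#'
#' @param root_path directory containing the two class directories.
#' @param class_dirs character vector of the two class directory names;
#'   defaults to the first two subdirectories in lexicographic order.
#' @param modality_hint optional modality tag, see [image_set()].
#' @return an `image_set`; ids are `"<class_dir>/<file>"`.
#' @export
load_image_set <- function(root_path, class_dirs = NULL, modality_hint = NULL) {
  if (!dir.exists(root_path)) {
    stop(sprintf("directory '%s' does not exist", root_path), call. = FALSE)
  }
  if (is.null(class_dirs)) {
    class_dirs <- sort(list.dirs(root_path, recursive = FALSE, full.names = FALSE))
  }
  if (length(class_dirs) != 2L) {
    stop("exactly two class directories are required", call. = FALSE)
  }
  images <- list(); labels <- integer(); ids <- character()
  for (cls in c(1L, 2L)) {
    d <- file.path(root_path, class_dirs[cls])
    if (!dir.exists(d)) {
      stop(sprintf("class directory '%s' does not exist", d), call. = FALSE)
    }
    files <- sort(list.files(d, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                             ignore.case = TRUE))
    if (length(files) == 0L) {
      stop(sprintf("class directory '%s' contains no readable images", d),
           call. = FALSE)
    }
    for (f in files) {
      img <- tryCatch(read_image_file(file.path(d, f)),
                      error = function(e) {
                        stop(sprintf("failed to read image '%s': %s",
                                     file.path(d, f), conditionMessage(e)),
                             call. = FALSE)
                      })
      images[[length(images) + 1L]] <- img
      labels <- c(labels, cls - 1L)
      ids <- c(ids, paste0(class_dirs[cls], "/", f))
    }
  }
  image_set(images, labels, ids, modality_hint)
}

# Decode one image file to a [0,1] array (H x W or H x W x 3).
# EBImage::readImage already rescales integer codes by bit depth (255 -> 1 for
# 8-bit, 65535 -> 1 for 16-bit); values are clamped defensively against
# out-of-gamut JPEG round-off.
read_image_file <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  # EBImage stores images as x-by-y; transpose to row (y) major
  if (length(dim(a)) == 2L) {
    a <- t(a)
  } else {
    a <- a[, , seq_len(min(dim(a)[3], 3L)), drop = FALSE]
    if (dim(a)[3] == 1L) {
      a <- t(a[, , 1L])
    } else {
      a <- aperm(a, c(2L, 1L, 3L))
    }
  }
  pmin(pmax(a, 0), 1)
}

#' Write an image set as a class-per-directory tree
#'
#' @param set an `image_set`.
#' @param root_path output directory (created if missing).
#' @param class_dirs names for the two class directories.
#' @param format `"png"` (8-bit) or `"tiff"` (16-bit).
#' @return `root_path`, invisibly.
#' @export
write_image_set <- function(set, root_path, class_dirs = c("class1", "class2"),
                            format = c("png", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(set, "image_set"))
  for (d in class_dirs) dir.create(file.path(root_path, d),
                                   recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(set$images)) {
    img <- set$images[[k]]
    a <- if (length(dim(img)) == 2L) t(img) else aperm(img, c(2L, 1L, 3L))
    fn <- paste0(gsub("[^A-Za-z0-9_.-]", "_", set$ids[k]), ".", format)
    out <- file.path(root_path, class_dirs[set$labels[k] + 1L], fn)
    EBImage::writeImage(EBImage::Image(a, colormode = if (length(dim(img)) == 2L)
      "Grayscale" else "Color"), out,
      bits.per.sample = if (format == "tiff") 16L else 8L)
  }
  invisible(root_path)
}

# Grayscale view of one image for handcrafted extraction: RGB is converted to
# luminance, except in fluorescence mode where the green emission plane is
# read directly.
as_gray <- function(img, channel = c("luminance", "green")) {
  channel <- match.arg(channel)
  if (length(dim(img)) == 2L) return(img)
  if (channel == "green") return(img[, , 2L])
  0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
}

# Channel rule implied by the modality: fluorescence features read plane G.
gray_channel_for <- function(set) {
  if (!is.null(set$modality_hint) && set$modality_hint == "IM-ACQ-3")
    "green" else "luminance"
}
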