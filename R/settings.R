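#' Artifact test batteries per imaging modality
#'
#' Each modality exposes three perturbation tests:
#' * `IM-ACQ-1` (2D transmission light): brightness, stage shift, defocus;
#' * `IM-ACQ-2` (3D phase contrast): brightness, local defocus, gel texture;
#' * `IM-ACQ-3` (3D fluorescence): autofluorescence, photobleach, saturate.
#'
#' @format a named list mapping modality to a character vector of the three
#'   test kinds, in test order 1..3.
#' @export
modality_tests <- list(
  "IM-ACQ-1" = c("brightness", "stage_shift", "defocus"),
  "IM-ACQ-2" = c("brightness", "local_defocus", "gel_texture"),
  "IM-ACQ-3" = c("autofluorescence", "photobleach", "saturate")
)

# Default parameter ranges per artifact kind: visually plausible,
# non-destructive acquisition drift. Every range brackets (or touches) the
# operator's identity point so that degenerate ranges give SENS = 0.
default_ranges <- function() {
  list(
    brightness.gain        = c(0.8, 1.3),
    brightness.offset      = c(-0.1, 0.1),
    brightness.slope       = c(-0.2, 0.2),
    stage_shift.dy         = c(-5, 5),
    stage_shift.dx         = c(-5, 5),
    defocus.sigma          = c(0.5, 3),
    local_defocus.radius   = c(8, 24),
    local_defocus.sigma    = c(0.5, 3),
    gel_texture.amplitude  = c(0.01, 0.05),
    gel_texture.length     = c(2, 8),
    autofluorescence.amplitude = c(0.02, 0.1),
    autofluorescence.scale = c(8, 32),
    photobleach.factor     = c(0.6, 0.95),
    saturate.gain          = c(1.1, 1.6)
  )
}

# Parameter names required by each artifact kind (prefix of range keys).
kind_params <- list(
  brightness       = c("gain", "offset", "slope"),
  stage_shift      = c("dy", "dx"),
  defocus          = c("sigma"),
  local_defocus    = c("radius", "sigma"),
  gel_texture      = c("amplitude", "length"),
  autofluorescence = c("amplitude", "scale"),
  photobleach      = c("factor"),
  saturate         = c("gain")
)

new_settings <- function(modality, th_dp, th_sens, feature_mode, network_name,
                         layer_name, ranges, seed, dp_rule,
                         stepwise_p_enter, stepwise_p_remove) {
  structure(
    list(modality = modality, th_dp = th_dp, th_sens = th_sens,
         feature_mode = feature_mode, network_name = network_name,
         layer_name = layer_name, ranges = ranges, seed = seed,
         dp_rule = dp_rule, stepwise_p_enter = stepwise_p_enter,
         stepwise_p_remove = stepwise_p_remove),
    class = "robusel_settings"
  )
}

validate_settings <- function(s) {
  if (is.null(s$modality) || !s$modality %in% names(modality_tests)) {
    stop("settings must name a modality among IM-ACQ-1, IM-ACQ-2, IM-ACQ-3",
         call. = FALSE)
  }
  if (!is.numeric(s$th_dp) || s$th_dp < 0.5 || s$th_dp > 1) {
    stop("th_dp must lie in [0.5, 1]", call. = FALSE)
  }
  if (!is.numeric(s$th_sens) || s$th_sens < 0) {
    stop("th_sens must be >= 0", call. = FALSE)
  }
  for (kind in modality_tests[[s$modality]]) {
    for (p in kind_params[[kind]]) {
      key <- paste0(kind, ".", p)
      rg <- s$ranges[[key]]
      if (is.null(rg) || length(rg) != 2L || anyNA(rg) || !all(is.finite(rg))) {
        stop(sprintf("missing or non-finite range for '%s'", key), call. = FALSE)
      }
      if (rg[1] > rg[2]) {
        stop(sprintf("range '%s' has min > max", key), call. = FALSE)
      }
    }
  }
  s$dp_rule <- match.arg(s$dp_rule, c("both", "pre", "post"))
  s
}

#' Default selection settings
#'
#' Constructs a `robusel_settings` object with the documented defaults:
#' `th_dp = 0.6`, `th_sens = 0.1`, seed 0, handcrafted feature mode, and the
#' default artifact parameter ranges. The discriminancy threshold applies, by
#' default, to both the pre- and the post-perturbation DP (`dp_rule =
#' "both"`).
#'
#' @param modality one of `"IM-ACQ-1"`, `"IM-ACQ-2"`, `"IM-ACQ-3"`.
#' @param ... named overrides for any settings field (e.g. `th_dp = 0.65`) or
#'   any range key (e.g. `brightness.gain = c(1, 1)`).
#' @return a `robusel_settings` object.
#' @export
default_settings <- function(modality = "IM-ACQ-1", ...) {
  s <- new_settings(modality = modality, th_dp = 0.6, th_sens = 0.1,
                    feature_mode = "handcrafted", network_name = NULL,
                    layer_name = NULL, ranges = default_ranges(), seed = 0L,
                    dp_rule = "both", stepwise_p_enter = 0.05,
                    stepwise_p_remove = 0.10)
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% names(s)) s[[nm]] <- dots[[nm]]
    else if (nm %in% names(s$ranges)) s$ranges[[nm]] <- as.numeric(dots[[nm]])
    else stop(sprintf("unknown settings field '%s'", nm), call. = FALSE)
  }
  validate_settings(s)
}

#' Parse a SETTING text file
#'
#' The SETTING file is UTF-8 plain text with one `key=value` pair per line;
#' `#` starts a comment and blank lines are ignored. Parameter ranges are
#' written as `key=min,max` (e.g. `brightness.gain=0.8,1.3`). Unknown keys are
#' tolerated with a warning. Absent optional keys take the documented
#' defaults (`th_dp=0.6`, `th_sens=0.1`, `seed=0`, default ranges); `modality`
#' is mandatory.
#'
#' @param path path to the SETTING file.
#' @return a `robusel_settings` object.
#' @seealso [write_settings()], [default_settings()]
#' @export
parse_settings <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("settings file '%s' does not exist", path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) {
    stop(sprintf("malformed settings line: '%s'", lines[bad][1]), call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))

  s <- new_settings(modality = NULL, th_dp = 0.6, th_sens = 0.1,
                    feature_mode = "handcrafted", network_name = NULL,
                    layer_name = NULL, ranges = default_ranges(), seed = 0L,
                    dp_rule = "both", stepwise_p_enter = 0.05,
                    stepwise_p_remove = 0.10)
  scalar_num <- c("th_dp", "th_sens", "stepwise_p_enter", "stepwise_p_remove")
  scalar_chr <- c("modality", "feature_mode", "network_name", "layer_name",
                  "dp_rule")
  for (i in seq_along(keys)) {
    key <- keys[i]; val <- vals[i]
    if (key %in% scalar_num) {
      s[[key]] <- as.numeric(val)
    } else if (key == "seed") {
      s$seed <- as.integer(val)
    } else if (key %in% scalar_chr) {
      s[[key]] <- val
    } else if (key %in% names(s$ranges)) {
      rg <- as.numeric(strsplit(val, ",")[[1]])
      if (length(rg) != 2L || anyNA(rg)) {
        stop(sprintf("range '%s' must be 'min,max'", key), call. = FALSE)
      }
      s$ranges[[key]] <- rg
    } else {
      warning(sprintf("ignoring unknown settings key '%s'", key), call. = FALSE)
    }
  }
  validate_settings(s)
}

#' Write settings to a SETTING text file
#'
#' Inverse of [parse_settings()]: `parse_settings(write_settings(s, f))`
#' reproduces `s`.
#'
#' @param settings a `robusel_settings` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_settings <- function(settings, path) {
  s <- validate_settings(settings)
  fmt <- function(x) sprintf("%.12g", x)
  lines <- c(
    paste0("modality=", s$modality),
    paste0("th_dp=", fmt(s$th_dp)),
    paste0("th_sens=", fmt(s$th_sens)),
    paste0("feature_mode=", s$feature_mode),
    if (!is.null(s$network_name)) paste0("network_name=", s$network_name),
    if (!is.null(s$layer_name)) paste0("layer_name=", s$layer_name),
    paste0("seed=", s$seed),
    paste0("dp_rule=", s$dp_rule),
    paste0("stepwise_p_enter=", fmt(s$stepwise_p_enter)),
    paste0("stepwise_p_remove=", fmt(s$stepwise_p_remove)),
    vapply(names(s$ranges), function(k) {
      paste0(k, "=", fmt(s$ranges[[k]][1]), ",", fmt(s$ranges[[k]][2]))
    }, "")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.robusel_settings <- function(x, ...) {
  cat(sprintf("<robusel_settings> modality %s | th_dp %.3g | th_sens %.3g | mode %s | seed %d\n",
              x$modality, x$th_dp, x$th_sens, x$feature_mode, x$seed))
  invisible(x)
}
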