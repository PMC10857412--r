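#' Accelerometer device specification
#'
#' A `device_spec` captures the sampling and analog-to-digital parameters that
#' determine what a body-worn MEMS accelerometer can represent: the per-axis
#' sampling rate, the bit depth of the stored codes, and the dynamic range
#' (accelerations are representable on \eqn{[-R, +R]} g). The number of
#' representable levels is `2^bit_depth`.
#'
#' @param label short device identifier used in outputs.
#' @param sampling_rate_hz samples per second per axis (positive).
#' @param bit_depth integer bits per stored sample, between 1 and 16.
#' @param dynamic_range_g half-range R in g; representable range is +/- R.
#' @param placement body placement, `"chest"` or `"hip"`.
#' @return An object of class `device_spec`.
#' @examples
#' device_spec("patch", 1.56, 8, 2, "chest")
#' @export
device_spec <- function(label, sampling_rate_hz, bit_depth, dynamic_range_g,
                        placement = c("chest", "hip")) {
  placement <- match.arg(placement)
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a positive number", call. = FALSE)
  }
  if (!is.numeric(bit_depth) || length(bit_depth) != 1L ||
      bit_depth != as.integer(bit_depth) || bit_depth < 1 || bit_depth > 16) {
    stop("bit_depth must be an integer in 1..16", call. = FALSE)
  }
  if (!is.numeric(dynamic_range_g) || length(dynamic_range_g) != 1L ||
      dynamic_range_g <= 0) {
    stop("dynamic_range_g must be positive", call. = FALSE)
  }
  structure(
    list(label = label,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         bit_depth = as.integer(bit_depth),
         dynamic_range_g = as.numeric(dynamic_range_g),
         placement = placement),
    class = "device_spec"
  )
}

#' @export
print.device_spec <- function(x, ...) {
  cat(sprintf("<device_spec> %s: %.4g Hz/axis, %d-bit (+/- %g g), %s-worn\n",
              x$label, x$sampling_rate_hz, x$bit_depth, x$dynamic_range_g,
              x$placement))
  invisible(x)
}

#' Built-in device specifications
#'
#' `chest_patch_spec()` describes the ECG patch's embedded accelerometer
#' (about 1.56 Hz per axis, 8-bit codes, +/- 2 g, chest-worn); the nominal
#' rate can be overridden when a recording header declares one.
#' `hip_monitor_spec()` describes the hip-worn research accelerometer
#' (40 Hz per axis, 12-bit codes, +/- 8 g).
#'
#' @param sampling_rate_hz per-axis sampling rate; defaults to the device's
#'   nominal rate.
#' @return A [device_spec()].
#' @examples
#' quantization_resolution(hip_monitor_spec())  # 0.00390625 g/level
#' @export
chest_patch_spec <- function(sampling_rate_hz = 1.56) {
  device_spec("chest_patch", sampling_rate_hz, 8L, 2, "chest")
}

#' @rdname chest_patch_spec
#' @export
hip_monitor_spec <- function(sampling_rate_hz = 40) {
  device_spec("hip_monitor", sampling_rate_hz, 12L, 8, "hip")
}

#' Quantization resolution of a device
#'
#' The width of one code level in g: `2 * dynamic_range_g / 2^bit_depth`.
#' For the 12-bit +/- 8 g hip monitor this is 2 x 8 / 4096 = 0.00390625 g
#' (about 0.004 g); for the 8-bit +/- 2 g chest patch it is
#' 2 x 2 / 256 = 0.015625 g (about 0.015 g). Quantization noise differs
#' between devices accordingly.
#'
#' @param spec a [device_spec()].
#' @return g per code level (scalar).
#' @export
quantization_resolution <- function(spec) {
  stopifnot(inherits(spec, "device_spec"))
  2 * spec$dynamic_range_g / 2^spec$bit_depth
}

# The zero-g code. Codes are offset-binary: code 2^(b-1) represents 0 g, so
# the representable grid is (code - 2^(b-1)) * step for codes 0 .. 2^b - 1,
# spanning the slightly asymmetric interval [-R, R - step] as is conventional
# for two's-complement-style MEMS converters. Centralised here so that an
# alternative zero offset (e.g. 2^(b-1) - 0.5) is a one-line change.
code_offset <- function(spec) 2^(spec$bit_depth - 1L)

# Codes -> g (affine map).
code_to_g <- function(code, spec) {
  (code - code_offset(spec)) * quantization_resolution(spec)
}

# g -> nearest code, clipped to the representable 0 .. 2^b - 1 range.
# Returns the integer codes; attribute "n_clipped" counts out-of-range inputs.
g_to_code <- function(g, spec) {
  step <- quantization_resolution(spec)
  code <- round(g / step) + code_offset(spec)
  lo <- 0
  hi <- 2^spec$bit_depth - 1
  n_clipped <- sum(code < lo | code > hi)
  code <- pmin(pmax(code, lo), hi)
  structure(code, n_clipped = n_clipped)
}

#' Snap a signal to a device's code grid
#'
#' Maps each value to the nearest representable level of the device's
#' analog-to-digital grid, clipping to the representable range. For in-range
#' inputs `|out - in| <= quantization_resolution(spec) / 2`; the operation is
#' idempotent.
#'
#' @param x numeric vector of accelerations in g.
#' @param spec a [device_spec()].
#' @return numeric vector of the same length on the device's grid.
#' @examples
#' quantize(0.013, chest_patch_spec())  # 0.015625
#' @export
quantize <- function(x, spec) {
  stopifnot(inherits(spec, "device_spec"))
  code <- g_to_code(x, spec)
  code_to_g(as.numeric(code), spec)
}
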