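#' Raw tri-axial accelerometer recording
#'
#' Container for a timestamped tri-axial acceleration series in g together
#' with its [device_spec()]. Sample `i` (1-based) is implicitly timestamped
#' `start_time + (i - 1) / sampling_rate_hz`.
#'
#' @param participant_id participant identifier.
#' @param device a [device_spec()].
#' @param start_time recording start, timezone-naive local clock time.
#' @param x,y,z equal-length numeric vectors of per-axis acceleration in g;
#'   every sample must lie within the device's dynamic range.
#' @param validate check the dynamic-range invariant (default TRUE). Set to
#'   FALSE only to build deliberately out-of-range input, e.g. to exercise
#'   [encode_zacl()]'s clipping.
#' @return An object of class `raw_accel`.
#' @export
raw_accel_recording <- function(participant_id, device, start_time, x, y, z,
                                validate = TRUE) {
  stopifnot(inherits(device, "device_spec"))
  if (length(x) != length(y) || length(y) != length(z)) {
    stop("x, y, z must have equal length", call. = FALSE)
  }
  rng <- device$dynamic_range_g
  if (validate) {
    for (axis in list(x, y, z)) {
      if (length(axis) && (min(axis) < -rng || max(axis) > rng)) {
        stop("sample outside the device dynamic range of +/- ", rng, " g",
             call. = FALSE)
      }
    }
  }
  structure(
    list(participant_id = as.character(participant_id),
         device = device,
         start_time = parse_naive_time(start_time),
         x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)),
    class = "raw_accel"
  )
}

#' @export
print.raw_accel <- function(x, ...) {
  n <- length(x$x)
  dur <- n / x$device$sampling_rate_hz
  cat(sprintf(
    "<raw_accel> participant %s, device %s\n  %d samples/axis from %s (%.2f h)\n",
    x$participant_id, x$device$label, n, format_naive_time(x$start_time),
    dur / 3600))
  invisible(x)
}

#' Sample timestamps of a recording
#'
#' @param rec a `raw_accel` recording (or any object with `start_time` and a
#'   device sampling rate).
#' @return POSIXct vector of per-sample timestamps.
#' @keywords internal
sample_times <- function(rec) {
  n <- length(rec$x)
  rec$start_time + (seq_len(n) - 1) / rec$device$sampling_rate_hz
}

#' Single-lead ECG series
#'
#' Container for an ECG voltage series in millivolts used for chest-patch
#' wear detection.
#'
#' @param participant_id participant identifier.
#' @param start_time recording start (naive local clock time).
#' @param sampling_rate_hz samples per second (the patch records at 199.8 Hz).
#' @param mv numeric vector of voltages in mV; must be finite.
#' @return An object of class `ecg_series`.
#' @export
ecg_series <- function(participant_id, start_time, sampling_rate_hz, mv) {
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be positive", call. = FALSE)
  }
  if (length(mv) && !all(is.finite(mv))) {
    stop("ECG values must be finite", call. = FALSE)
  }
  structure(
    list(participant_id = as.character(participant_id),
         start_time = parse_naive_time(start_time),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         mv = as.numeric(mv)),
    class = "ecg_series"
  )
}

#' @export
print.ecg_series <- function(x, ...) {
  cat(sprintf("<ecg_series> participant %s: %d samples at %.1f Hz from %s\n",
              x$participant_id, length(x$mv), x$sampling_rate_hz,
              format_naive_time(x$start_time)))
  invisible(x)
}
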