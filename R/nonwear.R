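# Device-specific non-wear detection and wear-validity filtering.
#
# Chest patch: the patch records ECG whenever it is attached, so wear is
# inferred from the ECG — timepoints whose deviation from a 2-s moving
# average is below 0.1 mV carry no cardiac signal and are labelled non-wear.
# Hip monitor: worn detection follows the epidemiological convention of
# flagging runs of >= 90 consecutive zero-activity minutes as non-wear.

new_nonwear_mask <- function(participant_id, device_label, minute_start, wear) {
  structure(
    data.frame(minute_start = minute_start, wear = as.logical(wear)),
    participant_id = as.character(participant_id),
    device_label = as.character(device_label),
    class = c("nonwear_mask", "data.frame")
  )
}

#' @export
print.nonwear_mask <- function(x, ...) {
  cat(sprintf("<nonwear_mask> participant %s (%s): %d minutes, %.1f%% worn\n",
              attr(x, "participant_id"), attr(x, "device_label"), nrow(x),
              if (nrow(x)) 100 * mean(x$wear) else NA_real_))
  invisible(x)
}

#' ECG-based non-wear detection for the chest patch
#'
#' The ECG is smoothed with a centred rectangular moving average of
#' `window_s` seconds (edges truncated); a timepoint is labelled non-wear
#' when the absolute difference between the raw and smoothed ECG is below
#' `threshold_mv`. Pointwise labels are aggregated to the minute grid: a
#' minute counts as worn iff at least `min_active_fraction` of its samples
#' deviate by `threshold_mv` or more. QRS complexes occupy roughly 10% of
#' samples at 60 bpm, so worn minutes clear the default 2% easily, while a
#' disconnected flat lead does not.
#'
#' @param ecg an [ecg_series()].
#' @param window_s moving-average window in seconds (default 2).
#' @param threshold_mv deviation threshold in millivolts (default 0.1).
#' @param min_active_fraction minimum fraction of above-threshold samples
#'   for a worn minute (default 0.02).
#' @return A minute-resolution `nonwear_mask` covering the recording span.
#' @export
ecg_nonwear <- function(ecg, window_s = 2, threshold_mv = 0.1,
                        min_active_fraction = 0.02) {
  stopifnot(inherits(ecg, "ecg_series"))
  x <- ecg$mv
  n <- length(x)
  if (n == 0L) stop("empty ECG series", call. = FALSE)
  fs <- ecg$sampling_rate_hz
  if (fs * window_s < 2) {
    stop("window too short: fewer than 2 samples per smoothing window",
         call. = FALSE)
  }
  h <- max(1L, as.integer(round(fs * window_s / 2)))
  active <- active_deviation_cpp(x, h, threshold_mv)
  # minute grid anchored at the recording's start minute, covering the span
  t0 <- as.numeric(ecg$start_time)
  m0 <- floor(t0 / 60) * 60
  tab <- minute_tabulate_cpp(active, fs, t0 - m0)
  n_tot <- tab$total
  nb <- length(n_tot)
  frac <- ifelse(n_tot > 0, tab$active / n_tot, 0)
  new_nonwear_mask(
    ecg$participant_id, "chest_patch",
    as.POSIXct(m0 + 60 * (seq_len(nb) - 1), origin = "1970-01-01", tz = "UTC"),
    frac >= min_active_fraction
  )
}

#' Zero-activity-run non-wear detection for the hip monitor
#'
#' Any maximal run of at least `run_minutes` consecutive zero-activity
#' minutes is labelled non-wear; all other minutes are worn. Vendor activity
#' counts are proprietary, so a documented minute-level proxy defines a
#' "zero-activity minute": the minute-level MAD of the hip vector magnitude
#' is below the device's quantization resolution (one code step,
#' 0.00390625 g for the 12-bit +/- 8 g monitor). A resting but worn device
#' shows sensor noise above one code step; an off-body device does not.
#' Minutes whose MAD is missing are treated as zero-activity.
#'
#' @param minute_activity an `epoch_series` at 60-s epochs (minute-level
#'   MAD), or a data.frame with `minute_start` and a numeric activity column
#'   named `mad` or `value`.
#' @param run_minutes minimum run length in minutes (default 90).
#' @param zero_threshold_g activity level below which a minute counts as
#'   zero (default one hip-monitor code step).
#' @return A minute-resolution `nonwear_mask`.
#' @export
actigraph_nonwear <- function(minute_activity, run_minutes = 90,
                              zero_threshold_g =
                                quantization_resolution(hip_monitor_spec())) {
  if (inherits(minute_activity, "epoch_series")) {
    if (attr(minute_activity, "epoch_length_s") != 60) {
      stop("minute_activity must be on a one-minute grid", call. = FALSE)
    }
    minute_start <- minute_activity$epoch_start
    v <- minute_activity$mad
    pid <- attr(minute_activity, "participant_id")
    dev <- attr(minute_activity, "device_label")
  } else {
    minute_start <- parse_naive_time(minute_activity$minute_start)
    v <- if (!is.null(minute_activity$mad)) minute_activity$mad else minute_activity$value
    pid <- if (!is.null(attr(minute_activity, "participant_id")))
      attr(minute_activity, "participant_id") else "unknown"
    dev <- "hip_monitor"
  }
  zero <- is.na(v) | v < zero_threshold_g
  wear <- rep(TRUE, length(zero))
  if (length(zero)) {
    r <- rle(zero)
    flag <- r$values & r$lengths >= run_minutes
    wear <- !inverse.rle(list(values = flag, lengths = r$lengths))
  }
  new_nonwear_mask(pid, dev, minute_start, wear)
}

#' Joint wear mask of two devices
#'
#' A minute is jointly worn iff it is worn in both masks; minutes covered by
#' only one (or neither) mask's span are non-wear. The result covers the
#' union of the two spans on a contiguous minute grid.
#'
#' @param mask_a,mask_b minute-resolution `nonwear_mask`s for the same
#'   participant.
#' @return A `nonwear_mask` with device label `"joint"`.
#' @export
joint_wear <- function(mask_a, mask_b) {
  stopifnot(inherits(mask_a, "nonwear_mask"), inherits(mask_b, "nonwear_mask"))
  pa <- attr(mask_a, "participant_id")
  pb <- attr(mask_b, "participant_id")
  if (!identical(pa, pb)) {
    stop("masks belong to different participants", call. = FALSE)
  }
  ta <- as.numeric(mask_a$minute_start)
  tb <- as.numeric(mask_b$minute_start)
  if (!nrow(mask_a) || !nrow(mask_b)) {
    warning("empty wear mask; joint wear is empty", call. = FALSE)
  } else if (max(ta) < min(tb) || max(tb) < min(ta)) {
    warning("device wear spans do not overlap; no jointly worn minutes",
            call. = FALSE)
  }
  lo <- min(c(ta, tb))
  hi <- max(c(ta, tb))
  grid <- seq(lo, hi, by = 60)
  wa <- rep(FALSE, length(grid))
  wb <- rep(FALSE, length(grid))
  wa[match(ta, grid)] <- mask_a$wear
  wb[match(tb, grid)] <- mask_b$wear
  new_nonwear_mask(
    pa, "joint",
    as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
    wa & wb
  )
}

#' Wear-validity inclusion filter
#'
#' A calendar day is valid iff the jointly worn minutes falling in the
#' daytime clock window (default 7 a.m.-11 p.m., i.e. `[07:00, 23:00)`)
#' total at least `min_hours`; a participant is included iff at least
#' `min_days` days are valid.
#'
#' @param mask minute-resolution joint wear mask (see [joint_wear()]).
#' @param min_days minimum number of valid days (default 3).
#' @param min_hours minimum in-window wear per valid day, in hours
#'   (default 10).
#' @param window_start_hour,window_end_hour daytime clock window bounds in
#'   hours (defaults 7 and 23; the window is half-open).
#' @return An object of class `validity_summary`: per-day in-window wear
#'   minutes and valid-day flags, the participant's valid-day count, and the
#'   inclusion decision.
#' @export
validity_filter <- function(mask, min_days = 3, min_hours = 10,
                            window_start_hour = 7, window_end_hour = 23) {
  stopifnot(inherits(mask, "nonwear_mask"))
  sod <- seconds_of_day(mask$minute_start)
  in_window <- sod >= window_start_hour * 3600 & sod < window_end_hour * 3600
  day <- naive_date(mask$minute_start)
  days <- sort(unique(day))
  wear_min <- vapply(days, function(d) {
    sum(mask$wear & in_window & day == d)
  }, numeric(1))
  valid <- wear_min >= min_hours * 60
  structure(
    list(participant_id = attr(mask, "participant_id"),
         days = data.frame(day = days, wear_minutes_in_window = wear_min,
                           valid = valid),
         n_valid_days = sum(valid),
         included = sum(valid) >= min_days,
         min_days = min_days, min_hours = min_hours,
         window = c(window_start_hour, window_end_hour)),
    class = "validity_summary"
  )
}

#' @export
print.validity_summary <- function(x, ...) {
  cat(sprintf(
    "<validity_summary> participant %s: %d/%d days valid (>= %g h in [%02d:00, %02d:00)) -> %s\n",
    x$participant_id, x$n_valid_days, nrow(x$days), x$min_hours,
    x$window[1], x$window[2], if (x$included) "included" else "excluded"))
  invisible(x)
}
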