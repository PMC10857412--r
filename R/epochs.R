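# Vector magnitude and MAD epoch summaries.
#
# MAD (mean amplitude deviation) over an epoch of H samples is
#   MAD = (1/H) * sum_h | r_h - mean(r) |
# computed on the vector magnitude r = sqrt(x^2 + y^2 + z^2). Because the
# epoch mean is subtracted, the static gravity component cancels and MAD
# reflects movement intensity regardless of sensor orientation.

#' Vector magnitude of a tri-axial recording
#'
#' Collapses the three axes to the Euclidean norm
#' `r_i = sqrt(x_i^2 + y_i^2 + z_i^2)` per sample.
#'
#' @param rec a [raw_accel_recording()].
#' @return An object of class `vm_series`: participant, device label, start
#'   time, sampling rate and the non-negative magnitude `values` in g.
#' @export
vector_magnitude <- function(rec) {
  stopifnot(inherits(rec, "raw_accel"))
  structure(
    list(participant_id = rec$participant_id,
         device_label = rec$device$label,
         start_time = rec$start_time,
         sampling_rate_hz = rec$device$sampling_rate_hz,
         values = vector_magnitude_cpp(rec$x, rec$y, rec$z)),
    class = "vm_series"
  )
}

#' @export
print.vm_series <- function(x, ...) {
  cat(sprintf("<vm_series> participant %s (%s): %d samples at %.4g Hz\n",
              x$participant_id, x$device_label, length(x$values),
              x$sampling_rate_hz))
  invisible(x)
}

#' Construct a vm_series directly
#'
#' Mostly useful in tests; [vector_magnitude()] is the normal constructor.
#'
#' @param participant_id,device_label,start_time,sampling_rate_hz,values
#'   fields of the series.
#' @return A `vm_series`.
#' @export
vm_series <- function(participant_id, device_label, start_time,
                      sampling_rate_hz, values) {
  if (length(values) && min(values) < 0) {
    stop("vector magnitudes must be non-negative", call. = FALSE)
  }
  structure(
    list(participant_id = as.character(participant_id),
         device_label = as.character(device_label),
         start_time = parse_naive_time(start_time),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         values = as.numeric(values)),
    class = "vm_series"
  )
}

#' MAD over a fixed epoch grid
#'
#' Partitions the magnitude series into contiguous, non-overlapping,
#' half-open epochs `[t, t + epoch_length_s)` on a grid anchored at local
#' midnight, and computes the mean amplitude deviation within each epoch at
#' the device's native rate. An epoch with fewer than
#' `min_fraction * epoch_length_s * sampling_rate_hz` samples (e.g. the
#' partial epochs at the recording edges) is reported as missing.
#'
#' @param vm a `vm_series` (see [vector_magnitude()]).
#' @param epoch_length_s epoch length in seconds; must be a positive
#'   multiple of 60 (the analysis windows are 60, 300, 600, 1800, 3600 and
#'   7200 s).
#' @param min_fraction minimum fraction of the nominal per-epoch sample
#'   count required for the epoch to be scored (default 0.9).
#' @return An object of class `epoch_series`: a data.frame with
#'   `epoch_start` (POSIXct), `mad` (g; NA where the epoch is unscored) and
#'   `n_samples`, plus participant/device/epoch-length attributes.
#' @export
epoch_mad <- function(vm, epoch_length_s, min_fraction = 0.9) {
  stopifnot(inherits(vm, "vm_series"))
  if (!is.numeric(epoch_length_s) || length(epoch_length_s) != 1L ||
      epoch_length_s <= 0 || epoch_length_s %% 60 != 0) {
    stop("epoch_length_s must be a positive multiple of 60 seconds",
         call. = FALSE)
  }
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]", call. = FALSE)
  }
  v <- vm$values
  fs <- vm$sampling_rate_hz
  if (!length(v)) {
    out <- data.frame(epoch_start = as.POSIXct(numeric(0), origin = "1970-01-01",
                                               tz = "UTC"),
                      mad = numeric(0), n_samples = integer(0))
    return(as_epoch_series(out, vm, epoch_length_s))
  }
  midnight <- local_midnight(vm$start_time)
  offset <- as.numeric(vm$start_time) - as.numeric(midnight)
  res <- epoch_mad_cpp(v, fs, offset, epoch_length_s)
  counts <- res$counts
  mad <- res$mad
  nominal <- epoch_length_s * fs
  mad[counts < min_fraction * nominal] <- NA_real_
  out <- data.frame(
    epoch_start = midnight + (res$first_epoch + seq_along(counts) - 1) *
      epoch_length_s,
    mad = mad,
    n_samples = counts
  )
  as_epoch_series(out, vm, epoch_length_s)
}

as_epoch_series <- function(df, vm, epoch_length_s) {
  structure(df,
            participant_id = vm$participant_id,
            device_label = vm$device_label,
            sampling_rate_hz = vm$sampling_rate_hz,
            epoch_length_s = epoch_length_s,
            class = c("epoch_series", "data.frame"))
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> participant %s (%s), %d-s epochs: %d epochs, %d scored\n",
              attr(x, "participant_id"), attr(x, "device_label"),
              attr(x, "epoch_length_s"), nrow(x), sum(!is.na(x$mad))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Time-synchronised pairing of two devices' epoch series
#'
#' Inner-joins two epoch series (same participant, same epoch length) on
#' their midnight-anchored epoch start timestamps, keeping only epochs that
#' are scored in both series and — when a joint wear mask is supplied —
#' fully jointly worn (every minute of the epoch worn on both devices).
#'
#' @param a reference-device `epoch_series` (hip monitor).
#' @param b test-device `epoch_series` (chest patch).
#' @param joint_wear optional minute-resolution wear mask from
#'   [joint_wear()]; epochs containing any non-worn minute are dropped.
#' @return An object of class `paired_epochs`: data.frame with
#'   `epoch_start`, `mad_a`, `mad_b`; attribute `dropped` counts epochs
#'   removed per reason.
#' @export
align_epoch_grids <- function(a, b, joint_wear = NULL) {
  stopifnot(inherits(a, "epoch_series"), inherits(b, "epoch_series"))
  la <- attr(a, "epoch_length_s")
  lb <- attr(b, "epoch_length_s")
  if (la != lb) {
    stop("epoch lengths differ (", la, " vs ", lb, " s)", call. = FALSE)
  }
  pa <- attr(a, "participant_id")
  pb <- attr(b, "participant_id")
  if (!identical(pa, pb)) {
    stop("cannot pair different participants ('", pa, "' vs '", pb, "')",
         call. = FALSE)
  }
  ka <- as.numeric(a$epoch_start)
  kb <- as.numeric(b$epoch_start)
  common <- intersect(ka, kb)
  ia <- match(common, ka)
  ib <- match(common, kb)
  mad_a <- a$mad[ia]
  mad_b <- b$mad[ib]
  scored <- !is.na(mad_a) & !is.na(mad_b)
  n_unscored <- sum(!scored)
  epoch_start <- as.POSIXct(common, origin = "1970-01-01", tz = "UTC")
  worn <- rep(TRUE, length(common))
  if (!is.null(joint_wear)) {
    worn <- epoch_fully_worn(joint_wear, epoch_start, la)
  }
  keep <- scored & worn
  dropped <- c(unmatched = length(ka) + length(kb) - 2L * length(common),
               unscored = n_unscored,
               nonwear = sum(scored & !worn))
  structure(
    data.frame(epoch_start = epoch_start[keep],
               mad_a = mad_a[keep], mad_b = mad_b[keep]),
    participant_id = pa,
    epoch_length_s = la,
    device_a = attr(a, "device_label"),
    device_b = attr(b, "device_label"),
    dropped = dropped,
    class = c("paired_epochs", "data.frame")
  )
}

#' @export
print.paired_epochs <- function(x, ...) {
  d <- attr(x, "dropped")
  cat(sprintf(
    "<paired_epochs> participant %s, %d-s epochs: %d pairs (%s vs %s)\n",
    attr(x, "participant_id"), attr(x, "epoch_length_s"), nrow(x),
    attr(x, "device_a"), attr(x, "device_b")))
  cat(sprintf("  dropped: %d unmatched, %d unscored, %d non-wear\n",
              d[["unmatched"]], d[["unscored"]], d[["nonwear"]]))
  invisible(x)
}

# TRUE for each epoch whose minutes are all worn in the minute mask; minutes
# outside the mask span count as not worn (conservative).
epoch_fully_worn <- function(mask, epoch_starts, epoch_length_s) {
  n_min <- epoch_length_s / 60
  m0 <- as.numeric(mask$minute_start[1])
  wear <- mask$wear
  nm <- length(wear)
  vapply(as.numeric(epoch_starts), function(t0) {
    j <- (t0 - m0) / 60 + seq_len(n_min)
    if (anyNA(j) || any(j < 1 | j > nm)) return(FALSE)
    all(wear[j])
  }, logical(1))
}
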