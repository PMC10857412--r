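# Independent brute-force oracles and small fixture builders.
# Oracles are deliberately naive (explicit loops, no shared code with the
# implementation) so they can vouch for the fast paths.

# Naive two-pass MAD over the midnight-anchored epoch grid.
naive_epoch_mad <- function(values, fs, start_time, epoch_length_s) {
  start <- as.numeric(as.POSIXct(start_time, tz = "UTC"))
  midnight <- floor(start / 86400) * 86400
  s <- (start - midnight) + (seq_along(values) - 1) / fs
  idx <- floor(s / epoch_length_s)
  out <- list()
  for (g in unique(idx)) {
    v <- values[idx == g]
    m <- sum(v) / length(v)
    out[[as.character(g)]] <- sum(abs(v - m)) / length(v)
  }
  data.frame(epoch_index = as.numeric(names(out)),
             mad = unlist(out, use.names = FALSE),
             n = as.vector(table(idx)[as.character(as.numeric(names(out)))]))
}

# Pointwise ECG wear rule, evaluated literally: centred rectangular moving
# average (edges truncated), deviation threshold, then per-minute fraction.
naive_ecg_wear_minutes <- function(mv, fs, window_s = 2, threshold_mv = 0.1,
                                   min_active_fraction = 0.02) {
  n <- length(mv)
  h <- max(1, round(fs * window_s / 2))
  active <- logical(n)
  for (i in seq_len(n)) {
    w <- mv[max(1, i - h):min(n, i + h)]
    active[i] <- abs(mv[i] - mean(w)) >= threshold_mv
  }
  minute <- floor((seq_len(n) - 1) / fs / 60)
  wear <- logical(max(minute) + 1)
  for (m in unique(minute)) {
    sel <- minute == m
    wear[m + 1] <- mean(active[sel]) >= min_active_fraction
  }
  wear
}

# Literal run-length scan: label minutes non-wear iff inside a maximal run
# of >= run_minutes consecutive zero minutes.
naive_zero_run_nonwear <- function(zero, run_minutes = 90) {
  n <- length(zero)
  wear <- rep(TRUE, n)
  i <- 1
  while (i <= n) {
    if (zero[i]) {
      j <- i
      while (j < n && zero[j + 1]) j <- j + 1
      if (j - i + 1 >= run_minutes) wear[i:j] <- FALSE
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  wear
}

# Sort-based quartiles with linear interpolation (independent of quantile()).
naive_quartiles <- function(x) {
  x <- sort(x)
  n <- length(x)
  interp <- function(p) {
    k <- (n - 1) * p + 1
    lo <- floor(k)
    hi <- ceiling(k)
    x[lo] + (k - lo) * (x[hi] - x[lo])
  }
  c(q1 = interp(0.25), median = interp(0.5), q3 = interp(0.75))
}

# Fixture builders ------------------------------------------------------

make_vm <- function(values, fs = 1, start = "2020-01-01T00:00:00",
                    id = "T01", device = "test") {
  vm_series(id, device, start, fs, values)
}

make_mask <- function(wear, start = "2020-01-01T00:00:00", id = "T01",
                      device = "dev") {
  madpair:::new_nonwear_mask(
    id, device,
    as.POSIXct(start, tz = "UTC") + 60 * (seq_along(wear) - 1),
    wear)
}

make_ecg <- function(mv, fs = 50, start = "2020-01-01T00:00:00", id = "T01") {
  ecg_series(id, start, fs, mv)
}

# Reduced-rate cohort configuration: same study design (wear schedules,
# noise, gains, drift) at lighter sampling rates so unit tests stay fast.
tiny_config <- function(n = 2, days = 3, hip_fs = 8, chest_fs = 1.56,
                        ecg_fs = 40, ...) {
  cohort_config(n_participants = n, days = days,
                chest_spec = chest_patch_spec(chest_fs),
                hip_spec = hip_monitor_spec(hip_fs),
                ecg_fs = ecg_fs, ...)
}
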