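# Synthetic paired-device cohort generator.
#
# Emulates the measurement chain of a chest-worn ECG patch and a hip-worn
# research accelerometer observing the same person: a shared latent
# activity-intensity profile, device-specific placement gain, sampling rate,
# quantization, sensor noise and quartz clock drift, a scheduled overnight
# removal of the hip device, and an ECG whose R-wave train drives the
# chest-patch wear detector. Ground truth is retained so detection and
# agreement can be scored against it.

#' Synthetic cohort configuration
#'
#' Defaults define the generator's reference study conditions: 20
#' participants wearing both devices for 5 days, the chest patch worn
#' continuously and the hip monitor removed overnight (23:00-07:00). Motion
#' is a band-limited walking-like oscillation (components in 1-3 Hz,
#' genuinely undersampled by the 1.56 Hz patch), worn-sensor noise is
#' 0.01 g per axis, placement is a scalar chest gain below 1 (the hip
#' reference reads slightly higher, as trunk-vs-hip placement differences
#' do), and each device's quartz clock drifts by up to +/- 50 ppm.
#'
#' @param n_participants cohort size (default 20).
#' @param days recording days per participant (default 5).
#' @param start_time recording start (local midnight by default).
#' @param chest_spec,hip_spec device specifications.
#' @param ecg_fs ECG sampling rate in Hz (default 199.8).
#' @param hip_off_hours clock hours during which the hip monitor is off,
#'   `c(start, end)` crossing midnight allowed (default `c(23, 7)`).
#' @param noise_sd_g per-axis white-noise SD in g while worn (default 0.01).
#' @param offbody_noise_step_frac off-body noise SD as a fraction of one
#'   quantization step (default 0.1, i.e. well below one code level).
#' @param chest_gain_range uniform range for the chest placement gain
#'   (default `c(0.85, 0.95)`; hip gain is 1).
#' @param drift_ppm_range uniform range of per-device clock drift in parts
#'   per million (default `c(-50, 50)`).
#' @param clock_offset_s_range uniform range of the per-device
#'   initialization clock offset in seconds (default `c(-10, 10)`),
#'   emulating devices set up from computers whose system times disagree.
#' @param hr_bpm_range uniform range of the (constant per-participant)
#'   heart rate in bpm (default `c(55, 80)`).
#' @param motion_band_hz frequency band of the motion oscillation in Hz
#'   (default `c(1, 3)`).
#' @param motion_components number of sinusoidal components drawn from the
#'   band per participant (default 3).
#' @param floor_g,peak_amplitude_g,bout_rate_per_hour,mean_bout_minutes,peak_hour,peak_width_hours
#'   latent-profile parameters, see [latent_intensity_profile()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 20, days = 5,
                          start_time = "2016-07-01T00:00:00",
                          chest_spec = chest_patch_spec(),
                          hip_spec = hip_monitor_spec(),
                          ecg_fs = 199.8,
                          hip_off_hours = c(23, 7),
                          noise_sd_g = 0.01,
                          offbody_noise_step_frac = 0.1,
                          chest_gain_range = c(0.85, 0.95),
                          drift_ppm_range = c(-50, 50),
                          clock_offset_s_range = c(-10, 10),
                          hr_bpm_range = c(55, 80),
                          motion_band_hz = c(1, 3),
                          motion_components = 3L,
                          floor_g = 0.01, peak_amplitude_g = 0.15,
                          bout_rate_per_hour = 4, mean_bout_minutes = 10,
                          peak_hour = 11, peak_width_hours = 3) {
  if (n_participants < 1 || n_participants != as.integer(n_participants)) {
    stop("config error: n_participants must be a positive integer",
         call. = FALSE)
  }
  if (days <= 0) stop("config error: days must be positive", call. = FALSE)
  if (noise_sd_g < 0 || offbody_noise_step_frac < 0 ||
      any(motion_band_hz <= 0) || motion_band_hz[1] > motion_band_hz[2] ||
      motion_components < 1 ||
      floor_g < 0 || peak_amplitude_g < 0 || bout_rate_per_hour < 0 ||
      mean_bout_minutes <= 0 || ecg_fs <= 0) {
    stop("config error: rates, amplitudes and noise levels must be non-negative",
         call. = FALSE)
  }
  stopifnot(inherits(chest_spec, "device_spec"), inherits(hip_spec, "device_spec"))
  structure(
    list(n_participants = as.integer(n_participants), days = days,
         start_time = parse_naive_time(start_time),
         chest_spec = chest_spec, hip_spec = hip_spec, ecg_fs = ecg_fs,
         hip_off_hours = hip_off_hours, noise_sd_g = noise_sd_g,
         offbody_noise_step_frac = offbody_noise_step_frac,
         chest_gain_range = chest_gain_range,
         drift_ppm_range = drift_ppm_range,
         clock_offset_s_range = clock_offset_s_range,
         hr_bpm_range = hr_bpm_range,
         motion_band_hz = motion_band_hz,
         motion_components = as.integer(motion_components),
         floor_g = floor_g, peak_amplitude_g = peak_amplitude_g,
         bout_rate_per_hour = bout_rate_per_hour,
         mean_bout_minutes = mean_bout_minutes,
         peak_hour = peak_hour, peak_width_hours = peak_width_hours),
    class = "cohort_config"
  )
}

#' Latent minute-level activity-intensity profile
#'
#' Generates a non-negative motion-amplitude profile lambda(t) in g at
#' minute resolution: a smooth Gaussian diurnal envelope (peaking late
#' morning, so activity is higher 8:00-14:00 than overnight) modulates both
#' the start rate and the amplitude of random activity bouts
#' (Poisson-seeded starts, geometric durations), on top of a constant
#' sedentary floor. Deterministic given the RNG state (or `seed`).
#'
#' @param days span in days.
#' @param floor_g sedentary floor amplitude in g.
#' @param peak_amplitude_g maximum bout amplitude in g.
#' @param bout_rate_per_hour bout start rate at the envelope peak.
#' @param mean_bout_minutes mean bout duration in minutes.
#' @param peak_hour,peak_width_hours centre and SD (hours) of the diurnal
#'   envelope.
#' @param seed optional integer seed; when NULL the current RNG state is
#'   used.
#' @return numeric vector of `days * 1440` per-minute amplitudes in g.
#' @export
latent_intensity_profile <- function(days, floor_g = 0.01,
                                     peak_amplitude_g = 0.15,
                                     bout_rate_per_hour = 4,
                                     mean_bout_minutes = 10,
                                     peak_hour = 11, peak_width_hours = 3,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_min <- round(days * 1440)
  hod <- (((seq_len(n_min) - 1L) %% 1440L) + 0.5) / 60
  env <- exp(-0.5 * ((hod - peak_hour) / peak_width_hours)^2)
  p_start <- pmin(1, bout_rate_per_hour / 60 * env)
  starts <- which(stats::runif(n_min) < p_start)
  amp <- numeric(n_min)
  for (s in starts) {
    dur <- stats::rgeom(1, 1 / mean_bout_minutes) + 1L
    idx <- s:min(n_min, s + dur - 1L)
    a <- stats::runif(1, 0.5, 1) * peak_amplitude_g
    amp[idx] <- pmax(amp[idx], a)
  }
  floor_g + env * amp
}

# Gravity orientation (unit vector) by placement: the resting orientation is
# idealised as one axis aligned with gravity, which keeps the static
# component exactly on both devices' code grids.
placement_gravity <- function(placement) {
  switch(placement, chest = c(1, 0, 0), hip = c(0, 0, 1),
         stop("unknown placement: ", placement, call. = FALSE))
}

# Minute-level wear schedule for one device given off-hours (possibly
# crossing midnight); NULL off_hours means continuously worn.
schedule_wear <- function(n_min, off_hours = NULL) {
  if (is.null(off_hours)) return(rep(TRUE, n_min))
  hod <- ((seq_len(n_min) - 1L) %% 1440L) / 60
  if (off_hours[1] <= off_hours[2]) {
    off <- hod >= off_hours[1] & hod < off_hours[2]
  } else {
    off <- hod >= off_hours[1] | hod < off_hours[2]
  }
  !off
}

#' Simulate one participant's ground truth
#'
#' Draws the participant-specific parameters (latent profile, placement
#' gains, clock drifts, heart rate, oscillation phases, render seeds) from
#' the given seed. Rendering to sensor signals is done separately by
#' [render_accel()] / [render_ecg()] so that raw samples need not be held
#' for the whole cohort at once.
#'
#' @param participant_id identifier.
#' @param seed integer seed for this participant's generator stream.
#' @param config a [cohort_config()].
#' @return An object of class `synthetic_truth`.
#' @export
simulate_participant <- function(participant_id, seed, config = cohort_config()) {
  set.seed(seed)
  n_min <- round(config$days * 1440)
  lambda <- latent_intensity_profile(
    config$days, config$floor_g, config$peak_amplitude_g,
    config$bout_rate_per_hour, config$mean_bout_minutes,
    config$peak_hour, config$peak_width_hours
  )
  n_comp <- config$motion_components
  w <- stats::runif(n_comp, 0.5, 1)
  truth <- list(
    participant_id = as.character(participant_id),
    seed = seed,
    start_time = config$start_time,
    days = config$days,
    ecg_fs = config$ecg_fs,
    # body-motion waveform parameters, shared by both devices
    motion_freqs = stats::runif(n_comp, config$motion_band_hz[1],
                                config$motion_band_hz[2]),
    motion_weights = w / sqrt(sum(w^2)),
    motion_phases = matrix(stats::runif(3 * n_comp, 0, 2 * pi), nrow = 3),
    noise_sd_g = config$noise_sd_g,
    offbody_noise_step_frac = config$offbody_noise_step_frac,
    lambda = lambda,
    wear = list(chest = schedule_wear(n_min, NULL),
                hip = schedule_wear(n_min, config$hip_off_hours)),
    gain = c(chest = stats::runif(1, config$chest_gain_range[1],
                                  config$chest_gain_range[2]),
             hip = 1),
    drift_ppm = c(chest = stats::runif(1, config$drift_ppm_range[1],
                                       config$drift_ppm_range[2]),
                  hip = stats::runif(1, config$drift_ppm_range[1],
                                     config$drift_ppm_range[2])),
    clock_offset_s = c(chest = stats::runif(1, config$clock_offset_s_range[1],
                                            config$clock_offset_s_range[2]),
                       hip = stats::runif(1, config$clock_offset_s_range[1],
                                          config$clock_offset_s_range[2])),
    hr_bpm = stats::runif(1, config$hr_bpm_range[1], config$hr_bpm_range[2]),
    render_seeds = c(chest = sample.int(2^31 - 2, 1),
                     hip = sample.int(2^31 - 2, 1),
                     ecg = sample.int(2^31 - 2, 1))
  )
  class(truth) <- "synthetic_truth"
  truth
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> participant %s: %g days, chest gain %.3f, drift %.1f/%.1f ppm, HR %.0f bpm\n",
    x$participant_id, x$days, x$gain[["chest"]], x$drift_ppm[["chest"]],
    x$drift_ppm[["hip"]], x$hr_bpm))
  invisible(x)
}

#' Worn intervals of a truth schedule
#'
#' @param truth a `synthetic_truth`.
#' @param device `"chest"` or `"hip"`.
#' @return data.frame with `start`, `end` (POSIXct, half-open worn
#'   intervals).
#' @export
wear_intervals <- function(truth, device = c("chest", "hip")) {
  device <- match.arg(device)
  w <- truth$wear[[device]]
  r <- rle(w)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  t0 <- truth$start_time
  data.frame(start = t0 + (starts[keep] - 1L) * 60,
             end = t0 + ends[keep] * 60)
}

#' Render a truth record to a device's accelerometer signal
#'
#' Per axis: a constant gravity component (unit vector set by placement) +
#' a zero-mean band-limited oscillation (the participant's body-motion
#' waveform, shared by both devices) whose per-sample amplitude is
#' `gain * lambda(t)` (split across axes) + white sensor noise, sampled at
#' the device's nominal rate under that device's clock drift (sample i
#' observes the latent process at
#' `t_i * (1 + drift_ppm * 1e-6)` but is timestamped nominally), then
#' snapped to the device's code grid by [quantize()]. During scheduled
#' non-wear the signal is the gravity constant plus noise well below one
#' code step.
#'
#' @param truth a `synthetic_truth`.
#' @param spec the [device_spec()] to render for; its placement selects the
#'   wear schedule, gain, drift and phases.
#' @return A [raw_accel_recording()].
#' @export
render_accel <- function(truth, spec) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(spec, "device_spec"))
  key <- spec$placement
  set.seed(truth$render_seeds[[key]])
  fs <- spec$sampling_rate_hz
  n <- floor(truth$days * 86400 * fs)
  step <- quantization_resolution(spec)
  m <- render_axes_cpp(
    n, fs, 1 + truth$drift_ppm[[key]] * 1e-6, truth$clock_offset_s[[key]],
    truth$gain[[key]] * truth$lambda / sqrt(3),
    truth$wear[[key]],
    truth$noise_sd_g, truth$offbody_noise_step_frac * step,
    placement_gravity(key), truth$motion_freqs, truth$motion_weights,
    truth$motion_phases,
    step, code_offset(spec), 2^spec$bit_depth - 1
  )
  raw_accel_recording(truth$participant_id, spec, truth$start_time,
                      m[, 1], m[, 2], m[, 3])
}

#' Render a truth record to the chest patch's ECG
#'
#' While the chest patch is worn: a periodic train of 1 mV half-sine
#' R-waves of ~0.1 s width at the participant's heart rate on a near-zero
#' baseline, which guarantees well over 2% of each worn minute's samples
#' deviate by >= 0.1 mV from a 2-s moving average. While off-body: a flat
#' baseline with noise below 0.01 mV. The chest clock drift applies.
#'
#' @param truth a `synthetic_truth`.
#' @param fs ECG sampling rate in Hz (default from the truth record,
#'   normally 199.8).
#' @return An [ecg_series()].
#' @export
render_ecg <- function(truth, fs = truth$ecg_fs) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$render_seeds[["ecg"]])
  n <- floor(truth$days * 86400 * fs)
  mv <- render_ecg_cpp(n, fs, 1 + truth$drift_ppm[["chest"]] * 1e-6,
                       truth$clock_offset_s[["chest"]],
                       truth$wear$chest, 60 / truth$hr_bpm, 0.1, 0.005)
  ecg_series(truth$participant_id, truth$start_time, fs, mv)
}

#' Simulate a paired-device cohort
#'
#' Draws every participant's ground truth from one master seed (a named
#' generator stream per participant guarantees reproducibility) and,
#' optionally, renders and writes each participant's sensor files in the
#' package's text/binary dialects together with a ground-truth JSON. With
#' `dir = NULL` the cohort stays lazy: raw signals are rendered on demand
#' (by [render_participant()] or [run_pipeline()]), which keeps memory flat
#' for native-rate cohorts.
#'
#' @param config a [cohort_config()].
#' @param seed master integer seed.
#' @param dir optional output directory; when given, each participant gets
#'   a subdirectory with `chest.zacl`/`chest.hea`, `hip.csv`, `ecg.csv` and
#'   `truth.json`.
#' @return An object of class `synthetic_cohort`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  p_seeds <- sample.int(2^31 - 2, n)
  participants <- lapply(seq_len(n), function(i) {
    simulate_participant(ids[i], p_seeds[i], config)
  })
  names(participants) <- ids
  cohort <- structure(
    list(config = config, seed = seed, participants = participants,
         dir = dir),
    class = "synthetic_cohort"
  )
  if (!is.null(dir)) write_cohort_files(cohort, dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants x %g days (seed %s)%s\n",
              length(x$participants), x$config$days, format(x$seed),
              if (is.null(x$dir)) " [lazy]" else paste0(" -> ", x$dir)))
  invisible(x)
}

#' Render one participant's sensor signals
#'
#' @param cohort a `synthetic_cohort`.
#' @param id participant id (or index).
#' @return list with `chest` and `hip` [raw_accel_recording()]s and an
#'   `ecg` [ecg_series()].
#' @export
render_participant <- function(cohort, id) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  truth <- if (is.character(id)) cohort$participants[[id]] else
    cohort$participants[[id]]
  if (is.null(truth)) stop("unknown participant: ", id, call. = FALSE)
  list(chest = render_accel(truth, cohort$config$chest_spec),
       hip = render_accel(truth, cohort$config$hip_spec),
       ecg = render_ecg(truth))
}

truth_to_json <- function(truth, path) {
  iv_chest <- wear_intervals(truth, "chest")
  iv_hip <- wear_intervals(truth, "hip")
  obj <- list(
    participant_id = truth$participant_id,
    seed = truth$seed,
    start_time = format_naive_time(truth$start_time),
    days = truth$days,
    gain = as.list(truth$gain),
    drift_ppm = as.list(truth$drift_ppm),
    clock_offset_s = as.list(truth$clock_offset_s),
    hr_bpm = truth$hr_bpm,
    noise_sd_g = truth$noise_sd_g,
    lambda_g = truth$lambda,
    wear_intervals = list(
      chest = data.frame(start = format_naive_time(iv_chest$start),
                         end = format_naive_time(iv_chest$end)),
      hip = data.frame(start = format_naive_time(iv_hip$start),
                       end = format_naive_time(iv_hip$end))
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

write_cohort_files <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (truth in cohort$participants) {
    pdir <- file.path(dir, truth$participant_id)
    dir.create(pdir, showWarnings = FALSE)
    chest <- render_accel(truth, cohort$config$chest_spec)
    write_zacl(chest, file.path(pdir, "chest.zacl"),
               file.path(pdir, "chest.hea"))
    hip <- render_accel(truth, cohort$config$hip_spec)
    write_actigraph_csv(hip, file.path(pdir, "hip.csv"))
    ecg <- render_ecg(truth)
    write_ecg_csv(ecg, file.path(pdir, "ecg.csv"))
    truth_to_json(truth, file.path(pdir, "truth.json"))
  }
  invisible(dir)
}
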