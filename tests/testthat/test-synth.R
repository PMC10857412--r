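# Synthetic cohort generator: latent profile, device rendering, ECG
# rendering, determinism.

test_that("latent profile is deterministic, non-negative and diurnal", {
  l1 <- latent_intensity_profile(2, seed = 99)
  l2 <- latent_intensity_profile(2, seed = 99)
  expect_identical(l1, l2)
  expect_length(l1, 2 * 1440)
  expect_true(all(l1 >= 0))

  # degenerate parameters give an identically zero profile
  l0 <- latent_intensity_profile(1, floor_g = 0, peak_amplitude_g = 0, seed = 1)
  expect_identical(l0, rep(0, 1440))

  # morning/early-afternoon activity exceeds overnight activity on average
  set.seed(41)
  morning <- overnight <- 0
  hod <- (((seq_len(1440) - 1) %% 1440) + 0.5) / 60
  for (i in 1:40) {
    l <- latent_intensity_profile(1)
    morning <- morning + mean(l[hod >= 8 & hod < 14])
    overnight <- overnight + mean(l[hod < 6])
  }
  expect_gt(morning, overnight)
})

test_that("a motionless noiseless truth renders to pure gravity", {
  cfg <- tiny_config(n = 1, days = 1,
                     floor_g = 0, peak_amplitude_g = 0, noise_sd_g = 0,
                     offbody_noise_step_frac = 0,
                     drift_ppm_range = c(0, 0))
  truth <- simulate_participant("Z1", 7, cfg)
  for (spec in list(cfg$chest_spec, cfg$hip_spec)) {
    rec <- render_accel(truth, spec)
    vm <- vector_magnitude(rec)
    expect_true(all(vm$values == 1))       # unit gravity, exactly on-grid
    e <- epoch_mad(vm, 300, min_fraction = 0.5)
    expect_true(all(e$mad[!is.na(e$mad)] == 0))
  }
})

test_that("equal-gain noiseless renders agree within summed quantization steps", {
  cfg <- tiny_config(n = 1, days = 1, noise_sd_g = 0,
                     offbody_noise_step_frac = 0,
                     chest_gain_range = c(1, 1),
                     drift_ppm_range = c(0, 0),
                     hip_off_hours = NULL)
  truth <- simulate_participant("Z2", 8, cfg)
  # fix well-conditioned component frequencies: a component aliasing to
  # near-DC at 1.56 Hz would make the 5-min sampled MADs legitimately
  # diverge, which is not what this bound is about
  truth$motion_freqs <- c(1.3, 2.0, 2.7)
  truth$clock_offset_s[] <- 0
  mad_chest <- epoch_mad(vector_magnitude(render_accel(truth, cfg$chest_spec)),
                         300, min_fraction = 0.5)
  mad_hip <- epoch_mad(vector_magnitude(render_accel(truth, cfg$hip_spec)),
                       300, min_fraction = 0.5)
  p <- align_epoch_grids(mad_hip, mad_chest)
  bound <- quantization_resolution(cfg$chest_spec) +
    quantization_resolution(cfg$hip_spec)
  expect_gt(nrow(p), 200)
  expect_lte(max(abs(p$mad_a - p$mad_b)), bound)
})

test_that("rendered ECG drives the wear detector to the scheduled intervals", {
  cfg <- tiny_config(n = 1, days = 1)
  truth <- simulate_participant("Z3", 9, cfg)

  # fully off-body: constant baseline -> everywhere non-wear
  t_off <- truth
  t_off$wear$chest <- rep(FALSE, length(t_off$wear$chest))
  off <- ecg_nonwear(render_ecg(t_off))
  expect_false(any(off$wear))

  # fully worn at 60 bpm -> everywhere wear
  t_on <- truth
  t_on$hr_bpm <- 60
  on <- ecg_nonwear(render_ecg(t_on))
  expect_true(all(on$wear))

  # scheduled 08:00-22:00 recovered within one minute at the boundaries
  t_sched <- truth
  hod <- ((seq_along(truth$wear$chest) - 1) %% 1440) / 60
  t_sched$wear$chest <- hod >= 8 & hod < 22
  det <- ecg_nonwear(render_ecg(t_sched))
  worn <- which(det$wear)
  day0 <- as.numeric(truth$start_time)
  first_min <- (as.numeric(det$minute_start[min(worn)]) - day0) / 60
  last_min <- (as.numeric(det$minute_start[max(worn)]) - day0) / 60
  expect_lte(abs(first_min - 8 * 60), 1)
  expect_lte(abs(last_min - (22 * 60 - 1)), 1)
  agreement <- mean(det$wear == t_sched$wear$chest)
  expect_gte(agreement, 0.99)
})

test_that("clock drift shifts the latent sampling as expected", {
  # 50 ppm over 7 days accumulates to about 30 s
  days <- 7
  drift <- 50
  shift_s <- days * 86400 * drift * 1e-6
  expect_equal(shift_s, 30.24)
  cfg <- tiny_config(n = 1, days = 1, noise_sd_g = 0,
                     offbody_noise_step_frac = 0, hip_off_hours = NULL)
  truth <- simulate_participant("Z4", 10, cfg)
  truth$drift_ppm[["hip"]] <- 0
  slow <- render_accel(truth, cfg$hip_spec)
  truth$drift_ppm[["hip"]] <- 5000   # exaggerated for a visible shift
  fast <- render_accel(truth, cfg$hip_spec)
  # same RNG stream, same gravity; only the latent sampling times moved
  expect_false(identical(slow$x, fast$x))
})

test_that("cohort simulation is reproducible and writes parseable dialects", {
  cfg <- tiny_config(n = 2, days = 1)
  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  co1 <- simulate_cohort(cfg, seed = 5, dir = d1)
  co2 <- simulate_cohort(cfg, seed = 5, dir = d2)
  for (f in c("chest.zacl", "chest.hea", "hip.csv", "ecg.csv", "truth.json")) {
    f1 <- file.path(d1, "P001", f)
    f2 <- file.path(d2, "P001", f)
    expect_identical(readBin(f1, "raw", file.info(f1)$size),
                     readBin(f2, "raw", file.info(f2)$size))
  }
  # files round-trip through the device_io readers
  chest <- read_zacl(file.path(d1, "P001", "chest.zacl"), participant_id = "P001")
  expect_equal(length(chest$x), floor(1 * 86400 * 1.56))
  hip <- read_actigraph_csv(file.path(d1, "P001", "hip.csv"))
  expect_equal(hip$device$sampling_rate_hz, 8)
  ecg <- read_ecg_csv(file.path(d1, "P001", "ecg.csv"))
  expect_equal(ecg$sampling_rate_hz, 40)
  # a different seed changes the data
  co3 <- simulate_cohort(cfg, seed = 6)
  expect_false(identical(co1$participants$P001$lambda,
                         co3$participants$P001$lambda))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("lazy and file-backed rendering agree", {
  cfg <- tiny_config(n = 1, days = 1)
  d <- file.path(tempdir(), "coh3")
  unlink(d, recursive = TRUE)
  co <- simulate_cohort(cfg, seed = 11, dir = d)
  lazy <- render_participant(co, "P001")
  hip_file <- read_actigraph_csv(file.path(d, "P001", "hip.csv"))
  # half a unit in the 6th decimal is the written precision
  expect_lte(max(abs(hip_file$x - lazy$hip$x)), 5.01e-7)
  chest_file <- read_zacl(file.path(d, "P001", "chest.zacl"))
  expect_equal(chest_file$x, lazy$chest$x)   # 8-bit codes are exact
  unlink(d, recursive = TRUE)
})

test_that("raising chest sensor noise degrades between-device agreement", {
  r_at_noise <- function(noise_sd, seed) {
    cfg <- tiny_config(n = 1, days = 1, hip_off_hours = NULL,
                       noise_sd_g = noise_sd)
    truth <- simulate_participant("N1", seed, cfg)
    # keep the hip reference clean so only the chest channel degrades
    hip_truth <- truth
    hip_truth$noise_sd_g <- 0.005
    a <- epoch_mad(vector_magnitude(render_accel(hip_truth, cfg$hip_spec)), 300)
    b <- epoch_mad(vector_magnitude(render_accel(truth, cfg$chest_spec)), 300)
    participant_agreement(align_epoch_grids(a, b))$pearson_r
  }
  seeds <- 101:105
  r_low <- mean(vapply(seeds, function(s) r_at_noise(0.005, s), numeric(1)))
  r_high <- mean(vapply(seeds, function(s) r_at_noise(0.12, s), numeric(1)))
  expect_gt(r_low, r_high)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_participants = 0), "config error")
  expect_error(cohort_config(days = -1), "config error")
  expect_error(cohort_config(noise_sd_g = -0.1), "config error")
})
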