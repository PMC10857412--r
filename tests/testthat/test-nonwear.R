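# ECG wear rule, zero-run rule, joint wear and the validity filter.

test_that("ECG rule labels flat, spiking and sub-threshold signals correctly", {
  fs <- 50
  ten_min <- 10 * 60 * fs
  t <- (seq_len(ten_min) - 1) / fs

  flat <- ecg_nonwear(make_ecg(rep(0, ten_min), fs))
  expect_false(any(flat$wear))

  square <- ecg_nonwear(make_ecg(ifelse(t %% 1 < 0.5, 1, -1), fs))
  expect_true(all(square$wear))

  sine <- ecg_nonwear(make_ecg(0.05 * sin(2 * pi * t), fs))
  expect_false(any(sine$wear))
})

test_that("ECG rule matches the brute-force pointwise oracle", {
  set.seed(21)
  fs <- 10
  for (i in 1:8) {
    n <- 3 * 60 * fs
    mv <- switch(1 + (i %% 4),
                 rnorm(n, 0, 0.3),
                 rep(0.02, n),
                 ifelse(seq_len(n) %% 10 == 0, 1, 0),
                 0.09 * sin(seq_len(n) / 5)) + rnorm(n, 0, 0.01)
    got <- ecg_nonwear(make_ecg(mv, fs))
    expect_equal(got$wear, naive_ecg_wear_minutes(mv, fs))
  }
})

test_that("ECG rule is threshold-monotone", {
  set.seed(22)
  fs <- 10
  mv <- rnorm(5 * 60 * fs, 0, 0.15)
  ecg <- make_ecg(mv, fs)
  prev <- ecg_nonwear(ecg, threshold_mv = 0.05)$wear
  for (thr in c(0.1, 0.2, 0.4)) {
    cur <- ecg_nonwear(ecg, threshold_mv = thr)$wear
    # raising the threshold never converts a non-wear minute to wear
    expect_true(all(cur <= prev))
    prev <- cur
  }
  expect_error(ecg_nonwear(make_ecg(numeric(0), fs)), "empty")
})

test_that("zero-run rule flags only maximal runs of at least run_minutes", {
  mk <- function(zero) {
    data.frame(minute_start = as.POSIXct("2020-01-01", tz = "UTC") +
                 60 * (seq_along(zero) - 1),
               value = ifelse(zero, 0, 0.05))
  }
  m90 <- actigraph_nonwear(mk(rep(TRUE, 90)))
  expect_false(any(m90$wear))
  m89 <- actigraph_nonwear(mk(rep(TRUE, 89)))
  expect_true(all(m89$wear))
  # an interrupting active minute splits the run below threshold
  zero <- rep(TRUE, 100)
  zero[50] <- FALSE
  expect_true(all(actigraph_nonwear(mk(zero))$wear))
})

test_that("zero-run rule equals a brute-force run scan on random strings", {
  set.seed(23)
  for (i in 1:300) {
    n <- sample(30:250, 1)
    zero <- runif(n) < runif(1, 0.3, 0.95)
    run_min <- sample(c(5, 10, 90), 1)
    df <- data.frame(minute_start = as.POSIXct("2020-01-01", tz = "UTC") +
                       60 * (seq_len(n) - 1),
                     value = ifelse(zero, 0, 1))
    got <- actigraph_nonwear(df, run_minutes = run_min, zero_threshold_g = 0.5)
    expect_identical(got$wear, naive_zero_run_nonwear(zero, run_min))
  }
})

test_that("joint wear is the minute-wise AND, idempotent and commutative", {
  a <- make_mask(c(TRUE, TRUE, FALSE, TRUE), device = "hip")
  b <- make_mask(c(TRUE, FALSE, FALSE, TRUE), device = "chest")
  j <- joint_wear(a, b)
  expect_equal(j$wear, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(joint_wear(a, a)$wear, a$wear)
  expect_equal(joint_wear(a, b)$wear, joint_wear(b, a)$wear)
})

test_that("joint wear intersects device spans", {
  day <- as.POSIXct("2020-01-01", tz = "UTC")
  a <- madpair:::new_nonwear_mask("T01", "hip", day + 3600 * 8 + 60 * (0:719),
                                  rep(TRUE, 720))   # 08:00-20:00
  b <- madpair:::new_nonwear_mask("T01", "chest", day + 3600 * 14 + 60 * (0:479),
                                  rep(TRUE, 480))   # 14:00-22:00
  j <- joint_wear(a, b)
  worn <- j$minute_start[j$wear]
  expect_equal(min(worn), day + 3600 * 14)
  expect_equal(max(worn), day + 3600 * 20 - 60)
  expect_equal(sum(j$wear), 6 * 60)
  # fully non-overlapping spans warn and yield no joint wear
  c_mask <- madpair:::new_nonwear_mask("T01", "chest",
                                       day + 86400 * 2 + 60 * (0:9),
                                       rep(TRUE, 10))
  expect_warning(j2 <- joint_wear(a, c_mask), "overlap")
  expect_false(any(j2$wear))
})

test_that("validity filter applies the 3-day / 10-h / daytime-window rule", {
  day <- as.POSIXct("2020-01-01", tz = "UTC")
  # exactly 600 worn minutes inside 07:00-23:00 on each of 3 days
  mk_days <- function(n_days, worn_min) {
    starts <- unlist(lapply(seq_len(n_days) - 1, function(d) {
      as.numeric(day) + d * 86400 + 3600 * 7 + 60 * (seq_len(16 * 60) - 1)
    }))
    wear <- rep(rep(c(TRUE, FALSE), c(worn_min, 16 * 60 - worn_min)), n_days)
    madpair:::new_nonwear_mask("T01", "joint",
                               as.POSIXct(starts, origin = "1970-01-01",
                                          tz = "UTC"), wear)
  }
  v3 <- validity_filter(mk_days(3, 600))
  expect_true(v3$included)            # "at least" boundaries are inclusive
  expect_equal(v3$n_valid_days, 3)
  v2 <- validity_filter(mk_days(3, 599))
  expect_false(v2$included)
  expect_false(validity_filter(mk_days(2, 960))$included)

  # wear only 23:00-09:00 -> 120 in-window minutes per day -> invalid
  starts <- as.numeric(day) + 3600 * 23 + 60 * (seq_len(600) - 1)
  night <- madpair:::new_nonwear_mask("T01", "joint",
                                      as.POSIXct(starts, origin = "1970-01-01",
                                                 tz = "UTC"), rep(TRUE, 600))
  vd <- validity_filter(night)
  expect_equal(sum(vd$days$wear_minutes_in_window), 120)
  expect_false(vd$included)
})

test_that("wear masks persist to the documented CSV layout", {
  m <- make_mask(c(TRUE, FALSE, TRUE), device = "hip")
  p <- file.path(tempdir(), "mask.csv")
  write_mask_csv(m, p)
  df <- read.csv(p)
  expect_named(df, c("participant", "device", "minute_start", "wear"))
  expect_equal(df$wear, c(TRUE, FALSE, TRUE))
})
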