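# Device specifications, quantization arithmetic, and the zacl / CSV
# dialects.

test_that("device specs validate their parameters", {
  expect_error(device_spec("d", -1, 8, 2), "sampling_rate_hz")
  expect_error(device_spec("d", 1, 0, 2), "bit_depth")
  expect_error(device_spec("d", 1, 17, 2), "bit_depth")
  expect_error(device_spec("d", 1, 8, 0), "dynamic_range_g")
  s <- chest_patch_spec()
  expect_equal(s$sampling_rate_hz, 1.56)
  expect_equal(2^s$bit_depth, 256)
  expect_equal(2^hip_monitor_spec()$bit_depth, 4096)
})

test_that("quantization resolution follows 2R / 2^bits", {
  expect_identical(quantization_resolution(hip_monitor_spec()), 2 * 8 / 4096)
  expect_identical(quantization_resolution(chest_patch_spec()), 2 * 2 / 256)
  # a 1-bit +/- 1 g converter has two levels one full range apart
  expect_identical(quantization_resolution(device_spec("b", 1, 1, 1)), 1.0)
})

test_that("quantize snaps to the nearest representable level", {
  spec <- chest_patch_spec()
  # independent check: enumerate all 256 code levels and pick the closest
  levels <- ((0:255) - 128) * quantization_resolution(spec)
  for (x in c(0.013, -0.7071, 0.5, 1.984, -2)) {
    expect_equal(quantize(x, spec), levels[which.min(abs(levels - x))])
  }
  expect_equal(quantize(0.013, spec), 0.015625)
  # grid values are fixed points; quantize is idempotent
  expect_identical(quantize(levels, spec), levels)
  set.seed(3)
  q1 <- quantize(rnorm(100), spec)
  expect_identical(quantize(q1, spec), q1)
  # out-of-range input clips to the extreme level
  hip <- hip_monitor_spec()
  expect_equal(quantize(9, hip), (4095 - 2048) * quantization_resolution(hip))
  expect_equal(quantize(-9, hip), -8)
  # error bound for in-range input
  set.seed(7)
  x <- runif(1000, -2, 1.984)
  expect_lte(max(abs(quantize(x, spec) - x)),
             quantization_resolution(spec) / 2)
})

test_that("zacl decoding deinterleaves trifectas with the offset-binary map", {
  p <- zacl_payload(c(128, 128, 160, 96, 128, 128),
                    header = list(start = "2016-07-01T09:00:00"))
  rec <- decode_zacl(p)
  expect_equal(rec$x, c(0, -0.5))
  expect_equal(rec$y, c(0, 0))
  expect_equal(rec$z, c(0.5, 0))
  expect_equal(rec$start_time, as.POSIXct("2016-07-01 09:00:00", tz = "UTC"))
  # minimum code maps to -R
  rec0 <- decode_zacl(zacl_payload(c(0, 0, 0), list(start = "2016-07-01T00:00:00")))
  expect_equal(c(rec0$x, rec0$y, rec0$z), c(-2, -2, -2))
  # conservation: every byte lands in exactly one axis
  set.seed(1)
  b <- sample(0:255, 3 * 17, replace = TRUE)
  r <- decode_zacl(zacl_payload(b, list(start = "2016-07-01T00:00:00")))
  expect_equal(length(r$x) + length(r$y) + length(r$z), length(b))
  expect_equal(r$x, ((b[seq(1, 51, 3)]) - 128) / 64)
})

test_that("zacl decoding rejects malformed payloads and missing metadata", {
  expect_error(decode_zacl(zacl_payload(rep(1, 7), list(start = "2016-07-01T00:00:00"))),
               "trifecta")
  expect_error(decode_zacl(zacl_payload(c(1, 2, 300), list(start = "2016-07-01T00:00:00"))),
               "0..255")
  expect_error(decode_zacl(zacl_payload(c(1, 2, 3), list(finish = "x"))),
               "missing metadata")
})

test_that("zacl encoding inverts decoding and clips out-of-range samples", {
  spec <- chest_patch_spec()
  rec <- raw_accel_recording("p", spec, "2016-07-01T00:00:00", 0.5, 0, 0)
  expect_identical(encode_zacl(rec)$raw_bytes, c(160L, 128L, 128L))
  # round trip within half a quantization step on random recordings
  set.seed(42)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    r <- raw_accel_recording("p", spec, "2016-07-01T00:00:00",
                             runif(n, -2, 1.98), runif(n, -2, 1.98),
                             runif(n, -2, 1.98))
    back <- decode_zacl(encode_zacl(r), spec)
    err <- max(abs(c(back$x - r$x, back$y - r$y, back$z - r$z)))
    expect_lte(err, 0.0078125)
  }
  # clipping is warned about, and the clipped code is the extreme one
  over <- raw_accel_recording("p", spec, "2016-07-01T00:00:00", 3, 0, 0,
                              validate = FALSE)
  expect_warning(pl <- encode_zacl(over), "clipped")
  expect_identical(pl$raw_bytes[1], 255L)
})

test_that("zacl files round-trip byte-identically through disk", {
  spec <- chest_patch_spec()
  set.seed(5)
  rec <- raw_accel_recording("p7", spec, "2016-07-01T09:00:00",
                             runif(30, -2, 1.9), runif(30, -2, 1.9),
                             runif(30, -2, 1.9))
  rec_q <- raw_accel_recording("p7", spec, "2016-07-01T09:00:00",
                               quantize(rec$x, spec), quantize(rec$y, spec),
                               quantize(rec$z, spec))
  zp <- file.path(tempdir(), "t.zacl")
  write_zacl(rec_q, zp)
  back <- read_zacl(zp, participant_id = "p7")
  expect_equal(back$x, rec_q$x)
  expect_equal(back$z, rec_q$z)
  expect_equal(back$start_time, rec_q$start_time)
})

test_that("header parsing handles defaults and inconsistencies", {
  h <- parse_header("start 2016-07-01T09:00:00\nfinish 2016-07-08T09:00:00\nfs_accel 1.56")
  expect_equal(h$sampling_rate_hz, 1.56)
  expect_equal(as.numeric(difftime(h$finish, h$start, units = "days")), 7)
  expect_warning(h2 <- parse_header("start 2016-07-01T09:00:00\nfinish 2016-07-02T09:00:00"),
                 "1.56")
  expect_equal(h2$sampling_rate_hz, 1.56)
  expect_error(parse_header("start 2016-07-08T00:00:00\nfinish 2016-07-01T00:00:00"),
               "inconsistent")
  expect_error(parse_header("start not-a-time\nfinish 2016-07-01T00:00:00"),
               "timestamp")
  expect_error(parse_header("finish 2016-07-01T00:00:00"), "missing metadata")
})

test_that("raw CSV dialect round-trips losslessly at written precision", {
  spec <- hip_monitor_spec()
  rec <- raw_accel_recording("p1", spec, "2016-07-01T00:00:00",
                             c(0.003906, -0.25, 7.5), c(0, 1, -1),
                             c(0.5, 0.25, 0.125))
  p <- file.path(tempdir(), "hip.csv")
  write_actigraph_csv(rec, p)
  back <- read_actigraph_csv(p, participant_id = "p1")
  expect_equal(back$x, rec$x, tolerance = 1e-6)
  expect_equal(back$y, rec$y, tolerance = 1e-6)
  expect_equal(back$z, rec$z, tolerance = 1e-6)
  expect_equal(back$device$sampling_rate_hz, 40)
  expect_equal(back$device$bit_depth, 12L)
  expect_equal(back$start_time, rec$start_time)
})

test_that("raw CSV parsing rejects ragged rows and missing header", {
  p <- file.path(tempdir(), "bad.csv")
  writeLines(c("# start 2016-07-01T00:00:00", "# fs 40", "# range_g 8",
               "# bits 12", "x,y,z", "0.1,0.2,0.3", "0.1,0.2"), p)
  expect_error(read_actigraph_csv(p), "parse error")
  writeLines(c("# start 2016-07-01T00:00:00", "x,y,z", "0,0,0"), p)
  expect_error(read_actigraph_csv(p), "missing metadata")
})

test_that("ECG CSV dialect round-trips", {
  ecg <- ecg_series("p1", "2016-07-01T00:00:00", 199.8, c(0.05, -1.25, 0.9999))
  p <- file.path(tempdir(), "ecg.csv")
  write_ecg_csv(ecg, p)
  back <- read_ecg_csv(p, "p1")
  expect_equal(back$mv, ecg$mv, tolerance = 1e-4)
  expect_equal(back$sampling_rate_hz, 199.8)
})
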