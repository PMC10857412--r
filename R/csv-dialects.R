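# Text dialects for the hip monitor's raw CSV export and for ECG series.
#
# Hip (research accelerometer) raw CSV:
#   # start <ISO-8601>
#   # fs <Hz>
#   # range_g <R>
#   # bits <n>
#   x,y,z
#   <one row per sample, g, 6 decimals>
#
# ECG CSV:
#   # start <ISO-8601>
#   # fs <Hz>
#   mv
#   <one row per sample, millivolts>

read_hash_header <- function(lines) {
  meta <- list()
  i <- 0L
  for (ln in lines) {
    if (!startsWith(ln, "#")) break
    i <- i + 1L
    m <- regmatches(ln, regexec("^#\\s*(\\S+)\\s+(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  list(meta = meta, n_header = i)
}

#' Read / write the hip monitor raw CSV dialect
#'
#' A plain-text raw tri-axial dialect: `#`-prefixed metadata lines (`start`,
#' `fs`, `range_g`, `bits`), then a `x,y,z` column header and one row per
#' sample in g. Round-trips are lossless at the written precision (6
#' decimals by default).
#'
#' @param path file to read or write.
#' @param participant_id participant label for the decoded recording.
#' @param placement body placement recorded in the constructed
#'   [device_spec()] (the dialect itself does not carry it).
#' @return `read_actigraph_csv()` a [raw_accel_recording()];
#'   `write_actigraph_csv()` invisibly the path.
#' @export
read_actigraph_csv <- function(path, participant_id = "unknown",
                               placement = "hip") {
  lines <- readLines(path, warn = FALSE)
  hdr <- read_hash_header(lines)
  meta <- hdr$meta
  for (key in c("start", "fs", "range_g", "bits")) {
    if (is.null(meta[[key]])) {
      stop("missing metadata: raw CSV header lacks '# ", key, "'",
           call. = FALSE)
    }
  }
  body <- lines[-seq_len(hdr$n_header)]
  if (!length(body) || trimws(body[1]) != "x,y,z") {
    stop("parse error: expected 'x,y,z' column header", call. = FALSE)
  }
  rows <- body[-1]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows)) {
    parts <- strsplit(rows, ",", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 3L)) {
      stop("parse error: row ", which(nf != 3L)[1],
           " has ", nf[nf != 3L][1], " fields (expected 3)", call. = FALSE)
    }
    m <- matrix(as.numeric(unlist(parts)), ncol = 3L, byrow = TRUE)
    if (anyNA(m)) stop("parse error: non-numeric sample value", call. = FALSE)
  } else {
    m <- matrix(numeric(0), ncol = 3L)
  }
  spec <- device_spec("hip_monitor", as.numeric(meta$fs),
                      as.integer(meta$bits), as.numeric(meta$range_g),
                      placement)
  raw_accel_recording(participant_id, spec, meta$start,
                      m[, 1], m[, 2], m[, 3])
}

#' @rdname read_actigraph_csv
#' @param rec recording to write.
#' @param digits decimals written per sample.
#' @export
write_actigraph_csv <- function(rec, path, digits = 6L) {
  stopifnot(inherits(rec, "raw_accel"))
  spec <- rec$device
  fmt <- paste0("%.", digits, "f")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(paste("# start", format_naive_time(rec$start_time)),
               paste("# fs", format(spec$sampling_rate_hz)),
               paste("# range_g", format(spec$dynamic_range_g)),
               paste("# bits", spec$bit_depth),
               "x,y,z"), con)
  if (length(rec$x)) {
    writeLines(paste(sprintf(fmt, rec$x), sprintf(fmt, rec$y),
                     sprintf(fmt, rec$z), sep = ","), con)
  }
  invisible(path)
}

#' Read / write the ECG CSV dialect
#'
#' `#`-prefixed metadata lines (`start`, `fs`), a `mv` column header, then
#' one voltage per row in millivolts.
#'
#' @param path file to read or write.
#' @param participant_id participant label.
#' @return `read_ecg_csv()` an [ecg_series()]; `write_ecg_csv()` invisibly
#'   the path.
#' @export
read_ecg_csv <- function(path, participant_id = "unknown") {
  lines <- readLines(path, warn = FALSE)
  hdr <- read_hash_header(lines)
  meta <- hdr$meta
  if (is.null(meta$start) || is.null(meta$fs)) {
    stop("missing metadata: ECG CSV header lacks '# start' or '# fs'",
         call. = FALSE)
  }
  body <- lines[-seq_len(hdr$n_header)]
  if (!length(body) || trimws(body[1]) != "mv") {
    stop("parse error: expected 'mv' column header", call. = FALSE)
  }
  vals <- body[-1]
  vals <- as.numeric(vals[nzchar(trimws(vals))])
  if (anyNA(vals)) stop("parse error: non-numeric ECG value", call. = FALSE)
  ecg_series(participant_id, meta$start, as.numeric(meta$fs), vals)
}

#' @rdname read_ecg_csv
#' @param ecg series to write.
#' @param digits decimals written per sample.
#' @export
write_ecg_csv <- function(ecg, path, digits = 4L) {
  stopifnot(inherits(ecg, "ecg_series"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(paste("# start", format_naive_time(ecg$start_time)),
               paste("# fs", format(ecg$sampling_rate_hz)),
               "mv"), con)
  if (length(ecg$mv)) writeLines(sprintf(paste0("%.", digits, "f"), ecg$mv), con)
  invisible(path)
}
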