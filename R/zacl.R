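# The chest patch's binary accelerometer dialect ("zacl"): a raw stream of
# 8-bit unsigned samples interleaved in trifectas x, y, z (so axis x occupies
# byte indices 1, 4, 7, ...), accompanied by a small text header ("hea") file
# carrying the recording start/finish timestamps and, optionally, the
# per-axis sampling rate.

#' Decode an interleaved 8-bit accelerometer payload
#'
#' The payload is a stream of 8-bit unsigned codes (0..255) structured in
#' trifectas of x, y and z: every third code forms one axis' time series.
#' Codes map to g via the offset-binary affine map
#' `g = (code - 128) * (2 * R / 256)` with R the device dynamic range.
#'
#' @param payload a `zacl_payload` as returned by [zacl_payload()] or
#'   [read_zacl()], i.e. a list with `raw_bytes` (integer codes 0..255 or a
#'   raw vector) and `header` (a list with at least `start`).
#' @param spec a [device_spec()] with `bit_depth = 8`; defaults to
#'   [chest_patch_spec()], with any header-declared sampling rate overriding
#'   the nominal 1.56 Hz.
#' @return A [raw_accel_recording()].
#' @examples
#' p <- zacl_payload(c(128, 128, 160, 96, 128, 128),
#'                   header = list(start = "2016-07-01T09:00:00"))
#' rec <- decode_zacl(p)
#' rec$x  # 0.0 -0.5
#' rec$z  # 0.5  0.0
#' @export
decode_zacl <- function(payload, spec = chest_patch_spec()) {
  stopifnot(inherits(spec, "device_spec"))
  if (spec$bit_depth != 8L) {
    stop("zacl payloads are 8-bit; got a ", spec$bit_depth, "-bit spec",
         call. = FALSE)
  }
  b <- payload$raw_bytes
  if (is.raw(b)) b <- as.integer(b)
  b <- as.numeric(b)
  if (length(b) %% 3L != 0L) {
    stop("malformed zacl payload: ", length(b),
         " bytes is not a whole number of x,y,z trifectas", call. = FALSE)
  }
  if (length(b) && (min(b) < 0 || max(b) > 255 || any(b != floor(b)))) {
    stop("malformed zacl payload: codes must be integers in 0..255",
         call. = FALSE)
  }
  hdr <- payload$header
  if (is.null(hdr) || is.null(hdr$start)) {
    stop("missing metadata: zacl header must provide a start timestamp",
         call. = FALSE)
  }
  if (!is.null(hdr$sampling_rate_hz)) {
    spec$sampling_rate_hz <- as.numeric(hdr$sampling_rate_hz)
  }
  g <- code_to_g(b, spec)
  idx <- seq_len(length(b) / 3L)
  raw_accel_recording(
    participant_id = if (!is.null(hdr$participant_id)) hdr$participant_id else "unknown",
    device = spec,
    start_time = hdr$start,
    x = g[3L * idx - 2L], y = g[3L * idx - 1L], z = g[3L * idx]
  )
}

#' Construct a zacl payload object
#'
#' @param raw_bytes integer codes in 0..255 (or a raw vector).
#' @param header list with `start` (required for decoding), optional `finish`,
#'   `sampling_rate_hz`, `participant_id`.
#' @return An object of class `zacl_payload`.
#' @export
zacl_payload <- function(raw_bytes, header = list()) {
  structure(list(raw_bytes = raw_bytes, header = header),
            class = "zacl_payload")
}

#' Encode a recording as an interleaved 8-bit payload
#'
#' Inverse of [decode_zacl()]: each sample is mapped to the nearest 8-bit
#' code (clipping out-of-range values to 0/255 with a warning) and the three
#' axes are interleaved into trifectas. Round-tripping a recording through
#' encode/decode perturbs each sample by at most half a quantization step
#' (0.0078125 g for the +/- 2 g patch).
#'
#' @param rec a [raw_accel_recording()] whose device has `bit_depth = 8`.
#' @return A [zacl_payload()] whose header carries the recording start/finish
#'   and sampling rate.
#' @export
encode_zacl <- function(rec) {
  stopifnot(inherits(rec, "raw_accel"))
  spec <- rec$device
  if (spec$bit_depth != 8L) {
    stop("zacl payloads are 8-bit; recording device is ", spec$bit_depth,
         "-bit", call. = FALSE)
  }
  n <- length(rec$x)
  codes <- matrix(0, nrow = 3L, ncol = n)
  clipped <- 0L
  for (k in 1:3) {
    cd <- g_to_code(rec[[c("x", "y", "z")[k]]], spec)
    clipped <- clipped + attr(cd, "n_clipped")
    codes[k, ] <- as.numeric(cd)
  }
  if (clipped > 0L) {
    warning(clipped, " sample(s) outside the +/- ", spec$dynamic_range_g,
            " g range were clipped to the nearest representable code",
            call. = FALSE)
  }
  finish <- rec$start_time + n / spec$sampling_rate_hz
  zacl_payload(
    raw_bytes = as.integer(codes),
    header = list(start = rec$start_time, finish = finish,
                  sampling_rate_hz = spec$sampling_rate_hz,
                  participant_id = rec$participant_id)
  )
}

#' Parse a zacl text header
#'
#' The header ("hea") dialect is plain key-value lines:
#' `start <ISO-8601>`, `finish <ISO-8601>`, and optionally `fs_accel <Hz>`.
#' When `fs_accel` is absent the patch's nominal rate of 1.56 Hz per axis is
#' assumed with a warning.
#'
#' @param text header file content as a single string or character vector of
#'   lines.
#' @return list with `start`, `finish` (POSIXct) and `sampling_rate_hz`.
#' @examples
#' parse_header("start 2016-07-01T09:00:00\nfinish 2016-07-08T09:00:00\nfs_accel 1.56")
#' @export
parse_header <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^(\\S+)\\s+(.*)$", lines))
  keys <- vapply(kv, function(m) if (length(m) == 3L) m[2] else NA_character_,
                 character(1))
  vals <- vapply(kv, function(m) if (length(m) == 3L) m[3] else NA_character_,
                 character(1))
  get1 <- function(key) {
    i <- which(keys == key)
    if (length(i)) vals[i[1]] else NULL
  }
  start <- get1("start")
  finish <- get1("finish")
  if (is.null(start) || is.null(finish)) {
    stop("missing metadata: header must contain 'start' and 'finish' lines",
         call. = FALSE)
  }
  start <- parse_naive_time(start)
  finish <- parse_naive_time(finish)
  if (finish < start) {
    stop("inconsistent header: finish (", format_naive_time(finish),
         ") precedes start (", format_naive_time(start), ")", call. = FALSE)
  }
  fs <- get1("fs_accel")
  if (is.null(fs)) {
    warning("header has no fs_accel line; assuming the nominal 1.56 Hz",
            call. = FALSE)
    fs <- 1.56
  } else {
    fs <- suppressWarnings(as.numeric(fs))
    if (is.na(fs) || fs <= 0) {
      stop("unparseable fs_accel value in header", call. = FALSE)
    }
  }
  list(start = start, finish = finish, sampling_rate_hz = fs)
}

#' Read / write zacl + header file pairs
#'
#' `read_zacl()` reads the binary payload and its companion text header and
#' decodes them to a recording; `write_zacl()` is the inverse fixture writer.
#'
#' @param zacl_path path to the binary payload file.
#' @param hea_path path to the text header; defaults to `zacl_path` with a
#'   `.hea` extension.
#' @param spec device spec for decoding (8-bit); defaults to
#'   [chest_patch_spec()].
#' @param participant_id participant label attached to the decoded recording.
#' @return `read_zacl()` a [raw_accel_recording()]; `write_zacl()` invisibly
#'   the paths written.
#' @export
read_zacl <- function(zacl_path, hea_path = sub("\\.[^.]*$", ".hea", zacl_path),
                      spec = chest_patch_spec(), participant_id = NULL) {
  bytes <- readBin(zacl_path, what = "raw", n = file.info(zacl_path)$size)
  hdr <- parse_header(readLines(hea_path, warn = FALSE))
  if (!is.null(participant_id)) hdr$participant_id <- participant_id
  decode_zacl(zacl_payload(bytes, hdr), spec)
}

#' @rdname read_zacl
#' @param rec recording to serialise (8-bit device).
#' @export
write_zacl <- function(rec, zacl_path,
                       hea_path = sub("\\.[^.]*$", ".hea", zacl_path)) {
  payload <- encode_zacl(rec)
  writeBin(as.raw(payload$raw_bytes), zacl_path)
  hdr <- payload$header
  writeLines(c(paste("start", format_naive_time(hdr$start)),
               paste("finish", format_naive_time(hdr$finish)),
               paste("fs_accel", format(hdr$sampling_rate_hz))),
             hea_path)
  invisible(c(zacl = zacl_path, hea = hea_path))
}
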