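# Internal clock-time helpers.
#
# All timestamps in the package are timezone-naive local clock times; they are
# represented as POSIXct in the "UTC" zone so that arithmetic is purely linear
# (no DST jumps) and the 7 a.m.-11 p.m. analysis window means wall-clock time.

#' Parse a timezone-naive ISO-8601-ish timestamp
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS` or `YYYY-MM-DD HH:MM:SS` (optionally with
#' fractional seconds) and returns a POSIXct in the package's naive clock
#' convention.
#'
#' @param x character vector of timestamps (or POSIXct, returned as-is after
#'   zone normalisation).
#' @return POSIXct vector.
#' @keywords internal
parse_naive_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- tryCatch(
    as.POSIXct(x, tz = "UTC",
               tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                              "%Y-%m-%d")),
    error = function(e) rep(as.POSIXct(NA), length(x))
  )
  if (anyNA(out) && !anyNA(x)) {
    stop("unparseable timestamp: ", paste(x[is.na(out)], collapse = ", "),
         call. = FALSE)
  }
  out
}

format_naive_time <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

# Midnight of the calendar day containing t (naive clock).
local_midnight <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 86400) * 86400,
             origin = "1970-01-01", tz = "UTC")
}

floor_minute <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

# Seconds since midnight of the same calendar day.
seconds_of_day <- function(t) {
  as.numeric(t) %% 86400
}

naive_date <- function(t) {
  as.Date(t, tz = "UTC")
}
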