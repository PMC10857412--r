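# Agreement statistics between the two devices' MAD series: per-participant
# Pearson correlation and MSE, cohort distribution summaries, Bland-Altman
# bias / limits of agreement, and diurnal mean profiles.

#' Per-participant agreement for one epoch length
#'
#' Computes the sample Pearson correlation and the mean squared error
#' between the paired MAD series of the reference (hip) and test (chest)
#' devices. The correlation is reported as missing when fewer than
#' `min_pairs` pairs are available or either series is constant (zero
#' variance); the MSE is always reported when at least one pair exists.
#'
#' @param paired a `paired_epochs` object from [align_epoch_grids()].
#' @param min_pairs minimum pairs for a correlation (default 10).
#' @return An object of class `agreement_result`: list with
#'   `participant_id`, `epoch_length_s`, `n_pairs`, `pearson_r` (possibly
#'   NA) and `mse` (g^2).
#' @export
participant_agreement <- function(paired, min_pairs = 10) {
  stopifnot(inherits(paired, "paired_epochs"))
  a <- paired$mad_a
  b <- paired$mad_b
  n <- length(a)
  r <- NA_real_
  if (n >= min_pairs && stats::sd(a) > 0 && stats::sd(b) > 0) {
    r <- stats::cor(a, b)
  }
  structure(
    list(participant_id = attr(paired, "participant_id"),
         epoch_length_s = attr(paired, "epoch_length_s"),
         n_pairs = n,
         pearson_r = r,
         mse = if (n > 0) mean((a - b)^2) else NA_real_),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> participant %s, %d-s epochs: n = %d, r = %s, MSE = %s g^2\n",
    x$participant_id, x$epoch_length_s, x$n_pairs,
    ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r)),
    ifelse(is.na(x$mse), "NA", sprintf("%.3g", x$mse))))
  invisible(x)
}

summary_stats <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(n = length(v), mean = mean(v), sd = stats::sd(v),
    median = q[2], q1 = q[1], q3 = q[3], min = min(v), max = max(v))
}

#' Cohort summary of per-participant agreement
#'
#' Summarises the distribution of participant-level correlations and MSEs
#' for one epoch length: mean, SD, median, quartiles (linear interpolation),
#' range, and the count/percent of participants whose correlation is
#' strictly below `threshold`. Participants with a missing correlation are
#' excluded from the correlation summary (their count is reported).
#'
#' @param results list of `agreement_result`s (one per participant).
#' @param threshold correlation threshold for the low-agreement count
#'   (default 0.8, strict `<`).
#' @return An object of class `cohort_summary` with `r` and `mse` stat
#'   vectors, `n_below_threshold`, `pct_below_threshold`, and counts.
#' @export
cohort_summary <- function(results, threshold = 0.8) {
  if (!length(results)) stop("no agreement results supplied", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "agreement_result")))
  r <- vapply(results, function(x) x$pearson_r, numeric(1))
  mse <- vapply(results, function(x) x$mse, numeric(1))
  epoch <- unique(vapply(results, function(x) x$epoch_length_s, numeric(1)))
  if (length(epoch) != 1L) {
    stop("results mix epoch lengths: ", paste(epoch, collapse = ", "),
         call. = FALSE)
  }
  r_ok <- r[!is.na(r)]
  if (!length(r_ok)) {
    stop("all participant correlations are missing", call. = FALSE)
  }
  mse_ok <- mse[!is.na(mse)]
  structure(
    list(epoch_length_s = epoch,
         n_participants = length(results),
         n_missing_r = sum(is.na(r)),
         r = summary_stats(r_ok),
         mse = summary_stats(mse_ok),
         threshold = threshold,
         n_below_threshold = sum(r_ok < threshold),
         pct_below_threshold = 100 * sum(r_ok < threshold) / length(r_ok)),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d-s epochs, %d participants (%d missing r)\n",
              x$epoch_length_s, x$n_participants, x$n_missing_r))
  cat(sprintf("  r:   mean %.3f (sd %.3f), median %.3f (IQR %.3f-%.3f)\n",
              x$r[["mean"]], x$r[["sd"]], x$r[["median"]], x$r[["q1"]],
              x$r[["q3"]]))
  cat(sprintf("  MSE: mean %.3g (sd %.3g) g^2\n",
              x$mse[["mean"]], x$mse[["sd"]]))
  cat(sprintf("  %d (%.2f%%) participants with r < %g\n",
              x$n_below_threshold, x$pct_below_threshold, x$threshold))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Computes the bias (mean of the paired differences `a - b`, reference
#' minus test), the 95% limits of agreement `bias +/- 1.96 * sd(diff)` with
#' the sample (n-1) standard deviation, and the percentage of differences
#' strictly outside the limits. At `level = "participant_mean"` the inputs
#' are per-participant mean MADs (one pair per participant); at
#' `level = "pooled"` they are all epoch pairs.
#'
#' @param a,b equal-length numeric vectors (reference and test values).
#' @param level `"participant_mean"` or `"pooled"` (annotation only).
#' @param epoch_length_s optional epoch length annotation.
#' @return An object of class `bland_altman`: n, mean_a, mean_b, bias,
#'   loa_low, loa_high, pct_outside, and the paired values for plotting.
#' @export
bland_altman <- function(a, b, level = c("participant_mean", "pooled"),
                         epoch_length_s = NA_real_) {
  level <- match.arg(level)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (length(b) != n) stop("a and b must have equal length", call. = FALSE)
  if (n < 2L) stop("Bland-Altman requires at least 2 pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  loa_low <- bias - 1.96 * s
  loa_high <- bias + 1.96 * s
  structure(
    list(level = level, epoch_length_s = epoch_length_s, n = n,
         mean_a = mean(a), mean_b = mean(b),
         bias = bias, sd_diff = s,
         loa_low = loa_low, loa_high = loa_high,
         pct_outside = 100 * mean(d < loa_low | d > loa_high),
         means = (a + b) / 2, diffs = d),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> level %s%s, n = %d\n", x$level,
              if (is.na(x$epoch_length_s)) "" else
                sprintf(" (%d-s epochs)", x$epoch_length_s), x$n))
  cat(sprintf("  bias %.6f g, limits of agreement (%.4f, %.4f), %.2f%% outside\n",
              x$bias, x$loa_low, x$loa_high, x$pct_outside))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "Mean of devices (g)",
                              ylab = "Difference, reference - test (g)",
                              main = NULL, ...) {
  if (is.null(main)) {
    main <- sprintf("Bland-Altman (%s%s)", x$level,
                    if (is.na(x$epoch_length_s)) "" else
                      sprintf(", %d-s epochs", x$epoch_length_s))
  }
  plot(x$means, x$diffs, pch = 16, cex = 0.5, col = "#00000055",
       xlab = xlab, ylab = ylab, main = main, ...)
  abline(h = x$bias, lwd = 2)
  abline(h = c(x$loa_low, x$loa_high), lty = 2, col = "red")
  invisible(x)
}

#' Diurnal mean profile of MAD by clock time
#'
#' Averages each device's MAD within clock-time bins of `epoch_length_s`
#' over all jointly worn participant-day epochs: bin `k` covers clock time
#' `[k * L, (k + 1) * L)` seconds after midnight. Bins with no contributing
#' epochs are reported missing.
#'
#' @param paired_list list of `paired_epochs` (one per participant, all at
#'   the same epoch length; the epoch grid is midnight-anchored).
#' @param epoch_length_s epoch length in seconds (default 300, the 5-min
#'   profile).
#' @return An object of class `diurnal_profile`: data.frame with
#'   `bin_start_s` (seconds after midnight), `clock` (HH:MM label),
#'   `mean_a`, `mean_b`, `n`.
#' @export
diurnal_profile <- function(paired_list, epoch_length_s = 300) {
  stopifnot(length(paired_list) > 0)
  for (p in paired_list) {
    stopifnot(inherits(p, "paired_epochs"))
    if (attr(p, "epoch_length_s") != epoch_length_s) {
      stop("paired series is at ", attr(p, "epoch_length_s"),
           "-s epochs, expected ", epoch_length_s, call. = FALSE)
    }
  }
  nb <- as.integer(86400 / epoch_length_s)
  sum_a <- numeric(nb)
  sum_b <- numeric(nb)
  n <- integer(nb)
  for (p in paired_list) {
    if (!nrow(p)) next
    bin <- as.integer(seconds_of_day(p$epoch_start) / epoch_length_s) + 1L
    n <- n + tabulate(bin, nb)
    sum_a <- sum_a + vapply(split(p$mad_a, factor(bin, levels = seq_len(nb))),
                            sum, numeric(1))
    sum_b <- sum_b + vapply(split(p$mad_b, factor(bin, levels = seq_len(nb))),
                            sum, numeric(1))
  }
  bin_start_s <- (seq_len(nb) - 1L) * epoch_length_s
  out <- data.frame(
    bin_start_s = bin_start_s,
    clock = sprintf("%02d:%02d", bin_start_s %/% 3600,
                    (bin_start_s %% 3600) %/% 60),
    mean_a = ifelse(n > 0, sum_a / n, NA_real_),
    mean_b = ifelse(n > 0, sum_b / n, NA_real_),
    n = n
  )
  structure(out, epoch_length_s = epoch_length_s,
            class = c("diurnal_profile", "data.frame"))
}

#' @export
plot.diurnal_profile <- function(x, xlab = "Clock time (h)",
                                 ylab = "Mean MAD (g)", ...) {
  h <- x$bin_start_s / 3600
  plot(h, x$mean_a, type = "l", lwd = 2, xlab = xlab, ylab = ylab,
       ylim = range(c(x$mean_a, x$mean_b), na.rm = TRUE), ...)
  lines(h, x$mean_b, lwd = 2, col = "red")
  legend("topright", legend = c("reference (hip)", "test (chest)"),
         col = c("black", "red"), lwd = 2, bty = "n")
  invisible(x)
}
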