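# End-to-end orchestration: ingest (or render) -> vector magnitude ->
# non-wear -> MAD epochs -> pairing -> agreement -> tables.

#' Pipeline run configuration
#'
#' All analysis thresholds are configuration, never hard-coded, so
#' sensitivity analyses are a one-argument change. Defaults are the
#' validation protocol's values: six epoch windows from 1 min to 2 h, the
#' 2-s / 0.1 mV ECG wear rule, the 90-min zero-run rule, and inclusion at
#' >= 3 days with >= 10 h of overlapping wear between 7:00 and 23:00.
#'
#' @param epoch_lengths epoch windows in seconds.
#' @param min_fraction minimum fraction of nominal samples for a scored
#'   epoch (default 0.9).
#' @param ecg_window_s,ecg_threshold_mv,min_active_fraction parameters of
#'   [ecg_nonwear()].
#' @param run_minutes,zero_threshold_g parameters of [actigraph_nonwear()];
#'   `zero_threshold_g = NULL` uses the hip device's quantization
#'   resolution.
#' @param min_days,min_hours,window_start_hour,window_end_hour parameters
#'   of [validity_filter()].
#' @param min_pairs minimum pairs for a participant correlation.
#' @param r_threshold low-agreement correlation threshold (default 0.8).
#' @param diurnal_epoch_s epoch length of the diurnal profile (default 300).
#' @return An object of class `run_config`.
#' @export
run_config <- function(epoch_lengths = c(60, 300, 600, 1800, 3600, 7200),
                       min_fraction = 0.9,
                       ecg_window_s = 2, ecg_threshold_mv = 0.1,
                       min_active_fraction = 0.02,
                       run_minutes = 90, zero_threshold_g = NULL,
                       min_days = 3, min_hours = 10,
                       window_start_hour = 7, window_end_hour = 23,
                       min_pairs = 10, r_threshold = 0.8,
                       diurnal_epoch_s = 300) {
  if (any(epoch_lengths <= 0 | epoch_lengths %% 60 != 0)) {
    stop("config error: epoch lengths must be positive multiples of 60 s",
         call. = FALSE)
  }
  if (ecg_window_s <= 0 || ecg_threshold_mv <= 0 || run_minutes <= 0 ||
      min_days <= 0 || min_hours <= 0 || min_pairs < 1) {
    stop("config error: thresholds must be positive", call. = FALSE)
  }
  if (window_start_hour < 0 || window_end_hour > 24 ||
      window_start_hour >= window_end_hour) {
    stop("config error: clock window must lie within one day", call. = FALSE)
  }
  structure(
    list(epoch_lengths = sort(unique(epoch_lengths)),
         min_fraction = min_fraction,
         ecg_window_s = ecg_window_s, ecg_threshold_mv = ecg_threshold_mv,
         min_active_fraction = min_active_fraction,
         run_minutes = run_minutes, zero_threshold_g = zero_threshold_g,
         min_days = min_days, min_hours = min_hours,
         window_start_hour = window_start_hour,
         window_end_hour = window_end_hour,
         min_pairs = min_pairs, r_threshold = r_threshold,
         diurnal_epoch_s = diurnal_epoch_s),
    class = "run_config"
  )
}

format_window <- function(L) {
  ifelse(L < 3600, paste0(L / 60, " min"), paste0(L / 3600, " h"))
}

# Participant loaders ---------------------------------------------------

participant_ids <- function(input) {
  if (inherits(input, "synthetic_cohort")) return(names(input$participants))
  if (is.character(input) && length(input) == 1L && dir.exists(input)) {
    dirs <- list.dirs(input, recursive = FALSE)
    return(sort(basename(dirs)))
  }
  stop("input must be a synthetic_cohort or an existing directory",
       call. = FALSE)
}

load_participant <- function(input, id) {
  if (inherits(input, "synthetic_cohort")) return(render_participant(input, id))
  pdir <- file.path(input, id)
  list(
    chest = read_zacl(file.path(pdir, "chest.zacl"),
                      file.path(pdir, "chest.hea"), participant_id = id),
    hip = read_actigraph_csv(file.path(pdir, "hip.csv"), participant_id = id),
    ecg = read_ecg_csv(file.path(pdir, "ecg.csv"), participant_id = id)
  )
}

# Per-participant stage -------------------------------------------------

process_participant <- function(input, id, config) {
  devs <- load_participant(input, id)
  vm_hip <- vector_magnitude(devs$hip)
  vm_chest <- vector_magnitude(devs$chest)
  ecg <- devs$ecg
  hip_spec <- devs$hip$device
  rm(devs)

  # hip MAD at every needed epoch length (one pass each); the 60-s series
  # doubles as the minute-level activity statistic for non-wear detection
  lengths_needed <- sort(unique(c(60, config$epoch_lengths)))
  eas <- lapply(lengths_needed, function(L) epoch_mad(vm_hip, L, config$min_fraction))
  names(eas) <- as.character(lengths_needed)
  zero_thr <- config$zero_threshold_g
  if (is.null(zero_thr)) zero_thr <- quantization_resolution(hip_spec)
  mask_hip <- actigraph_nonwear(eas[["60"]], config$run_minutes, zero_thr)
  mask_chest <- ecg_nonwear(ecg, config$ecg_window_s, config$ecg_threshold_mv,
                            config$min_active_fraction)
  rm(ecg)
  joint <- joint_wear(mask_hip, mask_chest)
  validity <- validity_filter(joint, config$min_days, config$min_hours,
                              config$window_start_hour, config$window_end_hour)
  out <- list(id = id, validity = validity, mask_hip = mask_hip,
              mask_chest = mask_chest, joint = joint)
  if (!validity$included) return(out)

  valid_days <- validity$days$day[validity$days$valid]
  joint_valid <- joint
  joint_valid$wear <- joint$wear & (naive_date(joint$minute_start) %in% valid_days)

  paired <- list()
  agreements <- list()
  for (L in config$epoch_lengths) {
    ea <- eas[[as.character(L)]]
    eb <- epoch_mad(vm_chest, L, config$min_fraction)
    p <- align_epoch_grids(ea, eb, joint_valid)
    paired[[as.character(L)]] <- p
    agreements[[as.character(L)]] <- participant_agreement(p, config$min_pairs)
  }
  out$paired <- paired
  out$agreements <- agreements
  out
}

#' Run the full paired-device validation pipeline
#'
#' Executes, for every participant and epoch length: ingestion (from a
#' directory in the package's file dialects, or lazy rendering of a
#' [simulate_cohort()] object), vector magnitude, per-device non-wear
#' detection, wear-validity filtering, MAD epoch summaries, epoch pairing,
#' and agreement statistics. Participants failing the validity filter (or
#' whose files fail to parse) are excluded with a logged reason and do not
#' contribute to any agreement output. Analyses use jointly worn epochs on
#' the valid days of included participants.
#'
#' @param input a `synthetic_cohort` or a directory with one subdirectory
#'   per participant (`chest.zacl`, `chest.hea`, `hip.csv`, `ecg.csv`).
#' @param config a [run_config()].
#' @param out_dir optional output directory for the result tables (CSV) and
#'   a JSON run report.
#' @param quiet suppress progress messages.
#' @return An object of class `mad_run` containing the cohort flow, the
#'   per-window cohort summaries, Bland-Altman results (participant-mean
#'   and pooled), the diurnal profile, the wear summary and the output
#'   tables.
#' @export
run_pipeline <- function(input, config = run_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  ids <- participant_ids(input)
  if (!length(ids)) stop("no participants found", call. = FALSE)
  say <- function(...) if (!quiet) message(...)

  results <- list()
  excluded <- data.frame(participant = character(0), reason = character(0))
  for (id in ids) {
    res <- tryCatch(
      process_participant(input, id, config),
      error = function(e) {
        say("participant ", id, " excluded: ", conditionMessage(e))
        structure(list(id = id, error = conditionMessage(e)),
                  class = "participant_error")
      }
    )
    if (inherits(res, "participant_error")) {
      excluded <- rbind(excluded, data.frame(
        participant = id, reason = paste("load/parse error:", res$error)))
      next
    }
    if (!res$validity$included) {
      say("participant ", id, " excluded: only ", res$validity$n_valid_days,
          " valid day(s)")
      excluded <- rbind(excluded, data.frame(
        participant = id,
        reason = sprintf("insufficient valid wear (%d day(s))",
                         res$validity$n_valid_days)))
      next
    }
    say("participant ", id, " included (", res$validity$n_valid_days,
        " valid days)")
    results[[id]] <- res
  }

  flow <- list(candidates = length(ids), included = length(results),
               excluded = nrow(excluded), exclusions = excluded)
  if (!length(results)) {
    warning("no participant passed the validity filter; all tables are empty",
            call. = FALSE)
  }

  summaries <- list()
  ba_participant <- list()
  ba_pooled <- list()
  for (L in config$epoch_lengths) {
    key <- as.character(L)
    agrs <- lapply(results, function(r) r$agreements[[key]])
    if (length(agrs)) {
      summaries[[key]] <- tryCatch(cohort_summary(agrs, config$r_threshold),
                                   error = function(e) NULL)
      pm_a <- vapply(results, function(r) mean(r$paired[[key]]$mad_a), numeric(1))
      pm_b <- vapply(results, function(r) mean(r$paired[[key]]$mad_b), numeric(1))
      ok <- !is.na(pm_a) & !is.na(pm_b)
      if (sum(ok) >= 2) {
        ba_participant[[key]] <- bland_altman(pm_a[ok], pm_b[ok],
                                              "participant_mean", L)
      }
      all_a <- unlist(lapply(results, function(r) r$paired[[key]]$mad_a))
      all_b <- unlist(lapply(results, function(r) r$paired[[key]]$mad_b))
      if (length(all_a) >= 2) {
        ba_pooled[[key]] <- bland_altman(all_a, all_b, "pooled", L)
      }
    }
  }

  diurnal <- NULL
  dkey <- as.character(config$diurnal_epoch_s)
  dlist <- lapply(results, function(r) r$paired[[dkey]])
  dlist <- dlist[!vapply(dlist, is.null, logical(1))]
  if (length(dlist)) diurnal <- diurnal_profile(dlist, config$diurnal_epoch_s)

  valid_days <- vapply(results, function(r) r$validity$n_valid_days, numeric(1))
  wear_summary <- if (length(valid_days)) {
    c(n = length(valid_days), mean = mean(valid_days),
      sd = if (length(valid_days) > 1) stats::sd(valid_days) else 0,
      min = min(valid_days), max = max(valid_days))
  } else {
    c(n = 0, mean = NA_real_, sd = NA_real_, min = NA_real_, max = NA_real_)
  }

  run <- structure(
    list(flow = flow,
         config = config,
         summaries = summaries,
         ba_participant = ba_participant,
         ba_pooled = ba_pooled,
         diurnal = diurnal,
         wear_summary = wear_summary,
         validity = lapply(results, function(r) r$validity),
         agreements = lapply(results, function(r) r$agreements),
         paired = lapply(results, function(r) r$paired),
         masks = lapply(results, function(r)
           list(hip = r$mask_hip, chest = r$mask_chest, joint = r$joint)),
         version = as.character(utils::packageVersion("madpair"))),
    class = "mad_run"
  )
  run$tables <- build_tables(run)
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

# Output tables mirroring the validation report's layout ----------------

build_tables <- function(run) {
  keys <- names(run$summaries)
  empty <- data.frame()
  if (!length(keys)) {
    return(list(table2_correlation = empty, table3_mse = empty,
                table4_ba_participant = empty, table5_ba_pooled = empty,
                fig2_diurnal = if (is.null(run$diurnal)) empty else
                  as.data.frame(run$diurnal)))
  }
  L <- as.numeric(keys)
  t2 <- do.call(rbind, lapply(keys, function(k) {
    s <- run$summaries[[k]]
    if (is.null(s)) return(NULL)
    data.frame(window = format_window(s$epoch_length_s),
               epoch_s = s$epoch_length_s, n_participants = s$n_participants,
               r_min = s$r[["min"]], r_max = s$r[["max"]],
               r_mean = s$r[["mean"]], r_sd = s$r[["sd"]],
               r_median = s$r[["median"]], r_q1 = s$r[["q1"]],
               r_q3 = s$r[["q3"]],
               n_below_threshold = s$n_below_threshold,
               pct_below_threshold = s$pct_below_threshold)
  }))
  t3 <- do.call(rbind, lapply(keys, function(k) {
    s <- run$summaries[[k]]
    if (is.null(s)) return(NULL)
    data.frame(window = format_window(s$epoch_length_s),
               epoch_s = s$epoch_length_s,
               mse_mean_g2 = s$mse[["mean"]], mse_sd_g2 = s$mse[["sd"]],
               mse_median_g2 = s$mse[["median"]],
               mse_mean_x1e6 = 1e6 * s$mse[["mean"]],
               mse_sd_x1e6 = 1e6 * s$mse[["sd"]],
               mse_median_x1e6 = 1e6 * s$mse[["median"]],
               mse_q1_x1e6 = 1e6 * s$mse[["q1"]],
               mse_q3_x1e6 = 1e6 * s$mse[["q3"]],
               mse_min_x1e6 = 1e6 * s$mse[["min"]],
               mse_max_x1e6 = 1e6 * s$mse[["max"]])
  }))
  ba_row <- function(ba) {
    data.frame(window = format_window(ba$epoch_length_s),
               epoch_s = ba$epoch_length_s, n = ba$n,
               mean_reference = ba$mean_a, mean_test = ba$mean_b,
               bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
               pct_outside = ba$pct_outside)
  }
  t4 <- do.call(rbind, lapply(run$ba_participant, ba_row))
  t5 <- do.call(rbind, lapply(run$ba_pooled, ba_row))
  list(table2_correlation = if (is.null(t2)) empty else t2,
       table3_mse = if (is.null(t3)) empty else t3,
       table4_ba_participant = if (is.null(t4)) empty else t4,
       table5_ba_pooled = if (is.null(t5)) empty else t5,
       fig2_diurnal = if (is.null(run$diurnal)) empty else
         as.data.frame(run$diurnal))
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(run$tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(run$tables[[nm]], p, row.names = FALSE)
    paths[nm] <- p
  }
  report <- list(
    software = paste("madpair", run$version),
    flow = list(candidates = run$flow$candidates,
                included = run$flow$included,
                excluded = run$flow$excluded,
                exclusions = run$flow$exclusions),
    wear_summary = as.list(run$wear_summary),
    config = unclass(run$config),
    tables = as.list(paths)
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.mad_run <- function(x, ...) {
  cat(sprintf("<mad_run> %d candidates: %d included, %d excluded\n",
              x$flow$candidates, x$flow$included, x$flow$excluded))
  if (nrow(x$flow$exclusions)) {
    for (i in seq_len(nrow(x$flow$exclusions))) {
      cat(sprintf("  - %s: %s\n", x$flow$exclusions$participant[i],
                  x$flow$exclusions$reason[i]))
    }
  }
  if (x$flow$included > 0 && !is.na(x$wear_summary[["mean"]])) {
    cat(sprintf("  valid days/participant: mean %.2f (sd %.2f, min %g, max %g)\n",
                x$wear_summary[["mean"]], x$wear_summary[["sd"]],
                x$wear_summary[["min"]], x$wear_summary[["max"]]))
  }
  t2 <- x$tables$table2_correlation
  if (nrow(t2)) {
    cat("  mean participant correlation by window:\n")
    for (i in seq_len(nrow(t2))) {
      cat(sprintf("    %-7s r = %.3f (sd %.3f)\n", t2$window[i],
                  t2$r_mean[i], t2$r_sd[i]))
    }
  }
  invisible(x)
}

#' @export
summary.mad_run <- function(object, ...) {
  print(object)
  invisible(object$tables)
}

#' Wear / valid-day statistics of a pipeline run
#'
#' Mean, SD, min and max of the number of valid days across included
#' participants.
#'
#' @param run a `mad_run` from [run_pipeline()].
#' @return named numeric vector `n`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_wear <- function(run) {
  stopifnot(inherits(run, "mad_run"))
  run$wear_summary
}

#' Persist epoch series / wear masks as CSV
#'
#' Flat-file forms of the intermediate objects:
#' `participant,device,epoch_start,epoch_s,mad_g,n_samples` for epoch
#' series and `participant,device,minute_start,wear` for masks.
#'
#' @param x an `epoch_series` or `nonwear_mask`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_epoch_csv <- function(x, path) {
  stopifnot(inherits(x, "epoch_series"))
  df <- data.frame(participant = attr(x, "participant_id"),
                   device = attr(x, "device_label"),
                   epoch_start = format_naive_time(x$epoch_start),
                   epoch_s = attr(x, "epoch_length_s"),
                   mad_g = x$mad, n_samples = x$n_samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epoch_csv
#' @export
write_mask_csv <- function(x, path) {
  stopifnot(inherits(x, "nonwear_mask"))
  df <- data.frame(participant = attr(x, "participant_id"),
                   device = attr(x, "device_label"),
                   minute_start = format_naive_time(x$minute_start),
                   wear = x$wear)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
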