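# End-to-end pipeline stages tying the modules together. Each stage reads
# config + inputs, writes CSV/TSV outputs stamped with the config hash and
# seed, and appends an ISO-8601-timestamped log line. Reruns with identical
# config are byte-identical (logs carry the only timestamps and live in a
# separate file).

writeStamped <- function(tab, path, config, sep = ",") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# zfvision seed=%d config_hash=%d", config$seed,
                     configHash(config)), con)
  utils::write.table(tab, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

appendLog <- function(dir, stage, message) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  stage, message)
  cat(line, "\n", sep = "", file = file.path(dir, "zfvision.log"),
      append = TRUE)
  invisible(line)
}

#' Simulate a hunting-assay cohort to disk
#'
#' Builds the incremental-intensity schedule, simulates `n_fish` eye-angle
#' traces from the response curve, and writes `schedule.csv`,
#' `fish_<id>.csv` tracking tables and `truth_<id>.csv` sidecars plus a
#' `cohort.tsv` manifest into `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A `zfRunConfig`; the global seed lives here.
#' @param n_fish Number of fish.
#' @param curve A [ResponseCurve-class].
#' @param schedule A [StimulusSchedule-class] (default: 20-epoch incremental
#'   paradigm).
#' @param detector_snr Injected event amplitude in noise-SD units.
#' @return Invisible list with the schedule and file paths.
#' @export
simulateHunting <- function(out_dir, config = defaultRunConfig(),
                            n_fish = 25, curve = ResponseCurve(),
                            schedule = buildIncrementalSchedule(),
                            detector_snr = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeScheduleCsv(schedule, file.path(out_dir, "schedule.csv"))
  sim <- genHuntingCohort(schedule, curve, n_fish, detector_snr = detector_snr,
                          seed = subSeed(config$seed, "simulate_hunting"))
  ids <- sprintf("%03d", seq_len(n_fish))
  tracking <- file.path(out_dir, paste0("fish_", ids, ".csv"))
  truthPaths <- file.path(out_dir, paste0("truth_", ids, ".csv"))
  for (f in seq_len(n_fish)) {
    writeTrackingCsv(sim$traces[[f]], tracking[f])
    writeTruthCsv(sim$truths[[f]], truthPaths[f])
  }
  writeStamped(data.frame(fish_id = paste0("fish_", ids),
                          tracking_file = basename(tracking),
                          truth_file = basename(truthPaths)),
               file.path(out_dir, "cohort.tsv"), config, sep = "\t")
  appendLog(out_dir, "simulate-hunting",
            sprintf("n_fish=%d seed=%d", n_fish, config$seed))
  invisible(list(schedule = schedule, tracking = tracking,
                 truth = truthPaths))
}

#' Detect hunting responses for a simulated or recorded cohort
#'
#' Reads `schedule.csv` and the `fish_*.csv` tracking tables from `in_dir`,
#' runs the convergence-event detector, and writes `events.csv`
#' (`fish_id,time_s,kind,eye,epoch_index`), `response_table.tsv` (binary
#' fish x epoch matrix) and `response_summary.tsv` (per-intensity response
#' percentages with Wilson CIs) into `out_dir`.
#'
#' @param in_dir Directory holding `schedule.csv` and `fish_*.csv`.
#' @param out_dir Output directory.
#' @param config A `zfRunConfig` (detector block is used).
#' @return Invisible [ResponseTable-class].
#' @export
detectHunting <- function(in_dir, out_dir = in_dir,
                          config = defaultRunConfig()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  schedule <- readScheduleCsv(file.path(in_dir, "schedule.csv"))
  if (!identical(normalizePath(in_dir), normalizePath(out_dir)))
    writeScheduleCsv(schedule, file.path(out_dir, "schedule.csv"))
  files <- sort(list.files(in_dir, pattern = "^fish_.*\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no fish_*.csv tracking files in ", in_dir,
                           call. = FALSE)
  traces <- lapply(files, readTrackingCsv)
  ids <- sub("\\.csv$", "", basename(files))
  params <- configDetectorParams(config)
  det <- detectCohortResponses(traces, schedule, params, fish_ids = ids)
  evTab <- do.call(rbind, lapply(ids, function(id) {
    ev <- det$events[[id]]
    if (!nrow(ev)) return(NULL)
    data.frame(fish_id = id, time_s = numFmt(ev$time_s), kind = ev$kind,
               eye = ev$eye, epoch_index = ev$epoch_index)
  }))
  if (is.null(evTab))
    evTab <- data.frame(fish_id = character(), time_s = character(),
                        kind = character(), eye = character(),
                        epoch_index = integer())
  writeStamped(evTab, file.path(out_dir, "events.csv"), config)
  mat <- responseMatrix(det$table)
  writeStamped(data.frame(fish_id = ids,
                          matrix(mat, nrow = nrow(mat),
                                 dimnames = list(NULL, paste0("epoch_",
                                   epochs(schedule)$index)))),
               file.path(out_dir, "response_table.tsv"), config, sep = "\t")
  summ <- summarizeResponses(det$table)
  per <- summ$per_intensity
  ci <- lapply(seq_len(nrow(per)), function(i)
    wilsonInterval(per$responses[i], per$trials[i]))
  per$ci_low_pct <- numFmt(100 * vapply(ci, `[[`, 0, "ci_low"))
  per$ci_high_pct <- numFmt(100 * vapply(ci, `[[`, 0, "ci_high"))
  per$response_pct <- numFmt(per$response_pct)
  writeStamped(per, file.path(out_dir, "response_summary.tsv"), config,
               sep = "\t")
  appendLog(out_dir, "detect-hunting",
            sprintf("n_fish=%d pooled=%s seed=%d", length(ids),
                    numFmt(summ$pooled$proportion), config$seed))
  invisible(det$table)
}

readResponseTableTsv <- function(path, schedule) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  ResponseTable(tab$fish_id, epochs(schedule)$intensity_percent, mat)
}

#' Statistical report for one or two detected cohorts
#'
#' For a single cohort: pooled and per-intensity response proportions with
#' Wilson 95% CIs. For two cohorts (e.g. wild type vs mutant): additionally
#' the pooled two-proportion z-test, per-intensity chi-square tests of
#' detections over displays, and a two-sample Kolmogorov-Smirnov test on the
#' per-intensity response proportions. Writes `stats_report.tsv`
#' (`test,group,statistic,p,notes`).
#'
#' @param dirs Character vector of one or two directories holding
#'   `schedule.csv` and `response_table.tsv` (from [detectHunting()]).
#' @param out_dir Output directory.
#' @param config A `zfRunConfig`.
#' @return Invisible data.frame of report rows.
#' @export
statsReport <- function(dirs, out_dir, config = defaultRunConfig()) {
  stopIfNot(length(dirs) %in% c(1L, 2L), "need one or two input directories")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  schedule <- readScheduleCsv(file.path(dirs[1L], "schedule.csv"))
  tables <- lapply(dirs, function(d)
    readResponseTableTsv(file.path(d, "response_table.tsv"), schedule))
  summs <- lapply(tables, summarizeResponses)
  rows <- list()
  for (g in seq_along(summs)) {
    s <- summs[[g]]
    ci <- wilsonInterval(s$pooled$successes, s$pooled$trials)
    rows[[length(rows) + 1L]] <- data.frame(
      test = "pooled_proportion", group = sprintf("group%d", g),
      statistic = numFmt(s$pooled$proportion), p = "",
      notes = sprintf("wilson95=[%s,%s] n=%d", numFmt(ci$ci_low),
                      numFmt(ci$ci_high), s$pooled$trials))
    for (i in seq_len(nrow(s$per_intensity))) {
      pi <- s$per_intensity[i, ]
      ci <- wilsonInterval(pi$responses, pi$trials)
      rows[[length(rows) + 1L]] <- data.frame(
        test = sprintf("intensity_%g_proportion", pi$intensity_percent),
        group = sprintf("group%d", g),
        statistic = numFmt(pi$responses / pi$trials), p = "",
        notes = sprintf("wilson95=[%s,%s] n=%d", numFmt(ci$ci_low),
                        numFmt(ci$ci_high), pi$trials))
    }
  }
  if (length(summs) == 2L) {
    a <- summs[[1L]]; b <- summs[[2L]]
    z <- twoProportionZTest(a$pooled$successes, a$pooled$trials,
                            b$pooled$successes, b$pooled$trials)
    rows[[length(rows) + 1L]] <- data.frame(
      test = "two_proportion_z", group = "group1-group2",
      statistic = numFmt(unname(z$statistic)), p = numFmt(z$p.value),
      notes = if (z$degenerate) "degenerate" else "")
    shared <- intersect(a$per_intensity$intensity_percent,
                        b$per_intensity$intensity_percent)
    for (v in shared) {
      pa <- a$per_intensity[a$per_intensity$intensity_percent == v, ]
      pb <- b$per_intensity[b$per_intensity$intensity_percent == v, ]
      margins <- c(pa$responses + pa$trials - pa$responses,
                   pb$responses + pb$trials - pb$responses)
      chi <- tryCatch(chi2Independence2x2(pa$responses,
                                          pa$trials - pa$responses,
                                          pb$responses,
                                          pb$trials - pb$responses),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        test = sprintf("intensity_%g_chi2", v), group = "group1-group2",
        statistic = if (is.null(chi)) "" else numFmt(unname(chi$statistic)),
        p = if (is.null(chi)) "" else numFmt(chi$p.value),
        notes = if (is.null(chi)) "degenerate margin" else "")
    }
    ks <- ksTwoSample(a$per_intensity$response_pct,
                      b$per_intensity$response_pct)
    rows[[length(rows) + 1L]] <- data.frame(
      test = "intensity_distribution_ks", group = "group1-group2",
      statistic = numFmt(unname(ks$statistic)), p = numFmt(ks$p.value),
      notes = sprintf("m=%d levels", nrow(a$per_intensity)))
  }
  report <- do.call(rbind, rows)
  writeStamped(report, file.path(out_dir, "stats_report.tsv"), config,
               sep = "\t")
  appendLog(out_dir, "stats-report", sprintf("groups=%d seed=%d",
                                             length(dirs), config$seed))
  invisible(report)
}

#' Quantify a directory of ERG traces
#'
#' Reads every `*.csv` ERG trace in `in_dir` and writes `erg_summary.tsv`
#' with baseline, amplitude and time-to-peak per file.
#'
#' @param in_dir Directory of ERG CSVs (`time_s,voltage_uV` + metadata).
#' @param out_dir Output directory.
#' @param config A `zfRunConfig` (`erg` block used).
#' @return Invisible summary data.frame.
#' @export
ergReport <- function(in_dir, out_dir = in_dir, config = defaultRunConfig()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- sort(list.files(in_dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop("no .csv traces in ", in_dir, call. = FALSE)
  rows <- lapply(files, function(f) {
    rec <- readERGCsv(f)
    bw <- measureBWave(rec, config$erg$search_window_s, config$erg$smooth_s)
    data.frame(file = basename(f), intensity_log = rec@intensityLog,
               band = rec@wavelengthBand,
               baseline_uV = numFmt(bw$baseline_uV),
               amplitude_uV = numFmt(bw$amplitude_uV),
               time_to_peak_s = numFmt(bw$time_to_peak_s))
  })
  out <- do.call(rbind, rows)
  writeStamped(out, file.path(out_dir, "erg_summary.tsv"), config, sep = "\t")
  appendLog(out_dir, "erg", sprintf("n_traces=%d", length(files)))
  invisible(out)
}

#' Process a directory of OPL line-scans
#'
#' Normalizes, smooths and grid-resamples every `*.csv` line-scan, then
#' writes the pooled per-channel mean/CI traces (`opl_pooled.tsv`) and the
#' channel-block mean Pearson correlation matrix (`opl_correlation.tsv`).
#'
#' @param in_dir Directory of OPL CSVs (`position,dapi,...`).
#' @param out_dir Output directory.
#' @param config A `zfRunConfig` (`opl` block used).
#' @return Invisible list with the pooled traces and correlation matrix.
#' @export
oplReport <- function(in_dir, out_dir = in_dir, config = defaultRunConfig()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- sort(list.files(in_dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop("no .csv line-scans in ", in_dir, call. = FALSE)
  profiles <- lapply(files, function(f)
    preprocessProfile(readOPLCsv(f), config$opl$smooth_points,
                      config$opl$grid_size))
  pooled <- poolProfiles(profiles)
  pooledTab <- do.call(rbind, lapply(names(pooled), function(ch)
    data.frame(channel = ch, position = numFmt(pooled[[ch]]$position),
               mean = numFmt(pooled[[ch]]$mean),
               ci_low = numFmt(pooled[[ch]]$ci_low),
               ci_high = numFmt(pooled[[ch]]$ci_high))))
  writeStamped(pooledTab, file.path(out_dir, "opl_pooled.tsv"), config,
               sep = "\t")
  chans <- setdiff(profileChannels(profiles[[1L]]),
                   profiles[[1L]]@referenceChannel)
  traces <- list()
  for (r in seq_along(profiles)) for (ch in chans)
    traces[[sprintf("retina%02d.%s", r, ch)]] <-
      profileChannel(profiles[[r]], ch)
  blocks <- channelBlockMeans(correlationMatrix(traces), chans)
  corTab <- data.frame(channel = rownames(blocks))
  for (ch in colnames(blocks)) corTab[[ch]] <- numFmt(blocks[, ch])
  writeStamped(corTab, file.path(out_dir, "opl_correlation.tsv"), config,
               sep = "\t")
  appendLog(out_dir, "opl", sprintf("n_retinas=%d", length(files)))
  invisible(list(pooled = pooled, correlation = blocks))
}

#' Quantify OMR trajectories per phase
#'
#' Reads an OMR tracking CSV, computes per-fish per-phase distance and
#' rightward-fraction metrics for a schedule, and writes `omr_metrics.tsv`.
#'
#' @param tracking_csv Path to `time_s,x_mm,y_mm,row_id` tracking CSV.
#' @param schedule An [OMRSchedule-class].
#' @param out_dir Output directory.
#' @param config A `zfRunConfig` (`omr` block used).
#' @return Invisible metrics data.frame.
#' @export
omrReport <- function(tracking_csv, schedule, out_dir,
                      config = defaultRunConfig()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trajs <- readOMRTrackingCsv(tracking_csv)
  met <- cohortPhaseMetrics(trajs, schedule, config$omr$filter_multiplier)
  out <- data.frame(fish_id = met$fish_id, block = met$block,
                    contrast = met$contrast, phase = met$phase,
                    total_mm = numFmt(met$total_mm),
                    rightward_mm = numFmt(met$rightward_mm),
                    fraction = ifelse(met$defined, numFmt(met$fraction), "NA"))
  writeStamped(out, file.path(out_dir, "omr_metrics.tsv"), config, sep = "\t")
  appendLog(out_dir, "omr", sprintf("n_fish=%d", length(trajs)))
  invisible(met)
}
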