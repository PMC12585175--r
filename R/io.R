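# File formats and configuration. Plain CSV/TSV throughout: the source data
# are small tabular time series, and bit-exact reproducibility plus
# diffability dominate. Readers validate and reject rather than silently
# coerce.

numFmt <- function(x) trimws(formatC(x, digits = 12, format = "g"))

#' Read a tracking CSV into an EyeTrace
#'
#' Expects a header with `time_s`, `left_angle_deg`, `right_angle_deg` and
#' optionally `tail_curvature_deg`. Non-monotone time stamps are rejected
#' with the offending row cited; NaN/NA runs covering more than 5% of the
#' trace are rejected; shorter gaps are linearly interpolated and flagged via
#' the `interpolated` attribute.
#'
#' @param path CSV file path.
#' @return An [EyeTrace-class]; attribute `interpolated` counts filled
#'   samples.
#' @export
readTrackingCsv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("time_s", "left_angle_deg", "right_angle_deg")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("tracking file '", path, "' misses column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (colname in intersect(c(need, "tail_curvature_deg"), names(tab)))
    if (!is.numeric(tab[[colname]]))
      stop("column '", colname, "' contains malformed numeric fields",
           call. = FALSE)
  bad <- which(diff(tab$time_s) <= 0)
  if (length(bad))
    stop("non-monotone time at data row ", bad[1L] + 1L, " of '", path, "'",
         call. = FALSE)
  nInterp <- 0L
  fill <- function(v) {
    na <- is.na(v)
    if (!any(na)) return(v)
    if (mean(na) > 0.05)
      stop("more than 5% missing samples in '", path, "'", call. = FALSE)
    nInterp <<- nInterp + sum(na)
    stats::approx(tab$time_s[!na], v[!na], xout = tab$time_s, rule = 2)$y
  }
  left <- fill(tab$left_angle_deg)
  right <- fill(tab$right_angle_deg)
  tailc <- if ("tail_curvature_deg" %in% names(tab))
    fill(tab$tail_curvature_deg) else NULL
  tr <- EyeTrace(tab$time_s, left, right, tail_curvature_deg = tailc)
  attr(tr, "interpolated") <- nInterp
  tr
}

#' Write an EyeTrace as a tracking CSV
#'
#' @param trace An [EyeTrace-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTrackingCsv <- function(trace, path) {
  stopifnot(is(trace, "EyeTrace"))
  tab <- data.frame(time_s = numFmt(trace@time),
                    left_angle_deg = numFmt(trace@leftAngle),
                    right_angle_deg = numFmt(trace@rightAngle))
  if (!is.null(trace@tailCurvature))
    tab$tail_curvature_deg <- numFmt(trace@tailCurvature)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read ground-truth event sidecar CSVs
#'
#' Sidecar format `event_times_s,kind,epoch`.
#'
#' @param truth An [EventTruth-class].
#' @param path File path.
#' @return `writeTruthCsv` returns `path` invisibly; `readTruthCsv` an
#'   [EventTruth-class].
#' @export
writeTruthCsv <- function(truth, path) {
  utils::write.csv(truthTable(truth), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTruthCsv
#' @export
readTruthCsv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  EventTruth(tab$event_times_s, tab$kind, tab$epoch)
}

#' Read an ERG CSV
#'
#' Expects `time_s,voltage_uV` plus either metadata columns
#' (`stimulus_onset_s`, `intensity_log`, `wavelength_band`) or explicit
#' arguments.
#'
#' @param path CSV path.
#' @param stimulus_onset_s,intensity_log,wavelength_band Metadata overriding
#'   any columns.
#' @return An [ERGRecording-class].
#' @export
readERGCsv <- function(path, stimulus_onset_s = NULL, intensity_log = NULL,
                       wavelength_band = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("time_s", "voltage_uV")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("ERG file misses column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  onset <- stimulus_onset_s %||% tab$stimulus_onset_s[1L]
  if (is.null(onset) || is.na(onset))
    stop("stimulus onset neither in file nor supplied", call. = FALSE)
  ERGRecording(tab$time_s, tab$voltage_uV, onset,
               intensity_log = intensity_log %||% tab$intensity_log[1L] %||% 0L,
               wavelength_band = wavelength_band %||%
                 tab$wavelength_band[1L] %||% "uv_blue")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Read an OPL line-scan CSV
#'
#' Expects `position` plus one column per channel including the nuclear
#' reference channel (extra channels permitted).
#'
#' @param path CSV path.
#' @param reference_channel Reference channel name (default `"dapi"`).
#' @return A raw [OPLProfile-class].
#' @export
readOPLCsv <- function(path, reference_channel = "dapi") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"position" %in% names(tab))
    stop("OPL file misses column: position", call. = FALSE)
  chans <- setdiff(names(tab), "position")
  if (!reference_channel %in% chans)
    stop("OPL file misses reference channel column: ", reference_channel,
         call. = FALSE)
  OPLProfile(tab$position, as.list(tab[chans]),
             reference_channel = reference_channel)
}

#' Read an OMR tracking CSV
#'
#' Expects `time_s,x_mm,y_mm` and either a `row_id` column (one trajectory
#' per row id) or raw points to be assigned via [assignRois()].
#'
#' @param path CSV path.
#' @return List of [SwimTrajectory-class] objects.
#' @export
readOMRTrackingCsv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("time_s", "x_mm", "y_mm")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("OMR tracking file misses column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"row_id" %in% names(tab))
    stop("OMR tracking file misses column: row_id (use assignRois for raw points)",
         call. = FALSE)
  lapply(split(tab, tab$row_id), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    SwimTrajectory(as.character(d$row_id[1L]), d$time_s, d$x_mm, d$y_mm)
  })
}

#' Write an OMR trajectory cohort as one CSV
#'
#' @param trajs List of [SwimTrajectory-class] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeOMRTrackingCsv <- function(trajs, path) {
  tab <- do.call(rbind, lapply(trajs, function(tr)
    data.frame(time_s = numFmt(tr@time), x_mm = numFmt(tr@x),
               y_mm = numFmt(tr@y), row_id = tr@fishId)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- run configuration ------------------------------------------------------

#' Default run configuration
#'
#' The configuration gathers every tunable of the pipeline: global seed,
#' detector parameters, ERG search window, OPL grid size and smoothing
#' window, OMR filter multiplier.
#'
#' @param seed Global seed; stage seeds derive from it via [subSeed()].
#' @return Nested list of class `zfRunConfig`.
#' @export
defaultRunConfig <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    detector = list(window_s = 0.5, threshold_multiplier = 4,
                    strong_multiplier = 6, coincidence_window_s = 0.25,
                    refractory_s = 0.5, epoch_grace_s = 1,
                    noise_method = "mean_abs"),
    erg = list(search_window_s = 1, smooth_s = 0),
    opl = list(grid_size = 1000L, smooth_points = 25L),
    omr = list(filter_multiplier = 2)),
    class = "zfRunConfig")
}

#' Write / read run configurations (YAML)
#'
#' Round-trips exactly: `readRunConfig(writeRunConfig(cfg, p))` equals `cfg`.
#'
#' @param config A `zfRunConfig` list.
#' @param path YAML file path.
#' @return `writeRunConfig` returns `path` invisibly; `readRunConfig` a
#'   `zfRunConfig`.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg$opl$grid_size <- as.integer(cfg$opl$grid_size)
  cfg$opl$smooth_points <- as.integer(cfg$opl$smooth_points)
  structure(cfg, class = "zfRunConfig")
}

#' Deterministic fingerprint of a run configuration
#'
#' @param config A `zfRunConfig`.
#' @return Integer hash embedded in output-file headers.
#' @export
configHash <- function(config) {
  stringHash31(paste(utils::capture.output(utils::str(unclass(config))),
                     collapse = "\n"))
}

#' Detector parameters from a run configuration
#' @param config A `zfRunConfig`.
#' @return A [DetectorParams-class].
#' @export
configDetectorParams <- function(config) {
  d <- config$detector
  detectorParams(d$window_s, d$threshold_multiplier, d$strong_multiplier,
                 d$coincidence_window_s, d$refractory_s, d$epoch_grace_s,
                 d$noise_method)
}
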