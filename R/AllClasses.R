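# S4 containers for the assay data. Constructors validate on creation; slots
# are reached through accessors, not `@`.

#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' StimulusSchedule: ordered epochs of a virtual-hunting paradigm
#'
#' Holds the per-epoch stimulus table (direction, intensity, onset, sweep
#' duration) together with the optical geometry of the projected dot: a ~4.9
#' degree dot swept across ~90 degrees of the screen at ~33 deg/s.
#'
#' @slot epochs data.frame with columns `index`, `direction`
#'   (`"left_to_right"`/`"right_to_left"`), `intensity_percent`, `onset_s`,
#'   `sweep_duration_s`.
#' @slot dotSizeDeg Angular dot size (degrees).
#' @slot sweepSpeedDegS Sweep speed on the screen (degrees/second).
#' @slot screenSpanDeg Screen span covered by one sweep (degrees).
#' @export
setClass("StimulusSchedule",
  representation(epochs = "data.frame", dotSizeDeg = "numeric",
                 sweepSpeedDegS = "numeric", screenSpanDeg = "numeric"),
  prototype(dotSizeDeg = 4.9, sweepSpeedDegS = 33, screenSpanDeg = 90))

setValidity("StimulusSchedule", function(object) {
  ep <- object@epochs
  need <- c("index", "direction", "intensity_percent", "onset_s", "sweep_duration_s")
  if (!all(need %in% names(ep)))
    return(paste("epochs must have columns:", paste(need, collapse = ", ")))
  if (nrow(ep) == 0L) return(TRUE)
  if (!all(ep$direction %in% c("left_to_right", "right_to_left")))
    return("direction must be left_to_right or right_to_left")
  if (any(ep$intensity_percent < 0 | ep$intensity_percent > 100))
    return("intensity_percent must lie in [0, 100]")
  if (any(ep$onset_s < 0) || any(ep$sweep_duration_s <= 0))
    return("onsets must be >= 0 and sweep durations > 0")
  if (is.unsorted(ep$onset_s, strictly = TRUE))
    return("epochs must be sorted by onset_s")
  if (nrow(ep) > 1L) {
    ends <- ep$onset_s + ep$sweep_duration_s
    if (any(ep$onset_s[-1L] < ends[-nrow(ep)] - 1e-9))
      return("epochs must not overlap")
  }
  ratio <- object@sweepSpeedDegS * ep$sweep_duration_s / object@screenSpanDeg
  if (any(ratio < 0.85 | ratio > 1.15))
    return("sweep speed x duration inconsistent with screen span (>15%)")
  TRUE
})

#' OMRSchedule: contrast blocks of the optomotor assay
#'
#' Each block presents four 30 s phases (centering, habituation, centering,
#' rightward stimulus); the red-band digital contrast of the block is drawn
#' from a seed-permuted contrast list.
#'
#' @slot contrasts Integer digital red levels (0-255), in presentation order.
#' @slot phaseDurationsS Durations of the four phases (seconds).
#' @slot gratingSpeedMmS Grating speed during centering/stimulus (mm/s).
#' @slot gratingPeriodMm Grating spatial period (mm).
#' @export
setClass("OMRSchedule",
  representation(contrasts = "integer", phaseDurationsS = "numeric",
                 gratingSpeedMmS = "numeric", gratingPeriodMm = "numeric"),
  prototype(phaseDurationsS = c(30, 30, 30, 30), gratingSpeedMmS = 14.5,
            gratingPeriodMm = 6))

setValidity("OMRSchedule", function(object) {
  if (length(object@contrasts) < 1L) return("at least one contrast required")
  if (any(object@contrasts < 0L | object@contrasts > 255L))
    return("contrasts must lie in [0, 255]")
  if (length(object@phaseDurationsS) != 4L || any(object@phaseDurationsS <= 0))
    return("phaseDurationsS must be four positive durations")
  TRUE
})

#' EyeTrace: synchronized eye-angle (and tail) time series for one larva
#'
#' Sign convention follows the tracking output: left-eye convergence is a
#' positive deflection of the left-eye angle, right-eye convergence a negative
#' deflection of the right-eye angle.
#'
#' @slot time Time stamps (seconds, strictly increasing).
#' @slot leftAngle Left-eye angle (degrees).
#' @slot rightAngle Right-eye angle (degrees).
#' @slot tailCurvature Total tail curvature (degrees) or NULL when untracked.
#' @slot rateHz Nominal sampling rate (Hz).
#' @export
setClass("EyeTrace",
  representation(time = "numeric", leftAngle = "numeric", rightAngle = "numeric",
                 tailCurvature = "numericOrNULL", rateHz = "numeric"))

setValidity("EyeTrace", function(object) {
  n <- length(object@time)
  if (n < 2L) return("trace needs at least 2 samples")
  if (length(object@leftAngle) != n || length(object@rightAngle) != n)
    return("angle series must match time length")
  if (!is.null(object@tailCurvature) && length(object@tailCurvature) != n)
    return("tail series must match time length")
  if (is.unsorted(object@time, strictly = TRUE))
    return("time must be strictly increasing")
  dt <- stats::median(diff(object@time))
  if (abs(object@rateHz * dt - 1) > 0.01)
    return("rateHz inconsistent with median time step (>1%)")
  TRUE
})

#' EventTruth: injected ground-truth events of a synthetic trace
#'
#' @slot times Event times (seconds, strictly increasing).
#' @slot kinds Event kinds: `"locking"`, `"tracking_left"`, `"tracking_right"`.
#' @slot epochs Epoch index of each event (0-based; NA when outside epochs).
#' @export
setClass("EventTruth",
  representation(times = "numeric", kinds = "character", epochs = "integer"))

setValidity("EventTruth", function(object) {
  if (length(object@times) != length(object@kinds) ||
      length(object@times) != length(object@epochs))
    return("times, kinds and epochs must have equal length")
  if (length(object@times) > 1L && is.unsorted(object@times, strictly = TRUE))
    return("event times must be strictly increasing")
  if (!all(object@kinds %in% c("locking", "tracking_left", "tracking_right")))
    return("unknown event kind")
  TRUE
})

#' ResponseCurve: logistic intensity-response relation used by the cohort
#' generator
#'
#' Response probability at intensity x is
#' `floor + (ceiling - floor) / (1 + exp(-slope * (x - midpoint)))`,
#' emulating the observed rise from ~40% intensity to a plateau.
#'
#' @slot floor,ceiling Probability bounds (0 <= floor <= ceiling <= 1).
#' @slot midpoint Intensity (percent) of half rise.
#' @slot slope Steepness (1/percent).
#' @export
setClass("ResponseCurve",
  representation(floor = "numeric", ceiling = "numeric", midpoint = "numeric",
                 slope = "numeric"))

setValidity("ResponseCurve", function(object) {
  if (object@floor < 0 || object@ceiling > 1 || object@floor > object@ceiling)
    return("need 0 <= floor <= ceiling <= 1")
  TRUE
})

#' DetectorParams: tuning of the convergence-event detector
#'
#' The detector compares each raw eye-angle track with its rolling average and
#' thresholds the residual at a multiple of the trace's own average noise.
#'
#' @slot windowS Rolling-average window (seconds).
#' @slot thresholdMultiplier Event threshold (noise multiples).
#' @slot strongMultiplier Single-eye (prey tracking) threshold (noise multiples).
#' @slot coincidenceWindowS Max left/right peak separation for a binocular
#'   locking event (seconds).
#' @slot refractoryS Minimal separation of events on one eye (seconds).
#' @slot epochGraceS Extra time after sweep end during which an event still
#'   counts for the epoch (seconds).
#' @slot noiseMethod `"mean_abs"` (average absolute residual) or `"mad"`
#'   (median absolute residual).
#' @export
setClass("DetectorParams",
  representation(windowS = "numeric", thresholdMultiplier = "numeric",
                 strongMultiplier = "numeric", coincidenceWindowS = "numeric",
                 refractoryS = "numeric", epochGraceS = "numeric",
                 noiseMethod = "character"),
  prototype(windowS = 0.5, thresholdMultiplier = 4, strongMultiplier = 6,
            coincidenceWindowS = 0.25, refractoryS = 0.5, epochGraceS = 1,
            noiseMethod = "mean_abs"))

setValidity("DetectorParams", function(object) {
  if (object@thresholdMultiplier <= 0 ||
      object@strongMultiplier < object@thresholdMultiplier)
    return("need strongMultiplier >= thresholdMultiplier > 0")
  if (object@windowS <= 0 || object@coincidenceWindowS <= 0 ||
      object@refractoryS <= 0)
    return("all windows must be > 0")
  if (!object@noiseMethod %in% c("mean_abs", "mad"))
    return("noiseMethod must be 'mean_abs' or 'mad'")
  TRUE
})

#' ResponseTable: fish x epoch binary hunting-response matrix
#'
#' @slot fishIds Fish labels (rows).
#' @slot intensities Stimulus intensity (percent) of each epoch (columns).
#' @slot responded Binary matrix, 1 when the fish produced at least one
#'   hunting event during the epoch window.
#' @export
setClass("ResponseTable",
  representation(fishIds = "character", intensities = "numeric",
                 responded = "matrix"))

setValidity("ResponseTable", function(object) {
  m <- object@responded
  if (nrow(m) != length(object@fishIds) || ncol(m) != length(object@intensities))
    return("matrix dimensions must match fishIds and intensities")
  if (length(m) && !all(m %in% c(0, 1))) return("entries must be 0/1")
  TRUE
})

#' ERGRecording: one electroretinogram voltage trace
#'
#' @slot time Time (seconds, strictly increasing).
#' @slot voltage Voltage (microvolts).
#' @slot stimulusOnsetS Flash onset (seconds); at least 50 ms of samples must
#'   precede it so the baseline window exists.
#' @slot intensityLog Stimulus attenuation (log units, -4..0).
#' @slot wavelengthBand `"uv_blue"`, `"green"` or `"red"`.
#' @export
setClass("ERGRecording",
  representation(time = "numeric", voltage = "numeric", stimulusOnsetS = "numeric",
                 intensityLog = "integer", wavelengthBand = "character"),
  prototype(intensityLog = 0L, wavelengthBand = "uv_blue"))

setValidity("ERGRecording", function(object) {
  if (length(object@time) != length(object@voltage))
    return("time and voltage must have equal length")
  if (length(object@time) < 2L) return("trace needs at least 2 samples")
  if (is.unsorted(object@time, strictly = TRUE))
    return("time must be strictly increasing")
  if (object@stimulusOnsetS - object@time[1L] < 0.05 - 1e-12)
    return("need >= 50 ms of pre-stimulus samples")
  if (!object@wavelengthBand %in% c("uv_blue", "green", "red"))
    return("wavelengthBand must be uv_blue, green or red")
  if (object@intensityLog < -4L || object@intensityLog > 0L)
    return("intensityLog must lie in [-4, 0]")
  TRUE
})

#' OPLProfile: multi-channel intensity line-scan along the outer plexiform
#' layer
#'
#' Arclength runs from the ventral end of the strike zone (position 0 by
#' convention). A nuclear reference channel (DAPI) is carried for
#' normalization.
#'
#' @slot arclength Positions along the OPL (raw units or, after
#'   normalization, fractions in [0, 1]); strictly increasing.
#' @slot channels Named list of intensity series, one per channel.
#' @slot referenceChannel Name of the nuclear reference channel.
#' @slot normalized TRUE after DAPI/max normalization.
#' @export
setClass("OPLProfile",
  representation(arclength = "numeric", channels = "list",
                 referenceChannel = "character", normalized = "logical"),
  prototype(referenceChannel = "dapi", normalized = FALSE))

setValidity("OPLProfile", function(object) {
  n <- length(object@arclength)
  if (n < 2L) return("profile needs at least 2 points")
  if (is.unsorted(object@arclength, strictly = TRUE))
    return("arclength must be strictly increasing")
  if (length(object@channels) == 0L || is.null(names(object@channels)))
    return("channels must be a named list")
  if (!all(vapply(object@channels, length, 1L) == n))
    return("all channels must match arclength length")
  if (!object@referenceChannel %in% names(object@channels))
    return("referenceChannel not present among channels")
  TRUE
})

#' SwimTrajectory: centroid path of one fish in the OMR arena
#'
#' @slot fishId Fish label.
#' @slot time Time (seconds, strictly increasing).
#' @slot x,y Arena coordinates (mm); x increases in the stimulus direction.
#' @export
setClass("SwimTrajectory",
  representation(fishId = "character", time = "numeric", x = "numeric",
                 y = "numeric"))

setValidity("SwimTrajectory", function(object) {
  n <- length(object@time)
  if (length(object@x) != n || length(object@y) != n)
    return("x and y must match time length")
  if (n > 1L && is.unsorted(object@time, strictly = TRUE))
    return("time must be strictly increasing")
  if (any(!is.finite(object@x)) || any(!is.finite(object@y)))
    return("coordinates must be finite")
  TRUE
})

## ---- show methods -----------------------------------------------------------

setMethod("show", "StimulusSchedule", function(object) {
  ep <- object@epochs
  cat(sprintf("StimulusSchedule: %d epochs, dot %.1f deg, sweep %.0f deg/s over %.0f deg\n",
              nrow(ep), object@dotSizeDeg, object@sweepSpeedDegS, object@screenSpanDeg))
  if (nrow(ep)) {
    cat(sprintf("  intensities: %s%%\n",
                paste(sort(unique(ep$intensity_percent)), collapse = ", ")))
    cat(sprintf("  span: %.1f - %.1f s\n", ep$onset_s[1L],
                ep$onset_s[nrow(ep)] + ep$sweep_duration_s[nrow(ep)]))
  }
})

setMethod("show", "OMRSchedule", function(object) {
  cat(sprintf("OMRSchedule: %d contrast blocks (%s), phases %s s, %.1f mm/s, period %.0f mm\n",
              length(object@contrasts), paste(object@contrasts, collapse = ", "),
              paste(object@phaseDurationsS, collapse = "/"),
              object@gratingSpeedMmS, object@gratingPeriodMm))
})

setMethod("show", "EyeTrace", function(object) {
  cat(sprintf("EyeTrace: %d samples at %.1f Hz (%.1f s)%s\n",
              length(object@time), object@rateHz, diff(range(object@time)),
              if (is.null(object@tailCurvature)) "" else ", tail tracked"))
})

setMethod("show", "EventTruth", function(object) {
  cat(sprintf("EventTruth: %d events (%s)\n", length(object@times),
              paste(names(table(object@kinds)), table(object@kinds),
                    sep = ":", collapse = ", ")))
})

setMethod("show", "ResponseCurve", function(object) {
  cat(sprintf("ResponseCurve: floor %.2f, ceiling %.2f, midpoint %.0f%%, slope %.2f /%%\n",
              object@floor, object@ceiling, object@midpoint, object@slope))
})

setMethod("show", "DetectorParams", function(object) {
  cat(sprintf(paste0("DetectorParams: window %.2f s, threshold %.1fx noise ",
                     "(strong %.1fx), coincidence %.2f s, refractory %.2f s, ",
                     "grace %.1f s, noise = %s\n"),
              object@windowS, object@thresholdMultiplier, object@strongMultiplier,
              object@coincidenceWindowS, object@refractoryS, object@epochGraceS,
              object@noiseMethod))
})

setMethod("show", "ResponseTable", function(object) {
  cat(sprintf("ResponseTable: %d fish x %d epochs, pooled response %.3f\n",
              nrow(object@responded), ncol(object@responded),
              if (length(object@responded)) mean(object@responded) else NA_real_))
})

setMethod("show", "ERGRecording", function(object) {
  cat(sprintf("ERGRecording: %d samples, onset %.3f s, log %d, band %s\n",
              length(object@time), object@stimulusOnsetS, object@intensityLog,
              object@wavelengthBand))
})

setMethod("show", "OPLProfile", function(object) {
  cat(sprintf("OPLProfile (%s): %d points, channels: %s (reference: %s)\n",
              if (object@normalized) "normalized" else "raw",
              length(object@arclength), paste(names(object@channels), collapse = ", "),
              object@referenceChannel))
})

setMethod("show", "SwimTrajectory", function(object) {
  cat(sprintf("SwimTrajectory '%s': %d samples over %.1f s\n", object@fishId,
              length(object@time),
              if (length(object@time) > 1L) diff(range(object@time)) else 0))
})

## ---- accessors --------------------------------------------------------------

#' Epoch table of a stimulus schedule
#' @param x A StimulusSchedule.
#' @return data.frame of epochs.
#' @export
epochs <- function(x) {
  stopifnot(is(x, "StimulusSchedule"))
  x@epochs
}

#' Number of epochs
#' @param x A StimulusSchedule.
#' @return Integer epoch count.
#' @export
nEpochs <- function(x) nrow(epochs(x))

#' Time stamps of a recording
#' @param x An EyeTrace, ERGRecording or SwimTrajectory.
#' @return Numeric vector of seconds.
#' @export
traceTime <- function(x) x@time

#' Eye-angle series of an EyeTrace
#' @param x An EyeTrace.
#' @param eye `"left"` or `"right"`.
#' @return Numeric vector of degrees.
#' @export
eyeAngle <- function(x, eye = c("left", "right")) {
  stopifnot(is(x, "EyeTrace"))
  switch(match.arg(eye), left = x@leftAngle, right = x@rightAngle)
}

#' Tail-curvature series of an EyeTrace (NULL when untracked)
#' @param x An EyeTrace.
#' @return Numeric vector of degrees or NULL.
#' @export
tailCurvature <- function(x) {
  stopifnot(is(x, "EyeTrace"))
  x@tailCurvature
}

#' Ground-truth events as a data.frame
#' @param x An EventTruth.
#' @return data.frame with `event_times_s`, `kind`, `epoch`.
#' @export
truthTable <- function(x) {
  stopifnot(is(x, "EventTruth"))
  data.frame(event_times_s = x@times, kind = x@kinds, epoch = x@epochs)
}

#' Response matrix of a ResponseTable
#' @param x A ResponseTable.
#' @return Binary matrix (fish x epoch).
#' @export
responseMatrix <- function(x) {
  stopifnot(is(x, "ResponseTable"))
  m <- x@responded
  dimnames(m) <- list(x@fishIds, NULL)
  m
}

#' Epoch intensities of a ResponseTable
#' @param x A ResponseTable.
#' @return Numeric vector of intensity percentages, one per epoch.
#' @export
epochIntensities <- function(x) {
  stopifnot(is(x, "ResponseTable"))
  x@intensities
}

#' Channel series of an OPLProfile
#' @param x An OPLProfile.
#' @param name Channel name.
#' @return Numeric intensity series.
#' @export
profileChannel <- function(x, name) {
  stopifnot(is(x, "OPLProfile"))
  if (!name %in% names(x@channels))
    stop("no channel named '", name, "'", call. = FALSE)
  x@channels[[name]]
}

#' Channel names of an OPLProfile
#' @param x An OPLProfile.
#' @return Character vector.
#' @export
profileChannels <- function(x) {
  stopifnot(is(x, "OPLProfile"))
  names(x@channels)
}

#' Evaluate a ResponseCurve at given intensities
#' @param curve A ResponseCurve.
#' @param intensity Intensity percentages.
#' @return Response probabilities.
#' @export
responseProbability <- function(curve, intensity) {
  stopifnot(is(curve, "ResponseCurve"))
  curve@floor + (curve@ceiling - curve@floor) *
    stats::plogis(curve@slope * (intensity - curve@midpoint))
}

## ---- light constructors -----------------------------------------------------

#' Construct an EyeTrace
#'
#' @param time_s Time stamps (seconds).
#' @param left_angle_deg,right_angle_deg Eye angles (degrees).
#' @param tail_curvature_deg Optional tail curvature (degrees).
#' @param rate_hz Sampling rate; inferred from the median time step if NULL.
#' @return An [EyeTrace-class] object.
#' @export
EyeTrace <- function(time_s, left_angle_deg, right_angle_deg,
                     tail_curvature_deg = NULL, rate_hz = NULL) {
  if (is.null(rate_hz)) rate_hz <- 1 / stats::median(diff(time_s))
  new("EyeTrace", time = as.numeric(time_s), leftAngle = as.numeric(left_angle_deg),
      rightAngle = as.numeric(right_angle_deg),
      tailCurvature = if (is.null(tail_curvature_deg)) NULL else as.numeric(tail_curvature_deg),
      rateHz = rate_hz)
}

#' Construct an EventTruth
#' @param event_times_s Event times (seconds, strictly increasing).
#' @param kinds Event kinds.
#' @param epochs 0-based epoch indices (NA allowed).
#' @return An [EventTruth-class] object.
#' @export
EventTruth <- function(event_times_s = numeric(), kinds = character(),
                       epochs = integer()) {
  new("EventTruth", times = as.numeric(event_times_s), kinds = as.character(kinds),
      epochs = as.integer(epochs))
}

#' Construct a ResponseCurve
#' @param floor,ceiling Probability bounds.
#' @param midpoint Half-rise intensity (percent).
#' @param slope Steepness (1/percent).
#' @return A [ResponseCurve-class] object.
#' @export
ResponseCurve <- function(floor = 0.05, ceiling = 0.8, midpoint = 55, slope = 0.15) {
  new("ResponseCurve", floor = floor, ceiling = ceiling, midpoint = midpoint,
      slope = slope)
}

#' Construct detector parameters
#'
#' Defaults: 0.5 s rolling window, event threshold 4x and single-eye
#' (tracking) threshold 6x the trace's average noise, 0.25 s binocular
#' coincidence window, 0.5 s refractory period, 1 s epoch grace.
#'
#' @param window_s Rolling-average window (seconds).
#' @param threshold_multiplier Event threshold in noise multiples.
#' @param strong_multiplier Single-eye tracking threshold in noise multiples.
#' @param coincidence_window_s Binocular pairing window (seconds).
#' @param refractory_s Per-eye merge window (seconds).
#' @param epoch_grace_s Post-sweep attribution grace (seconds).
#' @param noise_method `"mean_abs"` or `"mad"`.
#' @return A [DetectorParams-class] object.
#' @export
detectorParams <- function(window_s = 0.5, threshold_multiplier = 4,
                           strong_multiplier = 6, coincidence_window_s = 0.25,
                           refractory_s = 0.5, epoch_grace_s = 1,
                           noise_method = c("mean_abs", "mad")) {
  new("DetectorParams", windowS = window_s,
      thresholdMultiplier = threshold_multiplier,
      strongMultiplier = strong_multiplier,
      coincidenceWindowS = coincidence_window_s, refractoryS = refractory_s,
      epochGraceS = epoch_grace_s, noiseMethod = match.arg(noise_method))
}

#' Construct an ERGRecording
#' @param time_s Time stamps (seconds).
#' @param voltage_uV Voltage (microvolts).
#' @param stimulus_onset_s Flash onset (seconds, >= 0.05 after trace start).
#' @param intensity_log Attenuation in log units (-4..0).
#' @param wavelength_band `"uv_blue"`, `"green"` or `"red"`.
#' @return An [ERGRecording-class] object.
#' @export
ERGRecording <- function(time_s, voltage_uV, stimulus_onset_s,
                         intensity_log = 0L,
                         wavelength_band = c("uv_blue", "green", "red")) {
  new("ERGRecording", time = as.numeric(time_s), voltage = as.numeric(voltage_uV),
      stimulusOnsetS = stimulus_onset_s, intensityLog = as.integer(intensity_log),
      wavelengthBand = match.arg(wavelength_band))
}

#' Construct an OPLProfile
#' @param arclength Positions along the OPL (strictly increasing).
#' @param channels Named list of intensity series.
#' @param reference_channel Name of the nuclear reference channel.
#' @param normalized Whether the profile is already normalized.
#' @return An [OPLProfile-class] object.
#' @export
OPLProfile <- function(arclength, channels, reference_channel = "dapi",
                       normalized = FALSE) {
  new("OPLProfile", arclength = as.numeric(arclength),
      channels = lapply(channels, as.numeric),
      referenceChannel = reference_channel, normalized = normalized)
}

#' Construct a SwimTrajectory
#' @param fish_id Fish label.
#' @param time_s Time stamps (seconds).
#' @param x_mm,y_mm Arena coordinates (mm).
#' @return A [SwimTrajectory-class] object.
#' @export
SwimTrajectory <- function(fish_id, time_s, x_mm, y_mm) {
  new("SwimTrajectory", fishId = as.character(fish_id), time = as.numeric(time_s),
      x = as.numeric(x_mm), y = as.numeric(y_mm))
}

#' Construct a ResponseTable
#' @param fish_ids Fish labels.
#' @param intensities Epoch intensities (percent).
#' @param responded Binary fish x epoch matrix.
#' @return A [ResponseTable-class] object.
#' @export
ResponseTable <- function(fish_ids, intensities, responded) {
  new("ResponseTable", fishIds = as.character(fish_ids),
      intensities = as.numeric(intensities),
      responded = matrix(as.numeric(responded), nrow = length(fish_ids)))
}
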