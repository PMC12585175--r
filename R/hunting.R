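# Eye-convergence event detection. The detector compares each raw eye-angle
# track with a rolling average of itself and thresholds the residual at a
# multiple of the trace's own average noise, so it adapts to noisy recordings.

#' Centered rolling mean with partial edge windows
#'
#' @param values Numeric series.
#' @param window_points Window length in samples (1 <= window <= length).
#' @return Numeric series of the same length; windows shrink near the edges.
#' @examples
#' rollingMean(c(0, 0, 3, 0, 0), 3)
#' @export
rollingMean <- function(values, window_points) {
  if (length(values) == 0L) stop("empty series", call. = FALSE)
  rollingMeanCore(values, window_points)
}

#' Average noise of a trace around its rolling average
#'
#' The detector threshold derives from the trace's own noise, estimated as
#' the mean absolute residual between the raw series and its rolling average
#' (or the median absolute residual for outlier robustness).
#'
#' @param values Raw series.
#' @param smoothed Rolling average of the same series (equal length).
#' @param method `"mean_abs"` (default) or `"mad"`.
#' @return Non-negative noise estimate; 0 iff `values == smoothed`.
#' @export
estimateNoise <- function(values, smoothed, method = c("mean_abs", "mad")) {
  if (length(values) != length(smoothed))
    stop("'values' and 'smoothed' must have equal length", call. = FALSE)
  r <- abs(values - smoothed)
  switch(match.arg(method), mean_abs = mean(r), mad = stats::median(r))
}

# Peak scan of one convergence-signed series: residual local maxima above
# threshold_multiplier * noise, merged within the refractory window.
scanConvergencePeaks <- function(time_s, conv, params) {
  k <- max(1L, as.integer(round(params@windowS /
                                  stats::median(diff(time_s)))))
  if (k > length(conv)) stop("rolling window exceeds trace length", call. = FALSE)
  sm <- rollingMeanCore(conv, k)
  resid <- conv - sm
  noise <- estimateNoise(conv, sm, params@noiseMethod)
  if (noise == 0) return(list(events = data.frame(time_s = numeric(),
                                                  amplitude = numeric(),
                                                  amplitude_nu = numeric()),
                              noise = 0))
  idx <- localMaxima(resid)
  idx <- idx[resid[idx] > params@thresholdMultiplier * noise]
  if (length(idx)) {
    keep <- mergeRefractory(time_s[idx], resid[idx], params@refractoryS)
    idx <- idx[keep]
  }
  list(events = data.frame(time_s = time_s[idx], amplitude = resid[idx],
                           amplitude_nu = resid[idx] / noise),
       noise = noise)
}

#' Detect per-eye convergence peaks
#'
#' Each eye's convergence-signed deviation (raw minus rolling mean; the right
#' eye is sign-flipped so convergence is positive for both) is scanned for
#' local maxima exceeding `thresholdMultiplier` times the trace's average
#' noise; maxima closer than the refractory period are merged keeping the
#' larger.
#'
#' @param trace An [EyeTrace-class].
#' @param params A [DetectorParams-class].
#' @return List with `left` and `right` event data.frames (`time_s`,
#'   `amplitude` in degrees, `amplitude_nu` in noise units) and `noise`, the
#'   per-eye noise estimates (degrees).
#' @export
detectEyeEvents <- function(trace, params = detectorParams()) {
  stopifnot(is(trace, "EyeTrace"), is(params, "DetectorParams"))
  if (params@windowS >= diff(range(trace@time)))
    stop("rolling window must be shorter than the trace", call. = FALSE)
  l <- scanConvergencePeaks(trace@time, trace@leftAngle, params)
  r <- scanConvergencePeaks(trace@time, -trace@rightAngle, params)
  list(left = l$events, right = r$events,
       noise = c(left = l$noise, right = r$noise))
}

#' Classify per-eye peaks into hunting events
#'
#' Left/right peaks co-occurring within the coincidence window become one
#' binocular prey-locking event at their mean time; unpaired peaks whose
#' amplitude reaches `strongMultiplier` times the noise become single-eye
#' prey-tracking events; weaker unpaired peaks are discarded. Locking and
#' tracking events are pooled downstream.
#'
#' @param left_events,right_events Per-eye event data.frames from
#'   [detectEyeEvents()].
#' @param params A [DetectorParams-class].
#' @return data.frame with `time_s`, `kind` (`"locking"`/`"tracking"`), `eye`
#'   (`"both"`/`"left"`/`"right"`), `amplitude_nu`, time-sorted.
#' @export
classifyHuntingEvents <- function(left_events, right_events,
                                  params = detectorParams()) {
  stopifnot(is(params, "DetectorParams"))
  lt <- left_events$time_s; rt <- right_events$time_s
  usedR <- rep(FALSE, length(rt))
  out <- list()
  for (i in seq_along(lt)) {
    cand <- which(!usedR & abs(rt - lt[i]) <= params@coincidenceWindowS)
    if (length(cand)) {
      j <- cand[which.min(abs(rt[cand] - lt[i]))]
      usedR[j] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        time_s = (lt[i] + rt[j]) / 2, kind = "locking", eye = "both",
        amplitude_nu = max(left_events$amplitude_nu[i],
                           right_events$amplitude_nu[j]))
    } else if (left_events$amplitude_nu[i] >= params@strongMultiplier) {
      out[[length(out) + 1L]] <- data.frame(
        time_s = lt[i], kind = "tracking", eye = "left",
        amplitude_nu = left_events$amplitude_nu[i])
    }
  }
  for (j in which(!usedR)) {
    if (right_events$amplitude_nu[j] >= params@strongMultiplier)
      out[[length(out) + 1L]] <- data.frame(
        time_s = rt[j], kind = "tracking", eye = "right",
        amplitude_nu = right_events$amplitude_nu[j])
  }
  if (!length(out))
    return(data.frame(time_s = numeric(), kind = character(),
                      eye = character(), amplitude_nu = numeric()))
  res <- do.call(rbind, out)
  res[order(res$time_s), , drop = FALSE]
}

#' Detect hunting events on one trace
#'
#' Convenience wrapper running [detectEyeEvents()] then
#' [classifyHuntingEvents()].
#'
#' @param trace An [EyeTrace-class].
#' @param params A [DetectorParams-class].
#' @return Event data.frame as from [classifyHuntingEvents()].
#' @export
detectHuntingEvents <- function(trace, params = detectorParams()) {
  ev <- detectEyeEvents(trace, params)
  classifyHuntingEvents(ev$left, ev$right, params)
}

#' Detect stimulus-congruent tail-flick events
#'
#' Applies the same rolling-average / noise-threshold machinery to the total
#' tail curvature; a curvature peak counts only when its sign matches the
#' concurrent epoch's stimulus direction (positive curvature taken as
#' rightward bending, matched to left-to-right sweeps). Peaks outside any
#' epoch are dropped (direction match undefined). Tail events are kept out of
#' the default response summaries because tail tracking is unreliable in this
#' preparation.
#'
#' @param trace An [EyeTrace-class] with a tail channel.
#' @param schedule A [StimulusSchedule-class].
#' @param params A [DetectorParams-class].
#' @return data.frame with `time_s`, `kind = "tail"`, `direction`,
#'   `epoch_index`, `amplitude_nu`.
#' @export
detectTailEvents <- function(trace, schedule, params = detectorParams()) {
  stopifnot(is(trace, "EyeTrace"), is(schedule, "StimulusSchedule"))
  if (is.null(trace@tailCurvature))
    stop("trace has no tail-curvature channel", call. = FALSE)
  ep <- epochs(schedule)
  pos <- scanConvergencePeaks(trace@time, trace@tailCurvature, params)$events
  neg <- scanConvergencePeaks(trace@time, -trace@tailCurvature, params)$events
  all <- rbind(
    if (nrow(pos)) cbind(pos, direction = "left_to_right") else NULL,
    if (nrow(neg)) cbind(neg, direction = "right_to_left") else NULL)
  if (!is.null(all) && nrow(all) > 1L) {
    # one flick must not register in both directions: residual side-lobes of
    # a strong peak are suppressed by cross-sign refractory merging
    keep <- mergeRefractory(all$time_s, all$amplitude_nu, params@refractoryS)
    all <- all[keep, , drop = FALSE]
  }
  if (is.null(all) || !nrow(all))
    return(data.frame(time_s = numeric(), kind = character(),
                      direction = character(), epoch_index = integer(),
                      amplitude_nu = numeric()))
  epIdx <- rep(NA_integer_, nrow(all))
  ok <- rep(FALSE, nrow(all))
  for (i in seq_len(nrow(all))) {
    hit <- which(all$time_s[i] >= ep$onset_s &
                 all$time_s[i] <= ep$onset_s + ep$sweep_duration_s +
                   params@epochGraceS)
    if (length(hit)) {
      hit <- hit[1L]
      epIdx[i] <- ep$index[hit]
      ok[i] <- identical(all$direction[i], ep$direction[hit])
    }
  }
  res <- data.frame(time_s = all$time_s[ok],
                    kind = rep("tail", sum(ok)),
                    direction = all$direction[ok], epoch_index = epIdx[ok],
                    amplitude_nu = all$amplitude_nu[ok])
  res[order(res$time_s), , drop = FALSE]
}

#' Assign hunting events to schedule epochs
#'
#' An epoch is scored as responded (1) when at least one event falls inside
#' `[onset, onset + sweep_duration + grace_s]`; events outside every window
#' are kept but left unassigned.
#'
#' @param events Event data.frame with a `time_s` column (time-sorted).
#' @param schedule A [StimulusSchedule-class].
#' @param grace_s Post-sweep grace (seconds).
#' @return List with `responded` (binary vector, one per epoch) and `events`
#'   (the input with an `epoch_index` column, NA when unassigned).
#' @export
assignEventsToEpochs <- function(events, schedule, grace_s = 1) {
  stopifnot(is(schedule, "StimulusSchedule"))
  ep <- epochs(schedule)
  responded <- numeric(nrow(ep))
  epochIdx <- rep(NA_integer_, nrow(events))
  for (i in seq_len(nrow(events))) {
    hit <- which(events$time_s[i] >= ep$onset_s &
                 events$time_s[i] <= ep$onset_s + ep$sweep_duration_s + grace_s)
    if (length(hit)) {
      epochIdx[i] <- ep$index[hit[1L]]
      responded[hit[1L]] <- 1
    }
  }
  events$epoch_index <- epochIdx
  list(responded = responded, events = events)
}

#' Detect responses for a whole cohort
#'
#' Runs the detector on each trace and assembles the fish x epoch
#' [ResponseTable-class].
#'
#' @param traces List of [EyeTrace-class] objects.
#' @param schedule A [StimulusSchedule-class].
#' @param params A [DetectorParams-class].
#' @param fish_ids Optional fish labels.
#' @return List with `table` (a [ResponseTable-class]) and `events` (list of
#'   per-fish event data.frames).
#' @export
detectCohortResponses <- function(traces, schedule, params = detectorParams(),
                                  fish_ids = NULL) {
  stopifnot(is(schedule, "StimulusSchedule"), length(traces) >= 1L)
  if (is.null(fish_ids)) fish_ids <- sprintf("fish_%03d", seq_along(traces))
  ep <- epochs(schedule)
  mat <- matrix(0, nrow = length(traces), ncol = nrow(ep))
  evs <- vector("list", length(traces))
  for (f in seq_along(traces)) {
    events <- detectHuntingEvents(traces[[f]], params)
    asg <- assignEventsToEpochs(events, schedule, params@epochGraceS)
    mat[f, ] <- asg$responded
    evs[[f]] <- asg$events
  }
  names(evs) <- fish_ids
  list(table = ResponseTable(fish_ids, ep$intensity_percent, mat),
       events = evs)
}

#' Match detected events against generator ground truth
#'
#' Greedy one-to-one matching: each ground-truth event claims the nearest
#' unclaimed detection within `tol_s`. Used for detector validation on
#' synthetic cohorts.
#'
#' @param events Detected event data.frame (with `time_s`).
#' @param truth An [EventTruth-class].
#' @param tol_s Matching tolerance (seconds).
#' @return List with `n_truth`, `n_detected`, `n_matched`, `recall`,
#'   `timing_errors_s` (per matched event) and `n_unmatched_detections`.
#' @export
matchEventsToTruth <- function(events, truth, tol_s = 0.5) {
  tt <- truth@times
  dt <- events$time_s
  claimed <- rep(FALSE, length(dt))
  errs <- numeric()
  for (i in seq_along(tt)) {
    if (!length(dt)) break
    d <- abs(dt - tt[i])
    d[claimed] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol_s) {
      claimed[j] <- TRUE
      errs <- c(errs, dt[j] - tt[i])
    }
  }
  list(n_truth = length(tt), n_detected = length(dt), n_matched = sum(claimed),
       recall = if (length(tt)) sum(claimed) / length(tt) else NA_real_,
       timing_errors_s = errs, n_unmatched_detections = sum(!claimed))
}

#' Summarize a response table
#'
#' @param table A [ResponseTable-class].
#' @return List with `pooled` (successes, trials, proportion over all fish x
#'   epochs), `per_intensity` (data.frame of responses, trials and response
#'   percentage per intensity level) and `per_fish` (reaction counts).
#' @export
summarizeResponses <- function(table) {
  stopifnot(is(table, "ResponseTable"))
  m <- responseMatrix(table)
  if (!length(m)) stop("empty response table", call. = FALSE)
  ints <- epochIntensities(table)
  lev <- sort(unique(ints))
  per <- data.frame(
    intensity_percent = lev,
    n_epochs = vapply(lev, function(v) sum(ints == v), 0),
    responses = vapply(lev, function(v) sum(m[, ints == v, drop = FALSE]), 0),
    trials = vapply(lev, function(v) nrow(m) * sum(ints == v), 0))
  per$response_pct <- 100 * per$responses / per$trials
  list(pooled = list(successes = sum(m), trials = length(m),
                     proportion = mean(m)),
       per_intensity = per,
       per_fish = rowSums(m))
}
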