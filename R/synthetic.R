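# Seeded generators for each recording modality. Every generator is
# deterministic given (arguments, seed) and returns objects carrying known
# ground truth, so the downstream analyses have a parameter-recovery surface.

#' Generate a synthetic eye-angle trace with injected convergence events
#'
#' Baseline-zero left/right eye-angle traces with additive Gaussian frame
#' noise. At each ground-truth event a smooth raised-cosine convergence
#' deflection of the requested amplitude is injected with the tracking sign
#' convention (left-eye convergence positive on the left trace, right-eye
#' convergence negative on the right trace). Locking events deflect both
#' eyes; tracking events a single eye.
#'
#' @param schedule A [StimulusSchedule-class] (used to size the trace).
#' @param truth An [EventTruth-class] with the events to inject.
#' @param event_amplitude_deg Peak convergence deflection (degrees).
#' @param event_duration_s Total width of the raised-cosine bump (seconds).
#' @param noise_sd_deg Frame-noise standard deviation (degrees).
#' @param rate_hz Sampling rate (Hz).
#' @param seed Integer seed.
#' @param duration_s Trace duration; defaults to schedule end + 2 s.
#' @param tail Include a flat tail-curvature channel (with the same noise).
#' @return An [EyeTrace-class].
#' @export
genEyeTrace <- function(schedule, truth = EventTruth(),
                        event_amplitude_deg = 15, event_duration_s = 0.3,
                        noise_sd_deg = 1.5, rate_hz = 100, seed = 1L,
                        duration_s = NULL, tail = FALSE) {
  stopifnot(is(schedule, "StimulusSchedule"), is(truth, "EventTruth"))
  stopIfNot(rate_hz > 0, "'rate_hz' must be > 0")
  stopIfNot(noise_sd_deg >= 0, "'noise_sd_deg' must be >= 0")
  ep <- epochs(schedule)
  if (is.null(duration_s)) {
    endS <- if (nrow(ep)) max(ep$onset_s + ep$sweep_duration_s)
            else if (length(truth@times)) max(truth@times) + event_duration_s
            else 8
    duration_s <- endS + 2
  }
  if (length(truth@times) &&
      any(truth@times - event_duration_s / 2 < 0 |
          truth@times + event_duration_s / 2 > duration_s))
    stop("event window falls outside the trace duration", call. = FALSE)
  n <- as.integer(round(duration_s * rate_hz)) + 1L
  t <- (seq_len(n) - 1L) / rate_hz
  withSeed(seed, {
    left <- stats::rnorm(n, 0, noise_sd_deg)
    right <- stats::rnorm(n, 0, noise_sd_deg)
    tailc <- if (tail) stats::rnorm(n, 0, noise_sd_deg) else NULL
  })
  for (i in seq_along(truth@times)) {
    ctr <- truth@times[i]
    i0 <- max(1L, as.integer(ceiling((ctr - event_duration_s / 2) * rate_hz)) + 1L)
    i1 <- min(n, as.integer(floor((ctr + event_duration_s / 2) * rate_hz)) + 1L)
    sel <- i0:i1
    bump <- event_amplitude_deg * raisedCosine(t[sel], ctr, event_duration_s)
    kind <- truth@kinds[i]
    if (kind %in% c("locking", "tracking_left")) left[sel] <- left[sel] + bump
    if (kind %in% c("locking", "tracking_right")) right[sel] <- right[sel] - bump
  }
  EyeTrace(t, left, right, tail_curvature_deg = tailc, rate_hz = rate_hz)
}

#' Generate a cohort of synthetic hunting-assay traces
#'
#' For every fish and epoch, a binocular locking event is injected with the
#' probability the [ResponseCurve-class] assigns to the epoch's intensity; the
#' event amplitude is `detector_snr` times the frame-noise standard deviation.
#'
#' @param schedule A [StimulusSchedule-class].
#' @param curve A [ResponseCurve-class].
#' @param n_fish Number of fish (>= 1).
#' @param detector_snr Event amplitude in units of the frame-noise SD.
#' @param noise_sd_deg Frame-noise SD (degrees).
#' @param event_duration_s Event bump width (seconds).
#' @param rate_hz Sampling rate (Hz).
#' @param seed Integer seed.
#' @return List with `traces` (list of [EyeTrace-class]) and `truths` (list of
#'   [EventTruth-class]).
#' @export
genHuntingCohort <- function(schedule, curve, n_fish, detector_snr = 10,
                             noise_sd_deg = 1.5, event_duration_s = 0.3,
                             rate_hz = 100, seed = 1L) {
  stopifnot(is(schedule, "StimulusSchedule"), is(curve, "ResponseCurve"))
  stopIfNot(length(n_fish) == 1L && is.finite(n_fish) && n_fish >= 1,
            "'n_fish' must be >= 1")
  ep <- epochs(schedule)
  stopIfNot(nrow(ep) > 0, "schedule must contain epochs")
  p <- responseProbability(curve, ep$intensity_percent)
  amp <- detector_snr * noise_sd_deg
  margin <- max(event_duration_s / 2, 0.3)
  traces <- vector("list", n_fish)
  truths <- vector("list", n_fish)
  for (f in seq_len(n_fish)) {
    fseed <- subSeed(seed, paste0("cohort_fish_", f))
    drawn <- withSeed(fseed, {
      hit <- stats::runif(nrow(ep)) < p
      offs <- stats::runif(nrow(ep), margin, ep$sweep_duration_s - margin)
      list(hit = hit, offs = offs)
    })
    times <- (ep$onset_s + drawn$offs)[drawn$hit]
    truth <- EventTruth(times, rep("locking", length(times)),
                        ep$index[drawn$hit])
    traces[[f]] <- genEyeTrace(schedule, truth,
                               event_amplitude_deg = amp,
                               event_duration_s = event_duration_s,
                               noise_sd_deg = noise_sd_deg, rate_hz = rate_hz,
                               seed = subSeed(fseed, "trace"))
    truths[[f]] <- truth
  }
  list(traces = traces, truths = truths)
}

# Analytic peak time of the difference-of-exponentials b-wave, relative to
# stimulus onset.
bWavePeakTime <- function(tau_rise_s, tau_decay_s) {
  tau_rise_s * tau_decay_s / (tau_decay_s - tau_rise_s) *
    log(tau_decay_s / tau_rise_s)
}

#' Generate a synthetic ERG trace
#'
#' Voltage is a zero baseline plus a brief negative a-lobe (raised cosine just
#' after stimulus onset) plus a positive difference-of-exponentials b-wave
#' scaled so its analytic peak equals `b_amplitude_uV`, plus Gaussian noise.
#' The closed-form b-wave peak time is
#' `tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)`
#' after onset.
#'
#' @param b_amplitude_uV Analytic b-wave peak amplitude (microvolts).
#' @param a_amplitude_uV Magnitude of the negative a-lobe (microvolts).
#' @param tau_rise_s,tau_decay_s b-wave time constants (seconds,
#'   `tau_decay > tau_rise > 0`).
#' @param stimulus_onset_s Flash onset (seconds, >= 0.05 so a 50 ms baseline
#'   window exists).
#' @param noise_sd_uV Noise SD (microvolts).
#' @param rate_hz Sampling rate (Hz).
#' @param duration_s Trace duration (seconds).
#' @param seed Integer seed.
#' @param intensity_log,wavelength_band Metadata carried on the recording.
#' @return An [ERGRecording-class].
#' @export
genERGTrace <- function(b_amplitude_uV = 100, a_amplitude_uV = 20,
                        tau_rise_s = 0.05, tau_decay_s = 0.3,
                        stimulus_onset_s = 0.2, noise_sd_uV = 0,
                        rate_hz = 10000, duration_s = 2, seed = 1L,
                        intensity_log = 0L, wavelength_band = "uv_blue") {
  stopIfNot(tau_decay_s > tau_rise_s && tau_rise_s > 0,
            "need tau_decay_s > tau_rise_s > 0")
  if (stimulus_onset_s < 0.05)
    stop("stimulus_onset_s must be >= 0.05 s (baseline window undefined)",
         call. = FALSE)
  n <- as.integer(round(duration_s * rate_hz)) + 1L
  t <- (seq_len(n) - 1L) / rate_hz
  s <- pmax(t - stimulus_onset_s, 0)
  g <- exp(-s / tau_decay_s) - exp(-s / tau_rise_s)
  tpk <- bWavePeakTime(tau_rise_s, tau_decay_s)
  gmax <- exp(-tpk / tau_decay_s) - exp(-tpk / tau_rise_s)
  v <- if (b_amplitude_uV == 0) numeric(n) else b_amplitude_uV * g / gmax
  if (a_amplitude_uV != 0)
    v <- v - a_amplitude_uV * raisedCosine(t, stimulus_onset_s + 0.015, 0.03)
  if (noise_sd_uV > 0)
    v <- v + withSeed(seed, stats::rnorm(n, 0, noise_sd_uV))
  ERGRecording(t, v, stimulus_onset_s, intensity_log = intensity_log,
               wavelength_band = wavelength_band)
}

#' Generate a set of synthetic OPL intensity profiles
#'
#' Each retina gets one line-scan per channel: baseline plus a Gaussian bump
#' at the channel's peak position (jittered per retina) plus noise, over a
#' per-retina arclength whose point count varies around `n_points`. The
#' nuclear reference channel is flat at `dapi_level` plus noise. Arclength
#' starts at the ventral strike-zone end (position 0). Defaults emulate the
#' observed anisotropy: EAAT5b and UV cone pedicles peak in the strike zone
#' near the ventral origin, EAAT7 in the nasal patch.
#'
#' @param channel_specs Named list; each element a list/vector with
#'   `peak_position` (fraction of arclength in [0, 1]), `peak_width`
#'   (fraction), `baseline` (a.u.) and `peak_height` (a.u.).
#' @param dapi_level Reference-channel level (a.u.).
#' @param n_points Average points per trace (>= 100; ~3000 matches the
#'   original trace density).
#' @param n_retinas Number of retinas.
#' @param noise_sd Additive noise SD (a.u.).
#' @param position_jitter_sd Per-retina SD of the peak-position jitter
#'   (fraction of arclength).
#' @param seed Integer seed.
#' @return List of raw [OPLProfile-class] objects (reference channel
#'   `"dapi"`).
#' @export
genOPLProfiles <- function(channel_specs = list(
                             uv_cones = c(peak_position = 0.15, peak_width = 0.12,
                                          baseline = 0.25, peak_height = 1),
                             eaat5b = c(peak_position = 0.15, peak_width = 0.15,
                                        baseline = 0.35, peak_height = 1),
                             eaat7 = c(peak_position = 0.80, peak_width = 0.18,
                                       baseline = 0.35, peak_height = 1)),
                           dapi_level = 1, n_points = 3000, n_retinas = 11,
                           noise_sd = 0.05, position_jitter_sd = 0.03,
                           seed = 1L) {
  stopIfNot(n_points >= 100, "'n_points' must be >= 100")
  specs <- lapply(channel_specs, function(sp) as.list(sp))
  pos <- vapply(specs, function(sp) as.numeric(sp$peak_position), 0)
  if (any(pos < 0 | pos > 1))
    stop("peak positions must lie in [0, 1]", call. = FALSE)
  out <- vector("list", n_retinas)
  for (r in seq_len(n_retinas)) {
    out[[r]] <- withSeed(subSeed(seed, paste0("opl_retina_", r)), {
      nr <- as.integer(round(n_points * stats::runif(1, 0.9, 1.1)))
      lenUm <- stats::runif(1, 550, 650)   # arclength in raw (micron-like) units
      arc <- seq(0, lenUm, length.out = nr)
      frac <- arc / lenUm
      # one anatomical jitter per retina, shared by all channels
      jit <- stats::rnorm(1, 0, position_jitter_sd)
      ch <- lapply(specs, function(sp) {
        center <- min(max(as.numeric(sp$peak_position) + jit, 0), 1)
        as.numeric(sp$baseline) +
          as.numeric(sp$peak_height) *
            exp(-(frac - center)^2 / (2 * as.numeric(sp$peak_width)^2)) +
          stats::rnorm(nr, 0, noise_sd)
      })
      ch$dapi <- dapi_level + stats::rnorm(nr, 0, noise_sd)
      OPLProfile(arc, ch, reference_channel = "dapi")
    })
  }
  out
}

#' Generate bout-structured OMR swim trajectories
#'
#' Fish move in discrete swim bouts: bout onsets follow a Poisson process,
#' each bout displaces the fish along +x with probability `rightward_bias`
#' (else -x) at `bout_speed_mm_s` for `bout_duration_s`; between bouts the
#' fish is stationary up to tracking noise. Each fish is confined to its
#' arena row (positions clipped to the row length); y holds small jitter
#' around the row center.
#'
#' @param rightward_bias Probability that a bout is directed rightward
#'   (applies inside `bias_windows` when given, with 0.5 elsewhere).
#' @param bout_rate_hz Mean bout initiation rate (Hz).
#' @param bout_speed_mm_s Within-bout speed (mm/s; ~29 mm/s matches observed
#'   bout kinematics).
#' @param duration_s Recording duration (seconds).
#' @param rate_hz Camera frame rate (Hz).
#' @param n_fish Number of fish.
#' @param arena_rows Number of arena rows (fish are assigned cyclically).
#' @param seed Integer seed.
#' @param bout_duration_s Bout duration (seconds).
#' @param tracking_noise_mm Centroid tracking noise SD (mm); 0 disables it.
#' @param row_length_mm,row_height_mm Row geometry (mm).
#' @param bias_windows Optional data.frame with `t0`, `t1` columns; bouts
#'   starting inside any window use `rightward_bias`, others 0.5.
#' @return List of [SwimTrajectory-class] objects.
#' @export
genOMRTrajectories <- function(rightward_bias = 0.5, bout_rate_hz = 1,
                               bout_speed_mm_s = 29, duration_s = 60,
                               rate_hz = 30, n_fish = 10, arena_rows = 10,
                               seed = 1L, bout_duration_s = 0.15,
                               tracking_noise_mm = 0.02, row_length_mm = 160,
                               row_height_mm = 10, bias_windows = NULL) {
  if (rightward_bias < 0 || rightward_bias > 1)
    stop("'rightward_bias' must lie in [0, 1]", call. = FALSE)
  stopIfNot(bout_speed_mm_s > 0, "'bout_speed_mm_s' must be > 0")
  n <- as.integer(round(duration_s * rate_hz)) + 1L
  t <- (seq_len(n) - 1L) / rate_hz
  out <- vector("list", n_fish)
  for (f in seq_len(n_fish)) {
    row <- (f - 1L) %% arena_rows + 1L
    yc <- (row - 0.5) * row_height_mm
    out[[f]] <- withSeed(subSeed(seed, paste0("omr_fish_", f)), {
      starts <- numeric()
      tb <- stats::rexp(1, bout_rate_hz)
      while (tb < duration_s - bout_duration_s) {
        starts <- c(starts, tb)
        tb <- tb + bout_duration_s + stats::rexp(1, bout_rate_hz)
      }
      x <- rep(row_length_mm / 2, n)
      for (s in starts) {
        bias <- if (is.null(bias_windows)) rightward_bias
                else if (any(s >= bias_windows$t0 & s < bias_windows$t1))
                  rightward_bias else 0.5
        dir <- if (stats::runif(1) < bias) 1 else -1
        idx <- which(t >= s & t < s + bout_duration_s)
        if (!length(idx)) next
        i0 <- idx[1L]
        anchor <- if (i0 > 1L) t[i0 - 1L] else t[i0]
        seg <- pmin(pmax(x[i0] + dir * bout_speed_mm_s * (t[idx] - anchor), 0),
                    row_length_mm)
        x[idx] <- seg
        if (idx[length(idx)] < n)
          x[(idx[length(idx)] + 1L):n] <- seg[length(seg)]
      }
      xn <- x
      yn <- rep(yc, n)
      if (tracking_noise_mm > 0) {
        xn <- x + stats::rnorm(n, 0, tracking_noise_mm)
        yn <- yc + stats::rnorm(n, 0, tracking_noise_mm)
      }
      SwimTrajectory(sprintf("fish_%02d", f), t, xn, yn)
    })
  }
  out
}
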