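# Shared fixtures built in code: small traces, schedules and cohorts used
# across test files.

# Flat (noise-free) eye trace with optional tail channel.
flatTrace <- function(duration_s = 10, rate_hz = 100, tail = FALSE) {
  t <- seq(0, duration_s, by = 1 / rate_hz)
  EyeTrace(t, rep(0, length(t)), rep(0, length(t)),
           tail_curvature_deg = if (tail) rep(0, length(t)) else NULL,
           rate_hz = rate_hz)
}

# Trace with hand-placed raised-cosine convergence bumps on top of seeded
# noise; returns the trace and the bump times.
bumpTrace <- function(bump_times, amplitude = 10, noise_sd = 1,
                      duration_s = 30, rate_hz = 100, seed = 42,
                      eyes = "both") {
  sched <- new("StimulusSchedule",
               epochs = data.frame(index = integer(), direction = character(),
                                   intensity_percent = numeric(),
                                   onset_s = numeric(),
                                   sweep_duration_s = numeric()))
  kinds <- switch(eyes, both = "locking", left = "tracking_left",
                  right = "tracking_right")
  truth <- EventTruth(bump_times, rep(kinds, length(bump_times)),
                      rep(NA_integer_, length(bump_times)))
  genEyeTrace(sched, truth, event_amplitude_deg = amplitude,
              noise_sd_deg = noise_sd, rate_hz = rate_hz, seed = seed,
              duration_s = duration_s)
}

# Brute-force O(n*m) two-sample KS statistic: scan every observed point.
bruteForceKS <- function(xs, ys) {
  pts <- c(xs, ys)
  d <- 0
  for (q in pts) {
    fx <- sum(xs <= q) / length(xs)
    fy <- sum(ys <= q) / length(ys)
    d <- max(d, abs(fx - fy))
  }
  d
}

# Per-epoch false/true split of detected events against generator truth.
epochFalseEvents <- function(events_with_epochs, truth) {
  det <- events_with_epochs$epoch_index[!is.na(events_with_epochs$epoch_index)]
  truthEpochs <- truth@epochs
  sum(!det %in% truthEpochs)
}
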