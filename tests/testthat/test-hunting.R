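test_that("rolling mean is centered with partial edge windows", {
  expect_equal(rollingMean(rep(7, 10), 5), rep(7, 10))
  x <- c(2, 5, 1, 8, 3)
  expect_equal(rollingMean(x, 1), x)
  expect_equal(rollingMean(c(0, 0, 3, 0, 0), 3)[3], 1)
  # full-window limit: center equals the global mean
  expect_equal(rollingMean(x, 5)[3], mean(x))
  expect_error(rollingMean(numeric(), 1), "empty")
  expect_error(rollingMean(x, 6), "window")
})

test_that("rolling mean matches an independent partial-window oracle", {
  skip_if_not_installed("zoo")
  set.seed(11)
  x <- rnorm(200)
  for (k in c(3, 7, 25)) {
    oracle <- zoo::rollapply(x, k, mean, partial = TRUE, align = "center")
    expect_equal(rollingMean(x, k), as.numeric(oracle), tolerance = 1e-12)
  }
})

test_that("noise estimate is the average absolute residual", {
  x <- rnorm(50)
  expect_equal(estimateNoise(x, x), 0)
  resid <- rep(c(1, -1), 50)
  expect_equal(estimateNoise(resid, rep(0, 100)), 1)
  set.seed(5)
  g <- rnorm(1e5, sd = 2.5)
  expect_equal(estimateNoise(g, rep(0, 1e5)), 2.5 * sqrt(2 / pi),
               tolerance = 0.02)
  expect_equal(estimateNoise(g, rep(0, 1e5), method = "mad"),
               median(abs(g)))
  expect_error(estimateNoise(1:3, 1:4), "length")
})

test_that("eye-event detection finds injected bumps and nothing on silence", {
  expect_identical(nrow(detectEyeEvents(flatTrace())$left), 0L)
  expect_identical(nrow(detectEyeEvents(flatTrace())$right), 0L)

  # per-eye peaks at low noise: exactly one per eye, at the injection time
  lo <- bumpTrace(12, amplitude = 10, noise_sd = 0.3, seed = 2)
  evLo <- detectEyeEvents(lo)
  expect_equal(nrow(evLo$left), 1L)
  expect_equal(nrow(evLo$right), 1L)
  expect_lt(abs(evLo$left$time_s - 12), 0.5)

  # at realistic noise, stray single-eye peaks are discarded downstream:
  # classification still yields exactly one locking event
  tr <- bumpTrace(12, amplitude = 10, noise_sd = 1, seed = 2)
  hunt <- detectHuntingEvents(tr)
  expect_equal(nrow(hunt), 1L)
  expect_equal(hunt$kind, "locking")
  expect_lt(abs(hunt$time_s - 12), 0.5)

  # unreachable threshold: zero events
  hard <- detectorParams(threshold_multiplier = 1e6, strong_multiplier = 1e6)
  evh <- detectEyeEvents(tr, hard)
  expect_identical(nrow(evh$left), 0L)
  expect_identical(nrow(evh$right), 0L)

  expect_error(detectEyeEvents(tr, detectorParams(window_s = 1e4)), "window")
})

test_that("raising the threshold never increases the event count", {
  tr <- bumpTrace(c(5, 12, 20), amplitude = 8, noise_sd = 1.5, seed = 9)
  counts <- vapply(c(2, 3, 4, 6, 8), function(m) {
    ev <- detectEyeEvents(tr, detectorParams(threshold_multiplier = m,
                                             strong_multiplier = max(m, 6)))
    nrow(ev$left) + nrow(ev$right)
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("injecting only right-eye convergence yields no left events", {
  tr <- bumpTrace(c(6, 15), amplitude = 12, noise_sd = 0, seed = 1,
                  eyes = "right")
  ev <- detectEyeEvents(tr)
  expect_identical(nrow(ev$left), 0L)
  expect_equal(nrow(ev$right), 2L)
})

test_that("event classification separates locking, tracking and sub-strong peaks", {
  params <- detectorParams()
  mk <- function(t, nu) data.frame(time_s = t, amplitude = nu,
                                   amplitude_nu = nu)
  none <- mk(numeric(), numeric())

  lock <- classifyHuntingEvents(mk(10, 5), mk(10.1, 5), params)
  expect_equal(nrow(lock), 1L)
  expect_equal(lock$kind, "locking")
  expect_equal(lock$eye, "both")
  expect_equal(lock$time_s, 10.05)

  trackL <- classifyHuntingEvents(mk(10, 6), none, params)
  expect_equal(trackL$kind, "tracking")
  expect_equal(trackL$eye, "left")

  weak <- classifyHuntingEvents(mk(10, 5), none, params)
  expect_equal(nrow(weak), 0L)

  trackR <- classifyHuntingEvents(none, mk(3, 7), params)
  expect_equal(trackR$eye, "right")
})

test_that("tail events require a direction-congruent peak inside an epoch", {
  sched <- buildMaxIntensitySchedule(4, 2)   # epoch 0 L->R at 2 s, epoch 1 R->L at 9 s
  t <- seq(0, 20, by = 0.01)
  flat <- rep(0, length(t))
  mkTail <- function(tail) EyeTrace(t, flat, flat, tail_curvature_deg = tail,
                                    rate_hz = 100)
  noisyTail <- function(bumpAt = NULL, sign = 1) {
    set.seed(33)
    tail <- rnorm(length(t), 0, 1)
    if (!is.null(bumpAt))
      tail <- tail + sign * 10 * zfvision:::raisedCosine(t, bumpAt, 0.3)
    mkTail(tail)
  }
  expect_equal(nrow(detectTailEvents(mkTail(flat), sched)), 0L)
  # rightward (positive) peak during the left-to-right epoch counts
  hit <- detectTailEvents(noisyTail(3, +1), sched)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$epoch_index, 0L)
  # the same peak outside any epoch does not
  expect_equal(nrow(detectTailEvents(noisyTail(16, +1), sched)), 0L)
  # direction-incongruent peak during epoch 0 does not count
  expect_equal(nrow(detectTailEvents(noisyTail(3, -1), sched)), 0L)
  expect_error(detectTailEvents(flatTrace(), sched), "tail")
})

test_that("epoch assignment marks binary responses inside grace windows", {
  sched <- buildIncrementalSchedule()
  none <- assignEventsToEpochs(data.frame(time_s = numeric()), sched, 1)
  expect_equal(none$responded, rep(0, 20))

  ep <- epochs(sched)
  mid3 <- ep$onset_s[4] + 1.5   # mid-sweep of epoch index 3
  one <- assignEventsToEpochs(data.frame(time_s = mid3), sched, 1)
  expect_equal(which(one$responded == 1), 4L)
  expect_equal(one$events$epoch_index, 3L)

  two <- assignEventsToEpochs(data.frame(time_s = c(mid3, mid3 + 0.8)),
                              sched, 1)
  expect_equal(sum(two$responded), 1)

  # event outside all windows stays unassigned but is kept
  out <- assignEventsToEpochs(data.frame(time_s = ep$onset_s[2] - 1), sched, 1)
  expect_true(is.na(out$events$epoch_index))
  expect_equal(sum(out$responded), 0)
})

test_that("response summaries pool correctly at the degenerate extremes", {
  sched <- buildIncrementalSchedule()
  ints <- epochs(sched)$intensity_percent
  zero <- ResponseTable(sprintf("f%d", 1:10), ints, matrix(0, 10, 20))
  s0 <- summarizeResponses(zero)
  expect_equal(s0$pooled$proportion, 0)
  ones <- ResponseTable(sprintf("f%d", 1:10), ints, matrix(1, 10, 20))
  s1 <- summarizeResponses(ones)
  expect_equal(s1$pooled$proportion, 1)
  expect_true(all(s1$per_intensity$response_pct == 100))
  expect_equal(unname(s1$per_fish), rep(20, 10))
})

test_that("detector recovers a small synthetic cohort with correct timing", {
  sched <- buildIncrementalSchedule()
  curve <- ResponseCurve(0.2, 0.9, 50, 0.15)
  sim <- genHuntingCohort(sched, curve, n_fish = 5, detector_snr = 10,
                          seed = 21)
  params <- detectorParams()
  for (f in 1:5) {
    ev <- detectHuntingEvents(sim$traces[[f]], params)
    m <- matchEventsToTruth(ev, sim$truths[[f]], tol_s = params@windowS)
    expect_equal(m$n_matched, m$n_truth)
    expect_equal(m$n_unmatched_detections, 0L)
    if (length(m$timing_errors_s))
      expect_true(all(abs(m$timing_errors_s) <= params@windowS))
  }
})
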