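test_that("eye-trace generator injects events with the tracking sign convention", {
  sched <- buildMaxIntensitySchedule(4, 2)

  quiet <- genEyeTrace(sched, EventTruth(), noise_sd_deg = 0, seed = 1)
  expect_true(all(eyeAngle(quiet, "left") == 0))
  expect_true(all(eyeAngle(quiet, "right") == 0))

  truth <- EventTruth(3.5, "locking", 0L)
  tr <- genEyeTrace(sched, truth, event_amplitude_deg = 10, noise_sd_deg = 0,
                    seed = 1)
  t <- traceTime(tr)
  expect_equal(max(eyeAngle(tr, "left")), 10)
  expect_equal(min(eyeAngle(tr, "right")), -10)
  expect_equal(t[which.max(eyeAngle(tr, "left"))], 3.5)

  # tracking events deflect a single eye
  lt <- genEyeTrace(sched, EventTruth(3.5, "tracking_left", 0L),
                    event_amplitude_deg = 10, noise_sd_deg = 0, seed = 1)
  expect_equal(max(eyeAngle(lt, "left")), 10)
  expect_true(all(eyeAngle(lt, "right") == 0))

  a <- genEyeTrace(sched, truth, seed = 7)
  b <- genEyeTrace(sched, truth, seed = 7)
  expect_identical(eyeAngle(a, "left"), eyeAngle(b, "left"))
  expect_identical(eyeAngle(a, "right"), eyeAngle(b, "right"))

  expect_error(genEyeTrace(sched, EventTruth(500, "locking", NA_integer_),
                           seed = 1), "outside")
})

test_that("different seeds decorrelate generator noise", {
  sched <- buildMaxIntensitySchedule(4, 20)  # ~142 s at 100 Hz > 1e4 points
  a <- genEyeTrace(sched, EventTruth(), seed = 1)
  b <- genEyeTrace(sched, EventTruth(), seed = 2)
  expect_gt(length(traceTime(a)), 1e4)
  expect_lt(abs(cor(eyeAngle(a, "left"), eyeAngle(b, "left"))), 0.1)
})

test_that("cohort generator respects degenerate response curves", {
  sched <- buildIncrementalSchedule()
  none <- genHuntingCohort(sched, ResponseCurve(0, 0, 55, 0.15), n_fish = 3,
                           seed = 1)
  expect_true(all(vapply(none$truths, function(tt) length(tt@times), 1L) == 0L))
  all20 <- genHuntingCohort(sched, ResponseCurve(1, 1, 55, 0.15), n_fish = 5,
                            seed = 1)
  expect_true(all(vapply(all20$truths, function(tt) length(tt@times), 1L) == 20L))
  expect_error(genHuntingCohort(sched, ResponseCurve(), n_fish = 0, seed = 1),
               "n_fish")
})

test_that("injected event frequencies follow the generating curve", {
  sched <- buildIncrementalSchedule()
  curve <- ResponseCurve(0, 0.8, 55, 0.2)
  sim <- genHuntingCohort(sched, curve, n_fish = 200, seed = 3)
  ep <- epochs(sched)
  counts <- table(factor(unlist(lapply(sim$truths, function(tt) tt@epochs)),
                         levels = ep$index))
  byInt <- tapply(as.numeric(counts), ep$intensity_percent, sum)
  lv <- as.numeric(names(byInt))
  p <- responseProbability(curve, lv)
  n <- 200 * 2
  # every intensity within 3 binomial SD of the exact generating probability
  dev <- abs(byInt / n - p)
  tol <- 3 * sqrt(p * (1 - p) / n) + 1e-12
  expect_true(all(dev <= tol))
})

test_that("injected event counts are binomial per intensity (chi-square GOF)", {
  sched <- buildIncrementalSchedule()
  curve <- ResponseCurve(0.05, 0.8, 55, 0.15)
  ep <- epochs(sched)
  nFish <- 1000
  sim <- genHuntingCohort(sched, curve, n_fish = nFish, rate_hz = 20,
                          seed = 99)
  counts <- table(factor(unlist(lapply(sim$truths, function(tt) tt@epochs)),
                         levels = ep$index))
  byInt <- tapply(as.numeric(counts), ep$intensity_percent, sum)
  pv <- responseProbability(curve, as.numeric(names(byInt)))
  n <- nFish * 2
  x2 <- sum((byInt - n * pv)^2 / (n * pv * (1 - pv)))
  expect_gt(pchisq(x2, df = length(byInt), lower.tail = FALSE), 0.01)
})

test_that("ERG generator hits its analytic peak and closed-form peak time", {
  rec <- genERGTrace(b_amplitude_uV = 100, a_amplitude_uV = 0, noise_sd_uV = 0)
  expect_lt(abs(max(rec@voltage) - 100) / 100, 1e-6)

  flat <- genERGTrace(b_amplitude_uV = 0, a_amplitude_uV = 0, noise_sd_uV = 0)
  expect_true(all(flat@voltage == 0))

  # closed-form maximum of the difference of exponentials
  taus <- list(c(0.05, 0.3), c(0.02, 0.1), c(0.1, 0.5))
  for (tt in taus) {
    rec <- genERGTrace(100, 0, tt[1], tt[2], noise_sd_uV = 0)
    tpk <- rec@time[which.max(rec@voltage)] - rec@stimulusOnsetS
    analytic <- tt[1] * tt[2] / (tt[2] - tt[1]) * log(tt[2] / tt[1])
    expect_lt(abs(tpk - analytic), 1 / 10000 + 1e-12)
  }

  a <- genERGTrace(noise_sd_uV = 5, seed = 4)
  b <- genERGTrace(noise_sd_uV = 5, seed = 4)
  expect_identical(a@voltage, b@voltage)

  expect_error(genERGTrace(stimulus_onset_s = 0.01), "baseline")
  expect_error(genERGTrace(tau_rise_s = 0.3, tau_decay_s = 0.1), "tau")
})

test_that("OPL generator places peaks and honors determinism", {
  specs <- list(a = c(peak_position = 0.5, peak_width = 0.1, baseline = 0,
                      peak_height = 1),
                b = c(peak_position = 0.5, peak_width = 0.1, baseline = 0,
                      peak_height = 1))
  ps <- genOPLProfiles(specs, n_retinas = 1, noise_sd = 0,
                       position_jitter_sd = 0, seed = 1)
  p <- ps[[1]]
  arc <- p@arclength
  frac <- arc / arc[length(arc)]
  expect_equal(which.max(profileChannel(p, "a")), which.min(abs(frac - 0.5)))
  # identical specs give identical noise-free traces
  expect_identical(profileChannel(p, "a"), profileChannel(p, "b"))
  # trace density varies around n_points
  lens <- vapply(genOPLProfiles(n_retinas = 5, seed = 2),
                 function(q) length(q@arclength), 1L)
  expect_true(all(lens >= 0.9 * 3000 & lens <= 1.1 * 3000))
  expect_error(genOPLProfiles(list(a = c(peak_position = 1.5, peak_width = 0.1,
                                         baseline = 0, peak_height = 1))),
               "\\[0, 1\\]")
})

test_that("OMR trajectory generator produces biased bout walks", {
  up <- genOMRTrajectories(1, duration_s = 20, n_fish = 1,
                           tracking_noise_mm = 0, seed = 5)[[1]]
  expect_true(all(diff(up@x) >= 0))
  down <- genOMRTrajectories(0, duration_s = 20, n_fish = 1,
                             tracking_noise_mm = 0, seed = 5)[[1]]
  expect_true(all(diff(down@x) <= 0))

  a <- genOMRTrajectories(0.5, n_fish = 2, seed = 6)
  b <- genOMRTrajectories(0.5, n_fish = 2, seed = 6)
  expect_identical(a[[1]]@x, b[[1]]@x)

  expect_error(genOMRTrajectories(1.2), "\\[0, 1\\]")
})
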