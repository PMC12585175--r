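test_that("ROI assignment places points in rows with a lower-index tie-break", {
  pts <- data.frame(time_s = c(0, 1, 2, 3),
                    x_mm = c(10, 20, 30, 40),
                    y_mm = c(5, 10, 95, 150))  # center row1, boundary, row10, outside
  rois <- assignRois(pts, n_rows = 10, y_range = c(0, 100))
  expect_named(rois, c("row_1", "row_10"))
  # y = 10 sits on the row1/row2 boundary -> lower-index row 1
  expect_equal(length(rois$row_1@time), 2L)
  expect_equal(attr(rois, "dropped"), 1L)

  # bottom edge belongs to row 1
  edge <- assignRois(data.frame(time_s = 0, x_mm = 0, y_mm = 0),
                     n_rows = 10, y_range = c(0, 100))
  expect_named(edge, "row_1")
})

test_that("synthetic row-confined fish never cross-assign", {
  trajs <- genOMRTrajectories(0.5, duration_s = 10, n_fish = 10,
                              arena_rows = 10, seed = 4)
  pts <- do.call(rbind, lapply(seq_along(trajs), function(i)
    data.frame(time_s = trajs[[i]]@time + i * 1e-6,  # unique stamps per fish
               x_mm = trajs[[i]]@x, y_mm = trajs[[i]]@y, fish = i)))
  rois <- assignRois(pts, n_rows = 10, y_range = c(0, 100))
  expect_equal(length(rois), 10L)
  expect_equal(attr(rois, "dropped"), 0L)
  for (i in 1:10) {
    rowPts <- pts$fish[pts$y_mm > (i - 1) * 10 & pts$y_mm <= i * 10 |
                         (i == 1 & pts$y_mm == 0)]
    expect_true(all(rowPts == i))
  }
})

test_that("path length sums consecutive Euclidean distances", {
  tri <- SwimTrajectory("f", c(0, 1), c(0, 3), c(0, 4))
  expect_equal(pathLength(tri), 5)
  still <- SwimTrajectory("f", 0:5, rep(2, 6), rep(3, 6))
  expect_equal(pathLength(still), 0)
  square <- SwimTrajectory("f", 0:4, c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(pathLength(square), 4)
  expect_warning(p <- pathLength(SwimTrajectory("f", 0, 1, 1)), "fewer")
  expect_equal(p, 0)
})

test_that("speed filter retains bout steps and reports its threshold", {
  # constant speed: nothing exceeds 2x the mean
  t <- seq(0, 10, by = 0.1)
  const <- SwimTrajectory("f", t, t * 5, rep(0, length(t)))
  seg <- speedFilter(const)
  expect_equal(nrow(seg), 0L)
  expect_equal(attr(seg, "threshold_mm_s"), 10)

  # one fast bout amid stillness: exactly the bout's steps retained
  x <- rep(0, length(t))
  boutIdx <- 51:55
  x[boutIdx] <- cumsum(rep(3, 5))      # 30 mm/s for 5 frames
  x[56:length(t)] <- x[55]
  bout <- SwimTrajectory("f", t, x, rep(0, length(t)))
  segB <- speedFilter(bout)
  expect_equal(nrow(segB), 5L)
  expect_true(all(segB$t0 >= t[50] & segB$t1 <= t[55]))

  # multiplier 0 keeps every moving step
  seg0 <- speedFilter(bout, multiplier = 0)
  expect_equal(nrow(seg0), 5L)

  # complementary reading: slow steps
  segS <- speedFilter(bout, retain = "slow")
  expect_equal(nrow(segS), length(t) - 1L - 5L)

  expect_error(speedFilter(SwimTrajectory("f", c(0, 0.1), c(0, 1), c(0, 0)),
                           multiplier = 2)[0, ], NA)
})

test_that("rightward fraction is the distance share of increasing-x steps", {
  t <- seq(0, 10, by = 0.1)
  up <- SwimTrajectory("f", t, cumsum(rep(2, length(t))), rep(0, length(t)))
  segUp <- speedFilter(up, multiplier = 0)
  rf <- rightwardFraction(segUp, c(0, 10))
  expect_equal(rf$rightward_fraction, 1)

  down <- SwimTrajectory("f", t, -cumsum(rep(2, length(t))), rep(0, length(t)))
  rfD <- rightwardFraction(speedFilter(down, multiplier = 0), c(0, 10))
  expect_equal(rfD$rightward_fraction, 0)

  # empty window: undefined, not zero
  rfE <- rightwardFraction(segUp, c(20, 30))
  expect_false(rfE$defined)
  expect_true(is.na(rfE$rightward_fraction))
})

test_that("rightward fraction is invariant to time rescaling and y-shifts", {
  trajs <- genOMRTrajectories(0.7, duration_s = 30, n_fish = 1, seed = 13)
  tr <- trajs[[1]]
  base <- rightwardFraction(speedFilter(tr), c(0, 30))$rightward_fraction
  scaled <- SwimTrajectory("f", tr@time * 3, tr@x, tr@y)
  expect_equal(rightwardFraction(speedFilter(scaled),
                                 c(0, 90))$rightward_fraction, base)
  shifted <- SwimTrajectory("f", tr@time, tr@x, tr@y + 55)
  expect_equal(rightwardFraction(speedFilter(shifted),
                                 c(0, 30))$rightward_fraction, base)
})

test_that("bouts at the default design point pass the realized filter threshold", {
  trajs <- genOMRTrajectories(0.5, duration_s = 60, n_fish = 5, seed = 19)
  for (tr in trajs) {
    seg <- speedFilter(tr)
    thr <- attr(seg, "threshold_mm_s")
    expect_equal(thr, 2 * attr(seg, "mean_speed_mm_s"))
    expect_lt(thr, 29)          # bouts at ~29 mm/s pass
    expect_gt(nrow(seg), 0)
    expect_true(all(seg$speed_mm_s > thr))
  }
})

test_that("phase metrics separate habituation from stimulus windows", {
  sched <- buildOMRSchedule(c(255, 128), seed = 2)
  tab <- omrPhaseTable(sched)
  stimWin <- tab[tab$phase == "stimulus", c("onset_s", "duration_s")]
  biasWin <- data.frame(t0 = stimWin$onset_s,
                        t1 = stimWin$onset_s + stimWin$duration_s)
  dur <- max(tab$onset_s + tab$duration_s)
  trajs <- genOMRTrajectories(0.95, duration_s = dur, n_fish = 6, seed = 23,
                              bias_windows = biasWin)
  met <- cohortPhaseMetrics(trajs, sched)
  expect_true(all(c("habituation", "stimulus") %in% met$phase))
  agg <- tapply(met$fraction[met$defined], met$phase[met$defined], mean)
  expect_gt(agg["stimulus"], agg["habituation"])
  # habituation stays near neutral
  expect_lt(abs(agg["habituation"] - 0.5), 0.12)

  # a fish that never moves yields undefined fractions, not zeros
  still <- SwimTrajectory("s", seq(0, dur, by = 1), rep(10, dur + 1),
                          rep(5, dur + 1))
  expect_error(speedFilter(still), NA)
  metS <- phaseMetrics(still, sched)
  expect_true(all(!metS$defined))
  expect_true(all(is.na(metS$fraction)))
})
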