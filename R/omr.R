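# Optomotor-response trajectory metrics: row ROI assignment, path length,
# bout-retaining speed filter, distance-weighted rightward fractions per
# assay phase.

#' Assign tracked points to arena-row ROIs
#'
#' The arena is divided into `n_rows` equal horizontal bands; each point is
#' assigned to the row containing its y coordinate (points exactly on a
#' shared boundary go to the lower-index row). Points outside every row are
#' dropped and counted.
#'
#' @param points data.frame with `time_s`, `x_mm`, `y_mm`.
#' @param n_rows Number of rows (default 10).
#' @param y_range Arena y extent `c(min, max)` (mm).
#' @return List of [SwimTrajectory-class] objects (one per non-empty row,
#'   named `row_<i>`), with attribute `dropped` counting out-of-arena points.
#' @export
assignRois <- function(points, n_rows = 10, y_range = c(0, n_rows * 10)) {
  stopifnot(all(c("time_s", "x_mm", "y_mm") %in% names(points)))
  if (diff(y_range) <= 0) stop("invalid arena y range", call. = FALSE)
  breaks <- seq(y_range[1L], y_range[2L], length.out = n_rows + 1L)
  # (b[i-1], b[i]] bands: boundary points fall to the lower-index row
  row <- findInterval(points$y_mm, breaks, left.open = TRUE,
                      rightmost.closed = FALSE)
  row[points$y_mm == breaks[1L]] <- 1L
  inside <- row >= 1L & row <= n_rows
  dropped <- sum(!inside)
  out <- list()
  for (r in sort(unique(row[inside]))) {
    sel <- inside & row == r
    ord <- order(points$time_s[sel])
    out[[paste0("row_", r)]] <- SwimTrajectory(
      paste0("row_", r), points$time_s[sel][ord], points$x_mm[sel][ord],
      points$y_mm[sel][ord])
  }
  attr(out, "dropped") <- dropped
  out
}

#' Total path length of a trajectory
#'
#' Sum of Euclidean distances between consecutive coordinates.
#'
#' @param traj A [SwimTrajectory-class].
#' @return Path length (mm); 0 with a warning for single-point input.
#' @export
pathLength <- function(traj) {
  stopifnot(is(traj, "SwimTrajectory"))
  if (length(traj@time) < 2L) {
    warning("trajectory has fewer than 2 points; path length 0")
    return(0)
  }
  sum(sqrt(diff(traj@x)^2 + diff(traj@y)^2))
}

#' Step table of a trajectory
#'
#' @param traj A [SwimTrajectory-class].
#' @return data.frame with one row per consecutive-coordinate step: `t0`,
#'   `t1`, `dx`, `dist_mm`, `speed_mm_s`.
#' @keywords internal
trajectorySteps <- function(traj) {
  stopifnot(is(traj, "SwimTrajectory"))
  n <- length(traj@time)
  if (n < 2L) stop("trajectory needs >= 2 points", call. = FALSE)
  data.frame(t0 = traj@time[-n], t1 = traj@time[-1L], dx = diff(traj@x),
             dist_mm = sqrt(diff(traj@x)^2 + diff(traj@y)^2),
             speed_mm_s = sqrt(diff(traj@x)^2 + diff(traj@y)^2) /
               diff(traj@time))
}

#' Speed-filter a trajectory into movement bouts
#'
#' Per-step speed is the step distance over the step duration; steps faster
#' than `multiplier` times the trajectory's mean step speed are retained as
#' swim-bout movement and all other steps are discarded (swim displacement is
#' carried by bouts). The complementary reading — keeping the slow steps —
#' is available via `retain = "slow"`. The realized threshold in mm/s is
#' attached as an attribute.
#'
#' @param traj A [SwimTrajectory-class].
#' @param multiplier Threshold in multiples of the mean step speed
#'   (default 2; 0 retains every moving step).
#' @param retain `"fast"` (bouts, default) or `"slow"`.
#' @return data.frame of retained steps (columns as [trajectorySteps()]) with
#'   attributes `threshold_mm_s` and `mean_speed_mm_s`.
#' @export
speedFilter <- function(traj, multiplier = 2, retain = c("fast", "slow")) {
  retain <- match.arg(retain)
  st <- trajectorySteps(traj)
  if (sum(st$t1 - st$t0) <= 0) stop("zero total duration", call. = FALSE)
  meanSpeed <- mean(st$speed_mm_s)
  thr <- multiplier * meanSpeed
  keep <- if (retain == "fast") st$speed_mm_s > thr else st$speed_mm_s <= thr
  out <- st[keep, , drop = FALSE]
  attr(out, "threshold_mm_s") <- thr
  attr(out, "mean_speed_mm_s") <- meanSpeed
  out
}

#' Rightward movement fraction inside a phase window
#'
#' Rightward distance is the summed distance of retained steps with strictly
#' increasing x (`dx > 0`); the fraction is distance-weighted: rightward
#' distance over total retained distance inside the window. Steps must lie
#' fully inside the window to count.
#'
#' @param segments Retained step table from [speedFilter()].
#' @param window Phase window `c(t0, t1)` (seconds).
#' @return List with `total_distance_mm`, `rightward_distance_mm`,
#'   `rightward_fraction` (NA with `defined = FALSE` when no retained
#'   distance falls in the window).
#' @export
rightwardFraction <- function(segments, window) {
  stopifnot(length(window) == 2L)
  if (window[2L] <= window[1L])
    return(list(total_distance_mm = 0, rightward_distance_mm = 0,
                rightward_fraction = NA_real_, defined = FALSE))
  sel <- segments$t0 >= window[1L] & segments$t1 <= window[2L]
  tot <- sum(segments$dist_mm[sel])
  rw <- sum(segments$dist_mm[sel & segments$dx > 0])
  if (tot == 0)
    return(list(total_distance_mm = 0, rightward_distance_mm = 0,
                rightward_fraction = NA_real_, defined = FALSE))
  list(total_distance_mm = tot, rightward_distance_mm = rw,
       rightward_fraction = rw / tot, defined = TRUE)
}

#' Per-phase OMR metrics for one fish
#'
#' Computes distance and rightward-fraction metrics separately inside each
#' habituation and stimulus window of every contrast block; centering phases
#' are excluded. The trajectory is speed-filtered once (global mean speed)
#' and clipped to each window.
#'
#' @param traj A [SwimTrajectory-class].
#' @param schedule An [OMRSchedule-class].
#' @param multiplier Speed-filter multiplier.
#' @return data.frame with `fish_id`, `block`, `contrast`, `phase`,
#'   `total_mm`, `rightward_mm`, `fraction` (NA when undefined), `defined`.
#' @export
phaseMetrics <- function(traj, schedule, multiplier = 2) {
  stopifnot(is(traj, "SwimTrajectory"), is(schedule, "OMRSchedule"))
  tab <- omrPhaseTable(schedule)
  tab <- tab[tab$phase %in% c("habituation", "stimulus"), , drop = FALSE]
  span <- range(traj@time)
  if (max(tab$onset_s + tab$duration_s) > span[2L] + 1e-9)
    warning("schedule extends beyond the trajectory; windows clipped")
  seg <- speedFilter(traj, multiplier)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    w <- c(tab$onset_s[i], tab$onset_s[i] + tab$duration_s[i])
    rf <- rightwardFraction(seg, c(max(w[1L], span[1L]), min(w[2L], span[2L])))
    data.frame(fish_id = traj@fishId, block = tab$block[i],
               contrast = tab$contrast[i], phase = tab$phase[i],
               total_mm = rf$total_distance_mm,
               rightward_mm = rf$rightward_distance_mm,
               fraction = rf$rightward_fraction, defined = rf$defined)
  })
  do.call(rbind, rows)
}

#' Per-phase OMR metrics for a cohort
#'
#' @param trajs List of [SwimTrajectory-class] objects.
#' @param schedule An [OMRSchedule-class].
#' @param multiplier Speed-filter multiplier.
#' @return Row-bound [phaseMetrics()] table over all fish.
#' @export
cohortPhaseMetrics <- function(trajs, schedule, multiplier = 2) {
  do.call(rbind, lapply(trajs, phaseMetrics, schedule = schedule,
                        multiplier = multiplier))
}
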