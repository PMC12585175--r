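# Stimulus paradigms of the hunting and optomotor assays, encoded as data
# consumed by both the simulators and the detectors.

#' Build a maximum-intensity hunting schedule
#'
#' Epochs follow the paradigm timing: 2 s lead-in before the first sweep, 3 s
#' sweep (the ~4.9 degree dot crosses ~90 degrees of screen at ~33 deg/s), then
#' a configurable gap before the opposite-direction sweep. All epochs run at
#' 100% LED intensity and directions alternate starting left-to-right (the
#' larva's perspective).
#'
#' @param inter_epoch_gap_s Gap between the end of one sweep and the next
#'   onset (seconds, >= 0; 4 s in the original paradigm).
#' @param n_epochs Number of stimulus epochs (>= 1; 20 in the original
#'   paradigm).
#' @return A [StimulusSchedule-class].
#' @examples
#' buildMaxIntensitySchedule(4, 20)
#' @export
buildMaxIntensitySchedule <- function(inter_epoch_gap_s = 4, n_epochs = 20) {
  stopIfNot(length(n_epochs) == 1L && is.finite(n_epochs) && n_epochs >= 1,
            "'n_epochs' must be a positive integer")
  stopIfNot(length(inter_epoch_gap_s) == 1L && inter_epoch_gap_s >= 0,
            "'inter_epoch_gap_s' must be >= 0")
  n <- as.integer(n_epochs)
  sweep <- 3
  onsets <- 2 + (seq_len(n) - 1L) * (sweep + inter_epoch_gap_s)
  ep <- data.frame(
    index = seq_len(n) - 1L,
    direction = ifelse(seq_len(n) %% 2L == 1L, "left_to_right", "right_to_left"),
    intensity_percent = 100,
    onset_s = onsets,
    sweep_duration_s = sweep)
  new("StimulusSchedule", epochs = ep)
}

#' Build an incremental-intensity hunting schedule
#'
#' Each intensity step is replicated once per sweep direction, left-to-right
#' first; timing matches [buildMaxIntensitySchedule()]. Step 0% serves as the
#' no-stimulus control.
#'
#' @param intensity_steps Intensity percentages in [0, 100]
#'   (default `0, 10, ..., 90`).
#' @param inter_epoch_gap_s Gap between sweeps (seconds).
#' @return A [StimulusSchedule-class] with `2 * length(intensity_steps)`
#'   epochs.
#' @examples
#' buildIncrementalSchedule(seq(0, 90, by = 10))
#' @export
buildIncrementalSchedule <- function(intensity_steps = seq(0, 90, by = 10),
                                     inter_epoch_gap_s = 4) {
  stopIfNot(all(is.finite(intensity_steps)) || length(intensity_steps) == 0L,
            "'intensity_steps' must be finite")
  if (any(intensity_steps < 0 | intensity_steps > 100))
    stop("intensity steps must lie in [0, 100]", call. = FALSE)
  stopIfNot(length(inter_epoch_gap_s) == 1L && inter_epoch_gap_s >= 0,
            "'inter_epoch_gap_s' must be >= 0")
  n <- 2L * length(intensity_steps)
  sweep <- 3
  if (n == 0L) {
    ep <- data.frame(index = integer(), direction = character(),
                     intensity_percent = numeric(), onset_s = numeric(),
                     sweep_duration_s = numeric())
    return(new("StimulusSchedule", epochs = ep))
  }
  onsets <- 2 + (seq_len(n) - 1L) * (sweep + inter_epoch_gap_s)
  ep <- data.frame(
    index = seq_len(n) - 1L,
    direction = rep(c("left_to_right", "right_to_left"), length(intensity_steps)),
    intensity_percent = rep(intensity_steps, each = 2L),
    onset_s = onsets,
    sweep_duration_s = sweep)
  new("StimulusSchedule", epochs = ep)
}

#' Map a servo angle to the projected screen angle
#'
#' The servomotor carrying the LED turns by 20 degrees, which corresponds to
#' ~90 degrees on the projection screen; the mapping is a single linear gain
#' (default 90/20 = 4.5).
#'
#' @param servo_deg Servo angle (degrees).
#' @param gain Dimensionless screen/servo gain (> 0).
#' @return Screen angle (degrees).
#' @examples
#' servoToScreenAngle(20)  # 90
#' @export
servoToScreenAngle <- function(servo_deg, gain = 4.5) {
  stopIfNot(length(gain) == 1L && is.finite(gain) && gain > 0,
            "'gain' must be > 0")
  gain * servo_deg
}

#' Build an OMR contrast-block schedule
#'
#' Contrasts are presented in a seed-determined pseudo-random order; each
#' block runs four phases of 30 s (centering, habituation, centering,
#' rightward stimulus) with 14.5 mm/s moving gratings of 6 mm period.
#'
#' @param contrasts Digital red levels in [0, 255]
#'   (default `c(170, 43, 255, 85, 0, 213, 128)`).
#' @param seed Integer seed of the block permutation.
#' @return An [OMRSchedule-class].
#' @export
buildOMRSchedule <- function(contrasts = c(170, 43, 255, 85, 0, 213, 128),
                             seed = 1L) {
  if (length(contrasts) == 0L)
    stop("'contrasts' must be non-empty", call. = FALSE)
  if (any(contrasts < 0 | contrasts > 255))
    stop("contrasts must lie in [0, 255]", call. = FALSE)
  perm <- withSeed(subSeed(seed, "omr_schedule"), sample.int(length(contrasts)))
  new("OMRSchedule", contrasts = as.integer(contrasts[perm]))
}

#' Phase windows of an OMR schedule
#'
#' Expands an [OMRSchedule-class] into one row per phase with absolute onsets,
#' blocks in presentation order.
#'
#' @param schedule An OMRSchedule.
#' @return data.frame with `block`, `contrast`, `phase` (`centering1`,
#'   `habituation`, `centering2`, `stimulus`), `onset_s`, `duration_s`.
#' @export
omrPhaseTable <- function(schedule) {
  stopifnot(is(schedule, "OMRSchedule"))
  phases <- c("centering1", "habituation", "centering2", "stimulus")
  dur <- schedule@phaseDurationsS
  blockDur <- sum(dur)
  nb <- length(schedule@contrasts)
  data.frame(
    block = rep(seq_len(nb) - 1L, each = 4L),
    contrast = rep(schedule@contrasts, each = 4L),
    phase = rep(phases, nb),
    onset_s = rep((seq_len(nb) - 1L) * blockDur, each = 4L) +
      rep(cumsum(c(0, dur[-4L])), nb),
    duration_s = rep(dur, nb))
}

#' Write / read hunting schedules as CSV
#'
#' Plain CSV with header
#' `index,direction,intensity_percent,onset_s,sweep_duration_s`; a round trip
#' reproduces the schedule bit-exactly.
#'
#' @param schedule A [StimulusSchedule-class].
#' @param path Output file path.
#' @return `writeScheduleCsv` returns `path` invisibly; `readScheduleCsv`
#'   returns a [StimulusSchedule-class].
#' @export
writeScheduleCsv <- function(schedule, path) {
  stopifnot(is(schedule, "StimulusSchedule"))
  utils::write.csv(epochs(schedule), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeScheduleCsv
#' @export
readScheduleCsv <- function(path) {
  ep <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "direction", "intensity_percent", "onset_s", "sweep_duration_s")
  missing <- setdiff(need, names(ep))
  if (length(missing))
    stop("schedule file misses column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ep$index <- as.integer(ep$index)
  new("StimulusSchedule", epochs = ep[need])
}

#' Write / read OMR schedules as CSV
#'
#' Expanded phase-table CSV with header
#' `block,contrast,phase,onset_s,duration_s`.
#'
#' @param schedule An [OMRSchedule-class].
#' @param path Output file path.
#' @return `writeOMRScheduleCsv` returns `path` invisibly;
#'   `readOMRScheduleCsv` returns an [OMRSchedule-class].
#' @export
writeOMRScheduleCsv <- function(schedule, path) {
  utils::write.csv(omrPhaseTable(schedule), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeOMRScheduleCsv
#' @export
readOMRScheduleCsv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("block", "contrast", "phase", "onset_s", "duration_s")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("OMR schedule file misses column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  blocks <- tab[!duplicated(tab$block), , drop = FALSE]
  durations <- tab$duration_s[tab$block == blocks$block[1L]]
  new("OMRSchedule", contrasts = as.integer(blocks$contrast),
      phaseDurationsS = as.numeric(durations))
}
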