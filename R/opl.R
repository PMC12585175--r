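# OPL line-scan processing: DAPI/max normalization, rolling-average
# smoothing, grid resampling, pooling with 95% CI bands and Pearson
# correlation matrices of the pooled traces.

#' Normalize an OPL profile
#'
#' Each non-reference channel is divided pointwise by the nuclear reference
#' channel and then by its own maximum, yielding relative intensities in
#' [0, 1]; the arclength is mapped affinely onto [0, 1]. The reference
#' channel is floored at `max(reference) * 1e-3` to avoid division blow-ups
#' at image borders; if more than 1% of reference samples sit below that
#' floor the profile is rejected as degenerate. Normalization is idempotent:
#' the reference channel of a normalized profile is constant 1.
#'
#' @param p An [OPLProfile-class].
#' @return A normalized [OPLProfile-class].
#' @export
normalizeProfile <- function(p) {
  stopifnot(is(p, "OPLProfile"))
  ref <- p@channels[[p@referenceChannel]]
  eps <- max(ref) * 1e-3
  if (max(ref) <= 0 || mean(ref < eps) > 0.01)
    stop("degenerate reference channel (zeros beyond epsilon tolerance)",
         call. = FALSE)
  refFloored <- pmax(ref, eps)
  channels <- lapply(p@channels, function(ch) {
    r <- ch / refFloored
    r / max(r)
  })
  channels[[p@referenceChannel]] <- rep(1, length(ref))
  arc <- (p@arclength - p@arclength[1L]) /
    (p@arclength[length(p@arclength)] - p@arclength[1L])
  OPLProfile(arc, channels, reference_channel = p@referenceChannel,
             normalized = TRUE)
}

#' Smooth an intensity series with a rolling average
#'
#' Centered rolling mean (default window 25 points, matched to traces of
#' ~3000 points) with shrunken windows at the edges; output length equals
#' input length.
#'
#' @param values Numeric series.
#' @param window_points Window length in samples (>= 1).
#' @return Smoothed series.
#' @export
smoothProfile <- function(values, window_points = 25) {
  if (window_points < 1) stop("window must be >= 1", call. = FALSE)
  rollingMeanCore(values, window_points)
}

#' Smooth every channel of a normalized profile
#'
#' @param p A normalized [OPLProfile-class].
#' @param window_points Rolling-average window (samples).
#' @return The profile with all channels smoothed.
#' @export
smoothProfileChannels <- function(p, window_points = 25) {
  stopifnot(is(p, "OPLProfile"))
  OPLProfile(p@arclength, lapply(p@channels, smoothProfile, window_points),
             reference_channel = p@referenceChannel, normalized = p@normalized)
}

#' Resample a normalized profile onto a uniform grid
#'
#' Linear interpolation of each channel onto `n_grid` uniform positions in
#' [0, 1], so profiles of unequal length become poolable.
#'
#' @param p A normalized [OPLProfile-class] (positions in [0, 1]).
#' @param n_grid Number of grid points (>= 2; default 1000).
#' @return An [OPLProfile-class] on the uniform grid.
#' @export
resampleToGrid <- function(p, n_grid = 1000) {
  stopifnot(is(p, "OPLProfile"))
  if (n_grid < 2) stop("'n_grid' must be >= 2", call. = FALSE)
  if (length(p@arclength) < 2L)
    stop("profile needs at least 2 points", call. = FALSE)
  grid <- seq(0, 1, length.out = n_grid)
  channels <- lapply(p@channels, function(ch)
    stats::approx(p@arclength, ch, xout = grid, rule = 2)$y)
  OPLProfile(grid, channels, reference_channel = p@referenceChannel,
             normalized = p@normalized)
}

#' Full per-profile preprocessing chain
#'
#' Normalize (DAPI then trace maximum), smooth (rolling average), resample to
#' the pooling grid — in that order.
#'
#' @param p A raw [OPLProfile-class].
#' @param window_points Smoothing window (samples).
#' @param n_grid Pooling grid size.
#' @return A gridded, smoothed, normalized [OPLProfile-class].
#' @export
preprocessProfile <- function(p, window_points = 25, n_grid = 1000) {
  resampleToGrid(smoothProfileChannels(normalizeProfile(p), window_points),
                 n_grid)
}

#' Pool gridded profiles into mean traces with 95% CI bands
#'
#' Pointwise mean and normal-approximation 95% confidence band
#' (mean +/- 1.96 * sd / sqrt(n)) per channel.
#'
#' @param profiles List of [OPLProfile-class] objects on a common grid with
#'   identical channel sets.
#' @return Named list (one per channel) of data.frames with `position`,
#'   `mean`, `ci_low`, `ci_high`.
#' @export
poolProfiles <- function(profiles) {
  stopIfNot(length(profiles) >= 1L, "need at least one profile")
  grid <- profiles[[1L]]@arclength
  chans <- sort(names(profiles[[1L]]@channels))
  for (p in profiles) {
    if (length(p@arclength) != length(grid) ||
        any(abs(p@arclength - grid) > 1e-9))
      stop("profiles are not on a common grid", call. = FALSE)
    if (!identical(sort(names(p@channels)), chans))
      stop("profiles have mismatched channel sets", call. = FALSE)
  }
  n <- length(profiles)
  out <- lapply(chans, function(ch) {
    m <- vapply(profiles, function(p) p@channels[[ch]], numeric(length(grid)))
    m <- matrix(m, nrow = length(grid))
    mu <- rowMeans(m)
    sd <- if (n > 1L) apply(m, 1L, stats::sd) else rep(0, length(grid))
    half <- 1.96 * sd / sqrt(n)
    data.frame(position = grid, mean = mu, ci_low = mu - half,
               ci_high = mu + half)
  })
  names(out) <- chans
  out
}

#' Pearson correlation matrix of pooled traces
#'
#' Pairwise Pearson r over the common grid; the diagonal is 1 and the matrix
#' is symmetric (and positive semidefinite up to numerical tolerance).
#'
#' @param traces Named list of equal-length numeric series (e.g. one per
#'   fish x channel).
#' @return Symmetric correlation matrix with the trace labels as dimnames.
#' @export
correlationMatrix <- function(traces) {
  if (length(traces) < 2L) stop("need at least 2 traces", call. = FALSE)
  len <- unique(vapply(traces, length, 1L))
  if (length(len) != 1L) stop("traces must have equal length", call. = FALSE)
  vars <- vapply(traces, stats::var, 0)
  if (any(vars == 0))
    stop("zero-variance trace: ",
         paste(names(traces)[vars == 0], collapse = ", "), call. = FALSE)
  m <- do.call(cbind, traces)
  stats::cor(m)
}

#' Channel-block means of a per-trace correlation matrix
#'
#' When the correlation matrix holds one row per (retina x channel) trace,
#' this averages the off-diagonal entries between (and within) channel
#' blocks, giving a channel-level similarity summary.
#'
#' @param cormat Correlation matrix from [correlationMatrix()] whose labels
#'   are `"<retina>.<channel>"`.
#' @param channels Character vector of channel names to summarize.
#' @return Symmetric channel x channel matrix of mean correlations.
#' @export
channelBlockMeans <- function(cormat, channels) {
  lab <- sub("^.*\\.", "", rownames(cormat))
  out <- matrix(NA_real_, length(channels), length(channels),
                dimnames = list(channels, channels))
  for (a in channels) for (b in channels) {
    sel <- cormat[lab == a, lab == b, drop = FALSE]
    if (a == b) {
      keep <- upper.tri(sel)
      out[a, b] <- if (any(keep)) mean(sel[keep]) else 1
    } else out[a, b] <- mean(sel)
  }
  out
}
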