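# Internal helpers shared across modules: seeded RNG scoping, deterministic
# sub-seed derivation, rolling means with partial edge windows, peak finding.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded generators never perturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit hash of a string (multiplicative, mod 2^31 - 1).
# Used for config fingerprints and sub-seed derivation; not cryptographic.
stringHash31 <- function(s) {
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Derive a module-specific sub-seed from a global seed
#'
#' One global seed fans out to per-module streams via a stable string hash, so
#' stages are reproducible yet statistically independent.
#'
#' @param seed Integer global seed.
#' @param tag Character label of the consuming stage.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
subSeed <- function(seed, tag) {
  stopifnot(is.character(tag), length(tag) == 1L)
  h <- stringHash31(tag)
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483645 + 1)
}

# Centered rolling mean over k points with shrunken (partial) windows at the
# edges; odd k is symmetric, even k extends one extra point to the right.
rollingMeanCore <- function(x, k) {
  n <- length(x)
  if (n == 0L) stop("empty series", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("window must be in [1, length(x)]", call. = FALSE)
  if (k == 1L) return(as.numeric(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - (k - 1L) %/% 2L)
  hi <- pmin(n, i + k %/% 2L)
  cs <- c(0, cumsum(as.numeric(x)))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Indices of strict-left / weak-right local maxima (plateaus credited to their
# first sample).
localMaxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  core <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
  core
}

# Merge peaks closer than `refractory` seconds, keeping the larger one.
mergeRefractory <- function(times, values, refractory) {
  if (length(times) == 0L) return(integer())
  ord <- order(times)
  keep <- integer()
  cur <- ord[1L]
  for (j in ord[-1L]) {
    if (times[j] - times[cur] < refractory) {
      if (values[j] > values[cur]) cur <- j
    } else {
      keep <- c(keep, cur)
      cur <- j
    }
  }
  c(keep, cur)
}

# Raised-cosine bump of unit peak amplitude centered at `center` with total
# width `duration`; compactly supported and smooth.
raisedCosine <- function(t, center, duration) {
  u <- (t - center) / duration
  out <- numeric(length(t))
  inside <- abs(u) < 0.5
  out[inside] <- 0.5 * (1 + cos(2 * pi * u[inside]))
  out
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
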