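# Proportion and distribution statistics used for the behavioral
# comparisons, implemented from the closed forms. Results follow the base-R
# "htest" shape where a statistic and p-value are involved.

#' Wilson score interval for a binomial proportion
#'
#' @param successes Number of successes (0 <= successes <= trials).
#' @param trials Number of trials (>= 1).
#' @param confidence Confidence level (default 0.95).
#' @return List with `estimate`, `ci_low`, `ci_high`, `confidence`,
#'   `method = "wilson"`. The interval hits 0 exactly at 0 successes and 1
#'   exactly at all successes.
#' @examples
#' wilsonInterval(5, 10)
#' @export
wilsonInterval <- function(successes, trials, confidence = 0.95) {
  stopIfNot(length(successes) == 1L && length(trials) == 1L,
            "scalar counts required")
  if (trials < 1 || successes < 0 || successes > trials)
    stop("need 0 <= successes <= trials, trials >= 1", call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  center <- (p + z^2 / (2 * trials)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2))
  list(estimate = p, ci_low = max(0, center - half),
       ci_high = min(1, center + half), confidence = confidence,
       method = "wilson")
}

#' Two-proportion z-test (pooled)
#'
#' Pooled-proportion z statistic with a two-sided normal p-value. When the
#' pooled proportion is 0 or 1 the test is degenerate (zero variance) and a
#' flagged non-significant result (z = 0, p = 1) is returned — 0%-intensity
#' control epochs legitimately produce all-zero counts.
#'
#' @param x1,n1 Successes and trials of group 1.
#' @param x2,n2 Successes and trials of group 2.
#' @return An object of class `htest` with `statistic` (z), `p.value`,
#'   `estimate` (both proportions) and a `degenerate` flag.
#' @export
twoProportionZTest <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1 || x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2)
    stop("need 0 <= xi <= ni and ni >= 1", call. = FALSE)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  degenerate <- pp == 0 || pp == 1
  if (degenerate) {
    z <- 0; p <- 1
  } else {
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = c(z = z), p.value = p,
                 estimate = c(prop1 = p1, prop2 = p2),
                 degenerate = degenerate,
                 method = "two-proportion z-test (pooled)",
                 data.name = sprintf("%g/%g vs %g/%g", x1, n1, x2, n2)),
            class = "htest")
}

#' Pearson chi-square test of independence on a 2x2 table
#'
#' @param a,b,c,d Cell counts, row-wise: `rbind(c(a, b), c(c, d))`.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return An `htest` with `statistic` (X-squared, df = 1) and `p.value`.
#' @export
chi2Independence2x2 <- function(a, b, c, d, correct = FALSE) {
  o <- c(a, b, c, d)
  if (any(o < 0)) stop("counts must be >= 0", call. = FALSE)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  n <- a + b + c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    stop("zero margin in the 2x2 table", call. = FALSE)
  e <- c(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  adj <- if (correct) pmin(abs(o - e), 0.5) else 0
  stat <- sum((abs(o - e) - adj)^2 / e)
  structure(list(statistic = c(`X-squared` = stat), parameter = c(df = 1),
                 p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 method = paste0("Pearson chi-square (2x2",
                                 if (correct) ", Yates-corrected" else "", ")"),
                 data.name = sprintf("[%g %g; %g %g]", a, b, c, d)),
            class = "htest")
}

# Asymptotic Kolmogorov survival function Q(lambda) = 2 sum (-1)^(k-1)
# exp(-2 k^2 lambda^2).
kolmogorovSF <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

# Exact two-sided two-sample KS p-value (no-ties null): probability that a
# random interleaving of n and m ranks produces sup|ECDF difference| >= d,
# via the lattice-path recursion with paths zeroed once |i/n - j/m| >= d.
ksExactP <- function(n, m, d) {
  A <- matrix(0, n + 1L, m + 1L)
  A[1L, 1L] <- 1
  for (i in 0:n) for (j in 0:m) {
    if (i == 0L && j == 0L) next
    if (abs(i / n - j / m) >= d - 1e-12) { A[i + 1L, j + 1L] <- 0; next }
    acc <- 0
    if (i > 0L) acc <- acc + A[i, j + 1L] * i / (i + j)
    if (j > 0L) acc <- acc + A[i + 1L, j] * j / (i + j)
    A[i + 1L, j + 1L] <- acc
  }
  min(max(1 - A[n + 1L, m + 1L], 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum absolute difference of the two empirical CDFs. The
#' p-value uses the asymptotic Kolmogorov distribution with effective sample
#' size `n * m / (n + m)` by default; `exact = TRUE` switches to the exact
#' no-ties permutation distribution (feasible for `n * m <= 1e4`).
#'
#' @param xs,ys Numeric samples (non-empty).
#' @param exact Use the exact small-sample null distribution.
#' @return An `htest` with `statistic` (D) and `p.value`.
#' @export
ksTwoSample <- function(xs, ys, exact = FALSE) {
  n <- length(xs); m <- length(ys)
  if (n == 0L || m == 0L) stop("samples must be non-empty", call. = FALSE)
  pts <- sort(unique(c(xs, ys)))
  fx <- vapply(pts, function(q) sum(xs <= q), 0) / n
  fy <- vapply(pts, function(q) sum(ys <= q), 0) / m
  D <- max(abs(fx - fy))
  if (exact) {
    if (as.numeric(n) * m > 1e4)
      stop("exact p-value limited to n*m <= 1e4", call. = FALSE)
    p <- ksExactP(n, m, D)
    method <- "two-sample Kolmogorov-Smirnov (exact)"
  } else {
    ne <- n * m / (n + m)
    p <- kolmogorovSF(sqrt(ne) * D)
    method <- "two-sample Kolmogorov-Smirnov (asymptotic)"
  }
  structure(list(statistic = c(D = D), p.value = p, method = method,
                 data.name = sprintf("n = %d, m = %d", n, m)),
            class = "htest")
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorts the p-values ascending, applies the Sidak correction with
#' decreasing family size `1 - (1 - p_(i))^(m - i + 1)`, enforces
#' monotonicity down the sorted list, caps at 1 and restores the input
#' order.
#'
#' @param p_values Raw p-values in [0, 1].
#' @return Adjusted p-values in the input order (elementwise >= the raw
#'   values).
#' @examples
#' holmSidak(c(0.01, 0.04))  # 0.0199, 0.04
#' @export
holmSidak <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Two-sample t-test (Welch by default)
#'
#' Welch statistic with Satterthwaite degrees of freedom and a two-sided
#' p-value; `var_equal = TRUE` switches to the pooled-variance test.
#'
#' @param a,b Numeric samples with at least 2 values each.
#' @param var_equal Pooled-variance instead of Welch.
#' @return An `htest` with `statistic` (t), `parameter` (df) and `p.value`.
#' @export
welchTTest <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs >= 2 values", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (!is.finite(v1) || !is.finite(v2))
    stop("samples must have finite variance", call. = FALSE)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- if (se == 0) 0 else (mean(a) - mean(b)) / se
  p <- if (se == 0 && mean(a) == mean(b)) 1
       else 2 * stats::pt(-abs(tstat), df)
  structure(list(statistic = c(t = tstat), parameter = c(df = df),
                 p.value = p,
                 method = if (var_equal) "pooled-variance two-sample t-test"
                          else "Welch two-sample t-test",
                 data.name = sprintf("n = %d, %d", n1, n2)),
            class = "htest")
}
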