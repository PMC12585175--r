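test_that("wilson interval hits the closed form and its boundaries", {
  z0 <- wilsonInterval(0, 25)
  expect_equal(z0$ci_low, 0)
  expect_equal(z0$estimate, 0)
  zn <- wilsonInterval(25, 25)
  expect_equal(zn$ci_high, 1)

  # frozen hand evaluation of the score interval, z = qnorm(0.975)
  w <- wilsonInterval(5, 10, 0.95)
  expect_equal(w$ci_low, 0.2365930905, tolerance = 1e-9)
  expect_equal(w$ci_high, 0.7634069095, tolerance = 1e-9)
  expect_equal(w$estimate, 0.5)

  expect_error(wilsonInterval(11, 10), "successes")
  expect_error(wilsonInterval(1, 0), "trials")
})

test_that("wilson interval matches the prop.test score interval oracle", {
  for (x in c(1, 7, 19)) {
    ours <- wilsonInterval(x, 40)
    ref <- prop.test(x, 40, correct = FALSE)$conf.int
    expect_equal(ours$ci_low, ref[1], tolerance = 1e-9)
    expect_equal(ours$ci_high, ref[2], tolerance = 1e-9)
  }
})

test_that("two-proportion z-test follows the pooled closed form", {
  eq <- twoProportionZTest(5, 10, 5, 10)
  expect_equal(unname(eq$statistic), 0)
  expect_equal(eq$p.value, 1)

  a <- twoProportionZTest(18, 40, 9, 35)
  b <- twoProportionZTest(9, 35, 18, 40)
  expect_equal(unname(a$statistic), -unname(b$statistic))
  expect_equal(a$p.value, b$p.value)

  # frozen closed-form recomputation via the normal CDF
  big <- twoProportionZTest(180, 380, 100, 360)
  expect_equal(unname(big$statistic), 5.4922421107, tolerance = 1e-9)
  expect_equal(big$p.value, 3.968628194e-08, tolerance = 1e-6)

  deg <- twoProportionZTest(0, 10, 0, 12)
  expect_true(deg$degenerate)
  expect_equal(deg$p.value, 1)
  expect_equal(unname(deg$statistic), 0)

  expect_error(twoProportionZTest(-1, 10, 2, 10), "xi")
})

test_that("2x2 chi-square matches direct expected-count arithmetic", {
  flat <- chi2Independence2x2(10, 10, 10, 10)
  expect_equal(unname(flat$statistic), 0)
  expect_equal(flat$p.value, 1)

  # transposition invariance
  x1 <- chi2Independence2x2(20, 5, 10, 15)
  x2 <- chi2Independence2x2(20, 10, 5, 15)
  expect_equal(unname(x1$statistic), unname(x2$statistic))

  # frozen sum((O-E)^2/E) from the margins
  expect_equal(unname(x1$statistic), 8.3333333333, tolerance = 1e-9)
  expect_equal(x1$p.value, 0.003892417123, tolerance = 1e-9)

  ref <- suppressWarnings(chisq.test(rbind(c(20, 5), c(10, 15)),
                                     correct = FALSE))
  expect_equal(unname(x1$statistic), unname(ref$statistic), tolerance = 1e-12)
  refY <- suppressWarnings(chisq.test(rbind(c(20, 5), c(10, 15)),
                                      correct = TRUE))
  oursY <- chi2Independence2x2(20, 5, 10, 15, correct = TRUE)
  expect_equal(unname(oursY$statistic), unname(refY$statistic),
               tolerance = 1e-12)

  expect_error(chi2Independence2x2(0, 0, 3, 4), "margin")
})

test_that("z-squared equals chi-squared on shared 2x2 tables", {
  set.seed(8)
  for (i in 1:25) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    x1 <- sample.int(n1 - 1, 1); x2 <- sample.int(n2 - 1, 1)
    z <- twoProportionZTest(x1, n1, x2, n2)
    chi <- chi2Independence2x2(x1, n1 - x1, x2, n2 - x2)
    expect_lt(abs(unname(z$statistic)^2 - unname(chi$statistic)), 1e-10)
    expect_lt(abs(z$p.value - chi$p.value), 1e-10)
  }
})

test_that("KS statistic equals the brute-force ECDF scan for small samples", {
  ident <- ksTwoSample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(ident$statistic), 0)
  sep <- ksTwoSample(runif(8), runif(8) + 10)
  expect_equal(unname(sep$statistic), 1)

  set.seed(15)
  for (n in c(2, 5, 9, 12)) for (m in c(3, 7, 12)) {
    xs <- rnorm(n); ys <- rnorm(m, 0.5)
    ours <- ksTwoSample(xs, ys)
    expect_identical(unname(ours$statistic), bruteForceKS(xs, ys))
    # tied integer draws exercise the shared-point handling
    xi <- sample.int(4, n, replace = TRUE)
    yi <- sample.int(4, m, replace = TRUE)
    expect_identical(unname(ksTwoSample(xi, yi)$statistic),
                     bruteForceKS(xi, yi))
  }
})

test_that("KS p-values match ks.test asymptotically and exactly", {
  set.seed(16)
  xs <- rnorm(40); ys <- rnorm(35, 0.4)
  ours <- ksTwoSample(xs, ys)
  ref <- suppressWarnings(ks.test(xs, ys, exact = FALSE))
  expect_equal(unname(ours$statistic), unname(ref$statistic),
               tolerance = 1e-12)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-6)

  sx <- rnorm(7); sy <- rnorm(9, 1)
  oursEx <- ksTwoSample(sx, sy, exact = TRUE)
  refEx <- ks.test(sx, sy, exact = TRUE)
  expect_equal(oursEx$p.value, refEx$p.value, tolerance = 1e-10)

  expect_error(ksTwoSample(numeric(), 1:3), "non-empty")
})

test_that("holm-sidak adjustment follows the step-down formula", {
  expect_equal(holmSidak(0.2), 0.2)
  expect_equal(holmSidak(c(0, 0.5)), c(0, 0.5))
  expect_equal(holmSidak(c(0.01, 0.04)), c(0.0199, 0.04))

  set.seed(20)
  p <- runif(9)
  adj <- holmSidak(p)
  expect_true(all(adj >= p))
  perm <- sample.int(9)
  expect_equal(holmSidak(p[perm]), adj[perm])
  expect_true(all(holmSidak(rep(1, 4)) == 1))
  expect_error(holmSidak(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("welch test flags degenerate inputs sensibly", {
  same <- welchTTest(c(3, 3, 3), c(3, 3, 3))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  expect_error(welchTTest(1, c(1, 2)), "2 values")
})
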