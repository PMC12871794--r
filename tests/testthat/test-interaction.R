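test_that("noiseless interaction is recovered to machine precision", {
  set.seed(1)
  pgs <- rnorm(100); e <- rbinom(100, 1, 0.5)
  y <- 1 * pgs + 2 * e + 0.5 * pgs * e
  # a perfect fit makes lm's variance summary warn; the point estimate and
  # the (degenerate) p-value are still what the check needs
  f <- suppressWarnings(fitInteraction(y, pgs, e))
  expect_equal(f@gammaHat, 0.5, tolerance = 1e-10)
  expect_lt(f@pInteraction, 1e-200)
  expect_equal(f@nUsed, 100L)
})

test_that("coefficients equal the normal-equations oracle on a small dataset", {
  set.seed(12)
  n <- 12
  pgs <- rnorm(n); e <- rnorm(n); cv <- rnorm(n)
  y <- 0.3 + 0.8 * pgs - 0.5 * e + 0.2 * pgs * e + 0.1 * cv + rnorm(n, 0, 0.3)
  f <- fitInteraction(y, pgs, e, covariates = cbind(cov1 = cv))
  X <- cbind(1, pgs, e, cv, cv * e, pgs * e)
  orc <- olsOracle(X, y)
  # match terms by construction: interaction is the last oracle column
  expect_equal(unname(f@gammaHat), orc$beta[6], tolerance = 1e-10)
  expect_equal(unname(f@gammaSe), orc$se[6], tolerance = 1e-10)
  expect_equal(f@pInteraction, orc$p[6], tolerance = 1e-10)
})

test_that("oracle equivalence holds across random small instances", {
  for (s in 1:8) {
    set.seed(1000 + s)
    n <- sample(30:200, 1)
    pgs <- rnorm(n); e <- rbinom(n, 1, 0.5)
    y <- rnorm(n) + 0.2 * pgs * e
    f <- fitInteraction(y, pgs, e)
    orc <- olsOracle(cbind(1, pgs, e, pgs * e), y)
    expect_equal(unname(f@gammaHat), orc$beta[4], tolerance = 1e-9)
    expect_equal(f@pInteraction, orc$p[4], tolerance = 1e-9)
  }
})

test_that("degenerate designs are rejected with informative errors", {
  y <- rnorm(50); pgs <- rnorm(50)
  expect_error(fitInteraction(y, pgs, rep(1, 50)), "zero-variance environment")
  expect_error(fitInteraction(y, rep(2, 50), rbinom(50, 1, 0.5)), "zero-variance pgs")
  expect_error(fitInteraction(rep(1, 50), pgs, rbinom(50, 1, 0.5)), "zero-variance phenotype")
  e <- rbinom(50, 1, 0.5)
  expect_error(fitInteraction(y, pgs, e, covariates = cbind(a = e, b = e)),
               "rank-deficient")
})

test_that("rows with missing values are dropped and counted", {
  set.seed(3)
  y <- rnorm(60); pgs <- rnorm(60); e <- rbinom(60, 1, 0.5)
  y[c(2, 10)] <- NA; pgs[15] <- NA
  f <- fitInteraction(y, pgs, e)
  expect_equal(f@nUsed, 57L)
  g <- fitInteraction(y[-c(2, 10, 15)], pgs[-c(2, 10, 15)], e[-c(2, 10, 15)])
  expect_equal(f@gammaHat, g@gammaHat)
})

test_that("categorical environments use a joint interaction test", {
  set.seed(4)
  n <- 300
  pgs <- rnorm(n)
  e <- factor(sample(c("never", "previous", "current"), n, TRUE))
  y <- pgs + 0.5 * pgs * (e == "current") + rnorm(n)
  f <- fitInteraction(y, pgs, e)
  expect_length(f@gammaHat, 2)          # two non-reference contrasts
  expect_lt(f@pInteraction, 1e-4)
})

test_that("interaction p-value is invariant to positive affine maps of pgs", {
  set.seed(5)
  n <- 500
  pgs <- rnorm(n); e <- rbinom(n, 1, 0.5)
  y <- 0.5 * pgs + e + 0.2 * pgs * e + rnorm(n)
  p1 <- fitInteraction(y, pgs, e)@pInteraction
  p2 <- fitInteraction(y, 3.7 * pgs + 11, e)@pInteraction
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("fast per-column scan agrees exactly with the single fits", {
  set.seed(6)
  n <- 400; m <- 6
  G <- matrix(rnorm(n * m), n, m)
  e <- rbinom(n, 1, 0.5)
  y <- exp(0.3 * rowSums(G[, 1:2]) + 0.5 * e + rnorm(n, 0, 0.5))
  sc <- scanInteractions(y, G, e)
  for (j in seq_len(m)) {
    f <- fitInteraction(y, G[, j], e)
    expect_equal(sc$gammaHat[j], unname(f@gammaHat), tolerance = 1e-8)
    expect_equal(sc$p[j], f@pInteraction, tolerance = 1e-8)
  }
})

test_that("null interaction p-values are uniform", {
  set.seed(8)
  nrep <- 500
  ps <- vapply(seq_len(nrep), function(r) {
    n <- 400
    g <- rnorm(n); e <- rbinom(n, 1, 0.5)
    y <- 0.6 * g + 0.9 * e + rnorm(n)
    scanInteractions(y, matrix(g, ncol = 1), e)$p[1]
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("lambda profiling transforms, fits and classifies", {
  set.seed(9)
  cfg <- simulationConfig(nSamples = 8000, nPgs = 1, seed = 21,
                          observationScale = "exponential")
  ch <- simulateCohort(cfg)
  pr <- profileLambda(ch@yObserved, ch@G[, 1], ch@E)
  expect_s4_class(pr, "LambdaProfile")
  expect_length(pValues(pr), 25)
  expect_equal(pr@threshold, 0.05 / 26)
  i0 <- which(abs(lambdas(pr)) < 1e-12)
  i1 <- which(abs(lambdas(pr) - 1) < 1e-12)
  # additive on the log scale: significant untransformed, rescued at lambda=0
  expect_lt(pValues(pr)[i1], pr@threshold)
  expect_gt(pValues(pr)[i0], pr@threshold)
  expect_identical(classification(pr), "scale_dependent")
  expect_gt(rintP(pr), 0)
})

test_that("profiling errors are annotated with the offending lambda", {
  y <- rep(2, 100)  # positive but constant
  expect_error(profileLambda(y, rnorm(100), rbinom(100, 1, 0.5),
                             lambdas = c(0, 1)),
               "lambda = 0")
})

test_that("scale-dependence classification follows the decision rule", {
  lam <- c(0, 1)
  expect_identical(classifyScaleDependence(c(1e-10, 1e-10), lam, 1.4e-3),
                   "scale_independent")
  expect_identical(classifyScaleDependence(c(0.2, 1e-10), lam, 1.4e-3),
                   "scale_dependent")
  expect_identical(classifyScaleDependence(c(1e-10, 0.5), lam, 1.4e-3),
                   "not_significant")
  expect_error(classifyScaleDependence(c(0.1, 0.2), c(0, 0.5), 0.05),
               "default lambda")
})

test_that("robust standard errors are available as an option", {
  set.seed(10)
  n <- 300
  pgs <- rnorm(n); e <- rbinom(n, 1, 0.5)
  y <- pgs + e + rnorm(n) * (1 + e)  # heteroskedastic by group
  f0 <- fitInteraction(y, pgs, e, robust = FALSE)
  f1 <- fitInteraction(y, pgs, e, robust = TRUE)
  expect_false(isTRUE(all.equal(f0@gammaSe, f1@gammaSe)))
  expect_equal(f0@gammaHat, f1@gammaHat)  # point estimate unchanged
})
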