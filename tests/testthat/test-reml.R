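test_that("heritability decomposition is exact arithmetic on the components", {
  vc <- new("VarianceComponents", va = 2, vd = 1, ve = 1, logLik = 0)
  h <- heritabilities(vc)
  expect_equal(h$h2, 0.5)
  expect_equal(h$H2, 0.75)
  expect_equal(h$d2, 0.25)
  expect_equal(h$PDV, 1 / 3)
  expect_equal(h$H2 - h$h2, h$d2, tolerance = 1e-12)

  h0 <- heritabilities(new("VarianceComponents", va = 2, vd = 0, ve = 2,
                           logLik = 0))
  expect_equal(h0$H2, h0$h2)
  expect_equal(h0$d2, 0)
  expect_equal(h0$PDV, 0)

  hd <- heritabilities(new("VarianceComponents", va = 0, vd = 1, ve = 3,
                           logLik = 0))
  expect_equal(hd$h2, 0)
  expect_equal(hd$H2, 0.25)
  expect_equal(hd$PDV, 1)

  expect_error(new("VarianceComponents", va = -1, vd = 0, ve = 1, logLik = 0),
               "non-negative")
  hz <- heritabilities(new("VarianceComponents", va = 0, vd = 0, ve = 1,
                           logLik = 0))
  expect_false(hz$pdvDefined)
})

test_that("single-kernel REML recovers simulated variance components", {
  h2hat <- vapply(1:3, function(s) {
    M <- randomMarkers(250, 400, seed = 100 + s)
    p <- alleleFrequencies(M)
    Z <- additiveDesign(M, p)
    A <- additiveGRM(Z, p)
    set.seed(200 + s)
    u <- drop(Z %*% rnorm(400, sd = sqrt(2 / A@denominator)))  # Va ~ 2
    y <- setNames(u + rnorm(250, sd = 1), individualIds(M))
    fit <- suppressMessages(remlFit(y, list(A)))
    vc <- varComp(fit)
    vc@va / (vc@va + vc@ve)
  }, numeric(1))
  expect_lt(abs(mean(h2hat) - 2 / 3), 0.12)
})

test_that("pure-noise phenotypes give a near-zero genetic fraction", {
  frac <- vapply(1:3, function(s) {
    M <- randomMarkers(250, 400, seed = 300 + s)
    A <- additiveGRM(additiveDesign(M), alleleFrequencies(M))
    set.seed(400 + s)
    y <- setNames(rnorm(250), individualIds(M))
    vc <- varComp(suppressMessages(remlFit(y, list(A))))
    vc@va / (vc@va + vc@ve)
  }, numeric(1))
  expect_lt(mean(frac), 0.1)
})

test_that("restricted likelihood at the optimum dominates a coarse ratio grid", {
  M <- randomMarkers(60, 120, seed = 17)
  p <- alleleFrequencies(M)
  Z <- additiveDesign(M, p)
  A <- additiveGRM(Z, p)
  set.seed(18)
  y <- setNames(drop(Z %*% rnorm(120, sd = 0.15)) + rnorm(60),
                individualIds(M))
  fit <- suppressMessages(remlFit(y, list(A)))
  K <- grmMatrix(A); X <- matrix(1, 60, 1); n <- 60
  ll <- function(va, ve) {
    V <- va * K + diag(ve, n)
    ch <- chol(V); Vi <- chol2inv(ch)
    ViX <- Vi %*% X; XtViX <- crossprod(X, ViX)
    b <- solve(XtViX, crossprod(ViX, y)); r <- y - X %*% b
    -0.5 * (2 * sum(log(diag(ch))) + log(XtViX[1, 1]) +
              drop(crossprod(r, Vi %*% r)) + (n - 1) * log(2 * pi))
  }
  grid_ll <- sapply(exp(seq(-6, 6, length.out = 40)), function(ra)
    sapply(seq(0.1, 2.5, length.out = 15), function(ve) ll(ra * ve, ve)))
  expect_gte(varComp(fit)@logLik, max(grid_ll) - 1e-6)
})

test_that("a zero second kernel reproduces the single-kernel fit", {
  M <- randomMarkers(80, 100, seed = 23)
  p <- alleleFrequencies(M)
  Z <- additiveDesign(M, p)
  A <- additiveGRM(Z, p)
  set.seed(24)
  y <- setNames(drop(Z %*% rnorm(100, sd = 0.2)) + rnorm(80),
                individualIds(M))
  f1 <- suppressMessages(remlFit(y, list(A)))
  Zero <- matrix(0, 80, 80, dimnames = list(names(y), names(y)))
  f2 <- suppressMessages(remlFit(y, list(A, Zero)))
  expect_equal(varComp(f2)@va, varComp(f1)@va, tolerance = 1e-6)
  expect_equal(varComp(f2)@ve, varComp(f1)@ve, tolerance = 1e-6)
  expect_equal(varComp(f2)@vd, 0)
})

test_that("GBLUP predictions extend consistently to new individuals", {
  M <- randomMarkers(60, 80, seed = 31)
  # duplicate a genotype: i0060 is an exact copy of i0001
  d <- dosages(M)
  d[60, ] <- d[1, ]
  M <- MarkerMatrix(d)
  p <- alleleFrequencies(M)
  Z <- additiveDesign(M, p)
  A <- additiveGRM(Z, p)
  set.seed(32)
  y <- setNames(drop(Z %*% rnorm(80, sd = 0.3)) + rnorm(60, sd = 0.5),
                individualIds(M))
  trainIds <- individualIds(M)[1:50]
  testIds <- individualIds(M)[51:60]
  fit <- suppressMessages(remlFit(y[trainIds], list(A)))
  pred <- gblupPredict(fit, list(A), testIds)
  expect_true(all(is.finite(pred)))
  # a test individual genetically identical to a training individual gets
  # that individual's fitted genetic value
  fitted1 <- fit@b[1] + fit@blups$additive["i0001"]
  expect_equal(unname(pred["i0060"]), unname(fitted1), tolerance = 1e-8)
  # predicting training ids returns fitted values, with a warning
  expect_warning(pt <- gblupPredict(fit, list(A), trainIds[1:3]), "training")
  expect_equal(unname(pt),
               unname(fit@b[1] + fit@blups$additive[trainIds[1:3]]),
               tolerance = 1e-8)
})

test_that("two-kernel EM-REML finds little dominance when none was simulated", {
  # structured test-cross population, purely additive architecture
  spec <- testCrossSpec(41, nLines = 60, nLoci = 200, nCausalAdd = 40,
                        nCausalDom = 0, targetH2 = 0.6, targetD2 = 0)
  pop <- simulatePopulation(spec)
  sim <- simulatePhenotypes(pop)
  rec <- yearMeans(sim$phenotypes)
  p <- alleleFrequencies(pop$hybrids)
  A <- additiveGRM(additiveDesign(pop$hybrids, p), p)
  D <- dominanceGRM(dominanceDesign(pop$hybrids, p), p)
  y <- setNames(rec$value, rec$hybrid)
  f1 <- suppressMessages(remlFit(y, list(A)))
  f2 <- suppressMessages(remlFit(y, list(A, D)))
  vc2 <- varComp(f2)
  expect_lt(vc2@vd / (vc2@va + vc2@vd + vc2@ve), 0.12)
  expect_gte(vc2@logLik, varComp(f1)@logLik - 0.1)
  expect_equal(varComp(f2)@va, varComp(f1)@va, tolerance = 0.25)
})
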