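test_that("a single stump attributes only its split feature, as hand-computed", {
  set.seed(91)
  X <- matrix(sample(0:2, 300 * 5, TRUE), 300, 5,
              dimnames = list(sprintf("r%03d", 1:300), paste0("f", 1:5)))
  y <- ifelse(X[, 3] >= 1, 2, -1) + rnorm(300, sd = 0.01)
  prm <- list(nTrees = 1, learningRate = 1, maxLeaves = 2, minSamplesLeaf = 5,
              featureFraction = 1, rowFraction = 1, l1 = 0, l2 = 0)
  m <- fitBoosted(X, y, prm, seed = 1)
  phi <- shapAttributions(m, X)
  used <- m@trees$Feature[m@trees$Feature != "Leaf"]
  expect_length(used, 1)
  unused <- setdiff(paste0("f", 1:5), used)
  expect_true(all(phi[, unused] == 0))
  # hand-computed two-leaf Shapley value: phi = leaf value - cover-weighted mean
  tr <- m@trees
  leaves <- tr[tr$Feature == "Leaf", ]
  expectVal <- sum(leaves$Cover * leaves$Gain) / sum(leaves$Cover)
  margins <- predictBoosted(m, X) - m@baseScore
  expect_equal(unname(phi[, used]), unname(margins - expectVal),
               tolerance = 1e-10)
})

test_that("local accuracy holds in double precision and matches the backend", {
  set.seed(92)
  n <- 250
  M <- randomMarkers(n, 60, seed = 92)
  p <- alleleFrequencies(M)
  x <- concat2NP(additiveDesign(M, p), dominanceDesign(M, p))
  F <- features(x)
  y <- drop(F[, 1:4] %*% rnorm(4)) + drop(F[, 61:64] %*% rnorm(4)) +
    rnorm(n, sd = 0.4)
  m <- fitBoosted(F, y, testBoostParams(200), seed = 3,
                  blockLabels = blockLabels(x))
  phi <- shapAttributions(m, F)
  pred <- predictBoosted(m, F)
  expect_lt(max(abs(rowSums(phi) - pred)), 1e-9)
  # independent cross-check: the backend's float32 TreeSHAP
  ctr <- predict(m@booster, xgboost::xgb.DMatrix(F, nthread = 1),
                 predcontrib = TRUE)
  expect_lt(max(abs(phi - ctr)), 1e-4)
})

test_that("block proportions aggregate mean absolute attributions", {
  A <- cbind(a1 = c(1, -1), a2 = c(2, 0), d1 = c(0, 0), d2 = c(0, 0))
  lab <- c("additive", "additive", "dominance", "dominance")
  bp <- blockContributions(A, lab)
  expect_equal(unname(bp), c(1, 0), ignore_attr = TRUE)
  A2 <- cbind(a1 = c(1, 1), d1 = c(-1, 1))
  bp2 <- blockContributions(A2, c("additive", "dominance"))
  expect_equal(unname(bp2), c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(sum(bp2), 1)
  expect_warning(bp0 <- blockContributions(A * 0, lab), "undefined")
  expect_false(attr(bp0, "defined"))
})

test_that("top-marker ranking is stable, complete at k = p, row-order invariant", {
  set.seed(93)
  A <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  lab <- rep(c("additive", "dominance"), 3)
  full <- topMarkers(A, lab, k = 6)
  expect_equal(nrow(full), 6)
  expect_true(all(diff(full$meanAbs) <= 0))
  expect_error(topMarkers(A, lab, k = 7), "exceeds")
  expect_identical(topMarkers(A[sample(50), ], lab, k = 6)$feature,
                   full$feature)
  # ties break by original column order
  At <- cbind(x1 = c(1, -1), x2 = c(-1, 1), x3 = c(0.5, 0.5))
  expect_identical(topMarkers(At, k = 3)$feature, c("x1", "x2", "x3"))
})

test_that("a planted large dominance locus ranks first in most seeds", {
  wins <- 0L
  for (s in 1:10) {
    spec <- testCrossSpec(1000 + s, nLines = 50, nLoci = 60, nCausalAdd = 10,
                          nCausalDom = 1, targetH2 = 0.15, targetD2 = 0.55)
    pop <- simulatePopulation(spec)
    sim <- simulatePhenotypes(pop)
    rec <- yearMeans(sim$phenotypes)
    p <- alleleFrequencies(pop$hybrids)
    x <- concat2NP(additiveDesign(pop$hybrids, p),
                   dominanceDesign(pop$hybrids, p))
    F <- features(x)[rec$hybrid, ]
    rownames(F) <- rec$id
    m <- fitBoosted(F, rec$value, testBoostParams(150), seed = s,
                    blockLabels = blockLabels(x))
    phi <- shapAttributions(m, F)
    top <- topMarkers(phi, blockLabels(x), k = 1)
    planted <- paste0(attr(sim$truth, "causalDom"), "_D")
    if (top$feature == planted) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("interaction values are symmetric and concentrated on true pairs", {
  set.seed(97)
  n <- 250
  X <- matrix(sample(0:2, n * 10, TRUE), n, 10,
              dimnames = list(sprintf("r%03d", 1:n), paste0("f", 1:10)))
  y <- X[, 1] * X[, 2] + rnorm(n, sd = 0.2)
  m <- fitBoosted(X, y, testBoostParams(150), seed = 1)
  si <- suppressMessages(shapInteractions(m, X, k = 5))
  expect_equal(si$matrix, t(si$matrix), tolerance = 1e-6)
  expect_setequal(c(si$pairs$feature1[1], si$pairs$feature2[1]),
                  c("f1", "f2"))
})
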