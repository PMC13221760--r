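test_that("search-space bounds are validated and decoded within range", {
  sp <- searchSpace()
  expect_true(all(sp$lower < sp$upper))
  expect_error(searchSpace(nTrees = c(100, 50)), "invalid bounds")
  expect_error(searchSpace(learningRate = c(0, 0.3)), "positive")
})

test_that("tuning is deterministic and stays within bounds", {
  set.seed(51)
  X <- matrix(sample(0:2, 120 * 30, TRUE), 120, 30,
              dimnames = list(sprintf("r%03d", 1:120), paste0("f", 1:30)))
  y <- X[, 1] * 2 + rnorm(120, sd = 0.5)
  sp <- searchSpace(nTrees = c(30, 150))
  t1 <- tuneHyperparameters(X, y, space = sp, nIter = 5, innerFolds = 3,
                            seed = 7)
  t2 <- tuneHyperparameters(X, y, space = sp, nIter = 5, innerFolds = 3,
                            seed = 7)
  expect_identical(t1$best, t2$best)
  expect_equal(nrow(t1$log), 5)
  for (i in seq_len(nrow(sp))) {
    v <- t1$log[[sp$param[i]]]
    expect_true(all(v >= sp$lower[i] & v <= sp$upper[i]))
  }
  expect_error(tuneHyperparameters(X, rep(1, 120), space = sp, nIter = 3,
                                   innerFolds = 3, seed = 1), "zero variance")
  expect_error(tuneHyperparameters(X[1:2, ], y[1:2], space = sp, nIter = 3,
                                   innerFolds = 5, seed = 1), "innerFolds")
})

test_that("tuning finds configurations at least as good as the space midpoint", {
  wins <- 0L
  sp <- searchSpace(nTrees = c(30, 300))
  mid <- twonp:::.decode_point(rep(0.5, nrow(sp)), sp)
  for (s in 1:10) {
    set.seed(600 + s)
    n <- 200
    X <- matrix(sample(0:2, n * 40, TRUE), n, 40,
                dimnames = list(sprintf("r%03d", 1:n), paste0("f", 1:40)))
    y <- X[, 1] * 2 - X[, 2] + 0.5 * X[, 3] * X[, 4] + rnorm(n, sd = 0.7)
    tuned <- tuneHyperparameters(X, y, space = sp, nIter = 8, innerFolds = 3,
                                 seed = s)
    foldIdx <- local({set.seed(s); twonp:::.balanced_folds(n, 3)})
    midScore <- twonp:::.cv_mse(X, y, mid, foldIdx, seed = s)
    if (min(tuned$log$score) <= midScore) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("boosted fits are reproducible, and constant responses give constants", {
  set.seed(61)
  X <- matrix(sample(0:2, 200 * 40, TRUE), 200, 40,
              dimnames = list(sprintf("r%03d", 1:200), paste0("f", 1:40)))
  yconst <- rep(4.2, 200)
  m <- fitBoosted(X, yconst, testBoostParams(50), seed = 1)
  expect_equal(unname(predictBoosted(m, X)), rep(4.2, 200), tolerance = 1e-6)

  y <- 3 * X[, 1] + rnorm(200, sd = 0.1)
  m1 <- fitBoosted(X, y, testBoostParams(300), seed = 5)
  m2 <- fitBoosted(X, y, testBoostParams(300), seed = 5)
  p1 <- predictBoosted(m1, X)
  expect_identical(p1, predictBoosted(m2, X))
  expect_gt(cor(p1, y)^2, 0.95)
  expect_error(fitBoosted(X, c(y[-1], NA), testBoostParams(), seed = 1),
               "finite")
  expect_error(fitBoosted(X, y, list(nTrees = 10), seed = 1), "incomplete")
})

test_that("predictions align feature columns by name", {
  set.seed(71)
  X <- matrix(rnorm(100 * 10), 100, 10,
              dimnames = list(sprintf("r%03d", 1:100), paste0("f", 1:10)))
  y <- X[, 2] + rnorm(100, sd = 0.2)
  m <- fitBoosted(X, y, testBoostParams(80), seed = 2)
  p0 <- predictBoosted(m, X)
  expect_true(all(is.finite(p0)))
  perm <- sample(10)
  expect_identical(predictBoosted(m, X[, perm]), p0)
  Xbad <- X[, 1:9]
  expect_error(predictBoosted(m, Xbad), "mismatch.*f10")
  colnames(Xbad) <- c(paste0("f", 1:8), "other")
  expect_error(predictBoosted(m, Xbad), "mismatch")
})

test_that("the leakage guard rejects test-flagged rows in tuning and fitting", {
  set.seed(81)
  X <- matrix(sample(0:2, 60 * 10, TRUE), 60, 10,
              dimnames = list(sprintf("r%03d", 1:60), paste0("f", 1:10)))
  y <- rnorm(60)
  expect_error(
    tuneHyperparameters(X, y, nIter = 2, innerFolds = 3, seed = 1,
                        forbiddenIds = c("r010", "zzz")),
    "leakage guard.*r010")
  expect_error(
    fitBoosted(X, y, testBoostParams(), seed = 1, forbiddenIds = "r001"),
    "leakage guard")
  expect_silent(
    invisible(fitBoosted(X, y, testBoostParams(30), seed = 1,
                         forbiddenIds = c("not", "present"))))
})

test_that("a 2NP-trained model beats Z-only features on pure dominance signal", {
  wins <- 0L
  for (s in 1:10) {
    # purely heterozygosity-driven signal at 5 loci; shallow trees, where an
    # explicit dominance column (one split) pays off against raw dosage (two)
    spec <- testCrossSpec(700 + s, nLines = 70, nLoci = 80, nCausalAdd = 0,
                          nCausalDom = 5, targetH2 = 0, targetD2 = 0.6)
    pop <- simulatePopulation(spec)
    sim <- simulatePhenotypes(pop)
    rec <- yearMeans(sim$phenotypes)
    p <- alleleFrequencies(pop$hybrids)
    x <- concat2NP(additiveDesign(pop$hybrids, p),
                   dominanceDesign(pop$hybrids, p))
    Fall <- features(x)[rec$hybrid, ]
    rownames(Fall) <- rec$id
    Zonly <- blockMatrix(x, "additive")[rec$hybrid, ]
    rownames(Zonly) <- rec$id
    set.seed(900 + s)
    te <- sample(nrow(rec), 80)
    prm <- testBoostParams(300)
    prm$maxLeaves <- 7
    m2np <- fitBoosted(Fall[-te, ], rec$value[-te], prm, seed = s,
                       blockLabels = blockLabels(x))
    mz <- fitBoosted(Zonly[-te, ], rec$value[-te], prm, seed = s)
    r2np <- cor(rec$value[te], predictBoosted(m2np, Fall[te, ]))
    rz <- cor(rec$value[te], predictBoosted(mz, Zonly[te, ]))
    if (r2np > rz) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("boosted models round-trip through the native save format", {
  set.seed(95)
  X <- matrix(sample(0:2, 80 * 12, TRUE), 80, 12,
              dimnames = list(sprintf("r%03d", 1:80), paste0("f", 1:12)))
  y <- X[, 1] - X[, 2] + rnorm(80, sd = 0.3)
  m <- fitBoosted(X, y, testBoostParams(60), seed = 4,
                  blockLabels = rep(c("additive", "dominance"), 6))
  prefix <- tempfile()
  saveBoostedModel(m, prefix)
  m2 <- loadBoostedModel(prefix)
  expect_equal(predictBoosted(m2, X), predictBoosted(m, X), tolerance = 1e-12)
  expect_identical(blockLabels(m2), blockLabels(m))
  expect_equal(m2@params$nTrees, m@params$nTrees)
})

test_that("search spaces load from config files", {
  js <- tempfile(fileext = ".json")
  writeLines('{"search_space": {"nTrees": [50, 300], "l2": [0.5, 5]}}', js)
  sp <- searchSpaceFromConfig(js)
  expect_equal(sp$lower[sp$param == "nTrees"], 50)
  expect_equal(sp$upper[sp$param == "l2"], 5)
  expect_equal(sp$lower[sp$param == "learningRate"], 0.005)  # default kept
  writeLines('{"search_space": {"bogus": [1, 2]}}', js)
  expect_error(searchSpaceFromConfig(js), "unknown search-space")
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("search_space:", "  maxLeaves: [4, 64]"), yml)
  sp2 <- searchSpaceFromConfig(yml)
  expect_equal(sp2$upper[sp2$param == "maxLeaves"], 64)
})
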