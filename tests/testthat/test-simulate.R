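test_that("the cross design produces integer hybrid dosages by construction", {
  spec <- architectureSpec(nLines = 50, nTesters = 5, nLoci = 100,
                           nCausalAdd = 10, nCausalDom = 5, years = 2020:2021,
                           seed = 3)
  pop <- simulatePopulation(spec)
  H <- dosages(pop$hybrids)
  expect_lte(nrow(H), 250)
  expect_true(all(H == round(H)))
  # construction identity: hybrid dosage = (line + tester) / 2
  P <- dosages(pop$parents)
  for (i in sample(nrow(pop$pedigree), 10)) {
    ped <- pop$pedigree[i, ]
    expect_equal(H[ped$hybrid, ],
                 (P[ped$parent1, ] + P[ped$parent2, ]) / 2)
  }
  # parents fully inbred
  expect_true(all(P %in% c(0, 2)))
})

test_that("the generator is deterministic under a fixed seed", {
  spec <- testCrossSpec(11, nLines = 20, nLoci = 50)
  a <- simulatePhenotypes(simulatePopulation(spec))
  b <- simulatePhenotypes(simulatePopulation(spec))
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth, b$truth)
})

test_that("tester turnover assigns overlapping tester subsets per year", {
  spec <- g2fLikeSpec(nLoci = 50, nCausalAdd = 10, nCausalDom = 5, seed = 1)
  pop <- simulatePopulation(spec)
  sizes <- lengths(pop$testerAssignment)
  expect_true(all(sizes == 5))
  expect_gt(length(unique(unlist(pop$testerAssignment))), 5)  # turnover
  # consecutive years share testers
  expect_gt(length(intersect(pop$testerAssignment[[1]],
                             pop$testerAssignment[[2]])), 0)
})

test_that("truth decomposes exactly and respects architecture switches", {
  spec <- testCrossSpec(13, nCausalAdd = 15, nCausalDom = 8,
                        targetH2 = 0.5, targetD2 = 0.2)
  sim <- simulatePhenotypes(simulatePopulation(spec))
  tr <- sim$truth
  expect_equal(tr$total, tr$additive + tr$dominance + tr$epistatic,
               tolerance = 1e-12)
  expect_true(all(tr$epistatic == 0))  # no epistasis requested
  # realized component variances hit the targets exactly by rescaling
  expect_equal(var(tr$additive), 0.5, tolerance = 1e-10)
  expect_equal(var(tr$dominance), 0.2, tolerance = 1e-10)
  expect_error(architectureSpec(targetH2 = 0.9, targetD2 = 0.2), "at most 1")
  expect_error(architectureSpec(targetH2 = 0.5, nCausalAdd = 0), "causal")
})

test_that("zero residual variance makes phenotype means reproduce genetic values", {
  spec <- testCrossSpec(17, nCausalAdd = 10, nCausalDom = 5,
                        targetH2 = 0.8, targetD2 = 0.2)  # residual share 0
  sim <- simulatePhenotypes(simulatePopulation(spec))
  rec <- yearMeans(sim$phenotypes)
  g <- sim$truth$total[match(rec$hybrid, sim$truth$hybrid)]
  expect_equal(cor(rec$value, g), 1, tolerance = 1e-12)
})

test_that("the realized additive share of phenotype-mean variance tracks its target", {
  shares <- vapply(1:10, function(s) {
    spec <- testCrossSpec(2000 + s, nLines = 60, nLoci = 150,
                          nCausalAdd = 40, nCausalDom = 20,
                          targetH2 = 0.8, targetD2 = 0.1)
    sim <- simulatePhenotypes(simulatePopulation(spec))
    rec <- yearMeans(sim$phenotypes)
    var(sim$truth$additive) / var(rec$value)
  }, numeric(1))
  expect_true(all(shares > 0.7 & shares < 0.9))
})

test_that("hybrid genotypes cluster by tester on the leading PCs", {
  spec <- testCrossSpec(19, nLines = 40, nTesters = 4, nLoci = 200)
  pop <- simulatePopulation(spec)
  pc <- prcomp(dosages(pop$hybrids), rank. = 2)$x
  tester <- pop$pedigree$parent2[match(rownames(pc), pop$pedigree$hybrid)]
  # mean silhouette on tester labels over the first two PCs
  dm <- as.matrix(dist(pc))
  sil <- vapply(seq_len(nrow(pc)), function(i) {
    own <- tester == tester[i]
    a <- mean(dm[i, own & seq_len(nrow(pc)) != i])
    b <- min(vapply(setdiff(unique(tester), tester[i]), function(tt)
      mean(dm[i, tester == tt]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("simulated datasets round-trip through the CSV writers", {
  spec <- testCrossSpec(23, nLines = 10, nLoci = 30)
  pop <- simulatePopulation(spec)
  sim <- simulatePhenotypes(pop)
  dir <- tempfile()
  writeSimulation(pop, sim, dir)
  M <- readGenotypes(file.path(dir, "genotypes.csv"), "matrix")
  expect_identical(dosages(M), dosages(pop$hybrids))
  ped <- readPedigree(file.path(dir, "pedigree.csv"))
  expect_identical(ped$hybrid, pop$pedigree$hybrid)
  ph <- readPhenotypes(file.path(dir, "phenotypes.csv"))
  expect_equal(nrow(ph), nrow(sim$phenotypes))
})
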