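#' Architecture specification for the test-cross simulator
#'
#' Describes a line-by-tester hybrid breeding dataset with known genetic
#' architecture: population sizes, locus and causal-locus counts, target
#' variance fractions, trial structure and a seed. Heritability targets are
#' defined on the entry-mean basis — `targetH2` (`targetD2`) is the share of
#' additive (dominance) variance in the variance of per-hybrid phenotype
#' means, the standard reporting basis for multi-environment trials — so the
#' plot-level residual variance is `(1 - h2 - d2 - epi) * mean plots per
#' hybrid`.
#'
#' @param nLines,nTesters,nLoci population and genome sizes.
#' @param testersPerYear testers used per year (sliding assignment with
#'   turnover when smaller than `nTesters`).
#' @param nCausalAdd,nCausalDom,nCausalEpiPairs causal additive loci,
#'   dominance loci, and epistatic locus pairs.
#' @param targetH2,targetD2 target additive and dominance variance fractions
#'   (entry-mean basis).
#' @param epistasisShare target epistatic variance fraction.
#' @param epistasisTypes pair types cycled over the epistatic pairs:
#'   `"AA"` (additive x additive), `"AD"`, `"DD"`.
#' @param years trial years.
#' @param locationsPerYear,replicates field locations per year and
#'   replicates per location.
#' @param yearSd,locationSd standard deviations of year and location main
#'   effects (trait units; variance of hybrid means is scaled to 1).
#' @param traitName trait label used in the phenotype table.
#' @param seed integer seed; identical specs give identical data.
#' @return a list of class `"ArchitectureSpec"`.
#' @export
architectureSpec <- function(nLines = 50L, nTesters = 5L,
                             testersPerYear = nTesters, nLoci = 500L,
                             nCausalAdd = 40L, nCausalDom = 20L,
                             nCausalEpiPairs = 0L,
                             targetH2 = 0.5, targetD2 = 0.1,
                             epistasisShare = 0,
                             epistasisTypes = c("AA", "AD", "DD"),
                             years = 2018:2023, locationsPerYear = 2L,
                             replicates = 2L, yearSd = 0.5, locationSd = 0.3,
                             traitName = "sim_trait", seed = 1L) {
  spec <- list(nLines = as.integer(nLines), nTesters = as.integer(nTesters),
               testersPerYear = as.integer(testersPerYear),
               nLoci = as.integer(nLoci), nCausalAdd = as.integer(nCausalAdd),
               nCausalDom = as.integer(nCausalDom),
               nCausalEpiPairs = as.integer(nCausalEpiPairs),
               targetH2 = targetH2, targetD2 = targetD2,
               epistasisShare = epistasisShare,
               epistasisTypes = match.arg(epistasisTypes, several.ok = TRUE),
               years = as.integer(years),
               locationsPerYear = as.integer(locationsPerYear),
               replicates = as.integer(replicates), yearSd = yearSd,
               locationSd = locationSd, traitName = traitName,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(nLines > 0, nTesters > 0, nLoci > 0, testersPerYear > 0,
              testersPerYear <= nTesters,
              nCausalAdd <= nLoci, nCausalDom <= nLoci,
              locationsPerYear > 0, replicates > 0, length(years) >= 1)
    if (targetH2 < 0 || targetD2 < 0 || epistasisShare < 0 ||
        targetH2 + targetD2 + epistasisShare > 1)
      stop("variance targets must be non-negative and sum to at most 1")
    if (targetH2 > 0 && nCausalAdd == 0)
      stop("nonzero additive target requires causal additive loci")
    if (targetD2 > 0 && nCausalDom == 0)
      stop("nonzero dominance target requires causal dominance loci")
    if (epistasisShare > 0 && nCausalEpiPairs == 0)
      stop("nonzero epistasis target requires causal pairs")
  })
  class(spec) <- "ArchitectureSpec"
  spec
}

#' G2F-like simulation preset
#'
#' A dataset with the structure of a multi-year test-cross trial series:
#' 6 years, 50 lines crossed to 5 of 8 testers per year (sliding turnover),
#' 2 locations per year, 2 replicates, 2000 loci — small enough for
#' minutes-scale runs. Variance targets default to the upper-middle of the
#' heritability and dominance ranges seen in hybrid maize trials.
#'
#' @param ... overrides passed to [architectureSpec()].
#' @return an `"ArchitectureSpec"`.
#' @export
g2fLikeSpec <- function(...) {
  defaults <- list(nLines = 50L, nTesters = 8L, testersPerYear = 5L,
                   nLoci = 2000L, nCausalAdd = 60L, nCausalDom = 30L,
                   nCausalEpiPairs = 0L, targetH2 = 0.7, targetD2 = 0.1,
                   epistasisShare = 0, years = 2018:2023,
                   locationsPerYear = 2L, replicates = 2L)
  args <- list(...)
  do.call(architectureSpec, c(args, defaults[setdiff(names(defaults), names(args))]))
}

#' Simulate a line-by-tester hybrid population
#'
#' Parents are fully inbred (dosage 0/2) with reference-allele frequencies
#' drawn Uniform(0.05, 0.95) per locus. Every line is crossed to every
#' tester that appears in the year assignment; hybrid genotypes come from
#' [makeHybridGenotypes()], so heterozygosity arises exactly where the
#' parents differ and all hybrid dosages are integers.
#'
#' @param spec an [architectureSpec()].
#' @return list with `parents` and `hybrids` ([MarkerMatrix-class]),
#'   `pedigree` (hybrid, parent1 = line, parent2 = tester), `yearHybrids`
#'   (year -> hybrid ids), `testerAssignment` (year -> tester ids), and the
#'   spec.
#' @export
simulatePopulation <- function(spec) {
  stopifnot(inherits(spec, "ArchitectureSpec"))
  set.seed(spec$seed)
  p <- runif(spec$nLoci, 0.05, 0.95)
  lines <- sprintf("L%03d", seq_len(spec$nLines))
  testers <- sprintf("T%02d", seq_len(spec$nTesters))
  loci <- sprintf("snp%05d", seq_len(spec$nLoci))
  drawInbred <- function(ids) {
    d <- vapply(p, function(pp) 2 * rbinom(length(ids), 1, pp),
                numeric(length(ids)))
    d <- matrix(d, length(ids), spec$nLoci, dimnames = list(ids, loci))
    d
  }
  parents <- MarkerMatrix(rbind(drawInbred(lines), drawInbred(testers)))
  nY <- length(spec$years)
  assignment <- lapply(seq_len(nY), function(i) {
    idx <- ((i - 1) + seq_len(spec$testersPerYear) - 1) %% spec$nTesters + 1
    testers[sort(idx)]
  })
  names(assignment) <- as.character(spec$years)
  used <- sort(unique(unlist(assignment)))
  pedigree <- expand.grid(parent1 = lines, parent2 = used,
                          stringsAsFactors = FALSE)
  pedigree <- data.frame(hybrid = paste0(pedigree$parent1, "x", pedigree$parent2),
                         pedigree, stringsAsFactors = FALSE)
  hybrids <- makeHybridGenotypes(parents, pedigree)
  yearHybrids <- lapply(assignment, function(ts)
    pedigree$hybrid[pedigree$parent2 %in% ts])
  list(parents = parents, pedigree = pedigree, hybrids = hybrids,
       yearHybrids = yearHybrids, testerAssignment = assignment,
       frequencies = p, spec = spec)
}

# per-locus decomposition of the heterozygosity indicator into its
# additive-direction part (regression on dosage) and the orthogonal
# dominance deviation
.het_deviation <- function(M, locus) {
  x <- M[, locus]
  h <- as.numeric(x == 1)
  vx <- var(x)
  beta <- if (vx > 0) cov(h, x) / vx else 0
  xc <- x - mean(x)
  list(dev = h - mean(h) - beta * xc, bleed = beta * xc)
}

.scale_to <- function(v, target) {
  if (target <= 0) return(v * 0)
  s <- var(v)
  if (s <= 0) stop("a genetic component has zero variance but a positive target")
  v * sqrt(target / s)
}

#' Simulate phenotypes with known additive/dominance/epistatic architecture
#'
#' Additive values are `Z a` over the causal additive loci (`a` normal);
#' dominance acts through heterozygosity indicators at the causal dominance
#' loci — each indicator is decomposed per locus into its
#' additive-direction part (absorbed into the additive component) and the
#' orthogonal dominance deviation, so the dominance target is true
#' dominance variance. Epistatic values are products of the centered causal
#' codes (AA: z_i z_j, AD: z_i w_j, DD: w_i w_j, cycled over
#' `epistasisTypes`). Each genetic component is rescaled so its realized
#' variance over hybrids matches the target exactly; plot values add year
#' and location main effects and a Gaussian residual scaled to the
#' entry-mean targets (see [architectureSpec()]).
#'
#' @param pop population from [simulatePopulation()].
#' @param spec architecture spec (defaults to the population's).
#' @return list with `phenotypes` (long-format plot table: hybrid, year,
#'   location, replicate, trait, value) and `truth` (per-hybrid additive,
#'   dominance, epistatic and total genetic values plus attributes
#'   `causalAdd`, `causalDom`, `causalPairs`).
#' @export
simulatePhenotypes <- function(pop, spec = pop$spec) {
  stopifnot(inherits(spec, "ArchitectureSpec"))
  set.seed((spec$seed + 500009L) %% 2147483647L)
  M <- dosages(pop$hybrids)
  n <- nrow(M)
  loci <- colnames(M)
  # causal loci must actually vary in the realized population; dominance
  # loci additionally need heterozygosity variation beyond what the dosage
  # carries (in test-cross panels a tester-monomorphic locus has het == dosage)
  colVar <- apply(M, 2, var)
  hetVar <- apply(M == 1, 2, var)
  hetDosCov <- vapply(seq_along(loci), function(j)
    cov(as.numeric(M[, j] == 1), M[, j]), numeric(1))
  devVar <- hetVar - ifelse(colVar > 0, hetDosCov^2 / colVar, 0)
  polyAdd <- loci[colVar > 0]
  polyDom <- loci[devVar > 1e-12]
  if (length(polyAdd) < spec$nCausalAdd || length(polyDom) < spec$nCausalDom)
    stop("not enough polymorphic loci for the requested causal architecture")
  causalAdd <- sort(sample(polyAdd, spec$nCausalAdd))
  causalDom <- sort(sample(polyDom, spec$nCausalDom))
  Zc <- scale(M, center = TRUE, scale = FALSE)

  gA <- if (spec$nCausalAdd > 0)
    drop(Zc[, causalAdd, drop = FALSE] %*% rnorm(spec$nCausalAdd)) else numeric(n)
  gD <- numeric(n)
  if (spec$nCausalDom > 0) {
    deff <- rnorm(spec$nCausalDom)
    for (j in seq_len(spec$nCausalDom)) {
      hd <- .het_deviation(M, causalDom[j])
      gD <- gD + hd$dev * deff[j]
      gA <- gA + hd$bleed * deff[j]   # additive-direction part of the indicator
    }
  }
  gE <- numeric(n)
  pairs <- NULL
  if (spec$nCausalEpiPairs > 0) {
    pairIdx <- matrix(sample(loci, 2 * spec$nCausalEpiPairs, replace = FALSE),
                      ncol = 2)
    types <- rep_len(spec$epistasisTypes, spec$nCausalEpiPairs)
    eeff <- rnorm(spec$nCausalEpiPairs)
    code <- function(locus, kind) {
      if (kind == "z") Zc[, locus] else .het_deviation(M, locus)$dev
    }
    for (q in seq_len(spec$nCausalEpiPairs)) {
      k1 <- if (types[q] %in% c("AA", "AD")) "z" else "w"
      k2 <- if (types[q] == "AA") "z" else "w"
      v <- code(pairIdx[q, 1], k1) * code(pairIdx[q, 2], k2)
      gE <- gE + (v - mean(v)) * eeff[q]
    }
    pairs <- data.frame(locus1 = pairIdx[, 1], locus2 = pairIdx[, 2],
                        type = types, stringsAsFactors = FALSE)
  }

  gA <- .scale_to(gA, spec$targetH2)
  gD <- .scale_to(gD, spec$targetD2)
  gE <- .scale_to(gE, spec$epistasisShare)
  g <- gA + gD + gE
  truth <- data.frame(hybrid = rownames(M), additive = gA, dominance = gD,
                      epistatic = gE, total = g, stringsAsFactors = FALSE)
  attr(truth, "causalAdd") <- causalAdd
  attr(truth, "causalDom") <- causalDom
  attr(truth, "causalPairs") <- pairs

  plotsPerHybrid <- table(unlist(pop$yearHybrids)) *
    spec$locationsPerYear * spec$replicates
  rbar <- mean(plotsPerHybrid)
  veMean <- max(0, 1 - spec$targetH2 - spec$targetD2 - spec$epistasisShare)
  plotSd <- sqrt(veMean * rbar)

  gv <- setNames(g, rownames(M))
  years <- spec$years
  yearEff <- setNames(rnorm(length(years), 0, spec$yearSd), as.character(years))
  locs <- sprintf("L%d", seq_len(spec$locationsPerYear))
  recs <- list()
  for (yr in as.character(years)) {
    hy <- pop$yearHybrids[[yr]]
    locEff <- setNames(rnorm(length(locs), 0, spec$locationSd), locs)
    for (lc in locs) {
      for (rp in seq_len(spec$replicates)) {
        recs[[length(recs) + 1L]] <- data.frame(
          hybrid = hy, year = as.integer(yr), location = lc, replicate = rp,
          trait = spec$traitName,
          value = gv[hy] + yearEff[[yr]] + locEff[[lc]] +
            rnorm(length(hy), 0, plotSd),
          stringsAsFactors = FALSE)
      }
    }
  }
  phen <- do.call(rbind, recs)
  rownames(phen) <- NULL
  list(phenotypes = phen, truth = truth)
}

#' Per-hybrid, per-year phenotype means as benchmark records
#'
#' Aggregates the plot table to one record per hybrid x year (mean over
#' locations and replicates), with record ids `hybrid@year` — the input
#' shape expected by [runBenchmark()] and the fold planners.
#'
#' @param phenotypes plot table from [simulatePhenotypes()] (or real data in
#'   the same long format).
#' @return data.frame with id, hybrid, year, value.
#' @export
yearMeans <- function(phenotypes) {
  agg <- aggregate(value ~ hybrid + year, phenotypes, mean)
  data.frame(id = paste0(agg$hybrid, "@", agg$year), hybrid = agg$hybrid,
             year = agg$year, value = agg$value, stringsAsFactors = FALSE)
}

#' Write a simulated dataset as CSV files
#'
#' Emits `<dir>/genotypes.csv` (hybrid dosage matrix), `parents.csv`,
#' `pedigree.csv`, `phenotypes.csv` and `truth.csv`.
#'
#' @param pop population from [simulatePopulation()].
#' @param sim result of [simulatePhenotypes()].
#' @param dir output directory (created if needed).
#' @export
writeSimulation <- function(pop, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenotypes(pop$hybrids, file.path(dir, "genotypes.csv"))
  writeGenotypes(pop$parents, file.path(dir, "parents.csv"))
  write.csv(pop$pedigree, file.path(dir, "pedigree.csv"), row.names = FALSE)
  write.csv(sim$phenotypes, file.path(dir, "phenotypes.csv"), row.names = FALSE)
  write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
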