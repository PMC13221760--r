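# shared fixture builders (everything is generated in code)

randomMarkers <- function(n, m, seed = 1, probs = c(0.25, 0.5, 0.25),
                          prefix = "i") {
  set.seed(seed)
  MarkerMatrix(matrix(sample(0:2, n * m, TRUE, prob = probs), n, m,
                      dimnames = list(sprintf("%s%04d", prefix, seq_len(n)),
                                      sprintf("s%04d", seq_len(m)))))
}

# moderate fixed hyperparameters for untuned boosted fits in tests
testBoostParams <- function(nTrees = 150) {
  list(nTrees = nTrees, learningRate = 0.1, maxLeaves = 31, minSamplesLeaf = 5,
       featureFraction = 0.8, rowFraction = 0.8, l1 = 0, l2 = 1)
}

writeTestVcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("1", "100", "snp1", "A", "T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "snp2", "G", "C", ".", "PASS", ".", "GT",
          "0/1", "1/1", "./.", sep = "\t")
  ), path)
  path
}

writeMultiallelicVcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("1", "100", "snp1", "A", "T,C", ".", "PASS", ".", "GT",
          "0/1", "1/2", sep = "\t"),
    paste("1", "200", "snp2", "G", "C", ".", "PASS", ".", "GT",
          "0/0", "0/1", sep = "\t")
  ), path)
  path
}

# small single-year test-cross spec used across tests
testCrossSpec <- function(seed, nLines = 60, nTesters = 5, nLoci = 120, ...) {
  extra <- list(...)
  if (!"nCausalAdd" %in% names(extra)) extra$nCausalAdd <- max(2L, nLoci %/% 4L)
  if (!"nCausalDom" %in% names(extra)) extra$nCausalDom <- max(1L, nLoci %/% 8L)
  do.call(architectureSpec,
          c(list(nLines = nLines, nTesters = nTesters, nLoci = nLoci,
                 years = 2021L, locationsPerYear = 2L, replicates = 2L,
                 seed = seed), extra))
}
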