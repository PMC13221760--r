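#' Reference-allele frequencies per locus
#'
#' `p_i` is the mean non-missing dosage at locus i divided by 2. Computed by
#' default from all genotyped individuals (training candidates included),
#' since candidate genotypes are available at prediction time in genomic
#' selection; pass a row subset to restrict to the training set.
#'
#' @param M a [MarkerMatrix-class].
#' @param individuals optional ids to restrict the estimate to.
#' @return named numeric vector of frequencies in `[0, 1]`.
#' @export
alleleFrequencies <- function(M, individuals = NULL) {
  d <- dosages(M)
  if (!is.null(individuals)) d <- d[individuals, , drop = FALSE]
  n_obs <- colSums(!is.na(d))
  if (any(n_obs == 0))
    stop("all calls missing at locus/loci: ",
         paste(head(colnames(d)[n_obs == 0], 5), collapse = ", "))
  colMeans(d, na.rm = TRUE) / 2
}

#' Filter loci on minor allele frequency
#'
#' Removes loci whose minor allele frequency is below `threshold`; a locus
#' with MAF exactly at the threshold is retained.
#'
#' @param M a [MarkerMatrix-class].
#' @param threshold MAF cutoff in `[0, 0.5]` (default 0.01, i.e. loci with
#'   MAF below 1\% are dropped).
#' @return the filtered [MarkerMatrix-class]; attribute `"report"` carries a
#'   data.frame of all loci with their MAF and retention status.
#' @export
filterMAF <- function(M, threshold = 0.01) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  p <- alleleFrequencies(M)
  maf <- pmin(p, 1 - p)
  keep <- maf >= threshold
  if (!any(keep)) warning("no loci retained at MAF threshold ", threshold)
  out <- MarkerMatrix(dosages(M)[, keep, drop = FALSE],
                      fractional = M@fractional)
  attr(out, "report") <- data.frame(locus = locusIds(M), maf = unname(maf),
                                    retained = unname(keep))
  out
}

#' Impute missing dosages to the column mean
#'
#' Each missing call is replaced by `2 p_i` (the mean dosage), the neutral
#' choice for both the centered encodings and the tree learner.
#'
#' @param M a [MarkerMatrix-class].
#' @param p frequencies from [alleleFrequencies()]; estimated from `M` when
#'   omitted.
#' @return numeric dosage matrix with no missing values.
#' @export
imputeDosages <- function(M, p = alleleFrequencies(M)) {
  d <- dosages(M)
  if (length(p) != ncol(d)) stop("frequency vector length must match locus count")
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- 2 * p[idx[, 2]]
  d
}

#' Additive-centered design matrix Z
#'
#' `Z_ij = M_ij - 2 p_j`: dosages centered by twice the allele frequency.
#' Missing dosages are mean-imputed first, so a column whose frequency was
#' estimated from the same matrix sums to zero.
#'
#' @param M a [MarkerMatrix-class].
#' @param p allele frequencies (defaults to estimates from `M`).
#' @return numeric n x m matrix with individual/locus dimnames; attribute
#'   `"frequencies"` records the p used.
#' @export
additiveDesign <- function(M, p = alleleFrequencies(M)) {
  d <- imputeDosages(M, p)
  Z <- sweep(d, 2, 2 * p)
  attr(Z, "frequencies") <- p
  Z
}

#' Dominance-deviation design matrix W
#'
#' Vitezica (2013) coding per locus: dosage 0 -> `-2p^2`, dosage 1 -> `2pq`,
#' dosage 2 -> `-2q^2` with `q = 1 - p`. Monomorphic loci give all-zero
#' columns. Missing dosages are mean-imputed to `2p` first; a fractional
#' (expected) dosage d is coded by linear interpolation of the three states,
#' equivalently `2pq - (coding slope)` — concretely the piecewise-linear
#' interpolation between the flanking integer codes.
#'
#' The Vitezica columns are mean-zero only under exact Hardy-Weinberg
#' proportions; by default W is left as coded (test-cross populations
#' deviate from HWE by design). `center = TRUE` subtracts column means.
#'
#' @inheritParams additiveDesign
#' @param center subtract column means after coding.
#' @return numeric n x m matrix; attribute `"frequencies"` records p.
#' @export
dominanceDesign <- function(M, p = alleleFrequencies(M), center = FALSE) {
  d <- imputeDosages(M, p)
  q <- 1 - p
  c0 <- -2 * p^2
  c1 <- 2 * p * q
  c2 <- -2 * q^2
  W <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  for (j in seq_len(ncol(d))) {
    x <- d[, j]
    lo <- x <= 1
    # piecewise-linear in the dosage between the integer anchor codes
    W[lo, j]  <- c0[j] + (c1[j] - c0[j]) * x[lo]
    W[!lo, j] <- c1[j] + (c2[j] - c1[j]) * (x[!lo] - 1)
  }
  if (center) W <- sweep(W, 2, colMeans(W))
  attr(W, "frequencies") <- p
  W
}

#' Concatenate Z and W into the 2NP feature matrix
#'
#' Horizontal concatenation `[Z | W]`: the first m columns are the additive
#' encoding (names suffixed `_A`), the last m the dominance encoding
#' (suffixed `_D`), with per-column block labels retained for downstream
#' attribution aggregation.
#'
#' @param Z additive design from [additiveDesign()].
#' @param W dominance design from [dominanceDesign()].
#' @return a [TwoNPMatrix-class].
#' @export
concat2NP <- function(Z, W) {
  if (!identical(dim(Z), dim(W)))
    stop(sprintf("Z is %dx%d but W is %dx%d", nrow(Z), ncol(Z), nrow(W), ncol(W)))
  if (!identical(rownames(Z), rownames(W))) {
    bad <- which(rownames(Z) != rownames(W))[1]
    stop(sprintf("individual id mismatch at row %d: '%s' vs '%s'",
                 bad, rownames(Z)[bad], rownames(W)[bad]))
  }
  if (!identical(colnames(Z), colnames(W))) {
    bad <- which(colnames(Z) != colnames(W))[1]
    stop(sprintf("locus id mismatch at column %d: '%s' vs '%s'",
                 bad, colnames(Z)[bad], colnames(W)[bad]))
  }
  loci <- colnames(Z)
  f <- cbind(Z, W)
  colnames(f) <- c(paste0(loci, "_A"), paste0(loci, "_D"))
  pz <- attr(Z, "frequencies")
  if (is.null(pz)) pz <- rep(NA_real_, length(loci))
  new("TwoNPMatrix", features = f,
      blockLabels = rep(c("additive", "dominance"), each = length(loci)),
      sourceLocus = c(loci, loci), frequencies = unname(pz))
}

#' Extract one block of a TwoNPMatrix
#'
#' @param x a [TwoNPMatrix-class].
#' @param block `"additive"` or `"dominance"`.
#' @return the corresponding n x m sub-matrix (original locus ids restored).
#' @export
blockMatrix <- function(x, block = c("additive", "dominance")) {
  block <- match.arg(block)
  sel <- blockLabels(x) == block
  out <- features(x)[, sel, drop = FALSE]
  colnames(out) <- x@sourceLocus[sel]
  out
}

#' Write encoded matrices as delimited files
#'
#' Emits `<prefix>_Z.csv`, `<prefix>_W.csv` and `<prefix>_2NP.csv`; the 2NP
#' header carries the `_A`/`_D` block suffixes.
#'
#' @param x a [TwoNPMatrix-class].
#' @param prefix output path prefix.
#' @return the three paths, invisibly.
#' @export
writeEncodings <- function(x, prefix) {
  paths <- paste0(prefix, c("_Z.csv", "_W.csv", "_2NP.csv"))
  mats <- list(blockMatrix(x, "additive"), blockMatrix(x, "dominance"), features(x))
  for (i in 1:3) {
    df <- data.frame(id = rownames(mats[[i]]), mats[[i]], check.names = FALSE)
    write.table(df, paths[i], sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}
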