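#' Additive genomic relationship matrix (VanRaden)
#'
#' `A = Z Z' / sum_i 2 p_i (1 - p_i)`: the cross-product of the
#' additive-centered encoding scaled by the expected marker variance under
#' Hardy-Weinberg proportions, so the mean diagonal is near 1 in an
#' unstructured population.
#'
#' @param Z additive design from [additiveDesign()] (or any centered n x m
#'   matrix with individual rownames).
#' @param p allele frequencies used to build `Z` (defaults to its
#'   `"frequencies"` attribute).
#' @return a [GRM-class] of kind `"additive"`.
#' @export
additiveGRM <- function(Z, p = attr(Z, "frequencies")) {
  if (is.null(p)) stop("allele frequencies required (none attached to Z)")
  if (length(p) != ncol(Z)) stop("frequency vector length must match loci")
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop("zero scaling denominator: all loci are monomorphic")
  A <- tcrossprod(Z) / denom
  A <- (A + t(A)) / 2
  new("GRM", matrix = A, kind = "additive", denominator = denom)
}

#' Dominance genomic relationship matrix (Vitezica)
#'
#' `D = W W' / sum_i 4 p_i^2 q_i^2` with `q = 1 - p`.
#'
#' @param W dominance design from [dominanceDesign()].
#' @param p allele frequencies used to build `W`.
#' @return a [GRM-class] of kind `"dominance"`.
#' @export
dominanceGRM <- function(W, p = attr(W, "frequencies")) {
  if (is.null(p)) stop("allele frequencies required (none attached to W)")
  if (length(p) != ncol(W)) stop("frequency vector length must match loci")
  q <- 1 - p
  denom <- sum(4 * p^2 * q^2)
  if (denom <= 0) stop("zero scaling denominator: all loci are monomorphic")
  D <- tcrossprod(W) / denom
  D <- (D + t(D)) / 2
  new("GRM", matrix = D, kind = "dominance", denominator = denom)
}

#' Write a GRM as a delimited square matrix
#'
#' @param x a [GRM-class].
#' @param path output CSV (id header row and id first column).
#' @export
writeGRM <- function(x, path) {
  K <- grmMatrix(x)
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset a GRM to a set of individuals
#'
#' @param x a [GRM-class].
#' @param rows,cols individual ids (cols defaults to rows). Returns the raw
#'   sub-matrix (a rectangular cross-relationship block when `rows != cols`).
#' @return numeric matrix.
#' @export
grmBlock <- function(x, rows, cols = rows) {
  K <- grmMatrix(x)
  miss <- setdiff(c(rows, cols), rownames(K))
  if (length(miss)) stop("ids absent from GRM: ", paste(head(miss, 5), collapse = ", "))
  K[rows, cols, drop = FALSE]
}
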