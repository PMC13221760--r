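#' @import methods
#' @importFrom stats var sd cor cov rnorm runif rbinom optimize lm rstandard
#'   model.matrix setNames aggregate pnorm dnorm coef median dist predict
#' @importFrom utils head read.csv write.csv write.table
#' @useDynLib twonp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' MarkerMatrix: individuals-by-loci SNP dosage matrix
#'
#' Container for biallelic SNP dosages coded 0/1/2 (count of the reference
#' allele), with unique individual and locus identifiers. Missing genotypes
#' are stored as `NA`; they are preserved at I/O time and imputed to twice
#' the allele frequency only when an encoding is built. Hybrid matrices
#' produced from non-inbred parents may carry fractional expected dosages,
#' in which case `fractional` is `TRUE`.
#'
#' @slot dosages numeric matrix, rows = individuals, columns = loci; entries
#'   in `[0, 2]` or `NA`.
#' @slot fractional logical; `TRUE` when non-integer expected dosages are
#'   allowed (hybrids of heterozygous parents).
#' @export
setClass("MarkerMatrix",
  representation(dosages = "matrix", fractional = "logical"),
  prototype(fractional = FALSE)
)

setValidity("MarkerMatrix", function(object) {
  d <- object@dosages
  if (!is.numeric(d)) return("dosages must be a numeric matrix")
  if (nrow(d) < 1L || ncol(d) < 1L) return("need at least one individual and one locus")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    return("dosages must carry individual (row) and locus (column) names")
  if (anyDuplicated(rownames(d))) return("duplicated individual ids")
  if (anyDuplicated(colnames(d))) return("duplicated locus ids")
  v <- d[!is.na(d)]
  if (length(v) && (min(v) < 0 || max(v) > 2))
    return("dosages must lie in [0, 2]")
  if (!object@fractional && length(v) && any(v != round(v)))
    return("non-integer dosages present; use fractional = TRUE for expected dosages")
  TRUE
})

#' TwoNPMatrix: concatenated additive + dominance feature matrix
#'
#' The 2NP representation `[Z | W]`: the first m columns are the
#' additive-centered encoding Z, the last m the dominance-deviation encoding
#' W, with per-column block labels and source locus ids. Column names carry
#' `_A` / `_D` suffixes.
#'
#' @slot features numeric matrix, n x 2m.
#' @slot blockLabels character, one of `"additive"`/`"dominance"` per column.
#' @slot sourceLocus character, originating locus id per column.
#' @slot frequencies numeric, reference-allele frequencies used to build Z/W.
#' @export
setClass("TwoNPMatrix",
  representation(features = "matrix", blockLabels = "character",
                 sourceLocus = "character", frequencies = "numeric")
)

setValidity("TwoNPMatrix", function(object) {
  f <- object@features
  m2 <- ncol(f)
  if (m2 %% 2L != 0L) return("feature count must be even (m additive + m dominance)")
  m <- m2 %/% 2L
  if (length(object@blockLabels) != m2) return("one block label per column required")
  if (!all(object@blockLabels[seq_len(m)] == "additive") ||
      !all(object@blockLabels[m + seq_len(m)] == "dominance"))
    return("columns must be m additive then m dominance")
  if (length(object@sourceLocus) != m2) return("one source locus per column required")
  if (length(object@frequencies) != m) return("one frequency per locus required")
  if (is.null(rownames(f))) return("features must carry individual ids")
  TRUE
})

#' GRM: genomic relationship matrix
#'
#' Symmetric positive semidefinite n x n relationship matrix, tagged as
#' additive (VanRaden) or dominance (Vitezica), with the scaling denominator
#' retained.
#'
#' @slot matrix numeric n x n matrix with individual ids as dimnames.
#' @slot kind `"additive"` or `"dominance"`.
#' @slot denominator numeric scalar used to scale the cross-product.
#' @export
setClass("GRM",
  representation(matrix = "matrix", kind = "character", denominator = "numeric")
)

setValidity("GRM", function(object) {
  K <- object@matrix
  if (nrow(K) != ncol(K)) return("GRM must be square")
  if (is.null(rownames(K)) || !identical(rownames(K), colnames(K)))
    return("GRM must carry identical row/column individual ids")
  if (!object@kind %in% c("additive", "dominance"))
    return("kind must be 'additive' or 'dominance'")
  asym <- max(abs(K - t(K)))
  if (asym >= 1e-10) return(sprintf("GRM not symmetric (max asymmetry %g)", asym))
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8 * sum(diag(K)) / nrow(K))
    return(sprintf("GRM not positive semidefinite (min eigenvalue %g)", ev))
  TRUE
})

#' VarianceComponents: REML estimates for one trait
#'
#' Additive, dominance and residual variance components (trait-variance
#' units) together with the restricted log-likelihood at the optimum. `vd`
#' is zero for an additive-only fit.
#'
#' @slot va,vd,ve non-negative numeric scalars.
#' @slot logLik restricted log-likelihood at the optimum.
#' @export
setClass("VarianceComponents",
  representation(va = "numeric", vd = "numeric", ve = "numeric",
                 logLik = "numeric")
)

setValidity("VarianceComponents", function(object) {
  if (object@va < 0 || object@vd < 0 || object@ve < 0)
    return("variance components must be non-negative")
  if (object@va + object@vd + object@ve <= 0)
    return("total phenotypic variance must be positive")
  TRUE
})

#' GBLUPFit: fitted genomic mixed model
#'
#' Result of [remlFit()]: variance components, GLS fixed-effect estimates,
#' per-individual BLUPs for each fitted kernel, and the training-side
#' weights needed to extend predictions to unphenotyped individuals.
#'
#' @slot b fixed-effect estimates.
#' @slot blups list of per-kernel BLUP vectors (named by kernel kind).
#' @slot vc [VarianceComponents-class].
#' @slot trainIds individual ids, in model order.
#' @slot kernelKinds kinds of the fitted kernels, in order.
#' @slot w numeric; `V^{-1}(y - Xb)` on the training side.
#' @slot X fixed-effect design used.
#' @slot y phenotype vector used.
#' @slot trace data.frame convergence trace (iteration, components, logLik).
#' @slot converged logical.
#' @export
setClass("GBLUPFit",
  representation(b = "numeric", blups = "list", vc = "VarianceComponents",
                 trainIds = "character", kernelKinds = "character",
                 w = "numeric", X = "matrix", y = "numeric",
                 trace = "data.frame", converged = "logical")
)

#' BoostedModel: fitted gradient-boosted tree ensemble
#'
#' Wraps the fitted booster with everything needed for deterministic
#' double-precision prediction and exact TreeSHAP attribution: the parsed
#' tree table, base score, feature names, optional 2NP block labels, the
#' training ids, and the hyperparameter tuning log.
#'
#' @slot booster the backend booster object.
#' @slot params hyperparameters used for the final fit.
#' @slot featureNames training feature columns, in order.
#' @slot blockLabels `"additive"`/`"dominance"` per feature (length 0 when
#'   trained on raw dosages).
#' @slot trainIds row ids of the training set.
#' @slot baseScore double-precision global bias of the ensemble.
#' @slot trees parsed tree structure (data.frame).
#' @slot tuningLog data.frame of tuning iterations (0 rows if untuned).
#' @export
setClass("BoostedModel",
  representation(booster = "ANY", params = "list", featureNames = "character",
                 blockLabels = "character", trainIds = "character",
                 baseScore = "numeric", trees = "data.frame",
                 tuningLog = "data.frame")
)

setValidity("BoostedModel", function(object) {
  if (length(object@blockLabels) &&
      length(object@blockLabels) != length(object@featureNames))
    return("blockLabels must be empty or one per feature")
  TRUE
})

#' FoldPlan: train/test folds for one validation scheme
#'
#' Ordered list of folds, each a list with character vectors `train` and
#' `test` (record ids) plus a `meta` list (test year, tester group,
#' repetition, ...). All schemes guarantee `train` and `test` are disjoint
#' and `test` is non-empty.
#'
#' @slot scheme scheme name.
#' @slot folds list of folds.
#' @export
setClass("FoldPlan",
  representation(scheme = "character", folds = "list")
)

setValidity("FoldPlan", function(object) {
  for (i in seq_along(object@folds)) {
    f <- object@folds[[i]]
    if (!all(c("train", "test") %in% names(f)))
      return(sprintf("fold %d lacks train/test", i))
    if (length(f$test) == 0L) return(sprintf("fold %d has empty test set", i))
    if (length(intersect(f$train, f$test)))
      return(sprintf("fold %d has overlapping train and test ids", i))
  }
  TRUE
})

#' ShapSummary: aggregated feature attributions
#'
#' Per-feature mean absolute SHAP scores, the additive/dominance block
#' proportions of total absolute attribution, and the top-k ranking.
#'
#' @slot perFeature data.frame (feature, block, meanAbs), full ranking order.
#' @slot blockProportions named numeric (additive, dominance), sums to 1
#'   when defined.
#' @slot topK data.frame of the leading k features.
#' @slot defined logical; `FALSE` when all attributions are zero.
#' @export
setClass("ShapSummary",
  representation(perFeature = "data.frame", blockProportions = "numeric",
                 topK = "data.frame", defined = "logical")
)
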