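#' Accessors for twonp containers
#'
#' `dosages()`, `individualIds()` and `locusIds()` extract the dosage matrix
#' and its identifiers from a [MarkerMatrix-class]; `features()` and
#' `blockLabels()` extract the feature matrix and additive/dominance labels
#' from a [TwoNPMatrix-class] or [BoostedModel-class]; `grmMatrix()` and
#' `grmKind()` access a [GRM-class]; `varComp()` returns the
#' [VarianceComponents-class] of a [GBLUPFit-class]; `folds()` and
#' `scheme()` access a [FoldPlan-class].
#'
#' @param x object.
#' @return the corresponding slot content.
#' @name accessors
#' @aliases dosages individualIds locusIds features blockLabels grmMatrix
#'   grmKind varComp folds scheme
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))
#' @rdname accessors
#' @export
setGeneric("locusIds", function(x) standardGeneric("locusIds"))
#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname accessors
#' @export
setGeneric("blockLabels", function(x) standardGeneric("blockLabels"))
#' @rdname accessors
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))
#' @rdname accessors
#' @export
setGeneric("grmKind", function(x) standardGeneric("grmKind"))
#' @rdname accessors
#' @export
setGeneric("varComp", function(x) standardGeneric("varComp"))
#' @rdname accessors
#' @export
setGeneric("folds", function(x) standardGeneric("folds"))
#' @rdname accessors
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))

#' @rdname accessors
#' @export
setMethod("dosages", "MarkerMatrix", function(x) x@dosages)
#' @rdname accessors
#' @export
setMethod("individualIds", "MarkerMatrix", function(x) rownames(x@dosages))
#' @rdname accessors
#' @export
setMethod("locusIds", "MarkerMatrix", function(x) colnames(x@dosages))
#' @rdname accessors
#' @export
setMethod("individualIds", "TwoNPMatrix", function(x) rownames(x@features))
#' @rdname accessors
#' @export
setMethod("features", "TwoNPMatrix", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("blockLabels", "TwoNPMatrix", function(x) x@blockLabels)
#' @rdname accessors
#' @export
setMethod("blockLabels", "BoostedModel", function(x) x@blockLabels)
#' @rdname accessors
#' @export
setMethod("grmMatrix", "GRM", function(x) x@matrix)
#' @rdname accessors
#' @export
setMethod("grmKind", "GRM", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("individualIds", "GRM", function(x) rownames(x@matrix))
#' @rdname accessors
#' @export
setMethod("varComp", "GBLUPFit", function(x) x@vc)
#' @rdname accessors
#' @export
setMethod("folds", "FoldPlan", function(x) x@folds)
#' @rdname accessors
#' @export
setMethod("scheme", "FoldPlan", function(x) x@scheme)

#' @describeIn MarkerMatrix-class dimensions (individuals, loci).
#' @param x a `MarkerMatrix`.
#' @export
setMethod("dim", "MarkerMatrix", function(x) dim(x@dosages))

setMethod("show", "MarkerMatrix", function(object) {
  d <- object@dosages
  cat(sprintf("MarkerMatrix: %d individuals x %d loci\n", nrow(d), ncol(d)))
  nm <- sum(is.na(d))
  cat(sprintf("  missing calls: %d (%.2f%%)%s\n", nm, 100 * nm / length(d),
              if (object@fractional) "; fractional expected dosages allowed" else ""))
})

setMethod("show", "TwoNPMatrix", function(object) {
  m <- ncol(object@features) %/% 2L
  cat(sprintf("TwoNPMatrix: %d individuals x %d features (%d additive + %d dominance)\n",
              nrow(object@features), 2L * m, m, m))
})

setMethod("show", "GRM", function(object) {
  cat(sprintf("GRM (%s): %d individuals, scaling denominator %.6g, mean diagonal %.4f\n",
              object@kind, nrow(object@matrix), object@denominator,
              mean(diag(object@matrix))))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents: Va = %.4g, Vd = %.4g, Ve = %.4g (logLik %.4f)\n",
              object@va, object@vd, object@ve, object@logLik))
})

setMethod("show", "GBLUPFit", function(object) {
  cat(sprintf("GBLUPFit: %d individuals, kernels [%s], %s\n",
              length(object@trainIds), paste(object@kernelKinds, collapse = ", "),
              if (object@converged) "converged" else "NOT converged"))
  show(object@vc)
})

setMethod("show", "BoostedModel", function(object) {
  cat(sprintf("BoostedModel: %d features%s, %d training rows, %d trees\n",
              length(object@featureNames),
              if (length(object@blockLabels)) " (2NP additive/dominance blocks)" else "",
              length(object@trainIds), max(object@trees$Tree) + 1L))
  if (nrow(object@tuningLog))
    cat(sprintf("  tuned over %d SMBO iterations (best inner-CV MSE %.4g)\n",
                nrow(object@tuningLog), min(object@tuningLog$score)))
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan '%s': %d folds\n", object@scheme, length(object@folds)))
  sizes <- vapply(object@folds, function(f) length(f$test), integer(1))
  cat(sprintf("  test-set sizes: %s\n",
              paste(range(sizes), collapse = "-")))
})

setMethod("show", "ShapSummary", function(object) {
  cat("ShapSummary\n")
  if (object@defined) {
    cat(sprintf("  block proportions: additive %.3f, dominance %.3f\n",
                object@blockProportions[["additive"]],
                object@blockProportions[["dominance"]]))
  } else cat("  undefined (all attributions zero)\n")
  cat(sprintf("  top feature: %s\n",
              if (nrow(object@topK)) object@topK$feature[1] else "<none>"))
})
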