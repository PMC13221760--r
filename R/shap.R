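#' Exact TreeSHAP attributions for a boosted model
#'
#' Computes per-row, per-feature Shapley attributions by the path-dependent
#' TreeSHAP algorithm, evaluated in double precision over the model's parsed
#' tree structure. Local accuracy holds exactly: for every row, the
#' attributions plus the bias column equal the model prediction (as returned
#' by [predictBoosted()]) to numerical round-off. Features never used in a
#' split receive zero attribution everywhere.
#'
#' @param model a [BoostedModel-class].
#' @param features evaluation rows (named columns covering the training
#'   columns; typically the training set of the active fold).
#' @return numeric matrix `n x (p + 1)`: one column per feature plus a final
#'   `"BIAS"` column holding the expected model output.
#' @export
shapAttributions <- function(model, features) {
  X <- .align_features(model, features)
  tr <- model@trees
  ord <- order(tr$Tree, tr$Node)
  tr <- tr[ord, ]
  trees <- unique(tr$Tree)
  counts <- as.integer(table(factor(tr$Tree, levels = trees)))
  offsets <- as.integer(c(0L, cumsum(counts)))
  isLeaf <- tr$Feature == "Leaf"
  featIdx <- match(tr$Feature, model@featureNames) - 1L
  featIdx[isLeaf] <- -1L
  if (any(is.na(featIdx) & !isLeaf))
    stop("tree references unknown feature(s)")
  childNum <- function(v) {
    out <- rep(0L, length(v))
    ok <- !is.na(v)
    out[ok] <- as.integer(sub(".*-", "", v[ok]))
    out
  }
  phi <- .treeshap_cpp(X, offsets, featIdx,
                       ifelse(is.na(tr$Split), 0, tr$Split),
                       childNum(tr$Yes), childNum(tr$No), childNum(tr$Missing),
                       tr$Cover, ifelse(isLeaf, tr$Gain, 0))
  # the bias column carries the per-tree expectations plus the global base score
  phi[, ncol(phi)] <- phi[, ncol(phi)] + model@baseScore
  dimnames(phi) <- list(rownames(X), c(model@featureNames, "BIAS"))
  phi
}

#' Aggregate attributions into additive vs dominance block proportions
#'
#' Importance per feature is the mean absolute attribution across evaluated
#' rows; the proportion of a block is its share of the summed importances.
#' Proportions sum to 1 whenever any attribution is nonzero.
#'
#' @param attributions matrix from [shapAttributions()] (a `"BIAS"` column,
#'   if present, is dropped).
#' @param blockLabels `"additive"`/`"dominance"` per feature column, e.g.
#'   [blockLabels()] of the [TwoNPMatrix-class] or the model.
#' @return named numeric `c(additive = , dominance = )`; both `NA` with
#'   attribute `defined = FALSE` when all attributions are zero.
#' @export
blockContributions <- function(attributions, blockLabels) {
  A <- .drop_bias(attributions)
  if (length(blockLabels) != ncol(A))
    stop("need one block label per feature column")
  imp <- colMeans(abs(A))
  tot <- sum(imp)
  if (tot == 0) {
    warning("all attributions are zero; block proportions undefined")
    out <- c(additive = NA_real_, dominance = NA_real_)
    attr(out, "defined") <- FALSE
    return(out)
  }
  out <- c(additive = sum(imp[blockLabels == "additive"]) / tot,
           dominance = sum(imp[blockLabels == "dominance"]) / tot)
  attr(out, "defined") <- TRUE
  out
}

.drop_bias <- function(attributions) {
  cn <- colnames(attributions)
  if (!is.null(cn) && cn[length(cn)] == "BIAS")
    attributions[, -ncol(attributions), drop = FALSE]
  else attributions
}

#' Rank markers by mean absolute attribution
#'
#' @param attributions matrix from [shapAttributions()].
#' @param blockLabels block label per feature column (optional; `NA` labels
#'   are reported when omitted).
#' @param k number of top features to keep (default 20).
#' @return data.frame (feature, block, meanAbs), sorted non-increasing with
#'   ties broken by original column order.
#' @export
topMarkers <- function(attributions, blockLabels = NULL, k = 20L) {
  A <- .drop_bias(attributions)
  if (k > ncol(A)) stop("k exceeds the number of features")
  imp <- colMeans(abs(A))
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = colnames(A)[ord][seq_len(k)],
             block = if (is.null(blockLabels)) NA_character_ else blockLabels[ord][seq_len(k)],
             meanAbs = unname(imp[ord])[seq_len(k)],
             stringsAsFactors = FALSE)
}

#' Full SHAP summary for a fitted 2NP model
#'
#' Convenience wrapper: attributions on the supplied rows, block
#' proportions, and the top-k ranking, packaged as a [ShapSummary-class].
#'
#' @param model a [BoostedModel-class] trained on a 2NP matrix (with block
#'   labels).
#' @param features evaluation rows.
#' @param k top-k size.
#' @return a [ShapSummary-class].
#' @export
shapSummary <- function(model, features, k = 20L) {
  if (!length(blockLabels(model)))
    stop("model carries no block labels; train it on a 2NP matrix")
  phi <- shapAttributions(model, features)
  bp <- blockContributions(phi, blockLabels(model))
  A <- .drop_bias(phi)
  imp <- colMeans(abs(A))
  ord <- order(-imp, seq_along(imp))
  per <- data.frame(feature = colnames(A)[ord],
                    block = blockLabels(model)[ord],
                    meanAbs = unname(imp[ord]), stringsAsFactors = FALSE)
  new("ShapSummary", perFeature = per,
      blockProportions = if (isTRUE(attr(bp, "defined"))) c(bp) else c(additive = 0, dominance = 0),
      topK = per[seq_len(min(k, nrow(per))), ],
      defined = isTRUE(attr(bp, "defined")))
}

#' SHAP interaction values for the leading features (optional utility)
#'
#' Pairwise SHAP interaction values from the backend's tree-path algorithm,
#' reported for the top-k features by mean absolute attribution. Interaction
#' values are quadratic in the feature count and cubic-ish in memory, so
#' this utility caps both the evaluated rows and the feature count; it is
#' not part of the default pipeline and should be read as indicative, not
#' as evidence of causal interaction architecture.
#'
#' @param model a [BoostedModel-class].
#' @param features evaluation rows.
#' @param k number of leading features to report (default 20).
#' @param maxRows rows to evaluate (default 100; rows beyond this are
#'   dropped with a message).
#' @param maxFeatures hard cap on the model's feature count (the backend
#'   materializes the full p x p interaction tensor).
#' @return list with `pairs` (data.frame: feature1, feature2, meanAbs,
#'   sorted) and `matrix` (k x k mean absolute interaction block).
#' @export
shapInteractions <- function(model, features, k = 20L, maxRows = 100L,
                             maxFeatures = 600L) {
  p <- length(model@featureNames)
  if (p > maxFeatures)
    stop("interaction values need the full ", p, "x", p, " tensor; ",
         "limited to models with at most ", maxFeatures, " features")
  X <- .align_features(model, features)
  if (nrow(X) > maxRows) {
    message("evaluating interactions on the first ", maxRows, " rows")
    X <- X[seq_len(maxRows), , drop = FALSE]
  }
  phi <- shapAttributions(model, X)
  top <- topMarkers(phi, k = min(k, p))$feature
  inter <- predict(model@booster, xgboost::xgb.DMatrix(X, nthread = 1),
                   predinteraction = TRUE)
  dimnames(inter) <- list(rownames(X), c(model@featureNames, "BIAS"),
                          c(model@featureNames, "BIAS"))
  blk <- apply(abs(inter[, top, top, drop = FALSE]), c(2, 3), mean)
  idx <- which(upper.tri(blk), arr.ind = TRUE)
  pairs <- data.frame(feature1 = rownames(blk)[idx[, 1]],
                      feature2 = colnames(blk)[idx[, 2]],
                      meanAbs = blk[idx], stringsAsFactors = FALSE)
  pairs <- pairs[order(-pairs$meanAbs), ]
  rownames(pairs) <- NULL
  list(pairs = pairs, matrix = blk)
}
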