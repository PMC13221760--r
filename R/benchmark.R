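#' Model specifications for benchmarking
#'
#' Constructors returning the fit/predict pair that [runBenchmark()] drives.
#' All four follow the same contract: `fit(markers, train, seed,
#' forbiddenIds)` receives the training records only (the fold's test ids
#' are passed as the leakage guard and any attempt to use them errors), and
#' `predict(fitObj, markers, test)` returns one prediction per test record.
#'
#' `gblupAddModel()` fits single-kernel GBLUP on the VanRaden additive
#' relationship matrix; `gblupAddDomModel()` adds the Vitezica dominance
#' kernel; `boostModel()` fits the tuned gradient-boosted ensemble on raw
#' imputed dosages (`encoding = "raw"`, the LGBM-style baseline) or on the
#' 2NP matrix (`encoding = "2np"`, the 2NP boosted model). Allele
#' frequencies are computed once from all genotyped individuals (candidate
#' genotypes are available at prediction time in genomic selection); pass
#' `trainOnlyFreq = TRUE` to restrict them to each fold's training hybrids.
#'
#' @param trainOnlyFreq estimate allele frequencies from training hybrids
#'   only.
#' @param encoding feature encoding for the boosted model.
#' @param tune run [tuneHyperparameters()] inside the training set.
#' @param nIter,innerFolds,space tuning controls (see
#'   [tuneHyperparameters()]).
#' @param params fixed hyperparameters used when `tune = FALSE`.
#' @return a list with elements `name`, `fit`, `predict`.
#' @name modelSpecs
NULL

.freqs_for <- function(markers, train, trainOnlyFreq) {
  if (trainOnlyFreq) alleleFrequencies(markers, unique(train$hybrid))
  else alleleFrequencies(markers)
}

.record_kernel <- function(K, hybrids, ids) {
  Kr <- K[hybrids, hybrids, drop = FALSE]
  dimnames(Kr) <- list(ids, ids)
  Kr
}

#' @rdname modelSpecs
#' @export
gblupAddModel <- function(trainOnlyFreq = FALSE) {
  list(
    name = "gblup_add",
    fit = function(markers, train, seed = 1L, forbiddenIds = NULL) {
      .assert_no_leakage(train$id, forbiddenIds)
      p <- .freqs_for(markers, train, trainOnlyFreq)
      Z <- additiveDesign(markers, p)
      A <- grmMatrix(additiveGRM(Z, p))
      y <- setNames(train$value, train$id)
      fit <- remlFit(y, list(.record_kernel(A, train$hybrid, train$id)))
      list(fit = fit, A = A, train = train)
    },
    predict = function(obj, markers, test) {
      K <- obj$A[test$hybrid, obj$train$hybrid, drop = FALSE]
      drop(obj$fit@b[1] + varComp(obj$fit)@va * K %*% obj$fit@w)
    }
  )
}

#' @rdname modelSpecs
#' @export
gblupAddDomModel <- function(trainOnlyFreq = FALSE) {
  list(
    name = "gblup_addom",
    fit = function(markers, train, seed = 1L, forbiddenIds = NULL) {
      .assert_no_leakage(train$id, forbiddenIds)
      p <- .freqs_for(markers, train, trainOnlyFreq)
      Z <- additiveDesign(markers, p)
      W <- dominanceDesign(markers, p)
      A <- grmMatrix(additiveGRM(Z, p))
      D <- grmMatrix(dominanceGRM(W, p))
      y <- setNames(train$value, train$id)
      fit <- remlFit(y, list(.record_kernel(A, train$hybrid, train$id),
                             .record_kernel(D, train$hybrid, train$id)))
      list(fit = fit, A = A, D = D, train = train)
    },
    predict = function(obj, markers, test) {
      vc <- varComp(obj$fit)
      KA <- obj$A[test$hybrid, obj$train$hybrid, drop = FALSE]
      KD <- obj$D[test$hybrid, obj$train$hybrid, drop = FALSE]
      drop(obj$fit@b[1] + vc@va * KA %*% obj$fit@w + vc@vd * KD %*% obj$fit@w)
    }
  )
}

.boost_features <- function(markers, p, encoding) {
  if (encoding == "raw") {
    f <- imputeDosages(markers, p)
    list(features = f, blocks = NULL)
  } else {
    x <- concat2NP(additiveDesign(markers, p), dominanceDesign(markers, p))
    list(features = features(x), blocks = blockLabels(x))
  }
}

#' @rdname modelSpecs
#' @export
boostModel <- function(encoding = c("raw", "2np"), tune = TRUE, nIter = 20L,
                       innerFolds = 5L, space = searchSpace(), params = NULL,
                       trainOnlyFreq = FALSE) {
  encoding <- match.arg(encoding)
  if (!tune && is.null(params)) stop("fixed params required when tune = FALSE")
  list(
    name = if (encoding == "2np") "2nplgbm" else "lgbm",
    fit = function(markers, train, seed = 1L, forbiddenIds = NULL) {
      .assert_no_leakage(train$id, forbiddenIds)
      p <- .freqs_for(markers, train, trainOnlyFreq)
      enc <- .boost_features(markers, p, encoding)
      ftr <- enc$features[train$hybrid, , drop = FALSE]
      rownames(ftr) <- train$id
      y <- train$value
      prm <- params
      tl <- NULL
      if (tune) {
        tuned <- tuneHyperparameters(ftr, y, space = space, nIter = nIter,
                                     innerFolds = innerFolds, seed = seed,
                                     forbiddenIds = forbiddenIds)
        prm <- tuned$best
        tl <- tuned$log
      }
      model <- fitBoosted(ftr, y, prm, seed = seed, blockLabels = enc$blocks,
                          tuningLog = tl, forbiddenIds = forbiddenIds)
      list(model = model, p = p, encoding = encoding)
    },
    predict = function(obj, markers, test) {
      enc <- .boost_features(markers, obj$p, obj$encoding)
      fte <- enc$features[test$hybrid, , drop = FALSE]
      rownames(fte) <- test$id
      unname(predictBoosted(obj$model, fte))
    }
  )
}
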