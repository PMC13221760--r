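#' Hyperparameter search space for the boosted learner
#'
#' Bounds and scales for the tuned hyperparameters of the leaf-wise
#' gradient-boosted ensemble: number of trees, learning rate, maximum
#' leaves, minimum samples per leaf, feature- and row-subsampling fractions,
#' and L1/L2 penalties. Log-scaled dimensions are searched in log space;
#' integer dimensions are rounded after decoding.
#'
#' @param nTrees,learningRate,maxLeaves,minSamplesLeaf,featureFraction,rowFraction,l1,l2
#'   length-2 numeric bounds `c(lower, upper)` for each dimension.
#' @return data.frame with one row per dimension (param, lower, upper,
#'   scale, integer, backend name).
#' @export
searchSpace <- function(nTrees = c(100, 2000), learningRate = c(0.005, 0.3),
                        maxLeaves = c(8, 256), minSamplesLeaf = c(5, 100),
                        featureFraction = c(0.3, 1), rowFraction = c(0.5, 1),
                        l1 = c(0, 10), l2 = c(0, 10)) {
  sp <- data.frame(
    param = c("nTrees", "learningRate", "maxLeaves", "minSamplesLeaf",
              "featureFraction", "rowFraction", "l1", "l2"),
    lower = c(nTrees[1], learningRate[1], maxLeaves[1], minSamplesLeaf[1],
              featureFraction[1], rowFraction[1], l1[1], l2[1]),
    upper = c(nTrees[2], learningRate[2], maxLeaves[2], minSamplesLeaf[2],
              featureFraction[2], rowFraction[2], l1[2], l2[2]),
    scale = c("log", "log", "log", "linear", "linear", "linear", "linear", "linear"),
    integer = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  bad <- sp$lower >= sp$upper | !is.finite(sp$lower) | !is.finite(sp$upper)
  if (any(bad)) stop("invalid bounds for: ", paste(sp$param[bad], collapse = ", "))
  if (any(sp$scale == "log" & sp$lower <= 0))
    stop("log-scaled bounds must be positive")
  sp
}

.decode_point <- function(u, space) {
  v <- numeric(nrow(space))
  for (i in seq_len(nrow(space))) {
    v[i] <- if (space$scale[i] == "log") {
      exp(log(space$lower[i]) + u[i] * (log(space$upper[i]) - log(space$lower[i])))
    } else {
      space$lower[i] + u[i] * (space$upper[i] - space$lower[i])
    }
    if (space$integer[i]) v[i] <- round(v[i])
    v[i] <- min(max(v[i], space$lower[i]), space$upper[i])
  }
  setNames(as.list(v), space$param)
}

.xgb_param_list <- function(params, seed) {
  list(objective = "reg:squarederror", tree_method = "hist",
       grow_policy = "lossguide", max_depth = 0L,
       eta = params$learningRate, max_leaves = as.integer(params$maxLeaves),
       min_child_weight = params$minSamplesLeaf,
       colsample_bytree = params$featureFraction, subsample = params$rowFraction,
       alpha = params$l1, lambda = params$l2,
       nthread = 1L, seed = as.integer(seed %% .Machine$integer.max))
}

.train_xgb <- function(X, y, params, seed) {
  d <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(params = .xgb_param_list(params, seed), data = d,
                     nrounds = as.integer(params$nTrees), verbose = 0)
}

.assert_no_leakage <- function(ids, forbiddenIds) {
  if (is.null(forbiddenIds) || is.null(ids)) return(invisible(TRUE))
  hit <- intersect(ids, forbiddenIds)
  if (length(hit))
    stop("leakage guard: ", length(hit), " row(s) flagged as test supplied to ",
         "training (first: '", hit[1], "')")
  invisible(TRUE)
}

.cv_mse <- function(X, y, params, foldIdx, seed) {
  errs <- vapply(seq_along(foldIdx), function(f) {
    idx <- foldIdx[[f]]
    bst <- .train_xgb(X[-idx, , drop = FALSE], y[-idx], params, seed + f)
    pred <- predict(bst, xgboost::xgb.DMatrix(X[idx, , drop = FALSE], nthread = 1))
    mean((y[idx] - pred)^2)
  }, numeric(1))
  mean(errs)
}

.balanced_folds <- function(n, k) {
  split(sample.int(n), rep_len(seq_len(k), n))
}

# Gaussian-process expected improvement over the unit cube (minimisation).
.propose_ei <- function(U, scores, nCand = 512L) {
  d <- ncol(U)
  sdl <- sd(scores)
  ys <- if (sdl > 0) (scores - mean(scores)) / sdl else scores * 0
  dm <- as.matrix(dist(U))
  med <- median(dm[upper.tri(dm)])
  len <- max(0.5 * med, 0.05)
  Kn <- exp(-0.5 * (dm / len)^2) + diag(0.01 + 1e-8, nrow(U))
  alpha <- solve(Kn, ys)
  Kni <- solve(Kn)
  cand <- matrix(runif(nCand * d), nCand, d)
  d2 <- outer(rowSums(cand^2), rowSums(U^2), "+") - 2 * cand %*% t(U)
  Kc <- exp(-0.5 * pmax(d2, 0) / len^2)
  mu <- drop(Kc %*% alpha)
  s2 <- pmax(1 + 0.01 - rowSums((Kc %*% Kni) * Kc), 1e-12)
  s <- sqrt(s2)
  best <- min(ys)
  z <- (best - mu) / s
  ei <- (best - mu) * pnorm(z) + s * dnorm(z)
  cand[which.max(ei), ]
}

#' Bayesian hyperparameter optimisation for the boosted learner
#'
#' Sequential model-based optimisation: a Latin-hypercube initial design,
#' then a Gaussian-process surrogate with expected-improvement acquisition,
#' scoring each candidate by mean k-fold inner cross-validated MSE on the
#' supplied (training) rows. The inner folds are drawn once from `seed` and
#' reused for every candidate, so runs are deterministic. Rows flagged as
#' test by the active fold plan must never be passed in; `forbiddenIds`
#' enforces this.
#'
#' @param features numeric matrix with row ids (training rows only).
#' @param y response vector aligned with `features`.
#' @param space search space from [searchSpace()].
#' @param nIter total number of optimisation iterations (default 20).
#' @param innerFolds inner CV folds (default 5).
#' @param seed integer seed controlling folds, initial design and proposals.
#' @param forbiddenIds row ids that must not appear in `features` (leakage
#'   guard; typically the active fold's test ids).
#' @return list with `best` (named hyperparameter list), `log` (one row per
#'   iteration: parameters and inner-CV MSE) and `space`.
#' @export
tuneHyperparameters <- function(features, y, space = searchSpace(),
                                nIter = 20L, innerFolds = 5L, seed = 1L,
                                forbiddenIds = NULL) {
  features <- as.matrix(features)
  if (nrow(features) != length(y)) stop("features and y must be aligned")
  if (nrow(features) < innerFolds) stop("need at least innerFolds rows")
  if (var(y) == 0) stop("degenerate response: zero variance")
  .assert_no_leakage(rownames(features), forbiddenIds)
  d <- nrow(space)
  set.seed(seed)
  foldIdx <- .balanced_folds(nrow(features), innerFolds)
  nInit <- max(2L, min(nIter, ceiling(nIter / 3)))
  U <- lhs::randomLHS(nInit, d)
  scores <- numeric(0)
  logRows <- vector("list", nIter)
  for (it in seq_len(nIter)) {
    u <- if (it <= nInit) U[it, ] else .propose_ei(U, scores)
    if (it > nInit) U <- rbind(U, u)
    params <- .decode_point(u, space)
    sc <- .cv_mse(features, y, params, foldIdx, seed = seed + 131L * it)
    scores <- c(scores, sc)
    logRows[[it]] <- data.frame(iteration = it, as.data.frame(params), score = sc)
  }
  log <- do.call(rbind, logRows)
  best <- .decode_point(U[which.min(scores), ], space)
  list(best = best, log = log, space = space)
}

#' Fit a leaf-wise gradient-boosted regression ensemble
#'
#' Squared-error objective, histogram-based leaf-wise tree growth,
#' single-threaded and seeded so repeated runs are bit-reproducible. The
#' fitted ensemble is stored together with its parsed tree structure and
#' double-precision base score, which [predictBoosted()] and
#' [shapAttributions()] use for exact arithmetic.
#'
#' @param features numeric matrix with row and column names. For 2NP input
#'   pass `features(x)` of a [TwoNPMatrix-class] and its [blockLabels()].
#' @param y response vector.
#' @param params named list with nTrees, learningRate, maxLeaves,
#'   minSamplesLeaf, featureFraction, rowFraction, l1, l2 (e.g. the `best`
#'   element of [tuneHyperparameters()]).
#' @param seed integer seed.
#' @param blockLabels optional `"additive"`/`"dominance"` label per column.
#' @param tuningLog optional tuning log to attach.
#' @param forbiddenIds leakage guard as in [tuneHyperparameters()].
#' @return a [BoostedModel-class].
#' @export
fitBoosted <- function(features, y, params, seed = 1L, blockLabels = NULL,
                       tuningLog = NULL, forbiddenIds = NULL) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) stop("features must have column names")
  if (any(!is.finite(y))) stop("response must be finite")
  need <- searchSpace()$param
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("incomplete params; missing: ", paste(miss, collapse = ", "))
  .assert_no_leakage(rownames(features), forbiddenIds)
  if (!is.null(blockLabels) && length(blockLabels) != ncol(features))
    stop("one block label per feature column required")
  bst <- .train_xgb(features, y, params, seed)
  trees <- as.data.frame(xgboost::xgb.model.dt.tree(model = bst))
  cfg <- xgboost::xgb.config(bst)
  baseScore <- as.numeric(cfg$learner$learner_model_param$base_score)
  new("BoostedModel", booster = bst, params = params,
      featureNames = colnames(features),
      blockLabels = if (is.null(blockLabels)) character(0) else as.character(blockLabels),
      trainIds = if (is.null(rownames(features))) character(0) else rownames(features),
      baseScore = baseScore, trees = trees,
      tuningLog = if (is.null(tuningLog)) data.frame() else tuningLog)
}

.align_features <- function(model, features) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) stop("features must have column names")
  miss <- setdiff(model@featureNames, colnames(features))
  extra <- setdiff(colnames(features), model@featureNames)
  if (length(miss) || length(extra))
    stop("feature columns do not match training columns (first mismatch: '",
         c(miss, extra)[1], "')")
  features[, model@featureNames, drop = FALSE]
}

# leaf values per (tree, node) as a dense lookup
.leaf_lookup <- function(trees) {
  leaves <- trees[trees$Feature == "Leaf", c("Tree", "Node", "Gain")]
  nt <- max(trees$Tree) + 1L
  mx <- max(trees$Node) + 1L
  lut <- matrix(NA_real_, nt, mx)
  lut[cbind(leaves$Tree + 1L, leaves$Node + 1L)] <- leaves$Gain
  lut
}

#' Predict from a fitted boosted model
#'
#' Feature columns are realigned to the training order by name. The margin
#' is reconstructed in double precision: the backend routes each row to its
#' leaf, and the stored leaf values are summed in double together with the
#' base score, so predictions agree exactly with the sum of TreeSHAP
#' attributions.
#'
#' @param model a [BoostedModel-class].
#' @param features numeric matrix with named columns covering the training
#'   columns (any order).
#' @return named numeric vector of predictions.
#' @export
predictBoosted <- function(model, features) {
  X <- .align_features(model, features)
  leaf <- predict(model@booster, xgboost::xgb.DMatrix(X, nthread = 1),
                  predleaf = TRUE)
  if (is.null(dim(leaf))) leaf <- matrix(leaf, nrow = nrow(X))
  lut <- .leaf_lookup(model@trees)
  nt <- ncol(leaf)
  vals <- matrix(lut[cbind(rep(seq_len(nt), each = nrow(X)), as.vector(leaf) + 1L)],
                 nrow(X), nt)
  preds <- rowSums(vals) + model@baseScore
  if (anyNA(preds)) stop("internal error: unmatched leaf index")
  setNames(preds, rownames(X))
}

#' Save and reload a boosted model
#'
#' `saveBoostedModel()` writes the ensemble in the backend's native UBJSON
#' format (`<prefix>.model.ubj`) plus a JSON sidecar
#' (`<prefix>.sidecar.json`) holding the hyperparameters, feature names,
#' block labels, training ids and tuning log; `loadBoostedModel()` restores
#' the [BoostedModel-class] from the pair.
#'
#' @param model a [BoostedModel-class].
#' @param prefix output path prefix.
#' @return the two paths (save) / the restored model (load), invisibly.
#' @export
saveBoostedModel <- function(model, prefix) {
  mpath <- paste0(prefix, ".model.ubj")
  spath <- paste0(prefix, ".sidecar.json")
  xgboost::xgb.save(model@booster, mpath)
  side <- list(params = model@params, featureNames = model@featureNames,
               blockLabels = model@blockLabels, trainIds = model@trainIds,
               baseScore = model@baseScore,
               tuningLog = if (nrow(model@tuningLog)) model@tuningLog else NULL)
  jsonlite::write_json(side, spath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(model = mpath, sidecar = spath))
}

#' @rdname saveBoostedModel
#' @export
loadBoostedModel <- function(prefix) {
  bst <- xgboost::xgb.load(paste0(prefix, ".model.ubj"))
  side <- jsonlite::read_json(paste0(prefix, ".sidecar.json"),
                              simplifyVector = TRUE)
  trees <- as.data.frame(xgboost::xgb.model.dt.tree(model = bst))
  tl <- side$tuningLog
  new("BoostedModel", booster = bst, params = as.list(side$params),
      featureNames = as.character(unlist(side$featureNames)),
      blockLabels = as.character(unlist(side$blockLabels)),
      trainIds = as.character(unlist(side$trainIds)),
      baseScore = side$baseScore, trees = trees,
      tuningLog = if (is.null(tl)) data.frame() else as.data.frame(tl))
}

#' Read a search space from a YAML or JSON config file
#'
#' The file's `search_space` section maps dimension names (`nTrees`,
#' `learningRate`, `maxLeaves`, `minSamplesLeaf`, `featureFraction`,
#' `rowFraction`, `l1`, `l2`) to `[lower, upper]` bounds; omitted
#' dimensions keep their defaults.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a search-space data.frame as from [searchSpace()].
#' @export
searchSpaceFromConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  ss <- cfg$search_space
  if (is.null(ss)) stop("config has no 'search_space' section")
  known <- searchSpace()$param
  bad <- setdiff(names(ss), known)
  if (length(bad)) stop("unknown search-space dimension(s): ",
                        paste(bad, collapse = ", "))
  do.call(searchSpace, lapply(ss, function(b) as.numeric(unlist(b))))
}
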