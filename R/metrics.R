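#' Pearson prediction accuracy
#'
#' Sample Pearson correlation between observed and predicted values.
#' Requires at least 3 pairs; a constant vector makes the correlation
#' undefined, returned as `NA` with a warning.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
pearsonAccuracy <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3) stop("need at least 3 pairs")
  if (sd(observed) == 0 || sd(predicted) == 0) {
    warning("constant vector: correlation undefined")
    return(NA_real_)
  }
  cor(observed, predicted)
}

#' Chance-corrected selection efficiency
#'
#' With `k = round(fraction * n)` individuals selected, `I` the overlap
#' between the observed and predicted top-k sets and `C = k^2 / n` the
#' overlap expected by chance, the default efficiency is the coincidence
#' index `(I - C) / (k - C)`: 1 for perfect selection, ~0 under random
#' ranking. `literalN = TRUE` instead divides by `(n - C)` — the printed
#' formula with N read as the total number evaluated, whose maximum is far
#' below 1 at usual intensities. Ties are broken by stable original order.
#'
#' @param observed,predicted numeric vectors of equal length `n >= 1/fraction`.
#' @param fraction selected fraction (usual intensities: 0.05, 0.10, 0.20,
#'   0.30).
#' @param higherIsBetter selection direction (set `FALSE` for traits where
#'   low values are selected, e.g. earliness).
#' @param literalN use `n` instead of `k` in the denominator.
#' @return selection efficiency (dimensionless).
#' @examples
#' selectionEfficiency(1:10, 1:10, fraction = 0.2)   # 1
#' selectionEfficiency(1:10, c(6:10, 1:5), fraction = 0.2)  # (0-0.4)/(2-0.4)
#' @export
selectionEfficiency <- function(observed, predicted, fraction = 0.2,
                                higherIsBetter = TRUE, literalN = FALSE) {
  n <- length(observed)
  if (length(predicted) != n) stop("length mismatch")
  k <- round(fraction * n)
  if (k < 1) stop("selected fraction yields an empty selection (k = 0)")
  if (k >= n) stop("selected fraction must leave the selection a proper subset")
  s <- if (higherIsBetter) -1 else 1
  topObs <- order(s * observed, seq_len(n))[seq_len(k)]
  topPred <- order(s * predicted, seq_len(n))[seq_len(k)]
  I <- length(intersect(topObs, topPred))
  C <- k^2 / n
  denom <- if (literalN) n - C else k - C
  (I - C) / denom
}

#' Benchmark models over a fold plan
#'
#' For each fold and model: fit on the training records only (any
#' hyperparameter tuning runs inside the training set, with the fold's test
#' ids passed down as the leakage guard), predict the test records, and
#' compute Pearson accuracy plus selection efficiency at the requested
#' fractions. Results are aggregated as mean and standard error across
#' folds per model.
#'
#' @param models named list of model specifications (see [gblupAddModel()]
#'   and friends).
#' @param plan a [FoldPlan-class] whose ids index rows of `data`.
#' @param markers [MarkerMatrix-class] over all hybrids involved.
#' @param data data.frame with columns `id`, `hybrid`, `value` (plus
#'   whatever the plan used, e.g. `year`).
#' @param fractions selection-efficiency fractions.
#' @param seed integer; per-fold seeds are derived from it and the fold
#'   index so repetitions are independent but reproducible.
#' @return list with `perFold` (one row per fold x model) and `summary`
#'   (mean and standard error per model and metric).
#' @export
runBenchmark <- function(models, plan, markers, data,
                         fractions = c(0.05, 0.10, 0.20, 0.30), seed = 1L) {
  stopifnot(is(plan, "FoldPlan"), is(markers, "MarkerMatrix"))
  if (is.null(names(models)) || any(names(models) == ""))
    stop("models must be a named list")
  stopifnot(all(c("id", "hybrid", "value") %in% names(data)))
  rownames(data) <- data$id
  rows <- list()
  for (f in seq_along(folds(plan))) {
    fold <- folds(plan)[[f]]
    train <- data[fold$train, ]
    test <- data[fold$test, ]
    foldSeed <- (seed * 1009L + f * 97L) %% 2147483647L
    for (mn in names(models)) {
      mod <- models[[mn]]
      fitObj <- mod$fit(markers, train, seed = foldSeed,
                        forbiddenIds = fold$test)
      pred <- mod$predict(fitObj, markers, test)
      r <- suppressWarnings(pearsonAccuracy(test$value, pred))
      ses <- vapply(fractions, function(fr)
        selectionEfficiency(test$value, pred, fr), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = scheme(plan), fold = f, model = mn, nTest = nrow(test),
        pearson_r = r, t(setNames(ses, paste0("se_", fractions * 100))),
        check.names = FALSE)
    }
  }
  perFold <- do.call(rbind, rows)
  metrics <- setdiff(names(perFold), c("scheme", "fold", "model", "nTest"))
  summ <- do.call(rbind, lapply(split(perFold, perFold$model), function(d) {
    means <- colMeans(d[metrics], na.rm = TRUE)
    sems <- vapply(d[metrics], function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
    }, numeric(1))
    data.frame(model = d$model[1], metric = metrics, mean = unname(means),
               sem = unname(sems), row.names = NULL)
  }))
  rownames(summ) <- NULL
  list(perFold = perFold, summary = summ)
}
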