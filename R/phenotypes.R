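#' Screen phenotypic outliers within environments
#'
#' Within each environment (year x field location) and trait, fits the
#' two-way fixed-effect model `value ~ hybrid + replicate` and removes
#' records whose absolute standardized residual exceeds `thresholdSd`.
#' Environments where the model is saturated (no residual degrees of
#' freedom) are skipped with a warning.
#'
#' @param pheno long-format phenotype data.frame with columns
#'   hybrid, year, location, replicate, trait, value.
#' @param thresholdSd removal threshold in residual standard deviations
#'   (default 3; `Inf` disables screening).
#' @return list with `clean` (retained records) and `removed` (the flagged
#'   records with their standardized residuals).
#' @export
screenOutliers <- function(pheno, thresholdSd = 3) {
  stopifnot(all(c("hybrid", "year", "location", "replicate", "trait", "value")
                %in% names(pheno)))
  env <- interaction(pheno$trait, pheno$year, pheno$location, drop = TRUE)
  drop_idx <- logical(nrow(pheno))
  resids <- rep(NA_real_, nrow(pheno))
  for (e in levels(env)) {
    rows <- which(env == e)
    d <- pheno[rows, ]
    nh <- length(unique(d$hybrid))
    nr <- length(unique(d$replicate))
    if (nh < 2) next
    dfres <- nrow(d) - (nh + nr - 1)
    if (dfres < 1) {
      warning("environment '", e, "' is saturated; outlier screening skipped")
      next
    }
    fit <- lm(value ~ factor(hybrid) + factor(replicate), data = d)
    rs <- rstandard(fit)
    rs[!is.finite(rs)] <- 0
    resids[rows] <- rs
    drop_idx[rows] <- abs(rs) > thresholdSd
  }
  removed <- cbind(pheno[drop_idx, ], stdResidual = resids[drop_idx])
  list(clean = pheno[!drop_idx, ], removed = removed)
}

#' Stage-1 BLUEs: per-environment hybrid means adjusted for replicate
#'
#' Within each environment and trait, estimates hybrid BLUEs from the fixed
#' model `value ~ hybrid + replicate`, evaluated at the average replicate
#' effect so that a balanced two-replicate trial reduces to the plain hybrid
#' mean. A hybrid observed once with a missing replicate label is treated as
#' replicate 1 (warned).
#'
#' @param pheno (screened) phenotype data.frame.
#' @return data.frame with columns hybrid, trait, year, location, blue.
#' @export
stage1Blues <- function(pheno) {
  if (anyNA(pheno$replicate)) {
    warning("missing replicate labels treated as replicate 1")
    pheno$replicate[is.na(pheno$replicate)] <- 1L
  }
  env <- interaction(pheno$trait, pheno$year, pheno$location, drop = TRUE)
  out <- lapply(levels(env), function(e) {
    d <- pheno[env == e, ]
    hy <- factor(d$hybrid)
    rp <- factor(d$replicate)
    if (nlevels(rp) == 1L) {
      blues <- tapply(d$value, hy, mean)
    } else {
      fit <- lm(value ~ hy + rp, data = d)
      cf <- coef(fit)
      cf[is.na(cf)] <- 0
      repEff <- c(0, cf[paste0("rp", levels(rp)[-1])])
      hybEff <- c(0, cf[paste0("hy", levels(hy)[-1])])
      blues <- cf[["(Intercept)"]] + hybEff + mean(repEff)
      names(blues) <- levels(hy)
    }
    data.frame(hybrid = names(blues), trait = d$trait[1], year = d$year[1],
               location = d$location[1], blue = unname(blues),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Stage-2 BLUEs: hybrid estimates across field locations
#'
#' Fits `blue ~ hybrid (fixed) + location (random)` to the stage-1 table by
#' REML (spectral single-kernel fit on the location incidence kernel) and
#' returns `mu + H_i` per hybrid. With `perYear = TRUE` (default) the model
#' is fitted within each year, pooling locations within year, so the output
#' feeds year-aware validation schemes; `perYear = FALSE` pools everything.
#' A single field location overall returns the stage-1 values unchanged,
#' with a note.
#'
#' @param stage1 data.frame from [stage1Blues()].
#' @param perYear fit separately per year.
#' @return data.frame with columns hybrid, trait, year (`NA` when pooled),
#'   blue, nLocations.
#' @export
stage2Blues <- function(stage1, perYear = TRUE) {
  groups <- if (perYear) interaction(stage1$trait, stage1$year, drop = TRUE)
            else factor(stage1$trait)
  out <- lapply(levels(groups), function(g) {
    d <- stage1[groups == g, ]
    nl <- length(unique(d$location))
    res <- if (nl < 2) {
      message("single field location; returning stage-1 values unchanged")
      agg <- aggregate(blue ~ hybrid, d, mean)
      setNames(agg$blue, agg$hybrid)
    } else {
      .stage2_fit(d)
    }
    data.frame(hybrid = names(res), trait = d$trait[1],
               year = if (perYear) d$year[1] else NA_integer_,
               blue = unname(res), nLocations = nl, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.stage2_fit <- function(d) {
  hy <- factor(d$hybrid)
  X <- model.matrix(~ 0 + hy)
  colnames(X) <- levels(hy)
  L <- model.matrix(~ 0 + factor(d$location))
  Kloc <- tcrossprod(L)
  ids <- paste0("rec", seq_len(nrow(d)))
  dimnames(Kloc) <- list(ids, ids)
  rownames(X) <- ids
  y <- setNames(d$blue, ids)
  fit <- remlFit(y, list(Kloc), X = X)
  fit@b
}
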