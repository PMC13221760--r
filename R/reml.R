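#' REML variance components and GBLUP for one or two genomic kernels
#'
#' Fits `y = Xb + sum_k u_k + e` with `u_k ~ N(0, sigma2_k K_k)` and
#' `e ~ N(0, sigma2_e I)` by restricted maximum likelihood. A single kernel
#' is solved by spectral profiling of the variance ratio (eigendecomposition
#' of the projected kernel, then one-dimensional optimisation of the
#' restricted likelihood). Two kernels are fitted by EM-REML with
#' convergence declared at a relative log-likelihood change below `tol`,
#' components floored at `1e-10 * var(y)`.
#'
#' Kernels whose smallest eigenvalue is negative receive a
#' `1e-8 * mean(diag)` diagonal jitter (reported via a message).
#'
#' @param y named phenotype vector (one entry per training individual).
#' @param kernels list of 1-2 [GRM-class] objects (or plain symmetric
#'   matrices with id dimnames) covering the ids of `y`.
#' @param X fixed-effect design matrix (default: intercept only); must have
#'   full column rank.
#' @param tol relative log-likelihood convergence tolerance (two-kernel EM).
#' @param maxIter maximum EM iterations.
#' @return a [GBLUPFit-class].
#' @examples
#' set.seed(1)
#' M <- MarkerMatrix(matrix(sample(0:2, 40 * 60, TRUE), 40, 60,
#'   dimnames = list(sprintf("i%02d", 1:40), sprintf("s%02d", 1:60))))
#' Z <- additiveDesign(M)
#' A <- additiveGRM(Z)
#' g <- drop(Z[, 1:5] %*% rnorm(5, sd = 0.4))
#' y <- setNames(g + rnorm(40, sd = 0.5), individualIds(M))
#' fit <- remlFit(y, list(A))
#' varComp(fit)
#' @export
remlFit <- function(y, kernels, X = NULL, tol = 1e-8, maxIter = 500L) {
  if (is(kernels, "GRM")) kernels <- list(kernels)
  if (!length(kernels) %in% 1:2) stop("one or two kernels supported")
  if (any(!is.finite(y))) stop("phenotypes must be finite")
  ids <- names(y)
  if (is.null(ids)) stop("y must be named by individual id")
  n <- length(y)
  kinds <- character(length(kernels))
  Ks <- vector("list", length(kernels))
  for (k in seq_along(kernels)) {
    if (is(kernels[[k]], "GRM")) {
      kinds[k] <- grmKind(kernels[[k]])
      Ks[[k]] <- grmBlock(kernels[[k]], ids)
    } else {
      kinds[k] <- if (k == 1) "additive" else "dominance"
      Km <- as.matrix(kernels[[k]])
      miss <- setdiff(ids, rownames(Km))
      if (length(miss)) stop("kernel ", k, " missing ids: ", paste(head(miss, 5), collapse = ", "))
      Ks[[k]] <- Km[ids, ids]
    }
    Ks[[k]] <- .condition_kernel(Ks[[k]], k)
  }
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(ids, "(Intercept)"))
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")

  # an identically-zero kernel contributes nothing: drop it from the fit
  # and report a zero component for it
  active <- vapply(Ks, function(K) any(K != 0), logical(1))
  if (!any(active)) stop("all kernels are identically zero")
  Kact <- Ks[active]
  if (length(Kact) == 1L) {
    res <- .reml_spectral(y, X, Kact[[1]])
    sigAct <- res$va
  } else {
    res <- .reml_em(y, X, Kact, tol = tol, maxIter = maxIter)
    sigAct <- res$sigmas
  }
  sig <- numeric(length(Ks))
  sig[active] <- sigAct

  va <- sum(sig[kinds == "additive"])
  vd <- sum(sig[kinds == "dominance"])
  vc <- new("VarianceComponents", va = va, vd = vd, ve = res$ve,
            logLik = as.numeric(res$logLik))

  # GLS fixed effects and kernel BLUPs at the optimum
  V <- diag(res$ve, n)
  for (k in seq_along(Ks)) V <- V + sig[k] * Ks[[k]]
  Vi <- chol2inv(chol(V))
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  b <- drop(solve(XtViX, crossprod(ViX, y)))
  w <- drop(Vi %*% (y - X %*% b))
  blups <- lapply(seq_along(Ks), function(k) setNames(drop(sig[k] * Ks[[k]] %*% w), ids))
  names(blups) <- kinds

  new("GBLUPFit", b = setNames(b, colnames(X)), blups = blups, vc = vc,
      trainIds = ids, kernelKinds = kinds, w = w, X = X, y = unname(y),
      trace = res$trace, converged = res$converged)
}

.condition_kernel <- function(K, idx) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) {
    jit <- 1e-8 * mean(diag(K))
    message(sprintf("kernel %d: adding diagonal jitter %.3g (min eigenvalue %.3g)",
                    idx, jit, min(ev)))
    K <- K + diag(jit, nrow(K))
    if (min(ev) + jit < 0)
      stop(sprintf("kernel %d is not positive semidefinite after jitter", idx))
  }
  K
}

# Restricted log-likelihood for V = sum sig_k K_k + ve I (direct evaluation).
.reml_loglik <- function(y, X, Ks, sigmas, ve) {
  n <- length(y)
  V <- diag(ve, n)
  for (k in seq_along(Ks)) V <- V + sigmas[k] * Ks[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  b <- solve(XtViX, crossprod(ViX, y))
  r <- y - X %*% b
  quad <- drop(crossprod(r, Vi %*% r))
  as.numeric(-0.5 * (2 * sum(log(diag(ch))) +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       quad + (n - ncol(X)) * log(2 * pi)))
}

# Single kernel: EMMA-style spectral profiling of lambda = va/ve.
.reml_spectral <- function(y, X, K) {
  n <- length(y)
  p <- ncol(X)
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  es <- eigen(S %*% K %*% S, symmetric = TRUE)
  keep <- seq_len(n - p)
  xi <- es$values[keep]
  xi[xi < 0] <- 0
  U <- es$vectors[, keep, drop = FALSE]
  eta2 <- drop(crossprod(U, y))^2
  nq <- n - p
  ll <- function(loglam) {
    lam <- exp(loglam)
    d <- lam * xi + 1
    0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(sum(eta2 / d)) - sum(log(d)))
  }
  grid <- seq(-18, 18, length.out = 181)
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-10)
  # candidates: interior optimum and the lower boundary (va ~ 0)
  cand <- if (opt$objective >= vals[1]) opt$maximum else grid[1]
  lam <- exp(cand)
  ve <- sum(eta2 / (lam * xi + 1)) / nq
  va <- lam * ve
  trace <- data.frame(iteration = seq_along(grid), va = exp(grid) *
                        vapply(grid, function(g) sum(eta2 / (exp(g) * xi + 1)) / nq, numeric(1)),
                      logLik = vals)
  list(va = va, ve = ve, logLik = .reml_loglik(y, X, list(K), va, ve),
       trace = trace, converged = TRUE)
}

# Two kernels: EM-REML with guarded Aitken acceleration. Components near a
# boundary make plain EM creep at a geometric rate close to 1; every 10
# iterations the component vector is extrapolated elementwise and the jump is
# accepted only if it does not decrease the restricted likelihood.
.reml_em <- function(y, X, Ks, tol = 1e-8, maxIter = 500L) {
  n <- length(y)
  vy <- var(y)
  floor_v <- 1e-10 * vy
  nk <- length(Ks)
  theta <- rep(vy / (nk + 1), nk + 1)  # kernel components then residual
  ll_of <- function(th) .reml_loglik(y, X, Ks, th[seq_len(nk)], th[nk + 1])
  ll_old <- -Inf
  lastChange <- Inf
  trace <- vector("list", maxIter)
  converged <- FALSE
  hist3 <- list()
  for (it in seq_len(maxIter)) {
    V <- diag(theta[nk + 1], n)
    for (k in seq_len(nk)) V <- V + theta[k] * Ks[[k]]
    ch <- chol(V)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    P <- Vi - ViX %*% solve(XtViX, t(ViX))
    Py <- drop(P %*% y)
    ll <- as.numeric(-0.5 * (2 * sum(log(diag(ch))) +
                               determinant(XtViX, logarithm = TRUE)$modulus +
                               drop(crossprod(y, Py)) +
                               (n - ncol(X)) * log(2 * pi)))
    trace[[it]] <- c(iteration = it, setNames(theta[seq_len(nk)],
                                              paste0("sigma", seq_len(nk))),
                     ve = theta[nk + 1], logLik = ll)
    lastChange <- abs(ll - ll_old) / (abs(ll_old) + 1)
    if (is.finite(ll_old) && lastChange < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    new <- theta
    for (k in seq_len(nk)) {
      KPy <- Ks[[k]] %*% Py
      new[k] <- max(theta[k] + theta[k]^2 / n *
                      (drop(crossprod(Py, KPy)) - sum(P * Ks[[k]])), floor_v)
    }
    new[nk + 1] <- max(theta[nk + 1] + theta[nk + 1]^2 / n *
                         (sum(Py^2) - sum(diag(P))), floor_v)
    theta <- new
    hist3[[length(hist3) + 1L]] <- theta
    if (length(hist3) > 3) hist3 <- hist3[-1]
    if (length(hist3) == 3 && it %% 10 == 0) {
      d1 <- hist3[[2]] - hist3[[1]]
      d2 <- hist3[[3]] - hist3[[2]]
      rate <- ifelse(abs(d1) > 0, d2 / d1, 0)
      rate <- pmin(pmax(rate, 0), 0.9995)
      cand <- pmax(hist3[[3]] + d2 * rate / (1 - rate), floor_v)
      if (ll_of(cand) >= ll_of(theta)) theta <- cand
    }
  }
  if (!converged)
    stop("EM-REML did not converge in ", maxIter, " iterations ",
         "(last relative logLik change ",
         format(lastChange, digits = 3), ")")
  list(sigmas = theta[seq_len(nk)], ve = theta[nk + 1], logLik = ll,
       trace = as.data.frame(do.call(rbind, trace[seq_len(it)])),
       converged = converged)
}

#' Predict genetic values for new individuals from a GBLUP fit
#'
#' For each fitted kernel, the test-side genetic value is
#' `sigma2_k K[test, train] V^{-1} (y - Xb)`; the total prediction adds the
#' fixed-effect part `X_test b`. Test individuals already in the training
#' set receive their fitted values (with a warning).
#'
#' @param fit a [GBLUPFit-class].
#' @param kernels list of [GRM-class] covering train and test ids, in the
#'   same order as the kernels used for fitting.
#' @param testIds ids to predict.
#' @param Xtest fixed-effect design for the test ids (default: intercept).
#' @return named numeric vector of predictions.
#' @export
gblupPredict <- function(fit, kernels, testIds, Xtest = NULL) {
  if (is(kernels, "GRM")) kernels <- list(kernels)
  if (length(kernels) != length(fit@kernelKinds))
    stop("expected ", length(fit@kernelKinds), " kernel(s)")
  if (any(testIds %in% fit@trainIds))
    warning("some test ids were in the training set; returning fitted values for them")
  sig <- c(fit@vc@va, fit@vc@vd)[match(fit@kernelKinds, c("additive", "dominance"))]
  g <- numeric(length(testIds))
  for (k in seq_along(kernels)) {
    Kct <- grmBlock(kernels[[k]], testIds, fit@trainIds)
    g <- g + drop(sig[k] * Kct %*% fit@w)
  }
  if (is.null(Xtest)) Xtest <- matrix(1, length(testIds), ncol(fit@X))
  setNames(g + drop(as.matrix(Xtest) %*% fit@b), testIds)
}

#' Heritability decomposition from variance components
#'
#' Computes narrow-sense `h2 = Va/Vp`, broad-sense `H2 = (Va+Vd)/Vp`,
#' dominance fraction `d2 = Vd/Vp` and the dominance share of genetic
#' variance `PDV = Vd/(Va+Vd)`, with `Vp = Va + Vd + Ve`. PDV is reported as
#' 0 with `pdvDefined = FALSE` when the genetic variance is zero.
#'
#' @param vc a [VarianceComponents-class] (or a [GBLUPFit-class], whose
#'   components are used).
#' @return list with h2, H2, d2, PDV and pdvDefined.
#' @examples
#' heritabilities(new("VarianceComponents", va = 2, vd = 1, ve = 1, logLik = 0))
#' @export
heritabilities <- function(vc) {
  if (is(vc, "GBLUPFit")) vc <- varComp(vc)
  stopifnot(is(vc, "VarianceComponents"))
  vp <- vc@va + vc@vd + vc@ve
  vg <- vc@va + vc@vd
  list(h2 = vc@va / vp,
       H2 = vg / vp,
       d2 = vc@vd / vp,
       PDV = if (vg > 0) vc@vd / vg else 0,
       pdvDefined = vg > 0)
}

#' Serialize a GBLUP fit report to JSON
#'
#' Components, heritabilities and the convergence trace.
#'
#' @param fit a [GBLUPFit-class].
#' @param path output file.
#' @export
writeFitReport <- function(fit, path) {
  vc <- varComp(fit)
  rep <- list(
    components = list(va = vc@va, vd = vc@vd, ve = vc@ve, logLik = vc@logLik),
    heritabilities = heritabilities(vc)[1:4],
    fixedEffects = as.list(fit@b),
    converged = fit@converged,
    trace = fit@trace
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
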