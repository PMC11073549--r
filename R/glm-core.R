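## Mass-univariate OLS with optional AR(1) prewhitening and contrast
## inference. Shared by the node activation, edge, and gPPI analyses.

.check_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  q
}

## apply the AR(1) whitening filter to a matrix (rows = frames):
## row 1 scaled by sqrt(1 - rho^2), row t -> row_t - rho * row_{t-1}
.whiten <- function(M, rho) {
  M <- as.matrix(M)
  n <- nrow(M)
  W <- M - rho * rbind(0, M[-n, , drop = FALSE])
  W[1L, ] <- sqrt(1 - rho^2) * M[1L, , drop = FALSE]
  W
}

#' AR(1) prewhitening
#'
#' Estimates a first-order autoregressive coefficient per target from the
#' lag-1 autocorrelation of its OLS residuals (single Cochrane-Orcutt pass,
#' clipped to (-0.999, 0.999)), then applies the whitening filter to both
#' the response and the design: the first row is scaled by
#' `sqrt(1 - rho^2)` and row t becomes `row_t - rho * row_{t-1}`.
#'
#' @param y frames x targets numeric matrix (a vector is treated as one
#'   target)
#' @param X a [DesignMatrix-class] or plain numeric matrix, full column rank
#' @param pooled use a single rho (the across-target mean) for all targets
#' @return list with `y` (whitened responses), `X` (whitened design: a
#'   matrix when rho is shared, otherwise a list of per-target matrices)
#'   and `rho` (per-target coefficients)
#' @export
ar1Prewhiten <- function(y, X, pooled = FALSE) {
  y <- as.matrix(y)
  Xm <- if (is(X, "DesignMatrix")) X@values else as.matrix(X)
  if (nrow(y) < 3L) stop("prewhitening needs at least 3 frames")
  q <- .check_rank(Xm)
  res <- y - Xm %*% qr.coef(q, y)
  rho <- estimateAR1(res)
  if (pooled) rho <- rep(mean(rho), length(rho))
  yW <- y
  for (k in seq_len(ncol(y))) yW[, k] <- .whiten(y[, k, drop = FALSE], rho[k])
  ur <- unique(rho)
  if (length(ur) == 1L) {
    XW <- .whiten(Xm, ur)
  } else {
    XW <- lapply(rho, function(r) .whiten(Xm, r))
  }
  list(y = yW, X = XW, rho = rho)
}

#' Lag-1 autocorrelation per column
#' @param res frames x targets matrix of residuals (or raw series)
#' @param clip absolute bound applied to the estimate (default 0.999)
#' @return numeric vector of AR(1) coefficients
#' @export
estimateAR1 <- function(res, clip = 0.999) {
  res <- as.matrix(res)
  n <- nrow(res)
  num <- colSums(res[-1L, , drop = FALSE] * res[-n, , drop = FALSE])
  den <- colSums(res^2)
  rho <- ifelse(den > 0, num / den, 0)
  pmin(pmax(rho, -clip), clip)
}

#' Mass-univariate OLS fit
#'
#' Fits every target series on a common design by ordinary least squares,
#' optionally after AR(1) prewhitening of both sides and/or z-scoring of
#' the response and the non-intercept design columns.
#'
#' @param y frames x targets matrix (vector = one target)
#' @param X a [DesignMatrix-class] or numeric matrix, full column rank
#' @param prewhiten apply [ar1Prewhiten()] (default FALSE)
#' @param standardize z-score `y` and non-intercept columns of `X` before
#'   fitting (robustness toggle, default FALSE)
#' @param pooledRho pass `pooled = TRUE` to the prewhitener
#' @return a [GLMFit-class]
#' @export
glmFit <- function(y, X, prewhiten = FALSE, standardize = FALSE,
                   pooledRho = FALSE) {
  y <- as.matrix(y)
  Xm <- if (is(X, "DesignMatrix")) X@values else as.matrix(X)
  if (is.null(colnames(Xm))) colnames(Xm) <- paste0("x", seq_len(ncol(Xm)))
  n <- nrow(y)
  if (n < ncol(Xm)) stop("fewer frames than design columns")
  if (standardize) {
    y <- apply(y, 2L, function(v) {
      s <- stats::sd(v)
      if (s > 0) (v - mean(v)) / s else v - mean(v)
    })
    ic <- apply(Xm, 2L, function(v) all(v == v[1L]))
    Xm[, !ic] <- apply(Xm[, !ic, drop = FALSE], 2L, function(v) {
      s <- stats::sd(v)
      if (s > 0) (v - mean(v)) / s else v - mean(v)
    })
  }
  m <- ncol(y)
  p <- ncol(Xm)
  q0 <- .check_rank(Xm)
  dof <- n - p
  if (dof <= 0) stop("non-positive residual degrees of freedom")
  betas <- matrix(NA_real_, p, m,
                  dimnames = list(colnames(Xm), colnames(y)))
  sigma2 <- numeric(m)
  covU <- array(NA_real_, c(p, p, m))
  if (!prewhiten) {
    B <- qr.coef(q0, y)
    res <- y - Xm %*% B
    betas[] <- B
    sigma2 <- colSums(res^2) / dof
    cu <- chol2inv(qr.R(q0))
    for (k in seq_len(m)) covU[, , k] <- cu
    rho <- numeric(m)
  } else {
    ## whitened normal equations assembled from lag Gram matrices: with the
    ## AR(1) whitening filter D(rho), X*'X* = X'D'DX where
    ## D'D = (1 + rho^2) I - rho^2 (e_1 e_1' + e_T e_T') - rho (L + L')
    ## and L is the one-frame lag operator; identical to whitening both
    ## sides explicitly, but O(p^2) per target instead of O(T p^2)
    res0 <- y - Xm %*% qr.coef(q0, y)
    rho <- estimateAR1(res0)
    if (pooledRho) rho <- rep(mean(rho), m)
    S0 <- crossprod(Xm)
    Mlag <- crossprod(Xm[-1L, , drop = FALSE], Xm[-n, , drop = FALSE])
    Msym <- Mlag + t(Mlag)
    Eends <- tcrossprod(Xm[1L, ]) + tcrossprod(Xm[n, ])
    XtY <- crossprod(Xm, y)
    XtLy <- crossprod(Xm[-1L, , drop = FALSE], y[-n, , drop = FALSE])
    XtLty <- crossprod(Xm[-n, , drop = FALSE], y[-1L, , drop = FALSE])
    xEndsY <- outer(Xm[1L, ], y[1L, ]) + outer(Xm[n, ], y[n, ])
    yty <- colSums(y^2)
    ylag <- colSums(y[-1L, , drop = FALSE] * y[-n, , drop = FALSE])
    yEnds <- y[1L, ]^2 + y[n, ]^2
    for (k in seq_len(m)) {
      r <- rho[k]
      A <- (1 + r^2) * S0 - r^2 * Eends - r * Msym
      b <- (1 + r^2) * XtY[, k] - r^2 * xEndsY[, k] -
        r * (XtLy[, k] + XtLty[, k])
      cu <- chol2inv(chol(A))
      bk <- drop(cu %*% b)
      betas[, k] <- bk
      ystar2 <- (1 + r^2) * yty[k] - r^2 * yEnds[k] - 2 * r * ylag[k]
      sigma2[k] <- max(ystar2 - sum(b * bk), 0) / dof
      covU[, , k] <- cu
    }
  }
  new("GLMFit", coefficients = betas, sigma2 = sigma2, dof = as.numeric(dof),
      rho = rho, covUnscaled = covU, rank = ncol(Xm))
}

#' Contrast estimate, t and p from a GLMFit
#'
#' Computes `effect = c' beta` per target with variance
#' `sigma2 * c' (X'X)^-1 c` (whitened design when prewhitening was on),
#' the t statistic and the two-sided Student-t p value at the fit's
#' residual degrees of freedom. Targets with zero residual variance get a
#' +/-Inf t sentinel with p = 0 (and t = 0, p = 1 when the effect is also
#' zero), with a warning: degenerate noiseless targets must not abort a
#' mass-univariate loop.
#'
#' @param fit a [GLMFit-class]
#' @param weights contrast weight vector, length = regressors, not all zero;
#'   may be named to match design columns
#' @return a [StatMap-class] with one element per target
#' @export
glmContrast <- function(fit, weights) {
  p <- nrow(fit@coefficients)
  if (length(weights) != p)
    stop("contrast length ", length(weights), " != ", p, " regressors")
  if (all(weights == 0)) stop("contrast vector must not be all zero")
  if (!is.null(names(weights))) {
    if (!setequal(names(weights), rownames(fit@coefficients)))
      stop("contrast names do not match design columns")
    weights <- weights[rownames(fit@coefficients)]
  }
  m <- ncol(fit@coefficients)
  eff <- as.numeric(crossprod(weights, fit@coefficients))
  cvc <- vapply(seq_len(m), function(k)
    as.numeric(crossprod(weights, fit@covUnscaled[, , k] %*% weights)),
    numeric(1L))
  v <- fit@sigma2 * cvc
  tt <- numeric(m); pp <- numeric(m)
  ok <- v > 0
  tt[ok] <- eff[ok] / sqrt(v[ok])
  pp[ok] <- 2 * stats::pt(-abs(tt[ok]), df = fit@dof)
  if (any(!ok)) {
    warning("zero residual variance for ", sum(!ok),
            " target(s); t set to +/-Inf sentinel")
    tt[!ok] <- sign(eff[!ok]) * Inf
    pp[!ok] <- ifelse(eff[!ok] == 0, 1, 0)
    tt[!ok & eff == 0] <- 0
  }
  els <- colnames(fit@coefficients)
  if (is.null(els)) els <- paste0("el", seq_len(m))
  statMap(els, eff, tt, pp, fit@dof)
}

#' Contrast weights for a named design
#'
#' Convenience builder: a zero vector over the design's columns with the
#' given named entries set, e.g. incongruent minus congruent main effects.
#'
#' @param X a [DesignMatrix-class]
#' @param ... named weights, e.g. `incongruent = 1, congruent = -1`
#' @return named numeric vector over the design columns
#' @export
contrastWeights <- function(X, ...) {
  w <- structure(numeric(ncol(X@values)), names = colnames(X@values))
  set <- c(...)
  bad <- setdiff(names(set), names(w))
  if (length(bad)) stop("no design column named: ",
                        paste(bad, collapse = ", "))
  w[names(set)] <- set
  w
}
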