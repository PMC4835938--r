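## Weighted-residual REML for linear mixed models
##
## Model: y = X beta + sum_k Z_k u_k + e,  u_k ~ N(0, sigma_k^2 K_k),
##        e ~ N(0, W^-1 sigma_e^2) with diagonal weights W.
##
## The restricted likelihood is profiled over sigma_e^2 and maximized over
## the log variance ratios lambda_k = sigma_k^2 / sigma_e^2. Writing
## Htil = I + sum_k lambda_k M_k in the sqrt(W)-transformed metric, at most
## one "dense" term (q close to n, e.g. a pedigree polygenic effect) is
## absorbed by a one-off eigendecomposition; the remaining terms are
## handled through the Woodbury identity on a q x q system, which also
## yields the BLUPs as the mixed-model-equation solution. This makes exact
## per-marker re-estimation cheap inside scans: the decomposition depends
## only on the random structure, not on the fixed-effect design.

## Build the reusable part of a fit: transforms, rotation, inverses.
## random: named list; each element list(Z = n x q matrix or NULL for
## identity, K = q x q covariance or NULL for identity).
.remlPrep <- function(y, X0, random = list(), weights = NULL) {
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be > 0")
  sw <- sqrt(weights)
  yR <- sw * y
  X0R <- X0 * sw

  qk <- vapply(random, function(r) if (is.null(r$Z)) n else ncol(r$Z), 0L)
  denseIdx <- integer(0)
  if (length(random)) {
    cand <- which(qk > 0.6 * n)
    if (length(cand) > 1L)
      stop("at most one dense (q ~ n) random term is supported")
    denseIdx <- cand
  }

  U <- NULL
  dvals <- rep(0, n)
  if (length(denseIdx)) {
    r <- random[[denseIdx]]
    Md <- if (is.null(r$Z)) {
      if (is.null(r$K)) diag(weights) else sw * t(sw * r$K)
    } else {
      ZK <- if (is.null(r$K)) tcrossprod(r$Z) else r$Z %*% r$K %*% t(r$Z)
      sw * t(sw * ZK)
    }
    eg <- eigen(Md, symmetric = TRUE)
    U <- eg$vectors
    dvals <- pmax(eg$values, 0)
    yR <- crossprod(U, yR)[, 1]
    X0R <- crossprod(U, X0R)
  }

  others <- setdiff(seq_along(random), denseIdx)
  Tlist <- list()
  Kinv <- list()
  logdetK <- numeric(0)
  for (k in others) {
    r <- random[[k]]
    Z <- if (is.null(r$Z)) diag(n) else r$Z
    Tk <- Z * sw
    if (!is.null(U)) Tk <- crossprod(U, Tk)
    Tlist[[length(Tlist) + 1L]] <- Tk
    if (is.null(r$K)) {
      Kinv[[length(Kinv) + 1L]] <- diag(ncol(Z))
      logdetK <- c(logdetK, 0)
    } else {
      ch <- chol(r$K)
      Kinv[[length(Kinv) + 1L]] <- chol2inv(ch)
      logdetK <- c(logdetK, 2 * sum(log(diag(ch))))
    }
  }
  Tmat <- if (length(Tlist)) do.call(cbind, Tlist) else NULL
  qo <- vapply(Tlist, ncol, 0L)

  list(n = n, sw = sw, sumLogW = sum(log(weights)), yR = yR, X0R = X0R,
       U = U, dvals = dvals, denseIdx = denseIdx, others = others,
       Tmat = Tmat, qo = qo, Kinv = Kinv, logdetK = logdetK,
       termNames = names(random), nTerms = length(random))
}

## Sufficient statistics reused across evaluations when no dense term is
## present (the base metric is then constant), making each likelihood
## evaluation O(q^3) regardless of n.
.remlCache <- function(prep, X) {
  if (length(prep$denseIdx) || is.null(prep$Tmat)) return(NULL)
  list(S = crossprod(prep$Tmat),
       TX = crossprod(prep$Tmat, X),
       Ty = crossprod(prep$Tmat, prep$yR),
       XtX = crossprod(X),
       Xty = crossprod(X, prep$yR),
       yty = sum(prep$yR^2))
}

## Profiled -2 restricted log-likelihood and GLS pieces at given log ratios.
## theta is ordered: dense term first (if any), then the others.
.remlEval <- function(prep, X, theta, wantFit = FALSE, cache = NULL) {
  n <- prep$n
  p <- ncol(X)
  hasDense <- length(prep$denseIdx) > 0
  lamD <- if (hasDense) exp(theta[1]) else NA
  lamO <- if (length(theta) > hasDense)
    exp(theta[(hasDense + 1):length(theta)]) else numeric(0)

  v <- if (hasDense) 1 + lamD * prep$dvals else rep(1, n)
  logdetH <- sum(log(v))

  y <- prep$yR
  if (length(lamO)) {
    if (!is.null(cache)) {
      S <- cache$S
      Ty <- cache$Ty
      TX <- cache$TX
      XtX <- cache$XtX
      Xty <- cache$Xty
      yty <- cache$yty
    } else {
      Tm <- prep$Tmat
      Tv <- Tm / v
      S <- crossprod(Tm, Tv)                     # T' B^-1 T
      Ty <- crossprod(Tv, y)
      TX <- crossprod(Tv, X)
      XtX <- crossprod(X, X / v)
      Xty <- crossprod(X, y / v)
      yty <- sum(y^2 / v)
    }
    Ginv <- matrix(0, sum(prep$qo), sum(prep$qo))
    off <- 0L
    for (k in seq_along(lamO)) {
      ix <- off + seq_len(prep$qo[k])
      Ginv[ix, ix] <- prep$Kinv[[k]] / lamO[k]
      logdetH <- logdetH + prep$qo[k] * log(lamO[k]) + prep$logdetK[k]
      off <- off + prep$qo[k]
    }
    C <- Ginv + S
    cholC <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(cholC)) return(list(m2ll = 1e10))
    logdetH <- logdetH + 2 * sum(log(diag(cholC)))
    CiTy <- backsolve(cholC, backsolve(cholC, Ty, transpose = TRUE))
    CiTX <- backsolve(cholC, backsolve(cholC, TX, transpose = TRUE))
    XtHX <- XtX - crossprod(TX, CiTX)
    XtHy <- Xty - crossprod(TX, CiTy)
    ytHy <- yty - sum(Ty * CiTy)
  } else {
    XtHX <- crossprod(X, X / v)
    XtHy <- crossprod(X, y / v)
    ytHy <- sum(y^2 / v)
  }

  cholXtHX <- tryCatch(chol(XtHX), error = function(e) NULL)
  if (is.null(cholXtHX)) return(list(m2ll = 1e10))
  beta <- backsolve(cholXtHX, backsolve(cholXtHX, XtHy, transpose = TRUE))
  rss <- max(ytHy - sum(beta * XtHy), 1e-300)
  sigma2 <- rss / (n - p)
  m2ll <- (n - p) * (log(2 * pi) + 1 + log(sigma2)) + logdetH -
    prep$sumLogW + 2 * sum(log(diag(cholXtHX)))

  out <- list(m2ll = m2ll, beta = beta[, 1], sigma2 = sigma2)
  if (wantFit) {
    out$covBeta <- sigma2 * chol2inv(cholXtHX)
    if (length(lamO)) {
      Tr <- if (!is.null(cache)) Ty - TX %*% beta else
        crossprod(prep$Tmat, (y - X %*% beta) / v)
      out$blupAll <- backsolve(cholC,
                               backsolve(cholC, Tr, transpose = TRUE))[, 1]
    }
  }
  out
}

## Fit with optional extra fixed columns; returns estimates or an aliasing
## flag. lambdaLog fixes the variance ratios (fast scan mode).
.remlSolve <- function(prep, Xadd = NULL, lambdaLog = NULL,
                       wantBlup = FALSE) {
  X <- prep$X0R
  if (!is.null(Xadd)) {
    XaddR <- Xadd * prep$sw
    if (!is.null(prep$U)) XaddR <- crossprod(prep$U, XaddR)
    X <- cbind(X, XaddR)
  }
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    return(list(ok = FALSE, aliased = aliased))
  }
  if (prep$n - p < 1L) stop("fewer observations than fixed effects")

  nTheta <- prep$nTerms
  cache <- .remlCache(prep, X)
  if (nTheta == 0L) {
    ev <- .remlEval(prep, X, numeric(0), wantFit = TRUE, cache = cache)
    return(.packSolve(prep, ev, numeric(0), TRUE, p))
  }

  ## degenerate response: X already fits y exactly
  if (max(abs(qr.resid(qrX, prep$yR))) <
      1e-10 * (1 + max(abs(prep$yR)))) {
    ev <- .remlEval(prep, X, rep(-30, nTheta), wantFit = TRUE,
                    cache = cache)
    res <- .packSolve(prep, ev, rep(-Inf, nTheta), TRUE, p)
    res$varComponents[] <- 0
    res$sigma2 <- 0
    return(res)
  }

  if (!is.null(lambdaLog)) {
    ev <- .remlEval(prep, X, lambdaLog, wantFit = TRUE, cache = cache)
    return(.packSolve(prep, ev, lambdaLog, TRUE, p))
  }

  obj <- function(th) .remlEval(prep, X, th, cache = cache)$m2ll
  if (nTheta == 1L) {
    op <- stats::optimize(obj, interval = c(-20, 15), tol = 1e-10)
    theta <- op$minimum
    conv <- TRUE
  } else {
    op <- stats::optim(rep(0, nTheta), obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 2000))
    theta <- op$par
    conv <- op$convergence == 0L
  }
  ev <- .remlEval(prep, X, theta, wantFit = TRUE, cache = cache)
  .packSolve(prep, ev, theta, conv, p)
}

.packSolve <- function(prep, ev, theta, conv, p) {
  lam <- exp(theta)
  vc <- numeric(prep$nTerms)
  nm <- prep$termNames
  if (is.null(nm))
    nm <- if (prep$nTerms) paste0("term", seq_len(prep$nTerms)) else
      character(0)
  if (length(prep$denseIdx)) {
    ordNames <- c(nm[prep$denseIdx], nm[prep$others])
  } else ordNames <- nm
  vc <- lam * ev$sigma2
  names(vc) <- ordNames
  vc <- vc[nm]                      # restore user order
  blup <- list()
  if (!is.null(ev$blupAll)) {
    off <- 0L
    for (k in seq_along(prep$others)) {
      ix <- off + seq_len(prep$qo[k])
      u <- ev$blupAll[ix]
      names(u) <- colnames(prep$Tmat)[ix]
      blup[[nm[prep$others[k]]]] <- u
      off <- off + prep$qo[k]
    }
  }
  list(ok = TRUE, beta = ev$beta, covBeta = ev$covBeta,
       sigma2 = ev$sigma2, varComponents = vc,
       logLik = -ev$m2ll / 2, converged = conv, theta = theta,
       blup = blup, p = p)
}

#' Fit a linear mixed model by weighted REML
#'
#' Maximizes the restricted log-likelihood of
#' \deqn{y = X\beta + \sum_k Z_k u_k + e, \quad u_k \sim N(0, \sigma_k^2 K_k),
#'   \quad e \sim N(0, W^{-1}\sigma_e^2)}
#' over the variance ratios (log-parameterized, hence constrained
#' non-negative) and returns GLS fixed-effect estimates with standard
#' errors at the optimum. Non-convergence is flagged on the result rather
#' than raised; a singular fixed-effect design is an error naming the
#' aliased columns.
#'
#' @param y Numeric response.
#' @param X Fixed-effect design matrix (defaults to an intercept).
#' @param random Named list of random terms; each a list with \code{Z}
#'   (incidence matrix, or NULL for one effect per observation) and
#'   \code{K} (covariance structure, or NULL for identity).
#' @param weights Positive residual weights (diagonal of W).
#' @param blup Return BLUPs of the random effects where available.
#' @return A [RemlFit-class].
#' @examples
#' set.seed(1)
#' g <- gl(8, 10)
#' y <- rnorm(8)[g] + rnorm(80)
#' fit <- remlFit(y, random = list(sire = list(Z = stats::model.matrix(~ 0 + g))))
#' fit@varComponents
#' @export
remlFit <- function(y, X = NULL, random = list(), weights = NULL,
                    blup = FALSE) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  prep <- .remlPrep(y, X, random, weights)
  res <- .remlSolve(prep, wantBlup = blup)
  if (!res$ok)
    stop("singular fixed-effect design; aliased column(s): ",
         paste(res$aliased, collapse = ", "))
  se <- sqrt(pmax(diag(as.matrix(res$covBeta)), 0))
  names(res$beta) <- names(se) <- colnames(X)
  new("RemlFit", beta = res$beta, se = se,
      varComponents = c(res$varComponents, residual = res$sigma2),
      logLik = res$logLik, converged = res$converged, nobs = as.integer(n),
      blup = res$blup, optim = list(theta = res$theta))
}

#' Wald test of a fixed effect
#'
#' The statistic is estimate/SE, referred to the standard normal (with
#' thousands of observations the t reference is indistinguishable; the
#' approximation is documented in the methods vignette). Two-sided.
#'
#' @param fit A [RemlFit-class].
#' @param coefficient Name or index of the fixed effect.
#' @return list with statistic, p (two-sided) and mlog10p, the latter
#'   computed in log space so it stays finite and consistent with p.
#' @export
waldTest <- function(fit, coefficient) {
  b <- fit@beta[coefficient]
  s <- fit@se[coefficient]
  if (length(b) != 1L || is.na(b)) stop("unknown coefficient")
  z <- as.numeric(b / s)
  if (!is.finite(z)) z <- 0
  list(statistic = z,
       p = 2 * stats::pnorm(-abs(z)),
       mlog10p = .mlog10pNorm(z))
}

#' Likelihood-ratio test between nested REML fits
#'
#' Statistic \eqn{2(\ell_{full} - \ell_{null})} clipped at zero, referred
#' to a chi-square with 1 df (the variance component sits on the boundary
#' of its parameter space, so this reference is conservative).
#'
#' @param full,null Nested [RemlFit-class] objects sharing the same fixed
#'   effects and data.
#' @param df Degrees of freedom (default 1).
#' @return list with statistic and p.
#' @export
lrt <- function(full, null, df = 1) {
  stat <- max(0, 2 * (full@logLik - null@logLik))
  list(statistic = stat, p = stats::pchisq(stat, df, lower.tail = FALSE))
}
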