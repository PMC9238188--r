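# Spectral REML machinery shared by the expression-BLUP and eQTL stages.
# Model: y = X b + g + e, g ~ N(0, s2g * K), e ~ N(0, s2e * I). One
# eigendecomposition of K serves every response sharing the same K and the
# per-candidate GLS tests of the multi-locus scan.

#' Precompute the eigendecomposition cache for REML fits against a kinship
#'
#' @param K symmetric PSD matrix (genotypes or samples).
#' @param X fixed-effect design (defaults to an intercept).
#' @return list with eigenvalues (clipped at 0), eigenvectors, and the
#'   rotated design.
#' @export
reml_cache <- function(K, X = NULL) {
  n <- nrow(K)
  if (is.null(X)) X <- matrix(1, n, 1)
  e <- eigen(K, symmetric = TRUE)
  e$values <- pmax(e$values, 0)
  list(d = e$values, U = e$vectors, Xt = crossprod(e$vectors, X), n = n,
       logdet_xx = determinant(crossprod(X))$modulus[1])
}

# REML log-likelihood profile in the variance ratio lambda = s2g/s2e,
# computed on rotated data (yt = U'y, Xt = U'X).
reml_profile <- function(loglam, yt, Xt, d) {
  lam <- exp(loglam)
  n <- length(yt); c <- ncol(Xt)
  w <- 1 / (lam * d + 1)
  XtW <- Xt * w
  XtWX <- crossprod(Xt, XtW)
  b <- solve(XtWX, crossprod(XtW, yt))
  r <- yt - Xt %*% b
  rss <- sum(w * r^2)
  s2e <- rss / (n - c)
  ll <- -0.5 * ((n - c) * log(2 * pi * s2e) + (n - c) +
                  sum(log(lam * d + 1)) +
                  determinant(XtWX)$modulus[1])
  list(ll = ll, b = b, s2e = s2e, w = w)
}

#' REML fit of the one-random-effect mixed model
#'
#' Estimates the polygenic and residual variance components by bounded
#' scalar optimization of the restricted likelihood over the log variance
#' ratio in [-10, 10] (tolerance 1e-6), using a single eigendecomposition of
#' the kinship that can be shared across responses.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (full column rank); intercept-only
#'   when NULL.
#' @param K kinship (ignored when `cache` is given).
#' @param cache optional [reml_cache()] result.
#' @return list: s2g, s2e, h2, loglik, plus the weights and rotated
#'   quantities needed for downstream O(n) GLS tests.
#' @export
mixed_reml <- function(y, X = NULL, K = NULL, cache = NULL) {
  if (is.null(cache)) {
    if (is.null(K)) stop("provide K or cache")
    cache <- reml_cache(K, X)
  } else if (!is.null(X)) {
    cache$Xt <- crossprod(cache$U, X)
  }
  if (qr(cache$Xt)$rank < ncol(cache$Xt)) {
    stop("fixed-effect design is rank deficient (collinear columns)")
  }
  yt <- crossprod(cache$U, y)
  opt <- stats::optimize(function(l) reml_profile(l, yt, cache$Xt, cache$d)$ll,
                         lower = -10, upper = 10, maximum = TRUE,
                         tol = 1e-6)
  lam <- exp(opt$maximum)
  prof <- reml_profile(opt$maximum, yt, cache$Xt, cache$d)
  s2e <- prof$s2e
  s2g <- lam * s2e
  list(s2g = s2g, s2e = s2e, h2 = s2g / (s2g + s2e), loglik = opt$objective,
       lambda = lam, beta = prof$b, weights = prof$w, yt = as.numeric(yt),
       cache = cache)
}

# Batched GLS F-tests: given a REML fit (weights fixed), test each column of
# the rotated candidate matrix Gt as an extra fixed effect. Returns
# data.frame(beta, fstat, p). Candidates collinear with the current design
# (residual norm ~ 0) get p = NA.
gls_scan <- function(fit, Gt) {
  w <- fit$weights
  Xt <- fit$cache$Xt
  n <- length(fit$yt); c <- ncol(Xt)
  sw <- sqrt(w)
  Xs <- Xt * sw
  ys <- fit$yt * sw
  qx <- qr(Xs)
  ry <- qr.resid(qx, ys)
  RG <- qr.resid(qx, Gt * sw)
  gg <- colSums(RG^2)
  gy <- colSums(RG * ry)
  beta <- gy / gg
  rss0 <- sum(ry^2)
  rss1 <- rss0 - gy^2 / gg
  df2 <- n - c - 1
  f <- (rss0 - rss1) / (rss1 / df2)
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  bad <- gg < 1e-10 * max(gg, 1)
  beta[bad] <- NA_real_; p[bad] <- NA_real_; f[bad] <- NA_real_
  data.frame(beta = beta, fstat = f, p = p)
}
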