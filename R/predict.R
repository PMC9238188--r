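# Ridge prediction of phenotypes from SNPs (G), transcript BLUPs (T) or
# their concatenation (G+T), under repeated nested cross-validation.
# The solver works through the n x n dual so that p >> n costs O(n^2 p);
# all columns are standardized internally and coefficients are mapped back
# to the original predictor scale. In the concatenated model the joint
# standardization is what puts SNPs and transcripts on a common scale.

# internal: standardize columns, drop-none; constant columns scale to 0
std_cols <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd0 <- sd
  sd0[sd0 == 0] <- 1
  list(Xs = sweep(sweep(X, 2, mu), 2, sd0, "/"), mu = mu, sd = sd0,
       const = sd == 0)
}

#' Ridge regression fit with unpenalized intercept
#'
#' Minimizes `||y - b0 - X beta||^2 + lam ||beta_std||^2` where the penalty
#' applies to coefficients on the standardized predictor scale; returned
#' effects are on the original scale. Solved by SVD of the standardized
#' design (the dual route), unique for `lam > 0`.
#'
#' @param X predictor matrix (n x p).
#' @param y response.
#' @param lam ridge penalty (>= 0; `lam = 0` requires a full-column-rank
#'   tall X).
#' @return list: `effects` (length p, original scale), `intercept`.
#' @export
ridge_fit <- function(X, y, lam) {
  stopifnot(lam >= 0, ncol(X) >= 1, nrow(X) == length(y))
  if (lam == 0 && ncol(X) > nrow(X))
    stop("lam = 0 with p > n has no unique solution")
  s <- std_cols(X)
  yc <- y - mean(y)
  sv <- svd(s$Xs)
  dd <- sv$d
  keep <- dd > max(dd) * 1e-12
  if (lam == 0 && sum(keep) < ncol(X))
    stop("lam = 0 with rank-deficient X has no unique solution")
  shrink <- dd[keep] / (dd[keep]^2 + lam)
  beta_s <- sv$v[, keep, drop = FALSE] %*%
    (shrink * crossprod(sv$u[, keep, drop = FALSE], yc))
  beta <- as.numeric(beta_s) / s$sd
  beta[s$const] <- 0
  intercept <- mean(y) - sum(beta * s$mu)
  list(effects = stats::setNames(beta, colnames(X)), intercept = intercept)
}

# internal: eigen-dual ridge path. Returns predictions on X_new for every
# lambda, using training-set standardization. K trick: alpha solves
# (Xs Xs' + lam I) alpha = yc; beta = Xs' alpha; pred = Xs_new beta.
ridge_path_predict <- function(X_tr, y_tr, X_new, lambdas) {
  s <- std_cols(X_tr)
  yc <- y_tr - mean(y_tr)
  Kg <- tcrossprod(s$Xs)
  e <- eigen(Kg, symmetric = TRUE)
  d <- pmax(e$values, 0)
  uy <- crossprod(e$vectors, yc)
  Xn <- sweep(sweep(X_new, 2, s$mu), 2, s$sd, "/")
  Kn <- tcrossprod(Xn, s$Xs) %*% e$vectors        # n_new x n_tr
  preds <- matrix(0, nrow(X_new), length(lambdas))
  for (li in seq_along(lambdas)) {
    alpha <- uy / (d + lambdas[li])
    preds[, li] <- mean(y_tr) + Kn %*% alpha
  }
  preds
}

#' Default lambda grid for ridge CV
#'
#' Log-spaced from lambda_max (where all standardized coefficients are near
#' zero, taken as `n * var-scale` of the Gram spectrum) down four decades.
#'
#' @param X predictor matrix.
#' @param n_lambda grid length (default 100).
#' @return decreasing numeric vector.
#' @export
lambda_grid <- function(X, n_lambda = 100) {
  s <- std_cols(X)
  lmax <- max(colSums(s$Xs^2)) * 10
  exp(seq(log(lmax), log(lmax * 1e-4), length.out = n_lambda))
}

# internal: fold assignment depending only on (n, outer, repeats, seed)
make_folds <- function(n, outer, repeats, seed) {
  with_seed(substream_seed(seed, "folds"), {
    lapply(seq_len(repeats), function(r)
      sample(rep_len(seq_len(outer), n)))
  })
}

#' Nested cross-validated ridge prediction
#'
#' Per repeat, individuals are partitioned into `outer` folds; on each outer
#' training set the penalty is chosen by `inner`-fold CV minimizing
#' validation MSE, and one accuracy value -- the squared Pearson correlation
#' between observed and predicted in the held-out fold -- is recorded. Fold
#' assignments derive from the seed only, so models G, T and G+T fitted with
#' the same seed share identical partitions, which is what makes the
#' per-fold accuracy comparisons paired.
#'
#' @param X predictors; @param y response (non-constant).
#' @param outer,inner,repeats cross-validation geometry (defaults 5, 10, 50).
#' @param lambdas penalty grid (default [lambda_grid()]).
#' @param seed integer; drives fold sampling only.
#' @param return_effects also accumulate the mean, over all outer training
#'   fits at their selected penalties, of the coefficient vector on the
#'   original predictor scale (the cross-validation-averaged alternative to
#'   a single full-data refit for ranking).
#' @return object of class `model_fit`: list with `r2` (repeats x outer
#'   matrix), `lambda_selected` (per repeat x fold), `folds`, and `effects`
#'   when requested.
#' @export
nested_cv <- function(X, y, outer = 5, inner = 10, repeats = 50,
                      lambdas = NULL, seed = 1, return_effects = FALSE) {
  if (stats::sd(y) == 0) stop("constant response; accuracy undefined")
  n <- length(y)
  stopifnot(n >= outer * 2, nrow(X) == n)
  if (is.null(lambdas)) lambdas <- lambda_grid(X)
  folds <- make_folds(n, outer, repeats, seed)
  r2 <- matrix(NA_real_, repeats, outer)
  lam_sel <- matrix(NA_real_, repeats, outer)
  eff_sum <- if (return_effects) numeric(ncol(X)) else NULL
  for (r in seq_len(repeats)) {
    fo <- folds[[r]]
    for (k in seq_len(outer)) {
      tr <- which(fo != k); te <- which(fo == k)
      # standardize once on the outer training set; the inner folds reuse
      # submatrices of its Gram (inner re-centering would change the
      # selected penalty only marginally and costs 10x the linear algebra)
      s <- std_cols(X[tr, , drop = FALSE])
      Kg <- tcrossprod(s$Xs)
      fi <- rep_len(seq_len(inner), length(tr))
      mse <- matrix(0, inner, length(lambdas))
      for (j in seq_len(inner)) {
        itr <- which(fi != j); iva <- which(fi == j)
        e <- eigen(Kg[itr, itr], symmetric = TRUE)
        d <- pmax(e$values, 0)
        yc <- y[tr][itr] - mean(y[tr][itr])
        uy <- crossprod(e$vectors, yc)
        Kva <- Kg[iva, itr, drop = FALSE] %*% e$vectors
        for (li in seq_along(lambdas)) {
          pr <- mean(y[tr][itr]) + Kva %*% (uy / (d + lambdas[li]))
          mse[j, li] <- mean((pr - y[tr][iva])^2)
        }
      }
      best <- which.min(colMeans(mse))
      lam_sel[r, k] <- lambdas[best]
      e <- eigen(Kg, symmetric = TRUE)
      d <- pmax(e$values, 0)
      uy <- crossprod(e$vectors, y[tr] - mean(y[tr]))
      Xn <- sweep(sweep(X[te, , drop = FALSE], 2, s$mu), 2, s$sd, "/")
      Kte <- tcrossprod(Xn, s$Xs) %*% e$vectors
      alpha <- e$vectors %*% (uy / (d + lambdas[best]))
      pr <- mean(y[tr]) + Kte %*% (uy / (d + lambdas[best]))
      r2[r, k] <- if (stats::sd(pr) == 0) 0 else stats::cor(y[te], pr)^2
      if (return_effects) {
        # dual-to-primal: beta_std = Xs' alpha, back to original scale
        eff_sum <- eff_sum + as.numeric(crossprod(s$Xs, alpha)) / s$sd
      }
    }
  }
  structure(list(r2 = r2, lambda_selected = lam_sel, folds = folds,
                 outer = outer, inner = inner, repeats = repeats,
                 effects = if (return_effects)
                   stats::setNames(eff_sum / (repeats * outer), colnames(X))),
            class = "model_fit")
}

#' Compare paired accuracy distributions of two models
#'
#' Paired two-sided test on per-fold accuracies sharing the same fold
#' partitions: Wilcoxon signed-rank by default (the reported test), paired
#' t-test as the alternative. When every pairwise difference is zero the
#' p-value is reported as 1 with a flag.
#'
#' @param r2_multi,r2_single equal-length accuracy vectors (or `model_fit`
#'   objects).
#' @param test "wilcoxon" or "ttest".
#' @return list: mean_diff, p, sign ("+", "-", "0"), test, degenerate.
#' @export
compare_models <- function(r2_multi, r2_single,
                           test = c("wilcoxon", "ttest")) {
  test <- match.arg(test)
  a <- if (inherits(r2_multi, "model_fit")) as.numeric(r2_multi$r2) else r2_multi
  b <- if (inherits(r2_single, "model_fit")) as.numeric(r2_single$r2) else r2_single
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- a - b
  md <- mean(d)
  if (all(d == 0))
    return(list(mean_diff = 0, p = 1, sign = "0", test = test,
                degenerate = TRUE))
  p <- if (test == "wilcoxon")
    suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
  else if (stats::sd(d) <= 1e-10 * max(abs(d)))
    0  # (numerically) identical non-zero differences: t is infinite
  else stats::t.test(a, b, paired = TRUE)$p.value
  list(mean_diff = md, p = p, sign = if (md > 0) "+" else if (md < 0) "-" else "0",
       test = test, degenerate = FALSE)
}

#' Full-data ridge effects for ranking
#'
#' Chooses the penalty by 10-fold CV on all data (folds from the seed), then
#' refits once on everything; the resulting effect vector is what the
#' rank-change statistic consumes. Deterministic given the seed.
#'
#' @inheritParams nested_cv
#' @param inner folds for the penalty choice.
#' @return list: `effects`, `intercept`, `lambda`.
#' @export
full_effects <- function(X, y, lambdas = NULL, inner = 10, seed = 1) {
  if (is.null(lambdas)) lambdas <- lambda_grid(X)
  n <- length(y)
  fo <- with_seed(substream_seed(seed, "full_effects"),
                  sample(rep_len(seq_len(inner), n)))
  mse <- matrix(0, inner, length(lambdas))
  for (j in seq_len(inner)) {
    tr <- which(fo != j); va <- which(fo == j)
    pr <- ridge_path_predict(X[tr, , drop = FALSE], y[tr],
                             X[va, , drop = FALSE], lambdas)
    mse[j, ] <- colMeans((pr - y[va])^2)
  }
  lam <- lambdas[which.min(colMeans(mse))]
  fit <- ridge_fit(X, y, lam)
  list(effects = fit$effects, intercept = fit$intercept, lambda = lam)
}
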