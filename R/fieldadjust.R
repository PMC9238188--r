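# Field-trial adjustment: y = mu + block + genotype + eps, with eps either
# iid or separable AR1(rho_row) x AR1(rho_col), fitted by maximum likelihood
# so AIC is comparable across fixed-effect structures. Genotype enters as a
# fixed effect; the adjusted means feed the prediction stage, which
# re-models genetics itself, so shrinking twice is avoided.

# ML profile log-likelihood of a GLS fit with correlation matrix implied by
# (rho_r, rho_c); returns coefficients on the whitened design.
gls_ar1_fit <- function(y, X, row, col, rho_r, rho_c) {
  n <- length(y)
  if (rho_r == 0 && rho_c == 0) {
    Wy <- y; WX <- X; logdet <- 0
  } else {
    nr <- max(row); nc <- max(col)
    complete <- n == nr * nc && !anyDuplicated(cbind(row, col))
    if (complete) {
      Lr <- ar1_chol(nr, rho_r); Lc <- ar1_chol(nc, rho_c)
      ord <- order(row, col)       # y[ord] is row-major => vec of (nc x nr)
      whiten <- function(v) {
        M <- matrix(v[ord], nc, nr)
        out <- t(forwardsolve(Lr, t(forwardsolve(Lc, M))))
        res <- numeric(n); res[ord] <- as.numeric(out); res
      }
      Wy <- whiten(y)
      WX <- apply(X, 2, whiten)
      logdet <- 2 * (nc * sum(log(diag(Lr))) + nr * sum(log(diag(Lc))))
    } else {
      # conditional multivariate-normal likelihood on the observed cells
      R <- (rho_r^abs(outer(row, row, "-"))) *
           (rho_c^abs(outer(col, col, "-")))
      Lt <- tryCatch(chol(R), error = function(e) NULL)
      if (is.null(Lt)) return(list(loglik = -Inf))
      Wy <- forwardsolve(t(Lt), y)
      WX <- forwardsolve(t(Lt), X)
      logdet <- 2 * sum(log(diag(Lt)))
    }
  }
  fit <- stats::lm.fit(WX, Wy)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  list(loglik = -0.5 * (n * log(2 * pi * sigma2) + n + logdet),
       coef = fit$coefficients, sigma2 = sigma2, rank = fit$rank)
}

#' Adjust one field trait for block and autoregressive spatial heterogeneity
#'
#' Fits, by maximum likelihood, a set of candidate models
#' `y = mu + block + genotype + eps` where `eps` is iid or separable
#' AR1(rho_row) x AR1(rho_col), scanning the autoregressive parameter over a
#' grid (one common coarse value for rows and columns, then per-dimension
#' refinement at step 0.02), and selects the candidate with minimum AIC.
#' Returns genotype adjusted means (fixed-effect genotype estimates plus the
#' intercept and average block effect) under the winning model.
#'
#' @param field long data.frame with columns genotype, site, block, row, col,
#'   trait, value (the format produced by [simulate_phenotypes()]).
#' @param trait trait name to adjust.
#' @param site site code; required when `field` holds several sites.
#' @param rho_grid coarse grid for the common autoregressive parameter.
#' @param candidate_models subset of `iid`, `block`, `ar1`, `block_ar1`.
#' @param refine_step step of the local refinement around the best coarse rho.
#' @return list with `means` (named numeric, one adjusted mean per genotype;
#'   NA for genotypes that could not be estimated), `model` (selected
#'   candidate, rho_row, rho_col, AIC, log-likelihood) and `aic_table`.
#' @export
adjust_phenotype <- function(field, trait, site = NULL,
                             rho_grid = seq(-0.9, 0.9, by = 0.1),
                             candidate_models = c("iid", "block", "ar1",
                                                  "block_ar1"),
                             refine_step = 0.02) {
  d <- field[field$trait == trait, , drop = FALSE]
  if (!is.null(site)) d <- d[d$site == site, , drop = FALSE]
  if (length(unique(d$site)) > 1)
    stop("several sites present; pass `site`")
  if (nrow(d) < 2) stop("need at least 2 observations")
  any_spatial <- any(candidate_models %in% c("ar1", "block_ar1"))
  if (any_spatial && (is.null(d$row) || is.null(d$col) ||
                      anyNA(d$row) || anyNA(d$col)))
    stop("row/col layout required for spatial candidates")
  stopifnot(all(rho_grid > -1 & rho_grid < 1))

  gf <- factor(d$genotype)
  has_block <- !is.null(d$block) && length(unique(d$block)) > 1
  designs <- list(
    plain = stats::model.matrix(~gf),
    block = if (has_block)
      stats::model.matrix(~ factor(d$block) + gf) else NULL
  )
  n_block_cols <- if (has_block) length(unique(d$block)) - 1L else 0L

  fits <- list()
  for (cand in candidate_models) {
    use_block <- cand %in% c("block", "block_ar1") && has_block
    X <- if (use_block) designs$block else designs$plain
    spatial <- cand %in% c("ar1", "block_ar1")
    if (!spatial) {
      f <- gls_ar1_fit(d$value, X, d$row %||% seq_len(nrow(d)),
                       d$col %||% rep(1L, nrow(d)), 0, 0)
      k <- ncol(X) + 1
      fits[[cand]] <- c(f, list(rho_row = 0, rho_col = 0,
                                aic = -2 * f$loglik + 2 * k,
                                use_block = use_block))
    } else {
      ll <- vapply(rho_grid, function(r)
        gls_ar1_fit(d$value, X, d$row, d$col, r, r)$loglik, numeric(1))
      best <- rho_grid[which.max(ll)]
      rr <- best; rc <- best
      refine <- function(fixed, dim) {
        grid <- seq(max(-0.98, fixed - 4 * refine_step),
                    min(0.98, fixed + 4 * refine_step), by = refine_step)
        lls <- vapply(grid, function(r) {
          if (dim == "row") gls_ar1_fit(d$value, X, d$row, d$col, r, rc)$loglik
          else gls_ar1_fit(d$value, X, d$row, d$col, rr, r)$loglik
        }, numeric(1))
        grid[which.max(lls)]
      }
      rr <- refine(best, "row")
      rc <- refine(best, "col")
      f <- gls_ar1_fit(d$value, X, d$row, d$col, rr, rc)
      k <- ncol(X) + 1 + 2   # + sigma2 + two AR parameters
      fits[[cand]] <- c(f, list(rho_row = rr, rho_col = rc,
                                aic = -2 * f$loglik + 2 * k,
                                use_block = use_block))
    }
  }
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  winner <- names(fits)[which.min(aics)]
  fw <- fits[[winner]]
  cf <- fw$coef
  nb <- if (fw$use_block) n_block_cols else 0L
  block_mean <- if (nb > 0) mean(c(0, cf[2:(1 + nb)]), na.rm = TRUE) else 0
  g_eff <- c(0, cf[(2 + nb):length(cf)])
  means <- cf[1] + block_mean + g_eff
  names(means) <- levels(gf)
  list(means = means,
       model = list(candidate = winner, rho_row = fw$rho_row,
                    rho_col = fw$rho_col, aic = fw$aic, loglik = fw$loglik),
       aic_table = data.frame(candidate = names(fits), aic = unname(aics)))
}

#' Adjust all traits at all sites and assemble the phenotype matrix
#'
#' Traits measured at different sites are treated as different traits,
#' named `<trait>_<site>`.
#'
#' @inheritParams adjust_phenotype
#' @param traits optional subset of trait names.
#' @return list with `adjusted` (genotype x trait_site matrix) and `report`
#'   (one row per trait_site: selected model, rho, AIC).
#' @export
adjust_phenotypes <- function(field, traits = NULL,
                              rho_grid = seq(-0.9, 0.9, by = 0.1),
                              candidate_models = c("iid", "block", "ar1",
                                                   "block_ar1"),
                              refine_step = 0.02) {
  if (is.null(traits)) traits <- unique(field$trait)
  combos <- unique(field[field$trait %in% traits, c("trait", "site")])
  genotypes <- sort(unique(field$genotype))
  out <- matrix(NA_real_, length(genotypes), nrow(combos),
                dimnames = list(genotypes,
                                paste(combos$trait, combos$site, sep = "_")))
  rep_rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    a <- adjust_phenotype(field, combos$trait[i], combos$site[i],
                          rho_grid, candidate_models, refine_step)
    out[names(a$means), i] <- a$means
    rep_rows[[i]] <- data.frame(trait = combos$trait[i], site = combos$site[i],
                                model = a$model$candidate,
                                rho_row = a$model$rho_row,
                                rho_col = a$model$rho_col, aic = a$model$aic,
                                stringsAsFactors = FALSE)
  }
  list(adjusted = out, report = do.call(rbind, rep_rows))
}
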