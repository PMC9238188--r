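# Multi-locus mixed-model eQTL scan: forward inclusion / backward
# elimination of SNP cofactors under a polygenic mixed model, with the
# variance components re-estimated at every step, and mBonf model selection
# (largest model in which every cofactor passes the Bonferroni-corrected 5%
# threshold).

#' Realized kinship from standardized dosages
#'
#' Cross-product of column-standardized dosages divided by the number of
#' SNPs. Monomorphic SNPs are dropped; tiny negative eigenvalues are clipped
#' lazily by the REML machinery. Two identical genotypes share an
#' off-diagonal entry equal to their diagonal entries.
#'
#' @param geno a `genotype_matrix` or a plain dosage matrix
#'   (individuals x SNPs).
#' @return symmetric genotypes x genotypes matrix.
#' @export
kinship <- function(geno) {
  M <- if (inherits(geno, "genotype_matrix")) geno$dosages else geno
  if (nrow(M) < 2 || ncol(M) < 1) stop("need >= 2 genotypes and >= 1 SNP")
  sds <- apply(M, 2, stats::sd)
  M <- M[, sds > 0, drop = FALSE]
  if (ncol(M) == 0) stop("all SNPs are monomorphic")
  Ms <- scale(M)
  tcrossprod(Ms) / ncol(Ms)
}

#' Precompute rotated quantities for a transcriptome-wide multi-locus scan
#'
#' The kinship eigendecomposition and the rotated dosage matrix do not
#' depend on the response, so they are computed once and shared across
#' transcripts (scan results are independent of transcript order).
#'
#' @param geno dosage matrix or `genotype_matrix` (no missing values).
#' @param K kinship; computed from `geno` when NULL.
#' @return opaque precomputation list for [mlmm_scan()].
#' @export
mlmm_precompute <- function(geno, K = NULL) {
  G <- if (inherits(geno, "genotype_matrix")) geno$dosages else geno
  if (anyNA(G)) stop("missing dosages are not supported; impute upstream")
  if (is.null(K)) K <- kinship(G)
  cache <- reml_cache(K)
  list(G = G, Gt = crossprod(cache$U, G), cache = cache,
       snp_ids = colnames(G), n = nrow(G), p = ncol(G))
}

#' Multi-locus mixed-model scan for one response
#'
#' Step 0 is a single-marker mixed-model scan (each SNP as fixed effect
#' given the kinship random effect, variance components from the null
#' model). The forward phase adds the minimum-p candidate, re-estimates the
#' variance components with the enlarged fixed design, and re-tests all
#' remaining candidates; after `max_steps` forward inclusions the backward
#' phase removes the least significant cofactor one at a time until none is
#' left, re-estimating variance components at every elimination. Candidates
#' whose dosages correlate above 0.999 with a current cofactor are skipped.
#'
#' @param y response (one transcript's genotypic BLUPs), aligned to the rows
#'   of the dosage matrix.
#' @param pre result of [mlmm_precompute()]; alternatively pass `geno`/`K`.
#' @param geno,K used to build `pre` when it is NULL.
#' @param max_steps maximum number of forward inclusions.
#' @return object of class `stepwise_path`: list of steps, each with
#'   `direction` (forward/backward), `cofactors`, `cof_p`, `cof_beta`,
#'   `min_cand_p`, `s2g`, `s2e`. Step 1 of the list is the null scan.
#' @export
mlmm_scan <- function(y, pre = NULL, geno = NULL, K = NULL, max_steps = 10) {
  if (is.null(pre)) pre <- mlmm_precompute(geno, K)
  stopifnot(max_steps >= 1, length(y) == pre$n)
  n <- pre$n
  steps <- list()
  cof <- character(0)
  record <- function(direction) {
    X <- cbind(`(Intercept)` = 1, pre$G[, cof, drop = FALSE])
    if (n < ncol(X) + 2) return(NULL)
    fit <- mixed_reml(y, X = X, cache = pre$cache)
    # drop-one F tests for the cofactors, at this step's variance components
    cof_p <- cof_beta <- stats::setNames(numeric(length(cof)), cof)
    if (length(cof)) {
      sw <- sqrt(fit$weights)
      Xs <- fit$cache$Xt * sw
      ys <- fit$yt * sw
      for (ci in seq_along(cof)) {
        qx <- qr(Xs[, -(1 + ci), drop = FALSE])
        ry <- qr.resid(qx, ys)
        rg <- qr.resid(qx, Xs[, 1 + ci])
        gg <- sum(rg^2); gy <- sum(rg * ry)
        rss0 <- sum(ry^2); rss1 <- rss0 - gy^2 / gg
        df2 <- n - ncol(Xs)
        fstat <- (rss0 - rss1) / (rss1 / df2)
        cof_p[ci] <- stats::pf(fstat, 1, df2, lower.tail = FALSE)
        cof_beta[ci] <- gy / gg
      }
    }
    # candidate scan: all SNPs not in the model and not collinear with it
    cand <- setdiff(pre$snp_ids, cof)
    keep <- cand
    if (length(cof)) {
      cc <- suppressWarnings(
        stats::cor(pre$G[, cand, drop = FALSE], pre$G[, cof, drop = FALSE]))
      cc[is.na(cc)] <- 0
      keep <- cand[apply(abs(cc) < 0.999, 1, all)]
    }
    sc <- if (length(keep))
      gls_scan(fit, pre$Gt[, keep, drop = FALSE]) else NULL
    list(direction = direction, cofactors = cof, cof_p = cof_p,
         cof_beta = cof_beta,
         cand_ids = keep,
         cand_p = if (is.null(sc)) numeric(0) else stats::setNames(sc$p, keep),
         min_cand_p = if (is.null(sc) || all(is.na(sc$p))) NA_real_
                      else min(sc$p, na.rm = TRUE),
         s2g = fit$s2g, s2e = fit$s2e)
  }
  st <- record("forward")
  steps[[1]] <- st
  # forward phase
  for (k in seq_len(max_steps)) {
    st <- steps[[length(steps)]]
    if (!length(st$cand_ids) || all(is.na(st$cand_p))) break
    cof <- c(cof, names(which.min(st$cand_p)))
    nxt <- record("forward")
    if (is.null(nxt)) {
      warning("too few observations to extend the model; partial path")
      cof <- cof[-length(cof)]
      break
    }
    steps[[length(steps) + 1]] <- nxt
  }
  # backward phase
  while (length(cof) > 0) {
    st <- steps[[length(steps)]]
    worst <- names(which.max(st$cof_p))
    cof <- setdiff(cof, worst)
    steps[[length(steps) + 1]] <- record("backward")
  }
  structure(list(steps = steps, n_snps = pre$p, snp_ids = pre$snp_ids),
            class = "stepwise_path")
}

#' mBonf model selection on a stepwise path
#'
#' Returns the cofactors of the largest step in which every cofactor is
#' significant at the Bonferroni-corrected `alpha` (p <= alpha / n_snps,
#' boundary included), with effects and scores from that step's joint model.
#' Empty when no step qualifies.
#'
#' @param path a `stepwise_path`.
#' @param alpha significance level before correction.
#' @param n_snps Bonferroni denominator; defaults to the number of SNPs in
#'   the scan.
#' @return data.frame(snp_id, effect, p, score), zero rows if nothing is
#'   selected.
#' @export
select_mbonf <- function(path, alpha = 0.05, n_snps = NULL) {
  if (is.null(n_snps)) n_snps <- path$n_snps
  thr <- alpha / n_snps
  best <- NULL; best_size <- 0L
  for (st in path$steps) {
    k <- length(st$cofactors)
    if (k > best_size && k > 0 && all(!is.na(st$cof_p)) &&
        all(st$cof_p <= thr)) {
      best <- st; best_size <- k
    }
  }
  if (is.null(best))
    return(data.frame(snp_id = character(0), effect = numeric(0),
                      p = numeric(0), score = numeric(0)))
  data.frame(snp_id = best$cofactors, effect = unname(best$cof_beta),
             p = unname(best$cof_p), score = -log10(unname(best$cof_p)),
             stringsAsFactors = FALSE)
}

#' Transcriptome-wide eQTL mapping
#'
#' Runs [mlmm_scan()] + [select_mbonf()] for every transcript and stacks the
#' selected associations. Each transcript's result depends only on its own
#' response, so the table is invariant to transcript order.
#'
#' @param blups genotypes x transcripts matrix (from [genotype_blups()]).
#' @param geno `genotype_matrix` or dosage matrix aligned to the rows.
#' @param K optional kinship.
#' @param max_steps forward steps per transcript.
#' @param alpha mBonf level.
#' @return data.frame(transcript_id, snp_id, effect, p, score).
#' @export
eqtl_scan_all <- function(blups, geno, K = NULL, max_steps = 10, alpha = 0.05) {
  pre <- mlmm_precompute(geno, K)
  res <- vector("list", ncol(blups))
  for (j in seq_len(ncol(blups))) {
    path <- mlmm_scan(blups[, j], pre = pre, max_steps = max_steps)
    sel <- select_mbonf(path, alpha = alpha)
    if (nrow(sel))
      res[[j]] <- data.frame(transcript_id = colnames(blups)[j], sel,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(transcript_id = character(0), snp_id = character(0),
                      effect = numeric(0), p = numeric(0), score = numeric(0))
  rownames(out) <- NULL
  out
}
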