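# Transcript processing: filter lowly expressed transcripts, TMM
# normalisation, log2(CPM + 1), then one genotypic BLUP per transcript.
# Pipeline order is fixed: filter -> TMM -> log-CPM -> BLUP.

#' Filter lowly expressed transcripts
#'
#' Keeps transcripts with at least `min_count` in at least
#' `ceiling(min_prop * n_genotypes)` distinct genotypes. The rule operates at
#' the genotype level: a transcript is counted once per genotype regardless
#' of how many of its replicates pass. Column order is preserved; the rule
#' is `>=` so a transcript expressed in exactly the threshold fraction is
#' kept. Idempotent: re-filtering the output changes nothing.
#'
#' @param counts samples x transcripts matrix of non-negative integers.
#' @param sample_map data.frame(sample_id, genotype, batch) aligned to rows,
#'   or NULL to treat every sample as its own genotype.
#' @param min_count,min_prop the threshold: `min_count` reads in
#'   `min_prop` of the genotypes.
#' @return the filtered counts matrix.
#' @export
filter_transcripts <- function(counts, sample_map = NULL,
                               min_count = 1, min_prop = 0.10) {
  if (length(counts) == 0 || nrow(counts) == 0 || ncol(counts) == 0)
    stop("empty count matrix")
  geno <- if (is.null(sample_map)) rownames(counts) %||%
    as.character(seq_len(nrow(counts))) else
    sample_map$genotype[match(rownames(counts), sample_map$sample_id)]
  n_geno <- length(unique(geno))
  need <- ceiling(min_prop * n_geno)
  hit <- rowsum((counts >= min_count) * 1L, geno) > 0
  keep <- colSums(hit) >= need
  counts[, keep, drop = FALSE]
}

#' TMM normalisation factors
#'
#' Per-sample scaling factors by the trimmed mean of M-values: log-ratios
#' against a reference sample are double-trimmed (30% on M, 5% on A) and
#' averaged with precision weights, then the factors are rescaled to
#' geometric mean 1. The reference is the sample whose upper quartile of
#' scaled counts is closest to the mean upper quartile. Computation is
#' delegated to edgeR's implementation of the estimator.
#'
#' @param counts samples x transcripts matrix.
#' @param trim_m,trim_a trim fractions for the M and A components.
#' @return numeric vector of factors, one per sample, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  if (nrow(counts) < 2) stop("need at least 2 samples")
  if (any(rowSums(counts) <= 0)) stop("every sample needs a positive library size")
  f <- edgeR::calcNormFactors(t(counts), method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a,
                              doWeighting = TRUE)
  stats::setNames(as.numeric(f), rownames(counts))
}

#' log2 counts-per-million with a +1 offset
#'
#' `log2(count / (library_size * factor) * 1e6 + 1)`. The +1 offset (rather
#' than the +0.5 customary in a voom analysis) maps zero counts to exactly 0
#' and keeps all values non-negative, which the downstream modelling relies
#' on. Strictly increasing in the count for a fixed sample.
#'
#' @param counts samples x transcripts matrix.
#' @param norm_factors per-sample factors from [tmm_factors()] (default all 1).
#' @return real matrix, same shape as `counts`.
#' @export
log_cpm <- function(counts, norm_factors = NULL) {
  lib <- rowSums(counts)
  if (any(lib <= 0)) stop("zero library size")
  if (is.null(norm_factors)) norm_factors <- rep(1, nrow(counts))
  log2(counts / (lib * norm_factors) * 1e6 + 1)
}

#' Genotypic BLUPs of transcript expression
#'
#' Per transcript, fits `y = mu + batch (fixed) + genotype (random, iid) + e`
#' by REML over the single variance ratio and returns the predicted genotype
#' effects. Genotypes with a single replicate get shrunken predictions; a
#' transcript with no genetic variance yields BLUPs at (numerically) zero.
#' Column means of the result are zero by construction (random-effect
#' predictions under a model containing the intercept).
#'
#' If the batch factor is collinear with the intercept (a single batch) or
#' otherwise rank deficient, the batch term is dropped with a warning.
#'
#' @param logcpm samples x transcripts matrix from [log_cpm()].
#' @param sample_map data.frame(sample_id, genotype, batch) covering all rows.
#' @return genotypes x transcripts matrix of BLUPs.
#' @export
genotype_blups <- function(logcpm, sample_map) {
  ord <- match(rownames(logcpm), sample_map$sample_id)
  if (anyNA(ord)) stop("every sample must appear in sample_map")
  sm <- sample_map[ord, ]
  genos <- sort(unique(sm$genotype))
  m <- length(genos)
  n <- nrow(logcpm)
  Z <- matrix(0, n, m, dimnames = list(rownames(logcpm), genos))
  Z[cbind(seq_len(n), match(sm$genotype, genos))] <- 1
  X <- if (length(unique(sm$batch)) > 1)
    stats::model.matrix(~ factor(sm$batch)) else matrix(1, n, 1)
  if (qr(X)$rank < ncol(X)) {
    warning("batch design rank deficient; dropping batch term")
    X <- matrix(1, n, 1)
  }
  K <- tcrossprod(Z)
  cache <- reml_cache(K, X)
  Yt <- crossprod(cache$U, logcpm)       # rotate all transcripts at once
  ZtU <- crossprod(Z, cache$U)
  blups <- matrix(0, m, ncol(logcpm), dimnames = list(genos, colnames(logcpm)))
  for (j in seq_len(ncol(logcpm))) {
    yt <- Yt[, j]
    opt <- stats::optimize(function(l) reml_profile(l, yt, cache$Xt, cache$d)$ll,
                           lower = -10, upper = 10, maximum = TRUE, tol = 1e-6)
    prof <- reml_profile(opt$maximum, yt, cache$Xt, cache$d)
    lam <- exp(opt$maximum)
    # g_hat = s2g Z' V^{-1} (y - Xb); V^{-1} = U diag(w) U' / s2e, s2g = lam*s2e
    r <- yt - cache$Xt %*% prof$b
    blups[, j] <- lam * as.numeric(ZtU %*% (prof$w * r))
  }
  blups
}

#' Run the full expression processing chain
#'
#' filter -> TMM -> log-CPM -> genotypic BLUPs.
#'
#' @inheritParams filter_transcripts
#' @return list with `counts` (filtered), `norm_factors`, `logcpm`, `blups`.
#' @export
process_expression <- function(counts, sample_map,
                               min_count = 1, min_prop = 0.10) {
  fc <- filter_transcripts(counts, sample_map, min_count, min_prop)
  nf <- tmm_factors(fc)
  lc <- log_cpm(fc, nf)
  list(counts = fc, norm_factors = nf, logcpm = lc,
       blups = genotype_blups(lc, sample_map))
}
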