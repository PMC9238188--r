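test_that("kinship matches an elementwise formula oracle and is PSD", {
  set.seed(3)
  M <- matrix(rbinom(5 * 8, 2, 0.4), 5, 8)
  M[, 8] <- 1L                       # monomorphic: must be dropped
  K <- kinship(M)
  # oracle straight from the definition: standardized columns, crossprod / p
  Ms <- M[, apply(M, 2, sd) > 0, drop = FALSE]
  Ms <- sweep(sweep(Ms, 2, colMeans(Ms)), 2, apply(Ms, 2, sd), "/")
  Ko <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    Ko[i, j] <- sum(Ms[i, ] * Ms[j, ]) / ncol(Ms)
  expect_equal(K, Ko, tolerance = 1e-12, ignore_attr = TRUE)
  # identical genotypes share diagonal and off-diagonal entries
  M2 <- rbind(M[1:4, ], M[4, ])
  K2 <- kinship(M2)
  expect_equal(K2[4, 5], K2[4, 4], tolerance = 1e-12)
  expect_equal(K2[5, 5], K2[4, 4], tolerance = 1e-12)
  set.seed(8)
  K3 <- kinship(matrix(rbinom(200, 2, 0.3), 20, 10))
  expect_gt(min(eigen(K3, symmetric = TRUE)$values), -1e-8)
  expect_error(kinship(matrix(1, 4, 3)), "monomorphic")
})

test_that("REML optimum beats a dense grid of the variance ratio", {
  set.seed(5)
  n <- 80
  K <- kinship(matrix(rbinom(n * 60, 2, 0.35), n, 60))
  g <- t(chol(K + diag(1e-6, n))) %*% rnorm(n)
  y <- as.numeric(g + rnorm(n))
  fit <- mixed_reml(y, K = K)
  cache <- reml_cache(K)
  yt <- crossprod(cache$U, y)
  grid_ll <- vapply(seq(-10, 10, length.out = 100), function(l)
    redunrank:::reml_profile(l, yt, cache$Xt, cache$d)$ll, numeric(1))
  expect_gte(fit$loglik, max(grid_ll) - 1e-6)
})

test_that("heritability is recovered and controlled under the null", {
  set.seed(6)
  n <- 250
  G <- matrix(rbinom(n * 150, 2, 0.35), n, 150)
  K <- kinship(G)
  Kc <- t(chol(K + diag(1e-8, n)))
  h2 <- vapply(1:20, function(s) {
    set.seed(100 + s)
    g <- Kc %*% rnorm(n)
    g <- g / sd(g) * sqrt(0.5)
    y <- as.numeric(g + rnorm(n, 0, sqrt(0.5)))
    mixed_reml(y, K = K)$h2
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.5), 0.15)
  h0 <- vapply(1:50, function(s) {
    set.seed(200 + s)
    mixed_reml(rnorm(n), K = K)$h2
  }, numeric(1))
  expect_gte(mean(h0 < 0.1), 0.9)
})

test_that("step-0 p-values match an independently coded mixed-model scan", {
  set.seed(11)
  n <- 120; p <- 50
  G <- matrix(rbinom(n * p, 2, 0.4), n, p,
              dimnames = list(NULL, paste0("s", 1:p)))
  K <- kinship(G)
  y <- as.numeric(0.6 * G[, 7] + t(chol(K + diag(1e-6, n))) %*% rnorm(n) +
                    rnorm(n))
  path <- mlmm_scan(y, geno = G, K = K, max_steps = 1)
  got <- path$steps[[1]]$cand_p
  # oracle: dense REML (its own grid + optimize) and explicit GLS per SNP
  V_of <- function(l) l * K + diag(n)
  ll_of <- function(l) {
    V <- V_of(l); Vi <- solve(V)
    X <- matrix(1, n, 1)
    b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - 1)
    -0.5 * ((n - 1) * log(2 * pi * s2) + (n - 1) +
              determinant(V)$modulus[1] +
              determinant(t(X) %*% Vi %*% X)$modulus[1])
  }
  lhat <- optimize(function(ll) ll_of(exp(ll)), c(-10, 10),
                   maximum = TRUE, tol = 1e-9)$maximum
  Vi <- solve(V_of(exp(lhat)))
  W <- chol(Vi)
  pw <- vapply(seq_len(p), function(j) {
    Xf <- cbind(1, G[, j])
    Xw <- W %*% Xf; yw <- W %*% y
    f1 <- lm.fit(Xw, yw)
    f0 <- lm.fit(Xw[, 1, drop = FALSE], yw)
    rss1 <- sum(f1$residuals^2); rss0 <- sum(f0$residuals^2)
    fs <- (rss0 - rss1) / (rss1 / (n - 2))
    pf(fs, 1, n - 2, lower.tail = FALSE)
  }, numeric(1))
  expect_equal(unname(got[paste0("s", 1:p)]), pw, tolerance = 1e-6)
})

test_that("a planted QTL is picked up at step 1 and selected by mBonf", {
  set.seed(21)
  n <- 200; p <- 300
  G <- matrix(rbinom(n * p, 2, 0.4), n, p,
              dimnames = list(NULL, paste0("s", 1:p)))
  K <- kinship(G)
  q <- scale(G[, 42]) * sqrt(0.4)
  y <- as.numeric(q + rnorm(n, 0, sqrt(0.6)))
  path <- mlmm_scan(y, geno = G, K = K, max_steps = 3)
  first <- path$steps[[2]]$cofactors[1]
  r2 <- cor(G[, first], G[, "s42"])^2
  expect_true(first == "s42" || r2 > 0.8)
  sel <- select_mbonf(path, alpha = 0.05)
  expect_true("s42" %in% sel$snp_id ||
                any(cor(G[, sel$snp_id, drop = FALSE], G[, "s42"])^2 > 0.8))
})

test_that("mBonf selects the largest fully significant step", {
  fake_path <- function(steps) {
    structure(list(steps = steps, n_snps = 1000), class = "stepwise_path")
  }
  st <- function(cof, p) list(direction = "forward", cofactors = cof,
                              cof_p = setNames(p, cof),
                              cof_beta = setNames(rep(1, length(cof)), cof))
  thr <- 0.05 / 1000
  path <- fake_path(list(st(character(0), numeric(0)),
                         st("a", thr),                 # boundary: included
                         st(c("a", "b"), c(thr, 2e-5)),
                         st(c("a", "b", "c"), c(thr, 2e-5, 1e-3))))
  sel <- select_mbonf(path, alpha = 0.05)
  # exhaustive check over steps: step 3 is the largest with all p <= thr
  expect_setequal(sel$snp_id, c("a", "b"))
  # no significant step -> empty
  path0 <- fake_path(list(st(character(0), numeric(0)), st("a", 0.01)))
  expect_equal(nrow(select_mbonf(path0, alpha = 0.05)), 0)
  expect_equal(sel$score, -log10(sel$p), tolerance = 1e-12)
})

test_that("transcriptome scan results do not depend on transcript order", {
  w <- tiny_world(seed = 31, n_ind = 80, genes_per_chrom = 10)
  ex <- simulate_expression(w$geno, w$ann, n_cis = 5, n_trans = 5,
                            n_hubs = 1, hub_fanout = 2, effect_sd = 1.5,
                            seed = 31)
  ep <- process_expression(ex$counts, ex$sample_map)
  bl <- ep$blups[w$geno$ind_ids, ]
  eq1 <- eqtl_scan_all(bl, w$geno, max_steps = 2)
  eq2 <- eqtl_scan_all(bl[, rev(colnames(bl))], w$geno, max_steps = 2)
  key <- function(d) d[order(d$transcript_id, d$snp_id),
                       c("transcript_id", "snp_id", "p")]
  expect_equal(key(eq1), key(eq2), ignore_attr = TRUE)
})

test_that("missing dosages are rejected", {
  G <- matrix(rbinom(40, 2, 0.4), 10, 4)
  G[2, 2] <- NA
  expect_error(mlmm_precompute(G), "missing")
})
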