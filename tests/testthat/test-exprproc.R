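test_that("transcript filter applies the genotype-level 10% rule", {
  counts <- matrix(0L, 20, 3,
                   dimnames = list(sprintf("s%02d", 1:20), c("a", "b", "c")))
  sm <- data.frame(sample_id = rownames(counts),
                   genotype = rep(sprintf("g%02d", 1:10), each = 2),
                   batch = rep(c("b1", "b2"), 10), stringsAsFactors = FALSE)
  counts[, "b"] <- 5L                     # expressed everywhere
  counts[1:2, "c"] <- 1L                  # both replicates of one genotype
  # all-zero transcript "a" removed; "c" hits exactly 1/10 genotypes = 10%
  kept <- filter_transcripts(counts, sm, min_count = 1, min_prop = 0.10)
  expect_setequal(colnames(kept), c("b", "c"))
  # idempotent
  expect_identical(filter_transcripts(kept, sm), kept)
  expect_error(filter_transcripts(counts[, 0, drop = FALSE], sm), "empty")
})

test_that("TMM factors are 1 for identical and depth-scaled libraries", {
  base <- matrix(rpois(400, 50), 4, 100, byrow = TRUE,
                 dimnames = list(paste0("s", 1:4), NULL))
  base[2, ] <- base[1, ]; base[3, ] <- base[1, ]; base[4, ] <- base[1, ]
  expect_equal(unname(tmm_factors(base)), rep(1, 4), tolerance = 1e-12)
  scaled <- base
  scaled[2, ] <- base[1, ] * 2L            # pure depth change
  expect_equal(unname(tmm_factors(scaled[1:2, ])), rep(1, 2),
               tolerance = 1e-12)
})

test_that("TMM matches a brute-force trimmed weighted mean oracle", {
  # oracle coded directly from the TMM definition: M/A values against the
  # reference, double trim (30% on M, 5% on A), inverse-variance weights
  tmm_oracle <- function(counts, trim_m = 0.3, trim_a = 0.05) {
    lib <- rowSums(counts)
    uq <- apply(sweep(counts, 1, lib, "/"), 1, quantile, 0.75)
    ref <- which.min(abs(uq - mean(uq)))
    f <- vapply(seq_len(nrow(counts)), function(i) {
      if (i == ref) return(1)
      nO <- counts[i, ]; nR <- counts[ref, ]
      keep <- nO > 0 & nR > 0
      nO <- nO[keep]; nR <- nR[keep]
      M <- log2((nO / lib[i]) / (nR / lib[ref]))
      A <- 0.5 * log2((nO / lib[i]) * (nR / lib[ref]))
      w <- (lib[i] - nO) / (lib[i] * nO) + (lib[ref] - nR) / (lib[ref] * nR)
      # rank-based double trim: drop top/bottom trim_m of M and trim_a of A
      rM <- rank(M); rA <- rank(A); n <- length(M)
      loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
      loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
      sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
      2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
    }, numeric(1))
    f / exp(mean(log(f)))
  }
  set.seed(42)
  counts <- matrix(rnbinom(6 * 500, mu = 80, size = 5), 6, 500,
                   dimnames = list(paste0("s", 1:6), NULL))
  up <- sample.int(500, 50)
  counts[2, up] <- counts[2, up] * 8L      # composition shift in one sample
  expect_equal(unname(tmm_factors(counts)), unname(tmm_oracle(counts)),
               tolerance = 1e-10)
})

test_that("log-CPM closed forms and monotonicity hold", {
  counts <- matrix(c(0, 1, 10, 1e6 - 11), 1, 4)
  lc <- log_cpm(counts, 1)
  expect_identical(lc[1, 1], 0)
  counts2 <- matrix(c(1, 1e6 - 1), 1, 2)
  expect_equal(log_cpm(counts2, 1)[1, 1], 1, tolerance = 1e-12)
  expect_true(all(diff(lc[1, ]) > 0))
  expect_error(log_cpm(matrix(0, 1, 3)), "library")
})

test_that("genotype BLUPs shrink to zero under the null and centre at zero", {
  set.seed(77)
  n_g <- 60
  sm <- data.frame(sample_id = sprintf("s%03d", 1:(2 * n_g)),
                   genotype = rep(sprintf("g%02d", 1:n_g), each = 2),
                   batch = rep(c("b1", "b2"), n_g), stringsAsFactors = FALSE)
  y <- matrix(rnorm(2 * n_g * 40), 2 * n_g, 40,
              dimnames = list(sm$sample_id, paste0("t", 1:40)))
  bl <- genotype_blups(y, sm)
  expect_lt(max(abs(colMeans(bl))), 1e-8)
  # under the null the predictions are strongly shrunken: an order of
  # magnitude below the raw genotype-mean deviations on average, and the
  # typical transcript's largest prediction is a small fraction of the
  # residual sd (which is 1 here)
  mx <- apply(abs(bl), 2, max)
  raw <- apply(y, 2, function(v)
    max(abs(tapply(v, sm$genotype, mean) - mean(v))))
  expect_lt(mean(mx) / mean(raw), 1 / 3)
  expect_lt(median(mx), 0.25)
  # constant transcript -> all-zero BLUPs
  y0 <- matrix(3, 2 * n_g, 1, dimnames = list(sm$sample_id, "flat"))
  expect_equal(max(abs(genotype_blups(y0, sm))), 0, tolerance = 1e-10)
})

test_that("BLUPs equal shrunken genotype means, against a grid oracle", {
  set.seed(12)
  n_g <- 40
  sm <- data.frame(sample_id = sprintf("s%03d", 1:(2 * n_g)),
                   genotype = rep(sprintf("g%02d", 1:n_g), each = 2),
                   batch = "b1", stringsAsFactors = FALSE)
  g <- rnorm(n_g, 0, 1)
  y <- matrix(g[rep(1:n_g, each = 2)] + rnorm(2 * n_g, 0, 0.7), ncol = 1,
              dimnames = list(sm$sample_id, "t"))
  bl <- genotype_blups(y, sm)
  # oracle: profile REML over a lambda grid with explicit dense algebra
  Z <- model.matrix(~ 0 + factor(sm$genotype))
  X <- matrix(1, 2 * n_g, 1)
  grid <- exp(seq(-6, 6, length.out = 2000))
  ll <- vapply(grid, function(l) {
    V <- l * tcrossprod(Z) + diag(2 * n_g)
    Vi <- solve(V)
    b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (2 * n_g - 1)
    -0.5 * ((2 * n_g - 1) * log(2 * pi * s2) + (2 * n_g - 1) +
              determinant(V)$modulus[1] +
              determinant(t(X) %*% Vi %*% X)$modulus[1])
  }, numeric(1))
  lhat <- grid[which.max(ll)]
  V <- lhat * tcrossprod(Z) + diag(2 * n_g)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  ghat <- lhat * t(Z) %*% Vi %*% (y - X %*% b)
  expect_equal(unname(bl[, 1]), as.numeric(ghat), tolerance = 1e-3)
  # shrinkage: predictions lie between 0 and the centred genotype means
  cm <- tapply(y, sm$genotype, mean) - mean(y)
  expect_true(all(abs(bl[, 1]) <= abs(cm[rownames(bl)]) + 1e-8))
})
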