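test_that("squared-effect ranks follow the stated conventions", {
  r <- rank_squared(c(a = 0.1, b = -0.5, c = 0.2))
  expect_equal(unname(r), c(1, 3, 2))
  # ties share averaged ranks; sign flips change nothing
  expect_equal(unname(rank_squared(c(x = 2, y = -2))), c(1.5, 1.5))
  e <- c(a = 0.3, b = -1.2, c = 0.7)
  expect_identical(rank_squared(e), rank_squared(-e))
  expect_error(rank_squared(numeric(0)), "empty")
  expect_error(rank_squared(c(1, NA)), "finite")
})

test_that("the mean rank change reproduces its worked examples", {
  rs <- setNames(c(1, 2, 3), c("a", "b", "c"))
  rm_ <- setNames(c(3, 1, 2), c("a", "b", "c"))
  expect_equal(delta_rank(rm_, rs, c("a", "b", "c"))$delta, 0)
  rs4 <- setNames(1:4, letters[1:4])
  rm4 <- setNames(4:1, letters[1:4])
  expect_equal(delta_rank(rm4, rs4, c("a", "b"))$delta, 2)
  expect_equal(delta_rank(rs4, rs4, c("b", "d"))$delta, 0)
  # association-level multiplicity: a repeated member counts twice
  expect_equal(delta_rank(rm4, rs4, c("a", "a", "d"))$delta, (3 + 3 - 3) / 3)
  expect_error(delta_rank(rm4, rs4, character(0)), "empty")
})

test_that("rank changes are zero-sum over a full tie-free class", {
  set.seed(6)
  for (i in 1:5) {
    p <- 40
    eg <- setNames(rnorm(p), paste0("s", 1:p))
    egt <- setNames(rnorm(p), paste0("s", 1:p))
    d <- rank_squared(egt) - rank_squared(eg)
    expect_equal(sum(d), 0)
  }
})

test_that("the cross-trait regression matches a closed-form oracle", {
  x <- c(1, 2, 3); y <- 2 * x + 1
  perfect <- regress_delta_vs_advantage(x, y)
  expect_equal(perfect$r, 1, tolerance = 1e-12)
  set.seed(9)
  a <- rnorm(12); b <- 0.5 * a + rnorm(12)
  got <- regress_delta_vs_advantage(a, b)
  # oracle from covariance algebra and the t transform
  r0 <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t0 <- r0 * sqrt(10) / sqrt(1 - r0^2)
  p0 <- 2 * pt(abs(t0), 10, lower.tail = FALSE)
  expect_equal(got$r, r0, tolerance = 1e-12)
  expect_equal(got$p, p0, tolerance = 1e-12)
  expect_equal(got$slope, r0 * sd(b) / sd(a), tolerance = 1e-12)
  swapped <- regress_delta_vs_advantage(b, a)
  expect_equal(swapped$r, got$r, tolerance = 1e-12)
  expect_error(regress_delta_vs_advantage(1:2, 2:3), "3 traits")
  expect_error(regress_delta_vs_advantage(rep(1, 5), rnorm(5)), "variance")
})

test_that("rank_change_summary respects membership modes and class scales", {
  snps <- paste0("s", 1:6); trs <- paste0("t", 1:4)
  eg <- setNames(c(3, 2, 1, 0.5, 0.2, 0.1), snps)
  et <- setNames(c(1, 2, 3, 4), trs)
  egt <- setNames(c(c(0.1, 0.2, 1, 2, 3, 0.5), c(4, 3, 2, 1)),
                  c(snps, trs))
  eq <- data.frame(transcript_id = c("t1", "t2", "t3"),
                   snp_id = c("s1", "s2", "s2"),
                   class = c("CIS", "TRANS", "TRANS"),
                   stringsAsFactors = FALSE)
  snp_meta <- data.frame(snp_id = snps, chrom = "chr1",
                         pos_bp = seq(1000, 6000, 1000),
                         stringsAsFactors = FALSE)
  cats <- categorize_features(eq, snp_meta, trs)
  out <- rank_change_summary(eg, et, egt, cats)
  expect_setequal(out$category,
                  c("CIS_EQTL", "TRANS_EQTL", "NOT_EQTL",
                    "CIS_REGULATED", "TRANS_REGULATED", "NO_EQTL"))
  # s2 appears in two TRANS associations -> n = 2 at association level
  expect_equal(out$n[out$category == "TRANS_EQTL"], 2)
  out_d <- rank_change_summary(eg, et, egt, cats, dedup_snps = TRUE)
  expect_equal(out_d$n[out_d$category == "TRANS_EQTL"], 1)
  # hand check: rank of s1 in G is 6 (largest square), in GT-snp-block
  # squares (0.1,0.2,1,2,3,0.5) -> s1 rank 1; delta = -5
  expect_equal(out$delta[out$category == "CIS_EQTL"], -5)
})

test_that("the window scan reduces to the base analysis at window 0", {
  w <- tiny_world(seed = 41, n_ind = 60, genes_per_chrom = 15)
  ex <- tiny_expression(w, seed = 41, n_cis = 8, n_trans = 10,
                        hub_fanout = 4)
  eq <- classify_associations(ex$truth$true_eqtls, w$geno$snp_meta, w$ann,
                              12000)
  trs <- colnames(ex$truth$transcript_gv)
  set.seed(41)
  effs <- lapply(1:4, function(i) {
    p <- ncol(w$geno$dosages)
    list(g = setNames(rnorm(p), colnames(w$geno$dosages)),
         t = setNames(rnorm(length(trs)), trs),
         gt = setNames(rnorm(p + length(trs)),
                       c(colnames(w$geno$dosages), trs)))
  })
  names(effs) <- paste0("tr", 1:4)
  advg <- setNames(rnorm(4), names(effs))
  advt <- setNames(rnorm(4), names(effs))
  ws <- window_scan(eq, w$geno$snp_meta, trs, effs, advg, advt,
                    windows = c(0, 500))
  base_cats <- categorize_features(eq, w$geno$snp_meta, trs, 0)
  base_delta <- rank_change_summary(effs[[1]]$g, effs[[1]]$t, effs[[1]]$gt,
                                    base_cats)
  d0 <- ws[ws$window_bp == 0 & ws$category == "TRANS_EQTL", ]
  deltas <- vapply(effs, function(ef) {
    d <- rank_change_summary(ef$g, ef$t, ef$gt, base_cats)
    d$delta[d$category == "TRANS_EQTL"]
  }, numeric(1))
  ref <- regress_delta_vs_advantage(deltas, advg)
  expect_equal(d0$r, ref$r, tolerance = 1e-12)
  expect_equal(d0$p, ref$p, tolerance = 1e-12)
  # windows engulfing every SNP empty the NOT_EQTL category with a warning
  warns <- testthat::capture_warnings(
    window_scan(eq, w$geno$snp_meta, trs, effs, advg, advt,
                windows = c(2e6)))
  expect_true(any(grepl("NOT_EQTL", warns)))
})
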