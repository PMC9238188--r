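test_that("simulated genome respects counts, ordering and non-overlap", {
  ann <- simulate_genome(n_chrom = 2, genes_per_chrom = 10,
                         chrom_length_bp = 2e5, seed = 1)
  expect_equal(nrow(ann$genes), 20)
  expect_true(all(ann$genes$start_bp < ann$genes$end_bp))
  for (ch in unique(ann$genes$chrom)) {
    g <- ann$genes[ann$genes$chrom == ch, ]
    expect_false(is.unsorted(g$start_bp))
    expect_true(all(g$start_bp[-1] > g$end_bp[-nrow(g)]))
    expect_true(all(g$end_bp <= 2e5))
  }
  expect_false(anyDuplicated(ann$genes$gene_id) > 0)
  expect_error(simulate_genome(1, 100, 1e4), "fit")
})

test_that("genotype simulation meets the MAF filter and hosts SNPs in genes", {
  w <- tiny_world(seed = 3)
  maf <- colMeans(w$geno$dosages) / 2
  maf <- pmin(maf, 1 - maf)
  expect_true(min(maf) >= 0.05)
  g <- w$ann$genes[match(w$geno$snp_meta$host_gene_id, w$ann$genes$gene_id), ]
  expect_true(all(w$geno$snp_meta$pos_bp >= g$start_bp &
                    w$geno$snp_meta$pos_bp <= g$end_bp))
  expect_error(simulate_genotypes(w$ann, n_ind = 1), "2 individuals")
  expect_error(simulate_genotypes(w$ann, n_ind = 10, maf_min = 0.5), "maf_min")
})

test_that("adjacent-SNP correlation matches the LD target", {
  adj_cors <- function(geno) {
    sm <- geno$snp_meta
    out <- c()
    for (gid in unique(sm$host_gene_id)) {
      idx <- which(sm$host_gene_id == gid)
      if (length(idx) > 1)
        for (k in 2:length(idx))
          out <- c(out, suppressWarnings(
            cor(geno$dosages[, idx[k - 1]], geno$dosages[, idx[k]])))
    }
    out[is.finite(out)]
  }
  # independence baseline: mean r^2 of independent pairs ~ 1/n
  ann <- simulate_genome(2, 30, 1e6, seed = 5)
  r2 <- unlist(lapply(1:20, function(s) {
    g <- simulate_genotypes(ann, n_ind = 500, snps_per_gene = 3,
                            ld_rho = 0, seed = s)
    adj_cors(g)^2
  }))
  expect_lt(abs(mean(r2) - 1 / 500), 3 / 500)
  # strong-LD target within +-0.1 over >= 1000 pairs
  ann2 <- simulate_genome(4, 60, 2e6, seed = 6)
  g2 <- simulate_genotypes(ann2, n_ind = 400, snps_per_gene = 6,
                           ld_rho = 0.9, seed = 11)
  cors <- adj_cors(g2)
  expect_gt(length(cors), 1000)
  expect_lt(abs(mean(cors) - 0.9), 0.1)
})

test_that("expression counts carry planted effects, hubs and overdispersion", {
  w <- tiny_world(seed = 9, n_ind = 100)
  ex <- simulate_expression(w$geno, w$ann, n_cis = 10, n_trans = 50,
                            n_hubs = 1, hub_fanout = 50, seed = 9)
  hub <- ex$truth$hub_snps
  expect_length(hub, 1)
  expect_equal(sum(ex$truth$true_eqtls$snp_id == hub), 50)
  # over-Poisson dispersion on expressed transcripts
  mu <- colMeans(ex$counts); v <- apply(ex$counts, 2, var)
  keep <- mu > 1
  expect_gt(mean(v[keep] > mu[keep]), 0.9)
  # determinism: identical seed, bit-identical counts and truth
  ex2 <- simulate_expression(w$geno, w$ann, n_cis = 10, n_trans = 50,
                             n_hubs = 1, hub_fanout = 50, seed = 9)
  expect_identical(ex$counts, ex2$counts)
  expect_identical(ex$truth$true_eqtls, ex2$truth$true_eqtls)
  expect_error(simulate_expression(w$geno, w$ann, disp = 0), "disp")
})

test_that("null expression shows no dosage effects at nominal CI coverage", {
  w <- tiny_world(seed = 13, n_ind = 150, genes_per_chrom = 25)
  ex <- simulate_expression(w$geno, w$ann, n_cis = 20, n_trans = 20,
                            n_hubs = 1, hub_fanout = 5,
                            effect_sd = 0, gnoise_sd = 0, seed = 13)
  lc <- log_cpm(ex$counts)
  gmean <- rowsum(lc, ex$sample_map$genotype[
    match(rownames(lc), ex$sample_map$sample_id)])
  gmean <- gmean / as.vector(table(ex$sample_map$genotype)[rownames(gmean)])
  gmean <- gmean[w$geno$ind_ids, ]
  covered <- vapply(seq_len(ncol(gmean)), function(j) {
    s <- w$geno$dosages[, sample.int(ncol(w$geno$dosages), 1)]
    f <- summary(lm(gmean[, j] ~ s))$coefficients
    if (nrow(f) < 2) return(TRUE)
    abs(f[2, 1]) < 1.96 * f[2, 2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("a large planted cis effect shows up in the genotype BLUPs", {
  w <- tiny_world(seed = 21, n_ind = 200, genes_per_chrom = 20)
  ex <- simulate_expression(w$geno, w$ann, n_cis = 10, n_trans = 5,
                            n_hubs = 1, hub_fanout = 3,
                            effect_sd = 1.5, gnoise_sd = 0.2, seed = 21)
  ep <- process_expression(ex$counts, ex$sample_map)
  te <- ex$truth$true_eqtls
  te <- te[te$class == "CIS" & te$transcript_id %in% colnames(ep$blups), ]
  big <- te[which.max(abs(te$effect)), ]
  r <- cor(ep$blups[w$geno$ind_ids, big$transcript_id],
           w$geno$dosages[, big$snp_id])
  expect_gt(abs(r), 0.5)
})

test_that("planted eQTL classes agree with the positional rules", {
  w <- tiny_world(seed = 17)
  ex <- tiny_expression(w, seed = 17)
  reclassified <- classify_associations(ex$truth$true_eqtls, w$geno$snp_meta,
                                        w$ann, cis_max_bp = 12000)
  expect_identical(reclassified$class, ex$truth$true_eqtls$class)
})

test_that("field phenotypes honour the design and degenerate noiselessly", {
  w <- tiny_world(seed = 2, n_ind = 40)
  ex <- tiny_expression(w, seed = 2)
  sp <- trait_spec("t", v_snp_direct = 1, v_transcript_mediated = 0,
                   v_transcript_site1_only = 0, v_block = 0, v_spatial = 0,
                   v_residual = 0)
  ph <- simulate_phenotypes(w$geno, ex$truth, list(sp),
                            layout_spec = list(n_blocks = 3), seed = 2)
  expect_equal(nrow(ph$field), 40 * 3 * 2)
  for (s in c("ORL", "SAV")) {
    d <- ph$field[ph$field$site == s, ]
    expect_false(anyDuplicated(d[c("row", "col")]) > 0)
    m <- tapply(d$value, d$genotype, mean)
    truth <- ph$truth$genetic_value[[s]][names(m), "t"]
    expect_equal(as.numeric(m), as.numeric(truth), tolerance = 1e-12)
  }
  expect_error(trait_spec("bad", v_snp_direct = 0.9, v_residual = 0.3),
               "sum")
})

test_that("the spatial surface has the requested lag-1 autocorrelation", {
  rhos <- replicate(10, {
    L <- redunrank:::ar1_chol(30, 0.8)
    Lc <- redunrank:::ar1_chol(50, 0.8)
    S <- L %*% matrix(rnorm(30 * 50), 30, 50) %*% t(Lc)
    # pooled lag-1 correlation along rows (pooling avoids the short-series
    # demeaning bias of per-column estimates)
    cor(as.vector(S[-1, ]), as.vector(S[-nrow(S), ]))
  })
  expect_lt(abs(mean(rhos) - 0.8), 0.1)
})
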