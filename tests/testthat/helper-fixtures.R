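# Shared fixture builders. Everything is generated in code at test time;
# sizes are deliberately small so the default run stays fast.

tiny_world <- function(seed = 7, n_ind = 120, genes_per_chrom = 40,
                       snps_per_gene = 3, ...) {
  ann <- simulate_genome(2, genes_per_chrom, 1e6, seed = seed)
  geno <- simulate_genotypes(ann, n_ind = n_ind,
                             snps_per_gene = snps_per_gene, seed = seed)
  list(ann = ann, geno = geno)
}

tiny_expression <- function(w, n_cis = 15, n_trans = 20, n_hubs = 1,
                            hub_fanout = 8, seed = 7, ...) {
  simulate_expression(w$geno, w$ann, n_cis = n_cis, n_trans = n_trans,
                      n_hubs = n_hubs, hub_fanout = hub_fanout,
                      seed = seed, ...)
}

# simulate a small single-site field with known genotype values
sim_field <- function(seed, n_geno = 24, n_blocks = 3, rho = 0, v_spatial = 0,
                      v_block = 0.3, v_resid = 0.3, v_g = 1) {
  set.seed(seed)
  g <- rnorm(n_geno, 0, sqrt(v_g))
  n <- n_geno * n_blocks
  nc <- ceiling(sqrt(n)); nr <- ceiling(n / nc)
  idx <- seq_len(n)
  rows <- ((idx - 1) %/% nc) + 1
  cols <- ((idx - 1) %% nc) + 1
  geno_of <- unlist(lapply(seq_len(n_blocks), function(b) sample.int(n_geno)))
  block_of <- rep(seq_len(n_blocks), each = n_geno)
  S <- if (v_spatial > 0) {
    L1 <- redunrank:::ar1_chol(nr, rho); L2 <- redunrank:::ar1_chol(nc, rho)
    L1 %*% matrix(rnorm(nr * nc), nr, nc) %*% t(L2)
  } else matrix(0, nr, nc)
  b <- rnorm(n_blocks)
  val <- g[geno_of] + sqrt(v_block) * b[block_of] +
    sqrt(v_spatial) * S[cbind(rows, cols)] + sqrt(v_resid) * rnorm(n)
  list(field = data.frame(genotype = sprintf("g%02d", geno_of), site = "X",
                          block = block_of, row = rows, col = cols,
                          trait = "t", value = val, stringsAsFactors = FALSE),
       truth = setNames(g, sprintf("g%02d", seq_len(n_geno))))
}

# tiny flat DAG: k independent leaf terms under one root
flat_dag <- function(k = 4) {
  ids <- c("GO:ROOT", sprintf("GO:L%02d", seq_len(k)))
  go_dag(data.frame(term_id = ids, name = ids, namespace = "BP",
                    stringsAsFactors = FALSE),
         data.frame(child = ids[-1], parent = "GO:ROOT",
                    stringsAsFactors = FALSE))
}

# closed-form one-sided Fisher (enrichment) tail from factorials, coded
# directly from the hypergeometric definition, independent of phyper
fisher_tail_oracle <- function(k, K, N, n) {
  kmax <- min(K, n)
  if (k > kmax) return(0)
  lchoose_ <- function(a, b) lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)
  sum(exp(lchoose_(K, k:kmax) + lchoose_(N - K, n - (k:kmax)) -
            lchoose_(N, n)))
}
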