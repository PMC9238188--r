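# Shared settings for the analysis scripts. Everything downstream of this
# file is driven by the one root seed; results land under results/.

library(redunrank)

root_seed <- 1L
results_dir <- file.path("results")
if (!dir.exists(results_dir)) dir.create(results_dir, recursive = TRUE)

# desk-scale panel emulating the motivating study's structure: two-site
# field design, intragenic SNPs, transcript counts with hub-driven trans
# regulation, a trait panel spanning a redundancy gradient
panel_config <- validate_config(list(
  seed = root_seed,
  simulate = list(n_chrom = 2L, genes_per_chrom = 75L, chrom_length_bp = 1.5e6,
                  n_ind = 200L, snps_per_gene = 2L, ld_rho = 0.3,
                  n_cis = 30L, n_trans = 72L, n_hubs = 6L, hub_fanout = 12L,
                  effect_sd = 1.2, gnoise_sd = 0.8,
                  n_traits = 12L, v_site1_max = 0.35, n_blocks = 2L),
  adjust = list(candidate_models = c("iid", "block")),
  eqtl = list(max_steps = 4L),
  predict = list(repeats = 5L, n_lambda = 25L),
  rankstat = list(windows = c(0, 500, 5000, 25000)),
  goelim = list(n_terms = 80L)
))
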