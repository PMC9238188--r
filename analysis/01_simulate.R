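#!/usr/bin/env Rscript
# Stage 1 -- synthetic dataset. Generates the genome annotation, intragenic
# SNP dosages, transcript counts with a planted cis/trans eQTL architecture
# (six regulatory hubs), and a 12-trait two-site field phenotype panel whose
# traits differ only in how much signal flows through the trans-regulated
# transcript module. Writes every artifact, plus the ground truth, under
# results/.

source(file.path("analysis", "00_config.R"))
cs <- panel_config$simulate
stamp <- c(config_hash = content_hash(unclass(panel_config)),
           seed = root_seed)

ann <- simulate_genome(cs$n_chrom, cs$genes_per_chrom, cs$chrom_length_bp,
                       seed = root_seed)
geno <- simulate_genotypes(ann, n_ind = cs$n_ind,
                           snps_per_gene = cs$snps_per_gene,
                           ld_rho = cs$ld_rho, seed = root_seed)
expr <- simulate_expression(geno, ann, n_cis = cs$n_cis, n_trans = cs$n_trans,
                            n_hubs = cs$n_hubs, hub_fanout = cs$hub_fanout,
                            effect_sd = cs$effect_sd, gnoise_sd = cs$gnoise_sd,
                            seed = root_seed)
specs <- trait_panel_gradient(cs$n_traits, v_site1_max = cs$v_site1_max,
                              n_transcripts = cs$n_trans)
specs <- lapply(specs, function(s) { s$coherent_weights <- TRUE; s })
phen <- simulate_phenotypes(geno, expr$truth, specs,
                            layout_spec = list(n_blocks = cs$n_blocks),
                            shared_site1_module = TRUE,
                            shared_snp_module = TRUE, seed = root_seed)

write_gff3(ann, file.path(results_dir, "genes.gff3"))
write_genotypes(geno, file.path(results_dir, "geno"), stamp)
write_tsv(data.frame(sample_id = rownames(expr$counts), expr$counts,
                     check.names = FALSE),
          file.path(results_dir, "counts.tsv"), stamp)
write_tsv(expr$sample_map, file.path(results_dir, "sample_map.tsv"), stamp)
write_tsv(phen$field, file.path(results_dir, "phenotypes_field.tsv"), stamp)
write_tsv(expr$truth$true_eqtls,
          file.path(results_dir, "truth_eqtls.tsv"), stamp)
saveRDS_plain <- function(x, name)    # genotype-level truth kept as TSV too
  write_tsv(data.frame(genotype = rownames(x), x, check.names = FALSE),
            file.path(results_dir, name), stamp)
saveRDS_plain(phen$truth$genetic_value$ORL, "truth_gv_ORL.tsv")
saveRDS_plain(phen$truth$genetic_value$SAV, "truth_gv_SAV.tsv")

cat(sprintf(
  "simulated %d genotypes, %d SNPs (MAF >= 0.05), %d transcripts,\n",
  length(geno$ind_ids), ncol(geno$dosages), ncol(expr$counts)))
cat(sprintf("planted %d cis and %d trans associations (%d hubs x %d),\n",
            sum(expr$truth$true_eqtls$class == "CIS"),
            sum(expr$truth$true_eqtls$class == "TRANS"),
            cs$n_hubs, cs$hub_fanout))
cat(sprintf("field panel: %d traits x 2 sites x %d blocks -> %d records\n",
            cs$n_traits, cs$n_blocks, nrow(phen$field)))
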