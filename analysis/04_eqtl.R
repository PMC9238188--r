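#!/usr/bin/env Rscript
# Stage 4 -- eQTL mapping and classification. Multi-locus mixed-model scan
# per transcript (forward/backward with a kinship random effect), mBonf
# model selection, then positional cis/trans classification with the cis
# window derived from the within-gene associations when possible.

source(file.path("analysis", "00_config.R"))
geno <- read_genotypes(file.path(results_dir, "geno_dosages.tsv"), "tsv",
                       maf_min = NULL)
ann <- read_gff3(file.path(results_dir, "genes.gff3"))
bl_df <- as.data.frame(read_tsv(file.path(results_dir, "blups.tsv")))
blups <- as.matrix(bl_df[, -1]); rownames(blups) <- bl_df[[1]]
blups <- blups[geno$ind_ids, , drop = FALSE]

eq <- eqtl_scan_all(blups, geno, max_steps = panel_config$eqtl$max_steps,
                    alpha = panel_config$eqtl$alpha)
cis_max <- tryCatch(derive_cis_threshold(eq, geno$snp_meta, ann),
                    error = function(e) panel_config$classify$fallback_cis_max_bp)
eq <- classify_associations(eq, geno$snp_meta, ann, cis_max)
stamp <- c(config_hash = content_hash(unclass(panel_config)),
           seed = root_seed)
si <- match(eq$snp_id, geno$snp_meta$snp_id)
write_tsv(cbind(eq, chrom_snp = geno$snp_meta$chrom[si],
                pos_snp = geno$snp_meta$pos_bp[si]),
          file.path(results_dir, "eqtls.tsv"), stamp)

truth <- as.data.frame(read_tsv(file.path(results_dir, "truth_eqtls.tsv")))
cat(sprintf("detected %d associations for %d transcripts (cis window %d bp)\n",
            nrow(eq), length(unique(eq$transcript_id)), cis_max))
cat(sprintf("cis: %d (%.0f%%)  trans: %d (%.0f%%)\n",
            sum(eq$class == "CIS"), 100 * mean(eq$class == "CIS"),
            sum(eq$class == "TRANS"), 100 * mean(eq$class == "TRANS")))
cat(sprintf("planted architecture for reference: %d cis / %d trans\n",
            sum(truth$class == "CIS"), sum(truth$class == "TRANS")))
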