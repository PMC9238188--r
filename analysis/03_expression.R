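#!/usr/bin/env Rscript
# Stage 3 -- transcript processing. Filters low-expressed transcripts
# (>= 1 count in >= 10% of genotypes), computes TMM factors, log2(CPM + 1),
# and one genotypic BLUP per transcript from the batch-adjusted mixed model.

source(file.path("analysis", "00_config.R"))
counts_df <- as.data.frame(read_tsv(file.path(results_dir, "counts.tsv")))
counts <- as.matrix(counts_df[, -1])
rownames(counts) <- counts_df[[1]]
sample_map <- as.data.frame(read_tsv(file.path(results_dir, "sample_map.tsv")))

ep <- process_expression(counts, sample_map,
                         panel_config$exprproc$min_count,
                         panel_config$exprproc$min_prop)
stamp <- c(config_hash = content_hash(unclass(panel_config)),
           seed = root_seed)
write_tsv(data.frame(sample_id = names(ep$norm_factors),
                     tmm_factor = ep$norm_factors),
          file.path(results_dir, "tmm_factors.tsv"), stamp)
write_tsv(data.frame(genotype = rownames(ep$blups), ep$blups,
                     check.names = FALSE),
          file.path(results_dir, "blups.tsv"), stamp)

cat(sprintf("kept %d of %d transcripts after the 10%% filter\n",
            ncol(ep$counts), ncol(counts)))
cat(sprintf("TMM factors in [%.3f, %.3f] (geometric mean %.6f)\n",
            min(ep$norm_factors), max(ep$norm_factors),
            exp(mean(log(ep$norm_factors)))))
cat(sprintf("BLUP matrix: %d genotypes x %d transcripts\n",
            nrow(ep$blups), ncol(ep$blups)))
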