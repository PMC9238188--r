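#!/usr/bin/env Rscript
# Stage 2 -- field adjustment. Fits, per trait and site, the candidate
# models y = mu + block + genotype (+ AR1xAR1 residuals), selects by AIC
# and writes the genotype adjusted means used as traits downstream.

source(file.path("analysis", "00_config.R"))
field <- as.data.frame(read_tsv(file.path(results_dir,
                                          "phenotypes_field.tsv")))
adj <- adjust_phenotypes(field,
                         candidate_models = panel_config$adjust$candidate_models)
stamp <- c(config_hash = content_hash(unclass(panel_config)),
           seed = root_seed)
write_tsv(data.frame(genotype = rownames(adj$adjusted), adj$adjusted,
                     check.names = FALSE),
          file.path(results_dir, "adjusted_means.tsv"), stamp)
write_tsv(adj$report, file.path(results_dir, "adjustment_report.tsv"), stamp)

cat("adjusted", ncol(adj$adjusted), "trait-sites; selected models:\n")
print(table(adj$report$model))
truth <- as.data.frame(read_tsv(file.path(results_dir, "truth_gv_ORL.tsv")))
g <- truth$genotype
r <- vapply(colnames(truth)[-1], function(tr)
  cor(adj$adjusted[g, paste0(tr, "_ORL")], truth[[tr]]), numeric(1))
cat(sprintf("mean cor(adjusted means, true genetic values) at ORL: %.3f\n",
            mean(r)))
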