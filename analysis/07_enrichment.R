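#!/usr/bin/env Rscript
# Stage 7 -- GO enrichment of the rank-change extremes. For the steepest-
# gradient trait, takes the 2.5% tails of the per-transcript rank change
# between G+T and T, and tests term enrichment with one-sided Fisher tests
# under the elim decorrelation algorithm on a synthetic ontology annotated
# over the expressed transcripts.

source(file.path("analysis", "00_config.R"))
eff_t <- as.data.frame(read_tsv(file.path(results_dir, "effects_T.tsv")))
eff_gt <- as.data.frame(read_tsv(file.path(results_dir, "effects_GT.tsv")))
transcripts <- eff_t$feature
trait <- grep("_ORL$", colnames(eff_t), value = TRUE)
trait <- trait[length(trait)]

rk_t <- rank_squared(setNames(eff_t[[trait]], transcripts))
gt_t <- setNames(eff_gt[[trait]], eff_gt$feature)[transcripts]
rk_gt <- rank_squared(gt_t)
delta <- rk_gt - rk_t

go <- simulate_go(panel_config$goelim$n_terms, n_genes = length(transcripts),
                  terms_per_gene = panel_config$goelim$terms_per_gene,
                  seed = root_seed)
map <- setNames(transcripts, go$genes[seq_along(transcripts)])
ann_go <- go$ann[go$ann$gene %in% names(map), ]
ann_go$gene <- unname(map[ann_go$gene])

ext <- select_extremes(delta, q = panel_config$goelim$q)
res <- lapply(list(low = ext$low, high = ext$high), function(s)
  elim_fisher(s, transcripts, go$dag, ann_go,
              alpha = panel_config$goelim$alpha))
out <- rbind(data.frame(side = "low", res$low),
             data.frame(side = "high", res$high))
stamp <- c(config_hash = content_hash(unclass(panel_config)),
           seed = root_seed)
write_tsv(out, file.path(results_dir, "go_enrichment.tsv"), stamp)

cat(sprintf("trait %s: %d features per 2.5%% tail (cuts %.1f / %.1f)\n",
            trait, length(ext$low), ext$cut_low, ext$cut_high))
for (side in c("low", "high")) {
  r <- res[[side]]
  cat(sprintf("%s tail: %d significant terms at alpha = %.2f; top terms:\n",
              side, sum(r$significant), panel_config$goelim$alpha))
  print(utils::head(r[, c("term_id", "p_elim", "p_classic", "n_study")], 5),
        row.names = FALSE)
}
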