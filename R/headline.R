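# The headline experiment: a 12-trait panel with a redundancy gradient, run
# end to end (simulate -> adjust -> expression -> eQTL -> classify ->
# predict -> rank change), summarised by the cross-trait regression of the
# per-category mean rank change against the integration advantage at the
# transcriptome-sampling site. Default sizes are the frozen desk-scale
# study conditions; the methods vignette discusses how they were chosen and
# what they can and cannot show.

#' Run the redundancy-gradient panel once
#'
#' Twelve traits share a SNP backbone and a single trans-regulated
#' transcript module whose loading rises from 0 to `v_site1_max`; the
#' pipeline detects eQTLs, classifies them, fits G / T / G+T ridge models
#' under nested CV (5 outer, 10 inner, `repeats` repeats), computes
#' per-trait rank changes by predictor category, and regresses them against
#' the per-trait advantage of G+T over the single-omic model.
#'
#' @param seed integer; drives every random draw in the replicate.
#' @param n_ind,genes_per_chrom,snps_per_gene,ld_rho genotype panel size and
#'   marker structure.
#' @param n_cis,n_trans,n_hubs,hub_fanout,effect_sd,gnoise_sd planted eQTL
#'   architecture (all trans associations through hub loci).
#' @param n_traits,v_site1_max,v_snp,f_dosage trait panel gradient.
#' @param repeats CV repeats (scaled down from the 50 of a full analysis).
#' @param n_lambda penalty-grid resolution.
#' @param max_steps multi-locus scan depth.
#' @return list with `regressions` (per category: r, p, slope), `deltas`
#'   (trait x category), `advantage_g`, `advantage_t`, `eqtls`, `n_assoc`.
#' @export
run_headline_panel <- function(seed,
                               n_ind = 200, genes_per_chrom = 75,
                               snps_per_gene = 2, ld_rho = 0.3,
                               n_cis = 30, n_trans = 72, n_hubs = 6,
                               hub_fanout = 12, effect_sd = 1.2,
                               gnoise_sd = 0.8,
                               n_traits = 12, v_site1_max = 0.35,
                               v_snp = 0.25, f_dosage = 0.5,
                               repeats = 5, n_lambda = 25, max_steps = 4) {
  ann <- simulate_genome(2, genes_per_chrom, 1.5e6, seed = seed)
  geno <- simulate_genotypes(ann, n_ind = n_ind,
                             snps_per_gene = snps_per_gene,
                             ld_rho = ld_rho, seed = seed)
  expr <- simulate_expression(geno, ann, n_cis = n_cis, n_trans = n_trans,
                              n_hubs = n_hubs, hub_fanout = hub_fanout,
                              effect_sd = effect_sd, gnoise_sd = gnoise_sd,
                              seed = seed)
  specs <- trait_panel_gradient(n_traits, v_site1_max = v_site1_max,
                                v_snp = v_snp,
                                n_transcripts = n_trans,
                                n_snps_direct = 15, f_dosage = f_dosage)
  specs <- lapply(specs, function(s) { s$coherent_weights <- TRUE; s })
  phen <- simulate_phenotypes(geno, expr$truth, specs,
                              layout_spec = list(n_blocks = 2),
                              shared_site1_module = TRUE,
                              shared_snp_module = TRUE, seed = seed)
  adj <- adjust_phenotypes(phen$field, candidate_models = c("iid", "block"))
  ep <- process_expression(expr$counts, expr$sample_map)
  blups <- ep$blups[geno$ind_ids, , drop = FALSE]
  eq <- eqtl_scan_all(blups, geno, max_steps = max_steps)
  eq <- classify_associations(eq, geno$snp_meta, ann, 12000)
  cats <- categorize_features(eq, geno$snp_meta, colnames(blups))
  X_g <- geno$dosages; X_t <- blups; X_gt <- cbind(X_g, X_t)
  lams <- list(G = lambda_grid(X_g, n_lambda), T = lambda_grid(X_t, n_lambda),
               GT = lambda_grid(X_gt, n_lambda))
  traits <- paste0(vapply(specs, `[[`, character(1), "name"), "_",
                   phen$truth$layout$sites[1])
  adv_g <- adv_t <- stats::setNames(numeric(length(traits)), traits)
  deltas <- list()
  for (tr in traits) {
    y <- adj$adjusted[geno$ind_ids, tr]
    cvg <- nested_cv(X_g, y, 5, 10, repeats, lams$G, seed = seed,
                     return_effects = TRUE)
    cvt <- nested_cv(X_t, y, 5, 10, repeats, lams$T, seed = seed,
                     return_effects = TRUE)
    cvgt <- nested_cv(X_gt, y, 5, 10, repeats, lams$GT, seed = seed,
                      return_effects = TRUE)
    adv_g[tr] <- mean(cvgt$r2) - mean(cvg$r2)
    adv_t[tr] <- mean(cvgt$r2) - mean(cvt$r2)
    d <- rank_change_summary(cvg$effects, cvt$effects, cvgt$effects, cats)
    d$trait <- tr
    deltas[[tr]] <- d
  }
  deltas <- do.call(rbind, deltas)
  regressions <- list()
  for (cl in unique(deltas$category)) {
    dd <- deltas[deltas$category == cl, ]
    if (nrow(dd) < 3) next
    adv <- if (cl %in% c("CIS_EQTL", "TRANS_EQTL", "NOT_EQTL"))
      adv_g[dd$trait] else adv_t[dd$trait]
    regressions[[cl]] <- regress_delta_vs_advantage(dd$delta, adv)
  }
  list(regressions = regressions, deltas = deltas,
       advantage_g = adv_g, advantage_t = adv_t,
       eqtls = eq, n_assoc = nrow(eq),
       categories = cats)
}

#' Site-asymmetry experiment
#'
#' One trait carrying a transcript-mediated component expressed only at the
#' transcriptome-sampling site; fits G and G+T at both sites and returns the
#' advantage at each. Used to verify that the benefit of integration
#' concentrates where the transcripts were collected.
#'
#' @param seed integer seed.
#' @param n_ind,repeats scale knobs (kept small: the check is about the sign
#'   of a difference of means).
#' @return list with `adv_site1`, `adv_site2` (mean R2 GT minus G).
#' @export
run_site_asymmetry <- function(seed, n_ind = 120, repeats = 2) {
  ann <- simulate_genome(2, 60, 1.2e6, seed = seed)
  geno <- simulate_genotypes(ann, n_ind = n_ind, snps_per_gene = 2,
                             ld_rho = 0.3, seed = seed)
  expr <- simulate_expression(geno, ann, n_cis = 20, n_trans = 48,
                              n_hubs = 4, hub_fanout = 12,
                              effect_sd = 1.2, gnoise_sd = 0.8, seed = seed)
  spec <- trait_spec("t1", v_snp_direct = 0.25, v_transcript_mediated = 0,
                     v_transcript_site1_only = 0.35, v_block = 0.05,
                     v_spatial = 0, v_residual = 0.35,
                     n_snps_direct = 15, n_transcripts = 48,
                     mediator_pool = "trans", coherent_weights = TRUE,
                     f_dosage = 0.5)
  phen <- simulate_phenotypes(geno, expr$truth, list(spec),
                              layout_spec = list(n_blocks = 2), seed = seed)
  adj <- adjust_phenotypes(phen$field, candidate_models = c("iid", "block"))
  ep <- process_expression(expr$counts, expr$sample_map)
  blups <- ep$blups[geno$ind_ids, , drop = FALSE]
  X_g <- geno$dosages; X_gt <- cbind(X_g, blups)
  lg <- lambda_grid(X_g, 25); lgt <- lambda_grid(X_gt, 25)
  out <- numeric(2)
  sites <- phen$truth$layout$sites
  for (i in 1:2) {
    y <- adj$adjusted[geno$ind_ids, paste0("t1_", sites[i])]
    cvg <- nested_cv(X_g, y, 5, 10, repeats, lg, seed = seed)
    cvgt <- nested_cv(X_gt, y, 5, 10, repeats, lgt, seed = seed)
    out[i] <- mean(cvgt$r2) - mean(cvg$r2)
  }
  list(adv_site1 = out[1], adv_site2 = out[2])
}
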