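# Configuration, interchange readers/writers and end-to-end orchestration:
# simulate -> adjust -> exprproc -> eqtl -> classify -> predict -> rankstat
# -> goelim. TSV (tab, UTF-8, '.' decimal, header row) is the canonical
# interchange; VCF and GFF3 are accepted on ingest. Every stage draws its
# randomness from a named substream of the one root seed, so identical
# config + seed gives a bit-identical results bundle.

#' Default pipeline configuration
#'
#' Analysis defaults follow the motivating study: MAF filter 0.05, transcript
#' filter "at least 1 count in 10% of the genotypes", up to 10 multi-locus
#' steps with mBonf at 5%, cis window 12 kb (re-derived from the data when
#' possible), 5 outer / 10 inner folds with 50 repeats, 2.5% rank-change
#' extremes, GO alpha 0.05. Simulation sizes default to a desk-scale panel
#' (120 genotypes, 2 chromosomes x 200 genes, ~800 SNPs before filtering,
#' 400 transcripts, 6 traits).
#'
#' @return nested named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    simulate = list(
      n_chrom = 2L, genes_per_chrom = 200L, chrom_length_bp = 2e6,
      gene_length_range = c(1000L, 5000L),
      n_ind = 120L, snps_per_gene = 2L, maf_min = 0.05, ld_rho = 0.7,
      n_subpop = 1L, fst = 0.1,
      n_cis = 40L, n_trans = 60L, n_hubs = 2L, hub_fanout = 20L,
      effect_sd = 0.8, batch_sd = 0.2, disp = 0.15, gnoise_sd = 0.3,
      baseline_log_mean = 4.6, baseline_log_sd = 1,
      n_traits = 6L, v_site1_max = 0.5, n_blocks = 2L),
    adjust = list(rho_grid_step = 0.1,
                  candidate_models = c("iid", "block", "ar1", "block_ar1")),
    exprproc = list(min_count = 1, min_prop = 0.10),
    eqtl = list(max_steps = 10L, alpha = 0.05),
    classify = list(cis_max_bp = "auto", fallback_cis_max_bp = 12000),
    predict = list(outer = 5L, inner = 10L, repeats = 50L, n_lambda = 100L,
                   test = "wilcoxon"),
    rankstat = list(windows = c(0, 500, 5000, 25000), dedup_snps = FALSE),
    goelim = list(q = 0.025, alpha = 0.05, n_terms = 80L, terms_per_gene = 2)
  ), class = "pipeline_config")
}

#' Validate and merge a configuration against the defaults
#'
#' Unknown keys at either level are rejected; basic sanity constraints are
#' checked before any stage runs.
#'
#' @param config partial nested list (e.g. from [read_config()]).
#' @return complete `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  def <- default_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (sec in names(config)) {
    if (is.list(def[[sec]])) {
      badk <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(badk))
        stop("unknown keys in ", sec, ": ", paste(badk, collapse = ", "))
      def[[sec]][names(config[[sec]])] <- config[[sec]]
    } else {
      def[[sec]] <- config[[sec]]
    }
  }
  with(def$predict, {
    if (repeats < 1) stop("predict$repeats must be >= 1")
    if (outer < 2 || inner < 2) stop("fold counts must be >= 2")
  })
  if (def$simulate$maf_min <= 0 || def$simulate$maf_min >= 0.5)
    stop("maf_min must be in (0, 0.5)")
  if (def$eqtl$max_steps < 1) stop("eqtl$max_steps must be >= 1")
  def
}

#' Read a YAML configuration file
#' @param path YAML file with any subset of the keys of [default_config()].
#' @return validated `pipeline_config`.
#' @export
read_config <- function(path) validate_config(yaml::read_yaml(path))

#' A trait panel with a redundancy gradient
#'
#' `n_traits` traits sharing a constant direct-SNP variance fraction while
#' the transcript-mediated site-1-only fraction rises linearly from 0 to
#' `v_site1_max` (the residual fraction absorbs the difference, so
#' heritability rises along the gradient as it would across a real trait
#' panel). Traits at the top of the gradient route much of their signal
#' through trans-regulated transcripts -- the redundant predictors whose
#' rank the integration statistic tracks -- while the constant direct-SNP
#' background supplies the competing predictors that can overtake them
#' once integration hands their signal to the transcripts.
#'
#' @param n_traits number of traits.
#' @param v_site1_max site-1-only transcript-mediated fraction of the last
#'   trait.
#' @param v_snp constant direct-SNP fraction shared by all traits.
#' @param mediator_pool passed to [trait_spec()].
#' @param v_block,v_spatial,rho fractions and AR parameter for the field
#'   layer; the residual fraction absorbs the remainder.
#' @param n_transcripts,n_snps_direct mediator transcripts and causal SNPs
#'   per trait (see [trait_spec()]).
#' @return list of `trait_spec` objects.
#' @export
trait_panel_gradient <- function(n_traits = 12, v_site1_max = 0.35,
                                 v_snp = 0.25,
                                 mediator_pool = "trans",
                                 v_block = 0.05, v_spatial = 0, rho = 0.8,
                                 n_transcripts = 96, n_snps_direct = 15,
                                 f_dosage = 0.5) {
  lapply(seq_len(n_traits), function(i) {
    v_s1 <- v_site1_max * (i - 1) / max(1, n_traits - 1)
    trait_spec(sprintf("trait%02d", i),
               v_snp_direct = v_snp,
               v_transcript_mediated = 0,
               v_transcript_site1_only = v_s1,
               v_block = v_block, v_spatial = v_spatial,
               v_residual = 1 - v_snp - v_s1 - v_block - v_spatial,
               mediator_pool = mediator_pool, f_dosage = f_dosage,
               rho_row = rho, rho_col = rho,
               n_transcripts = n_transcripts, n_snps_direct = n_snps_direct)
  })
}

#' Write a genome annotation as GFF3-lite
#' @param ann `genome_annotation`; @param path output file.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     ann$chromosomes$chrom, ann$chromosomes$length_bp),
             sprintf("%s\tredunrank\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     ann$genes$chrom, ann$genes$start_bp, ann$genes$end_bp,
                     ann$genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3-lite gene annotation
#' @param path GFF3 file with gene features carrying `ID=`.
#' @return `genome_annotation`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  seqs <- grep("^##sequence-region", lines, value = TRUE)
  chrom_df <- do.call(rbind, lapply(strsplit(seqs, "\\s+"), function(f)
    data.frame(chrom = f[2], length_bp = as.integer(f[4]),
               stringsAsFactors = FALSE)))
  rows <- lines[!startsWith(lines, "#")]
  f <- strsplit(rows, "\t")
  f <- f[vapply(f, function(x) length(x) >= 9 && x[3] == "gene", logical(1))]
  genes <- do.call(rbind, lapply(f, function(x) data.frame(
    gene_id = sub("^.*ID=([^;]+).*$", "\\1", x[9]), chrom = x[1],
    start_bp = as.integer(x[4]), end_bp = as.integer(x[5]),
    stringsAsFactors = FALSE)))
  genes$midpoint_bp <- (genes$start_bp + genes$end_bp) %/% 2L
  structure(list(chromosomes = chrom_df, genes = genes),
            class = "genome_annotation")
}

#' Write genotypes as dosage + SNP meta TSVs
#' @param geno `genotype_matrix`; @param prefix file prefix (writes
#'   `<prefix>_dosages.tsv` and `<prefix>_snps.tsv`).
#' @param comment provenance comment for [write_tsv()].
#' @return character vector of the two paths, invisibly.
#' @export
write_genotypes <- function(geno, prefix, comment = NULL) {
  d <- data.frame(individual = rownames(geno$dosages),
                  geno$dosages, check.names = FALSE,
                  stringsAsFactors = FALSE)
  p1 <- write_tsv(d, paste0(prefix, "_dosages.tsv"), comment)
  p2 <- write_tsv(geno$snp_meta, paste0(prefix, "_snps.tsv"), comment)
  invisible(c(p1, p2))
}

#' Read genotypes from TSV or VCF
#'
#' TSV format: the pair written by [write_genotypes()]. VCF: biallelic SNP
#' records only (multi-allelic records are skipped with a warning), dosages
#' as alt-allele counts; missing genotypes are an error (imputation belongs
#' upstream). SNPs below `maf_min` realized minor allele frequency are
#' removed; the boundary is kept (rule is `>=`).
#'
#' @param path dosage TSV path or VCF path.
#' @param format "tsv" or "vcf".
#' @param snp_meta_path companion SNP meta TSV (tsv format only; defaults to
#'   the `_snps.tsv` sibling).
#' @param maf_min minor-allele-frequency filter; NULL disables.
#' @return `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"),
                           snp_meta_path = NULL, maf_min = 0.05) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- as.data.frame(read_tsv(path))
    ind <- d[[1]]
    M <- as.matrix(d[, -1, drop = FALSE])
    rownames(M) <- ind
    if (is.null(snp_meta_path))
      snp_meta_path <- sub("_dosages\\.tsv$", "_snps.tsv", path)
    meta <- as.data.frame(read_tsv(snp_meta_path))
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("vcfR is required for VCF input")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1 |
      nchar(fix[, "ALT"]) != 1
    if (any(multi)) warning(sum(multi), " non-biallelic-SNP records skipped")
    gt <- vcfR::extract.gt(v, element = "GT")[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    count_alt <- function(g) {
      a <- strsplit(g, "[/|]")
      vapply(a, function(x) sum(as.integer(x)), integer(1))
    }
    if (anyNA(gt) || any(grepl("\\.", gt)))
      stop("missing genotypes in VCF; impute upstream")
    M <- t(apply(gt, 1, count_alt))
    M <- t(M)   # individuals x SNPs
    ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                  paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"])
    colnames(M) <- ids
    rownames(M) <- colnames(gt)
    meta <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                       pos_bp = as.integer(fix[, "POS"]),
                       host_gene_id = NA_character_, stringsAsFactors = FALSE)
  }
  if (anyNA(M)) stop(sum(is.na(M)), " missing dosages; impute upstream")
  if (!is.null(maf_min)) {
    maf <- colMeans(M) / 2
    maf <- pmin(maf, 1 - maf)
    keep <- maf >= maf_min
    M <- M[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  structure(list(dosages = M, snp_meta = meta, ind_ids = rownames(M)),
            class = "genotype_matrix")
}

#' Run the full pipeline
#'
#' Executes every stage on simulated data: generate genome/genotypes/
#' expression/phenotypes, adjust field phenotypes, process expression to
#' genotypic BLUPs, map eQTLs, classify them, fit G / T / G+T ridge models
#' under nested CV, compute rank changes and their regressions against
#' integration advantage per site, and run the GO enrichment on the
#' rank-change extremes of the steepest-gradient trait. When `out_dir` is
#' given every intermediate table is written as TSV stamped with the config
#' hash and seed.
#'
#' @param config a `pipeline_config` (see [validate_config()]).
#' @param out_dir optional output directory.
#' @return results bundle (named list of all stage outputs).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  config <- validate_config(unclass(config))
  seed <- config$seed
  stamp <- c(config_hash = content_hash(unclass(config)), seed = seed)
  sv <- function(x, name) if (!is.null(out_dir))
    write_tsv(x, file.path(out_dir, paste0(name, ".tsv")), stamp)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  cs <- config$simulate
  ann <- simulate_genome(cs$n_chrom, cs$genes_per_chrom, cs$chrom_length_bp,
                         cs$gene_length_range, seed = seed)
  geno <- simulate_genotypes(ann, cs$n_ind, cs$snps_per_gene, cs$maf_min,
                             cs$ld_rho, cs$n_subpop, cs$fst, seed = seed)
  expr <- simulate_expression(geno, ann, cs$n_cis, cs$n_trans, cs$n_hubs,
                              cs$hub_fanout, cs$effect_sd, cs$batch_sd,
                              cs$disp, cs$gnoise_sd,
                              baseline_log_mean = cs$baseline_log_mean,
                              baseline_log_sd = cs$baseline_log_sd,
                              seed = seed)
  specs <- trait_panel_gradient(cs$n_traits, cs$v_site1_max)
  phen <- simulate_phenotypes(geno, expr$truth, specs,
                              layout_spec = list(n_blocks = cs$n_blocks),
                              seed = seed)
  sv(phen$field, "phenotypes_field")

  adj <- adjust_phenotypes(phen$field,
                           rho_grid = seq(-0.9, 0.9,
                                          by = config$adjust$rho_grid_step),
                           candidate_models = config$adjust$candidate_models)
  sv(data.frame(genotype = rownames(adj$adjusted), adj$adjusted,
                check.names = FALSE), "adjusted_means")
  sv(adj$report, "adjustment_report")

  ep <- process_expression(expr$counts, expr$sample_map,
                           config$exprproc$min_count, config$exprproc$min_prop)
  blups <- ep$blups[geno$ind_ids, , drop = FALSE]
  sv(data.frame(genotype = rownames(blups), blups, check.names = FALSE),
     "blups")

  eq <- eqtl_scan_all(blups, geno, max_steps = config$eqtl$max_steps,
                      alpha = config$eqtl$alpha)
  cis_max <- config$classify$cis_max_bp
  if (identical(cis_max, "auto")) {
    cis_max <- tryCatch(derive_cis_threshold(eq, geno$snp_meta, ann),
                        error = function(e)
                          config$classify$fallback_cis_max_bp)
  }
  eq <- classify_associations(eq, geno$snp_meta, ann, cis_max)
  sv(cbind(eq, chrom_snp = geno$snp_meta$chrom[match(eq$snp_id,
                                                     geno$snp_meta$snp_id)],
           pos_snp = geno$snp_meta$pos_bp[match(eq$snp_id,
                                                geno$snp_meta$snp_id)]),
     "eqtls")
  cats <- categorize_features(eq, geno$snp_meta, colnames(blups))

  # --- prediction: G, T, G+T per trait_site, shared fold partitions
  traits <- colnames(adj$adjusted)
  X_g <- geno$dosages
  X_t <- blups
  X_gt <- cbind(X_g, X_t)
  cp <- config$predict
  lams <- list(G = lambda_grid(X_g, cp$n_lambda),
               T = lambda_grid(X_t, cp$n_lambda),
               GT = lambda_grid(X_gt, cp$n_lambda))
  r2_rows <- list(); fits <- list(); effects <- list(); comp_rows <- list()
  for (tr in traits) {
    y <- adj$adjusted[, tr]
    ok <- is.finite(y)
    fits[[tr]] <- list(
      G = nested_cv(X_g[ok, , drop = FALSE], y[ok], cp$outer, cp$inner,
                    cp$repeats, lams$G, seed = seed),
      T = nested_cv(X_t[ok, , drop = FALSE], y[ok], cp$outer, cp$inner,
                    cp$repeats, lams$T, seed = seed),
      GT = nested_cv(X_gt[ok, , drop = FALSE], y[ok], cp$outer, cp$inner,
                     cp$repeats, lams$GT, seed = seed))
    effects[[tr]] <- list(
      g = full_effects(X_g[ok, , drop = FALSE], y[ok], lams$G,
                       seed = seed)$effects,
      t = full_effects(X_t[ok, , drop = FALSE], y[ok], lams$T,
                       seed = seed)$effects,
      gt = full_effects(X_gt[ok, , drop = FALSE], y[ok], lams$GT,
                        seed = seed)$effects)
    for (mm in c("G", "T", "GT")) {
      r2m <- fits[[tr]][[mm]]$r2
      r2_rows[[paste(tr, mm)]] <- data.frame(
        trait = tr, model = mm,
        repeat_ = rep(seq_len(nrow(r2m)), ncol(r2m)),
        fold = rep(seq_len(ncol(r2m)), each = nrow(r2m)),
        r2 = as.numeric(r2m), stringsAsFactors = FALSE)
    }
    for (mm in c("G", "T")) {
      cmp <- compare_models(fits[[tr]]$GT, fits[[tr]][[mm]],
                            test = cp$test)
      comp_rows[[paste(tr, mm)]] <- data.frame(
        trait = tr, against = mm, mean_diff = cmp$mean_diff, p = cmp$p,
        sign = cmp$sign, stringsAsFactors = FALSE)
    }
  }
  r2_long <- do.call(rbind, c(r2_rows, list(make.row.names = FALSE)))
  comparisons <- do.call(rbind, c(comp_rows, list(make.row.names = FALSE)))
  sv(r2_long, "r2"); sv(comparisons, "comparisons")

  adv_g <- vapply(fits, function(f) mean(f$GT$r2) - mean(f$G$r2), numeric(1))
  adv_t <- vapply(fits, function(f) mean(f$GT$r2) - mean(f$T$r2), numeric(1))

  # per-site rank-change regressions over the window scan
  sites <- phen$truth$layout$sites
  regressions <- list(); deltas <- list()
  for (s in sites) {
    tr_s <- grep(paste0("_", s, "$"), traits, value = TRUE)
    if (length(tr_s) < 3) next
    ws <- window_scan(eq, geno$snp_meta, colnames(blups),
                      effects_by_trait = effects[tr_s],
                      advantages_g = adv_g[tr_s], advantages_t = adv_t[tr_s],
                      windows = config$rankstat$windows,
                      dedup_snps = config$rankstat$dedup_snps)
    ws$site <- s
    regressions[[s]] <- ws
    dl <- lapply(tr_s, function(tr) {
      d <- rank_change_summary(effects[[tr]]$g, effects[[tr]]$t,
                               effects[[tr]]$gt, cats,
                               config$rankstat$dedup_snps)
      d$trait <- tr
      d
    })
    deltas[[s]] <- do.call(rbind, dl)
  }
  regressions <- do.call(rbind, regressions)
  deltas <- do.call(rbind, deltas)
  sv(deltas, "rank_change_deltas"); sv(regressions, "rank_change_regressions")

  # --- GO enrichment on the steepest-gradient site-1 trait
  go <- simulate_go(config$goelim$n_terms, n_genes = ncol(blups),
                    terms_per_gene = config$goelim$terms_per_gene,
                    seed = seed)
  # map the synthetic gene universe onto the transcript ids
  gene_map <- stats::setNames(colnames(blups), go$genes[seq_len(ncol(blups))])
  ann_go <- go$ann[go$ann$gene %in% names(gene_map), ]
  ann_go$gene <- unname(gene_map[ann_go$gene])
  go_trait <- traits[grepl(paste0("_", sites[1], "$"), traits)]
  go_trait <- go_trait[length(go_trait)]
  ef <- effects[[go_trait]]
  rk_change <- rank_squared(ef$gt[names(ef$t)]) - rank_squared(ef$t)
  ext <- select_extremes(rk_change, config$goelim$q)
  enr <- lapply(list(low = ext$low, high = ext$high), function(gset)
    elim_fisher(gset, colnames(blups), go$dag, ann_go,
                alpha = config$goelim$alpha))
  go_tab <- rbind(data.frame(side = "low", enr$low,
                             stringsAsFactors = FALSE),
                  data.frame(side = "high", enr$high,
                             stringsAsFactors = FALSE))
  sv(go_tab, "go_enrichment")

  list(config = config, annotation = ann, genotypes = geno,
       expression = expr, phenotypes = phen, adjusted = adj,
       exprproc = ep, blups = blups, eqtls = eq, cis_max_bp = cis_max,
       categories = cats, fits = fits, effects = effects, r2 = r2_long,
       comparisons = comparisons, advantage_g = adv_g, advantage_t = adv_t,
       deltas = deltas, regressions = regressions, go = go_tab)
}
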