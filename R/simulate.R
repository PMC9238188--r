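#' Simulate a compact genome annotation
#'
#' Generates a multi-chromosome genome with non-overlapping genes, the
#' positional frame on which cis/trans classification of eQTLs operates.
#' The default of 19 chromosomes mirrors the chromosome count of the
#' *Populus trichocarpa* reference assembly on which poplar eQTL maps are
#' drawn; lengths and gene density are deliberately compact so that desk-scale
#' simulations still produce both within-gene and distant SNP-gene pairs.
#'
#' @param n_chrom number of chromosomes.
#' @param genes_per_chrom genes placed on each chromosome.
#' @param chrom_length_bp chromosome length in bp.
#' @param gene_length_range length-2 integer vector, min/max gene length.
#' @param seed integer seed; identical seed gives bit-identical output.
#' @return an object of class `genome_annotation`: list with `chromosomes`
#'   (data.frame: chrom, length_bp) and `genes` (data.frame: gene_id, chrom,
#'   start_bp, end_bp, midpoint_bp), genes sorted by start within chromosome.
#' @export
simulate_genome <- function(n_chrom = 19, genes_per_chrom = 100,
                            chrom_length_bp = 2e6,
                            gene_length_range = c(1000L, 5000L), seed = 1) {
  stopifnot(n_chrom >= 1, genes_per_chrom >= 1,
            length(gene_length_range) == 2, diff(gene_length_range) >= 0)
  with_seed(substream_seed(seed, "genome"), {
    genes <- vector("list", n_chrom)
    for (ch in seq_len(n_chrom)) {
      len <- sample(gene_length_range[1]:gene_length_range[2],
                    genes_per_chrom, replace = TRUE)
      slack <- chrom_length_bp - sum(len) - genes_per_chrom
      if (slack < 0) {
        stop("genes cannot fit on chromosome ", ch,
             " without overlap; increase chrom_length_bp or shrink genes")
      }
      # random partition of the slack into inter-gene gaps (>= 1 bp apart)
      cuts <- sort(sample.int(slack + 1L, genes_per_chrom, replace = TRUE) - 1L)
      gaps <- c(cuts[1], diff(cuts)) + 1L
      start <- cumsum(gaps) + c(0L, cumsum(len[-genes_per_chrom]))
      end <- start + len - 1L
      genes[[ch]] <- data.frame(
        gene_id = sprintf("g%02d_%04d", ch, seq_len(genes_per_chrom)),
        chrom = sprintf("chr%02d", ch),
        start_bp = start, end_bp = end,
        stringsAsFactors = FALSE
      )
    }
    genes <- do.call(rbind, genes)
    genes$midpoint_bp <- (genes$start_bp + genes$end_bp) %/% 2L
    ann <- list(
      chromosomes = data.frame(chrom = sprintf("chr%02d", seq_len(n_chrom)),
                               length_bp = chrom_length_bp,
                               stringsAsFactors = FALSE),
      genes = genes
    )
    class(ann) <- "genome_annotation"
    ann
  })
}

#' Simulate intragenic SNP dosages with tunable local LD
#'
#' SNPs are placed inside gene spans only, emulating genotyping derived from
#' RNA-seq reads (which samples intragenic space). Haplotypes are generated
#' per gene block by a first-order Markov chain whose transition
#' probabilities are chosen so that adjacent SNPs have dosage correlation
#' `ld_rho` in expectation, decaying geometrically with distance in SNPs.
#' Optional subpopulation structure follows the Balding-Nichols model.
#' SNPs whose realized minor allele frequency falls below `maf_min` are
#' removed, as is standard practice before association mapping.
#'
#' @param ann a `genome_annotation`.
#' @param n_ind number of individuals (genotypes).
#' @param snps_per_gene SNPs drawn per gene before the MAF filter.
#' @param maf_min minor-allele-frequency threshold (rule is `>=`).
#' @param ld_rho target correlation between adjacent intragenic SNPs, in [0, 1).
#' @param n_subpop number of subpopulations (1 = panmictic, the default).
#' @param fst Balding-Nichols differentiation when `n_subpop > 1`.
#' @param seed integer seed.
#' @return object of class `genotype_matrix`: list with `dosages`
#'   (individuals x SNPs integer matrix in 0/1/2), `snp_meta` (snp_id, chrom,
#'   pos_bp, host_gene_id), `ind_ids`.
#' @export
simulate_genotypes <- function(ann, n_ind = 241, snps_per_gene = 10,
                               maf_min = 0.05, ld_rho = 0.7,
                               n_subpop = 1, fst = 0.1, seed = 1) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (n_ind < 2) stop("need at least 2 individuals")
  if (maf_min <= 0 || maf_min >= 0.5) stop("maf_min must be in (0, 0.5)")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  with_seed(substream_seed(seed, "genotypes"), {
    ind_ids <- sprintf("ind%03d", seq_len(n_ind))
    subpop <- rep(seq_len(n_subpop), length.out = n_ind)
    genes <- ann$genes
    n_hap <- 2L * n_ind
    dos_list <- vector("list", nrow(genes))
    meta_list <- vector("list", nrow(genes))
    for (gi in seq_len(nrow(genes))) {
      g <- genes[gi, ]
      span <- g$end_bp - g$start_bp + 1L
      k <- min(snps_per_gene, span)
      pos <- sort(sample.int(span, k)) + g$start_bp - 1L
      p0 <- stats::runif(1, max(0.10, maf_min), 0.5)
      p <- pmin(0.5, pmax(maf_min,
                          p0 + stats::runif(k, -0.05, 0.05)))
      # per-subpopulation allele frequencies (Balding-Nichols)
      pmat <- matrix(p, nrow = n_subpop, ncol = k, byrow = TRUE)
      if (n_subpop > 1) {
        a <- (1 - fst) / fst
        for (s in seq_len(n_subpop)) {
          pmat[s, ] <- stats::rbeta(k, p * a, (1 - p) * a)
          pmat[s, ] <- pmin(0.95, pmax(0.02, pmat[s, ]))
        }
      }
      hp <- pmat[rep(subpop, each = 2L), , drop = FALSE]  # n_hap x k freqs
      hap <- matrix(0L, n_hap, k)
      hap[, 1] <- as.integer(stats::runif(n_hap) < hp[, 1])
      if (k > 1) for (j in 2:k) {
        pa <- hp[, j - 1]; pb <- hp[, j]
        cv <- ld_rho * sqrt(pa * (1 - pa) * pb * (1 - pb))
        pr <- ifelse(hap[, j - 1] == 1L, pb + cv / pa, pb - cv / (1 - pa))
        hap[, j] <- as.integer(stats::runif(n_hap) < pmin(1, pmax(0, pr)))
      }
      dos_list[[gi]] <- hap[seq(1, n_hap, 2), , drop = FALSE] +
        hap[seq(2, n_hap, 2), , drop = FALSE]
      meta_list[[gi]] <- data.frame(chrom = g$chrom, pos_bp = pos,
                                    host_gene_id = g$gene_id,
                                    stringsAsFactors = FALSE)
    }
    dosages <- do.call(cbind, dos_list)
    snp_meta <- do.call(rbind, meta_list)
    maf <- colMeans(dosages) / 2
    maf <- pmin(maf, 1 - maf)
    keep <- maf >= maf_min
    dosages <- dosages[, keep, drop = FALSE]
    snp_meta <- snp_meta[keep, , drop = FALSE]
    snp_meta <- data.frame(snp_id = sprintf("s%06d", seq_len(nrow(snp_meta))),
                           snp_meta, stringsAsFactors = FALSE)
    rownames(snp_meta) <- NULL
    dimnames(dosages) <- list(ind_ids, snp_meta$snp_id)
    geno <- list(dosages = dosages, snp_meta = snp_meta, ind_ids = ind_ids,
                 subpop = subpop)
    class(geno) <- "genotype_matrix"
    geno
  })
}

#' Simulate transcript counts with a planted cis/trans eQTL architecture
#'
#' One transcript per annotated gene. Counts follow a negative-binomial model
#' whose log-scale mean is baseline + batch effect + the sum of planted eQTL
#' dosage effects + a genotype-level noise term. The genotype-level noise is
#' what makes transcripts informative about phenotypes beyond what the
#' genotyped SNPs carry, the ingredient behind any integration advantage.
#' Cis effects are assigned to SNPs inside the target gene; trans effects to
#' SNPs hosted by other genes at least `cis_max_bp` from the target midpoint
#' (or on another chromosome), so planted labels agree with the positional
#' classification rules. `n_hubs` of the trans-acting SNPs each regulate
#' `hub_fanout` transcripts, emulating regulatory hub loci.
#'
#' @param geno a `genotype_matrix`.
#' @param ann the `genome_annotation` used to build `geno`.
#' @param n_cis,n_trans number of cis / trans associations to plant
#'   (`n_trans` includes the hub associations).
#' @param n_hubs,hub_fanout hub loci and transcripts regulated per hub.
#' @param effect_sd sd of planted allelic effects on the log count scale.
#' @param batch_sd sd of per-transcript batch effects (log scale).
#' @param disp negative-binomial dispersion (> 0); variance = mu + disp * mu^2.
#' @param gnoise_sd sd of genotype-level expression noise (log scale).
#' @param reps_per_genotype integer vector of replicates (1 or 2) per
#'   genotype, or NULL for the default in which roughly 90% of genotypes have
#'   two replicates and the rest one (the 218:23 ratio of the motivating
#'   poplar panel).
#' @param baseline_log_mean,baseline_log_sd baseline abundance distribution
#'   (natural-log scale).
#' @param cis_max_bp positional window used to keep planted trans SNPs away
#'   from their targets.
#' @param seed integer seed.
#' @return list with `counts` (samples x transcripts integer matrix),
#'   `sample_map` (sample_id, genotype, batch) and `truth` (list:
#'   `true_eqtls` data.frame(snp_id, transcript_id, effect, class),
#'   `transcript_gv` genotype x transcript matrix of genetic values on the
#'   log scale).
#' @export
simulate_expression <- function(geno, ann, n_cis = 60, n_trans = 90,
                                n_hubs = 2, hub_fanout = 25,
                                effect_sd = 0.6, batch_sd = 0.2, disp = 0.15,
                                gnoise_sd = 0.3, reps_per_genotype = NULL,
                                baseline_log_mean = 4.6, baseline_log_sd = 1,
                                cis_max_bp = 12000, seed = 1) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(ann, "genome_annotation"))
  if (disp <= 0) stop("disp must be > 0")
  if (n_hubs * hub_fanout > n_trans)
    stop("n_trans must cover the hub associations (n_hubs * hub_fanout)")
  with_seed(substream_seed(seed, "expression"), {
    genes <- ann$genes
    m <- length(geno$ind_ids)
    q <- nrow(genes)
    transcripts <- genes$gene_id
    if (is.null(reps_per_genotype)) {
      n2 <- round(m * 218 / 241)
      reps_per_genotype <- rep(1L, m)
      reps_per_genotype[sample.int(m, n2)] <- 2L
    }
    reps_per_genotype <- rep(as.integer(reps_per_genotype), length.out = m)
    if (!all(reps_per_genotype %in% 1:2))
      stop("reps_per_genotype must be 1 or 2")

    snp_meta <- geno$snp_meta
    gene_by_id <- genes[match(transcripts, genes$gene_id), ]
    # --- plant cis associations: SNP inside target gene span
    host_tab <- split(seq_len(nrow(snp_meta)), snp_meta$host_gene_id)
    cis_genes <- intersect(transcripts, names(host_tab))
    if (length(cis_genes) < n_cis) stop("not enough SNP-bearing genes for n_cis")
    cis_targets <- sample(cis_genes, n_cis)
    cis_snp_idx <- vapply(cis_targets, function(g) {
      idx <- host_tab[[g]]
      idx[sample.int(length(idx), 1L)]
    }, integer(1))
    # --- plant trans associations: hubs first, then singletons
    trans_pairs <- list()
    far_enough <- function(snp_i, tgt_gene) {
      srow <- snp_meta[snp_i, ]
      grow <- genes[match(tgt_gene, genes$gene_id), ]
      srow$chrom != grow$chrom ||
        abs(srow$pos_bp - grow$midpoint_bp) > cis_max_bp
    }
    hub_snps <- sample.int(nrow(snp_meta), n_hubs)
    for (h in hub_snps) {
      ok <- transcripts[vapply(transcripts, function(g) far_enough(h, g), logical(1))]
      trans_pairs[[length(trans_pairs) + 1L]] <-
        data.frame(snp = h, transcript = sample(ok, hub_fanout),
                   stringsAsFactors = FALSE)
    }
    n_single <- n_trans - n_hubs * hub_fanout
    if (n_single > 0) {
      sp <- sample.int(nrow(snp_meta), n_single, replace = TRUE)
      tg <- character(n_single)
      for (i in seq_len(n_single)) {
        repeat {
          cand <- sample(transcripts, 1L)
          if (far_enough(sp[i], cand)) { tg[i] <- cand; break }
        }
      }
      trans_pairs[[length(trans_pairs) + 1L]] <-
        data.frame(snp = sp, transcript = tg, stringsAsFactors = FALSE)
    }
    trans_pairs <- do.call(rbind, trans_pairs)

    eqtls <- rbind(
      data.frame(snp = cis_snp_idx, transcript = cis_targets,
                 class = "CIS", stringsAsFactors = FALSE),
      data.frame(snp = trans_pairs$snp, transcript = trans_pairs$transcript,
                 class = "TRANS", stringsAsFactors = FALSE)
    )
    eqtls <- eqtls[!duplicated(eqtls[c("snp", "transcript")]), ]
    eqtls$effect <- stats::rnorm(nrow(eqtls), 0, effect_sd)

    # --- genotype-level genetic value of each transcript (log scale)
    gv_eqtl <- matrix(0, m, q, dimnames = list(geno$ind_ids, transcripts))
    dos_c <- scale(geno$dosages, center = TRUE, scale = FALSE)
    for (i in seq_len(nrow(eqtls))) {
      j <- match(eqtls$transcript[i], transcripts)
      gv_eqtl[, j] <- gv_eqtl[, j] + eqtls$effect[i] * dos_c[, eqtls$snp[i]]
    }
    gv_noise <- matrix(stats::rnorm(m * q, 0, gnoise_sd), m, q,
                       dimnames = dimnames(gv_eqtl))
    transcript_gv <- gv_eqtl + gv_noise

    # --- samples: replicate r of a genotype sits in batch r
    sample_geno <- rep(seq_len(m), reps_per_genotype)
    sample_rep <- unlist(lapply(reps_per_genotype, seq_len))
    sample_ids <- sprintf("%s_r%d", geno$ind_ids[sample_geno], sample_rep)
    n_s <- length(sample_ids)
    b0 <- stats::rnorm(q, baseline_log_mean, baseline_log_sd)
    batch_eff <- matrix(stats::rnorm(2L * q, 0, batch_sd), 2L, q)
    eta <- matrix(b0, n_s, q, byrow = TRUE) +
      transcript_gv[sample_geno, , drop = FALSE] +
      batch_eff[sample_rep, , drop = FALSE]
    counts <- matrix(stats::rnbinom(n_s * q, mu = exp(eta), size = 1 / disp),
                     n_s, q, dimnames = list(sample_ids, transcripts))
    list(
      counts = counts,
      sample_map = data.frame(sample_id = sample_ids,
                              genotype = geno$ind_ids[sample_geno],
                              batch = sprintf("batch%d", sample_rep),
                              stringsAsFactors = FALSE),
      truth = list(
        true_eqtls = data.frame(snp_id = snp_meta$snp_id[eqtls$snp],
                                transcript_id = eqtls$transcript,
                                effect = eqtls$effect, class = eqtls$class,
                                stringsAsFactors = FALSE),
        transcript_gv = transcript_gv,
        transcript_gv_eqtl = gv_eqtl,
        hub_snps = snp_meta$snp_id[hub_snps],
        params = list(effect_sd = effect_sd, batch_sd = batch_sd, disp = disp,
                      gnoise_sd = gnoise_sd, cis_max_bp = cis_max_bp)
      )
    )
  })
}

#' Default specification for one simulated trait
#'
#' Variance fractions are relative to the total plot-level variance of the
#' trait. `v_transcript_site1_only` is a genetic component mediated by
#' transcripts that expresses only at the first site, the device that creates
#' a site asymmetry in the benefit of adding transcripts to the predictor
#' set (transcripts are sampled at one site, and capture genotype-by-
#' environment signal specific to it).
#'
#' @param name trait name.
#' @param v_snp_direct variance through direct SNP effects.
#' @param v_transcript_mediated variance through transcript genetic values,
#'   expressed at both sites.
#' @param v_transcript_site1_only transcript-mediated variance at site 1 only.
#' @param v_block,v_spatial,v_residual block, spatial AR1xAR1 and iid
#'   plot-level fractions.
#' @param n_snps_direct,n_transcripts numbers of causal SNPs / mediator
#'   transcripts drawn.
#' @param mediator_pool which transcripts mediate: "trans" (trans-regulated),
#'   "cis", or "any".
#' @param coherent_weights align each mediator's weight sign with the sign
#'   of its largest planted eQTL effect, so that a regulator locus
#'   contributes coherently (rather than with random cancellation) to the
#'   mediated trait component -- the picture of a hub driving a pathway in
#'   one direction.
#' @param f_dosage when non-NULL, fix the fraction of the transcript-
#'   mediated component that is driven by the mediators' eQTL dosages (the
#'   remainder coming from their genotype-level intrinsic variation), by
#'   standardizing the two parts separately before mixing. Pins down how
#'   SNP-visible the mediated signal is, instead of leaving that ratio to
#'   the luck of the weight draw.
#' @param rho_row,rho_col autoregressive parameters of the spatial surface.
#' @return a `trait_spec` list.
#' @export
trait_spec <- function(name, v_snp_direct = 0.3, v_transcript_mediated = 0.2,
                       v_transcript_site1_only = 0, v_block = 0.05,
                       v_spatial = 0.1, v_residual = 0.25,
                       n_snps_direct = 20, n_transcripts = 10,
                       mediator_pool = c("trans", "cis", "any"),
                       coherent_weights = FALSE, f_dosage = NULL,
                       rho_row = 0.8, rho_col = 0.8) {
  v <- c(v_snp_direct, v_transcript_mediated, v_transcript_site1_only,
         v_block, v_spatial, v_residual)
  if (any(v < 0) || sum(v) > 1 + 1e-8)
    stop("variance fractions must be non-negative and sum to <= 1")
  structure(list(name = name, v_snp_direct = v_snp_direct,
                 v_transcript_mediated = v_transcript_mediated,
                 v_transcript_site1_only = v_transcript_site1_only,
                 v_block = v_block, v_spatial = v_spatial,
                 v_residual = v_residual, n_snps_direct = n_snps_direct,
                 n_transcripts = n_transcripts,
                 mediator_pool = match.arg(mediator_pool),
                 coherent_weights = coherent_weights, f_dosage = f_dosage,
                 rho_row = rho_row, rho_col = rho_col),
            class = "trait_spec")
}

# AR1 correlation Cholesky factor (lower), unit marginal variance
ar1_chol <- function(n, rho) {
  if (n == 1L) return(matrix(1, 1, 1))
  L <- matrix(0, n, n)
  L[, 1] <- rho^(0:(n - 1))
  s <- sqrt(1 - rho^2)
  for (j in 2:n) L[j:n, j] <- s * rho^(0:(n - j))
  L
}

#' Simulate multi-site field phenotypes over a randomized complete block design
#'
#' Each site holds every genotype once per block on a rectangular grid
#' (blocks are contiguous bands of plots, genotypes randomized within block).
#' Plot values are genotype genetic value + block effect + a separable
#' first-order autoregressive spatial surface + iid noise, with the relative
#' weights set by each trait's `trait_spec`. Site 2 reuses the same genetic
#' values minus the transcript-site1-only component, so any downstream
#' site asymmetry in integration advantage is attributable to that component.
#'
#' @param geno a `genotype_matrix`.
#' @param truth_expr the `truth` element returned by [simulate_expression()].
#' @param trait_specs list of [trait_spec()] objects.
#' @param layout_spec list with `sites` (2 site codes, default ORL/SAV) and
#'   `n_blocks` (default 6, a randomized complete block design with 6 blocks).
#' @param shared_site1_module draw the site-1-only mediator combination once
#'   and reuse it across traits (each trait still applies its own loading
#'   `sqrt(v_transcript_site1_only)`): the picture of a single
#'   tissue-specific regulatory module feeding many traits to different
#'   degrees, versus an independent mediator draw per trait.
#' @param seed integer seed.
#' @return list with `field` (long data.frame: genotype, site, block, row,
#'   col, trait, value) and `truth` (list: `genetic_value` per site
#'   genotype x trait matrices, spatial and block parameters drawn).
#' @export
simulate_phenotypes <- function(geno, truth_expr, trait_specs,
                                layout_spec = NULL,
                                shared_site1_module = FALSE,
                                shared_snp_module = FALSE, seed = 1) {
  stopifnot(inherits(geno, "genotype_matrix"), is.list(trait_specs))
  if (is.null(layout_spec)) layout_spec <- list()
  sites <- layout_spec$sites %||% c("ORL", "SAV")
  n_blocks <- layout_spec$n_blocks %||% 6L
  m <- length(geno$ind_ids)
  with_seed(substream_seed(seed, "phenotypes"), {
    n_plots <- m * n_blocks
    n_cols <- ceiling(sqrt(n_plots))
    n_rows <- ceiling(n_plots / n_cols)
    tnames <- vapply(trait_specs, `[[`, character(1), "name")
    if (anyDuplicated(tnames)) stop("duplicate trait names")

    # genotype-level components shared across sites
    gv <- list()
    for (s in sites) gv[[s]] <- matrix(0, m, length(trait_specs),
                                       dimnames = list(geno$ind_ids, tnames))
    dos_c <- scale(geno$dosages, center = TRUE, scale = FALSE)
    tgv <- truth_expr$transcript_gv
    tgv_eqtl <- truth_expr$transcript_gv_eqtl
    te <- truth_expr$true_eqtls
    pool_of <- function(pool) {
      switch(pool,
        trans = unique(te$transcript_id[te$class == "TRANS"]),
        cis = unique(te$transcript_id[te$class == "CIS"]),
        any = colnames(tgv))
    }
    zstd <- function(x) {
      sdx <- stats::sd(x)
      if (sdx == 0) return(x * 0)
      (x - mean(x)) / sdx
    }
    trait_arch <- list()
    comp <- function(spec, what) {
      if (what == "snp") {
        idx <- sample.int(ncol(dos_c), min(spec$n_snps_direct, ncol(dos_c)))
        w <- stats::rnorm(length(idx))
        list(z = zstd(dos_c[, idx, drop = FALSE] %*% w),
             members = colnames(dos_c)[idx], weights = w)
      } else {
        pool <- pool_of(spec$mediator_pool)
        if (length(pool) == 0) stop("empty mediator pool for ", spec$name)
        idx <- sample(pool, min(spec$n_transcripts, length(pool)))
        w <- stats::rnorm(length(idx))
        if (isTRUE(spec$coherent_weights)) {
          # weight sign follows the mediator's strongest planted effect
          sgn <- vapply(idx, function(t) {
            ee <- te$effect[te$transcript_id == t]
            if (length(ee)) sign(ee[which.max(abs(ee))]) else
              sample(c(-1, 1), 1)
          }, numeric(1))
          w <- abs(w) * sgn
        }
        z <- if (!is.null(spec$f_dosage)) {
          ze <- zstd(tgv_eqtl[, idx, drop = FALSE] %*% w)
          zn <- zstd((tgv[, idx, drop = FALSE] -
                        tgv_eqtl[, idx, drop = FALSE]) %*% w)
          zstd(sqrt(spec$f_dosage) * ze + sqrt(1 - spec$f_dosage) * zn)
        } else zstd(tgv[, idx, drop = FALSE] %*% w)
        list(z = z, members = idx, weights = w)
      }
    }
    zero <- list(z = numeric(m), members = character(0), weights = numeric(0))
    shared_s1 <- NULL; shared_snp <- NULL
    for (k in seq_along(trait_specs)) {
      sp <- trait_specs[[k]]
      z_snp <- if (sp$v_snp_direct > 0) {
        if (shared_snp_module) {
          if (is.null(shared_snp)) shared_snp <- comp(sp, "snp")
          shared_snp
        } else comp(sp, "snp")
      } else zero
      z_med <- if (sp$v_transcript_mediated > 0) comp(sp, "tr") else zero
      z_s1 <- if (sp$v_transcript_site1_only > 0) {
        if (shared_site1_module) {
          if (is.null(shared_s1)) shared_s1 <- comp(sp, "tr")
          shared_s1
        } else comp(sp, "tr")
      } else zero
      base <- sqrt(sp$v_snp_direct) * z_snp$z +
        sqrt(sp$v_transcript_mediated) * z_med$z
      gv[[sites[1]]][, k] <- base + sqrt(sp$v_transcript_site1_only) * z_s1$z
      gv[[sites[2]]][, k] <- base
      trait_arch[[sp$name]] <- list(
        causal_snps = z_snp$members, snp_weights = z_snp$weights,
        mediators_common = z_med$members, mediator_weights = z_med$weights,
        mediators_site1 = z_s1$members, mediator_site1_weights = z_s1$weights)
    }

    rows_of <- integer(n_plots); cols_of <- integer(n_plots)
    idx <- seq_len(n_plots)
    rows_of <- ((idx - 1L) %/% n_cols) + 1L
    cols_of <- ((idx - 1L) %% n_cols) + 1L
    recs <- vector("list", length(sites) * length(trait_specs))
    ri <- 0L
    blk_truth <- list()
    for (s in sites) {
      # plot layout: block b occupies plots ((b-1)m+1):(bm); genotypes
      # randomized within block
      geno_of <- unlist(lapply(seq_len(n_blocks),
                               function(b) sample.int(m)))
      block_of <- rep(seq_len(n_blocks), each = m)
      for (k in seq_along(trait_specs)) {
        sp <- trait_specs[[k]]
        b_eff <- stats::rnorm(n_blocks)
        Lr <- ar1_chol(n_rows, sp$rho_row)
        Lc <- ar1_chol(n_cols, sp$rho_col)
        S <- Lr %*% matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols) %*% t(Lc)
        val <- gv[[s]][geno_of, k] +
          sqrt(sp$v_block) * b_eff[block_of] +
          sqrt(sp$v_spatial) * S[cbind(rows_of, cols_of)] +
          sqrt(sp$v_residual) * stats::rnorm(n_plots)
        ri <- ri + 1L
        recs[[ri]] <- data.frame(
          genotype = geno$ind_ids[geno_of], site = s, block = block_of,
          row = rows_of, col = cols_of, trait = sp$name, value = as.numeric(val),
          stringsAsFactors = FALSE)
        blk_truth[[paste(s, sp$name, sep = ":")]] <-
          list(block_effects = b_eff, rho_row = sp$rho_row, rho_col = sp$rho_col)
      }
    }
    list(field = do.call(rbind, recs),
         truth = list(genetic_value = gv, trait_arch = trait_arch,
                      layout = list(
                        n_rows = n_rows, n_cols = n_cols, n_blocks = n_blocks,
                        sites = sites),
                      per_site_trait = blk_truth))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
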