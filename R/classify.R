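# Positional cis/trans classification of eQTL associations and the
# predictor-category masks used by the rank-change statistic. Coordinates
# are 1-based inclusive (GFF3 convention); gene midpoint is
# floor((start + end) / 2).

#' Classify SNP-transcript associations as CIS or TRANS
#'
#' Three rules, applied in order per association: (1) SNP on a different
#' chromosome from its target gene -> TRANS; (2) SNP position within the
#' target gene span -> CIS; (3) otherwise TRANS if the distance from the SNP
#' to the gene midpoint exceeds `cis_max_bp`, CIS if not. A pure function of
#' the coordinates: input order never changes labels.
#'
#' @param eqtls data.frame with columns transcript_id, snp_id (e.g. from
#'   [eqtl_scan_all()]); the transcript id must match a gene id in `ann`.
#' @param snp_meta data.frame(snp_id, chrom, pos_bp).
#' @param ann `genome_annotation`.
#' @param cis_max_bp midpoint-distance threshold for rule 3 (default the
#'   12 kb threshold estimated on the motivating dataset; see
#'   [derive_cis_threshold()]).
#' @return `eqtls` with a `class` column ("CIS"/"TRANS").
#' @export
classify_associations <- function(eqtls, snp_meta, ann, cis_max_bp = 12000) {
  stopifnot(cis_max_bp > 0)
  si <- match(eqtls$snp_id, snp_meta$snp_id)
  gi <- match(eqtls$transcript_id, ann$genes$gene_id)
  if (anyNA(si)) stop("unknown snp_id: ", eqtls$snp_id[which(is.na(si))[1]])
  if (anyNA(gi)) stop("unknown gene id: ",
                      eqtls$transcript_id[which(is.na(gi))[1]])
  sc <- snp_meta$chrom[si]; sp <- snp_meta$pos_bp[si]
  g <- ann$genes[gi, ]
  cls <- ifelse(sc != g$chrom, "TRANS",
         ifelse(sp >= g$start_bp & sp <= g$end_bp, "CIS",
         ifelse(abs(sp - g$midpoint_bp) > cis_max_bp, "TRANS", "CIS")))
  eqtls$class <- cls
  eqtls
}

#' Derive the cis distance threshold from within-gene associations
#'
#' The maximum distance between a within-gene (rule 2) eQTL and the midpoint
#' of the gene it targets; on the motivating dataset this estimate was 12 kb.
#'
#' @inheritParams classify_associations
#' @return distance in bp.
#' @export
derive_cis_threshold <- function(eqtls, snp_meta, ann) {
  si <- match(eqtls$snp_id, snp_meta$snp_id)
  gi <- match(eqtls$transcript_id, ann$genes$gene_id)
  g <- ann$genes[gi, ]
  sp <- snp_meta$pos_bp[si]
  within <- snp_meta$chrom[si] == g$chrom & sp >= g$start_bp & sp <= g$end_bp
  if (!any(within))
    stop("no within-gene association found; supply cis_max_bp explicitly")
  max(abs(sp[within] - g$midpoint_bp[within]))
}

#' Build predictor categories from classified associations
#'
#' Association-level labels for SNPs (CIS_EQTL / TRANS_EQTL), NOT_EQTL for
#' the remaining SNPs, and transcript labels CIS_REGULATED / TRANS_REGULATED
#' (at least one association of that class) or NO_EQTL. With `window_bp > 0`
#' every SNP within that distance of a labelled SNP (same chromosome)
#' inherits one association-level label per (labelled SNP, class) pair it
#' sits next to -- a SNP near both a CIS and a TRANS top SNP carries both
#' labels (multi-label contract).
#'
#' @param eqtls classified associations (output of
#'   [classify_associations()]).
#' @param snp_meta data.frame(snp_id, chrom, pos_bp) for all SNPs.
#' @param transcript_ids all transcript ids in the expression matrix.
#' @param window_bp window half-width around detected SNPs; 0 reproduces the
#'   base labelling exactly.
#' @return list of class `feature_categories`: `snp_assoc`
#'   (data.frame snp_id, class; association-level, window-extended),
#'   `not_eqtl_snps`, `transcript_class` (named vector over
#'   `transcript_ids`), `window_bp`.
#' @export
categorize_features <- function(eqtls, snp_meta, transcript_ids,
                                window_bp = 0) {
  stopifnot(window_bp >= 0, !is.null(eqtls$class))
  assoc <- data.frame(snp_id = eqtls$snp_id, class = eqtls$class,
                      stringsAsFactors = FALSE)
  if (window_bp > 0 && nrow(assoc)) {
    top <- unique(assoc[c("snp_id", "class")])
    ti <- match(top$snp_id, snp_meta$snp_id)
    extra <- vector("list", nrow(top))
    for (i in seq_len(nrow(top))) {
      near <- snp_meta$chrom == snp_meta$chrom[ti[i]] &
        abs(snp_meta$pos_bp - snp_meta$pos_bp[ti[i]]) <= window_bp &
        snp_meta$snp_id != top$snp_id[i]
      if (any(near))
        extra[[i]] <- data.frame(snp_id = snp_meta$snp_id[near],
                                 class = top$class[i],
                                 stringsAsFactors = FALSE)
    }
    extra <- do.call(rbind, extra)
    if (!is.null(extra)) {
      # one inherited label per (neighbour SNP, class); base association
      # multiplicities are preserved untouched
      extra <- extra[!duplicated(extra), ]
      assoc <- rbind(assoc, extra)
    }
  }
  labelled <- unique(assoc$snp_id)
  tcls <- rep("NO_EQTL", length(transcript_ids))
  names(tcls) <- transcript_ids
  cis_t <- unique(eqtls$transcript_id[eqtls$class == "CIS"])
  trans_t <- unique(eqtls$transcript_id[eqtls$class == "TRANS"])
  structure(list(
    snp_assoc = data.frame(
      snp_id = assoc$snp_id,
      class = paste0(assoc$class, "_EQTL"), stringsAsFactors = FALSE),
    not_eqtl_snps = setdiff(snp_meta$snp_id, labelled),
    transcript_class = list(
      CIS_REGULATED = intersect(transcript_ids, cis_t),
      TRANS_REGULATED = intersect(transcript_ids, trans_t),
      NO_EQTL = setdiff(transcript_ids, union(cis_t, trans_t))),
    window_bp = window_bp), class = "feature_categories")
}
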