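# The rank-change statistic: within-class ranks of squared ridge effects,
# the per-category mean rank change between the concatenated and the
# single-omic model, and its cross-trait regression against integration
# advantage. Ranks run 1 (smallest squared effect) to omega (largest), so a
# negative mean change reads as a loss of importance after integration.

#' Rank squared effects within a predictor class
#'
#' Ascending ranks of squared effects (1 = least important, omega = most
#' important), average ranks on ties, computed within one class (SNPs among
#' the p SNPs, transcripts among the q transcripts) so the rank scale is
#' identical across the single- and multi-omic models. Invariant to sign
#' flips of the effects.
#'
#' @param effects named numeric vector of effects for one class.
#' @return named rank vector over the same features.
#' @export
rank_squared <- function(effects) {
  if (length(effects) == 0) stop("empty predictor class")
  if (any(!is.finite(effects))) stop("effects must be finite")
  rank(effects^2, ties.method = "average")
}

#' Mean rank change over a category (the rank-change statistic)
#'
#' Arithmetic mean over `members` of (rank in the multi-omic model - rank in
#' the single-omic model). Membership is association-level by default: a
#' SNP carrying k same-class associations appears k times in `members` and
#' contributes k times. Over a full tie-free class the changes sum to zero
#' (both rank vectors are permutations of the same set), which is exactly
#' why category subsets carry signal.
#'
#' @param ranks_multi,ranks_single rank vectors from [rank_squared()] over
#'   the same class.
#' @param members character vector of feature names (repeats allowed);
#'   must be non-empty.
#' @return list: `delta` (mean change), `var` (variance of per-member
#'   changes), `n` (number of members).
#' @export
delta_rank <- function(ranks_multi, ranks_single, members) {
  if (length(members) == 0) stop("empty member set")
  if (!all(members %in% names(ranks_multi)) ||
      !all(members %in% names(ranks_single)))
    stop("members must belong to the ranked class")
  d <- ranks_multi[members] - ranks_single[members]
  list(delta = mean(d), var = if (length(d) > 1) stats::var(d) else NA_real_,
       n = length(d))
}

#' Cross-trait regression of rank change against integration advantage
#'
#' Pearson correlation (two-sided p from the t transform) and least-squares
#' line between the per-trait mean rank change of a category and the
#' per-trait advantage of the concatenated model over its single-omic
#' counterpart.
#'
#' @param deltas,advantages equal-length per-trait vectors (n >= 3, both
#'   non-constant).
#' @return list: r, p, slope, intercept, n.
#' @export
regress_delta_vs_advantage <- function(deltas, advantages) {
  if (length(deltas) != length(advantages)) stop("length mismatch")
  ok <- is.finite(deltas) & is.finite(advantages)
  x <- deltas[ok]; y <- advantages[ok]
  if (length(x) < 3) stop("need at least 3 traits")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  sl <- ct$estimate * stats::sd(y) / stats::sd(x)
  list(r = unname(ct$estimate), p = ct$p.value, slope = unname(sl),
       intercept = mean(y) - unname(sl) * mean(x), n = length(x))
}

#' Per-trait, per-category rank-change summary
#'
#' Computes the rank-change statistic for the six predictor categories of
#' one trait, given the effect vectors of the three models. SNP categories
#' use association-level membership; transcript categories feature-level.
#' Categories with no members are absent from the result, not zero.
#'
#' @param effects_g,effects_t,effects_gt named effect vectors from the G, T
#'   and G+T fits (G+T names must contain all G and T names).
#' @param cats a `feature_categories` object.
#' @param dedup_snps collapse repeated same-class SNP associations to one
#'   membership each (feature-level alternative; default FALSE).
#' @return data.frame(category, delta, var, n).
#' @export
rank_change_summary <- function(effects_g, effects_t, effects_gt, cats,
                                dedup_snps = FALSE) {
  snps <- names(effects_g); trs <- names(effects_t)
  rk_g <- rank_squared(effects_g)
  rk_t <- rank_squared(effects_t)
  rk_gt_snp <- rank_squared(effects_gt[snps])
  rk_gt_tr <- rank_squared(effects_gt[trs])
  rows <- list()
  add <- function(category, d) {
    rows[[length(rows) + 1]] <<- data.frame(
      category = category, delta = d$delta, var = d$var, n = d$n,
      stringsAsFactors = FALSE)
  }
  for (cl in c("CIS_EQTL", "TRANS_EQTL")) {
    mem <- cats$snp_assoc$snp_id[cats$snp_assoc$class == cl]
    if (dedup_snps) mem <- unique(mem)
    mem <- mem[mem %in% snps]
    if (length(mem)) add(cl, delta_rank(rk_gt_snp, rk_g, mem))
  }
  if (length(cats$not_eqtl_snps)) {
    mem <- intersect(cats$not_eqtl_snps, snps)
    if (length(mem)) add("NOT_EQTL", delta_rank(rk_gt_snp, rk_g, mem))
  }
  for (cl in c("CIS_REGULATED", "TRANS_REGULATED", "NO_EQTL")) {
    mem <- intersect(cats$transcript_class[[cl]], trs)
    if (length(mem)) add(cl, delta_rank(rk_gt_tr, rk_t, mem))
  }
  do.call(rbind, rows)
}

#' Window-robustness scan of the cross-trait regressions
#'
#' Re-derives the predictor categories for windows of increasing size around
#' the detected SNPs, recomputes the per-trait rank changes and re-runs the
#' regression against advantage, returning the correlation trajectory per
#' category. The window-0 entry equals the base analysis exactly. Categories
#' that empty out at a window (e.g. NOT_EQTL once windows engulf every SNP)
#' are dropped from that window with a warning.
#'
#' @param eqtls classified association table.
#' @param snp_meta,transcript_ids passed to [categorize_features()].
#' @param effects_by_trait named list, one element per trait: list with
#'   `g`, `t`, `gt` effect vectors.
#' @param advantages_g,advantages_t per-trait advantage vectors (G+T minus
#'   G, and G+T minus T), aligned to `effects_by_trait`.
#' @param windows ascending window sizes in bp (0 allowed).
#' @param dedup_snps see [rank_change_summary()].
#' @return data.frame(window_bp, category, r, p, slope, n_traits).
#' @export
window_scan <- function(eqtls, snp_meta, transcript_ids, effects_by_trait,
                        advantages_g, advantages_t,
                        windows = c(0, 500, 5000, 25000),
                        dedup_snps = FALSE) {
  stopifnot(!is.unsorted(windows))
  snp_cats <- c("CIS_EQTL", "TRANS_EQTL", "NOT_EQTL")
  out <- list()
  for (w in windows) {
    cats <- categorize_features(eqtls, snp_meta, transcript_ids, window_bp = w)
    per_trait <- lapply(effects_by_trait, function(ef)
      rank_change_summary(ef$g, ef$t, ef$gt, cats, dedup_snps))
    all_cats <- unique(unlist(lapply(per_trait, function(x) x$category)))
    for (cl in all_cats) {
      d <- vapply(per_trait, function(x) {
        i <- match(cl, x$category)
        if (is.na(i)) NA_real_ else x$delta[i]
      }, numeric(1))
      adv <- if (cl %in% snp_cats) advantages_g else advantages_t
      ok <- is.finite(d)
      if (sum(ok) < 3) {
        warning("category ", cl, " dropped at window ", w, ": too few traits")
        next
      }
      reg <- regress_delta_vs_advantage(d[ok], adv[ok])
      out[[length(out) + 1]] <- data.frame(
        window_bp = w, category = cl, r = reg$r, p = reg$p,
        slope = reg$slope, n_traits = reg$n, stringsAsFactors = FALSE)
    }
    missing_cats <- setdiff(c(snp_cats, "CIS_REGULATED", "TRANS_REGULATED",
                              "NO_EQTL"), all_cats)
    if (length(missing_cats))
      warning("categories empty at window ", w, ": ",
              paste(missing_cats, collapse = ", "))
  }
  do.call(rbind, out)
}
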