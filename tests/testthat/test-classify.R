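toy_ann <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    start_bp = c(5000L, 100000L, 2000L),
    end_bp = c(7000L, 160000L, 4000L),
    stringsAsFactors = FALSE)
  genes$midpoint_bp <- (genes$start_bp + genes$end_bp) %/% 2L
  structure(list(chromosomes = data.frame(chrom = c("chr1", "chr2"),
                                          length_bp = 5e5,
                                          stringsAsFactors = FALSE),
                 genes = genes), class = "genome_annotation")
}

toy_snps <- function() data.frame(
  snp_id = c("s1", "s2", "s3", "s4", "s5"),
  chrom = c("chr1", "chr1", "chr1", "chr1", "chr1"),
  pos_bp = c(1000L, 5500L, 95000L, 125000L, 5800L),
  stringsAsFactors = FALSE)

test_that("the three positional rules classify as stated", {
  ann <- toy_ann(); snps <- toy_snps()
  eq <- data.frame(
    transcript_id = c("gC", "gA", "gB", "gB"),
    snp_id = c("s1", "s2", "s3", "s4"),
    stringsAsFactors = FALSE)
  got <- classify_associations(eq, snps, ann, cis_max_bp = 12000)
  # s1 -> gC: different chromosome -> TRANS
  # s2 inside gA's span -> CIS
  # s3 -> gB: outside the span, |95000 - 130000| = 35 kb > 12 kb -> TRANS
  # s4 -> gB: inside gB's span -> CIS (rule 2)
  expect_equal(got$class, c("TRANS", "CIS", "TRANS", "CIS"))
  # order invariance: permuting rows permutes labels identically
  got2 <- classify_associations(eq[4:1, ], snps, ann, cis_max_bp = 12000)
  expect_equal(got2$class, rev(got$class))
  expect_error(classify_associations(
    data.frame(transcript_id = "nope", snp_id = "s1"), snps, ann), "unknown")
})

test_that("the cis threshold equals the hand-computed maximum distance", {
  ann <- toy_ann(); snps <- toy_snps()
  eq <- data.frame(
    transcript_id = c("gA", "gA", "gB", "gB"),
    snp_id = c("s2", "s5", "s3", "s4"),
    stringsAsFactors = FALSE)
  # within-gene associations and midpoint distances: s2 in gA
  # (|5500-6000| = 500), s5 in gA (|5800-6000| = 200), s4 in gB
  # (|125000-130000| = 5000); s3 is outside every span and does not count
  expect_equal(derive_cis_threshold(eq, snps, ann), 5000)
  eq_none <- data.frame(transcript_id = "gC", snp_id = "s1",
                        stringsAsFactors = FALSE)
  expect_error(derive_cis_threshold(eq_none, snps, ann), "cis_max_bp")
})

test_that("feature categories conserve counts and extend through windows", {
  ann <- toy_ann(); snps <- toy_snps()
  eq <- classify_associations(
    data.frame(transcript_id = c("gC", "gA", "gB"),
               snp_id = c("s1", "s2", "s3"), stringsAsFactors = FALSE),
    snps, ann, 12000)
  transcripts <- c("gA", "gB", "gC")
  base <- categorize_features(eq, snps, transcripts, window_bp = 0)
  expect_equal(nrow(base$snp_assoc), 3)  # association-level conservation
  expect_setequal(base$not_eqtl_snps, c("s4", "s5"))
  expect_setequal(base$transcript_class$CIS_REGULATED, "gA")
  expect_setequal(base$transcript_class$TRANS_REGULATED, c("gB", "gC"))
  expect_length(base$transcript_class$NO_EQTL, 0)
  # s5 at 5800 sits 300 bp from the CIS SNP s2 (5500): window 500 captures
  # it, window 100 does not
  w500 <- categorize_features(eq, snps, transcripts, window_bp = 500)
  expect_true(any(w500$snp_assoc$snp_id == "s5" &
                    w500$snp_assoc$class == "CIS_EQTL"))
  expect_false("s5" %in% w500$not_eqtl_snps)
  w100 <- categorize_features(eq, snps, transcripts, window_bp = 100)
  expect_false("s5" %in% w100$snp_assoc$snp_id)
  expect_true("s5" %in% w100$not_eqtl_snps)
  # window 0 is exactly the base labelling
  expect_identical(base$snp_assoc,
                   categorize_features(eq, snps, transcripts, 0)$snp_assoc)
})
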