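test_that("F_ROH hand arithmetic and the length-class identity", {
  summ <- roh_sample_summary(
    data.frame(sample_id = "a", chrom = c("1", "2"),
               start_bp = c(1, 1), end_bp = c(2.5e6 + 1, 1.6e6 + 1),
               n_snps = c(100L, 80L), length_bp = c(2.5e6, 1.6e6)),
    c("a", "b"))
  fr <- f_roh(summ, 3e9)
  expect_equal(fr$f_roh[1], 4.1e6 / 3e9)
  expect_equal(fr$f_roh_lt5[1], 4.1e6 / 3e9)
  expect_equal(fr$f_roh_gt5[1], 0)
  expect_equal(fr[fr$sample_id == "b", -1], data.frame(f_roh = 0,
               f_roh_lt5 = 0, f_roh_gt5 = 0, row.names = 2L))
  # one 6 Mb segment: all in the long class
  summ2 <- roh_sample_summary(
    data.frame(sample_id = "a", chrom = "1", start_bp = 1, end_bp = 6e6 + 1,
               n_snps = 200L, length_bp = 6e6), "a")
  fr2 <- f_roh(summ2, 3e9)
  expect_equal(fr2$f_roh, 0.002)
  expect_equal(fr2$f_roh_gt5, 0.002)
  expect_equal(fr2$f_roh_lt5, 0)
  expect_equal(fr2$f_roh, fr2$f_roh_lt5 + fr2$f_roh_gt5)
  expect_error(f_roh(summ, 0), "positive")
})

test_that("F_SNP matches hand arithmetic and is null under random mating", {
  # 3 SNPs at p = 0.5: E(HOM) = 1.5 per sample
  g <- toy_geno(rbind(c(2L, 2L, 0L),    # all homozygous -> (3-1.5)/1.5 = 1
                      c(1L, 1L, 1L),    # all het -> (0-1.5)/1.5 = -1
                      c(0L, 1L, 2L),
                      c(1L, 0L, 1L)))
  stopifnot(all(allele_frequencies(g)$p == 0.5))
  fs <- f_snp(g)
  expect_equal(fs$f_snp[1], 1)
  expect_equal(fs$f_snp[2], -1)
  # random mating: mean F_SNP ~ 0
  set.seed(5)
  p <- stats::runif(400, 0.1, 0.9)
  gr <- toy_geno(hwe_genotypes(300, p))
  expect_lt(abs(mean(f_snp(gr)$f_snp)), 0.01)
})

test_that("F_SNP outside ROH follows the restricted formula", {
  # 10 SNPs at p = 0.5; 4 inside a ROH (all hom), 4 of the 6 outside hom
  pos <- 1:10 * 1e5
  x <- c(2L, 2L, 2L, 2L, 2L, 2L, 0L, 0L, 1L, 1L)
  # rows 2-3 balance frequencies to p = 0.5 at every SNP
  bal <- rbind(c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
               c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 1L, 1L))
  calls <- rbind(x, bal)
  rownames(calls) <- NULL
  g <- toy_geno(calls, pos = pos)
  p <- allele_frequencies(g)
  stopifnot(all(p$p == 0.5))
  seg <- data.frame(sample_id = g$samples$sample_id[1], chrom = "1",
                    start_bp = 1e5, end_bp = 4e5, n_snps = 4L,
                    length_bp = 3e5)
  fo <- f_snp_outside_roh(g, seg, p)
  # O' = 8 - 4 = 4, N' = 6, E' = (6/10) * 5 = 3 -> (4-3)/(6-3) = 1/3
  expect_equal(fo$f_snp_outside_roh[1], 1 / 3)
  # no ROH: reduces exactly to F_SNP
  none <- seg[0, ]
  expect_equal(f_snp_outside_roh(g, none, p)$f_snp_outside_roh,
               f_snp(g, p)$f_snp)
  # all SNPs inside ROH: undefined, flagged NA
  all_seg <- data.frame(sample_id = g$samples$sample_id[1], chrom = "1",
                        start_bp = 1, end_bp = 1e6 + 1, n_snps = 10L,
                        length_bp = 1e6)
  expect_true(is.na(f_snp_outside_roh(g, all_seg, p)$f_snp_outside_roh[1]))
})

test_that("F_GRM matches the single-SNP closed forms", {
  g <- toy_geno(rbind(2L, 1L, 0L))
  stopifnot(allele_frequencies(g)$p == 0.5)
  fg <- f_grm(g)
  # (x^2 - (1+2p) x + 2 p^2) / (2 p q) at p = 0.5
  expect_equal(fg$f_grm, c((4 - 2 * 2 + 0.5) / 0.5,
                           (1 - 2 + 0.5) / 0.5,
                           (0 - 0 + 0.5) / 0.5))
  expect_equal(fg$f_grm[1], 1)
  expect_equal(fg$f_grm[2], -1)
  set.seed(6)
  gr <- toy_geno(hwe_genotypes(300, stats::runif(400, 0.1, 0.9)))
  expect_lt(abs(mean(f_grm(gr)$f_grm)), 0.01)
  expect_error(f_grm(toy_geno(matrix(2L, 3, 2))), "polymorphic")
})

test_that("estimators are invariant to which allele is counted", {
  set.seed(9)
  calls <- hwe_genotypes(60, stats::runif(300, 0.1, 0.9))
  calls[sample(length(calls), 200)] <- NA
  g <- toy_geno(calls)
  swapped <- toy_geno(2L - calls)
  seg <- data.frame(sample_id = g$samples$sample_id[1:3], chrom = "1",
                    start_bp = c(1, 5e4, 1e5), end_bp = c(6e4, 1.5e5, 2e5),
                    n_snps = 10L, length_bp = 6e4)
  expect_equal(f_snp(g)$f_snp, f_snp(swapped)$f_snp)
  expect_equal(f_grm(g)$f_grm, f_grm(swapped)$f_grm)
  expect_equal(f_snp_outside_roh(g, seg)$f_snp_outside_roh,
               f_snp_outside_roh(swapped, seg)$f_snp_outside_roh)
})

test_that("the length-class identity is exact and the outside-ROH
           difference approximation holds on cohort data", {
  b <- small_roh_cohort(seed = 17, snps_per_chr = 2500, n_chr = 5,
                        matings = c(unrelated = 6, first_cousin = 18,
                                    full_sib = 6))
  seg <- call_roh(b$genotypes)
  prof <- inbreeding_profile(b$genotypes, seg, b$gmap$genome_size_bp)
  expect_equal(prof$f_roh, prof$f_roh_lt5 + prof$f_roh_gt5)
  gap <- abs(prof$f_snp_outside_roh - (prof$f_snp - prof$f_roh))
  expect_lt(stats::median(gap, na.rm = TRUE), 0.02)
  expect_lt(max(gap, na.rm = TRUE), 0.06)
})

test_that("MAF-binned excess homozygosity restricts the F_SNP formula", {
  set.seed(10)
  p <- stats::runif(500, 0.06, 0.94)
  g <- toy_geno(hwe_genotypes(80, p))
  whole <- excess_homozygosity_by_maf(g, c(0, 0.5))
  expect_length(whole, 1)
  expect_equal(whole[[1]]$f_maf, f_snp(g)$f_snp)
  binned <- excess_homozygosity_by_maf(g, c(0, 0.1, 0.3, 0.5))
  expect_length(binned, 3)
  mono <- toy_geno(cbind(matrix(2L, 10, 3), hwe_genotypes(10, 0.4)))
  res <- excess_homozygosity_by_maf(mono, c(0, 0.01))
  expect_true(all(is.na(res[[1]]$f_maf)))
  expect_match(attr(res[[1]], "flagged"), "monomorphic")
})

test_that("cohort census separates consanguinity from the Wahlund pattern", {
  # consanguineous regime: mean F_ROH ~ F_IS
  b <- small_roh_cohort(seed = 23, snps_per_chr = 2500, n_chr = 5,
                        matings = c(first_cousin = 30))
  seg <- call_roh(b$genotypes)
  prof <- inbreeding_profile(b$genotypes, seg, b$gmap$genome_size_bp)
  cs <- cohort_f_summary(prof)
  expect_equal(cs$mean_f_roh, cs$f_is, tolerance = 0.35)
  expect_gt(cs$f_is, 0.02)
  # random mating: F_IS ~ 0
  set.seed(11)
  gr <- toy_geno(hwe_genotypes(200, stats::runif(500, 0.1, 0.9)))
  profr <- inbreeding_profile(gr, call_roh(gr)[0, ], 3e9)
  expect_lt(abs(cohort_f_summary(profr)$f_is), 0.02)
  # admixed two-subpopulation cohort: excess SNP homozygosity (Wahlund)
  # without elevated F_ROH
  nv <- 500
  p1 <- stats::runif(nv, 0.1, 0.9)
  p2 <- pmin(pmax(p1 + sample(c(-1, 1), nv, TRUE) * 0.35, 0.02), 0.98)
  gw <- toy_geno(rbind(hwe_genotypes(100, p1), hwe_genotypes(100, p2)))
  profw <- inbreeding_profile(gw, call_roh(gw)[0, ], 3e9)
  csw <- cohort_f_summary(profw)
  expect_gt(csw$f_is, 0.05)
  expect_equal(csw$mean_f_roh, 0)
})
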