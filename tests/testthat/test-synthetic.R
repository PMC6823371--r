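test_that("founder pools honour the requested frequency spectrum", {
  gmap <- genetic_map(n_chr = 1, chr_length_bp = 1e6)
  map <- random_variant_map(gmap, snps_per_chr = 200)
  fo <- simulate_founders(300, map, list(dist = "fixed", p = 0.5), seed = 3)
  expect_equal(mean(fo$haps), 0.5, tolerance = 0.02)
  # minimal pool: 2 founders, 1 SNP -> 4 labelled haplotype alleles
  map1 <- map[1, , drop = FALSE]
  fo2 <- simulate_founders(2, map1, seed = 4)
  expect_equal(dim(fo2$haps), c(4L, 1L))
  # empirical allele frequencies track the sampled per-SNP frequencies
  fo3 <- simulate_founders(500, map,
                           list(dist = "beta", shape1 = 0.5, shape2 = 0.5,
                                min = 0.02, max = 0.98), seed = 5)
  emp <- colMeans(fo3$haps)
  expect_gt(stats::cor(emp, fo3$freq), 0.98)
  expect_lt(max(abs(emp - fo3$freq)), 0.12)
  expect_error(simulate_founders(10, map, list(dist = "fixed", p = 0),
                                 seed = 1),
               "degenerate")
})

test_that("gene-dropping matches pedigree autozygosity expectations", {
  gmap <- genetic_map(n_chr = 12, chr_length_bp = 5e7)
  map <- random_variant_map(gmap, snps_per_chr = 10)
  types <- c(unrelated = 0, second_cousin = 1 / 64, first_cousin = 1 / 16,
             avuncular = 1 / 8, full_sib = 1 / 4, parent_offspring = 1 / 4)
  n_fam <- 60
  for (ty in names(types)) {
    des <- pedigree_design(stats::setNames(n_fam, ty))
    fo <- simulate_founders(6 * n_fam, map, seed = 11)
    gd <- gene_drop(des, fo, gmap, seed = match(ty, names(types)) * 13L)
    ft <- true_autozygosity(gd$truth, gmap$genome_size_bp,
                            gd$samples$sample_id)
    if (ty == "unrelated") {
      expect_equal(nrow(gd$truth), 0L)
      expect_true(all(ft == 0))
    } else {
      se <- stats::sd(ft) / sqrt(length(ft))
      expect_lt(abs(mean(ft) - types[[ty]]), 3 * se + 1e-12)
    }
  }
})

test_that("IBD truth segments are valid and autozygosity is bounded", {
  gmap <- genetic_map(n_chr = 6, chr_length_bp = 4e7)
  map <- random_variant_map(gmap, snps_per_chr = 10)
  des <- pedigree_design(c(full_sib = 25))
  fo <- simulate_founders(50, map, seed = 2)
  gd <- gene_drop(des, fo, gmap, seed = 6)
  tr <- gd$truth
  expect_true(all(tr$end_bp >= tr$start_bp))
  expect_true(all(tr$start_bp >= 1))
  expect_true(all(tr$end_bp <= 4e7))
  # non-overlap within sample x chromosome
  by_sc <- split(tr, paste(tr$sample_id, tr$chrom))
  for (s in by_sc) {
    s <- s[order(s$start_bp), ]
    if (nrow(s) > 1)
      expect_true(all(s$start_bp[-1] > s$end_bp[-nrow(s)]))
  }
  ft <- true_autozygosity(tr, gmap$genome_size_bp, gd$samples$sample_id)
  expect_true(all(ft >= 0 & ft <= 1))
  # offspring genotypes are homozygous at every SNP inside a true segment
  g <- gd$genotypes
  for (k in sample(nrow(tr), 20)) {
    i <- match(tr$sample_id[k], g$samples$sample_id)
    j <- which(g$map$chrom == tr$chrom[k] &
                 g$map$pos_bp >= tr$start_bp[k] &
                 g$map$pos_bp <= tr$end_bp[k])
    if (length(j))
      expect_true(all(g$calls[i, j] %in% c(0L, 2L)))
  }
})

test_that("true_autozygosity does hand arithmetic and handles bounds", {
  tr <- data.frame(sample_id = "s1", chrom = "1", start_bp = 1,
                   end_bp = 3e7)
  expect_equal(unname(true_autozygosity(tr, 3e9)), 0.01)
  empty <- tr[0, ]
  expect_equal(unname(true_autozygosity(empty, 3e9, "s1")), 0)
  whole <- data.frame(sample_id = "s1", chrom = as.character(1:2),
                      start_bp = c(1, 1), end_bp = c(5e7, 5e7))
  expect_equal(unname(true_autozygosity(whole, 1e8)), 1)
  expect_error(true_autozygosity(tr, 0), "genome_size_bp")
})

test_that("trait simulation recovers the configured load and logit effect", {
  # no genetics, no noise -> constant intercept
  g0 <- toy_geno(hwe_genotypes(20, rep(0.5, 5)))
  m0 <- trait_model(intercept = 3, resid_sd = 0, covariates = c())
  ph0 <- simulate_traits(g0, m0, seed = 1)
  expect_equal(ph0$y, rep(3, 20))
  # recessive load B: slope of trait on true autozygosity ~ -B
  b <- small_roh_cohort(seed = 99, snps_per_chr = 50, n_chr = 12,
                        matings = c(unrelated = 60, first_cousin = 120,
                                    full_sib = 60),
                        load_b = 16, resid_sd = 0.5,
                        covariate_effects = c())
  expect_equal(b$load_b, 16)
  fit <- stats::lm(b$phenotypes$y ~ b$f_true)
  ci <- stats::confint(fit)[2, ]
  expect_gt(-16, ci[1])
  expect_lt(-16, ci[2])
  # binary: configured OR at F = 0.0625 is recovered by logistic fit
  n <- 6000
  f <- stats::runif(n, 0, 0.25)
  gb <- toy_geno(matrix(2L, n, 1))
  names(f) <- gb$samples$sample_id
  mb <- trait_model(covariates = c(),
                    binary = list(base_prev = 0.5,
                                  lnor_per_f = log(0.65) / 0.0625))
  ph <- simulate_traits(gb, mb, seed = 8, f_true = f)
  est <- fit_binary(ph$y, f, method = "logit")
  expect_equal(unname(est$or_0.0625), 0.65, tolerance = 0.08)
})

test_that("cohort simulation is deterministic and exposes heterogeneity", {
  cfg <- cohort_config(matings = c(unrelated = 6, first_cousin = 10),
                       snps_per_chr = 60, n_chr = 4, n_causal = 40)
  b1 <- simulate_cohort(cfg, seed = 5)
  b2 <- simulate_cohort(cfg, seed = 5)
  expect_identical(b1$genotypes$calls, b2$genotypes$calls)
  expect_identical(b1$phenotypes, b2$phenotypes)
  expect_identical(b1$truth, b2$truth)
  # causal loci are hidden from the emitted array
  expect_false(any(grepl("^causal_", b1$genotypes$map$id)))
  expect_true(all(grepl("^causal_", b1$causal_genotypes$map$id)))
  # cohorts designed around different unions differ in mean F
  b3 <- simulate_cohort(cohort_config(matings = c(full_sib = 16),
                                      snps_per_chr = 60, n_chr = 4,
                                      n_causal = 40), seed = 5)
  expect_gt(mean(b3$f_true), mean(b1$f_true) + 0.05)
})

test_that("confounder correlates with consanguinity as configured and is
           constant within sibships", {
  cfg <- cohort_config(matings = c(unrelated = 25, first_cousin = 25,
                                   full_sib = 25),
                       sibs_per_family = 2, snps_per_chr = 40, n_chr = 4,
                       n_causal = 20,
                       confounder = list(sd = 1, effect = 2, cor = 0.8))
  b <- simulate_cohort(cfg, seed = 21)
  ph <- b$phenotypes
  # constant within family (siblings share parents, hence the confounder)
  spread <- tapply(ph$confounder, ph$family_id, function(z) diff(range(z)))
  expect_true(all(spread == 0))
  fam <- !duplicated(ph$family_id)
  r <- stats::cor(ph$confounder[fam], b$samples$expected_f[fam])
  expect_equal(r, 0.8, tolerance = 0.15)
  # cor = 0 leaves the confounder independent of mating type
  cfg0 <- cfg
  cfg0$confounder$cor <- 0
  b0 <- simulate_cohort(cfg0, seed = 22)
  fam0 <- !duplicated(b0$phenotypes$family_id)
  r0 <- stats::cor(b0$phenotypes$confounder[fam0],
                   b0$samples$expected_f[fam0])
  expect_lt(abs(r0), 0.25)
  # within sibships true autozygosity varies while the confounder cannot
  f_by_fam <- tapply(b$f_true[match(ph$sample_id, names(b$f_true))],
                     ph$family_id, function(z) diff(range(z)))
  consang <- tapply(b$samples$expected_f, b$samples$family_id, max) > 0
  expect_gt(mean(f_by_fam[consang] > 0), 0.7)
})
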