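#!/usr/bin/env Rscript
# Stage 1: simulate three cohorts with contrasting consanguinity regimes
# and a shared rare-recessive trait architecture (inbreeding load B = 16
# trait units), on a downscaled genome of 8 x 50 Mb.
#
# Genotypes (PLINK bed/bim/fam), phenotypes and IBD truth go to
# scratch/cohorts/ (large, regenerable); a small design summary goes to
# results/.

library(autozyg)

out_dir <- "scratch/cohorts"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cohorts <- list(
  # consanguineous cohort: many first-cousin and closer unions
  consang = cohort_config(
    matings = c(unrelated = 20, second_cousin = 20, first_cousin = 60,
                avuncular = 20, full_sib = 10),
    sibs_per_family = 2, n_chr = 8, snps_per_chr = 2200, load_b = 16),
  # cosmopolitan cohort: mostly outbred, a few distant unions
  cosmo = cohort_config(
    matings = c(unrelated = 90, second_cousin = 30, first_cousin = 20),
    sibs_per_family = 2, n_chr = 8, snps_per_chr = 2200, load_b = 16),
  # consanguineous cohort with a social confounder tracking parental
  # relatedness (tests the within-sibling design downstream)
  confounded = cohort_config(
    matings = c(unrelated = 30, second_cousin = 20, first_cousin = 50,
                avuncular = 20, full_sib = 10),
    sibs_per_family = 2, n_chr = 8, snps_per_chr = 2200, load_b = 16,
    confounder = list(sd = 1, effect = 4, cor = 0.9))
)

summary_rows <- list()
for (nm in names(cohorts)) {
  seed <- 1000L + match(nm, names(cohorts))
  b <- simulate_cohort(cohorts[[nm]], seed = seed)
  prefix <- file.path(out_dir, nm)
  write_genotypes(b$genotypes, prefix, dialect = "bed")
  write.table(b$phenotypes, paste0(prefix, "_phenotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(b$truth, paste0(prefix, "_ibd_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("genome_size_bp\t%g", b$gmap$genome_size_bp),
               sprintf("seed\t%d", seed),
               sprintf("load_b\t%g", b$load_b)),
             paste0(prefix, "_meta.tsv"))
  summary_rows[[nm]] <- data.frame(
    cohort = nm, n = n_samples(b$genotypes),
    snps = n_variants(b$genotypes),
    mean_f_true = mean(b$f_true), load_b = b$load_b, seed = seed)
  cat(sprintf("%-10s n = %3d, mean true autozygosity = %.4f\n",
              nm, n_samples(b$genotypes), mean(b$f_true)))
}
des <- do.call(rbind, summary_rows)
write.table(des, "results/cohort_design.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nThe three cohorts span the autozygosity range of real consortium\n")
cat("cohorts: the consanguineous designs average ~6-8% of the genome\n")
cat("autozygous, the cosmopolitan one several-fold less.\n")
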