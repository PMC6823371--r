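#!/usr/bin/env Rscript
# Stage 3: per-cohort effect estimation. For each cohort: residualize the
# trait on age/sex, then fit every model class — univariate regressions
# on F_ROH / F_SNP / F_GRM, the ROH-length-partitioned model, the
# bivariate F_ROH + F_GRM model, sex-specific fits, the within-sibling
# estimator, and the ten-bin intercept-referenced trait means.
#
# One results file per cohort (the unit that would be returned to the
# central analysts in a consortium), all rows also pooled in stage 4.

library(autozyg)

in_dir <- "scratch/cohorts"
cohort_names <- c("consang", "cosmo", "confounded")
dir.create("results", showWarnings = FALSE)

all_results <- list()
for (nm in cohort_names) {
  prefix <- file.path(in_dir, nm)
  g <- read_genotypes(prefix, dialect = "bed")
  phen <- read.table(paste0(prefix, "_phenotypes.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE,
                     colClasses = c(sample_id = "character",
                                    family_id = "character"))
  meta <- read.table(paste0(prefix, "_meta.tsv"), sep = "\t",
                     row.names = 1)
  bundle <- list(genotypes = g, phenotypes = phen,
                 gmap = list(genome_size_bp = meta["genome_size_bp", 1]))
  cr <- run_cohort(bundle, run_config(traits = "y"), cohort_id = nm)
  write_cohort_results(cr, file.path("scratch", paste0(nm, "_effects.tsv")))
  write.table(cr$bins$y, file.path("scratch", paste0(nm, "_bins.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  all_results[[nm]] <- cr
  uni <- cr$results[cr$results$model_tag == "uni_froh", ]
  ws <- cr$results[cr$results$model_tag == "within_sibs", ]
  cat(sprintf("%-10s beta_FROH = %6.2f (se %.2f); within-sibs = %6.2f (se %.2f)\n",
              nm, uni$beta, uni$se,
              if (nrow(ws)) ws$beta else NA, if (nrow(ws)) ws$se else NA))
}
saved <- do.call(rbind, lapply(all_results, `[[`, "results"))
write.table(saved, "results/cohort_effects.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nThe configured inbreeding load is B = 16 trait units. Power is\n")
cat("concentrated in the consanguineous cohorts (as in real consortium\n")
cat("data, where the most homozygous cohorts carry far more information\n")
cat("per sample); the cosmopolitan estimates are accordingly noisy. In\n")
cat("the confounded cohort the population slope is pushed far from -16\n")
cat("while the within-sibling estimate, which only uses Mendelian\n")
cat("segregation within families, is not.\n")
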