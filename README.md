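# autozyg

Tools for quantifying inbreeding depression from SNP-array genotypes —
and for validating every step of that analysis against simulations with
known ground truth.

## The problem

Offspring of related parents carry long genomic segments that are
identical by descent on both haplotypes (autozygous). If the variants
that depress fitness-related traits are rare and recessive — the
dominance hypothesis — trait values should decline linearly with the
autozygous genome fraction, and the signal should ride on runs of
homozygosity (ROH) rather than on the chance homozygosity of common
SNPs. Testing this at scale means calling ROH uniformly across many
cohorts, regressing traits on genomic inbreeding coefficients within
each cohort, and pooling by fixed-effect meta-analysis; confounding by
the social correlates of consanguinity is the central threat, met by a
within-sibling design in which variation in autozygosity comes only
from Mendelian segregation.

`autozyg` implements this chain end to end for researchers in
population and statistical genetics:

* **Simulation with truth** — `simulate_founders()`, `gene_drop()`,
  `simulate_traits()`, `simulate_cohort()`: founder haplotypes dropped
  through consanguineous pedigrees (first-cousin, avuncular, full-sib,
  parent–offspring, …) with Poisson recombination, exact IBD-truth
  segments, a rare-recessive trait architecture with closed-form
  inbreeding load `B = Σ |d| q (1 − q)`, optional social confounder.
* **ROH calling** — `call_roh()`: the standard sliding-window scan
  (50-SNP windows, ≤1 het / ≤5 missing per window, runs ≥50 SNPs,
  ≥1.5 Mb, gap ≤1 Mb, ≥1 SNP / 50 kb), tested for exact equality
  against a brute-force oracle.
* **Inbreeding estimators** — `inbreeding_profile()`: F_ROH (split at
  5 Mb, with the identity F_ROH = F_ROH<5Mb + F_ROH>5Mb exact), excess
  SNP homozygosity F_SNP, its outside-ROH restriction, the
  GRM-diagonal estimator F_GRM, and MAF-binned excess homozygosity.
* **Per-cohort models** — `residualize()` / `grammar_residuals()`
  (REML/BLUP for family structure), `fit_univariate()`,
  `fit_partitioned()`, `fit_bivariate()`, `fit_binary()` (logit and
  scaled-linear ln(OR) routes), `bin_trait_means()` on the ten canonical
  F_ROH bins, `estimate_kinship()` + `select_full_sibs()` +
  `within_sib_effect()` for the confounding-immune design.
* **Meta-analysis** — `ivw_meta()`, `meta_bins()`, `ratio_bootstrap()`:
  fixed-effect inverse-variance pooling and parametric-bootstrap ratio
  summaries.
* **Pipeline** — `run_cohort()` / `run_meta()` execute QC → ROH →
  estimators → all model classes → pooling; PLINK ped/map and
  bed/bim/fam I/O via `read_genotypes()` / `write_genotypes()`.

The `analysis/` directory holds a numbered workflow
(`01_simulate_cohorts.R` … `04_meta_analysis.R`) that runs a three-cohort
study — consanguineous, cosmopolitan, and consanguineous-with-confounder
— writing tables under `results/`.

## Worked example

Simulate a consanguineous cohort (170 offspring of unions spanning
expected autozygosity 0–0.25 on an 8 × 50 Mb genome, inbreeding load
B = 16 trait units carried by 200 hidden rare recessives), then run the
whole per-cohort analysis:

```r
library(autozyg)

b <- simulate_cohort(cohort_config(
  matings = c(unrelated = 20, second_cousin = 10, first_cousin = 40,
              avuncular = 10, full_sib = 5),
  sibs_per_family = 2, n_chr = 8, snps_per_chr = 2200, load_b = 16),
  seed = 11)
b
#> cohort_bundle: 170 offspring, 17600 array SNPs, 340 true IBD segments
#>   mean true autozygosity 0.0614; load B = 16.00

cr <- run_cohort(b, run_config(traits = "y"), cohort_id = "demo")
cr$results[cr$results$model_tag %in%
             c("uni_froh", "partitioned_outside", "partitioned_gt5",
               "within_sibs"), c("model_tag", "beta", "se", "n")]
#>            model_tag   beta    se   n
#>             uni_froh -15.98  2.08 170
#>  partitioned_outside -30.49 18.37 170
#>      partitioned_gt5 -16.35  2.23 170
#>          within_sibs -16.89  3.17 170
```

Reading the output: the trait declines by ~16 units per unit F_ROH —
the configured load (`beta` is per unit F, so the first-cousin-offspring
effect is `0.0625 × beta ≈ −1.0` trait units, reported in the
`beta_0.0625` column). Long-ROH homozygosity carries the full effect
(`partitioned_gt5 ≈ −16`) while SNP homozygosity outside ROH is noisy
and compatible with zero — the rare-recessive signature. The
within-sibling estimate, built only from Mendelian-segregation
differences between 85 sibling pairs, agrees with the population
estimate, which is what rules out household-level confounding.

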