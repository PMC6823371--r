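---
title: "Measuring inbreeding depression with runs of homozygosity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring inbreeding depression with runs of homozygosity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

## The scientific problem

Offspring of related parents inherit stretches of genome that are
identical by descent on both chromosomes (autozygous). If trait-depressing
alleles are rare and recessive, autozygosity exposes them as homozygotes,
and trait values decline linearly with the autozygous genome fraction —
inbreeding depression under the dominance hypothesis. The observable
footprint of autozygosity on a SNP array is a run of homozygosity (ROH):
a long stretch in which every genotyped SNP is homozygous.

`autozyg` implements the full analysis chain used to quantify this
effect from array genotypes: ROH calling, genomic inbreeding
coefficients, per-cohort regression designs (including a within-sibling
design that is immune to social confounding), and fixed-effect
meta-analysis across cohorts. Because individual-level biobank data
cannot be redistributed, the package pairs every stage with a
gene-dropping simulator whose ground truth (IBD segments, trait
architecture) is known exactly, so each stage is verified by parameter
recovery rather than by reference to inaccessible data.

## The generative model behind the simulator

**Pedigrees and recombination.** `simulate_founders()` draws founder
haplotypes site-independently at frequencies sampled from a configurable
spectrum (default: counted-allele frequency uniform on 0.05–0.5, the
post-QC regime of a genotyping array). `gene_drop()` transmits
haplotypes through pedigrees for six union types — unrelated,
second-cousin, first-cousin, avuncular, full-sibling and
parent–offspring matings — whose offspring have expected autozygosity
0, 1/64, 1/16, 1/8, 1/4 and 1/4 (the kinship of the parents). Gametes
receive Poisson crossovers at a uniform 1 cM/Mb with no interference;
a uniform map keeps these expectations analytic. The default genome is
deliberately downscaled (22 chromosomes × 50 Mb; the workflow scripts
use 8 × 50 Mb, and the genome size is always a configuration value, with
3 Gb the value to use for real human data). A smaller genome preserves
every expectation but inflates the between-offspring variance of
realized autozygosity — convenient for testing, but remember that
Monte-Carlo standard errors are wider than they would be genome-wide.

**Traits.** The trait model operationalises directional dominance:
`n_causal` rare loci (deleterious-allele frequency q drawn from
0.005–0.05 by default) each depress the trait by `d < 0` when homozygous.
The inbreeding load is `B = sum |d| q (1 - q)`, and the expected
regression of the trait on true autozygosity is exactly `-B`; the
generator solves `d` from a target `B` (default 16 trait units, chosen so
that desk-scale cohorts of a few hundred samples estimate it with a
standard error of a few units) so recovery tests have a closed-form
truth. Causal loci are excluded from the emitted SNP array by default:
they are rare (below the 5% MAF filter anyway), and hiding them makes
ROH the only path from genotype to trait, mirroring the claimed
mechanism. Binary traits are drawn from a logistic model with a
configured ln(odds ratio) per unit autozygosity. An optional
family-level confounder with chosen correlation to parental kinship and
chosen effect on the trait injects exactly the kind of social
confounding the within-sibling design is meant to remove.

**What the simulator does not emulate.** No linkage disequilibrium among
founders (so ROH can only arise through pedigree IBD — chance ROH from
haplotype structure are absent, making the caller's job slightly easier
than on real data); no selection; no genotyping error; no X chromosome;
no assortative mating. Passing tests therefore demonstrate correctness
of the algorithms and estimators under the stated model, not robustness
to artefacts real arrays can show.

## ROH calling

`call_roh()` reimplements the standard sliding-window scan with the
consortium parameterisation as defaults: 50-SNP windows sliding one SNP
at a time; a window is homozygous if it has at most 1 heterozygous and 5
missing calls; a SNP is ROH-eligible if at least 5% of the fully
contained windows covering it are homozygous; maximal eligible runs are
split at inter-SNP gaps over 1000 kb, trimmed to start and end on a
homozygous non-missing call, and kept if they have ≥ 50 SNPs, span
≥ 1500 kb (inclusive) and average at most 50 kb per SNP. SNPs with MAF
below 5% are removed before scanning and no LD pruning is applied.

Numerical conventions that change borderline calls, fixed here and
asserted in tests:

* segment length is `end_bp - start_bp` (span between first and last
  SNP), matching the reference tool's kb reporting;
* "> 1.5 Mb" is implemented as `length >= 1,500,000`;
* windows are only those fully contained in a chromosome, so SNPs within
  49 SNPs of an end have proportionally fewer containing windows (the
  hit-rate denominator adjusts); chromosomes with fewer SNPs than one
  window are skipped with a warning;
* the window hit threshold (0.05) is not part of the published seven
  parameters; the reference implementation's default is adopted and
  exposed.

The test suite pins the caller to an independent brute-force window-scan
oracle on toy chromosomes (exact equality of all segment sets), so the
semantics above are the package's definition of the algorithm, not an
approximation of someone else's binary. A practical consequence of the
hit-rate rule worth knowing: the first and last couple of SNPs of a long
homozygous stretch sit in too few homozygous windows to qualify, so
calls start a SNP or two inside the true IBD boundary.

## Inbreeding estimators

For each sample the package computes:

* `f_roh` — summed ROH length over the autosomal genome length
  (configurable denominator; 3 Gb for real data), split into `f_roh_lt5`
  and `f_roh_gt5` at 5 Mb (`>= 5 Mb` counts as long). The total is
  formed as the sum of the two classes so the partition identity is
  exact to the last bit.
* `f_snp` — excess homozygosity `(O(HOM) - E(HOM)) / (N - E(HOM))` with
  `E(HOM) = sum(1 - 2pq)` over the sample's non-missing SNPs, in-sample
  allele frequencies including the index individual (as the standard
  implementation does; the resulting O(1/n) bias is negligible at cohort
  scale and is documented rather than corrected).
* `f_snp_outside_roh` — the same statistic restricted to SNPs outside
  the sample's ROH, via the count adjustments
  `O' = O - N_SNP_ROH`, `E' = E (N - N_ROH)/N`, `N' = N - N_ROH`. It
  reduces exactly to `f_snp` when there are no ROH and satisfies
  `f_snp_outside_roh ≈ f_snp - f_roh` on cohorts where ROH carry the
  excess homozygosity (asserted with an empirical tolerance of 0.02 on
  the median in tests).
* `f_grm` — the GRM-diagonal estimator, the per-sample mean of
  `(x^2 - (1+2p)x + 2p^2) / (2pq)` over polymorphic non-missing SNPs.
* `excess_homozygosity_by_maf()` — `f_snp` restricted to MAF bins, for
  showing that rare-variant homozygosity tracks `f_roh` while
  common-variant homozygosity tracks `f_grm`.

All estimators are invariant to which allele is counted; degenerate
denominators (monomorphic panels, all SNPs inside ROH) are flagged `NA`
rather than silently zeroed.

## Per-cohort effect models

Analysis is two-step for computational thrift: the trait is first
residualized on all fixed covariates (`residualize()`, ordinary least
squares; the fitted intercept is kept for the bin analysis), then the
residuals are regressed on the inbreeding measure of interest. In
family-structured cohorts `grammar_residuals()` replaces the first step:
`y = Xb + u + e` with `u ~ N(0, sigma_g^2 A)` for a genomic relationship
matrix `A`, estimated by REML on a one-dimensional heritability profile
after eigendecomposition of `A`, residuals `y - Xb - u` with `u` the
BLUP. When the profile is flat (e.g. `A = I`) or the variance estimate
hits the zero boundary the procedure collapses to ordinary least
squares by design. The residual-based slope inherits some shrinkage from
BLUP when heritability is high; tests therefore treat mixed-model
residuals as a variance-control device, and parameter-recovery checks
run on the OLS route.

The model classes are: univariate slopes on `f_roh`, `f_snp`, `f_grm`;
the partitioned model (outside-ROH homozygosity + short ROH + long ROH
jointly); the bivariate `f_roh + f_grm` model with conditional effects;
logistic and scaled-linear (`y / var(y)`, then the linear two-step)
estimates for binary traits, both on the ln(OR) scale, with
`OR_0.0625 = exp(0.0625 beta)` reported for the first-cousin-offspring
scale; sex-specific univariate fits; ten fixed F_ROH bins
(`{0, 0.002, 0.0041, 0.0067, 0.0108, 0.0186, 0.0333, 0.06, 0.10, 0.18,
1.0}`, left-closed/right-open with the last bin closed so F_ROH = 0 and
F_ROH = 1 are both binnable) with intercept-referenced mean residuals;
and the within-sibling estimator.

**Within-sibling design.** Full siblings are found either from pedigree
labels (simulated cohorts) or from the genotypes: a method-of-moments
kinship estimator (both-heterozygous and opposite-homozygote counts:
`phi = (N_AaAa - 2 N_AAaa) / (N_Aa(i) + N_Aa(j))`) with full siblings
selected as pairs with kinship > 0.175 and IBS0 > 0.001 — the IBS0
condition is what separates siblings from parent–offspring pairs at the
same kinship — merged into sibships by transitive closure, keeping
monozygotic-twin-like pairs (extra trait replicates at identical F
improve the within-family variance estimate). F_ROH and the trait
residual are expressed as deviations from the family mean and the slope
fitted through the origin: deviations sum to zero by construction, so an
intercept is redundant (one is available behind a flag and estimates
~0; the no-intercept fit is the default). Because consortium
protocols leave open whether clustered errors were used, the function
reports both the naive and the family-clustered (CR0 sandwich) standard
error; downstream code uses the naive one, and the clustered column is
there for sensitivity analysis. Since sibling differences in F arise
only from Mendelian segregation, this estimator is unbiased under any
family-level confounding — the property the confounder-injection test
verifies.

## Meta-analysis

`ivw_meta()` is the closed-form fixed-effect inverse-variance pool
(`beta = sum(b/se^2)/sum(1/se^2)`, `se = 1/sqrt(sum(1/se^2))`), with
Cochran's Q reported descriptively only — no random-effects model is
fitted, deliberately. Tests cross-check against `metafor`'s fixed-effect
fit. `meta_bins()` pools the per-bin intercept-referenced means, which
is why the bins subtract the F_ROH = 0 intercept: cohorts differ in mean
F_ROH, so residuals must be referenced to a common point before
pooling. `ratio_bootstrap()` summarises ratios of effect estimates
(e.g. within-sibling : population) across traits by a **parametric**
bootstrap — each replicate redraws every estimate from its normal
sampling distribution — because the meta-analysis stage only ever sees
summary statistics, making resampling of individuals impossible; the
normality-of-ratio problem that motivates a bootstrap in the first
place (denominators close to zero) is flagged via a `|beta|/se < 2`
warning on the denominator. Both equal-weight and precision-weighted
pooling across traits are reported, since the weighting convention is a
genuinely open choice; equal weight is the headline number.

## QC and I/O conventions

`qc_filter()` removes SNPs with missingness > 3% or MAF < 5% (strict
inequality: a SNP at exactly 5% survives), then samples with
missingness > 3%. SNP filters run before sample filters; the order is
unstated in consortium protocols but changes marginal missingness, so it
is fixed, documented and reported in the QC report. MAF is always
`min(p, 1-p)` on in-sample frequencies — no external reference panel is
assumed anywhere. Genotype I/O supports PLINK ped/map text and
bed/bim/fam binary (SNP-major, magic `6c 1b 01`), written by hand
against the documented layout and round-trip-tested bit-exactly; calls
count the A1 allele, positions are 1-based inclusive, and missingness is
a distinct sentinel (`NA`), never conflated with a homozygote.

## Problem sizes and numerical tolerances

The shipped tests and workflow run at desk scale, chosen so the full
suite completes in a few minutes while every Monte-Carlo check retains
power: recovery replicates use 8 × 50 Mb genomes with 2,200 SNPs per
chromosome (44 SNPs/Mb, comfortably above the ~33/Mb the density filter
needs) and cohorts of 76–280 offspring; the pedigree-expectation checks
use 200–250 offspring on a 20 × 50 Mb (1 Gb) genome and accept within
three Monte-Carlo standard errors; load recovery pools 50 replicate
cohorts by IVW and accepts within the pooled 95% CI plus a 10% margin
for the measurement-error attenuation inherent to called (rather than
true) F_ROH. REML declares the likelihood flat below an improvement of
1e-6; perfect separation in logistic fits is detected at fitted
probabilities within 1e-10 of the boundary.

## Known limitations

* The ROH caller's behaviour on edge cases not covered by the public
  description of the reference tool (e.g. overlapping candidate runs
  after trimming) is defined by this package's brute-force oracle; on
  real data, borderline segments may differ from other implementations
  by a SNP or two at the boundaries.
* Without LD in the founders, chance (non-IBD) ROH essentially never
  occur in simulation, so the false-positive behaviour of the caller on
  LD-rich real genomes is untested here.
* `f_maf` bins are computed on hard calls only; imputed-dosage variants
  of the statistic are out of scope.
* Binary traits get no mixed model (none is attempted in the logistic
  route), matching standard practice at consortium scale.
* Pedigree-based F and ROH-region mapping of individual loci are out of
  scope.
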