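#' Genomic inbreeding coefficient from ROH totals
#'
#' F_ROH is the summed length of called ROH divided by the autosomal
#' genome length (3 Gb for the human genome; configurable for downscaled
#' simulated genomes). The split into segments shorter and longer than
#' 5 Mb satisfies the exact identity
#' `f_roh = f_roh_lt5 + f_roh_gt5`.
#'
#' @param summary per-sample totals from [roh_sample_summary()]
#' @param genome_size_bp autosomal genome length (denominator)
#' @return data frame: `sample_id`, `f_roh`, `f_roh_lt5`, `f_roh_gt5`
#' @export
f_roh <- function(summary, genome_size_bp = 3e9) {
  if (genome_size_bp <= 0) stop("genome_size_bp must be positive")
  lt5 <- summary$kb_lt5 * 1000 / genome_size_bp
  gt5 <- summary$kb_gt5 * 1000 / genome_size_bp
  # the total is formed from the two length classes so that the identity
  # f_roh == f_roh_lt5 + f_roh_gt5 holds to the last bit
  data.frame(sample_id = summary$sample_id,
             f_roh = lt5 + gt5, f_roh_lt5 = lt5, f_roh_gt5 = gt5,
             stringsAsFactors = FALSE)
}

# expected homozygous count per sample over its non-missing SNPs
ehom_terms <- function(p) 1 - 2 * p * (1 - p)

#' Method-of-moments inbreeding from excess SNP homozygosity
#'
#' F_SNP = (O(HOM) - E(HOM)) / (N - E(HOM)) per sample, where O(HOM) is
#' the observed homozygous count, E(HOM) the Hardy-Weinberg expectation
#' sum(1 - 2 p q) over that sample's non-missing SNPs, and N its
#' non-missing SNP count. In-sample allele frequencies (including the
#' index individual) are used, as in the standard implementation; the
#' resulting small-sample bias is negligible at cohort scale.
#'
#' @param g a [genotype_matrix()]
#' @param p optional [allele_frequencies()] table (defaults to in-sample)
#' @return data frame `sample_id`, `f_snp` (`NA` flagged when all SNPs
#'   are monomorphic so the denominator vanishes)
#' @export
f_snp <- function(g, p = allele_frequencies(g)) {
  nonmiss <- !is.na(g$calls)
  hom <- nonmiss & g$calls != 1L
  e_terms <- ehom_terms(p$p)
  o_hom <- rowSums(hom)
  e_hom <- as.numeric(nonmiss %*% e_terms)
  n <- rowSums(nonmiss)
  denom <- n - e_hom
  val <- ifelse(abs(denom) < .Machine$double.eps^0.5, NA_real_,
                (o_hom - e_hom) / denom)
  data.frame(sample_id = g$samples$sample_id, f_snp = val,
             stringsAsFactors = FALSE)
}

# logical matrix: is SNP j inside one of sample i's segments
snp_in_roh_matrix <- function(g, segments) {
  ns <- n_samples(g)
  nv <- n_variants(g)
  inroh <- matrix(FALSE, ns, nv)
  if (!nrow(segments)) return(inroh)
  sidx <- match(segments$sample_id, g$samples$sample_id)
  for (k in seq_len(nrow(segments))) {
    j <- which(g$map$chrom == segments$chrom[k] &
                 g$map$pos_bp >= segments$start_bp[k] &
                 g$map$pos_bp <= segments$end_bp[k])
    if (length(j)) inroh[sidx[k], j] <- TRUE
  }
  inroh
}

#' Excess SNP homozygosity outside called ROH
#'
#' The F_SNP statistic restricted to each sample's SNPs outside its ROH:
#' O'(HOM) = O(HOM) - (homozygous SNPs inside ROH),
#' E'(HOM) = E(HOM) x (N - N_ROH)/N, N' = N - N_ROH, and
#' F = (O' - E') / (N' - E'). With no ROH it reduces exactly to [f_snp()],
#' and approximately F_SNPoutsideROH = F_SNP - F_ROH on cohorts where ROH
#' carry most excess homozygosity.
#'
#' @param g a [genotype_matrix()]
#' @param segments ROH calls from [call_roh()]
#' @param p optional allele-frequency table
#' @return data frame `sample_id`, `f_snp_outside_roh` (`NA` flagged when
#'   all SNPs fall inside ROH or the denominator vanishes)
#' @export
f_snp_outside_roh <- function(g, segments, p = allele_frequencies(g)) {
  nonmiss <- !is.na(g$calls)
  hom <- nonmiss & g$calls != 1L
  inroh <- snp_in_roh_matrix(g, segments)
  e_terms <- ehom_terms(p$p)
  o_hom <- rowSums(hom)
  e_hom <- as.numeric(nonmiss %*% e_terms)
  n <- rowSums(nonmiss)
  n_roh <- rowSums(nonmiss & inroh)
  n_snp_roh <- rowSums(hom & inroh)
  o_prime <- o_hom - n_snp_roh
  e_prime <- ifelse(n > 0, (n - n_roh) / n * e_hom, NA_real_)
  n_prime <- n - n_roh
  denom <- n_prime - e_prime
  val <- ifelse(is.na(denom) | abs(denom) < .Machine$double.eps^0.5,
                NA_real_, (o_prime - e_prime) / denom)
  data.frame(sample_id = g$samples$sample_id, f_snp_outside_roh = val,
             stringsAsFactors = FALSE)
}

#' GRM-diagonal inbreeding estimator
#'
#' The single-point estimator based on the diagonal of the genomic
#' relationship matrix (PLINK's `--ibc` Fhat3): the per-sample mean over
#' polymorphic non-missing SNPs of
#' (x^2 - (1 + 2p) x + 2 p^2) / (2 p (1 - p)),
#' where x counts copies of the counted allele with frequency p.
#'
#' @param g a [genotype_matrix()]
#' @param p optional allele-frequency table
#' @return data frame `sample_id`, `f_grm`
#' @export
f_grm <- function(g, p = allele_frequencies(g)) {
  poly <- !is.na(p$p) & p$p > 0 & p$p < 1
  if (!any(poly)) stop("no polymorphic SNPs for f_grm")
  x <- g$calls[, poly, drop = FALSE]
  pv <- p$p[poly]
  # term_ij = (x^2 - (1+2p) x + 2 p^2) / (2 p (1-p))
  t2p2 <- 2 * pv * pv
  den <- 2 * pv * (1 - pv)
  terms <- sweep(x * x, 2, den, "/") -
    sweep(x, 2, (1 + 2 * pv) / den, "*") +
    matrix(rep(t2p2 / den, each = nrow(x)), nrow(x))
  terms[is.na(x)] <- NA
  val <- rowMeans(terms, na.rm = TRUE)
  data.frame(sample_id = g$samples$sample_id, f_grm = val,
             stringsAsFactors = FALSE)
}

#' Excess homozygosity within minor-allele-frequency bins
#'
#' The F_SNP statistic computed on the subset of SNPs whose in-sample MAF
#' falls in each requested bin; used to show that rare-variant
#' homozygosity tracks F_ROH while common-variant homozygosity tracks
#' F_GRM.
#'
#' @param g a [genotype_matrix()]
#' @param bins numeric vector of bin edges on MAF (left-closed,
#'   right-open; the last bin is closed)
#' @param p optional allele-frequency table
#' @return list with one data frame per bin (`sample_id`, `f_maf`), named
#'   by bin; bins with no SNPs or only monomorphic SNPs yield `NA` values
#'   with a `flagged` attribute
#' @export
excess_homozygosity_by_maf <- function(g, bins, p = allele_frequencies(g)) {
  maf <- pmin(p$p, 1 - p$p)
  out <- list()
  for (b in seq_len(length(bins) - 1)) {
    lo <- bins[b]; hi <- bins[b + 1]
    inb <- !is.na(maf) & maf >= lo &
      (maf < hi | (b == length(bins) - 1 & maf <= hi))
    nm <- sprintf("[%g,%g%s", lo, hi,
                  if (b == length(bins) - 1) "]" else ")")
    if (!any(inb)) {
      res <- data.frame(sample_id = g$samples$sample_id, f_maf = NA_real_)
      attr(res, "flagged") <- "empty bin"
    } else {
      sub <- genotype_matrix(g$calls[, inb, drop = FALSE],
                             g$map[inb, , drop = FALSE], g$samples)
      fs <- f_snp(sub, p = p[inb, , drop = FALSE])
      res <- data.frame(sample_id = fs$sample_id, f_maf = fs$f_snp)
      if (all(is.na(res$f_maf))) attr(res, "flagged") <- "monomorphic bin"
    }
    out[[nm]] <- res
  }
  out
}

#' Full per-sample inbreeding profile
#'
#' Convenience wrapper computing all estimators from a genotype matrix and
#' its ROH calls, with the exact identity
#' `f_roh == f_roh_lt5 + f_roh_gt5` per sample.
#'
#' @param g a [genotype_matrix()]
#' @param segments ROH calls from [call_roh()]
#' @param genome_size_bp genome length for the F_ROH denominator
#' @return data frame with columns `sample_id`, `f_roh`, `f_roh_lt5`,
#'   `f_roh_gt5`, `f_snp`, `f_snp_outside_roh`, `f_grm`
#' @export
inbreeding_profile <- function(g, segments, genome_size_bp = 3e9) {
  summ <- roh_sample_summary(segments, g$samples$sample_id)
  p <- allele_frequencies(g)
  fr <- f_roh(summ, genome_size_bp)
  fs <- f_snp(g, p)
  fo <- f_snp_outside_roh(g, segments, p)
  fg <- f_grm(g, p)
  out <- Reduce(function(a, b) merge(a, b, by = "sample_id", sort = FALSE),
                list(fr, fs, fo, fg))
  out[match(g$samples$sample_id, out$sample_id), , drop = FALSE]
}

#' Cohort-level inbreeding census
#'
#' Summarises a cohort for the mean-F_ROH vs F_IS classification: F_IS is
#' the mean individual departure from Hardy-Weinberg equilibrium (the mean
#' of per-sample F_SNP). Consanguineous cohorts sit near the
#' F_ROH = F_IS line; admixed cohorts show F_IS > 0 without elevated
#' F_ROH (Wahlund pattern).
#'
#' @param profiles output of [inbreeding_profile()]
#' @return one-row data frame: `mean_f_roh`, `sd_f_roh`, `f_is`, `n`
#' @export
cohort_f_summary <- function(profiles) {
  stopifnot(nrow(profiles) >= 2)
  data.frame(mean_f_roh = mean(profiles$f_roh),
             sd_f_roh = stats::sd(profiles$f_roh),
             f_is = mean(profiles$f_snp, na.rm = TRUE),
             n = nrow(profiles))
}

#' Write an inbreeding-profile TSV
#' @param profiles output of [inbreeding_profile()]
#' @param path output file
#' @return invisibly, the path
#' @export
write_profiles <- function(profiles, path) {
  out <- profiles
  names(out) <- c("IID", "F_ROH", "F_ROH_LT5", "F_ROH_GT5", "F_SNP",
                  "F_SNP_OUTSIDE_ROH", "FHAT3")[seq_along(out)]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
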