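# Shared fixture builders and independent oracles.

# genotype_matrix from a calls matrix and positions on one chromosome
toy_geno <- function(calls, pos = NULL, chrom = "1") {
  calls <- as.matrix(calls)
  nv <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(nv) * 1000
  map <- data.frame(chrom = rep_len(chrom, nv), pos_bp = as.numeric(pos),
                    id = sprintf("rs%d", seq_len(nv)),
                    a1 = rep_len("A", nv), a2 = rep_len("B", nv),
                    stringsAsFactors = FALSE)
  genotype_matrix(calls, map)
}

# draw n HWE genotypes at counted-allele frequencies p (vector per SNP)
hwe_genotypes <- function(n, p) {
  nv <- length(p)
  matrix(stats::rbinom(n * nv, 2L, rep(p, each = n)), nrow = n)
}

# Brute-force sliding-window ROH scan: an independent, loop-everything
# implementation of the stated algorithm, used as the oracle for call_roh.
roh_oracle <- function(g, params = roh_params()) {
  af <- allele_frequencies(g)
  maf <- pmin(af$p, 1 - af$p)
  keep <- !is.na(maf) & maf >= params$maf_floor
  calls <- g$calls[, keep, drop = FALSE]
  map <- g$map[keep, , drop = FALSE]
  w <- params$window_snp
  res <- list()
  for (ch in unique(map$chrom)) {
    jdx <- which(map$chrom == ch)
    pos <- map$pos_bp[jdx]
    n <- length(jdx)
    if (n < w) next
    for (i in seq_len(nrow(calls))) {
      x <- calls[i, jdx]
      # every fully contained window: homozygous or not
      hom_win <- logical(n - w + 1)
      for (ws in seq_len(n - w + 1)) {
        win <- x[ws:(ws + w - 1)]
        hom_win[ws] <- sum(win == 1, na.rm = TRUE) <= params$window_het &&
          sum(is.na(win)) <= params$window_missing
      }
      # per-SNP hit rate over containing windows
      elig <- logical(n)
      for (j in seq_len(n)) {
        wins <- max(1, j - w + 1):min(n - w + 1, j)
        elig[j] <- mean(hom_win[wins]) >= params$window_hit_threshold
      }
      # maximal eligible runs, split at big gaps
      j <- 1
      while (j <= n) {
        if (!elig[j]) { j <- j + 1; next }
        k <- j
        while (k < n && elig[k + 1] &&
               pos[k + 1] - pos[k] <= params$max_gap_kb * 1000) k <- k + 1
        run <- j:k
        # trim flanking het/missing
        hom <- !is.na(x[run]) & x[run] != 1
        if (any(hom)) {
          a <- run[which(hom)[1]]
          b <- run[rev(which(hom))[1]]
          n_snps <- b - a + 1
          len <- pos[b] - pos[a]
          if (n_snps >= params$min_snp && len >= params$min_kb * 1000 &&
              len / n_snps <= params$max_density_kb_per_snp * 1000) {
            res[[length(res) + 1]] <- data.frame(
              sample_id = g$samples$sample_id[i], chrom = ch,
              start_bp = pos[a], end_bp = pos[b],
              n_snps = n_snps, length_bp = len,
              stringsAsFactors = FALSE)
          }
        }
        j <- k + 1
      }
    }
  }
  if (!length(res))
    return(data.frame(sample_id = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), length_bp = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# small cohort with ROH-resolvable SNP density, for estimator tests
small_roh_cohort <- function(seed = 42,
                             matings = c(unrelated = 10,
                                         first_cousin = 25,
                                         avuncular = 8, full_sib = 4),
                             sibs = 1, snps_per_chr = 2500, n_chr = 8,
                             ...) {
  simulate_cohort(cohort_config(matings = matings,
                                sibs_per_family = sibs,
                                n_chr = n_chr,
                                snps_per_chr = snps_per_chr, ...),
                  seed = seed)
}
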