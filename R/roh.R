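#' Parameters for sliding-window ROH detection
#'
#' Defaults follow the standard SNP-array parameterisation used in large
#' consortium analyses of autozygosity: 50-SNP windows, runs of at least
#' 50 SNPs and 1500 kb, gaps up to 1000 kb, at most 1 het and 5 missing
#' calls per window, density at least one SNP per 50 kb. The window hit
#' threshold (fraction of homozygous windows a SNP must sit in to be
#' ROH-eligible) is the reference implementation's 0.05 default.
#'
#' @param window_snp window size in SNPs
#' @param min_snp minimum SNPs per emitted segment
#' @param min_kb minimum segment length in kb (inclusive)
#' @param max_gap_kb maximum inter-SNP gap within a run, kb
#' @param max_density_kb_per_snp maximum kb per SNP within a segment
#' @param window_missing maximum missing calls for a homozygous window
#' @param window_het maximum heterozygous calls for a homozygous window
#' @param window_hit_threshold minimum proportion of homozygous windows
#'   containing a SNP for it to be ROH-eligible
#' @param maf_floor SNPs with minor allele frequency strictly below this
#'   are removed before calling
#' @return a `roh_params` list
#' @export
roh_params <- function(window_snp = 50, min_snp = 50, min_kb = 1500,
                       max_gap_kb = 1000, max_density_kb_per_snp = 50,
                       window_missing = 5, window_het = 1,
                       window_hit_threshold = 0.05, maf_floor = 0.05) {
  stopifnot(window_snp >= 1, min_snp >= 0, min_kb >= 0, max_gap_kb >= 0,
            window_hit_threshold > 0, window_hit_threshold <= 1)
  structure(as.list(environment()), class = "roh_params")
}

#' Call runs of homozygosity with a sliding window
#'
#' Reimplements the standard sliding-window ROH scan: (i) SNPs with MAF
#' below `maf_floor` are dropped; (ii) a window of `window_snp` SNPs
#' slides one SNP at a time along each chromosome, and is homozygous if it
#' has at most `window_het` heterozygous and `window_missing` missing
#' calls; (iii) each SNP's hit rate is the fraction of windows containing
#' it that are homozygous (near chromosome ends the denominator counts
#' only fully contained windows); a SNP is eligible when the rate reaches
#' `window_hit_threshold`; (iv) maximal runs of eligible SNPs are split at
#' inter-SNP gaps above `max_gap_kb`, trimmed so that they start and end
#' on a homozygous non-missing call, then filtered by `min_snp`, `min_kb`
#' (inclusive: a run of exactly `min_kb` is kept) and density. Segment
#' length is `end_bp - start_bp`, the span between first and last SNP.
#'
#' Chromosomes with fewer SNPs than `window_snp` (after the MAF filter)
#' are skipped with a warning.
#'
#' @param g a [genotype_matrix()] (already quality controlled)
#' @param params a [roh_params()]
#' @return data frame of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`
#' @export
call_roh <- function(g, params = roh_params()) {
  validate_genotype_matrix(g)
  af <- allele_frequencies(g)
  maf <- pmin(af$p, 1 - af$p)
  keep <- !is.na(maf) & maf >= params$maf_floor
  calls <- g$calls[, keep, drop = FALSE]
  map <- g$map[keep, , drop = FALSE]
  out <- list()
  skipped <- character(0)
  for (ch in unique(map$chrom)) {
    cidx <- which(map$chrom == ch)
    pos <- map$pos_bp[cidx]
    if (is.unsorted(pos, strictly = TRUE))
      stop("variant map not sorted on chromosome ", ch)
    if (length(cidx) < params$window_snp) {
      skipped <- c(skipped, ch)
      next
    }
    sub <- calls[, cidx, drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      seg <- roh_scan_one(sub[i, ], pos, params)
      if (!is.null(seg) && nrow(seg)) {
        seg$sample_id <- g$samples$sample_id[i]
        seg$chrom <- ch
        out[[length(out) + 1L]] <- seg
      }
    }
  }
  if (length(skipped))
    warning("chromosome(s) with fewer than window_snp SNPs skipped: ",
            paste(skipped, collapse = ", "))
  if (!length(out))
    return(data.frame(sample_id = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), length_bp = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[, c("sample_id", "chrom", "start_bp", "end_bp", "n_snps",
                 "length_bp")]
  rownames(res) <- NULL
  res
}

# window scan for one sample on one chromosome
roh_scan_one <- function(x, pos, params) {
  n <- length(x)
  w <- params$window_snp
  het <- !is.na(x) & x == 1L
  mis <- is.na(x)
  nW <- n - w + 1L
  cs_het <- c(0, cumsum(het))
  cs_mis <- c(0, cumsum(mis))
  win_het <- cs_het[(w + 1):(n + 1)] - cs_het[1:nW]
  win_mis <- cs_mis[(w + 1):(n + 1)] - cs_mis[1:nW]
  hom_win <- win_het <= params$window_het & win_mis <= params$window_missing
  cs_hw <- c(0, cumsum(hom_win))
  j <- seq_len(n)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(nW, j)
  n_win <- hi - lo + 1L
  hits <- cs_hw[hi + 1L] - cs_hw[lo]
  elig <- hits / n_win >= params$window_hit_threshold
  if (!any(elig)) return(NULL)
  runs <- run_bounds(elig)
  segs <- list()
  max_gap <- params$max_gap_kb * 1000
  for (r in seq_len(nrow(runs))) {
    idx <- runs$start[r]:runs$end[r]
    # split at large inter-SNP gaps
    if (length(idx) > 1) {
      gap_break <- which(diff(pos[idx]) > max_gap)
      piece_start <- c(1L, gap_break + 1L)
      piece_end <- c(gap_break, length(idx))
    } else {
      piece_start <- 1L
      piece_end <- 1L
    }
    for (pz in seq_along(piece_start)) {
      pidx <- idx[piece_start[pz]:piece_end[pz]]
      seg <- trim_and_filter(pidx, x, pos, params)
      if (!is.null(seg)) segs[[length(segs) + 1L]] <- seg
    }
  }
  if (!length(segs)) return(NULL)
  do.call(rbind, segs)
}

run_bounds <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

trim_and_filter <- function(pidx, x, pos, params) {
  hom <- !is.na(x[pidx]) & x[pidx] != 1L
  if (!any(hom)) return(NULL)
  first <- pidx[which(hom)[1]]
  last <- pidx[which(hom)[sum(hom)]]
  n_snps <- last - first + 1L
  len <- pos[last] - pos[first]
  if (n_snps < params$min_snp) return(NULL)
  if (len < params$min_kb * 1000) return(NULL)
  if (len / n_snps > params$max_density_kb_per_snp * 1000) return(NULL)
  data.frame(start_bp = pos[first], end_bp = pos[last],
             n_snps = n_snps, length_bp = len)
}

#' Per-sample ROH summary
#'
#' Totals of called segments per sample, split by the 5 Mb length class
#' used for the partitioned inbreeding estimators; a segment of exactly
#' 5 Mb counts as long ("greater than 5 Mb" class).
#'
#' @param segments segment data frame from [call_roh()]
#' @param sample_ids ids to report; samples without segments get zeros
#' @return data frame: `sample_id`, `n_segments`, `total_kb`, `kb_lt5`,
#'   `kb_gt5`, `n_lt5`, `n_gt5`
#' @export
roh_sample_summary <- function(segments, sample_ids) {
  out <- data.frame(sample_id = sample_ids, n_segments = 0L, total_kb = 0,
                    kb_lt5 = 0, kb_gt5 = 0, n_lt5 = 0L, n_gt5 = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(segments)) {
    long <- segments$length_bp >= 5e6
    agg <- function(vals, ids) {
      a <- tapply(vals, ids, sum)
      i <- match(names(a), out$sample_id)
      list(i = i[!is.na(i)], v = as.numeric(a)[!is.na(i)])
    }
    a <- agg(rep(1L, nrow(segments)), segments$sample_id)
    out$n_segments[a$i] <- a$v
    a <- agg(segments$length_bp / 1000, segments$sample_id)
    out$total_kb[a$i] <- a$v
    if (any(!long)) {
      s <- segments[!long, ]
      a <- agg(s$length_bp / 1000, s$sample_id)
      out$kb_lt5[a$i] <- a$v
      a <- agg(rep(1L, nrow(s)), s$sample_id)
      out$n_lt5[a$i] <- a$v
    }
    if (any(long)) {
      s <- segments[long, ]
      a <- agg(s$length_bp / 1000, s$sample_id)
      out$kb_gt5[a$i] <- a$v
      a <- agg(rep(1L, nrow(s)), s$sample_id)
      out$n_gt5[a$i] <- a$v
    }
  }
  out
}

#' Write segments in a `.hom`-style TSV
#'
#' @param segments segment data frame from [call_roh()]
#' @param path output file
#' @return invisibly, the path
#' @export
write_roh <- function(segments, path) {
  out <- data.frame(IID = segments$sample_id, CHR = segments$chrom,
                    POS1 = segments$start_bp, POS2 = segments$end_bp,
                    KB = segments$length_bp / 1000, NSNP = segments$n_snps)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
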