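#' Construct a genotype matrix object
#'
#' The central data container: biallelic autosomal genotype calls for a set
#' of samples, together with a physical variant map and a sample table.
#' Calls count copies of the A1 ("counted") allele, so `2` means homozygous
#' A1, `0` homozygous A2, `1` heterozygous and `NA` missing.
#'
#' @param calls integer matrix, samples x variants, entries in
#'   \{0, 1, 2, NA\}. Row names are taken as sample ids if `samples` is
#'   missing; column names as variant ids.
#' @param map data frame with columns `chrom`, `pos_bp` (1-based physical
#'   position), `id`, `a1`, `a2`. Must be sorted with strictly increasing
#'   positions within each chromosome.
#' @param samples data frame with columns `sample_id`, `family_id`,
#'   `father_id`, `mother_id`, `sex` (one of "male", "female", "unknown").
#'   Missing parent ids are `NA`; a sample must have both or neither.
#' @return an object of class `genotype_matrix` (a list with elements
#'   `calls`, `map`, `samples`).
#' @export
genotype_matrix <- function(calls, map, samples = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) {
    ids <- rownames(calls)
    if (is.null(ids)) ids <- paste0("S", seq_len(nrow(calls)))
    samples <- data.frame(sample_id = ids, family_id = ids,
                          father_id = NA_character_, mother_id = NA_character_,
                          sex = "unknown", stringsAsFactors = FALSE)
  }
  map <- as.data.frame(map)
  samples <- as.data.frame(samples)
  g <- structure(list(calls = calls, map = map, samples = samples),
                 class = "genotype_matrix")
  validate_genotype_matrix(g)
  g
}

validate_genotype_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- g$calls
  map <- g$map
  samples <- g$samples
  need <- c("chrom", "pos_bp", "id", "a1", "a2")
  if (!all(need %in% names(map)))
    stop("variant map must have columns: ", paste(need, collapse = ", "))
  if (ncol(calls) != nrow(map))
    stop("dimension mismatch: ", ncol(calls), " call columns vs ",
         nrow(map), " map rows")
  if (nrow(calls) != nrow(samples))
    stop("dimension mismatch: ", nrow(calls), " call rows vs ",
         nrow(samples), " samples")
  if (anyDuplicated(samples$sample_id))
    stop("sample ids are not unique")
  bad <- !(calls %in% c(0L, 1L, 2L)) & !is.na(calls)
  if (any(bad)) stop("genotype calls must be in {0, 1, 2, NA}")
  has_f <- !is.na(samples$father_id)
  has_m <- !is.na(samples$mother_id)
  if (any(has_f != has_m))
    stop("parent ids must be both present or both absent per sample")
  # positions strictly increasing within chromosome
  if (nrow(map) > 1) {
    same <- map$chrom[-1] == map$chrom[-nrow(map)]
    up <- diff(map$pos_bp) > 0
    if (any(same & !up))
      stop("variant positions must be strictly increasing within chromosomes")
  }
  invisible(g)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls),
      "variants on", length(unique(x$map$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missingness %.3f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / variants
#' @param g a `genotype_matrix`
#' @return integer count
#' @export
n_samples <- function(g) nrow(g$calls)

#' @rdname n_samples
#' @export
n_variants <- function(g) ncol(g$calls)

#' Per-variant allele frequencies of the counted allele
#'
#' Frequencies are computed in-sample from non-missing calls only:
#' p_j = (sum of counted-allele copies at j) / (2 * non-missing samples at j).
#' Variants with no non-missing calls get `NA` and are flagged.
#'
#' @param g a `genotype_matrix`
#' @return data frame with columns `id`, `p` (counted-allele frequency) and
#'   `n_obs` (non-missing call count per variant).
#' @export
allele_frequencies <- function(g) {
  n_obs <- colSums(!is.na(g$calls))
  tot <- colSums(g$calls, na.rm = TRUE)
  p <- ifelse(n_obs > 0, tot / (2 * n_obs), NA_real_)
  data.frame(id = g$map$id, p = p, n_obs = n_obs,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quality-control filter for genotype matrices
#'
#' Removes variants with missingness above `max_snp_missing` or minor allele
#' frequency strictly below `min_maf` (a SNP at exactly the threshold is
#' retained), then removes samples with missingness above
#' `max_sample_missing` computed on the retained variants. SNP filters are
#' applied before sample filters; the order matters for marginal
#' missingness and is reported.
#'
#' @param g a `genotype_matrix`
#' @param max_snp_missing,min_maf,max_sample_missing thresholds in `[0, 1]`
#' @return a list with `genotypes` (the filtered `genotype_matrix`) and
#'   `report` (a data frame of per-rule removal counts).
#' @export
qc_filter <- function(g, max_snp_missing = 0.03, min_maf = 0.05,
                      max_sample_missing = 0.03) {
  stopifnot(max_snp_missing >= 0, max_snp_missing <= 1,
            min_maf >= 0, min_maf <= 1,
            max_sample_missing >= 0, max_sample_missing <= 1)
  snp_miss <- colMeans(is.na(g$calls))
  af <- allele_frequencies(g)
  maf <- pmin(af$p, 1 - af$p)
  drop_miss <- snp_miss > max_snp_missing
  drop_maf <- is.na(maf) | maf < min_maf
  keep_snp <- !(drop_miss | drop_maf)
  if (!any(keep_snp))
    stop("qc_filter removed all variants")
  calls <- g$calls[, keep_snp, drop = FALSE]
  samp_miss <- rowMeans(is.na(calls))
  keep_samp <- samp_miss <= max_sample_missing
  out <- genotype_matrix(calls[keep_samp, , drop = FALSE],
                         g$map[keep_snp, , drop = FALSE],
                         g$samples[keep_samp, , drop = FALSE])
  report <- data.frame(
    rule = c("snp_missingness", "snp_maf", "sample_missingness"),
    threshold = c(max_snp_missing, min_maf, max_sample_missing),
    removed = c(sum(drop_miss), sum(drop_maf & !drop_miss), sum(!keep_samp)),
    stringsAsFactors = FALSE)
  list(genotypes = out, report = report)
}

# ---- PLINK I/O ------------------------------------------------------------

#' Read genotypes from PLINK files
#'
#' Supports the text ped/map dialect and the binary bed/bim/fam dialect
#' (SNP-major bed, magic bytes 0x6c 0x1b 0x01). `path` is the file prefix
#' without extension. Calls count the A1 allele, matching the bim A1 column.
#'
#' @param path file prefix (no extension)
#' @param dialect "bed" (binary) or "ped" (text)
#' @return a `genotype_matrix`
#' @export
read_genotypes <- function(path, dialect = c("bed", "ped")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") read_plink_bed(path) else read_plink_ped(path)
}

#' Write genotypes to PLINK files
#'
#' Inverse of [read_genotypes()]; the binary dialect is bit-compatible with
#' the standard SNP-major bed/bim/fam layout, and a write/read round trip is
#' the identity on calls, map and sample ids (missing calls included).
#'
#' @param g a `genotype_matrix`
#' @param path file prefix (no extension)
#' @param dialect "bed" or "ped"
#' @return invisibly, the character vector of files written
#' @export
write_genotypes <- function(g, path, dialect = c("bed", "ped")) {
  dialect <- match.arg(dialect)
  validate_genotype_matrix(g)
  if (dialect == "bed") write_plink_bed(g, path) else write_plink_ped(g, path)
}

sex_to_plink <- function(sex) {
  ifelse(sex == "male", 1L, ifelse(sex == "female", 2L, 0L))
}

plink_to_sex <- function(code) {
  ifelse(code == 1, "male", ifelse(code == 2, "female", "unknown"))
}

fam_frame <- function(g) {
  s <- g$samples
  data.frame(fid = s$family_id,
             iid = s$sample_id,
             pat = ifelse(is.na(s$father_id), "0", s$father_id),
             mat = ifelse(is.na(s$mother_id), "0", s$mother_id),
             sex = sex_to_plink(s$sex),
             pheno = -9L, stringsAsFactors = FALSE)
}

samples_from_fam <- function(fam) {
  data.frame(sample_id = as.character(fam[[2]]),
             family_id = as.character(fam[[1]]),
             father_id = ifelse(fam[[3]] == "0", NA_character_,
                                as.character(fam[[3]])),
             mother_id = ifelse(fam[[4]] == "0", NA_character_,
                                as.character(fam[[4]])),
             sex = plink_to_sex(fam[[5]]),
             stringsAsFactors = FALSE)
}

read_plink_ped <- function(path) {
  ped_file <- paste0(path, ".ped")
  map_file <- paste0(path, ".map")
  if (!file.exists(ped_file) || !file.exists(map_file))
    stop("missing .ped/.map file at prefix ", path)
  map_raw <- if (file.info(map_file)$size == 0) {
    data.frame(V1 = character(), V2 = character(), V3 = numeric(),
               V4 = integer(), stringsAsFactors = FALSE)
  } else {
    utils::read.table(map_file, header = FALSE,
                      colClasses = c("character", "character",
                                     "numeric", "integer"))
  }
  nv <- nrow(map_raw)
  ped <- utils::read.table(ped_file, header = FALSE,
                           colClasses = "character")
  if (ncol(ped) != 6 + 2 * nv)
    stop("format error: ped has ", ncol(ped), " columns, expected ",
         6 + 2 * nv, " for ", nv, " variants")
  ns <- nrow(ped)
  a_odd <- as.matrix(ped[, 6 + seq(1, 2 * nv, by = 2), drop = FALSE])
  a_evn <- as.matrix(ped[, 6 + seq(2, 2 * nv, by = 2), drop = FALSE])
  calls <- matrix(NA_integer_, ns, nv)
  a1 <- character(nv)
  a2 <- character(nv)
  for (j in seq_len(nv)) {
    al <- c(a_odd[, j], a_evn[, j])
    obs <- sort(unique(al[al != "0"]))
    if (length(obs) > 2)
      stop("format error: variant ", map_raw[j, 2], " has >2 alleles")
    # fewer than two observed alleles: pad with placeholder for A2
    a1[j] <- if (length(obs) >= 1) obs[1] else "0"
    a2[j] <- if (length(obs) == 2) obs[2] else "0"
    miss <- a_odd[, j] == "0" | a_evn[, j] == "0"
    x <- (a_odd[, j] == a1[j]) + (a_evn[, j] == a1[j])
    x[miss] <- NA_integer_
    calls[, j] <- as.integer(x)
  }
  map <- data.frame(chrom = map_raw[[1]], pos_bp = map_raw[[4]],
                    id = map_raw[[2]], a1 = a1, a2 = a2,
                    stringsAsFactors = FALSE)
  genotype_matrix(calls, map, samples_from_fam(ped[, 1:6]))
}

write_plink_ped <- function(g, path) {
  ped_file <- paste0(path, ".ped")
  map_file <- paste0(path, ".map")
  map <- g$map
  utils::write.table(
    data.frame(map$chrom, map$id, rep(0, nrow(map)), map$pos_bp),
    map_file, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  ns <- nrow(g$calls)
  nv <- ncol(g$calls)
  al <- matrix("0", ns, 2 * nv)
  for (j in seq_len(nv)) {
    x <- g$calls[, j]
    first <- ifelse(is.na(x), "0", ifelse(x >= 1, map$a1[j], map$a2[j]))
    second <- ifelse(is.na(x), "0", ifelse(x == 2, map$a1[j], map$a2[j]))
    al[, 2 * j - 1] <- first
    al[, 2 * j] <- second
  }
  out <- cbind(fam_frame(g), as.data.frame(al, stringsAsFactors = FALSE))
  utils::write.table(out, ped_file, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(ped_file, map_file))
}

read_plink_bed <- function(path) {
  bed_file <- paste0(path, ".bed")
  bim_file <- paste0(path, ".bim")
  fam_file <- paste0(path, ".fam")
  for (f in c(bed_file, bim_file, fam_file))
    if (!file.exists(f)) stop("missing file: ", f)
  bim <- if (file.info(bim_file)$size == 0) {
    data.frame(V1 = character(), V2 = character(), V3 = numeric(),
               V4 = integer(), V5 = character(), V6 = character(),
               stringsAsFactors = FALSE)
  } else {
    utils::read.table(bim_file, header = FALSE,
                      colClasses = c("character", "character", "numeric",
                                     "integer", "character", "character"))
  }
  fam <- utils::read.table(fam_file, header = FALSE,
                           colClasses = "character")
  nv <- nrow(bim)
  ns <- nrow(fam)
  bpr <- ceiling(ns / 4)  # bytes per variant, SNP-major
  con <- file(bed_file, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 3)
  if (length(magic) < 3 || magic[1] != as.raw(0x6c) ||
      magic[2] != as.raw(0x1b) || magic[3] != as.raw(0x01))
    stop("format error: not a SNP-major bed file")
  raw <- readBin(con, "raw", n = bpr * nv)
  if (length(raw) != bpr * nv)
    stop("format error: bed payload has wrong size")
  bits <- matrix(as.integer(rawToBits(raw)), nrow = 8 * bpr)
  lo <- bits[seq(1, 8 * bpr, by = 2), , drop = FALSE][seq_len(ns), ,
                                                      drop = FALSE]
  hi <- bits[seq(2, 8 * bpr, by = 2), , drop = FALSE][seq_len(ns), ,
                                                      drop = FALSE]
  code <- lo + 2L * hi  # per-sample 2-bit code, samples x variants
  # 00 -> hom A1 (2), 01 -> missing, 10 -> het (1), 11 -> hom A2 (0)
  calls <- matrix(NA_integer_, ns, nv)
  calls[code == 0L] <- 2L
  calls[code == 2L] <- 1L
  calls[code == 3L] <- 0L
  map <- data.frame(chrom = bim[[1]], pos_bp = bim[[4]], id = bim[[2]],
                    a1 = bim[[5]], a2 = bim[[6]], stringsAsFactors = FALSE)
  genotype_matrix(calls, map, samples_from_fam(fam))
}

write_plink_bed <- function(g, path) {
  bed_file <- paste0(path, ".bed")
  bim_file <- paste0(path, ".bim")
  fam_file <- paste0(path, ".fam")
  map <- g$map
  utils::write.table(
    data.frame(map$chrom, map$id, rep(0, nrow(map)), map$pos_bp,
               map$a1, map$a2),
    bim_file, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  utils::write.table(fam_frame(g), fam_file, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  ns <- nrow(g$calls)
  nv <- ncol(g$calls)
  bpr <- ceiling(ns / 4)
  # per-call 2-bit codes: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(3L, ns, nv)
  code[g$calls == 2L] <- 0L
  code[g$calls == 1L] <- 2L
  code[is.na(g$calls)] <- 1L
  bits <- matrix(0L, 8 * bpr, nv)
  bits[seq(1, 2 * ns, by = 2), ] <- code %% 2L
  bits[seq(2, 2 * ns, by = 2), ] <- code %/% 2L
  payload <- packBits(as.integer(bits), type = "raw")
  con <- file(bed_file, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(payload, con)
  invisible(c(bed_file, bim_file, fam_file))
}
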