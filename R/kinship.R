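#' Pairwise method-of-moments kinship and IBS0
#'
#' For every sample pair, estimates genomic kinship with the
#' within-family moment estimator
#' phi = (N_AaAa - 2 N_AAaa) / (N_Aa(i) + N_Aa(j)),
#' where N_AaAa counts SNPs at which both samples are heterozygous,
#' N_AAaa counts opposite-homozygote SNPs and N_Aa(i) the heterozygous
#' SNPs of sample i, all over pairwise-complete SNPs. IBS0 is the
#' opposite-homozygote proportion: near zero for parent-offspring pairs,
#' clearly positive for full siblings, which is what separates the two at
#' equal kinship.
#'
#' @param g a [genotype_matrix()]
#' @param min_snps warn when fewer SNPs than this are available
#' @return data frame: `id1`, `id2`, `n_snps` (pairwise complete),
#'   `kinship`, `ibs0`; pairs with no overlapping non-missing SNPs get
#'   `NA` and are flagged via a `flagged` attribute
#' @export
estimate_kinship <- function(g, min_snps = 1000) {
  validate_genotype_matrix(g)
  if (n_variants(g) < min_snps)
    warning("only ", n_variants(g),
            " SNPs; kinship moments may be unstable")
  X <- g$calls
  nm <- !is.na(X)
  hom0 <- nm & X == 0L
  hom2 <- nm & X == 2L
  het <- nm & X == 1L
  mode(nm) <- "numeric"; mode(hom0) <- "numeric"
  mode(hom2) <- "numeric"; mode(het) <- "numeric"
  n_pair <- tcrossprod(nm)
  n_ibs0 <- tcrossprod(hom0, hom2) + tcrossprod(hom2, hom0)
  n_hethet <- tcrossprod(het)
  het_i <- het %*% t(nm)   # het in i over sites non-missing in j
  ns <- n_samples(g)
  ut <- which(upper.tri(n_pair), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  denom <- het_i[cbind(i, j)] + het_i[cbind(j, i)]
  kin <- ifelse(denom > 0,
                (n_hethet[cbind(i, j)] - 2 * n_ibs0[cbind(i, j)]) / denom,
                NA_real_)
  ibs0 <- ifelse(n_pair[cbind(i, j)] > 0,
                 n_ibs0[cbind(i, j)] / n_pair[cbind(i, j)], NA_real_)
  out <- data.frame(id1 = g$samples$sample_id[i],
                    id2 = g$samples$sample_id[j],
                    n_snps = n_pair[cbind(i, j)],
                    kinship = kin, ibs0 = ibs0, stringsAsFactors = FALSE)
  if (any(out$n_snps == 0))
    attr(out, "flagged") <- "pair(s) with no overlapping non-missing SNPs"
  out
}

#' Select full-sibling sibships from a pairwise kinship table
#'
#' Full siblings are relative pairs with genomic kinship above `kin_min`
#' and IBS0 above `ibs0_min` (the IBS0 condition excludes
#' parent-offspring pairs, which share kinship 1/4 but essentially never
#' carry opposite homozygotes). Qualifying pairs are merged into
#' sibships by transitive closure; monozygotic-twin-like pairs
#' (kinship near 1/2) are retained, since extra trait measurements at
#' identical F improve the within-family variance estimate.
#'
#' @param pairs output of [estimate_kinship()]
#' @param kin_min,ibs0_min selection thresholds
#' @return list of `sibship` objects: each a list with `family`,
#'   `members` (>= 2 sample ids) and `mz_like` (logical: contains a
#'   kinship > 0.4 pair); components in which some member pairs fail the
#'   kinship threshold are flagged via attribute `flagged`
#' @export
select_full_sibs <- function(pairs, kin_min = 0.175, ibs0_min = 0.001) {
  ok <- !is.na(pairs$kinship) & !is.na(pairs$ibs0) &
    pairs$kinship > kin_min & pairs$ibs0 > ibs0_min
  q <- pairs[ok, , drop = FALSE]
  if (!nrow(q)) return(list())
  ids <- unique(c(q$id1, q$id2))
  comp <- stats::setNames(seq_along(ids), ids)
  # union-find by repeated relabelling (small n)
  for (k in seq_len(nrow(q))) {
    a <- comp[[q$id1[k]]]; b <- comp[[q$id2[k]]]
    if (a != b) comp[comp == b] <- a
  }
  out <- list()
  inconsistent <- character(0)
  for (cc in unique(comp)) {
    members <- names(comp)[comp == cc]
    sub <- pairs[pairs$id1 %in% members & pairs$id2 %in% members, ,
                 drop = FALSE]
    if (any(!is.na(sub$kinship) & sub$kinship <= kin_min))
      inconsistent <- c(inconsistent, paste(members, collapse = "+"))
    out[[length(out) + 1L]] <- structure(
      list(family = sprintf("SIB%03d", length(out) + 1L),
           members = members,
           mz_like = any(sub$kinship > 0.4, na.rm = TRUE)),
      class = "sibship")
  }
  if (length(inconsistent))
    attr(out, "flagged") <- paste("inconsistent component(s):",
                                  paste(inconsistent, collapse = "; "))
  out
}

#' Sibships from pedigree labels
#'
#' Convenience for simulated cohorts where both parents are known:
#' samples sharing both parent ids form a sibship.
#'
#' @param samples sample table with `father_id`/`mother_id`
#' @return list of `sibship` objects (families of size >= 2 only)
#' @export
sibships_from_pedigree <- function(samples) {
  key <- paste(samples$father_id, samples$mother_id)
  key[is.na(samples$father_id)] <- NA
  out <- list()
  for (k in unique(key[!is.na(key)])) {
    members <- samples$sample_id[!is.na(key) & key == k]
    if (length(members) >= 2)
      out[[length(out) + 1L]] <- structure(
        list(family = sprintf("SIB%03d", length(out) + 1L),
             members = members, mz_like = FALSE), class = "sibship")
  }
  out
}

#' Within-sibling effect of F_ROH
#'
#' Both F_ROH and the trait residual are expressed as deviations from the
#' family mean; since sibling differences in autozygosity arise purely
#' from Mendelian segregation, the resulting slope is free of any shared
#' family or social confounding. The regression is a least-squares fit of
#' residual deviations on F deviations through the origin (deviations sum
#' to zero by construction); family-clustered standard errors are
#' reported alongside the naive ones. Optionally an intercept can be
#' included via `intercept = TRUE` (it is estimated at ~0).
#'
#' @param eps residual trait for all samples (named or aligned with
#'   `sample_ids`)
#' @param f_roh per-sample F_ROH aligned with `sample_ids`
#' @param sibships list of sibships from [select_full_sibs()] or
#'   [sibships_from_pedigree()]
#' @param sample_ids ids aligning `eps`/`f_roh`
#' @param intercept include an intercept in the deviation regression
#' @return one-row effect data frame with tag `within_sibs` and an extra
#'   `se_cluster` column
#' @export
within_sib_effect <- function(eps, f_roh, sibships, sample_ids,
                              intercept = FALSE) {
  e <- eps_vector(eps)
  stopifnot(length(e) == length(sample_ids),
            length(f_roh) == length(sample_ids))
  if (!length(sibships)) stop("no sibships supplied")
  names(e) <- sample_ids
  names(f_roh) <- sample_ids
  dev_f <- numeric(0); dev_e <- numeric(0); fam <- character(0)
  for (s in sibships) {
    m <- intersect(s$members, sample_ids)
    if (length(m) < 2) next
    dev_f <- c(dev_f, f_roh[m] - mean(f_roh[m]))
    dev_e <- c(dev_e, e[m] - mean(e[m]))
    fam <- c(fam, rep(s$family, length(m)))
  }
  if (length(fam) < 2)
    stop("no sibship with at least 2 phenotyped members")
  if (sum(dev_f^2) == 0)
    stop("no within-family F_ROH variance (all siblings identical)")
  fit <- if (intercept) stats::lm(dev_e ~ dev_f) else
    stats::lm(dev_e ~ dev_f - 1)
  cf <- summary(fit)$coefficients
  beta <- cf["dev_f", 1]
  se_naive <- cf["dev_f", 2]
  # family-clustered (CR0) sandwich se for the slope
  u <- stats::resid(fit) * dev_f
  meat <- sum(tapply(u, fam, sum)^2)
  bread <- sum(dev_f^2)
  se_cluster <- sqrt(meat) / bread
  new_effect(beta, se_naive, length(dev_e), "within_sibs",
             extra = data.frame(se_cluster = se_cluster,
                                n_families = length(unique(fam))))
}
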