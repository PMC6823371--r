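#' Run configuration for the per-cohort analysis
#'
#' @param roh a [roh_params()] list
#' @param genome_size_bp F_ROH denominator; `NULL` means take it from the
#'   cohort bundle's genetic map (3e9 for real human data)
#' @param covariates phenotype columns used as fixed covariates
#' @param traits quantitative trait columns to analyse
#' @param binary_traits binary (0/1) trait columns to analyse
#' @param bin_bounds F_ROH bin bounds for the binned-mean analysis
#' @param use_grm estimate mixed-model (REML/BLUP) residuals with a GRM
#'   built from the array SNPs instead of plain least squares
#' @param qc apply [qc_filter()] before analysis
#' @param subset optional logical vector or function(samples) selecting a
#'   sample subgroup (adoptee-style subgroup analyses)
#' @return a `run_config` list
#' @export
run_config <- function(roh = roh_params(), genome_size_bp = NULL,
                       covariates = c("age", "sex"), traits = "y",
                       binary_traits = character(0),
                       bin_bounds = froh_bin_bounds(),
                       use_grm = FALSE, qc = TRUE, subset = NULL) {
  structure(as.list(environment()), class = "run_config")
}

covariate_design <- function(phen, covariates) {
  cols <- lapply(covariates, function(nm) {
    v <- phen[[nm]]
    if (is.null(v)) stop("covariate column missing: ", nm)
    if (is.character(v) || is.factor(v))
      as.numeric(as.character(v) == "male") else as.numeric(v)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariates
  # constant columns (e.g. sex within a single-sex subgroup) are dropped
  keep <- apply(X, 2, function(v) stats::var(v) > 0)
  cbind(`(Intercept)` = 1, X[, keep, drop = FALSE])
}

# GRM from standardized genotypes (mean imputation for missing calls)
compute_grm <- function(g) {
  p <- allele_frequencies(g)
  poly <- !is.na(p$p) & p$p > 0 & p$p < 1
  X <- g$calls[, poly, drop = FALSE]
  pv <- p$p[poly]
  Z <- sweep(X, 2, 2 * pv)
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, sqrt(2 * pv * (1 - pv)), "/")
  A <- tcrossprod(Z) / ncol(Z)
  dimnames(A) <- list(g$samples$sample_id, g$samples$sample_id)
  A
}

#' Analyse one cohort end to end
#'
#' Executes the per-cohort stages on a simulated bundle (or any object
#' with the same fields): QC filtering, ROH calling, inbreeding profiles,
#' residualization, and all configured effect models per trait:
#' univariate regressions on F_ROH / F_SNP / F_GRM, the partitioned and
#' bivariate models, binary logit and scaled-linear estimates,
#' sex-specific fits, the within-sibling estimator (when sibships exist)
#' and the binned-mean summaries. No stage mutates its inputs and the
#' run is deterministic.
#'
#' @param bundle a `cohort_bundle` from [simulate_cohort()], or a list
#'   with `genotypes` (a [genotype_matrix()]) and `phenotypes`
#' @param config a [run_config()]
#' @param cohort_id label recorded in the results
#' @return a `cohort_results` list: `results` (one row per trait x model:
#'   `cohort`, `trait`, `model_tag`, `beta`, `se`, `n`, ...), `bins`
#'   (per-trait bin tables), `profiles`, `qc_report`, `log`
#' @export
run_cohort <- function(bundle, config = run_config(), cohort_id = "cohort1") {
  g <- bundle$genotypes
  phen <- bundle$phenotypes
  miss <- setdiff(phen$sample_id, g$samples$sample_id)
  extra <- setdiff(g$samples$sample_id, phen$sample_id)
  if (length(miss) || length(extra))
    stop("sample id mismatch between genotypes and phenotypes; ",
         "phenotype-only: [", paste(miss, collapse = ", "),
         "]; genotype-only: [", paste(extra, collapse = ", "), "]")
  phen <- phen[match(g$samples$sample_id, phen$sample_id), , drop = FALSE]
  log <- list()
  if (!is.null(config$subset)) {
    keep <- if (is.function(config$subset)) config$subset(g$samples) else
      config$subset
    g <- genotype_matrix(g$calls[keep, , drop = FALSE], g$map,
                         g$samples[keep, , drop = FALSE])
    phen <- phen[keep, , drop = FALSE]
    log$subset <- sum(keep)
  }
  qc_report <- NULL
  if (isTRUE(config$qc)) {
    qc <- qc_filter(g)
    qc_report <- qc$report
    kept <- qc$genotypes$samples$sample_id
    phen <- phen[match(kept, phen$sample_id), , drop = FALSE]
    g <- qc$genotypes
    log$qc <- c(samples = n_samples(g), snps = n_variants(g))
  }
  genome_size <- config$genome_size_bp %||%
    (if (!is.null(bundle$gmap)) bundle$gmap$genome_size_bp else 3e9)
  segments <- call_roh(g, config$roh)
  log$roh_segments <- nrow(segments)
  profiles <- inbreeding_profile(g, segments, genome_size)
  X <- covariate_design(phen, config$covariates)
  A <- if (isTRUE(config$use_grm)) compute_grm(g) else NULL
  sibs <- sibships_from_pedigree(g$samples)

  res_rows <- list()
  bins <- list()
  add <- function(rows, trait) {
    rows$trait <- trait
    rows$cohort <- cohort_id
    res_rows[[length(res_rows) + 1L]] <<- rows
  }
  for (tr in config$traits) {
    y <- phen[[tr]]
    if (is.null(y)) stop("trait column missing: ", tr)
    eps <- if (is.null(A)) residualize(y, X) else
      grammar_residuals(y, X, A)
    uni <- fit_univariate(eps, profiles$f_roh, "uni_froh")
    add(uni, tr)
    add(fit_univariate(eps, profiles$f_snp, "uni_fsnp"), tr)
    add(fit_univariate(eps, profiles$f_grm, "uni_fgrm"), tr)
    add(fit_partitioned(eps, profiles$f_snp_outside_roh,
                        profiles$f_roh_lt5, profiles$f_roh_gt5), tr)
    add(fit_bivariate(eps, profiles$f_roh, profiles$f_grm), tr)
    for (sx in c("male", "female")) {
      in_sx <- g$samples$sex == sx
      if (sum(in_sx) >= 3 && stats::var(profiles$f_roh[in_sx]) > 0) {
        bx <- fit_univariate(eps$eps[in_sx], profiles$f_roh[in_sx],
                             paste0("by_sex:", sx))
        add(bx, tr)
      }
    }
    if (length(sibs) >= 2) {
      ws <- try(within_sib_effect(eps, profiles$f_roh, sibs,
                                  g$samples$sample_id), silent = TRUE)
      if (!inherits(ws, "try-error")) add(ws, tr)
    }
    bins[[tr]] <- bin_trait_means(eps, uni$intercept, profiles$f_roh,
                                  config$bin_bounds)
  }
  for (tr in config$binary_traits) {
    y <- phen[[tr]]
    if (is.null(y)) stop("binary trait column missing: ", tr)
    bl <- try(fit_binary(y, profiles$f_roh, X, "logit"), silent = TRUE)
    if (!inherits(bl, "try-error")) add(bl, tr)
    la <- try(fit_binary(y, profiles$f_roh, X, "linapprox"),
              silent = TRUE)
    if (!inherits(la, "try-error")) add(la, tr)
  }
  results <- do.call(rbind_fill, res_rows)
  first <- c("cohort", "trait", "model_tag", "beta", "se", "n")
  results <- results[, c(first, setdiff(names(results), first))]
  structure(list(results = results, bins = bins, profiles = profiles,
                 segments = segments, qc_report = qc_report, log = log,
                 schema = "autozyg-results-v1"),
            class = "cohort_results")
}

# rbind data frames with unequal columns (missing filled with NA)
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  out <- lapply(dfs, function(d) {
    for (nm in setdiff(cols, names(d))) d[[nm]] <- NA
    d[, cols, drop = FALSE]
  })
  do.call(rbind, out)
}

#' Meta-analyse a set of per-cohort results
#'
#' Pools every (trait, model tag) estimate class present across cohorts
#' by fixed-effect inverse-variance meta-analysis, and pools the binned
#' trait means. Estimate classes absent from all cohorts are skipped
#' with a warning.
#'
#' @param cohort_results list of [run_cohort()] outputs
#' @param expected_tags estimate classes expected (defaults to all
#'   produced tags); absent ones trigger the warning
#' @return list with `effects` (pooled one row per trait x tag) and
#'   `bins` (per-trait pooled bin tables)
#' @export
run_meta <- function(cohort_results, expected_tags = NULL) {
  stopifnot(length(cohort_results) >= 1)
  schemas <- vapply(cohort_results, function(cr) cr$schema %||% "?", "")
  if (length(unique(schemas)) > 1)
    stop("results schema version mismatch: ",
         paste(unique(schemas), collapse = " vs "))
  all_res <- do.call(rbind, lapply(cohort_results, `[[`, "results"))
  if (!is.null(expected_tags)) {
    absent <- setdiff(expected_tags, unique(all_res$model_tag))
    if (length(absent))
      warning("estimate class(es) absent from all cohorts: ",
              paste(absent, collapse = ", "))
  }
  keys <- unique(all_res[, c("trait", "model_tag")])
  pooled <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- all_res[all_res$trait == keys$trait[i] &
                     all_res$model_tag == keys$model_tag[i], ]
    sub <- sub[!is.na(sub$beta) & !is.na(sub$se) & sub$se > 0, ]
    if (!nrow(sub)) return(NULL)
    ivw_meta(sub)
  })
  effects <- do.call(rbind, pooled)
  traits <- unique(unlist(lapply(cohort_results,
                                 function(cr) names(cr$bins))))
  bins <- lapply(stats::setNames(traits, traits), function(tr) {
    bl <- lapply(cohort_results, function(cr) cr$bins[[tr]])
    bl <- bl[!vapply(bl, is.null, TRUE)]
    meta_bins(bl)
  })
  list(effects = effects, bins = bins)
}

#' Write a per-cohort results TSV
#' @param cr a [run_cohort()] result
#' @param path output file
#' @return invisibly, the path
#' @export
write_cohort_results <- function(cr, path) {
  utils::write.table(cr$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
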