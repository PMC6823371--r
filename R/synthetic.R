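#' Pedigree designs for simulated consanguineous cohorts
#'
#' Describes how many families of each consanguineous mating type to
#' simulate and how many full siblings each union produces. Offspring of
#' the six supported unions have expected autozygosity equal to the
#' kinship of their parents: 0 (unrelated), 1/64 (second cousins), 1/16
#' (first cousins), 1/8 (avuncular), 1/4 (full siblings) and 1/4
#' (parent-offspring).
#'
#' @param matings named integer vector: families per mating type. Names
#'   must come from `names(mating_expected_f())`.
#' @param sibs_per_family offspring per union (all full siblings)
#' @return a `pedigree_design` list
#' @export
pedigree_design <- function(matings = c(first_cousin = 100),
                            sibs_per_family = 1) {
  known <- names(mating_expected_f())
  if (is.null(names(matings)) || !all(names(matings) %in% known))
    stop("mating types must be among: ", paste(known, collapse = ", "))
  stopifnot(all(matings >= 0), sibs_per_family >= 1)
  structure(list(matings = matings, sibs_per_family = sibs_per_family),
            class = "pedigree_design")
}

#' Expected offspring autozygosity by mating type
#' @return named numeric vector of pedigree expectations
#' @export
mating_expected_f <- function() {
  c(unrelated = 0, second_cousin = 1 / 64, first_cousin = 1 / 16,
    avuncular = 1 / 8, full_sib = 1 / 4, parent_offspring = 1 / 4)
}

# founders needed to seed one family of each type
founders_per_family <- c(unrelated = 2, second_cousin = 6, first_cousin = 4,
                         avuncular = 3, full_sib = 2, parent_offspring = 2)

#' Genetic map for the simulator
#'
#' A uniform physical/genetic map: equal-length chromosomes and a constant
#' recombination rate, so pedigree expectations stay analytic. The default
#' is a downscaled genome of 22 chromosomes of 50 Mb.
#'
#' @param n_chr number of autosomes
#' @param chr_length_bp chromosome length in base pairs
#' @param rate_cM_Mb recombination rate, centimorgan per megabase
#' @return a `genetic_map` list with `chrom`, `length_bp`, `rate_cM_Mb`
#'   and `genome_size_bp`
#' @export
genetic_map <- function(n_chr = 22, chr_length_bp = 5e7, rate_cM_Mb = 1.0) {
  stopifnot(n_chr >= 1, chr_length_bp > 0, rate_cM_Mb >= 0)
  structure(list(chrom = as.character(seq_len(n_chr)),
                 length_bp = rep(chr_length_bp, n_chr),
                 rate_cM_Mb = rate_cM_Mb,
                 genome_size_bp = n_chr * chr_length_bp),
            class = "genetic_map")
}

#' Build a variant map with evenly sampled SNP positions
#'
#' @param gmap a [genetic_map()]
#' @param snps_per_chr SNPs per chromosome, placed uniformly at random
#' @param prefix id prefix
#' @return a variant map data frame (`chrom`, `pos_bp`, `id`, `a1`, `a2`)
#' @export
random_variant_map <- function(gmap, snps_per_chr = 1000, prefix = "snp") {
  maps <- lapply(seq_along(gmap$chrom), function(ci) {
    pos <- sort(sample.int(gmap$length_bp[ci], snps_per_chr))
    data.frame(chrom = gmap$chrom[ci], pos_bp = pos,
               id = sprintf("%s_%s_%d", prefix, gmap$chrom[ci],
                            seq_len(snps_per_chr)),
               a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

#' Simulate a pool of founder haplotypes
#'
#' Haplotype alleles are drawn independently per site at frequencies
#' sampled from `maf_spectrum` (no linkage disequilibrium among founders);
#' each founder haplotype carries a unique ancestral label used for
#' identity-by-descent tracking downstream.
#'
#' @param n number of founder individuals (2n haplotypes)
#' @param map variant map data frame
#' @param maf_spectrum list describing the counted-allele frequency
#'   distribution: `list(dist = "uniform", min, max)`,
#'   `list(dist = "beta", shape1, shape2, min, max)` or
#'   `list(dist = "fixed", p)`.
#' @param seed integer seed
#' @return a `founder_pool` list with `haps` (2n x variants 0/1 matrix),
#'   `freq` (sampled counted-allele frequencies), `map` and `n`
#' @export
simulate_founders <- function(n, map,
                              maf_spectrum = list(dist = "uniform",
                                                  min = 0.05, max = 0.5),
                              seed = 1) {
  stopifnot(n >= 2)
  set.seed(seed)
  nv <- nrow(map)
  freq <- sample_maf_spectrum(maf_spectrum, nv)
  if (all(freq <= 0 | freq >= 1))
    stop("degenerate frequency spectrum: all frequencies 0 or 1")
  haps <- matrix(stats::rbinom(2 * n * nv, 1L,
                               rep(freq, each = 2 * n)), nrow = 2 * n)
  storage.mode(haps) <- "integer"
  structure(list(haps = haps, freq = freq, map = map, n = n),
            class = "founder_pool")
}

sample_maf_spectrum <- function(spec, nv) {
  dist <- spec$dist %||% "uniform"
  switch(dist,
         uniform = stats::runif(nv, spec$min %||% 0.05, spec$max %||% 0.5),
         beta = {
           lo <- spec$min %||% 0
           hi <- spec$max %||% 1
           p <- stats::rbeta(nv, spec$shape1 %||% 0.5, spec$shape2 %||% 0.5)
           pmin(pmax(p, lo), hi)
         },
         fixed = rep(spec$p, nv),
         stop("unknown maf_spectrum dist: ", dist))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- haplotype machinery ---------------------------------------------------
# A haplotype is, per chromosome, a 3-column matrix (start, end, src)
# tiling [1, L] in 1-based inclusive coordinates; src is the ancestral
# founder haplotype label. A plain matrix keeps the many small meiosis
# operations fast.
founder_individual <- function(idx, gmap) {
  # idx: founder number; haplotype labels 2*idx-1 and 2*idx
  one <- function(lab) {
    lapply(seq_along(gmap$chrom), function(ci)
      matrix(c(1, gmap$length_bp[ci], lab), nrow = 1,
             dimnames = list(NULL, c("start", "end", "src"))))
  }
  list(h1 = one(2L * idx - 1L), h2 = one(2L * idx))
}

# recombine two parental chromosome haplotypes into one gamete chromosome
gamete_chrom <- function(seg1, seg2, L, rate_cM_Mb) {
  n_x <- stats::rpois(1, L / 1e6 * rate_cM_Mb / 100)
  cur <- sample.int(2L, 1L)
  if (n_x == 0) return(if (cur == 1L) seg1 else seg2)
  xpos <- sort(stats::runif(n_x, 1, L))
  bounds <- c(1, floor(xpos) + 1, L + 1)
  parts <- vector("list", length(bounds) - 1)
  for (i in seq_len(length(bounds) - 1)) {
    s <- bounds[i]; e <- bounds[i + 1] - 1
    if (e < s) { cur <- 3L - cur; next }
    seg <- if (cur == 1L) seg1 else seg2
    keep <- seg[, 2L] >= s & seg[, 1L] <= e
    sub <- seg[keep, , drop = FALSE]
    sub[, 1L] <- pmax(sub[, 1L], s)
    sub[, 2L] <- pmin(sub[, 2L], e)
    parts[[i]] <- sub
    cur <- 3L - cur
  }
  out <- do.call(rbind, parts)
  merge_adjacent_segments(out)
}

merge_adjacent_segments <- function(seg) {
  n <- nrow(seg)
  if (n <= 1) return(seg)
  new_run <- c(TRUE, seg[-1, 3L] != seg[-n, 3L] |
                 seg[-1, 1L] != seg[-n, 2L] + 1)
  last <- c(which(new_run)[-1] - 1, n)
  cbind(start = seg[new_run, 1L], end = seg[last, 2L],
        src = seg[new_run, 3L])
}

meiosis <- function(ind, gmap) {
  lapply(seq_along(gmap$chrom), function(ci)
    gamete_chrom(ind$h1[[ci]], ind$h2[[ci]], gmap$length_bp[ci],
                 gmap$rate_cM_Mb))
}

make_child <- function(pa, pb, gmap) {
  list(h1 = meiosis(pa, gmap), h2 = meiosis(pb, gmap))
}

# build the two consanguineous parents for one family; founders are taken
# from the pool starting at founder index `at`
build_parents <- function(type, at, gmap) {
  f <- function(k) founder_individual(at + k - 1L, gmap)
  switch(type,
    unrelated = list(p1 = f(1), p2 = f(2), used = 2L),
    full_sib = {
      a <- f(1); b <- f(2)
      list(p1 = make_child(a, b, gmap), p2 = make_child(a, b, gmap),
           used = 2L)
    },
    parent_offspring = {
      a <- f(1); b <- f(2)
      list(p1 = a, p2 = make_child(a, b, gmap), used = 2L)
    },
    avuncular = {
      a <- f(1); b <- f(2); sp <- f(3)
      s1 <- make_child(a, b, gmap)  # uncle/aunt
      s2 <- make_child(a, b, gmap)
      niece <- make_child(s2, sp, gmap)
      list(p1 = s1, p2 = niece, used = 3L)
    },
    first_cousin = {
      gp1 <- f(1); gp2 <- f(2); sp1 <- f(3); sp2 <- f(4)
      s1 <- make_child(gp1, gp2, gmap)
      s2 <- make_child(gp1, gp2, gmap)
      c1 <- make_child(s1, sp1, gmap)
      c2 <- make_child(s2, sp2, gmap)
      list(p1 = c1, p2 = c2, used = 4L)
    },
    second_cousin = {
      gg1 <- f(1); gg2 <- f(2)
      spa <- f(3); spb <- f(4); spc <- f(5); spd <- f(6)
      s1 <- make_child(gg1, gg2, gmap)
      s2 <- make_child(gg1, gg2, gmap)
      g1 <- make_child(s1, spa, gmap)
      g2 <- make_child(s2, spb, gmap)
      c1 <- make_child(g1, spc, gmap)
      c2 <- make_child(g2, spd, gmap)
      list(p1 = c1, p2 = c2, used = 6L)
    },
    stop("unknown mating type: ", type))
}

# genotype one individual at the SNPs of `map` given the founder pool
genotypes_from_haps <- function(ind, founders, gmap) {
  map <- founders$map
  x <- integer(nrow(map))
  for (ci in seq_along(gmap$chrom)) {
    idx <- which(map$chrom == gmap$chrom[ci])
    if (!length(idx)) next
    pos <- map$pos_bp[idx]
    src1 <- seg_src_at(ind$h1[[ci]], pos)
    src2 <- seg_src_at(ind$h2[[ci]], pos)
    x[idx] <- founders$haps[cbind(src1, idx)] +
      founders$haps[cbind(src2, idx)]
  }
  x
}

seg_src_at <- function(seg, pos) {
  seg[findInterval(pos, seg[, 1L]), 3L]
}

# autozygous spans: intervals where both haplotypes carry the same
# ancestral label
autozygous_segments <- function(ind, gmap) {
  out <- vector("list", length(gmap$chrom))
  for (ci in seq_along(gmap$chrom)) {
    h1 <- ind$h1[[ci]]; h2 <- ind$h2[[ci]]
    starts <- sort(unique(c(h1[, 1L], h2[, 1L])))
    ends <- c(starts[-1] - 1, gmap$length_bp[ci])
    s1 <- seg_src_at(h1, starts)
    s2 <- seg_src_at(h2, starts)
    ibd <- s1 == s2
    if (!any(ibd)) next
    seg <- merge_adjacent_segments(
      cbind(start = starts[ibd], end = ends[ibd], src = 1))
    out[[ci]] <- data.frame(chrom = gmap$chrom[ci],
                            start_bp = seg[, 1L], end_bp = seg[, 2L],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Gene-drop founder haplotypes through consanguineous pedigrees
#'
#' Gametes are formed with Poisson crossovers at the map rate (no
#' interference); an offspring genotype is the sum of its two transmitted
#' haplotypes, and the IBD truth marks every span where both transmitted
#' haplotypes descend from the same founder haplotype. Siblings within a
#' family share both parents, so their autozygosity differs only through
#' Mendelian segregation.
#'
#' @param design a [pedigree_design()]
#' @param founders a [simulate_founders()] pool
#' @param gmap a [genetic_map()]
#' @param seed integer seed
#' @return list with `genotypes` (a [genotype_matrix()] of the offspring),
#'   `truth` (data frame `sample_id`, `chrom`, `start_bp`, `end_bp` of
#'   autozygous segments) and `samples` (offspring table with
#'   `mating_type` and `expected_f`)
#' @export
gene_drop <- function(design, founders, gmap, seed = 1) {
  stopifnot(inherits(design, "pedigree_design"),
            inherits(founders, "founder_pool"),
            inherits(gmap, "genetic_map"))
  set.seed(seed)
  need <- sum(founders_per_family[names(design$matings)] * design$matings)
  if (founders$n < need)
    stop("not enough founders: need ", need, ", have ", founders$n)
  exp_f <- mating_expected_f()
  at <- 1L
  fam_i <- 0L
  geno_rows <- list()
  truth_rows <- list()
  samp_rows <- list()
  for (type in names(design$matings)) {
    for (k in seq_len(design$matings[[type]])) {
      fam_i <- fam_i + 1L
      par <- build_parents(type, at, gmap)
      at <- at + par$used
      fam_id <- sprintf("F%04d", fam_i)
      for (s in seq_len(design$sibs_per_family)) {
        child <- make_child(par$p1, par$p2, gmap)
        sid <- sprintf("%s_%d", fam_id, s)
        geno_rows[[sid]] <- genotypes_from_haps(child, founders, gmap)
        tr <- autozygous_segments(child, gmap)
        if (!is.null(tr) && nrow(tr))
          truth_rows[[sid]] <- cbind(sample_id = sid, tr)
        samp_rows[[sid]] <- data.frame(
          sample_id = sid, family_id = fam_id,
          father_id = paste0(fam_id, "_p1"),
          mother_id = paste0(fam_id, "_p2"),
          sex = sample(c("male", "female"), 1),
          mating_type = type, expected_f = exp_f[[type]],
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- do.call(rbind, geno_rows)
  samples <- do.call(rbind, samp_rows)
  rownames(samples) <- NULL
  truth <- if (length(truth_rows)) {
    tr <- do.call(rbind, truth_rows)
    rownames(tr) <- NULL
    tr
  } else {
    data.frame(sample_id = character(), chrom = character(),
               start_bp = numeric(), end_bp = numeric(),
               stringsAsFactors = FALSE)
  }
  g <- genotype_matrix(calls, founders$map, samples)
  list(genotypes = g, truth = truth, samples = samples)
}

#' True autozygous genome fraction from IBD truth segments
#'
#' @param truth truth data frame from [gene_drop()]
#' @param genome_size_bp autosomal genome length used as denominator
#' @param sample_ids optional ids to report (zeros for samples without
#'   segments)
#' @return named numeric vector of per-sample fractions
#' @export
true_autozygosity <- function(truth, genome_size_bp, sample_ids = NULL) {
  stopifnot(genome_size_bp > 0)
  if (is.null(sample_ids)) sample_ids <- unique(truth$sample_id)
  out <- stats::setNames(numeric(length(sample_ids)), sample_ids)
  if (nrow(truth)) {
    len <- truth$end_bp - truth$start_bp + 1
    agg <- tapply(len, truth$sample_id, sum)
    hit <- intersect(names(agg), sample_ids)
    out[hit] <- agg[hit] / genome_size_bp
  }
  out
}

# ---- trait simulation ------------------------------------------------------

#' Specify a generative trait architecture
#'
#' Operationalises the directional-dominance mechanism: rare recessive
#' loci each depress the trait by `d` when homozygous for the deleterious
#' (counted) allele. The theoretical inbreeding load is
#' B = sum over loci of |d| q (1 - q); the expected regression slope of
#' the trait on true autozygosity is -B (for deleterious `d < 0`).
#'
#' @param recessive data frame `id`, `q`, `d`: causal locus ids (variant
#'   ids in the causal genotype matrix), deleterious-allele frequencies and
#'   homozygous deviations (deleterious loci have `d < 0`)
#' @param additive data frame `id`, `effect` of additive loci (optional)
#' @param covariates named numeric vector of covariate effects; a standard
#'   normal covariate is generated per name ("sex" uses the 0/1 male
#'   indicator instead)
#' @param intercept trait intercept
#' @param resid_sd residual standard deviation
#' @param sex_multiplier named numeric `c(male=, female=)` scaling of the
#'   recessive (inbreeding) term per sex
#' @param binary `NULL` for a quantitative trait, or
#'   `list(base_prev =, lnor_per_f =)` for a binary trait drawn from a
#'   logistic model with the stated ln(odds ratio) per unit autozygosity
#' @param confounder `NULL`, or `list(sd =, effect =, cor =)`: a
#'   family-level variable with correlation `cor` to the parental-mating
#'   expected autozygosity, affecting the trait by `effect` per sd
#' @return a `trait_model` list
#' @export
trait_model <- function(recessive = NULL, additive = NULL,
                        covariates = c(age = 0, sex = 0),
                        intercept = 0, resid_sd = 1,
                        sex_multiplier = c(male = 1, female = 1),
                        binary = NULL, confounder = NULL) {
  if (!is.null(recessive))
    stopifnot(all(recessive$q > 0), all(recessive$q < 1))
  structure(list(recessive = recessive, additive = additive,
                 covariates = covariates, intercept = intercept,
                 resid_sd = resid_sd, sex_multiplier = sex_multiplier,
                 binary = binary, confounder = confounder),
            class = "trait_model")
}

#' Theoretical inbreeding load of a trait model
#' @param model a [trait_model()]
#' @return B = sum |d| q (1-q) over recessive loci
#' @export
trait_load <- function(model) {
  if (is.null(model$recessive)) return(0)
  with(model$recessive, sum(abs(d) * q * (1 - q)))
}

#' Simulate phenotypes on top of gene-dropped genotypes
#'
#' @param genotypes a [genotype_matrix()] carrying the causal loci named in
#'   the model (typically the full matrix from [gene_drop()] before the
#'   causal loci are hidden from the emitted SNP array)
#' @param model a [trait_model()]
#' @param seed integer seed
#' @param f_true per-sample true autozygosity (needed for binary traits)
#' @param expected_f per-sample parental-mating expected autozygosity
#'   (needed when the model has a confounder)
#' @param trait_name column name of the simulated trait
#' @return phenotype data frame: `sample_id`, `family_id`, `sex`,
#'   generated covariates, `confounder` (if any) and the trait column
#' @export
simulate_traits <- function(genotypes, model, seed = 1, f_true = NULL,
                            expected_f = NULL, trait_name = "y") {
  stopifnot(inherits(model, "trait_model"))
  set.seed(seed)
  s <- genotypes$samples
  n <- nrow(s)
  eta <- rep(model$intercept, n)
  out <- data.frame(sample_id = s$sample_id, family_id = s$family_id,
                    sex = s$sex, stringsAsFactors = FALSE)
  # generated covariates
  for (nm in names(model$covariates)) {
    z <- if (nm == "sex") as.numeric(s$sex == "male") else stats::rnorm(n)
    out[[nm]] <- z
    eta <- eta + model$covariates[[nm]] * z
  }
  # recessive (directional-dominance) term, sex-scaled
  if (!is.null(model$recessive)) {
    idx <- match(model$recessive$id, genotypes$map$id)
    if (anyNA(idx))
      stop("causal loci missing from genotypes: ",
           paste(model$recessive$id[is.na(idx)], collapse = ", "))
    hom <- genotypes$calls[, idx, drop = FALSE] == 2L
    dom <- hom %*% model$recessive$d
    mult <- model$sex_multiplier[s$sex]
    mult[is.na(mult)] <- 1
    eta <- eta + as.numeric(dom) * mult
  }
  if (!is.null(model$additive)) {
    idx <- match(model$additive$id, genotypes$map$id)
    if (anyNA(idx)) stop("additive loci missing from genotypes")
    eta <- eta +
      as.numeric(genotypes$calls[, idx, drop = FALSE] %*%
                   model$additive$effect)
  }
  if (!is.null(model$confounder)) {
    if (is.null(expected_f))
      stop("confounder requires per-sample expected_f")
    cf <- model$confounder
    fam <- s$family_id
    fam_first <- !duplicated(fam)
    ef <- expected_f[fam_first]
    z_f <- if (stats::sd(ef) > 0) as.numeric(scale(ef)) else rep(0, sum(fam_first))
    noise <- stats::rnorm(sum(fam_first))
    z_fam <- cf$cor * z_f + sqrt(max(0, 1 - cf$cor^2)) * noise
    z <- z_fam[match(fam, fam[fam_first])]
    out$confounder <- cf$sd * z
    eta <- eta + cf$effect * z
  }
  if (is.null(model$binary)) {
    out[[trait_name]] <- eta + stats::rnorm(n, 0, model$resid_sd)
  } else {
    if (is.null(f_true))
      stop("binary trait requires per-sample true autozygosity f_true")
    lin <- stats::qlogis(model$binary$base_prev) +
      model$binary$lnor_per_f * f_true[s$sample_id] + (eta - model$intercept)
    out[[trait_name]] <- stats::rbinom(n, 1L, stats::plogis(lin))
  }
  out
}

# ---- cohort assembly -------------------------------------------------------

#' Configuration for a simulated cohort
#'
#' Defaults describe a desk-scale consanguineous cohort on a downscaled
#' genome (22 x 50 Mb, 1 cM/Mb): a mix of unions spanning expected
#' autozygosity 0 to 0.25, an array of common SNPs (in-sample MAF drawn
#' uniformly on 0.05-0.5), and rare recessive causal loci that are
#' excluded from the emitted SNP array, mimicking untyped rare variants.
#'
#' @param matings named vector of family counts per mating type
#' @param sibs_per_family siblings per union
#' @param n_chr,chr_length_bp,rate_cM_Mb genetic map, see [genetic_map()]
#' @param snps_per_chr array SNPs per chromosome
#' @param maf_spectrum array-SNP frequency spectrum, see
#'   [simulate_founders()]
#' @param n_causal number of rare recessive causal loci
#' @param causal_q_range deleterious-allele frequency range of causal loci
#' @param load_b total inbreeding load B in trait units
#' @param resid_sd,covariate_effects,sex_multiplier,confounder,binary
#'   trait-model settings, see [trait_model()]
#' @param keep_causal keep causal loci in the emitted array (default
#'   FALSE: ROH is the only signal path)
#' @return a `cohort_config` list
#' @export
cohort_config <- function(matings = c(unrelated = 40, second_cousin = 20,
                                      first_cousin = 60, avuncular = 20,
                                      full_sib = 10),
                          sibs_per_family = 1,
                          n_chr = 22, chr_length_bp = 5e7, rate_cM_Mb = 1.0,
                          snps_per_chr = 1000,
                          maf_spectrum = list(dist = "uniform",
                                              min = 0.05, max = 0.5),
                          n_causal = 200,
                          causal_q_range = c(0.005, 0.05),
                          load_b = 16,
                          resid_sd = 1,
                          covariate_effects = c(age = 0.5, sex = 0.5),
                          sex_multiplier = c(male = 1, female = 1),
                          confounder = NULL,
                          binary = NULL,
                          keep_causal = FALSE) {
  structure(as.list(environment()), class = "cohort_config")
}

derive_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + stage
}

#' Simulate a complete cohort bundle
#'
#' Composes [simulate_founders()], [gene_drop()] and [simulate_traits()]
#' into a cohort with known autozygosity and trait architecture:
#' genotypes (causal loci hidden by default), IBD truth, phenotypes,
#' sibship labels and the full configuration. Deterministic given `seed`.
#'
#' @param config a [cohort_config()]
#' @param seed master seed; per-stage streams are derived from it and
#'   logged in the bundle
#' @return a `cohort_bundle` list: `genotypes`, `causal_genotypes`,
#'   `truth`, `phenotypes`, `samples`, `f_true`, `load_b`, `gmap`,
#'   `config`, `seeds`
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- c(map = derive_seed(seed, 1L), founders = derive_seed(seed, 2L),
             drop = derive_seed(seed, 3L), traits = derive_seed(seed, 4L))
  gmap <- genetic_map(config$n_chr, config$chr_length_bp, config$rate_cM_Mb)
  design <- pedigree_design(config$matings, config$sibs_per_family)

  set.seed(seeds[["map"]])
  array_map <- random_variant_map(gmap, config$snps_per_chr)
  causal <- NULL
  full_map <- array_map
  if (config$n_causal > 0) {
    causal_chr <- sample(gmap$chrom, config$n_causal, replace = TRUE)
    causal_map <- data.frame(
      chrom = causal_chr,
      pos_bp = vapply(causal_chr, function(ch)
        sample.int(gmap$length_bp[match(ch, gmap$chrom)], 1), numeric(1)),
      id = sprintf("causal_%d", seq_len(config$n_causal)),
      a1 = "A", a2 = "B", stringsAsFactors = FALSE)
    full_map <- rbind(array_map, causal_map)
    full_map <- full_map[order(match(full_map$chrom, gmap$chrom),
                               full_map$pos_bp), ]
    # drop coincident positions (keep first)
    dup <- duplicated(full_map[, c("chrom", "pos_bp")])
    full_map <- full_map[!dup, ]
    rownames(full_map) <- NULL
    q <- stats::runif(config$n_causal, config$causal_q_range[1],
                      config$causal_q_range[2])
    d <- -config$load_b / (config$n_causal * q * (1 - q))
    causal <- data.frame(id = causal_map$id, q = q, d = d,
                         stringsAsFactors = FALSE)
    causal <- causal[causal$id %in% full_map$id, ]
  }

  set.seed(seeds[["founders"]])
  need <- sum(founders_per_family[names(design$matings)] * design$matings)
  founders <- simulate_founders(need, full_map, config$maf_spectrum,
                                seed = seeds[["founders"]])
  # overwrite causal-locus founder alleles at their configured rare
  # frequencies (counted allele = deleterious allele)
  if (!is.null(causal)) {
    cidx <- match(causal$id, full_map$id)
    founders$freq[cidx] <- causal$q
    founders$haps[, cidx] <-
      matrix(stats::rbinom(nrow(founders$haps) * length(cidx), 1L,
                           rep(causal$q, each = nrow(founders$haps))),
             nrow = nrow(founders$haps))
  }

  dropped <- gene_drop(design, founders, gmap, seed = seeds[["drop"]])
  f_true <- true_autozygosity(dropped$truth, gmap$genome_size_bp,
                              sample_ids = dropped$samples$sample_id)

  is_causal <- grepl("^causal_", full_map$id)
  g_all <- dropped$genotypes
  causal_genotypes <- genotype_matrix(
    g_all$calls[, is_causal, drop = FALSE],
    g_all$map[is_causal, , drop = FALSE], g_all$samples)
  array_keep <- if (config$keep_causal) rep(TRUE, nrow(full_map)) else
    !is_causal
  genotypes <- genotype_matrix(g_all$calls[, array_keep, drop = FALSE],
                               g_all$map[array_keep, , drop = FALSE],
                               g_all$samples)

  model <- trait_model(
    recessive = causal,
    covariates = config$covariate_effects,
    resid_sd = config$resid_sd,
    sex_multiplier = config$sex_multiplier,
    confounder = config$confounder)
  phenotypes <- simulate_traits(causal_genotypes, model,
                                seed = seeds[["traits"]],
                                f_true = f_true,
                                expected_f = dropped$samples$expected_f)
  if (!is.null(config$binary)) {
    bin_model <- trait_model(covariates = c(),
                             binary = config$binary)
    bin <- simulate_traits(causal_genotypes, bin_model,
                           seed = derive_seed(seed, 5L),
                           f_true = f_true, trait_name = "y_bin")
    phenotypes$y_bin <- bin$y_bin
  }

  structure(list(genotypes = genotypes, causal_genotypes = causal_genotypes,
                 truth = dropped$truth, phenotypes = phenotypes,
                 samples = dropped$samples, f_true = f_true,
                 load_b = trait_load(model), model = model, gmap = gmap,
                 config = config, seed = seed, seeds = seeds),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle:", n_samples(x$genotypes), "offspring,",
      n_variants(x$genotypes), "array SNPs,",
      nrow(x$truth), "true IBD segments\n")
  cat(sprintf("  mean true autozygosity %.4f; load B = %.2f\n",
              mean(x$f_true), x$load_b))
  invisible(x)
}
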