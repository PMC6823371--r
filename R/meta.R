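#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-cohort effect estimates sharing a trait and model tag:
#' pooled beta = sum(b_i / se_i^2) / sum(1 / se_i^2), pooled
#' se = 1 / sqrt(sum(1 / se_i^2)), with a two-sided normal p value.
#' Cochran's Q is reported descriptively; the model is strictly
#' fixed-effect.
#'
#' @param estimates data frame of effect rows (columns `beta`, `se`, `n`,
#'   `model_tag`; optional `trait`)
#' @return one-row data frame: `model_tag`, `beta`, `se`, `z`, `p`, `q`,
#'   `k`, `n_total`
#' @export
ivw_meta <- function(estimates) {
  if (!nrow(estimates)) stop("empty estimate list")
  if (length(unique(estimates$model_tag)) > 1)
    stop("mixed model tags in meta-analysis input")
  if ("trait" %in% names(estimates) &&
      length(unique(estimates$trait)) > 1)
    stop("mixed traits in meta-analysis input")
  if (any(is.na(estimates$se)) || any(estimates$se <= 0))
    stop("standard errors must be positive")
  w <- 1 / estimates$se^2
  beta <- sum(w * estimates$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  q <- sum(w * (estimates$beta - beta)^2)
  out <- data.frame(model_tag = estimates$model_tag[1], beta = beta,
                    se = se, z = z, p = 2 * stats::pnorm(-abs(z)), q = q,
                    k = nrow(estimates), n_total = sum(estimates$n))
  if ("trait" %in% names(estimates))
    out <- cbind(trait = estimates$trait[1], out)
  out
}

#' Meta-analysis of binned trait means
#'
#' Pools the per-bin mean intercept-referenced residuals and mean F_ROH
#' across cohorts by inverse-variance weighting. All cohorts must have
#' used the canonical bin bounds; bins empty in a cohort (or singleton
#' bins without a standard error) contribute nothing to that bin's pooled
#' mean.
#'
#' @param bin_list list of per-cohort [bin_trait_means()] tables
#' @return pooled bin table: `bin`, `lower`, `upper`, `k`, `n`,
#'   `mean_f_roh`, `se_f_roh`, `mean_eps`, `se_eps`
#' @export
meta_bins <- function(bin_list) {
  stopifnot(length(bin_list) >= 1)
  ref <- bin_list[[1]][, c("bin", "lower", "upper")]
  for (b in bin_list)
    if (!isTRUE(all.equal(b[, c("bin", "lower", "upper")], ref,
                          check.attributes = FALSE)))
      stop("cohorts used different bin bounds")
  nb <- nrow(ref)
  out <- cbind(ref, k = 0L, n = 0L, mean_f_roh = NA_real_,
               se_f_roh = NA_real_, mean_eps = NA_real_,
               se_eps = NA_real_)
  for (i in seq_len(nb)) {
    rows <- do.call(rbind, lapply(bin_list, function(b) b[i, ]))
    ok <- !is.na(rows$mean_eps) & !is.na(rows$se_eps) & rows$se_eps > 0
    out$n[i] <- sum(rows$n)
    out$k[i] <- sum(ok)
    if (any(ok)) {
      we <- 1 / rows$se_eps[ok]^2
      out$mean_eps[i] <- sum(we * rows$mean_eps[ok]) / sum(we)
      out$se_eps[i] <- 1 / sqrt(sum(we))
      okf <- ok & !is.na(rows$se_f_roh) & rows$se_f_roh > 0
      if (any(okf)) {
        wf <- 1 / rows$se_f_roh[okf]^2
        out$mean_f_roh[i] <- sum(wf * rows$mean_f_roh[okf]) / sum(wf)
        out$se_f_roh[i] <- 1 / sqrt(sum(wf))
      }
    }
  }
  out
}

#' Bootstrap median and 95% CI of a ratio of effect estimates
#'
#' Compares two estimation routes (for example within-sibling vs
#' population effects) across traits on a unitless scale. Each
#' replicate draws every numerator and denominator estimate from its
#' normal sampling distribution, forms the per-trait ratio and pools
#' across traits (equal weight by default; precision-weighted pooling of
#' the ratios is reported alongside). The summary is the median and
#' percentile 2.5/97.5 bounds over replicates; the bootstrap is
#' parametric because only summary statistics reach the meta-analysis
#' stage. Results are deterministic given `seed`.
#'
#' @param num,den data frames with columns `trait`, `beta`, `se`;
#'   matched by `trait`
#' @param reps bootstrap replicates (>= 1000)
#' @param seed integer seed
#' @return a `ratio_summary` list: `median`, `ci` (2.5/97.5 percentiles),
#'   `median_wt`, `ci_wt` (precision-weighted variant), `reps`, `seed`,
#'   `n_traits`, `unstable` (TRUE when a denominator has |beta|/se < 2,
#'   flagging ratio instability)
#' @export
ratio_bootstrap <- function(num, den, reps = 10000, seed = 1) {
  stopifnot(reps >= 1000)
  m <- merge(num, den, by = "trait", suffixes = c("_num", "_den"))
  if (!nrow(m)) stop("no traits shared between numerator and denominator")
  set.seed(seed)
  nt <- nrow(m)
  unstable <- any(abs(m$beta_den) / m$se_den < 2)
  bn <- matrix(stats::rnorm(reps * nt, rep(m$beta_num, each = reps),
                            rep(m$se_num, each = reps)), nrow = reps)
  bd <- matrix(stats::rnorm(reps * nt, rep(m$beta_den, each = reps),
                            rep(m$se_den, each = reps)), nrow = reps)
  ratios <- bn / bd
  pooled <- rowMeans(ratios)
  # precision-weighted variant: weight traits by the precision of the
  # plug-in ratio (delta-method variance)
  var_r <- (m$se_num^2 / m$beta_den^2) +
    (m$beta_num^2 * m$se_den^2 / m$beta_den^4)
  wt <- 1 / pmax(var_r, 1e-12)
  pooled_wt <- as.numeric(ratios %*% wt) / sum(wt)
  structure(list(median = stats::median(pooled),
                 ci = stats::quantile(pooled, c(0.025, 0.975),
                                      names = FALSE),
                 median_wt = stats::median(pooled_wt),
                 ci_wt = stats::quantile(pooled_wt, c(0.025, 0.975),
                                         names = FALSE),
                 reps = reps, seed = seed, n_traits = nt,
                 unstable = unstable),
            class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf(
    "ratio (equal weight): median %.3f [95%% CI %.3f, %.3f], %d traits, %d reps\n",
    x$median, x$ci[1], x$ci[2], x$n_traits, x$reps))
  if (x$unstable)
    cat("  warning: denominator effect(s) close to zero; ratio unstable\n")
  invisible(x)
}
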