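#' Residualize a trait on fixed covariates
#'
#' First stage of the two-step effect-estimation procedure: the trait is
#' regressed on all fixed covariates (ordinary least squares) and the
#' residuals carry forward to every subsequent model. The fitted
#' intercept is retained for the intercept-referenced bin analysis.
#'
#' @param y numeric trait vector
#' @param X covariate design matrix (should include an intercept column
#'   named `(Intercept)`; one is prepended if absent)
#' @return a `residual_trait` list: `eps` (residuals), `mu` (fitted
#'   intercept), `coef`, `X`
#' @export
residualize <- function(y, X) {
  X <- as.matrix(X)
  if (!"(Intercept)" %in% colnames(X))
    X <- cbind(`(Intercept)` = 1, X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  b <- qr.coef(qx, y)
  eps <- as.numeric(y - X %*% b)
  structure(list(eps = eps, mu = b[["(Intercept)"]], coef = b, X = X),
            class = "residual_trait")
}

#' Mixed-model trait residuals via REML/BLUP
#'
#' For family-structured cohorts the trait is modelled as
#' y = Xb + u + e with u ~ N(0, sigma_g^2 A), A the genomic relationship
#' matrix. Variance components are estimated by restricted maximum
#' likelihood after eigendecomposition of A (one-dimensional profile over
#' the heritability ratio), and the returned residuals are
#' y - X b_hat - u_hat with u_hat the BLUP. When the REML profile is flat
#' or the genetic variance estimate is at the zero boundary this reduces
#' to [residualize()].
#'
#' @param y trait vector
#' @param X covariate design matrix
#' @param A symmetric positive semi-definite GRM (samples x samples)
#' @param tol relative tolerance for declaring the likelihood flat /
#'   the boundary solution
#' @return a `residual_trait` list with extra elements `sigma_g2`,
#'   `sigma_e2`, `h2`
#' @export
grammar_residuals <- function(y, X, A, tol = 1e-6) {
  X <- as.matrix(X)
  if (!"(Intercept)" %in% colnames(X))
    X <- cbind(`(Intercept)` = 1, X)
  n <- length(y)
  stopifnot(nrow(A) == n, ncol(A) == n)
  if (max(abs(A - t(A))) > 1e-8 * max(1, max(abs(A))))
    stop("GRM is not symmetric")
  eig <- eigen(A, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values), 1))
    stop("GRM is not positive semi-definite")
  D <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- as.numeric(crossprod(U, y))
  Xs <- crossprod(U, X)
  pX <- ncol(X)
  neg_reml <- function(h2) {
    v <- h2 * D + (1 - h2)
    w <- 1 / v
    XtWX <- crossprod(Xs, Xs * w)
    b <- solve(XtWX, crossprod(Xs, ys * w))
    r <- ys - Xs %*% b
    s2 <- sum(w * r^2) / (n - pX)
    as.numeric(0.5 * (sum(log(v)) + (n - pX) * log(s2) +
                        determinant(XtWX)$modulus))
  }
  opt <- stats::optimize(neg_reml, c(1e-8, 1 - 1e-8))
  at0 <- neg_reml(1e-8)
  h2 <- if (at0 - opt$objective < tol * max(1, abs(at0))) 0 else opt$minimum
  v <- h2 * D + (1 - h2)
  w <- 1 / v
  XtWX <- crossprod(Xs, Xs * w)
  b <- solve(XtWX, crossprod(Xs, ys * w))
  r <- as.numeric(ys - Xs %*% b)
  s2_tot <- sum(w * r^2) / (n - pX)
  us <- (h2 * D) / v * r
  u <- as.numeric(U %*% us)
  eps <- as.numeric(y - X %*% b - u)
  structure(list(eps = eps, mu = b[match("(Intercept)", colnames(X))],
                 coef = stats::setNames(as.numeric(b), colnames(X)), X = X,
                 sigma_g2 = h2 * s2_tot, sigma_e2 = (1 - h2) * s2_tot,
                 h2 = h2),
            class = "residual_trait")
}

new_effect <- function(beta, se, n, tag, intercept = NA_real_,
                       extra = NULL) {
  out <- data.frame(model_tag = tag, beta = beta, se = se, n = n,
                    intercept = intercept, stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  rownames(out) <- NULL
  out
}

eps_vector <- function(eps) {
  if (inherits(eps, "residual_trait")) eps$eps else as.numeric(eps)
}

#' Univariate effect of an inbreeding estimator on a residualized trait
#'
#' Simple linear regression of the trait residuals on a per-sample
#' inbreeding measure; the slope is the per-unit-F effect. The
#' `beta_0.0625` column rescales it to the expected autozygosity of
#' first-cousin offspring for interpretability.
#'
#' @param eps residual trait (a [residualize()] result or numeric vector)
#' @param f per-sample inbreeding estimator values
#' @param tag model tag recorded with the estimate
#' @return one-row effect data frame: `model_tag`, `beta`, `se`, `n`,
#'   `intercept`, `beta_0.0625`
#' @export
fit_univariate <- function(eps, f, tag = "uni_froh") {
  e <- eps_vector(eps)
  stopifnot(length(e) == length(f))
  ok <- !is.na(e) & !is.na(f)
  e <- e[ok]; f <- f[ok]
  if (length(e) < 3) stop("need at least 3 samples")
  if (stats::var(f) == 0) stop("inbreeding estimator has zero variance")
  fit <- stats::lm(e ~ f)
  sm <- summary(fit)$coefficients
  new_effect(sm["f", 1], sm["f", 2], length(e), tag,
             intercept = sm["(Intercept)", 1],
             extra = data.frame(beta_0.0625 = 0.0625 * sm["f", 1]))
}

#' Partitioned homozygosity model
#'
#' Joint multiple regression of trait residuals on SNP homozygosity
#' outside ROH and on the short (<5 Mb) and long (>5 Mb) ROH fractions,
#' separating the effect of homozygosity borne by ROH from that of
#' single-SNP homozygosity. Under a rare-recessive architecture the two
#' ROH coefficients match the inbreeding load while the outside-ROH
#' coefficient is null.
#'
#' @param eps residual trait
#' @param f_snp_outside,f_roh_lt5,f_roh_gt5 per-sample components
#' @return three-row effect data frame with tags
#'   `partitioned_outside`, `partitioned_lt5`, `partitioned_gt5`; a
#'   collinear component yields `NA` beta/se and a `flagged` attribute
#'   rather than being silently dropped
#' @export
fit_partitioned <- function(eps, f_snp_outside, f_roh_lt5, f_roh_gt5) {
  e <- eps_vector(eps)
  X <- cbind(outside = f_snp_outside, lt5 = f_roh_lt5, gt5 = f_roh_gt5)
  ok <- stats::complete.cases(cbind(e, X))
  e <- e[ok]; X <- X[ok, , drop = FALSE]
  fit <- stats::lm(e ~ X)
  cf <- summary(fit)$coefficients
  tags <- c("partitioned_outside", "partitioned_lt5", "partitioned_gt5")
  rows <- lapply(seq_len(3), function(k) {
    nm <- paste0("X", colnames(X)[k])
    if (nm %in% rownames(cf)) {
      new_effect(cf[nm, 1], cf[nm, 2], length(e), tags[k],
                 intercept = cf["(Intercept)", 1])
    } else {
      new_effect(NA_real_, NA_real_, length(e), tags[k])
    }
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$beta))
    attr(out, "flagged") <- paste("collinear component(s):",
                                  paste(out$model_tag[is.na(out$beta)],
                                        collapse = ", "))
  out
}

#' Bivariate model with two inbreeding estimators
#'
#' Joint regression of trait residuals on F_ROH and F_GRM, returning the
#' conditional effects of each given the other. When causal variants are
#' rare and tagged by ROH, the conditional F_ROH effect dominates.
#'
#' @param eps residual trait
#' @param f_roh,f_grm per-sample estimators
#' @return two-row effect data frame with tags `bivariate_froh`,
#'   `bivariate_fgrm`
#' @export
fit_bivariate <- function(eps, f_roh, f_grm) {
  e <- eps_vector(eps)
  ok <- stats::complete.cases(cbind(e, f_roh, f_grm))
  e <- e[ok]; f1 <- f_roh[ok]; f2 <- f_grm[ok]
  if (abs(stats::cor(f1, f2)) >= 1 - 1e-12)
    stop("F_ROH and F_GRM are perfectly collinear")
  fit <- stats::lm(e ~ f1 + f2)
  cf <- summary(fit)$coefficients
  rbind(new_effect(cf["f1", 1], cf["f1", 2], length(e), "bivariate_froh",
                   intercept = cf["(Intercept)", 1]),
        new_effect(cf["f2", 1], cf["f2", 2], length(e), "bivariate_fgrm",
                   intercept = cf["(Intercept)", 1]))
}

#' Effect of inbreeding on a binary trait
#'
#' Two estimation routes on the ln(odds-ratio) scale: a full logistic
#' model with the inbreeding measure and covariates fitted simultaneously
#' ("logit"), and the scaled linear approximation ("linapprox") in which
#' the 0/1 outcome is divided by its variance and analysed with the usual
#' linear two-step, giving asymptotically unbiased ln(OR) estimates. The
#' `or_0.0625` column reports exp(0.0625 beta), the odds ratio for
#' first-cousin-offspring autozygosity.
#'
#' @param y 0/1 outcome vector
#' @param f per-sample inbreeding estimator
#' @param X covariate design matrix (may be NULL for intercept only)
#' @param method "logit" or "linapprox"
#' @return one-row effect data frame with tag `binary_logit` or
#'   `binary_linapprox`
#' @export
fit_binary <- function(y, f, X = NULL, method = c("logit", "linapprox")) {
  method <- match.arg(method)
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("outcome has a single class")
  if (stats::var(f) == 0) stop("inbreeding estimator has zero variance")
  if (is.null(X)) X <- matrix(1, length(y), 1,
                              dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (method == "logit") {
    Xn <- X[, colnames(X) != "(Intercept)", drop = FALSE]
    dat <- data.frame(y = y, f = f, Xn)
    fit <- suppressWarnings(stats::glm(y ~ ., data = dat,
                                       family = stats::binomial()))
    mu_hat <- stats::fitted(fit)
    if (any(mu_hat > 1 - 1e-10) || any(mu_hat < 1e-10)) {
      sep <- names(which.max(abs(stats::coef(fit)[-1])))
      stop("perfect separation in logistic model (predictor: ", sep, ")")
    }
    cf <- summary(fit)$coefficients
    new_effect(cf["f", 1], cf["f", 2], length(y), "binary_logit",
               intercept = cf["(Intercept)", 1],
               extra = data.frame(or_0.0625 = exp(0.0625 * cf["f", 1])))
  } else {
    ys <- y / stats::var(y)
    res <- residualize(ys, X)
    est <- fit_univariate(res, f, tag = "binary_linapprox")
    est$or_0.0625 <- exp(0.0625 * est$beta)
    est
  }
}

#' Canonical F_ROH bin bounds
#'
#' The ten fixed bins used for the intercept-referenced trait-mean
#' analysis; successive bounds correspond to offspring of increasingly
#' close unions.
#' @return numeric vector of 11 bounds
#' @export
froh_bin_bounds <- function() {
  c(0, 0.002, 0.0041, 0.0067, 0.0108, 0.0186, 0.0333, 0.06, 0.10, 0.18,
    1.0)
}

#' Mean trait residuals in bins of similar F_ROH
#'
#' Individuals are allocated to ten fixed F_ROH groups (left-closed,
#' right-open intervals; the last bin closed at 1) and the mean
#' intercept-referenced residual (eps - mu, i.e. relative to the
#' F_ROH = 0 intercept) and mean F_ROH are reported per bin with
#' standard errors. Empty bins are reported with n = 0.
#'
#' @param eps residual trait
#' @param mu fitted intercept of the univariate F_ROH model (the
#'   `intercept` column of [fit_univariate()])
#' @param f_roh per-sample F_ROH
#' @param bounds bin bounds; defaults to [froh_bin_bounds()]
#' @return data frame: `bin`, `lower`, `upper`, `n`, `mean_f_roh`,
#'   `se_f_roh`, `mean_eps`, `se_eps`
#' @export
bin_trait_means <- function(eps, mu, f_roh, bounds = froh_bin_bounds()) {
  e <- eps_vector(eps) - mu
  if (any(f_roh < 0 | f_roh > 1, na.rm = TRUE))
    stop("F_ROH outside [0, 1]")
  nb <- length(bounds) - 1
  idx <- findInterval(f_roh, bounds, rightmost.closed = TRUE)
  out <- data.frame(bin = seq_len(nb), lower = bounds[-length(bounds)],
                    upper = bounds[-1], n = 0L, mean_f_roh = NA_real_,
                    se_f_roh = NA_real_, mean_eps = NA_real_,
                    se_eps = NA_real_)
  for (b in seq_len(nb)) {
    in_b <- which(idx == b)
    out$n[b] <- length(in_b)
    if (length(in_b)) {
      out$mean_f_roh[b] <- mean(f_roh[in_b])
      out$mean_eps[b] <- mean(e[in_b])
      if (length(in_b) > 1) {
        out$se_f_roh[b] <- stats::sd(f_roh[in_b]) / sqrt(length(in_b))
        out$se_eps[b] <- stats::sd(e[in_b]) / sqrt(length(in_b))
      }
    }
  }
  out
}
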