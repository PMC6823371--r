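test_that("residualization centers, annihilates perfect fits, and
           orthogonalizes", {
  y <- c(3, 5, 7, 9, 11)
  r <- residualize(y, matrix(1, 5, 1, dimnames = list(NULL, "(Intercept)")))
  expect_equal(r$eps, y - mean(y))
  expect_equal(r$mu, mean(y))
  x <- 1:5
  r2 <- residualize(2 + 3 * x, cbind(x = x))
  expect_equal(r2$eps, rep(0, 5), tolerance = 1e-12)
  set.seed(1)
  X <- cbind(a = stats::rnorm(100), b = stats::rnorm(100))
  y3 <- 1 + X %*% c(0.5, -2) + stats::rnorm(100)
  r3 <- residualize(as.numeric(y3), X)
  expect_lt(max(abs(crossprod(cbind(1, X), r3$eps))), 1e-9)
  expect_error(residualize(y3, cbind(a = X[, 1], b = X[, 1])),
               "collinear.*b")
})

test_that("mixed-model residuals collapse to OLS and recover variance
           components", {
  set.seed(2)
  n <- 120
  X <- cbind(x = stats::rnorm(n))
  y <- as.numeric(2 + X + stats::rnorm(n))
  ols <- residualize(y, X)
  gr <- grammar_residuals(y, X, diag(n))
  expect_equal(gr$eps, ols$eps, tolerance = 1e-6)
  expect_equal(gr$h2, 0)
  # family-block GRM (sibships of 4) with sigma_g^2 = sigma_e^2 = 1
  set.seed(3)
  n_fam <- 140
  blk <- matrix(0.5, 4, 4); diag(blk) <- 1
  A <- kronecker(diag(n_fam), blk)
  nf <- 4 * n_fam
  u <- as.numeric(crossprod(chol(A), stats::rnorm(nf)))
  Xf <- cbind(x = stats::rnorm(nf))
  yf <- as.numeric(1 + 0.5 * Xf + u + stats::rnorm(nf))
  grf <- grammar_residuals(yf, Xf, A)
  ratio <- grf$sigma_g2 / grf$sigma_e2
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 2.5)
  # heritability-0 trait: boundary solution, residuals match OLS
  y0 <- as.numeric(1 + 0.5 * Xf + stats::rnorm(nf))
  gr0 <- grammar_residuals(y0, Xf, A)
  expect_lt(gr0$h2, 0.15)
  Abad <- diag(n); Abad[1, 2] <- 0.5
  expect_error(grammar_residuals(y, X, Abad), "symmetric")
  expect_error(grammar_residuals(y, X, -diag(n)), "semi-definite")
})

test_that("univariate fits are exact on noiseless input and invariant to
           centering", {
  f <- seq(0, 0.25, length.out = 20)
  est <- suppressWarnings(fit_univariate(-2 * f, f))
  expect_equal(unname(est$beta), -2)
  expect_lt(est$se, 1e-12)
  expect_equal(unname(est$beta_0.0625), -0.125)
  set.seed(4)
  eps <- stats::rnorm(50)
  f2 <- stats::runif(50)
  e1 <- fit_univariate(eps, f2)
  e2 <- fit_univariate(eps, f2 - mean(f2))
  expect_equal(e1$beta, e2$beta)
  expect_equal(e1$se, e2$se)
  # permuted estimator carries no signal
  set.seed(5)
  z <- replicate(30, {
    e <- fit_univariate(-10 * f2 + stats::rnorm(50), sample(f2))
    e$beta / e$se
  })
  expect_lt(abs(mean(z)), 0.75)
  expect_error(fit_univariate(eps, rep(0.1, 50)), "variance")
})

test_that("partitioned fits flag collinearity and vanish on zero input", {
  set.seed(6)
  n <- 80
  fo <- stats::rnorm(n, 0, 0.01)
  lt <- stats::runif(n, 0, 0.05)
  gt <- stats::runif(n, 0, 0.1)
  zero <- fit_partitioned(rep(0, n), fo, lt, gt)
  expect_equal(unname(zero$beta), rep(0, 3), tolerance = 1e-10)
  dup <- fit_partitioned(stats::rnorm(n), fo, lt, lt)
  expect_true(any(is.na(dup$beta)))
  expect_match(attr(dup, "flagged"), "collinear")
})

test_that("bivariate conditional effect matches univariate when the second
           estimator is pure noise", {
  set.seed(7)
  n <- 4000
  f <- stats::runif(n, 0, 0.25)
  eps <- -16 * f + stats::rnorm(n)
  fg <- f + stats::rnorm(n, 0, 0.05)
  bi <- fit_bivariate(eps, f, fg)
  uni <- fit_univariate(eps, f)
  expect_equal(bi$beta[bi$model_tag == "bivariate_froh"], uni$beta,
               tolerance = 0.1)
  expect_lt(abs(bi$beta[bi$model_tag == "bivariate_fgrm"]),
            2.5 * bi$se[bi$model_tag == "bivariate_fgrm"] + 0.5)
  expect_error(fit_bivariate(eps, f, f), "collinear")
})

test_that("binary fits reproduce a hand-computed contingency-table OR", {
  # binary exposure f in {0, 0.0625}; counts chosen for a clean OR
  y <- c(rep(1, 300), rep(0, 100), rep(1, 60), rep(0, 40))
  f <- c(rep(0, 400), rep(0.0625, 100))
  or_hand <- (60 * 100) / (40 * 300)  # 0.5
  est <- fit_binary(y, f, method = "logit")
  expect_equal(unname(est$beta), log(or_hand) / 0.0625, tolerance = 1e-6)
  expect_equal(unname(est$or_0.0625), 0.5, tolerance = 1e-6)
  expect_error(fit_binary(rep(1, 10), stats::runif(10)), "single class")
  expect_error(fit_binary(y, rep(0.1, 500)), "variance")
  # perfect separation is reported
  ys <- c(rep(0, 20), rep(1, 20))
  fs <- c(stats::runif(20, 0, 0.1), stats::runif(20, 0.2, 0.3))
  expect_error(fit_binary(ys, fs, method = "logit"), "separation")
})

test_that("binned means use the canonical bounds and reference the
           intercept", {
  bounds <- froh_bin_bounds()
  expect_length(bounds, 11)
  f <- c(0, 0.05, 0.001, 0.17, 0.5)
  eps <- c(1, 2, 3, 4, 5)
  bt <- bin_trait_means(eps, mu = 1, f_roh = f, bounds = bounds)
  expect_equal(nrow(bt), 10)
  expect_equal(bt$n[7], 1L)               # 0.05 in [0.0333, 0.06)
  expect_equal(bt$mean_f_roh[7], 0.05)
  expect_equal(bt$n[1], 2L)               # 0 and 0.001 in [0, 0.002)
  expect_equal(bt$mean_eps[1], mean(c(1, 3) - 1))
  expect_equal(bt$n[9], 1L)               # 0.17 in [0.10, 0.18)
  expect_equal(bt$n[10], 1L)              # 0.5 in [0.18, 1]
  expect_equal(sum(bt$n), 5)
  expect_error(bin_trait_means(eps, 0, c(f[-5], 1.2)), "outside")
  # on a linear trait the bin means fall on the fitted line
  set.seed(8)
  n <- 2000
  fr <- stats::runif(n, 0, 0.25)
  e <- -10 * fr + stats::rnorm(n, 0, 0.3)
  u <- fit_univariate(e, fr)
  btl <- bin_trait_means(e, u$intercept, fr, bounds)
  pred <- u$beta * btl$mean_f_roh
  ok <- btl$n > 10
  expect_lt(max(abs(btl$mean_eps[ok] - pred[ok]) /
                  pmax(btl$se_eps[ok], 1e-9)), 4)
})

test_that("moment kinship separates sibs, parent-offspring and unrelated
           pairs", {
  set.seed(9)
  nv <- 4000
  p <- stats::runif(nv, 0.1, 0.9)
  draw_hap <- function(gp) stats::rbinom(nv, 1, gp / 2)
  # simulate parent genotype pairs and drop unlinked gametes
  pa <- stats::rbinom(nv, 2, p); pb <- stats::rbinom(nv, 2, p)
  child <- function() draw_hap(pa) + draw_hap(pb)
  sib1 <- child(); sib2 <- child()
  unrel <- stats::rbinom(nv, 2, p)
  po_parent <- pa
  po_child <- draw_hap(pa) + stats::rbinom(nv, 1, p)
  dup <- sib1
  calls <- rbind(sib1, sib2, unrel, po_parent, po_child, dup)
  rownames(calls) <- NULL
  g <- toy_geno(calls)
  k <- estimate_kinship(g, min_snps = 100)
  pair <- function(i, j)
    k[(k$id1 == g$samples$sample_id[i] & k$id2 == g$samples$sample_id[j]) |
        (k$id1 == g$samples$sample_id[j] & k$id2 == g$samples$sample_id[i]), ]
  expect_equal(pair(1, 6)$kinship, 0.5, tolerance = 0.02)   # duplicate
  expect_equal(pair(1, 6)$ibs0, 0)
  expect_equal(pair(1, 2)$kinship, 0.25, tolerance = 0.05)  # full sibs
  expect_gt(pair(1, 2)$ibs0, 0.001)
  expect_equal(pair(4, 5)$kinship, 0.25, tolerance = 0.05)  # parent-child
  expect_lt(pair(4, 5)$ibs0, 0.001)
  expect_lt(abs(pair(1, 3)$kinship), 0.05)                  # unrelated
  # sibship selection: sibs+duplicate merge, parent-offspring excluded
  sibs <- select_full_sibs(k)
  expect_length(sibs, 1)
  expect_setequal(sibs[[1]]$members,
                  g$samples$sample_id[c(1, 2, 6)])
  expect_true(sibs[[1]]$mz_like)
  none <- select_full_sibs(k[abs(k$kinship) < 0.1, ])
  expect_length(none, 0)
})

test_that("within-sibling deviations give the hand-computed slope and
           reject degenerate families", {
  sib <- list(structure(list(family = "SIB001", members = c("a", "b"),
                             mz_like = FALSE), class = "sibship"))
  est <- suppressWarnings(
    within_sib_effect(c(1, 0), c(0.01, 0.03), sib, c("a", "b")))
  expect_equal(unname(est$beta), -50)
  # MZ-only families: no within-family F variance
  expect_error(within_sib_effect(c(1, 0), c(0.02, 0.02), sib, c("a", "b")),
               "variance")
  expect_error(within_sib_effect(1, 0.01, sib, "a"), "sibship")
})
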