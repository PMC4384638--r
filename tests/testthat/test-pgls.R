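make_star_vcv <- function(n, depth = 1) {
  taxa <- paste0("t", seq_len(n))
  M <- diag(depth, n)
  dimnames(M) <- list(taxa, taxa)
  structure(list(taxa = taxa, V = M, lambda = "untransformed"),
            class = "phylo_vcv")
}

test_that("PGLS with identity-scaled covariance equals OLS exactly", {
  n <- 12
  V <- make_star_vcv(n, depth = 2.5)
  dat <- withr::with_seed(1, data.frame(y = rnorm(n), x = rnorm(n),
                                        row.names = V$taxa))
  fit <- pgls_fit(y ~ x, dat, V, lambda = 1, df_convention = "standard")
  ols <- summary(lm(y ~ x, dat))
  expect_equal(unname(fit$coefficients), unname(coef(ols)[, 1]),
               tolerance = 1e-12)
  expect_equal(unname(fit$standard_errors), unname(coef(ols)[, 2]),
               tolerance = 1e-12)
  expect_equal(unname(fit$t_values), unname(coef(ols)[, 3]),
               tolerance = 1e-12)
  expect_equal(unname(fit$p_values), unname(coef(ols)[, 4]),
               tolerance = 1e-12)
})

test_that("lambda = 0 on an ultrametric tree reduces PGLS to OLS", {
  tr <- simulate_yule_tree(14, 1, seed = 121)
  V <- phylo_vcv(tr)
  dat <- withr::with_seed(2, data.frame(y = rnorm(14), x = rnorm(14),
                                        row.names = V$taxa))
  fit <- pgls_fit(y ~ x, dat, V, lambda = 0, df_convention = "standard")
  ols <- summary(lm(y ~ x, dat))
  expect_equal(unname(fit$coefficients), unname(coef(ols)[, 1]),
               tolerance = 1e-10)
  expect_equal(unname(fit$t_values), unname(coef(ols)[, 3]),
               tolerance = 1e-10)
})

test_that("whitened fit matches brute-force explicit-inverse GLS", {
  for (seed in c(131L, 132L, 133L)) {
    n <- sample(5:12, 1)
    tr <- simulate_yule_tree(n, 1, seed = seed)
    V <- phylo_vcv(tr)
    dat <- withr::with_seed(seed, data.frame(y = rnorm(n), x = rnorm(n),
                                             row.names = V$taxa))
    for (lam in c(0.3, 1)) {
      fit <- pgls_fit(y ~ x, dat, V, lambda = lam,
                      df_convention = "standard")
      M <- lambda_transform(V, lam)$V
      bf <- bf_gls(dat$y, cbind(1, dat$x), M, df = n - 2)
      expect_equal(unname(fit$coefficients), bf$beta, tolerance = 1e-9)
      expect_equal(unname(fit$standard_errors), bf$se, tolerance = 1e-9)
      expect_equal(unname(fit$t_values), bf$t, tolerance = 1e-9)
    }
  }
})

test_that("t equals coefficient over SE; whitened residuals orthogonal to design", {
  tr <- simulate_yule_tree(10, 1, seed = 141)
  V <- phylo_vcv(tr)
  dat <- withr::with_seed(3, data.frame(y = rnorm(10), x = rnorm(10),
                                        row.names = V$taxa))
  fit <- pgls_fit(y ~ x, dat, V, lambda = 0.7, df_convention = "standard")
  expect_equal(unname(fit$t_values),
               unname(fit$coefficients / fit$standard_errors),
               tolerance = 1e-12)
  M <- lambda_transform(V, 0.7)$V
  # orthogonality: X' V^-1 r = 0
  r <- fit$residuals[V$taxa]
  X <- cbind(1, dat$x)
  expect_equal(as.numeric(t(X) %*% solve(M, r)), c(0, 0), tolerance = 1e-8)
})

test_that("PGLS agrees with nlme::gls under Brownian correlation", {
  skip_if_not_installed("nlme")
  skip_if_not_installed("ape")
  tr <- simulate_yule_tree(12, 1, seed = 151)
  V <- phylo_vcv(tr)
  dat <- withr::with_seed(4, data.frame(y = rnorm(12), x = rnorm(12),
                                        sp = V$taxa, row.names = V$taxa))
  fit <- pgls_fit(y ~ x, dat[, 1:2], V, lambda = 1,
                  df_convention = "standard")
  atr <- ape::read.tree(text = write_newick(tr))
  g <- nlme::gls(y ~ x, data = dat,
                 correlation = ape::corBrownian(1, atr, form = ~sp),
                 method = "ML")
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-8)
  expect_equal(unname(fit$t_values),
               unname(summary(g)$tTable[, "t-value"]), tolerance = 1e-8)
  expect_equal(fit$log_likelihood, as.numeric(logLik(g)), tolerance = 1e-6)
})

test_that("collinear designs and taxa mismatches are rejected", {
  tr <- simulate_yule_tree(8, 1, seed = 161)
  V <- phylo_vcv(tr)
  dat <- withr::with_seed(5, data.frame(y = rnorm(8), x = rnorm(8),
                                        row.names = V$taxa))
  dat$x2 <- 2 * dat$x
  expect_error(pgls_fit(y ~ x + x2, dat, V, 1), "collinear.*x2|singular")
  dat2 <- dat[rev(rownames(dat)), ]
  expect_error(pgls_fit(y ~ x, dat2, V, 1), "mismatch")
})

test_that("lambda ML estimation maximizes the profile and flags star trees", {
  tr <- simulate_yule_tree(30, 1, seed = 171)
  V <- phylo_vcv(tr)
  y <- simulate_bm_traits(tr, 1, lambda = 0.6, seed = 172)[[1]]
  dat <- data.frame(y = y, row.names = V$taxa)
  est <- estimate_lambda_ml(y ~ 1, dat, V)
  expect_false(est$flat)
  ll_hat <- max(est$profile$log_likelihood)
  expect_gte(ll_hat,
             est$profile$log_likelihood[est$profile$lambda == 0])
  expect_gte(ll_hat,
             est$profile$log_likelihood[est$profile$lambda == 1])

  Vstar <- make_star_vcv(10)
  dstar <- withr::with_seed(6, data.frame(y = rnorm(10),
                                          row.names = Vstar$taxa))
  est_star <- estimate_lambda_ml(y ~ 1, dstar, Vstar)
  expect_true(est_star$flat)
  expect_true(is.na(est_star$lambda_hat))
})

test_that("lambda ML matches phytools::phylosig", {
  skip_if_not_installed("phytools")
  skip_if_not_installed("ape")
  tr <- simulate_yule_tree(40, 1, seed = 181)
  y <- simulate_bm_traits(tr, 1, lambda = 0.7, seed = 182)[[1]]
  V <- phylo_vcv(tr)
  est <- estimate_lambda_ml(y ~ 1, data.frame(y = y, row.names = V$taxa), V)
  atr <- ape::read.tree(text = write_newick(tr))
  ps <- phytools::phylosig(atr, setNames(y, V$taxa)[atr$tip.label],
                           method = "lambda")
  expect_equal(est$lambda_hat, ps$lambda, tolerance = 1e-3)
})

test_that("residualizing against an orthogonal covariate centers the trait", {
  V <- make_star_vcv(9)
  tr_names <- V$taxa
  trait <- setNames(c(1, 2, 3, 4, 5, 6, 7, 8, 9), tr_names)
  quad <- (1:9 - 5)^2
  covariate <- setNames(quad - mean(quad), tr_names)  # orthogonal to trait
  res <- pgls_residualize(trait, covariate, V, lambda = 1)
  expect_equal(unname(res), unname(trait - mean(trait)), tolerance = 1e-10)
})

test_that("residual-residual correlation recovers a known partial structure", {
  # y = b*z + e_y, x = c*z + e_x with independent e: after removing z the
  # residual correlation should be near zero; with correlated e it is positive
  tr <- simulate_yule_tree(100, 1, seed = 191)
  V <- phylo_vcv(tr)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.7   # traits 1,2 share structure beyond trait 3
  X <- simulate_bm_traits(tr, R, lambda = 1, seed = 192)
  z <- setNames(X[[3]], rownames(X))
  x <- setNames(X[[1]], rownames(X))
  y <- setNames(X[[2]], rownames(X))
  rx <- pgls_residualize(x, z, V, 1)
  ry <- pgls_residualize(y, z, V, 1)
  # raw residual correlation (not contrast-based) is still informative of sign
  expect_gt(cor(rx, ry), 0.3)
})
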