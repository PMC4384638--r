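test_that("Yule trees are ultrametric, correctly sized, and seed-determined", {
  tr <- simulate_yule_tree(2, 1, seed = 1)
  expect_equal(length(tr$tip.label), 2L)
  expect_true(is_ultrametric(tr))

  t1 <- simulate_yule_tree(50, 1.5, seed = 7)
  t2 <- simulate_yule_tree(50, 1.5, seed = 7)
  expect_identical(write_newick(t1), write_newick(t2))
  t3 <- simulate_yule_tree(50, 1.5, seed = 8)
  expect_false(identical(write_newick(t1), write_newick(t3)))
  expect_true(is_ultrametric(t1))

  expect_error(simulate_yule_tree(1, 1, seed = 1), "n_taxa")
  expect_error(simulate_yule_tree(5, -1, seed = 1), "birth_rate")
  expect_error(simulate_yule_tree(5, 1), "seed")
})

test_that("Yule depth matches the closed-form expectation", {
  n <- 8
  b <- 2
  reps <- 1000
  depths <- vapply(seq_len(reps), function(i) {
    tr <- simulate_yule_tree(n, b, seed = 20000 + i)
    max(phylo_vcv(tr)$V)
  }, numeric(1))
  expected <- sum(1 / ((2:n) * b))
  # each epoch is Exp(k b); var of the sum gives the Monte-Carlo band
  mc_sd <- sqrt(sum(1 / (((2:n) * b)^2)) / reps)
  expect_lt(abs(mean(depths) - expected), 4 * mc_sd)
})

test_that("zero-rate traits stay at the root state; variance scales as sigma2*T", {
  tr <- simulate_yule_tree(10, 1, seed = 31)
  flat <- simulate_bm_traits(tr, 0, root_state = 2.5, seed = 32)
  expect_true(all(abs(flat[[1]] - 2.5) < 1e-6))

  # fixed two-taxon tree of known depth T: leaf variance = sigma2 * T
  tr2 <- parse_newick("((a:1,b:1):1,c:2);")
  sigma2 <- 1.7
  reps <- 1000
  vals <- vapply(seq_len(reps), function(i) {
    simulate_bm_traits(tr2, sigma2, seed = 40000 + i)["c", 1]
  }, numeric(1))
  # var(c) = sigma2 * 2; sd of a sample variance ~ var * sqrt(2/(n-1))
  expect_lt(abs(var(vals) - sigma2 * 2), 4 * sigma2 * 2 * sqrt(2 / (reps - 1)))
})

test_that("leaf covariance converges to rate x lambda-transformed tree covariance", {
  tr <- simulate_yule_tree(6, 1, seed = 51)
  lam <- 0.5
  Vl <- lambda_transform(phylo_vcv(tr), lam)$V
  reps <- 1000
  M <- t(vapply(seq_len(reps), function(i) {
    as.numeric(simulate_bm_traits(tr, 1, lambda = lam, seed = 60000 + i)[[1]])
  }, numeric(6)))
  emp <- cov(M)
  se <- 3 * max(diag(Vl)) / sqrt(reps)
  expect_lt(max(abs(emp - Vl)), 3 * se)
})

test_that("count rounding perturbs r2 only slightly at fixture scale", {
  # traits scaled like the study: counts with sd ~ 2.7 on mean ~ 7
  diffs <- vapply(1:30, function(i) {
    tr <- simulate_yule_tree(14, 1, seed = 70000 + i)
    R <- matrix(c(7, 0.8 * sqrt(7 * 0.09), 0.8 * sqrt(7 * 0.09), 0.09), 2, 2)
    X <- simulate_bm_traits(tr, R, root_state = c(7, 1.3), seed = 71000 + i)
    cont <- X[[1]]
    rounded <- pmax(0, round(cont))
    if (sd(rounded) == 0) return(0)
    r2a <- cor(cont, X[[2]])^2
    r2b <- cor(rounded, X[[2]])^2
    abs(r2a - r2b)
  }, numeric(1))
  expect_lt(mean(diffs), 0.05)
})

test_that("correlated-trait recovery: FIC slope and ML lambda near truth", {
  rho <- 0.8
  R <- matrix(c(1, rho, rho, 1), 2, 2)
  tr <- simulate_yule_tree(200, 1, seed = 81)
  V <- phylo_vcv(tr)
  reps <- 60   # light recovery check; the full 500-replicate run lives in
               # the acceptance suite
  slopes <- numeric(reps)
  lambdas <- numeric(reps)
  for (i in seq_len(reps)) {
    X <- simulate_bm_traits(tr, R, lambda = 1, seed = 90000 + i)
    x <- setNames(X[[1]], rownames(X))
    y <- setNames(X[[2]], rownames(X))
    slopes[i] <- fic_regression(felsenstein_contrasts(tr, x),
                                felsenstein_contrasts(tr, y),
                                "standard")$coefficients[["x"]]
    est <- estimate_lambda_ml(y ~ 1,
                              data.frame(y = y[V$taxa], row.names = V$taxa),
                              V)
    lambdas[i] <- est$lambda_hat
  }
  expect_lt(abs(mean(slopes) - rho), 0.05)
  expect_lt(abs(mean(lambdas) - 1), 0.05)
})

test_that("the null battery is reproducible and validates its input", {
  out1 <- simulate_null_battery(n_taxa = 10, n_replicates = 50, seed = 5)
  out2 <- simulate_null_battery(n_taxa = 10, n_replicates = 50, seed = 5)
  expect_identical(out1, out2)
  expect_setequal(out1$method, c("pearson", "fic", "pgls"))
  expect_true(all(out1$rate >= 0 & out1$rate <= 1))
  expect_true(all(out1$ci_lower <= out1$rate & out1$rate <= out1$ci_upper))
  expect_error(simulate_null_battery(10, 0, seed = 1), "positive")
  expect_error(simulate_null_battery(10, 10), "seed")
})

test_that("naive Pearson over-rejects on a deeply imbalanced tree", {
  # pectinate tree: long shared paths induce strong covariance that the
  # uncorrected test ignores
  n <- 14
  labs <- paste0("s", 1:n)
  nwk <- paste0(strrep("(", n - 1), labs[1], ":1,", labs[2], ":1)",
                paste0(vapply(3:n, function(i)
                  paste0(":1,", labs[i], ":", i - 1, ")"), character(1)),
                  collapse = ""), ";")
  tr <- parse_newick(nwk)
  expect_true(is_ultrametric(tr))
  out <- simulate_null_battery(tree = tr, n_replicates = 400, seed = 11)
  expect_gt(out$rate[out$method == "pearson"], 0.07)
  expect_lt(out$rate[out$method == "fic"], 0.12)
})
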