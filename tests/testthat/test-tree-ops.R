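test_that("phylo_vcv matches hand-checked examples", {
  V <- phylo_vcv(parse_newick("(A:1,B:1);"))$V
  expect_equal(unname(V), diag(2), ignore_attr = TRUE)

  V3 <- phylo_vcv(parse_newick("((A:1,B:1):1,C:2);"))$V
  expect_equal(unname(diag(V3)), c(2, 2, 2))
  expect_equal(V3["A", "B"], 1)
  expect_equal(V3["A", "C"], 0)
  expect_equal(V3["B", "C"], 0)
})

test_that("phylo_vcv equals brute-force MRCA path lengths on random trees", {
  for (seed in c(31L, 32L, 33L, 34L)) {
    tr <- simulate_yule_tree(sample(4:12, 1), 1, seed = seed)
    expect_equal(phylo_vcv(tr)$V, bf_vcv(tr), tolerance = 1e-12)
  }
})

test_that("vcv is symmetric, PSD, with dominant diagonal", {
  tr <- simulate_yule_tree(15, 1, seed = 99)
  V <- phylo_vcv(tr)$V
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10))
  expect_true(all(diag(V) >= apply(V - diag(diag(V)), 1, max)))
})

test_that("lambda transform scales off-diagonals only and keeps PSD", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  V <- phylo_vcv(tr)
  expect_equal(lambda_transform(V, 1)$V, V$V)
  V0 <- lambda_transform(V, 0)$V
  expect_equal(unname(V0), diag(diag(V$V)), ignore_attr = TRUE)
  Vh <- lambda_transform(V, 0.5)$V
  expect_equal(Vh["A", "B"], 0.5)
  expect_equal(diag(Vh), diag(V$V))
  expect_error(lambda_transform(V, 1.2), "\\[0, 1\\]")
  expect_error(lambda_transform(lambda_transform(V, 0.5), 0.5),
               "already")
  # linearity off-diagonal + PSD across lambda
  tr2 <- simulate_yule_tree(10, 1, seed = 41)
  V2 <- phylo_vcv(tr2)
  for (lam in c(0, 0.25, 0.5, 0.75, 1)) {
    M <- lambda_transform(V2, lam)$V
    off <- M - diag(diag(M))
    expect_equal(off, lam * (V2$V - diag(diag(V2$V))), tolerance = 1e-12)
    expect_true(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) >
                  -1e-10)
  }
})

test_that("pruning keeps depths from the new root and drops the rest", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  pr <- prune_to_taxa(tr, c("A", "B"))
  expect_setequal(pr$tip.label, c("A", "B"))
  # the branch above the MRCA of {A,B} is discarded
  expect_equal(unname(diag(phylo_vcv(pr)$V)), c(1, 1))

  expect_identical(canonical_newick(prune_to_taxa(tr, c("A", "B", "C"))),
                   canonical_newick(tr))
  expect_error(prune_to_taxa(tr, c("A", "Z")), "Z")
})

test_that("pruned covariance is the submatrix shifted by the new root depth", {
  for (seed in c(51L, 52L, 53L)) {
    tr <- simulate_yule_tree(12, 1, seed = seed)
    keep <- sort(sample(tr$tip.label, 6))
    V_full <- phylo_vcv(tr)$V[keep, keep]
    pr <- prune_to_taxa(tr, keep)
    V_sub <- phylo_vcv(pr)$V[keep, keep]
    # the discarded constant is the smallest shared depth of the kept set
    shift <- V_full - V_sub
    expect_true(max(abs(shift - shift[1, 1])) < 1e-10)
    expect_true(shift[1, 1] >= -1e-10)
    # keeping two leaves on opposite sides of the root discards nothing
  }
  tr <- parse_newick("((A:1,B:2):1,(C:1,D:1):2);")
  keep <- c("A", "C")
  expect_equal(phylo_vcv(prune_to_taxa(tr, keep))$V[keep, keep],
               phylo_vcv(tr)$V[keep, keep], tolerance = 1e-12)
})

test_that("ultrametricity is detected with a relative tolerance", {
  expect_true(is_ultrametric(parse_newick("(A:1,B:1);")))
  expect_true(is_ultrametric(parse_newick("((A:1,B:1):1,C:2);")))
  expect_false(is_ultrametric(parse_newick("(A:1,B:2);")))
  expect_true(is_ultrametric(simulate_yule_tree(30, 2, seed = 5)))
})

test_that("polytomy resolution is deterministic and covariance-neutral", {
  tr <- parse_newick("(A:2,B:2,C:2,D:2);")
  r1 <- resolve_polytomies(tr)
  r2 <- resolve_polytomies(tr)
  expect_identical(canonical_newick(r1), canonical_newick(r2))
  expect_equal(sum(r1$edge.length == 0), 2L)  # ladder of zero branches
  expect_equal(phylo_vcv(r1)$V[tr$tip.label, tr$tip.label],
               phylo_vcv(tr)$V, tolerance = 1e-12)
})
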