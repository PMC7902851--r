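test_that("the equal rule resolves the three-taxon worked case", {
  clad <- ape::read.tree(text = "((A,B),C);")
  tt <- timescale_equal(clad, c(A = 10, B = 10, C = 20),
                        node_constraints = data.frame(mrca_of = "A;C",
                                                      min_age = 30))
  # hand-executed: node(A,B) starts at 10 (zero branches to A and B), root
  # constrained to 30; the 20-Myr slack root->node is split equally, putting
  # node(A,B) at 20 and every branch at 10 Myr
  expect_equal(tt$root_age, 30)
  ntip <- 3L
  node_ab <- ape::getMRCA(tt$phy, c("A", "B"))
  expect_equal(unname(tt$node_ages[node_ab]), 20)
  expect_true(all(tt$phy$edge.length > 0))
  expect_equal(sort(tt$phy$edge.length), c(10, 10, 10, 10))
})

test_that("constraints pin extant node ages and invalid constraints error", {
  clad <- ape::read.tree(text = "((A,B),C);")
  tt <- timescale_equal(clad, c(A = 0, B = 0, C = 0),
                        node_constraints = data.frame(
                          mrca_of = c("A;B", "A;C"), min_age = c(40, 90)))
  expect_equal(unname(tt$node_ages[ape::getMRCA(tt$phy, c("A", "B"))]), 40)
  expect_equal(tt$root_age, 90)
  expect_error(
    timescale_equal(clad, c(A = 50, B = 0, C = 0),
                    node_constraints = data.frame(mrca_of = "A;B",
                                                  min_age = 10)),
    "younger than a descendant")
})

test_that("a strictly positive configuration is a fixed point; root chains need slack", {
  # constraints already produce positive branches everywhere: ages must be
  # returned exactly as implied, with no redistribution
  clad <- ape::read.tree(text = "((A,B),C);")
  ts <- timescale_equal(clad, c(A = 10, B = 20, C = 30),
                        node_constraints = data.frame(
                          mrca_of = c("A;B", "A;C"), min_age = c(25, 40)),
                        root_extension = 0)
  expect_equal(unname(ts$node_ages[ape::getMRCA(ts$phy, c("A", "B"))]), 25)
  expect_equal(ts$root_age, 40)
  expect_equal(ts$root_extended, 0)
  expect_true(all(ts$phy$edge.length > 0))

  # identical tip ages collapse the whole tree: root extension required
  clad3 <- ape::read.tree(text = "((A,B),C);")
  expect_error(timescale_equal(clad3, c(A = 5, B = 5, C = 5),
                               root_extension = 0),
               "root_extension")
  ok <- timescale_equal(clad3, c(A = 5, B = 5, C = 5), root_extension = 3)
  expect_true(all(ok$phy$edge.length > 0))
  expect_equal(ok$root_age, 8)
})

test_that("equal time-scaling yields positive branches on random cladograms", {
  for (r in 1:100) {
    tr <- make_tree(10, seed = 7000 + r, n_fossil = sample(0:6, 1))
    ts <- timescale_equal(tr$cladogram, tr$fads)
    expect_true(all(ts$phy$edge.length > 0))
    # total depth = oldest FAD plus any root extension
    expect_gte(ts$root_age, max(tr$fads))
  }
})

test_that("brownian covariance matches worked cases and the ape oracle", {
  cherry <- ape::read.tree(text = "(A:3,B:3);")
  Cc <- brownian_cov(cherry)$C
  expect_equal(unname(Cc), rbind(c(3, 0), c(0, 3)))

  tr3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C3 <- brownian_cov(tr3)$C[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(unname(C3), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))

  for (r in 1:10) {
    tr <- make_tree(10, seed = 300 + r, n_fossil = 4)
    C1 <- brownian_cov(tr$time_tree)$C
    C2 <- ape::vcv(tr$time_tree$phy)
    expect_lt(max(abs(C1[rownames(C2), colnames(C2)] - C2)), 1e-10)
  }
  # ultrametric tree: constant diagonal
  tru <- make_tree(12, seed = 77)
  expect_lt(diff(range(diag(brownian_cov(tru$time_tree)$C))), 1e-10)
  unrooted <- ape::unroot(ape::read.tree(text = "((A:1,B:1):1,C:1,D:1);"))
  expect_error(brownian_cov(unrooted), "rooted")
})

test_that("lambda transform scales off-diagonals, keeps the diagonal and PSD", {
  tr3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- brownian_cov(tr3)
  expect_equal(lambda_transform(C, 1)$C, C$C)
  expect_equal(unname(lambda_transform(C, 0)$C), diag(diag(C$C)))
  C008 <- lambda_transform(C, 0.08)$C
  expect_equal(C008["A", "B"], 0.08)
  expect_equal(diag(C008), diag(C$C))

  tr <- make_tree(15, seed = 8, n_fossil = 5)
  Cb <- brownian_cov(tr$time_tree)$C
  prev <- NULL
  for (lam in seq(0, 1, by = 0.1)) {
    Cl <- lambda_transform(Cb, lam)
    expect_silent(chol(Cl))               # PSD via Cholesky success
    off <- Cl[upper.tri(Cl)]
    if (!is.null(prev)) expect_true(all(off >= prev - 1e-12))
    prev <- off
  }
  expect_error(lambda_transform(Cb, 1.2), "lambda")
})

test_that("pruning preserves pairwise tip distances and covariance blocks", {
  tr <- make_tree(10, seed = 5, n_fossil = 4)
  full <- tr$time_tree
  expect_identical(prune_tree(full, full$phy$tip.label), full)
  set.seed(31)
  for (r in 1:5) {
    keep <- sample(full$phy$tip.label, 5)
    pr <- prune_tree(full, keep)
    d_full <- ape::cophenetic.phylo(full$phy)[keep, keep]
    d_sub <- ape::cophenetic.phylo(pr$phy)[keep, keep]
    expect_lt(max(abs(d_full - d_sub)), 1e-9)
    # covariance of the pruned tree equals the submatrix of the full one
    expect_lt(max(abs(brownian_cov(pr)$C[keep, keep] -
                        brownian_cov(full)$C[keep, keep])), 1e-9)
  }
  # two retained tips keep their original path length
  two <- prune_tree(full, full$phy$tip.label[c(2, 7)])
  d0 <- ape::cophenetic.phylo(full$phy)[full$phy$tip.label[c(2, 7)],
                                        full$phy$tip.label[c(2, 7)]]
  expect_equal(sum(two$phy$edge.length), unname(d0[1, 2]), tolerance = 1e-9)
  expect_error(prune_tree(full, "nope"), "unknown taxa")
})
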