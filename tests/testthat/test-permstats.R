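test_that("exhaustive Procrustes ANOVA p equals brute-force enumeration", {
  set.seed(17)
  Y <- matrix(rnorm(6 * 5), 6)
  g <- rep(c("a", "b"), each = 3)
  res <- procrustes_anova(Y, g, exact = TRUE)
  # independent oracle: enumerate all 20 assignments, classical F formula
  sets <- combn(6, 3)
  Fs <- apply(sets, 2, function(s)
    classical_f(Y, ifelse(seq_len(6) %in% s, "a", "b")))
  F_obs <- classical_f(Y, g)
  expect_equal(res$F, F_obs, tolerance = 1e-10)
  expect_equal(res$p, mean(Fs >= F_obs - 1e-12))
  expect_identical(ncol(sets), 20L)
})

test_that("sampled permutation p converges to the exhaustive value", {
  set.seed(23)
  Y <- matrix(rnorm(8 * 4), 8)
  g <- rep(c("a", "b"), each = 4)
  p_exact <- procrustes_anova(Y, g, exact = TRUE)$p
  p_mc <- procrustes_anova(Y, g, n_perm = 9999, seed = 5)$p
  expect_lt(abs(p_mc - p_exact), 3 / sqrt(9999) + 0.02)
})

test_that("null constructions give small R2 and large p", {
  set.seed(2)
  base <- matrix(rnorm(5 * 6), 5)
  Y <- rbind(base, base)        # identical group means by duplication
  g <- rep(c("a", "b"), each = 5)
  res <- procrustes_anova(Y, g, n_perm = 499, seed = 3)
  expect_lt(res$R2, 0.05)
  expect_gt(res$p, 0.9)
})

test_that("seeded runs are reproducible and respect the p-value floor", {
  set.seed(4)
  Y <- matrix(rnorm(12 * 3), 12)
  Y[7:12, 1] <- Y[7:12, 1] + 4
  g <- rep(c("a", "b"), each = 6)
  r1 <- procrustes_anova(Y, g, n_perm = 199, seed = 42)
  r2 <- procrustes_anova(Y, g, n_perm = 199, seed = 42)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$Z, r2$Z)
  expect_gte(r1$p, 1 / 200)
  r3 <- procrustes_anova(Y, g, n_perm = 199, seed = 43)
  expect_lt(abs(r3$p - r1$p), 0.05)
  expect_error(procrustes_anova(Y, c("a", rep("b", 11)), n_perm = 9),
               "at least 2 members")
})

test_that("identity covariance reproduces the ordinary fit exactly", {
  set.seed(6)
  Y <- matrix(rnorm(10 * 4), 10)
  rownames(Y) <- paste0("t", 1:10)
  g <- rep(c("a", "b"), each = 5)
  plain <- procrustes_anova(Y, g, n_perm = 299, seed = 9)
  gls <- procrustes_anova(Y, g, n_perm = 299, seed = 9, cov = diag(10))
  expect_equal(gls$F, plain$F, tolerance = 1e-12)
  expect_identical(gls$p, plain$p)

  # singular covariance is surfaced with advice
  Cs <- matrix(1, 10, 10)
  expect_error(procrustes_anova(Y, g, n_perm = 9, cov = Cs), "lambda")
})

test_that("the phylogenetic fit differs under a real tree covariance", {
  tr <- make_tree(12, seed = 15)
  C <- brownian_cov(tr$time_tree)
  X <- simulate_brownian_traits(tr$time_tree,
    stats::setNames(rep(c("a", "b"), 6), tr$time_tree$phy$tip.label),
    delta = 1, sigma2_bm = 0.05, seed = 15)
  g <- rep(c("a", "b"), 6)
  names(g) <- rownames(X)
  plain <- procrustes_anova(X, g, n_perm = 199, seed = 1)
  gls <- procrustes_anova(X, g, n_perm = 199, seed = 1, cov = C)
  expect_false(isTRUE(all.equal(plain$F, gls$F)))
  expect_s3_class(gls, "perm_test")
})

test_that("pairwise shape tests cover each pair and are order-invariant", {
  set.seed(8)
  Y <- matrix(rnorm(24 * 4), 24)
  rownames(Y) <- sprintf("t%02d", 1:24)
  g <- rep(c("a", "b", "c", "d"), each = 6)
  tab <- pairwise_shape_tests(Y, g, n_perm = 99, seed = 2)
  expect_equal(nrow(tab), 6L)
  expect_setequal(paste(tab$group1, tab$group2),
                  c("a b", "a c", "a d", "b c", "b d", "c d"))
  # permuted input rows give identical results (matching by taxon id)
  perm <- sample(24)
  tab2 <- pairwise_shape_tests(Y[perm, ], g[perm], n_perm = 99, seed = 2)
  expect_equal(tab2, tab)
  # two groups: same test as the direct call
  sel <- g %in% c("a", "b")
  direct <- procrustes_anova(Y[sel, ][order(rownames(Y)[sel]), ],
                             g[sel][order(rownames(Y)[sel])],
                             n_perm = 99, seed = jawmorph:::derive_seed(2, 1))
  tab3 <- pairwise_shape_tests(Y[sel, ], g[sel], n_perm = 99, seed = 2)
  expect_equal(tab3$F[1], direct$F)
  expect_equal(tab3$p[1], direct$p)
})

test_that("univariate PERMANOVA equals the classical ANOVA F", {
  set.seed(11)
  v <- rnorm(18)
  g <- rep(c("a", "b", "c"), each = 6)
  res <- permanova_oneway(v, g, n_perm = 99, seed = 1)
  f_aov <- summary(stats::aov(v ~ g))[[1]][["F value"]][1]
  expect_equal(res$F, f_aov, tolerance = 1e-10)
})

test_that("multivariate PERMANOVA F matches the vegan oracle", {
  set.seed(13)
  V <- matrix(rnorm(20 * 3), 20)
  V[11:20, ] <- V[11:20, ] + 0.8
  g <- rep(c("a", "b"), each = 10)
  res <- permanova_oneway(V, g, n_perm = 99, seed = 1)
  veg <- vegan::adonis2(dist(V) ~ g, permutations = 9)
  expect_equal(res$F, veg$F[1], tolerance = 1e-8)
  expect_equal(res$R2, veg$R2[1], tolerance = 1e-8)
})

test_that("PERMANOVA is invariant to shifting and scaling of the data", {
  set.seed(14)
  V <- matrix(rnorm(15 * 2), 15)
  g <- rep(c("a", "b", "c"), each = 5)
  base <- permanova_oneway(V, g, n_perm = 199, seed = 7)
  shifted <- permanova_oneway(V + 100, g, n_perm = 199, seed = 7)
  scaled <- permanova_oneway(V * 3.7, g, n_perm = 199, seed = 7)
  expect_equal(shifted$F, base$F, tolerance = 1e-10)
  expect_identical(shifted$p, base$p)
  expect_equal(scaled$F, base$F, tolerance = 1e-10)
  expect_identical(scaled$p, base$p)
  expect_error(permanova_oneway(rep(1, 10), rep(c("a", "b"), 5), n_perm = 9),
               "constant")
})

test_that("equal group means put PERMANOVA p near its maximum", {
  set.seed(15)
  base <- rnorm(8)
  v <- c(base, base)
  g <- rep(c("a", "b"), each = 8)
  res <- permanova_oneway(v, g, n_perm = 499, seed = 2)
  expect_gt(res$p, 0.95)
})

test_that("pairwise PERMANOVA reports one uncorrected p per pair", {
  set.seed(16)
  v <- rnorm(24) + rep(c(0, 0, 3, 3), each = 6)
  g <- rep(c("a", "b", "c", "d"), each = 6)
  res <- permanova_oneway(v, g, n_perm = 199, seed = 3, pairwise = TRUE)
  expect_equal(nrow(res$pairwise), 6L)
  ab <- res$pairwise[res$pairwise$group1 == "a" & res$pairwise$group2 == "b", ]
  cd <- res$pairwise[res$pairwise$group1 == "a" & res$pairwise$group2 == "c", ]
  expect_gt(ab$p, 0.05)   # same distribution
  expect_lte(cd$p, 0.05)  # separated by 3 SDs
})
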