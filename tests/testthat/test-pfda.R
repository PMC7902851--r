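make_labelled_traits <- function(n = 50, n_train = 30, sep = 3, seed = 1) {
  set.seed(seed)
  labels_all <- sample(rep(c("carnivore", "herbivore", "insectivore"),
                           length.out = n))
  centers <- rbind(carnivore = c(0, sep), herbivore = c(-sep, -1),
                   insectivore = c(sep, -1))
  X <- centers[labels_all, ] + matrix(rnorm(n * 2), n)
  X <- cbind(X, matrix(rnorm(n * 3, sd = 0.5), n))
  rownames(X) <- sprintf("t%02d", seq_len(n))
  colnames(X) <- paste0("PC", 1:5)
  list(X = X,
       labels = stats::setNames(labels_all, rownames(X))[seq_len(n_train)],
       truth = stats::setNames(labels_all, rownames(X)))
}

test_that("phylogenetic whitening satisfies its defining identity", {
  set.seed(21)
  X <- matrix(rnorm(12 * 3), 12)
  expect_equal(phylo_whiten(X, diag(12)), X)
  expect_equal(phylo_whiten(X, 4 * diag(12)), X / 2)
  A <- matrix(rnorm(144), 12)
  C <- crossprod(A) + diag(12)
  W <- jawmorph:::gls_whitener(C)
  expect_lt(max(abs(W %*% C %*% t(W) - diag(12))), 1e-8)
  expect_error(phylo_whiten(X, matrix(1, 12, 12)), "singular")
})

test_that("with a star tree and lambda 0 the pFDA matches the LDA oracle", {
  d <- make_labelled_traits(n = 50, n_train = 30, seed = 31)
  tree <- star_tree(rownames(d$X))
  fit <- fit_pfda(d$X, d$labels, tree,
                  config = list(n_pcs = 5, lambda = 0,
                                classes = sort(unique(d$labels))))
  orc <- MASS::lda(d$X[names(d$labels), ], grouping = factor(d$labels))
  pred_orc <- as.character(predict(orc, d$X)$class)
  expect_identical(unname(fit$predicted), pred_orc)
  post_orc <- predict(orc, d$X)$posterior
  expect_lt(max(abs(fit$posterior[, colnames(post_orc)] - post_orc)), 1e-6)
})

test_that("posteriors are proper and permutation-equivariant", {
  d <- make_labelled_traits(seed = 32)
  tr <- make_tree(50, seed = 32, tip_labels = rownames(d$X))
  fit <- fit_pfda(d$X, d$labels, tr$time_tree,
                  config = list(n_pcs = 5, lambda = 0.3))
  expect_lt(max(abs(rowSums(fit$posterior) - 1)), 1e-10)
  expect_true(all(fit$posterior >= 0 & fit$posterior <= 1))
  expect_lte(ncol(fit$scores), 2L)   # at most classes - 1 axes
  perm <- sample(nrow(d$X))
  fit2 <- fit_pfda(d$X[perm, ], d$labels, tr$time_tree,
                   config = list(n_pcs = 5, lambda = 0.3))
  expect_equal(fit2$posterior, fit$posterior[perm, ], tolerance = 1e-9)
  expect_identical(unname(fit2$predicted), unname(fit$predicted[perm]))
})

test_that("widely separated classes are learnt perfectly", {
  d <- make_labelled_traits(sep = 12, seed = 33)   # ~10 within-class SDs
  tree <- star_tree(rownames(d$X))
  fit <- fit_pfda(d$X, d$labels, tree, config = list(n_pcs = 5, lambda = 0))
  expect_equal(fit$training_rate, 1)
  fossil_post <- fit$posterior[!fit$is_training, ]
  truth <- d$truth[rownames(d$X)[!fit$is_training]]
  expect_true(all(fossil_post[cbind(seq_along(truth), match(truth,
    colnames(fossil_post)))] > 0.99))
})

test_that("a taxon at a class centroid takes that class under equal priors", {
  d <- make_labelled_traits(n = 30, n_train = 30, sep = 4, seed = 34)
  centroid <- colMeans(d$X[d$labels == "herbivore", , drop = FALSE])
  X <- rbind(d$X, query = centroid)
  tree <- star_tree(rownames(X))
  fit <- fit_pfda(X, d$labels, tree,
                  config = list(n_pcs = 5, lambda = 0, priors = "equal"))
  expect_identical(unname(fit$predicted["query"]), "herbivore")
  expect_equal(names(which.max(fit$posterior["query", ])), "herbivore")
})

test_that("raising a class prior never lowers that class's posteriors", {
  d <- make_labelled_traits(seed = 35)
  tree <- star_tree(rownames(d$X))
  prop <- fit_pfda(d$X, d$labels, tree, config = list(n_pcs = 5, lambda = 0))
  eq <- fit_pfda(d$X, d$labels, tree,
                 config = list(n_pcs = 5, lambda = 0, priors = "equal"))
  # herbivore prior rises from its training share to 1/3 or falls; check the
  # monotone direction classwise
  for (cl in colnames(prop$posterior)) {
    dir <- sign(eq$priors[cl] - prop$priors[cl])
    if (dir == 0) next
    expect_true(all(dir * (eq$posterior[, cl] - prop$posterior[, cl])
                    >= -1e-9))
  }
})

test_that("degenerate inputs are rejected with clear messages", {
  d <- make_labelled_traits(seed = 36)
  tree <- star_tree(rownames(d$X))
  expect_error(fit_pfda(d$X, d$labels, tree, config = list(n_pcs = 9)),
               "n_pcs")
  one <- d$labels[d$labels != "herbivore"]
  one <- c(one, d$labels[d$labels == "herbivore"][1])
  expect_error(fit_pfda(d$X, one, tree, config = list(n_pcs = 5)),
               "fewer than 2")
  Xna <- d$X; rownames(Xna) <- NULL
  expect_error(fit_pfda(Xna, d$labels, tree), "row names")
})

test_that("lambda selection honours a single-point grid and the tie-break", {
  d <- make_labelled_traits(sep = 12, seed = 37)
  tr <- make_tree(50, seed = 37, tip_labels = rownames(d$X))
  sel1 <- select_lambda(d$X, d$labels, tr$time_tree, grid = 0.08,
                        config = list(n_pcs = 5))
  expect_equal(sel1$lambda, 0.08)
  # zero phylogenetic signal and wide separation: flat criterion, smallest
  # grid value wins
  labels2 <- stats::setNames(rep(c("A", "B"), 20),
                             make_tree(40, seed = 38)$time_tree$phy$tip.label)
  tr2 <- make_tree(40, seed = 38)
  X2 <- simulate_brownian_traits(tr2$time_tree, labels2, delta = 3,
                                 sigma2_bm = 0, sigma_obs = 0.2, seed = 38)
  sel2 <- select_lambda(X2, labels2, tr2$time_tree,
                        config = list(n_pcs = 4, classes = c("A", "B")))
  expect_identical(sel2$trace$misclassified,
                   rep(0L, nrow(sel2$trace)))
  expect_equal(sel2$lambda, min(sel2$trace$lambda))
})
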