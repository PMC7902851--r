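#' Phylogenetic whitening transform
#'
#' Left-multiplies a data matrix by the inverse Cholesky factor `W` of a
#' phylogenetic covariance, so that `W C W' = I`: rows become decorrelated
#' under the Brownian model. With `cov = I` the data are returned unchanged.
#'
#' @param X n x p matrix, rows in the covariance's taxon order.
#' @param cov `phylo_cov` or n x n covariance matrix.
#' @return transformed matrix of the same shape.
#' @export
phylo_whiten <- function(X, cov) {
  X <- as.matrix(X)
  C <- resolve_cov(cov, rownames(X))
  if (nrow(C) != nrow(X)) stop("cov and X disagree on taxon count")
  W <- gls_whitener(C)
  out <- W %*% X
  dimnames(out) <- dimnames(X)
  out
}

#' Phylogenetic flexible discriminant analysis
#'
#' Classifies taxa into diet classes from leading shape-PC scores while
#' accounting for phylogenetic covariance. The Brownian covariance of the
#' full tree (training + predict taxa) is lambda-transformed and its inverse
#' Cholesky factor whitens the predictors together with the intercept
#' column (each row keeps its own whitened-intercept loading, as in GLS).
#' Flexible discriminant analysis by optimal scoring, with linear regression
#' as the scoring engine, is then fit on the whitened training rows only and
#' applied to all rows; with an identity covariance this reduces exactly to
#' a canonical (linear) discriminant of the raw predictors. Posterior
#' probabilities come from a Gaussian class model with shared within-class
#' covariance in discriminant space, i.e. the LDA-consistent model.
#'
#' @param pc_scores n x m matrix of PC scores with taxon-id row names
#'   (training and predict taxa together).
#' @param labels_training named character vector of diet classes for the
#'   training taxa; taxa absent from it are treated as predict rows.
#' @param tree `time_tree`/`phylo` covering all taxa, or a precomputed
#'   `phylo_cov`/matrix.
#' @param config list: `n_pcs` (leading PCs used, default 7), `lambda`
#'   (Pagel's lambda in `[0, 1]`, default 0.08), `priors` (`"proportional"`
#'   to training class sizes, the default, or `"equal"`), `classes`
#'   (optional ordered label set).
#' @return a `pfda_result`: `axes` (predictor-space directions, columns
#'   `DA1..`), `scores` (all taxa), `posterior` (n x K), `predicted`,
#'   `training_rate`, `class_means_da`, `config`, `is_training`.
#' @export
fit_pfda <- function(pc_scores, labels_training, tree,
                     config = list()) {
  cfg <- utils::modifyList(
    list(n_pcs = 7L, lambda = 0.08, priors = "proportional", classes = NULL),
    config)
  X <- as.matrix(pc_scores)
  if (is.null(rownames(X))) stop("pc_scores needs taxon-id row names")
  if (cfg$n_pcs < 1L || cfg$n_pcs > ncol(X))
    stop("n_pcs must lie in 1..", ncol(X))
  X <- X[, seq_len(cfg$n_pcs), drop = FALSE]
  n <- nrow(X)
  is_training <- rownames(X) %in% names(labels_training)
  lab <- labels_training[rownames(X)[is_training]]
  classes <- if (is.null(cfg$classes)) sort(unique(lab)) else cfg$classes
  if (length(classes) < 2L) stop("need at least 2 classes")
  if (!all(lab %in% classes)) stop("training label outside the class set")
  cnt <- table(factor(lab, levels = classes))
  if (any(cnt < 2L)) stop("class with fewer than 2 training members: ",
                          paste(names(cnt)[cnt < 2L], collapse = ", "))

  # canonical internal order: training rows first (the lower-triangular
  # whitener then never mixes predict rows into training rows), sorted by
  # taxon id within block so results are invariant to input row order
  # (the Cholesky factor depends on row order); outputs are restored to
  # input order
  ord <- order(!is_training, rownames(X))
  X <- X[ord, , drop = FALSE]
  is_tr <- is_training[ord]
  n_tr <- sum(is_tr)
  g <- factor(labels_training[rownames(X)[is_tr]], levels = classes)
  K <- length(classes)
  priors <- if (identical(cfg$priors, "equal")) rep(1 / K, K)
            else as.numeric(cnt) / sum(cnt)
  names(priors) <- classes

  C <- if (inherits(tree, c("time_tree", "phylo")))
    brownian_cov(tree, lambda = cfg$lambda)
  else lambda_transform(tree, cfg$lambda)
  Cm <- if (inherits(C, "phylo_cov")) C$C else as.matrix(C)
  if (is.null(rownames(Cm))) {
    # unnamed covariance: assume input pc_scores row order
    dimnames(Cm) <- list(rownames(pc_scores), rownames(pc_scores))
  }
  Cm <- Cm[rownames(X), rownames(X)]
  Xw <- phylo_whiten(cbind(`(Intercept)` = 1, X), Cm)
  Xw_tr <- Xw[seq_len(n_tr), , drop = FALSE]

  # optimal scoring: regress whitened class indicators on whitened
  # predictors, then extract the non-trivial scorings
  Yind <- stats::model.matrix(~ g - 1)
  colnames(Yind) <- classes
  Yw <- gls_whitener(Cm[seq_len(n_tr), seq_len(n_tr)]) %*% Yind
  qrx <- qr(Xw_tr)
  if (qrx$rank < ncol(Xw_tr))
    stop("whitened design is rank deficient; reduce n_pcs")
  B <- qr.coef(qrx, Yw)
  Yhat <- Xw_tr %*% B
  D <- crossprod(Yw) / n_tr
  M <- (crossprod(Yw, Yhat) + crossprod(Yhat, Yw)) / (2 * n_tr)
  ed <- eigen(D, symmetric = TRUE)
  if (min(ed$values) < 1e-12 * max(ed$values))
    stop("degenerate class-indicator covariance")
  Dih <- ed$vectors %*% (t(ed$vectors) / sqrt(ed$values))
  eo <- eigen(Dih %*% M %*% Dih, symmetric = TRUE)
  Theta <- Dih %*% eo$vectors
  # the trivial scoring (constant over classes) is fit perfectly through the
  # whitened intercept: eigenvalue 1; real scorings have eigenvalue < 1
  triv <- which(eo$values > 1 - 1e-8)
  if (!length(triv)) {
    sds <- apply(Theta, 2L, stats::sd)
    triv <- which.min(sds)
  }
  keep <- setdiff(order(eo$values, decreasing = TRUE), triv)
  naxes <- min(K - 1L, ncol(X), length(keep))
  keep <- keep[seq_len(naxes)]
  eta <- Xw %*% B %*% Theta[, keep, drop = FALSE]   # variates, all rows

  # canonical discriminant + shared-covariance Gaussian model on the
  # training variates
  eta_tr <- eta[seq_len(n_tr), , drop = FALSE]
  Mcl <- do.call(rbind, lapply(classes, function(cl)
    colMeans(eta_tr[g == cl, , drop = FALSE])))
  rownames(Mcl) <- classes
  Sw <- matrix(0, naxes, naxes)
  for (cl in classes) {
    R <- sweep(eta_tr[g == cl, , drop = FALSE], 2L, Mcl[cl, ])
    Sw <- Sw + crossprod(R)
  }
  Sw <- Sw / (n_tr - K)
  es <- eigen(Sw, symmetric = TRUE)
  if (min(es$values) < 1e-12 * max(es$values))
    stop("pooled within-class covariance is singular; reduce n_pcs")
  Sih <- es$vectors %*% (t(es$vectors) / sqrt(es$values))

  coef_full <- B %*% Theta[, keep, drop = FALSE] %*% Sih  # on [1, X] whitened
  grand <- colSums(Mcl * priors)
  scores <- sweep(eta, 2L, grand) %*% Sih
  mda <- sweep(Mcl, 2L, grand) %*% Sih
  flip <- vapply(seq_len(naxes), function(j) {
    v <- coef_full[-1L, j]
    sign(v[which.max(abs(v))])
  }, 1)
  scores <- sweep(scores, 2L, flip, `*`)
  mda <- sweep(mda, 2L, flip, `*`)
  coef_full <- sweep(coef_full, 2L, flip, `*`)
  colnames(scores) <- colnames(mda) <- colnames(coef_full) <-
    paste0("DA", seq_len(naxes))

  logpost <- vapply(classes, function(cl)
    log(priors[cl]) - 0.5 * rowSums(sweep(scores, 2L, mda[cl, ])^2),
    numeric(n))
  if (n == 1L) logpost <- matrix(logpost, 1L)
  logpost <- logpost - apply(logpost, 1L, max)
  post <- exp(logpost)
  post <- post / rowSums(post)
  colnames(post) <- classes
  predicted <- classes[max.col(post, ties.method = "first")]
  names(predicted) <- rownames(X)
  training_rate <- mean(predicted[seq_len(n_tr)] == as.character(g))

  # restore input row order
  inv <- order(ord)
  structure(
    list(axes = coef_full, scores = scores[inv, , drop = FALSE],
         posterior = post[inv, , drop = FALSE],
         predicted = predicted[inv],
         training_rate = training_rate, class_means_da = mda,
         priors = priors, config = cfg, is_training = is_training,
         taxon_ids = rownames(pc_scores)),
    class = "pfda_result")
}

#' @export
print.pfda_result <- function(x, ...) {
  cat(sprintf("<pfda_result> %d taxa (%d training), %d classes, lambda = %g, training rate %.1f%%\n",
              length(x$taxon_ids), sum(x$is_training),
              ncol(x$posterior), x$config$lambda, 100 * x$training_rate))
  invisible(x)
}

#' Select Pagel's lambda for the discriminant by grid search
#'
#' Fits the discriminant at every grid value and returns the lambda with the
#' fewest misclassified training taxa, breaking ties toward the smallest
#' lambda (the weakest phylogenetic correction consistent with the data).
#' Grid values at which the whitening is singular are skipped.
#'
#' @inheritParams fit_pfda
#' @param grid non-empty vector of candidate lambdas in `[0, 1]`.
#' @return list with `lambda` (the selection), `trace` (data frame `lambda`,
#'   `misclassified`, `training_rate`).
#' @export
select_lambda <- function(pc_scores, labels_training, tree,
                          grid = c(0, 0.25, 0.5, 0.75, 1),
                          config = list()) {
  if (!length(grid)) stop("empty lambda grid")
  if (any(grid < 0 | grid > 1)) stop("grid values must lie in [0, 1]")
  grid <- sort(grid)
  n_tr <- sum(rownames(as.matrix(pc_scores)) %in% names(labels_training))
  rows <- lapply(grid, function(l) {
    fit <- tryCatch(
      fit_pfda(pc_scores, labels_training, tree,
               config = utils::modifyList(config, list(lambda = l))),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(lambda = l,
               misclassified = as.integer(round((1 - fit$training_rate) * n_tr)),
               training_rate = fit$training_rate)
  })
  trace <- do.call(rbind, rows)
  if (is.null(trace) || !nrow(trace))
    stop("whitening singular at every grid lambda")
  best <- trace$lambda[which.min(trace$misclassified)]  # ties -> smallest
  list(lambda = best, trace = trace)
}
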