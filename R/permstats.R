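#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) s <- (s * 48271 + as.double(i)) %% 2147483647
  as.integer(s)
}

perm_test_result <- function(R2, F, Z, p, n_permutations, seed, df_eff,
                             df_res, SS_eff, SS_res) {
  structure(list(R2 = R2, F = F, Z = Z, p = p,
                 n_permutations = n_permutations, seed = seed,
                 df_eff = df_eff, df_res = df_res,
                 SS_eff = SS_eff, SS_res = SS_res),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> R2 = %.4f, F = %.4f, Z = %.3f, p = %.4g (%s permutations, seed %s)\n",
              x$R2, x$F, x$Z, x$p,
              if (is.na(x$n_permutations)) "exhaustive" else x$n_permutations,
              x$seed))
  invisible(x)
}

resolve_cov <- function(cov, ids) {
  if (is.null(cov)) return(NULL)
  C <- if (inherits(cov, "phylo_cov")) cov$C else as.matrix(cov)
  if (!is.null(ids) && !is.null(rownames(C))) {
    miss <- setdiff(ids, rownames(C))
    if (length(miss)) stop("covariance is missing taxa: ",
                           paste(miss, collapse = ", "))
    C <- C[ids, ids, drop = FALSE]
  }
  C
}

gls_whitener <- function(C) {
  U <- tryCatch(chol(C), error = function(e)
    stop("phylogenetic covariance is singular or not positive definite; ",
         "consider lambda < 1 or pruning duplicate tips"))
  backsolve(U, diag(nrow(C)), transpose = TRUE)  # W with W C W' = I
}

#' Procrustes ANOVA by residual randomization
#'
#' One-factor ANOVA on multivariate (flattened Procrustes coordinate) data,
#' with significance from residual randomization (RRPP): residuals of the
#' intercept-only model are permuted across rows and the pseudo-F refit.
#' When a phylogenetic covariance is supplied, data and design are first
#' GLS-transformed by the inverse Cholesky factor (a PGLS-style fit) and the
#' randomization operates in the transformed space. With a single factor the
#' Type II conditional sums of squares reduce to the ordinary sequential
#' ones; only one-factor models are accepted.
#'
#' The reported p-value counts the observed statistic in both numerator and
#' denominator, so its minimum is `1/(n_perm + 1)`. `Z` is the effect size in
#' permutation-SD units of log F.
#'
#' @param data n x p numeric matrix (rows = taxa) or an `aligned_shapes`
#'   object (flattened internally).
#' @param groups length-n factor or character vector.
#' @param n_perm number of random permutations (`9999` mirrors common
#'   practice; tests use fewer).
#' @param seed integer seed; results are bit-reproducible given it.
#' @param cov optional `phylo_cov` (or matrix) over the same taxa, matched by
#'   row name when available.
#' @param exact enumerate all distinct two-group label assignments instead
#'   of sampling (two groups, no `cov` only).
#' @return a `perm_test` result.
#' @export
procrustes_anova <- function(data, groups, n_perm = 999, seed = 1,
                             cov = NULL, exact = FALSE) {
  if (inherits(data, "aligned_shapes")) {
    ids <- data$taxon_ids
    data <- flatten_shapes(data$coords)
    rownames(data) <- ids
  }
  Y <- as.matrix(data)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 members")
  n <- nrow(Y)
  C <- resolve_cov(cov, rownames(Y))

  X_full <- stats::model.matrix(~groups)
  X_red <- matrix(1, n, 1)
  if (!is.null(C)) {
    W <- gls_whitener(C)
    Y <- W %*% Y
    X_full <- W %*% X_full
    X_red <- W %*% X_red
  }
  Qf <- qr.Q(qr(X_full))
  Qr <- qr.Q(qr(X_red))
  df_eff <- nlevels(groups) - 1L
  df_res <- n - nlevels(groups)

  ss_res <- function(Ym, Q) sum(Ym^2) - sum((crossprod(Q, Ym))^2)
  fstat <- function(Ym) {
    sr_full <- ss_res(Ym, Qf)
    sr_red <- ss_res(Ym, Qr)
    c(F = ((sr_red - sr_full) / df_eff) / (sr_full / df_res),
      SS_eff = sr_red - sr_full, SS_res = sr_full, SS_tot = sr_red)
  }
  obs <- fstat(Y)
  fit_red <- Qr %*% crossprod(Qr, Y)
  E <- Y - fit_red

  if (exact) {
    if (!is.null(C)) stop("exact enumeration is only supported without cov")
    if (nlevels(groups) != 2L)
      stop("exact enumeration is only supported for two groups")
    n1 <- sum(groups == levels(groups)[1])
    sets <- utils::combn(n, n1)
    Fs <- apply(sets, 2L, function(s) {
      g <- factor(ifelse(seq_len(n) %in% s, levels(groups)[1],
                         levels(groups)[2]))
      Xp <- stats::model.matrix(~g)
      Qp <- qr.Q(qr(Xp))
      sr_full <- ss_res(Y, Qp)
      sr_red <- obs["SS_tot"]
      ((sr_red - sr_full) / df_eff) / (sr_full / df_res)
    })
    tol <- 1e-12 * max(1, obs["F"])
    p <- sum(Fs >= obs["F"] - tol) / ncol(sets)
    lf <- log(Fs[Fs > 0])
    Z <- if (obs["F"] > 0 && length(lf) > 1)
      (log(obs["F"]) - mean(lf)) / stats::sd(lf) else NA_real_
    return(perm_test_result(unname(obs["SS_eff"] / obs["SS_tot"]),
                            unname(obs["F"]), unname(Z), p, NA_integer_,
                            seed, df_eff, df_res,
                            unname(obs["SS_eff"]), unname(obs["SS_res"])))
  }

  Fs <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      Yp <- fit_red + E[sample.int(n), , drop = FALSE]
      unname(fstat(Yp)["F"])
    }, 1)
  })
  tol <- 1e-12 * max(1, obs["F"])
  p <- (1 + sum(Fs >= obs["F"] - tol)) / (n_perm + 1)
  lf <- log(Fs[Fs > 0])
  Z <- if (obs["F"] > 0 && length(lf) > 1)
    (log(obs["F"]) - mean(lf)) / stats::sd(lf) else NA_real_
  perm_test_result(unname(obs["SS_eff"] / obs["SS_tot"]), unname(obs["F"]),
                   unname(Z), p, n_perm, seed, df_eff, df_res,
                   unname(obs["SS_eff"]), unname(obs["SS_res"]))
}

#' Pairwise Procrustes ANOVAs between groups
#'
#' One test per unordered group pair, each on the pair's data subset, with
#' the phylogenetic covariance (when given) pruned to the pair. p-values are
#' reported uncorrected. Pair sub-seeds are derived from `seed` and the pair
#' identity by taxon-independent hashing, so permuted input row order leaves
#' results unchanged.
#'
#' @inheritParams procrustes_anova
#' @return data frame with one row per pair: `group1`, `group2`, `R2`, `F`,
#'   `Z`, `p`.
#' @export
pairwise_shape_tests <- function(data, groups, n_perm = 999, seed = 1,
                                 cov = NULL) {
  if (inherits(data, "aligned_shapes")) {
    ids <- data$taxon_ids
    data <- flatten_shapes(data$coords)
    rownames(data) <- ids
  }
  Y <- as.matrix(data)
  groups <- as.character(groups)
  # canonical row order by taxon id so results are order-invariant
  if (!is.null(rownames(Y))) {
    ord <- order(rownames(Y))
    Y <- Y[ord, , drop = FALSE]
    groups <- groups[ord]
  }
  lev <- sort(unique(groups))
  if (length(lev) < 2L) stop("need at least 2 groups")
  pairs <- utils::combn(lev, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    sel <- groups %in% c(g1, g2)
    res <- procrustes_anova(Y[sel, , drop = FALSE], groups[sel],
                            n_perm = n_perm,
                            seed = derive_seed(seed, j),
                            cov = cov)
    data.frame(group1 = g1, group2 = g2, R2 = res$R2, F = res$F,
               Z = res$Z, p = res$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

permanova_f <- function(D2, groups) {
  n <- nrow(D2)
  a <- nlevels(groups)
  ss_tot <- sum(D2[upper.tri(D2)]) / n
  ss_w <- 0
  for (g in levels(groups)) {
    m <- which(groups == g)
    Dg <- D2[m, m, drop = FALSE]
    ss_w <- ss_w + sum(Dg[upper.tri(Dg)]) / length(m)
  }
  ss_a <- ss_tot - ss_w
  c(F = (ss_a / (a - 1)) / (ss_w / (n - a)),
    SS_eff = ss_a, SS_res = ss_w, SS_tot = ss_tot)
}

#' One-way PERMANOVA (Euclidean distances)
#'
#' Anderson's pseudo-F from the pairwise squared-distance partition of
#' univariate or multivariate Euclidean data, with significance from raw
#' label permutation. For univariate data this pseudo-F equals the classical
#' one-way ANOVA F. The pairwise variant reports one uncorrected p per
#' unordered group pair.
#'
#' @param values numeric vector or n x p matrix.
#' @param groups length-n factor/character.
#' @param n_perm permutations (default 9999).
#' @param seed integer seed.
#' @param pairwise also run every unordered pair on its data subset.
#' @return a `perm_test`; with `pairwise = TRUE`, a list with `overall` and
#'   `pairwise` (data frame `group1`, `group2`, `F`, `p`).
#' @export
permanova_oneway <- function(values, groups, n_perm = 9999, seed = 1,
                             pairwise = FALSE) {
  V <- as.matrix(values)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 members")
  if (all(stats::dist(V) == 0)) stop("constant values: F is undefined")
  D2 <- as.matrix(stats::dist(V))^2
  n <- nrow(D2)
  obs <- permanova_f(D2, groups)
  Fs <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      unname(permanova_f(D2, groups[sample.int(n)])["F"]), 1)
  })
  tol <- 1e-12 * max(1, obs["F"])
  p <- (1 + sum(Fs >= obs["F"] - tol)) / (n_perm + 1)
  lf <- log(Fs[Fs > 0])
  Z <- if (obs["F"] > 0 && length(lf) > 1)
    (log(obs["F"]) - mean(lf)) / stats::sd(lf) else NA_real_
  overall <- perm_test_result(unname(obs["SS_eff"] / obs["SS_tot"]),
                              unname(obs["F"]), unname(Z), p, n_perm, seed,
                              nlevels(groups) - 1L, n - nlevels(groups),
                              unname(obs["SS_eff"]), unname(obs["SS_res"]))
  if (!pairwise) return(overall)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  tab <- lapply(seq_len(ncol(pairs)), function(j) {
    sel <- groups %in% pairs[, j]
    res <- permanova_oneway(V[sel, , drop = FALSE], droplevels(groups[sel]),
                            n_perm = n_perm, seed = derive_seed(seed, j))
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               F = res$F, p = res$p, stringsAsFactors = FALSE)
  })
  list(overall = overall, pairwise = do.call(rbind, tab))
}
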