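#' Principal-component morphospace of aligned shapes
#'
#' Eigendecomposition of the covariance matrix of flattened Procrustes-aligned
#' coordinates about their mean. Axis signs follow a deterministic
#' convention: each loading vector is oriented so its largest-magnitude
#' element is positive, making runs bit-comparable.
#'
#' @param aligned an `aligned_shapes` object, or a k x 2 x n array; normally
#'   the extant (training) subset of a joint superimposition.
#' @param ids optional taxon ids for the score rows (taken from `aligned`
#'   when it is an `aligned_shapes`).
#' @return a `morphospace` object: `mean_vector` (length 2k), `loadings`
#'   (2k x m, orthonormal), `eigenvalues` (non-increasing), `scores`
#'   (n x m, columns `PC1..PCm`), `variance_fractions`.
#' @export
fit_pca <- function(aligned, ids = NULL) {
  if (inherits(aligned, "aligned_shapes")) {
    if (is.null(ids)) ids <- aligned$taxon_ids
    aligned <- aligned$coords
  }
  n <- dim(aligned)[3]
  if (n < 3L) stop("need at least 3 configurations for a morphospace")
  X <- flatten_shapes(aligned)
  mean_vector <- colMeans(X)
  Xc <- sweep(X, 2L, mean_vector)
  m <- min(n - 1L, ncol(X) - 4L)  # 2k minus the 4 similarity dof removed by GPA
  s <- svd(Xc, nu = 0, nv = m)
  eig <- (s$d[seq_len(m)]^2) / (n - 1L)
  loadings <- s$v
  flip <- vapply(seq_len(m), function(j) {
    v <- loadings[, j]
    sign(v[which.max(abs(v))])
  }, 1)
  loadings <- sweep(loadings, 2L, flip, `*`)
  scores <- Xc %*% loadings
  colnames(scores) <- paste0("PC", seq_len(m))
  rownames(scores) <- ids
  total_var <- sum(Xc^2) / (n - 1L)
  structure(
    list(mean_vector = mean_vector, loadings = loadings, eigenvalues = eig,
         scores = scores, variance_fractions = eig / total_var,
         taxon_ids = ids),
    class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  cat(sprintf("<morphospace> %d shapes, %d axes; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), length(x$eigenvalues),
              100 * x$variance_fractions[1],
              100 * x$variance_fractions[min(2, length(x$eigenvalues))]))
  invisible(x)
}

#' Project shapes into an existing morphospace
#'
#' Out-of-sample projection: fossil (or any) aligned coordinates, superimposed
#' in the same frame as the shapes the morphospace was fit on, are centered on
#' the stored mean vector and multiplied by the PC loadings. Projecting a
#' training shape reproduces its stored score.
#'
#' @param morphospace a `morphospace` object.
#' @param aligned `aligned_shapes` or k x 2 x n array in the same frame.
#' @param ids optional row ids.
#' @return score matrix (n x m, columns `PC1..PCm`).
#' @export
project_shapes <- function(morphospace, aligned, ids = NULL) {
  if (inherits(aligned, "aligned_shapes")) {
    if (is.null(ids)) ids <- aligned$taxon_ids
    aligned <- aligned$coords
  }
  if (length(dim(aligned)) == 2L) aligned <- array(aligned, c(dim(aligned), 1L))
  X <- flatten_shapes(aligned)
  if (ncol(X) != length(morphospace$mean_vector))
    stop("dimension mismatch: shapes have ", ncol(X), " coordinates, ",
         "morphospace expects ", length(morphospace$mean_vector))
  scores <- sweep(X, 2L, morphospace$mean_vector) %*% morphospace$loadings
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- ids
  scores
}

#' Convex-hull occupancy of a morphospace
#'
#' Builds the convex hull of each group on a chosen PC pair and reports, for
#' every query point, whether it falls inside each hull (boundary counts as
#' inside). Groups with fewer than 3 distinct non-collinear points have no
#' hull and are flagged `NA`.
#'
#' @param scores_2d n x 2 matrix of group-point coordinates.
#' @param group_labels length-n group factor/character.
#' @param query_points q x 2 matrix.
#' @return q x n_groups logical matrix (`NA` column where a hull is
#'   undefined), with a `degenerate` attribute naming hull-less groups.
#' @export
hull_occupancy <- function(scores_2d, group_labels, query_points) {
  scores_2d <- as.matrix(scores_2d)
  query_points <- as.matrix(query_points)
  groups <- sort(unique(as.character(group_labels)))
  out <- matrix(NA, nrow(query_points), length(groups),
                dimnames = list(rownames(query_points), groups))
  degenerate <- character(0)
  for (g in groups) {
    pts <- scores_2d[group_labels == g, , drop = FALSE]
    hull <- unique(pts[grDevices::chull(pts), , drop = FALSE])
    if (nrow(hull) < 3L) {
      degenerate <- c(degenerate, g)
      next
    }
    out[, g] <- apply(query_points, 1L, point_in_polygon, poly = hull)
  }
  attr(out, "degenerate") <- degenerate
  out
}

# point-in-convex-polygon: inside iff on the same side of (or on) every edge,
# for vertices in chull order (counter-clockwise from grDevices::chull).
point_in_polygon <- function(p, poly, tol = 1e-12) {
  nv <- nrow(poly)
  scale <- max(abs(poly), 1)
  for (i in seq_len(nv)) {
    a <- poly[i, ]; b <- poly[if (i == nv) 1L else i + 1L, ]
    cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (cross > tol * scale^2) return(FALSE)  # chull order is clockwise
  }
  TRUE
}
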