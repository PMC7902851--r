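#' Ordinary Procrustes rotation
#'
#' Rotates `shape` onto `target` with the rotation (no reflection) that
#' minimizes the summed squared point-wise distances, via the SVD
#' construction. Both shapes must already be centered and of unit centroid
#' size.
#'
#' @param shape,target k x 2 matrices, centered, unit centroid size.
#' @param allow_reflection permit an orientation-reversing fit (off by
#'   default: mirrored jaws are data errors better surfaced than absorbed).
#' @return list with `rotated` (k x 2) and `distance` (the partial Procrustes
#'   distance, i.e. the root of the minimized sum of squares).
#' @export
opa_rotate <- function(shape, target, allow_reflection = FALSE) {
  k <- nrow(shape)
  if (k < 3L) stop("need at least 3 landmarks")
  if (!all(dim(shape) == dim(target))) stop("shapes differ in landmark count")
  if (max(abs(shape)) == 0 || max(abs(target)) == 0)
    stop("degenerate configuration: all points coincident")
  s <- svd(crossprod(target, shape))
  sig <- diag(2)
  if (!allow_reflection)
    sig[2, 2] <- sign(det(s$u %*% t(s$v)))
  R <- s$v %*% sig %*% t(s$u)
  rotated <- shape %*% R
  list(rotated = rotated, distance = sqrt(sum((rotated - target)^2)))
}

#' Generalized Procrustes analysis with optional semi-landmark sliding
#'
#' Iterative superimposition: each configuration is centered, scaled to unit
#' centroid size and rotated to the running consensus, and the consensus is
#' recomputed, until its root-mean-square change falls below `tol`. When
#' `slide = TRUE`, each cycle additionally lets every sliding semi-landmark
#' move along the chord between its chain neighbours so as to minimize the
#' chosen criterion against the consensus, followed by re-normalization and
#' re-rotation.
#'
#' @param configs list of [landmark_config()] with identical landmark count
#'   and semantics.
#' @param slide slide semi-landmarks (requires curves on the configurations).
#' @param criterion `"procdist"` (squared distance to the consensus point,
#'   the Procrustes-distance criterion; default) or `"bending"` (thin-plate
#'   spline bending energy against the consensus).
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   consensus RMS change of the plain superimposition cycles.
#' @param max_sweeps,slide_tol cap and relative-improvement tolerance for
#'   the sliding sweeps (each sweep is followed by re-superimposition to
#'   convergence; sweeps stop when the criterion improves by less than
#'   `slide_tol` of its value, since semi-landmarks can otherwise creep
#'   along the outline indefinitely at numerically irrelevant gain).
#' @return an `aligned_shapes` object: `coords` (k x 2 x n array), `consensus`
#'   (k x 2, the coordinate-wise mean of the aligned configurations),
#'   `centroid_sizes`, `taxon_ids`, `curves`, `iterations_used`,
#'   `final_change`, `criterion_trace` (criterion value per sliding sweep).
#' @export
gpa <- function(configs, slide = FALSE, criterion = c("procdist", "bending"),
                max_iter = 100L, tol = 1e-8, max_sweeps = 50L,
                slide_tol = 1e-6) {
  criterion <- match.arg(criterion)
  n <- length(configs)
  if (n < 2L) stop("need at least 2 configurations")
  ks <- vapply(configs, function(cf) nrow(cf$coords), 1L)
  if (length(unique(ks)) != 1L)
    stop("mixed landmark counts: ", paste(unique(ks), collapse = ", "))
  k <- ks[1]
  curves <- configs[[1]]$curves
  nb <- slider_neighbours(configs[[1]])
  if (slide && nrow(nb) == 0L)
    stop("slide = TRUE but configurations define no sliding semi-landmarks")

  sizes <- numeric(n)
  arr <- array(NA_real_, c(k, 2L, n))
  for (i in seq_len(n)) {
    x <- center_shape(configs[[i]]$coords)
    sizes[i] <- sqrt(sum(x^2))
    if (sizes[i] <= 0) stop("degenerate configuration: ", configs[[i]]$taxon_id)
    arr[, , i] <- x / sizes[i]
  }

  consensus <- arr[, , 1L]
  consensus <- consensus / sqrt(sum(consensus^2))
  it <- 0L

  superimpose <- function(arr, consensus) {
    change <- Inf
    its <- 0L
    while (its < max_iter && change > tol) {
      its <- its + 1L
      for (i in seq_len(n))
        arr[, , i] <- opa_rotate(arr[, , i], consensus)$rotated
      new_consensus <- apply(arr, c(1L, 2L), mean)
      new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
      change <- sqrt(mean((new_consensus - consensus)^2))
      consensus <- new_consensus
    }
    list(arr = arr, consensus = consensus, its = its, change = change)
  }

  st <- superimpose(arr, consensus)
  arr <- st$arr; consensus <- st$consensus; it <- st$its
  change <- st$change
  if (change > tol)
    warning(sprintf("GPA did not converge in %d iterations (last change %.3g)",
                    max_iter, change))

  trace <- numeric(0)
  if (slide) {
    crit_val <- sum((arr - as.vector(consensus))^2)
    for (sweep in seq_len(max_sweeps)) {
      arr <- slide_semilandmarks(arr, consensus, nb, criterion)
      for (i in seq_len(n)) {
        x <- center_shape(arr[, , i])
        arr[, , i] <- opa_rotate(x / sqrt(sum(x^2)), consensus)$rotated
      }
      st <- superimpose(arr, consensus)
      arr <- st$arr; consensus <- st$consensus; it <- it + st$its
      new_crit <- sum((arr - as.vector(consensus))^2)
      trace <- c(trace, new_crit)
      if (crit_val - new_crit < slide_tol * crit_val) {
        crit_val <- new_crit
        break
      }
      crit_val <- new_crit
    }
  }

  # final rotation pass so the stored consensus is the plain mean
  for (i in seq_len(n))
    arr[, , i] <- opa_rotate(arr[, , i], consensus)$rotated
  structure(
    list(coords = arr, consensus = apply(arr, c(1L, 2L), mean),
         centroid_sizes = sizes,
         taxon_ids = vapply(configs, `[[`, "", "taxon_id"),
         curves = curves, iterations_used = it, final_change = change,
         criterion_trace = trace),
    class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf("<aligned_shapes> %d configurations x %d landmarks; %d iterations, final change %.3g\n",
              dim(x$coords)[3], dim(x$coords)[1], x$iterations_used,
              x$final_change))
  invisible(x)
}

#' Slide semi-landmarks along their tangent directions
#'
#' Each sliding semi-landmark moves only along the unit chord between its
#' chain neighbours. Under the Procrustes-distance criterion the optimal
#' displacement is the closed-form projection `t = d . (c - x)` of the
#' residual to the consensus point onto the unit tangent `d`. Under the
#' bending-energy criterion all sliders of a configuration are solved
#' jointly against the thin-plate spline bending-energy matrix of the
#' consensus.
#'
#' @param aligned k x 2 x n array of aligned coordinates.
#' @param consensus k x 2 reference shape.
#' @param neighbours matrix from [slider_neighbours()].
#' @param criterion `"procdist"` or `"bending"`.
#' @return the adjusted k x 2 x n array.
#' @export
slide_semilandmarks <- function(aligned, consensus, neighbours,
                                criterion = c("procdist", "bending")) {
  criterion <- match.arg(criterion)
  if (nrow(neighbours) == 0L) stop("no sliding semi-landmarks defined")
  n <- dim(aligned)[3]
  Lk <- if (criterion == "bending") bending_energy_matrix(consensus) else NULL
  for (i in seq_len(n)) {
    x <- aligned[, , i]
    tang <- x[neighbours[, "nxt"], , drop = FALSE] -
      x[neighbours[, "prev"], , drop = FALSE]
    len <- sqrt(rowSums(tang^2))
    if (any(len <= 0)) stop("degenerate chain: coincident slider neighbours")
    tang <- tang / len
    idx <- neighbours[, "idx"]
    if (criterion == "procdist") {
      resid <- consensus[idx, , drop = FALSE] - x[idx, , drop = FALSE]
      tt <- rowSums(tang * resid)
      x[idx, ] <- x[idx, , drop = FALSE] + tang * tt
    } else {
      x[idx, ] <- slide_bending(x, consensus, idx, tang, Lk)
    }
    aligned[, , i] <- x
  }
  aligned
}

# Thin-plate spline bending-energy matrix of a 2D reference shape:
# the upper-left k x k block of the inverse of the TPS system matrix.
bending_energy_matrix <- function(ref) {
  k <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  K <- ifelse(d2 > 0, d2 * log(d2) / 2, 0)   # U(r) = r^2 log r
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Linv <- pinv(L)
  Linv[1:k, 1:k, drop = FALSE]
}

# Joint tangent-sliding solve minimizing the bending energy of (x - ref):
# for slider displacements t (one scalar per slider along its unit tangent),
# minimize (v + T t)' (I_2 kron B) (v + T t), v = vec difference per axis.
slide_bending <- function(x, ref, idx, tang, B) {
  m <- length(idx)
  diff <- x - ref
  # quadratic form decomposes over x/y axes with the same B
  Txx <- matrix(0, nrow(x), m); Tyy <- matrix(0, nrow(x), m)
  Txx[cbind(idx, seq_len(m))] <- tang[, 1]
  Tyy[cbind(idx, seq_len(m))] <- tang[, 2]
  A <- t(Txx) %*% B %*% Txx + t(Tyy) %*% B %*% Tyy
  b <- t(Txx) %*% B %*% diff[, 1] + t(Tyy) %*% B %*% diff[, 2]
  tt <- -pinv(A) %*% b
  x[idx, , drop = FALSE] + tang * as.vector(tt)
}
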