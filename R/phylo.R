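#' Time-scale a cladogram from appearance dates ("equal" method)
#'
#' Node ages are initialised to the oldest first-appearance date (FAD) among
#' their descendant tips, honouring any node-age constraints that are older;
#' tips terminate at their FAD (0 for extant taxa). Zero-length branches are
#' then removed by the "equal" rule: the duration of the nearest ancestral
#' branch with positive slack is re-divided equally along the chain of
#' zero-length descendant branches. When a zero-length chain reaches the root
#' itself, the root is extended back by `root_extension` to create slack.
#' Polytomies are accepted and kept.
#'
#' @param cladogram ape `phylo`; branch lengths, if any, are ignored.
#' @param tip_ages named numeric vector of FADs in Ma (0 for extant tips);
#'   names must cover every tip.
#' @param node_constraints optional data frame with columns `mrca_of`
#'   (semicolon-separated pair of tip labels identifying a node) and
#'   `min_age` (Ma). The root can be constrained via any tip pair spanning it.
#' @param root_extension extra depth (Myr) granted to the root when a
#'   zero-length chain reaches it; with `root_extension = 0` such a chain is
#'   an error advising a positive value.
#' @return a `time_tree`: `phy` (ape `phylo` with branch lengths in Myr),
#'   `node_ages` (named by node number), `tip_ages`, `root_age`,
#'   `root_extended` (Myr actually added).
#' @export
timescale_equal <- function(cladogram, tip_ages, node_constraints = NULL,
                            root_extension = 1) {
  phy <- stats::reorder(cladogram, "cladewise")  # parents before children
  ntip <- length(phy$tip.label)
  if (ntip < 2L) stop("need at least 2 tips")
  miss <- setdiff(phy$tip.label, names(tip_ages))
  if (length(miss)) stop("tips missing from age table: ",
                         paste(miss, collapse = ", "))
  if (root_extension < 0) stop("root_extension must be >= 0")
  nnode <- phy$Nnode
  root <- ntip + 1L
  parent <- integer(ntip + nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]

  ages <- numeric(ntip + nnode)
  ages[seq_len(ntip)] <- tip_ages[phy$tip.label]
  # postorder max over descendant tips
  for (e in rev(seq_len(nrow(phy$edge)))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    ages[p] <- max(ages[p], ages[ch])
  }
  if (!is.null(node_constraints) && nrow(node_constraints)) {
    for (r in seq_len(nrow(node_constraints))) {
      tips <- trimws(strsplit(node_constraints$mrca_of[r], ";")[[1]])
      bad <- setdiff(tips, phy$tip.label)
      if (length(bad)) stop("constraint names unknown tips: ",
                            paste(bad, collapse = ", "))
      node <- ape::getMRCA(phy, tips)
      min_age <- node_constraints$min_age[r]
      if (min_age < ages[node])
        stop("constraint on node of (", node_constraints$mrca_of[r],
             ") at ", min_age, " Ma is younger than a descendant tip (",
             ages[node], " Ma)")
      ages[node] <- max(ages[node], min_age)
    }
    # propagate constraint-raised ages rootward
    for (e in rev(seq_len(nrow(phy$edge)))) {
      p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      ages[p] <- max(ages[p], ages[ch])
    }
  }

  root_extended <- 0
  tol <- 1e-12
  repeat {
    bl <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
    zero <- which(bl <= tol)
    if (!length(zero)) break
    # handle the zero edge whose parent is shallowest (closest to root)
    depth_of <- function(v) { d <- 0L; while (v != root) { v <- parent[v]; d <- d + 1L }; d }
    e <- zero[which.min(vapply(phy$edge[zero, 1], depth_of, 0L))]
    ch <- phy$edge[e, 2]; p <- phy$edge[e, 1]
    chain <- c(ch, p)                 # bottom-up path of zero branches
    top <- p
    while (top != root && ages[parent[top]] - ages[top] <= tol) {
      top <- parent[top]
      chain <- c(chain, top)
    }
    if (top == root) {
      if (root_extension <= 0)
        stop("zero-length chain reaches the root; rerun with root_extension > 0")
      ages[root] <- ages[root] + root_extension
      root_extended <- root_extended + root_extension
      anchor <- root
    } else {
      anchor <- parent[top]
      chain <- c(chain, anchor)
    }
    # chain is [child, intermediates..., anchor]; re-space intermediates
    span <- ages[anchor] - ages[ch]
    m <- length(chain) - 2L
    step <- span / (m + 1L)
    for (j in seq_len(m))
      ages[chain[j + 1L]] <- ages[ch] + j * step
  }

  phy$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  structure(
    list(phy = phy,
         node_ages = ages,
         tip_ages = stats::setNames(ages[seq_len(ntip)], phy$tip.label),
         root_age = ages[root],
         root_extended = root_extended),
    class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("<time_tree> %d tips, root age %.2f Ma%s\n",
              length(x$phy$tip.label), x$root_age,
              if (x$root_extended > 0)
                sprintf(" (root extended by %g Myr)", x$root_extended) else ""))
  invisible(x)
}

as_phylo <- function(tree) {
  if (inherits(tree, "time_tree")) tree$phy else tree
}

#' Brownian phylogenetic covariance matrix
#'
#' Expected trait covariance under Brownian motion on a time tree:
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j, and
#' `C[i, i]` the root-to-tip path length. Computed by explicit edge
#' traversal of node depths.
#'
#' @param tree a `time_tree` or rooted ape `phylo` with branch lengths.
#' @param lambda optional Pagel's lambda applied before returning (see
#'   [lambda_transform()]).
#' @return a `phylo_cov`: `C` (n x n, tip-labelled), `taxa`, `lambda`.
#' @export
brownian_cov <- function(tree, lambda = 1) {
  phy <- as_phylo(tree)
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  phy <- stats::reorder(phy, "cladewise")  # parents before children
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  depth <- numeric(ntip + phy$Nnode)
  # a root edge (stem retained by pruning) is shared by every tip pair
  depth[root] <- if (!is.null(phy$root.edge)) phy$root.edge else 0
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    depth[ch] <- depth[p] + phy$edge.length[e]
  }
  mrca <- ape::mrca(phy)
  C <- matrix(depth[mrca], ntip, ntip,
              dimnames = list(phy$tip.label, phy$tip.label))
  diag(C) <- depth[seq_len(ntip)]
  out <- structure(list(C = C, taxa = phy$tip.label, lambda = 1),
                   class = "phylo_cov")
  if (lambda != 1) out <- lambda_transform(out, lambda)
  out
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies off-diagonal entries by `lambda` and preserves the diagonal:
#' `lambda = 1` is the full Brownian expectation, `lambda = 0` a star
#' phylogeny (independent tips). The result stays symmetric positive
#' semi-definite for `lambda` in `[0, 1]`.
#'
#' @param cov a `phylo_cov` or plain covariance matrix.
#' @param lambda value in `[0, 1]`.
#' @return same type as `cov`, transformed.
#' @export
lambda_transform <- function(cov, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  C <- if (inherits(cov, "phylo_cov")) cov$C else cov
  d <- diag(C)
  C <- C * lambda
  diag(C) <- d
  if (inherits(cov, "phylo_cov")) {
    cov$C <- C
    cov$lambda <- cov$lambda * lambda
    cov
  } else C
}

#' Prune a tree to a taxon subset
#'
#' Induced subtree preserving all path lengths between retained tips;
#' degree-2 nodes are collapsed by summing branch lengths.
#'
#' @param tree `time_tree` or ape `phylo`.
#' @param keep_taxa tip labels to retain.
#' @return same type as `tree`.
#' @export
prune_tree <- function(tree, keep_taxa) {
  phy <- as_phylo(tree)
  unknown <- setdiff(keep_taxa, phy$tip.label)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (setequal(keep_taxa, phy$tip.label)) return(tree)
  pruned <- ape::keep.tip(phy, keep_taxa)
  if (inherits(tree, "time_tree")) {
    pruned <- stats::reorder(pruned, "cladewise")
    tip_ages <- tree$tip_ages[pruned$tip.label]
    ntip <- length(pruned$tip.label)
    depth <- numeric(ntip + pruned$Nnode)
    for (e in seq_len(nrow(pruned$edge)))
      depth[pruned$edge[e, 2]] <- depth[pruned$edge[e, 1]] +
        pruned$edge.length[e]
    basal_age <- unname(tip_ages[1] + depth[1])
    # keep the stem back to the original root so Brownian covariances of
    # pruned trees are exact submatrices of the full-tree covariance
    pruned$root.edge <- tree$root_age - basal_age
    structure(
      list(phy = pruned,
           node_ages = basal_age - depth,
           tip_ages = tip_ages,
           root_age = tree$root_age,
           root_extended = tree$root_extended),
      class = "time_tree")
  } else pruned
}
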