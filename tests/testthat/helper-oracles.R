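# Independent oracles and small fixtures shared across the suite.

# centered, unit-size copy of a shape
cs <- function(m) {
  m <- sweep(m, 2L, colMeans(m))
  m / sqrt(sum(m^2))
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

unit_square <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)

# Naive alternating-minimization GPA oracle: plain-mean consensus, explicit
# closed-form 2D rotation angle per step (independent of the SVD route).
# Returns the total Procrustes sum of squares about the final consensus.
gpa_oracle_ss <- function(shapes, iters = 200) {
  shapes <- lapply(shapes, cs)
  for (it in seq_len(iters)) {
    consensus <- Reduce(`+`, shapes) / length(shapes)
    shapes <- lapply(shapes, function(x) {
      num <- sum(x[, 2] * consensus[, 1] - x[, 1] * consensus[, 2])
      den <- sum(x * consensus)
      x %*% rot2(atan2(num, den))
    })
  }
  consensus <- Reduce(`+`, shapes) / length(shapes)
  sum(vapply(shapes, function(x) sum((x - consensus)^2), 1))
}

# classical one-way multivariate ANOVA F via group-mean arithmetic
classical_f <- function(Y, g) {
  g <- factor(g)
  m <- colMeans(Y)
  ssb <- 0; ssw <- 0
  for (lv in levels(g)) {
    Yg <- Y[g == lv, , drop = FALSE]
    mg <- colMeans(Yg)
    ssb <- ssb + nrow(Yg) * sum((mg - m)^2)
    ssw <- ssw + sum(sweep(Yg, 2L, mg)^2)
  }
  (ssb / (nlevels(g) - 1)) / (ssw / (nrow(Y) - nlevels(g)))
}

# tiny synthetic spec for fast end-to-end tests
small_spec <- function(seed, ...) {
  synthetic_spec(
    n_training = c(herbivore = 4, carnivore = 6, insectivore = 5,
                   omnivore = 8),
    n_fossil = 8, seed = seed, ...)
}

# study-sized default spec
study_spec <- function(seed, ...) synthetic_spec(seed = seed, ...)

fda_classes <- c("carnivore", "herbivore", "insectivore")

# align + PCA + projection on a synthetic dataset; shared by several tests
analyse_shapes <- function(ds, slide = TRUE) {
  al <- gpa(ds$configs, slide = slide)
  tr <- ds$taxa$taxon_id[ds$taxa$role == "training"]
  pr <- ds$taxa$taxon_id[ds$taxa$role == "predict"]
  msp <- fit_pca(al$coords[, , match(tr, al$taxon_ids), drop = FALSE],
                 ids = tr)
  fossil <- if (length(pr))
    project_shapes(msp, al$coords[, , match(pr, al$taxon_ids), drop = FALSE],
                   ids = pr)
  else NULL
  list(aligned = al, morphospace = msp, fossil_scores = fossil,
       training_ids = tr, predict_ids = pr)
}

# star time tree with unit tip branches (identity Brownian covariance)
star_tree <- function(labels) {
  phy <- ape::stree(length(labels), type = "star")
  phy$tip.label <- labels
  phy$edge.length <- rep(1, nrow(phy$edge))
  phy$root.edge <- 0   # mark as rooted
  phy
}
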