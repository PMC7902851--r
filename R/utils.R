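# small shared numerics

center_shape <- function(x) sweep(x, 2L, colMeans(x))

centroid_size <- function(x) sqrt(sum(center_shape(x)^2))

# Moore-Penrose pseudo-inverse via SVD; used for the joint bending-energy
# sliding solve, where the quadratic form can be rank-deficient.
pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 1)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

flatten_shapes <- function(coords) {
  # k x 2 x n array -> n x 2k matrix, row per configuration (x1 y1 x2 y2 ...)
  n <- dim(coords)[3]
  t(apply(coords, 3L, function(m) as.vector(t(m))))
}

unflatten_shape <- function(v) {
  matrix(v, ncol = 2L, byrow = TRUE)
}
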