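test_that("ordinary Procrustes rotation matches similarity and mirror expectations", {
  sq <- cs(unit_square)
  expect_lt(opa_rotate(cs(unit_square %*% rot2(pi / 2)), sq)$distance, 1e-10)
  # reflection disallowed: a mirrored shape keeps positive distance
  mir <- cs(unit_square %*% diag(c(-1, 1)))
  expect_gt(opa_rotate(mir, sq)$distance, 0.1)
  expect_lt(opa_rotate(mir, sq, allow_reflection = TRUE)$distance, 1e-10)
  expect_error(opa_rotate(sq[1:2, ], sq[1:2, ]), "3 landmarks")
  expect_error(opa_rotate(matrix(0, 4, 2), sq), "degenerate")
})

test_that("rotation fit agrees with a fine grid search over the angle", {
  sq2 <- unit_square
  sq2[2, ] <- sq2[2, ] + c(0.1, -0.05)
  a <- cs(sq2); b <- cs(unit_square)
  angles <- seq(0, 2 * pi, length.out = 200001)
  grid_d <- sqrt(min(vapply(angles, function(t)
    sum((a %*% rot2(t) - b)^2), 1)))
  expect_equal(opa_rotate(a, b)$distance, grid_d, tolerance = 1e-6)
})

test_that("GPA aligns similarity-transformed copies of one shape exactly", {
  tmpl <- jaw_template()
  set.seed(42)
  configs <- lapply(1:5, function(i) {
    sc <- exp(runif(1, -1, 1))
    landmark_config(paste0("c", i),
                    sweep(sc * tmpl$coords %*% rot2(runif(1, 0, 2 * pi)),
                          2L, -runif(2, -10, 10)),
                    tmpl$fixed_idx, tmpl$curves)
  })
  al <- gpa(configs)
  for (i in 1:4) for (j in (i + 1):5)
    expect_lt(sqrt(sum((al$coords[, , i] - al$coords[, , j])^2)), 1e-8)
  # invariants
  expect_lt(max(abs(apply(al$coords, 3L, colMeans))), 1e-8)
  expect_lt(max(abs(apply(al$coords, 3L, function(m) sqrt(sum(m^2))) - 1)),
            1e-8)
  expect_lt(max(abs(al$consensus - apply(al$coords, c(1, 2), mean))), 1e-8)
})

test_that("two-shape GPA is symmetric and its consensus is the midpoint", {
  tmpl <- jaw_template()
  set.seed(1)
  a <- tmpl$coords
  b <- tmpl$coords + matrix(rnorm(length(a), sd = 0.05), nrow(a))
  mk <- function(m, id) landmark_config(id, m, tmpl$fixed_idx, tmpl$curves)
  al12 <- gpa(list(mk(a, "a"), mk(b, "b")))
  al21 <- gpa(list(mk(b, "b"), mk(a, "a")))
  mid <- (al12$coords[, , 1] + al12$coords[, , 2]) / 2
  expect_lt(max(abs(al12$consensus - mid)), 1e-8)
  d12 <- sqrt(sum((al12$coords[, , 1] - al12$coords[, , 2])^2))
  d21 <- sqrt(sum((al21$coords[, , 1] - al21$coords[, , 2])^2))
  expect_equal(d12, d21, tolerance = 1e-8)
})

test_that("GPA total sum of squares matches the alternating-minimization oracle", {
  tmpl <- jaw_template()
  set.seed(7)
  shapes <- lapply(1:10, function(i)
    tmpl$coords + matrix(rnorm(128, sd = 0.1), 64))
  configs <- lapply(seq_along(shapes), function(i)
    landmark_config(paste0("s", i), shapes[[i]], tmpl$fixed_idx, tmpl$curves))
  al <- gpa(configs)
  ss <- sum((al$coords - as.vector(al$consensus))^2)
  expect_equal(ss, gpa_oracle_ss(shapes), tolerance = 1e-6)
})

test_that("alignment is invariant to input order up to a global rotation", {
  ds <- synth_dataset(small_spec(3))
  al <- gpa(ds$configs)
  perm <- rev(seq_along(ds$configs))
  al2 <- gpa(ds$configs[perm])
  d1 <- as.matrix(dist(t(apply(al$coords, 3L, as.vector))))
  d2 <- as.matrix(dist(t(apply(al2$coords, 3L, as.vector))))[
    order(perm), order(perm)]
  expect_lt(max(abs(d1 - d2)), 1e-8)
  expect_error(gpa(c(ds$configs[1], list(landmark_config("bad",
    unit_square, 1:4)))), "mixed landmark counts")
})

test_that("single-slider adjustment matches the 1-D grid-search oracle", {
  ds <- synth_dataset(small_spec(2))
  al <- gpa(ds$configs, slide = FALSE)
  nb <- jawmorph:::slider_neighbours(ds$configs[[1]])
  slid <- slide_semilandmarks(al$coords, al$consensus, nb)
  for (r in c(1L, 10L, 40L)) {
    i <- nb[r, "idx"]
    x <- al$coords[, , 1]
    d <- x[nb[r, "nxt"], ] - x[nb[r, "prev"], ]
    d <- d / sqrt(sum(d^2))
    ts <- seq(-0.05, 0.05, length.out = 200001)
    obj <- vapply(ts, function(t)
      sum((x[i, ] + t * d - al$consensus[i, ])^2), 1)
    t_grid <- ts[which.min(obj)]
    t_closed <- sum(d * (slid[i, , 1] - x[i, ]))
    expect_lt(abs(t_closed - t_grid), 1e-6)
  }
  # a slider already at its optimum does not move
  opt <- al$coords
  opt[nb[1, "idx"], , 1] <- al$consensus[nb[1, "idx"], ] # place at target
  x <- opt[, , 1]
  d <- x[nb[1, "nxt"], ] - x[nb[1, "prev"], ]
  # project target onto tangent: displacement along d must be ~0 afterwards
  slid2 <- slide_semilandmarks(opt, al$consensus, nb)
  t0 <- sum((d / sqrt(sum(d^2))) * (slid2[nb[1, "idx"], , 1] -
                                      x[nb[1, "idx"], ]))
  expect_lt(abs(t0), 1e-10)
})

test_that("sliding criterion is non-increasing and never worse than no sliding", {
  ds <- synth_dataset(small_spec(5))
  al_ns <- gpa(ds$configs, slide = FALSE)
  al_s <- gpa(ds$configs, slide = TRUE)
  expect_gte(length(al_s$criterion_trace), 5L)
  expect_true(all(diff(al_s$criterion_trace) <= 1e-12))
  crit_ns <- sum((al_ns$coords - as.vector(al_ns$consensus))^2)
  expect_lte(al_s$criterion_trace[length(al_s$criterion_trace)], crit_ns)
})

test_that("bending-energy sliding runs and reduces the bending criterion", {
  ds <- synth_dataset(small_spec(6))
  al <- gpa(ds$configs, slide = FALSE)
  nb <- jawmorph:::slider_neighbours(ds$configs[[1]])
  B <- jawmorph:::bending_energy_matrix(al$consensus)
  bend <- function(arr) sum(vapply(seq_len(dim(arr)[3]), function(i) {
    df <- arr[, , i] - al$consensus
    sum(df[, 1] * (B %*% df[, 1])) + sum(df[, 2] * (B %*% df[, 2]))
  }, 1))
  slid <- slide_semilandmarks(al$coords, al$consensus, nb, "bending")
  expect_lte(bend(slid), bend(al$coords) + 1e-10)
  al_b <- gpa(ds$configs, slide = TRUE, criterion = "bending")
  expect_s3_class(al_b, "aligned_shapes")
})
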