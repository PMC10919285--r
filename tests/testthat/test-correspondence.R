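test_that("correspondence returns the requested particle count on every shape", {
  set.seed(2)
  surfaces <- lapply(1:3, function(k)
    ellipsoid_surface(semiaxes = c(10, 8, 14) + rnorm(3, 0, 0.5), n = 500))
  ps <- optimize_correspondence(surfaces, m = 64, iters = 3, seed = 7)
  expect_s3_class(ps, "particle_system")
  expect_equal(ps$m, 64)
  expect_length(ps$shapes, 3)
  for (s in ps$shapes) expect_equal(dim(s), c(64L, 3L))
})

test_that("the energy trace is non-increasing over accepted steps", {
  set.seed(3)
  surfaces <- lapply(1:3, function(k)
    ellipsoid_surface(semiaxes = c(10, 8, 14) + rnorm(3, 0, 0.5), n = 500))
  ps <- optimize_correspondence(surfaces, m = 64, iters = 4, seed = 7)
  tr <- ps$trace
  for (st in unique(tr$stage)) {
    q <- tr$Q[tr$stage == st]
    expect_true(all(diff(q) <= 1e-9))
  }
})

test_that("particles lie on (near) their source surfaces", {
  set.seed(4)
  surfaces <- lapply(1:2, function(k)
    ellipsoid_surface(semiaxes = c(10, 8, 14), n = 800))
  ps <- optimize_correspondence(surfaces, m = 48, iters = 3, seed = 1)
  for (k in 1:2) {
    cand <- sweep(surfaces[[k]], 2, colMeans(surfaces[[k]]))
    d <- musclesegkit:::cpp_knn(ps$shapes[[k]], cand, 1L)$dist[, 1]
    # within the local sample spacing of the candidate cloud
    spacing <- mean(musclesegkit:::cpp_knn(cand, cand, 2L)$dist[, 2])
    expect_lt(max(d), 3 * spacing)
  }
})

test_that("optimised correspondence compacts ensemble variance", {
  # the same cohort sampled with random (uncorresponded) orderings must give
  # a much higher total PCA variance than the optimised correspondence:
  # variance compaction is the purpose of the optimisation
  set.seed(6)
  cohort <- lapply(1:5, function(k)
    ellipsoid_surface(semiaxes = c(10, 8, 14 + rnorm(1)), n = 600))
  ps <- optimize_correspondence(cohort, m = 64, iters = 4, seed = 2)
  X_opt <- do.call(rbind, lapply(ps$shapes, flat3))
  var_opt <- sum(apply(X_opt, 2, stats::var))
  X_rnd <- do.call(rbind, lapply(cohort, function(s) {
    cc <- sweep(s, 2, colMeans(s))
    flat3(cc[sample(nrow(cc), 64), ])
  }))
  var_rnd <- sum(apply(X_rnd, 2, stats::var))
  expect_lt(var_opt, var_rnd / 10)
})

test_that("degenerate inputs are rejected", {
  s <- ellipsoid_surface(n = 100)
  expect_error(optimize_correspondence(list(s), m = 16), "at least 2")
  expect_error(optimize_correspondence(list(s, s), m = 500), "fewer candidate")
})
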