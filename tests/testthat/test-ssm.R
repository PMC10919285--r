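test_that("PCA recovers a planted single mode from exact correspondences", {
  pl <- planted_ellipsoid_cohort(n_shapes = 10, m = 128, seed = 5)
  model <- fit_pca(pl$shapes)
  expect_s3_class(model, "shape_space_model")
  # one real mode: first eigenvalue carries essentially all variance
  expect_gt(model$eigenvalues[1] / sum(model$eigenvalues), 0.99)
  # and it is the planted direction (up to sign)
  cosine <- abs(sum(model$modes[, 1] * pl$planted_direction))
  expect_gt(cosine, 0.99)
})

test_that("a cohort of N shapes yields at most N - 1 modes", {
  pl <- planted_ellipsoid_cohort(n_shapes = 10, m = 128, seed = 5)
  model <- fit_pca(pl$shapes)
  expect_lte(n_modes(model), 9)
  expect_equal(model$n_input_shapes, 10)
  # eigenvalues are non-negative and descending
  expect_true(all(model$eigenvalues >= 0))
  expect_true(all(diff(model$eigenvalues) <= 1e-9))
})

test_that("synthesis at s = 0 returns the mean shape", {
  pl <- planted_ellipsoid_cohort(seed = 6)
  model <- fit_pca(pl$shapes)
  mean_shape <- synthesize_shape(model, mode_index = 1, s = 0)
  expect_equal(flat3(mean_shape), unname(model$mean))
  expect_error(synthesize_shape(model, mode_index = 99), "out of range")
})

test_that("synthesis walks linearly along the chosen mode", {
  pl <- planted_ellipsoid_cohort(seed = 7)
  model <- fit_pca(pl$shapes)
  p_plus <- synthesize_shape(model, 1, 1)
  p_minus <- synthesize_shape(model, 1, -1)
  mid <- (flat3(p_plus) + flat3(p_minus)) / 2
  expect_equal(mid, unname(model$mean), tolerance = 1e-10)
  step <- flat3(p_plus) - unname(model$mean)
  expect_equal(sqrt(sum(step^2)), sqrt(model$eigenvalues[1]),
               tolerance = 1e-8)
})

test_that("Procrustes alignment removes translations before PCA", {
  pl <- planted_ellipsoid_cohort(seed = 8)
  set.seed(9)
  shifted <- lapply(pl$shapes, function(s)
    sweep(s, 2, rnorm(3, 0, 20), `+`))
  m0 <- fit_pca(pl$shapes)
  m1 <- fit_pca(shifted)
  # translations must not leak into the shape modes
  expect_gt(m1$eigenvalues[1] / sum(m1$eigenvalues), 0.99)
  cosine <- abs(sum(m0$modes[, 1] * m1$modes[, 1]))
  expect_gt(cosine, 0.999)
})

test_that("shape models survive a JSON round trip", {
  pl <- planted_ellipsoid_cohort(seed = 10)
  model <- fit_pca(pl$shapes)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_shape_model(model, path)
  back <- read_shape_model(path)
  expect_equal(back$mean, unname(model$mean))
  expect_equal(back$modes, unname(model$modes))
  expect_equal(back$eigenvalues, model$eigenvalues)
  expect_equal(back$m, model$m)
  expect_equal(back$origin, model$origin)
})

test_that("end-to-end pipeline recovers a dominant planted mode from masks", {
  # generate a single-mode phantom cohort, run the full correspondence + PCA
  # pipeline and check the first mode dominates (the discrete pipeline cannot
  # be bit-exact, but the planted structure must clearly emerge)
  spec <- phantom_spec(grid_shape = c(28, 28, 40), n_muscles = 2, seed = 33,
                       shape_family = "single_mode")
  coh <- generate_cohort(spec, 6)
  surfs <- lapply(coh, function(s) extract_surface(s$labels, 1))
  ps <- optimize_correspondence(surfs, m = 64, iters = 4, seed = 3)
  model <- fit_pca(ps)
  expect_gt(model$eigenvalues[1] / sum(model$eigenvalues), 0.5)
})
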