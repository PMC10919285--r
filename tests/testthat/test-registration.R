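make_smooth_volume <- function(dims = c(32, 32, 32)) {
  sm <- array(0, dims)
  ax <- lapply(dims, function(n) seq(0, 3, length.out = n))
  for (k in 1:5)
    sm <- sm + outer(sin(k * ax[[1]] + k),
                     outer(cos(k * ax[[2]]), sin(ax[[3]] + k)))
  msk_volume(sm)
}

make_smooth_field <- function(dims, ns, max_disp, seed = 1) {
  set.seed(seed)
  gd <- musclesegkit:::node_grid_dims(dims, ns)
  nodes <- array(0, c(gd, 3))
  for (c in 1:3) {
    g <- array(rnorm(prod(gd)), gd)
    g <- (g + g[c(1, 1:(gd[1] - 1)), , ] + g[, c(1, 1:(gd[2] - 1)), ] +
            g[, , c(1, 1:(gd[3] - 1))]) / 4
    nodes[, , , c] <- g / max(abs(g)) * max_disp
  }
  displacement_field(nodes, ns, dims, c(1, 1, 1))
}

test_that("registering a volume to itself returns (almost) no displacement", {
  vol <- make_smooth_volume()
  reg <- register(vol, vol, registration_params(max_iters = 30))
  expect_lt(max(abs(field_dense(reg$field))), 0.1)
})

test_that("a pure translation is recovered", {
  vol <- make_smooth_volume(c(40, 40, 40))
  v <- unclass(vol)
  tv <- v
  tv[1:37, , ] <- v[4:40, , ]      # target = reference shifted by +3 in x
  reg <- register(vol, msk_volume(tv), registration_params(max_iters = 60))
  inner <- field_dense(reg$field)[8:32, 8:32, 8:32, ]
  u_mean <- apply(inner, 4, mean)
  expect_lt(abs(u_mean[1] - 3), 0.5)
  expect_lt(abs(u_mean[2]), 0.5)
  expect_lt(abs(u_mean[3]), 0.5)
})

test_that("a smooth synthetic warp is recovered to sub-voxel accuracy", {
  dims <- c(32, 32, 32)
  vol <- make_smooth_volume(dims)
  fld <- make_smooth_field(dims, ns = 6, max_disp = 4, seed = 12)
  warped <- warp_volume(vol, fld)
  reg <- register(vol, warped, registration_params(max_iters = 80))
  du <- field_dense(reg$field) - field_dense(fld)
  inner <- du[7:26, 7:26, 7:26, ]
  epe <- sqrt(inner[, , , 1]^2 + inner[, , , 2]^2 + inner[, , , 3]^2)
  expect_lt(mean(epe), 1)
})

test_that("an extreme smoothness weight forces a near-constant field", {
  dims <- c(32, 32, 32)
  vol <- make_smooth_volume(dims)
  warped <- warp_volume(vol, make_smooth_field(dims, 6, 3, seed = 2))
  reg <- register(vol, warped,
                  registration_params(smoothing_lambda = 1e6, max_iters = 30))
  spread <- max(apply(reg$field$nodes, 4, function(a) diff(range(a))))
  expect_lt(spread, 0.1)
})

test_that("the objective trace is non-increasing", {
  vol <- make_smooth_volume()
  warped <- warp_volume(vol, make_smooth_field(dim(vol), 6, 3, seed = 3))
  reg <- register(vol, warped, registration_params(max_iters = 20))
  for (tr in reg$traces) expect_true(all(diff(tr) <= 0))
})

test_that("label maps register through per-label distance channels", {
  coh <- fx_small_cohort()
  reg <- register(coh[[1]]$labels, coh[[2]]$labels, augmentation_params())
  w <- warp_labels(coh[[1]]$labels, reg$field)
  d_before <- mean(evaluate_subject(coh[[1]]$labels, coh[[2]]$labels)$dsc)
  d_after <- mean(evaluate_subject(w, coh[[2]]$labels)$dsc)
  expect_gt(d_after, d_before)
  # warping never invents labels
  expect_true(all(label_values(w) %in% label_values(coh[[1]]$labels)))
})

test_that("a zero field warps to the identity", {
  vol <- make_smooth_volume(c(20, 20, 20))
  gd <- musclesegkit:::node_grid_dims(dim(vol), 5)
  fld <- displacement_field(array(0, c(gd, 3)), 5, dim(vol))
  expect_equal(unclass(warp_volume(vol, fld)), unclass(vol))
})

test_that("mismatched vocabularies and grids are rejected", {
  coh <- fx_small_cohort()
  l <- unclass(coh[[1]]$labels)
  l[l == 4L] <- 3L                  # drop label 4
  expect_error(register(msk_labelmap(l, msk_spacing(coh[[1]]$labels)),
                        coh[[2]]$labels), "vocabulary")
  small <- msk_volume(array(0, c(8, 8, 8)))
  expect_error(register(small, make_smooth_volume(c(10, 10, 10))), "grid|dim")
})
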