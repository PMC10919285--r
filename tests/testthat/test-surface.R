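test_that("extract_surface returns boundary voxel centres in mm", {
  lm <- msk_labelmap(array(0L, c(10, 10, 10)), spacing = c(1, 1, 2))
  m <- unclass(lm); m[4:7, 4:7, 4:7] <- 1L
  lm <- msk_labelmap(m, spacing = c(1, 1, 2))
  pts <- extract_surface(lm, 1)
  # a 4^3 cube has 4^3 - 2^3 = 56 boundary voxels
  expect_equal(nrow(pts), 56)
  # all points are centres of mask voxels, in mm (z scaled by spacing)
  expect_true(all(pts[, 1] %in% ((4:7) - 0.5)))
  expect_true(all(pts[, 3] %in% (((4:7) - 0.5) * 2)))
  expect_error(extract_surface(lm, 9), "absent")
})

test_that("mask surface normals point outward", {
  lm <- fx_ellipsoid_mask()
  pts <- extract_surface(lm, 1)
  nrm <- mask_surface_normals(lm, 1, pts)
  expect_equal(dim(nrm), dim(pts))
  # unit length
  expect_equal(unname(sqrt(rowSums(nrm^2))), rep(1, nrow(nrm)),
               tolerance = 1e-6)
  # outward: positive dot product with the radial direction for nearly all
  # boundary points of a convex shape
  ctr <- colMeans(pts)
  rad <- sweep(pts, 2, ctr)
  agree <- rowSums(nrm * rad) > 0
  expect_gt(mean(agree), 0.98)
})

test_that("ellipsoid_surface samples the requested analytic surface", {
  pts <- ellipsoid_surface(center = c(1, 2, 3), semiaxes = c(4, 5, 6),
                           n = 200)
  expect_equal(dim(pts), c(200L, 3L))
  u <- sweep(pts, 2, c(1, 2, 3))
  r <- (u[, 1] / 4)^2 + (u[, 2] / 5)^2 + (u[, 3] / 6)^2
  expect_equal(unname(r), rep(1, 200), tolerance = 1e-8)
})

test_that("boundary extraction keeps compartments separate", {
  coh <- fx_small_cohort()
  s1 <- extract_surface(coh[[1]]$labels, 1)
  s2 <- extract_surface(coh[[1]]$labels, 2)
  # surfaces of different labels are different point sets
  expect_false(isTRUE(all.equal(s1[seq_len(min(nrow(s1), nrow(s2))), ],
                                s2[seq_len(min(nrow(s1), nrow(s2))), ])))
})
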