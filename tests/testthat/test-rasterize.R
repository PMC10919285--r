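test_that("a voxel cube survives the surface -> rasterise round trip exactly", {
  cube <- array(0L, c(24, 24, 24)); cube[7:18, 7:18, 7:18] <- 1L
  lm <- msk_labelmap(cube)
  surf <- extract_surface(lm, 1)
  back <- rasterize_shape(surf, lm,
                          normals = mask_surface_normals(lm, 1, surf))
  expect_equal(dsc(unclass(back) == 1, cube == 1), 1)
})

test_that("an ellipsoid round trip recovers the mask to sub-voxel accuracy", {
  lm <- fx_ellipsoid_mask()
  surf <- extract_surface(lm, 1)
  back <- rasterize_shape(surf, lm,
                          normals = mask_surface_normals(lm, 1, surf))
  expect_gt(dsc(unclass(back) == 1, unclass(lm) == 1), 0.95)
})

test_that("signed distance is negative inside, positive outside", {
  lm <- fx_ellipsoid_mask()
  surf <- extract_surface(lm, 1)
  sdf <- signed_distance_field(surf, lm,
                               normals = mask_surface_normals(lm, 1, surf))
  msk <- unclass(lm) == 1
  # deep interior / far exterior must have unambiguous signs
  d_in <- musclesegkit:::cpp_edt(!msk, c(1, 1, 1))
  d_out <- musclesegkit:::cpp_edt(msk, c(1, 1, 1))
  expect_true(all(sdf[d_in > 2] < 0))
  expect_true(all(sdf[d_out > 2] > 0))
})

test_that("analytic ellipsoid rasterises to the expected volume", {
  pts <- ellipsoid_surface(center = c(14, 14, 14), semiaxes = c(8, 6, 9),
                           n = 800)
  lab <- rasterize_shape(pts, list(dim = c(28, 28, 28), spacing = c(1, 1, 1)))
  vol <- sum(unclass(lab) == 1)
  expect_equal(vol, 4 / 3 * pi * 8 * 6 * 9, tolerance = 0.15)
})

test_that("degenerate point sets are rejected", {
  geo <- list(dim = c(10, 10, 10), spacing = c(1, 1, 1))
  expect_error(signed_distance_field(matrix(1, 3, 3), geo), "degenerate")
  flat <- cbind(runif(50, 1, 9), runif(50, 1, 9), 5)
  expect_error(signed_distance_field(flat, geo), "coplanar|degenerate")
})

test_that("points wholly outside the grid give an empty mask with a warning", {
  pts <- ellipsoid_surface(center = c(100, 100, 100), semiaxes = c(3, 3, 3),
                           n = 100)
  expect_warning(
    lab <- rasterize_shape(pts, list(dim = c(10, 10, 10),
                                     spacing = c(1, 1, 1))),
    "outside")
  expect_equal(sum(unclass(lab)), 0)
})
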