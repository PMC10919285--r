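test_that("a phantom subject carries the requested grid, spacing and labels", {
  spec <- phantom_spec(grid_shape = c(24, 24, 36), spacing_mm = c(1, 1, 1.5),
                       n_muscles = 3, seed = 4)
  s <- generate_subject(spec, id = "P1")
  expect_s3_class(s, "msk_subject")
  expect_identical(dim(s$volume), c(24L, 24L, 36L))
  expect_identical(dim(s$labels), c(24L, 24L, 36L))
  expect_equal(msk_spacing(s$volume), c(1, 1, 1.5))
  expect_identical(label_values(s$labels), 1:3)
})

test_that("cohort generation is deterministic in the seed", {
  spec <- phantom_spec(grid_shape = c(20, 20, 28), n_muscles = 2, seed = 9)
  c1 <- generate_cohort(spec, 3)
  c2 <- generate_cohort(spec, 3)
  expect_identical(unclass(c1[[2]]$volume), unclass(c2[[2]]$volume))
  expect_identical(unclass(c1[[3]]$labels), unclass(c2[[3]]$labels))
  c3 <- generate_cohort(spec, 3, seed = 10)
  expect_false(identical(unclass(c1[[1]]$volume), unclass(c3[[1]]$volume)))
})

test_that("cohort subjects differ from each other in shape", {
  coh <- fx_small_cohort()
  l1 <- unclass(coh[[1]]$labels)
  l2 <- unclass(coh[[2]]$labels)
  expect_gt(sum(l1 != l2), 0)
  # but share the label vocabulary
  expect_identical(label_values(coh[[1]]$labels),
                   label_values(coh[[2]]$labels))
})

test_that("muscle compartments are bright and mutually distinct in intensity", {
  coh <- fx_small_cohort()
  v <- unclass(coh[[1]]$volume)
  l <- unclass(coh[[1]]$labels)
  # muscles are brighter than the unlabeled surround on average (the
  # background also contains the bright fat sheath, so only the direction of
  # the contrast is a stable property, not its magnitude)
  expect_gt(mean(v[l > 0]), mean(v[l == 0]))
  # each compartment has its own mean intensity, separated beyond noise
  mus <- vapply(label_values(coh[[1]]$labels), function(k) mean(v[l == k]),
                numeric(1))
  expect_gt(min(diff(sort(mus))), 3)
})

test_that("cohort survives a NIfTI write/read round trip", {
  coh <- fx_small_cohort()[1:2]
  dir <- tempfile("cohort")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "cohort.json")))
  back <- read_cohort(dir)
  expect_length(back, 2)
  expect_equal(unclass(back[[1]]$volume), unclass(coh[[1]]$volume),
               tolerance = 1e-6)
  expect_identical(as.integer(unclass(back[[2]]$labels)),
                   as.integer(unclass(coh[[2]]$labels)))
  expect_equal(msk_spacing(back[[1]]$labels), msk_spacing(coh[[1]]$labels))
})

test_that("morph jitter scales cohort shape variability", {
  spec <- phantom_spec(grid_shape = c(24, 24, 32), n_muscles = 2, seed = 3)
  still <- generate_cohort(spec, 3, morph_jitter = 0)
  expect_identical(unclass(still[[1]]$labels), unclass(still[[2]]$labels))
  moving <- generate_cohort(spec, 3, morph_jitter = 1)
  expect_gt(sum(unclass(moving[[1]]$labels) != unclass(moving[[2]]$labels)), 0)
})
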