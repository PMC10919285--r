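test_that("metrics agree with brute-force oracles on random mask pairs", {
  sp <- c(1, 1.5, 2)   # anisotropic, so spacing handling is exercised
  for (seed in 1:25) {
    p <- random_mask_pair(seed)
    expect_equal(dsc(p$a, p$b), oracle_dsc(p$a, p$b))
    expect_equal(rve(p$a, p$b, spacing = sp), oracle_rve(p$a, p$b, sp))
    expect_equal(hausdorff(p$a, p$b, spacing = sp),
                 oracle_hausdorff(p$a, p$b, sp))
  }
})

test_that("identity masks give perfect scores", {
  p <- random_mask_pair(99)
  expect_equal(dsc(p$a, p$a), 1)
  expect_equal(rve(p$a, p$a), 0)
  expect_equal(hausdorff(p$a, p$a), 0)
})

test_that("disjoint masks give zero overlap", {
  a <- array(FALSE, c(10, 10, 10)); a[2:4, 2:4, 2:4] <- TRUE
  b <- array(FALSE, c(10, 10, 10)); b[7:9, 7:9, 7:9] <- TRUE
  expect_equal(dsc(a, b), 0)
})

test_that("distances scale linearly and volumes cubically with spacing", {
  p <- random_mask_pair(7)
  h1 <- hausdorff(p$a, p$b, spacing = c(1, 1, 1))
  h2 <- hausdorff(p$a, p$b, spacing = c(2, 2, 2))
  expect_equal(h2, 2 * h1)
  # RVE is a volume ratio: spacing cancels
  expect_equal(rve(p$a, p$b, spacing = c(1, 1, 1)),
               rve(p$a, p$b, spacing = c(3, 3, 3)))
})

test_that("dsc of two empty masks is 1 by convention", {
  e <- array(FALSE, c(5, 5, 5))
  expect_equal(dsc(e, e), 1)
})

test_that("empty masks are rejected where a surface or volume is required", {
  e <- array(FALSE, c(5, 5, 5))
  f <- array(FALSE, c(5, 5, 5)); f[3, 3, 3] <- TRUE
  expect_error(rve(f, e), "reference")
  expect_error(hausdorff(e, f), "empty")
  expect_error(hausdorff(f, e), "empty")
})

test_that("mismatched grids are rejected", {
  a <- array(TRUE, c(4, 4, 4))
  b <- array(TRUE, c(5, 4, 4))
  expect_error(dsc(a, b), "grid|dim")
})

test_that("evaluate_subject scores every reference label and flags misses", {
  ref <- msk_labelmap(array(0L, c(8, 8, 8)))
  prd <- msk_labelmap(array(0L, c(8, 8, 8)))
  r <- unclass(ref); r[2:4, 2:4, 2:4] <- 1L; r[5:7, 5:7, 5:7] <- 2L
  p <- unclass(prd); p[2:4, 2:4, 2:4] <- 1L   # label 2 never predicted
  ref <- msk_labelmap(r); prd <- msk_labelmap(p)
  ev <- evaluate_subject(prd, ref)
  expect_identical(ev$label, 1:2)
  expect_equal(ev$dsc[1], 1)
  expect_equal(ev$dsc[2], 0)
  expect_equal(ev$rve[2], 1)
  expect_true(is.na(ev$hausdorff_mm[2]))
  expect_identical(ev$missing, c(FALSE, TRUE))
})

test_that("evaluate_subject rejects labels absent from the reference", {
  lm <- msk_labelmap(array(1L, c(4, 4, 4)))
  expect_error(evaluate_subject(lm, lm, labels = 3), "absent")
})
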