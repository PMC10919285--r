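test_that("exact Wilcoxon p equals full sign-flip enumeration", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n, 0.1, 1), 3)
    while (any(d == 0) || anyDuplicated(abs(d))) d <- round(rnorm(n, 0.1, 1), 3)
    enum <- wilcoxon_exact_enum(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(enum$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(enum$statistic, unname(ref$statistic))
  }
})

test_that("enumeration rejects zeros, ties and large n", {
  expect_error(wilcoxon_exact_enum(c(0, 1, 2)), "zero")
  expect_error(wilcoxon_exact_enum(c(1, -1, 2)), "tie")
  expect_error(wilcoxon_exact_enum(rnorm(25)), "n")
})

test_that("compare_models detects a real paired difference", {
  set.seed(8)
  a <- runif(10, 0.80, 0.84)
  b <- a + runif(10, 0.02, 0.05)   # b consistently better
  cm <- compare_models(b, a)
  expect_equal(cm$n, 10)
  expect_true(cm$wilcoxon_exact)
  expect_lt(cm$wilcoxon_p_value, 0.05)
  expect_true(cm$significant)
  expect_equal(cm$wilcoxon_p_value, wilcoxon_exact_enum(b - a)$p_value,
               tolerance = 1e-12)
})

test_that("compare_models on identical scores is degenerate, not significant", {
  a <- c(0.8, 0.82, 0.85, 0.9)
  cm <- compare_models(a, a)
  expect_true(cm$degenerate)
  expect_false(cm$significant)
  expect_equal(cm$wilcoxon_p_value, 1)
})

test_that("normality assessment runs a KS test against a fitted normal", {
  set.seed(41)
  a <- rnorm(30, 0.8, 0.02)
  b <- rnorm(30, 0.82, 0.02)
  cm <- compare_models(b, a)
  expect_true(cm$ks_p_value >= 0 && cm$ks_p_value <= 1)
  expect_identical(cm$normal, cm$ks_p_value > cm$alpha)
})

test_that("mismatched score lengths are rejected", {
  expect_error(compare_models(1:3 / 10, 1:4 / 10), "length")
})
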