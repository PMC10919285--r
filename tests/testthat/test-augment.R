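test_that("the default plan grows N subjects to N + 3(N-1)", {
  coh <- fx_small_cohort()                 # N = 4
  plan <- augmentation_plan(coh)
  expect_s3_class(plan, "augmentation_plan")
  expect_equal(nrow(plan), 3 * (length(coh) - 1))
  # round-robin: each target skips a different subject
  skipped <- vapply(split(plan$reference_id, plan$target_index), function(r)
    setdiff(vapply(coh, function(s) s$id, character(1)), r), character(1))
  expect_equal(length(unique(skipped)), 3)
  expect_false(anyDuplicated(plan$new_id) > 0)
})

test_that("plan covers arbitrary target tables and rejects duplicates", {
  coh <- fx_small_cohort()
  tg <- data.frame(mode_index = c(1, 2), s = c(0.5, -1))
  plan <- augmentation_plan(coh, tg)
  expect_equal(nrow(plan), 2 * (length(coh) - 1))
  expect_setequal(unique(plan$mode_index), c(1, 2))
  coh2 <- coh
  coh2[[2]]$id <- coh2[[1]]$id
  expect_error(augmentation_plan(coh2), "duplicate")
})

test_that("build_ssms fits one model per label with donor surfaces", {
  ssms <- fx_small_ssms()
  coh <- fx_small_cohort()
  expect_s3_class(ssms, "msk_ssm_set")
  expect_length(ssms, length(label_values(coh[[1]]$labels)))
  for (mod in ssms) {
    expect_s3_class(mod, "shape_space_model")
    expect_lte(n_modes(mod), length(coh) - 1)
    expect_false(is.null(mod$donor))
  }
})

test_that("build_ssms rejects inconsistent label vocabularies", {
  coh <- fx_small_cohort()
  l <- unclass(coh[[2]]$labels)
  l[l == 4L] <- 3L
  coh[[2]] <- msk_subject(coh[[2]]$id, coh[[2]]$volume,
                          msk_labelmap(l, msk_spacing(coh[[2]]$labels)))
  expect_error(build_ssms(coh, m = 32), "vocabulary")
})

test_that("synthesised targets are valid label maps on the reference grid", {
  ssms <- fx_small_ssms()
  coh <- fx_small_cohort()
  tgt <- fx("small_target", function()
    build_target_labels(ssms, coh[[1]]$labels, mode_index = 1, s = 0))
  expect_s3_class(tgt, "msk_labelmap")
  expect_identical(dim(tgt), dim(coh[[1]]$labels))
  expect_identical(label_values(tgt), label_values(coh[[1]]$labels))
  # the mean-shape target resembles the cohort (it is their shape average)
  ev <- evaluate_subject(tgt, coh[[1]]$labels)
  expect_gt(mean(ev$dsc), 0.5)
})

test_that("produce_subject yields matched pairs reproducible from the field", {
  ssms <- fx_small_ssms()
  coh <- fx_small_cohort()
  tgt <- fx("small_target", function()
    build_target_labels(ssms, coh[[1]]$labels, mode_index = 1, s = 0))
  aug <- produce_subject(coh[[2]], tgt, "A1",
                         target_info = list(mode_index = 1, s = 0))
  expect_s3_class(aug, "msk_subject")
  expect_equal(aug$id, "A1")
  expect_equal(aug$provenance$type, "augmented")
  expect_equal(aug$provenance$reference, coh[[2]]$id)
  # the stored field reproduces the augmented labels bit for bit
  re <- warp_labels(coh[[2]]$labels, aug$provenance$field)
  expect_identical(unclass(re), unclass(aug$labels))
  # and the image was carried through the same field
  expect_identical(dim(aug$volume), dim(coh[[2]]$volume))
})

test_that("augment_cohort produces the full fan-out with provenance", {
  coh <- fx_small_cohort()
  out <- fx("small_augmented", function()
    augment_cohort(coh, ssms = fx_small_ssms()))
  expect_length(out, length(coh) + 3 * (length(coh) - 1))
  ids <- vapply(out, function(s) s$id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  plan <- attr(out, "plan")
  expect_equal(nrow(plan), 3 * (length(coh) - 1))
  added <- out[(length(coh) + 1):length(out)]
  for (k in seq_along(added)) {
    expect_equal(added[[k]]$provenance$type, "augmented")
    expect_equal(added[[k]]$id, plan$new_id[k])
    expect_equal(added[[k]]$provenance$reference, plan$reference_id[k])
  }
})

test_that("every augmented subject matches its target well", {
  coh <- fx_small_cohort()
  out <- fx("small_augmented", function()
    augment_cohort(coh, ssms = fx_small_ssms()))
  targets <- attr(out, "targets")
  added <- out[(length(coh) + 1):length(out)]
  dmins <- vapply(added, function(s) {
    tgt <- targets[[as.character(s$provenance$target$target_index)]]
    min(evaluate_subject(s$labels, tgt)$dsc)
  }, numeric(1))
  expect_gt(min(dmins), 0.7)
})
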