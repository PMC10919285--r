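test_that("the learning rate schedule is exactly geometric", {
  expect_equal(learning_rate(1), 0.01)
  for (e in 1:100) expect_identical(learning_rate(e), 0.01 * 0.9^(e - 1))
  expect_equal(learning_rate(3, lr0 = 0.1, decay = 0.5), 0.025)
  expect_error(learning_rate(0), "epoch")
})

test_that("training configuration defaults follow the architecture", {
  expect_equal(train_config("unet")$batch_size, 16L)
  expect_equal(train_config("unetpp")$batch_size, 16L)
  expect_equal(train_config("ffu")$batch_size, 10L)
  expect_equal(train_config("affu")$batch_size, 10L)
  expect_equal(train_config("unet")$crop, 256L)
  expect_equal(train_config("ffu")$crop, 125L)
  expect_equal(train_config("unet")$epochs, 100L)
  expect_equal(train_config("unet")$lr0, 0.01)
  expect_equal(train_config("unet")$lr_decay, 0.9)
  expect_equal(train_config("unet", batch_size = 4)$batch_size, 4L)
})

test_that("volumes are z-scored per volume", {
  set.seed(2)
  v <- msk_volume(array(rnorm(1000, 50, 7), c(10, 10, 10)))
  z <- normalize_volume(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(as.vector(z)), 1, tolerance = 1e-12)
  flat <- normalize_volume(msk_volume(array(5, c(4, 4, 4))))
  expect_true(all(flat == 0))
})

test_that("training logs the schedule and improves on a tiny task", {
  spec <- phantom_spec(grid_shape = c(24, 24, 16), n_muscles = 1, seed = 17)
  coh <- generate_cohort(spec, 3)
  cfg <- train_config("unet", epochs = 3, base_width = 2, depth = 4,
                      crop = 24, seed = 5)
  model <- fx("tiny_model", function() train(coh, cfg))
  expect_s3_class(model, "msk_model")
  expect_equal(model$history$epoch, 1:3)
  expect_identical(model$history$lr, 0.01 * 0.9^(0:2))
  expect_true(all(is.finite(model$history$train_loss)))
  expect_equal(model$best_epoch,
               model$history$epoch[which.max(model$history$val_dsc)])
  # validation subjects never contribute training slices
  expect_length(model$val_subjects, 1)
})

test_that("prediction returns a label map on the input grid", {
  spec <- phantom_spec(grid_shape = c(24, 24, 16), n_muscles = 1, seed = 17)
  coh <- generate_cohort(spec, 3)
  cfg <- train_config("unet", epochs = 3, base_width = 2, depth = 4,
                      crop = 24, seed = 5)
  model <- fx("tiny_model", function() train(coh, cfg))
  pred <- predict_labels(model, coh[[1]]$volume)
  expect_s3_class(pred, "msk_labelmap")
  expect_identical(dim(pred), dim(coh[[1]]$volume))
  expect_true(all(unclass(pred) %in% 0:1))
  # deterministic
  pred2 <- predict_labels(model, coh[[1]]$volume)
  expect_identical(unclass(pred), unclass(pred2))
})

test_that("leave-one-out bookkeeping evaluates every (subject, label) once", {
  spec <- phantom_spec(grid_shape = c(20, 20, 16), n_muscles = 3, seed = 23)
  coh <- generate_cohort(spec, 5)
  stub_register(coh)
  ex <- run_experiment(coh, design = "cross_validation",
                       trainer = stub_trainer, predictor = stub_predictor)
  expect_equal(nrow(ex$results), 5 * 3)
  expect_equal(sort(unique(ex$results$subject)),
               sort(vapply(coh, function(s) s$id, character(1))))
  expect_length(ex$folds, 5)
  for (k in seq_along(ex$folds)) {
    expect_length(ex$folds[[k]]$train, 4)
    expect_false(ex$folds[[k]]$test %in% ex$folds[[k]]$train)
  }
  # the stub predicts the reference itself: perfect scores
  expect_true(all(ex$results$dsc == 1))
})

test_that("cross-cohort design trains once and scores the test cohort", {
  spec <- phantom_spec(grid_shape = c(20, 20, 16), n_muscles = 2, seed = 29)
  train_coh <- generate_cohort(spec, 3)
  test_coh <- generate_cohort(spec, 4, seed = 31)
  for (k in seq_along(test_coh)) test_coh[[k]]$id <- sprintf("T%02d", k)
  stub_register(c(train_coh, test_coh))
  ex <- run_experiment(train_coh, design = "cross_cohort",
                       test_cohort = test_coh,
                       trainer = stub_trainer, predictor = stub_predictor)
  expect_equal(nrow(ex$results), 4 * 2)
  expect_true(all(ex$results$dsc == 1))
  expect_length(ex$models, 1)
  expect_error(run_experiment(train_coh, design = "cross_cohort",
                              test_cohort = train_coh,
                              trainer = stub_trainer,
                              predictor = stub_predictor),
               "shares")
})

test_that("augmented folds exclude subjects derived from the held-out one", {
  spec <- phantom_spec(grid_shape = c(20, 20, 16), n_muscles = 2, seed = 37)
  coh <- generate_cohort(spec, 3)
  extra <- lapply(seq_along(coh), function(k)
    msk_subject(sprintf("%s_T01", coh[[k]]$id), coh[[k]]$volume,
                coh[[k]]$labels,
                provenance = list(type = "augmented",
                                  reference = coh[[k]]$id)))
  stub_register(coh)
  ex <- run_experiment(coh, design = "augmented", extra = extra,
                       trainer = stub_trainer, predictor = stub_predictor)
  ids <- vapply(coh, function(s) s$id, character(1))
  for (k in seq_along(ex$folds)) {
    held <- ex$folds[[k]]$test
    expect_false(sprintf("%s_T01", held) %in% ex$folds[[k]]$train)
    # the other augmented subjects are included
    expect_equal(sum(grepl("_T01$", ex$folds[[k]]$train)), length(coh) - 1)
  }
})
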