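# Training and prediction for the 2-D segmentation networks, plus the
# experiment designs used to evaluate them (leave-one-out cross-validation,
# cross-cohort testing, and training on an augmented cohort).
#
# Volumes are segmented slice by slice along the third axis: each axial slice
# is one training sample. Images are z-scored per volume, training slices are
# randomly cropped, and optimisation is SGD with momentum under a per-epoch
# geometric learning-rate decay.

#' Training configuration
#'
#' Defaults follow the architecture: the fusion networks ("ffu"/"affu") use a
#' smaller batch because their multi-scale fusion path holds more activations
#' per sample.
#'
#' @param arch one of "unet", "unetpp", "ffu", "affu".
#' @param epochs number of training epochs.
#' @param batch_size samples per SGD step; `NULL` picks 16 for
#'   "unet"/"unetpp" and 10 for "ffu"/"affu".
#' @param lr0 initial learning rate.
#' @param lr_decay per-epoch geometric decay factor.
#' @param momentum SGD momentum coefficient.
#' @param crop square crop side for training slices; `NULL` picks 256 for
#'   "unet"/"unetpp" and 125 for "ffu"/"affu", each clamped to the slice side
#'   when the slices are smaller.
#' @param val_fraction fraction of training *subjects* held out for
#'   validation (at least one subject).
#' @param stop_dsc optional validation-Dice target; training stops early at
#'   the end of the first epoch whose validation DSC reaches it.
#' @param base_width,depth,aspp_rates passed to [network_config()].
#' @param seed integer seed controlling initialisation, the validation split
#'   and crop sampling.
#' @return list of class `train_config`.
#' @export
train_config <- function(arch = c("unet", "unetpp", "ffu", "affu"),
                         epochs = 100, batch_size = NULL,
                         lr0 = 0.01, lr_decay = 0.9, momentum = 0.9,
                         crop = NULL, val_fraction = 0.2, stop_dsc = NULL,
                         base_width = 64, depth = 5,
                         aspp_rates = c(1, 2, 4, 8), seed = 1) {
  arch <- match.arg(arch)
  if (is.null(batch_size))
    batch_size <- if (arch %in% c("unet", "unetpp")) 16L else 10L
  if (is.null(crop))
    crop <- if (arch %in% c("unet", "unetpp")) 256L else 125L
  stopifnot(epochs >= 1, batch_size >= 1, lr0 > 0,
            lr_decay > 0, lr_decay <= 1, val_fraction > 0, val_fraction < 1)
  structure(list(arch = arch, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 lr_decay = lr_decay, momentum = momentum,
                 crop = as.integer(crop), val_fraction = val_fraction,
                 stop_dsc = stop_dsc,
                 base_width = as.integer(base_width),
                 depth = as.integer(depth), aspp_rates = aspp_rates,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' The schedule is geometric: `lr0 * decay^(epoch - 1)`, so the first epoch
#' trains at `lr0` exactly.
#'
#' @param epoch 1-based epoch index.
#' @param lr0 initial learning rate.
#' @param decay per-epoch decay factor.
#' @return the learning rate.
#' @export
learning_rate <- function(epoch, lr0 = 0.01, decay = 0.9) {
  stopifnot(epoch >= 1)
  lr0 * decay^(epoch - 1)
}

#' Z-score normalise a volume
#'
#' @param volume an [msk_volume()] or plain array.
#' @return array of the same shape with zero mean and unit variance (left
#'   unscaled when the volume is constant).
#' @export
normalize_volume <- function(volume) {
  v <- unclass(volume)
  attributes(v) <- list(dim = dim(v))
  s <- stats::sd(as.vector(v))
  if (s < 1e-12) v - mean(v) else (v - mean(v)) / s
}

# Slice dataset: every axial slice of every subject, with a subject index so
# splits can be made per subject (slices of one subject never straddle the
# train/validation boundary).
slice_dataset <- function(subjects) {
  imgs <- list(); labs <- list(); subj <- integer()
  for (k in seq_along(subjects)) {
    v <- normalize_volume(subjects[[k]]$volume)
    l <- unclass(subjects[[k]]$labels)
    nz <- dim(v)[3]
    for (z in seq_len(nz)) {
      imgs[[length(imgs) + 1L]] <- v[, , z]
      labs[[length(labs) + 1L]] <- l[, , z]
      subj <- c(subj, k)
    }
  }
  list(images = imgs, labels = labs, subject = subj)
}

random_crop <- function(img, lab, side) {
  d <- dim(img)
  side <- min(side, d[1], d[2])
  i0 <- if (d[1] > side) sample.int(d[1] - side + 1L, 1L) else 1L
  j0 <- if (d[2] > side) sample.int(d[2] - side + 1L, 1L) else 1L
  list(img = img[i0:(i0 + side - 1L), j0:(j0 + side - 1L)],
       lab = lab[i0:(i0 + side - 1L), j0:(j0 + side - 1L)])
}

# Stack a list of equally-sized slices into (H, W, 1, B) / (H, W, B)
stack_images <- function(slices) {
  d <- dim(slices[[1]])
  array(unlist(slices, use.names = FALSE), c(d[1], d[2], 1, length(slices)))
}
stack_labels <- function(slices) {
  d <- dim(slices[[1]])
  array(as.integer(unlist(slices, use.names = FALSE)),
        c(d[1], d[2], length(slices)))
}

# One SGD-with-momentum update over the gradients left by ag_backward().
sgd_step <- function(net, touched, vel, lr, momentum) {
  for (nm in names(touched)) {
    g <- touched[[nm]]$grad
    if (is.null(g)) next
    v <- if (is.null(vel[[nm]])) 0 else vel[[nm]]
    v <- momentum * v - lr * g
    vel[[nm]] <- v
    net$params[[nm]] <- net$params[[nm]] + v
  }
  vel
}

# Mean foreground-class Dice of hard predictions against labels, the model
# selection score on the validation slices.
mean_class_dsc <- function(pred, lab, n_classes) {
  cls <- seq_len(n_classes - 1L)        # skip background
  ds <- vapply(cls, function(c) {
    a <- pred == c; b <- lab == c
    if (!any(a) && !any(b)) return(NA_real_)
    2 * sum(a & b) / (sum(a) + sum(b))
  }, numeric(1))
  if (all(is.na(ds))) 1 else mean(ds, na.rm = TRUE)
}

predict_slices <- function(net, imgs, batch_size = 8L) {
  out <- vector("list", length(imgs))
  i <- 1L
  while (i <= length(imgs)) {
    j <- min(i + batch_size - 1L, length(imgs))
    x <- stack_images(imgs[i:j])
    fw <- network_forward(net, x, train = FALSE)
    p <- softmax_probs(fw$logits$value)
    for (b in seq_len(j - i + 1L))
      out[[i + b - 1L]] <- apply(p[, , , b, drop = FALSE][, , , 1], c(1, 2),
                                 which.max) - 1L
    i <- j + 1L
  }
  out
}

#' Train a segmentation network on a list of subjects
#'
#' Subjects are split into training and validation sets (whole subjects, so
#' no volume contributes slices to both), slices are z-scored per volume, and
#' the network is trained with momentum SGD under the geometric
#' learning-rate schedule of [learning_rate()]. Training slices are randomly
#' cropped each epoch; validation slices are used whole. The returned model
#' is the epoch checkpoint with the best validation Dice.
#'
#' @param subjects list of [msk_subject()]s.
#' @param config a [train_config()].
#' @param n_classes number of output classes including background; `NULL`
#'   infers `max(label) + 1` over the subjects.
#' @param verbose print a line per epoch.
#' @return list of class `msk_model`: `net` (best checkpoint), `config`,
#'   `n_classes`, `history` (per-epoch data.frame with `epoch`, `lr`,
#'   `train_loss`, `val_dsc`), `best_epoch`, `val_subjects`.
#' @export
train <- function(subjects, config = train_config(), n_classes = NULL,
                  verbose = FALSE) {
  stopifnot(length(subjects) >= 2)
  if (is.null(n_classes))
    n_classes <- max(vapply(subjects, function(s)
      max(as.vector(s$labels)), numeric(1))) + 1L
  set.seed(config$seed)
  n <- length(subjects)
  n_val <- max(1L, round(config$val_fraction * n))
  val_idx <- sample.int(n, n_val)
  ds_tr <- slice_dataset(subjects[-val_idx])
  ds_va <- slice_dataset(subjects[val_idx])

  cfg <- network_config(config$arch, n_classes = n_classes,
                        base_width = config$base_width, depth = config$depth,
                        aspp_rates = config$aspp_rates, seed = config$seed)
  net <- build_network(cfg)
  vel <- list()
  n_tr <- length(ds_tr$images)
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), val_dsc = numeric())
  best <- list(dsc = -Inf, epoch = 0L, params = NULL, bn = NULL)
  first_loss <- NA_real_

  for (e in seq_len(config$epochs)) {
    lr <- learning_rate(e, config$lr0, config$lr_decay)
    ord <- sample.int(n_tr)
    losses <- numeric()
    i <- 1L
    while (i <= n_tr) {
      j <- min(i + config$batch_size - 1L, n_tr)
      idx <- ord[i:j]
      cr <- lapply(idx, function(k)
        random_crop(ds_tr$images[[k]], ds_tr$labels[[k]], config$crop))
      x <- stack_images(lapply(cr, `[[`, "img"))
      y <- stack_labels(lapply(cr, `[[`, "lab"))
      fw <- network_forward(net, x, train = TRUE, labels = y)
      ag_backward(fw$loss)
      losses <- c(losses, fw$loss$value)
      vel <- sgd_step(net, fw$params, vel, lr, config$momentum)
      i <- j + 1L
    }
    tl <- mean(losses)
    if (is.na(first_loss)) first_loss <- tl
    if (!is.finite(tl) || tl > 20 * max(first_loss, 1))
      stop(sprintf("training diverged at epoch %d (loss %.3g)", e, tl))
    preds <- predict_slices(net, ds_va$images)
    vd <- mean(vapply(seq_along(preds), function(k)
      mean_class_dsc(preds[[k]], ds_va$labels[[k]], n_classes), numeric(1)))
    hist <- rbind(hist, data.frame(epoch = e, lr = lr, train_loss = tl,
                                   val_dsc = vd))
    if (vd > best$dsc)
      best <- list(dsc = vd, epoch = e, params = net$params,
                   bn = lapply(net$bn, function(s) as.list(s)))
    if (verbose)
      cat(sprintf("epoch %3d  lr %.5f  loss %.4f  val DSC %.4f\n",
                  e, lr, tl, vd))
    if (!is.null(config$stop_dsc) && vd >= config$stop_dsc) break
  }
  # restore the best checkpoint
  net$params <- best$params
  for (nm in names(best$bn)) {
    net$bn[[nm]]$mean <- best$bn[[nm]]$mean
    net$bn[[nm]]$var <- best$bn[[nm]]$var
  }
  structure(list(net = net, config = config, n_classes = n_classes,
                 history = hist, best_epoch = best$epoch,
                 val_subjects = vapply(subjects[val_idx], function(s) s$id,
                                       character(1))),
            class = "msk_model")
}

#' @export
print.msk_model <- function(x, ...) {
  cat(sprintf("<msk_model %s> %d epochs, best val DSC %.4f at epoch %d\n",
              x$config$arch, nrow(x$history),
              max(x$history$val_dsc), x$best_epoch))
  invisible(x)
}

#' Segment a volume with a trained model
#'
#' The volume is z-scored, segmented slice by slice (deterministic: no crops,
#' batch norm in inference mode) and the per-voxel argmax label returned.
#'
#' @param model an `msk_model` from [train()].
#' @param volume an [msk_volume()].
#' @return an [msk_labelmap()] of predicted labels on the volume's grid.
#' @export
predict_labels <- function(model, volume) {
  stopifnot(inherits(model, "msk_model"))
  v <- normalize_volume(volume)
  imgs <- lapply(seq_len(dim(v)[3]), function(z) v[, , z])
  preds <- predict_slices(model$net, imgs)
  out <- array(0L, dim(v))
  for (z in seq_along(preds)) out[, , z] <- preds[[z]]
  msk_labelmap(out, spacing = msk_spacing(volume))
}

#' Run a segmentation experiment over a cohort
#'
#' Three designs are supported. `"cross_validation"` trains one model per
#' held-out subject (leave-one-out) and evaluates it on that subject.
#' `"cross_cohort"` trains a single model on `cohort` and evaluates it on
#' every subject of `test_cohort`. `"augmented"` behaves like
#' `"cross_validation"` but adds `extra` (augmented) subjects to every
#' training set; augmented subjects derived from the held-out original (their
#' provenance names it as reference) are excluded from that fold, so no fold
#' sees any version of its test subject.
#'
#' @param cohort list of [msk_subject()]s used for training.
#' @param design one of "cross_validation", "cross_cohort", "augmented".
#' @param test_cohort evaluation subjects for "cross_cohort".
#' @param extra additional training subjects for "augmented" (typically the
#'   augmented part of an [augment_cohort()] result).
#' @param config a [train_config()].
#' @param trainer,predictor the training and prediction functions; default
#'   [train()] and [predict_labels()]. Injectable so the experiment
#'   bookkeeping can be exercised with a cheap surrogate model.
#' @param ... passed on to `trainer`.
#' @return list of class `msk_experiment`: `design`, `results` (data.frame
#'   with one row per evaluated (subject, label): `subject`, `label`, `dsc`,
#'   `rve`, `hausdorff_mm`, `missing`), `models` (one per fold, or one for
#'   "cross_cohort"), `folds` (train/test ids per fold).
#' @export
run_experiment <- function(cohort,
                           design = c("cross_validation", "cross_cohort",
                                      "augmented"),
                           test_cohort = NULL, extra = NULL,
                           config = train_config(),
                           trainer = train, predictor = predict_labels, ...) {
  design <- match.arg(design)
  ids <- vapply(cohort, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids in cohort")

  eval_one <- function(model, subject) {
    pred <- predictor(model, subject$volume)
    ev <- evaluate_subject(msk_labelmap(unclass(pred),
                                        spacing = msk_spacing(subject$labels)),
                           subject$labels)
    cbind(subject = subject$id, ev)
  }

  if (design == "cross_cohort") {
    if (is.null(test_cohort)) stop("cross_cohort needs a test_cohort")
    tids <- vapply(test_cohort, function(s) s$id, character(1))
    if (length(intersect(ids, tids)) > 0)
      stop("test_cohort shares subjects with the training cohort: ",
           paste(intersect(ids, tids), collapse = ", "))
    model <- trainer(cohort, config, ...)
    res <- do.call(rbind, lapply(test_cohort, eval_one, model = model))
    folds <- list(list(train = ids, test = tids))
    models <- list(model)
  } else {
    if (design == "augmented") {
      if (is.null(extra)) stop("augmented design needs `extra` subjects")
      ref_of <- vapply(extra, function(s)
        s$provenance$reference %||% NA_character_, character(1))
    }
    folds <- vector("list", length(cohort))
    models <- vector("list", length(cohort))
    res <- NULL
    for (k in seq_along(cohort)) {
      trs <- cohort[-k]
      if (design == "augmented")
        trs <- c(trs, extra[is.na(ref_of) | ref_of != ids[k]])
      model <- trainer(trs, config, ...)
      res <- rbind(res, eval_one(model, cohort[[k]]))
      folds[[k]] <- list(train = vapply(trs, function(s) s$id, character(1)),
                         test = ids[k])
      models[[k]] <- model
    }
  }
  rownames(res) <- NULL
  structure(list(design = design, results = res, models = models,
                 folds = folds),
            class = "msk_experiment")
}

#' @export
print.msk_experiment <- function(x, ...) {
  cat(sprintf("<msk_experiment %s> %d folds, %d evaluated labels, mean DSC %.4f\n",
              x$design, length(x$folds), nrow(x$results),
              mean(x$results$dsc)))
  invisible(x)
}
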