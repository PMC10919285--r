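# Shape-model-driven cohort augmentation.
#
# From an annotated cohort: (1) build one PCA shape model per muscle label
# from optimized particle correspondences; (2) synthesise whole-subject
# target label maps at chosen shape-space coordinates (the model mean and the
# one-SD shapes of the first mode); (3) deformably register each reference
# subject's labels onto each target and carry the image and labels through
# the same displacement field. Every target is paired with all but one
# original subject in a round-robin, so a cohort of N grows to N + T*(N-1)
# subjects (10 -> 37 with the default three targets).

#' Build per-label shape-space models from a cohort
#'
#' For every muscle label, extracts each subject's surface point cloud, runs
#' particle correspondence across the cohort, and fits a PCA shape model.
#'
#' @param cohort list of [msk_subject()]s sharing one grid and label
#'   vocabulary.
#' @param labels labels to model; defaults to all non-zero labels of the
#'   first subject.
#' @param m particles per shape (default 256).
#' @param iters correspondence iterations per stage.
#' @param seed integer seed for the correspondence optimiser.
#' @return named list of `shape_space_model`s (class `msk_ssm_set`), one per
#'   label, each carrying the label id as attribute `"label"`.
#' @export
build_ssms <- function(cohort, labels = NULL, m = 256, iters = 6, seed = 1) {
  stopifnot(length(cohort) >= 2)
  for (s in cohort[-1]) check_same_grid(cohort[[1]]$labels, s$labels)
  if (is.null(labels)) labels <- label_values(cohort[[1]]$labels)
  vocab_ok <- vapply(cohort, function(s)
    setequal(label_values(s$labels), labels), logical(1))
  if (!all(vocab_ok))
    stop("subjects ", paste(which(!vocab_ok), collapse = ", "),
         " do not carry the expected label vocabulary")
  models <- lapply(labels, function(l) {
    surfs <- lapply(cohort, function(s) extract_surface(s$labels, l))
    ps <- optimize_correspondence(surfs, m = m, iters = iters,
                                  seed = seed + l)
    mod <- fit_pca(ps)
    # donor surface for rasterisation: the first subject's dense boundary
    # cloud with outward normals from its mask's signed-distance gradient,
    # plus the donor's particle positions, all in the centred model frame.
    # Synthesised shapes are rasterised by carrying the particle
    # displacements onto this dense cloud, which is far more robust than
    # rasterising the sparse particles directly.
    cc <- colMeans(ps$shapes[[1]])   # residual centring of the model frame
    mod$donor <- list(
      cloud = sweep(surfs[[1]], 2, ps$alignment$translations[1, ] + cc),
      normals = mask_surface_normals(cohort[[1]]$labels, l, surfs[[1]]),
      particles = sweep(ps$shapes[[1]], 2, cc))
    attr(mod, "label") <- l
    mod
  })
  names(models) <- as.character(labels)
  structure(models, class = "msk_ssm_set")
}

#' Augmentation plan: shape-space targets and round-robin references
#'
#' The default targets are the shape-model mean and the plus/minus one-SD
#' shapes of the first principal mode. Each target is paired with all but one
#' original subject; the left-out subject rotates round-robin so every
#' original is skipped by at most ceil(T / N) targets. A cohort of N subjects
#' therefore yields T * (N - 1) augmented subjects.
#'
#' @param cohort list of [msk_subject()]s.
#' @param targets data.frame with columns `mode_index` and `s` (SD units),
#'   one row per target; `NULL` gives the default mean / +1 SD / -1 SD of
#'   mode 1.
#' @return data.frame of class `augmentation_plan` with one row per planned
#'   augmented subject: `target_index`, `mode_index`, `s`, `reference_id`,
#'   `new_id`.
#' @export
augmentation_plan <- function(cohort, targets = NULL) {
  n <- length(cohort)
  if (n < 2) stop("augmentation needs at least 2 subjects")
  ids <- vapply(cohort, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids in cohort")
  if (is.null(targets))
    targets <- data.frame(mode_index = c(1, 1, 1), s = c(0, 1, -1))
  stopifnot(all(c("mode_index", "s") %in% names(targets)))
  rows <- lapply(seq_len(nrow(targets)), function(t) {
    skip <- ((t - 1) %% n) + 1          # round-robin left-out subject
    refs <- ids[-skip]
    data.frame(target_index = t,
               mode_index = targets$mode_index[t],
               s = targets$s[t],
               reference_id = refs,
               new_id = sprintf("%s_T%02d", refs, t))
  })
  plan <- do.call(rbind, rows)
  class(plan) <- c("augmentation_plan", "data.frame")
  plan
}

# Carry a synthesised particle shape onto the model's dense donor cloud:
# the per-particle displacement (synthesised minus donor particles) is
# interpolated at every dense donor point by inverse-distance weighting of
# the k nearest particles. Rasterising the dense deformed cloud is far more
# robust than rasterising the sparse particles themselves.
densify_synthesis <- function(model, synth, k = 4) {
  if (is.null(model$donor))
    stop("model carries no donor surface; rebuild it with build_ssms()")
  delta <- synth - model$donor$particles
  kn <- cpp_knn(model$donor$cloud, model$donor$particles, as.integer(k))
  w <- 1 / (kn$dist + 1e-6)
  w <- w / rowSums(w)
  d_dense <- vapply(1:3, function(c)
    rowSums(w * matrix(delta[kn$idx, c], nrow(w))), numeric(nrow(w)))
  list(points = model$donor$cloud + d_dense, normals = model$donor$normals)
}

#' Synthesise a whole-subject target label map from shape models
#'
#' Each label's shape is synthesised at the requested shape-space coordinate,
#' rasterised to a signed distance field on the reference grid, and the
#' fields are composited: a voxel takes the label whose surface it is most
#' interior to. Voxels claimed by more than one label are resolved that way.
#' Adjacent compartments legitimately contest a thin band along shared faces,
#' so only deep conflicts count as inconsistency: voxels that lie more than
#' one voxel inside two different shapes. If those exceed `max_overlap` of
#' the total foreground, an error names the offending labels.
#'
#' @param ssms an `msk_ssm_set` from [build_ssms()].
#' @param reference_grid a volume/label map or `list(dim =, spacing =)`.
#' @param mode_index,s shape-space coordinate passed to
#'   [synthesize_shape()] for every label.
#' @param max_overlap largest tolerated fraction of deeply multiply-claimed
#'   foreground voxels (default 0.05).
#' @return a [msk_labelmap()] of the composite target.
#' @export
build_target_labels <- function(ssms, reference_grid, mode_index = 1, s = 0,
                                max_overlap = 0.05) {
  stopifnot(inherits(ssms, "msk_ssm_set"))
  geo <- grid_geometry(reference_grid)
  labels <- as.integer(names(ssms))
  depth <- mean(geo$spacing)          # "deep" = more than one voxel inside
  sdf_min <- array(Inf, geo$dim)
  win <- array(0L, geo$dim)
  n_claim <- array(0L, geo$dim)
  n_deep <- array(0L, geo$dim)
  for (i in seq_along(ssms)) {
    pts <- synthesize_shape(ssms[[i]], mode_index = mode_index, s = s)
    dens <- densify_synthesis(ssms[[i]], pts)
    pts <- sweep(dens$points, 2, ssms[[i]]$origin, `+`)
    sdf <- signed_distance_field(pts, geo, normals = dens$normals)
    inside <- sdf < 0
    n_claim <- n_claim + inside
    n_deep <- n_deep + (sdf < -depth)
    take <- inside & sdf < sdf_min
    sdf_min[take] <- sdf[take]
    win[take] <- labels[i]
  }
  fg <- n_claim > 0L
  if (any(fg)) {
    ov <- sum(n_deep > 1L) / sum(fg)
    if (ov > max_overlap) {
      bad <- sort(unique(win[n_deep > 1L]))
      stop(sprintf(
        "synthesised shapes deeply overlap on %.1f%% of foreground (> %.0f%%); labels involved: %s",
        100 * ov, 100 * max_overlap, paste(bad, collapse = ", ")))
    }
  }
  msk_labelmap(win, spacing = geo$spacing)
}

#' Registration parameters scaled for augmentation on test-size grids
#'
#' Phantom compartments span only 10-20 voxels on the default 48 x 48 x 96
#' grid, so the registration that carries a reference onto a synthesised
#' target needs a finer nodal grid, a lighter smoothness weight and a
#' boundary-focused similarity (small distance clamp) than the defaults of
#' [registration_params()], which suit whole-volume alignment. Two pyramid
#' levels give the capture range; 20 L-BFGS iterations per level suffice
#' because the SDF-channel objective is smooth.
#'
#' @return a [registration_params()] object.
#' @export
augmentation_params <- function() {
  registration_params(nodal_spacing_vox = 2, smoothing_lambda = 5,
                      max_iters = 20, pyramid_levels = 2,
                      clamp_dist_vox = 3)
}

#' Produce one augmented subject from a reference and a target label map
#'
#' Registers the reference subject's label map onto the target and applies
#' the recovered displacement field to the reference image (trilinear) and
#' labels (nearest neighbour). The field is stored in the provenance, so the
#' augmented labels can be reproduced exactly by re-warping the reference.
#'
#' @param reference a [msk_subject()].
#' @param target_labels a [msk_labelmap()] on the reference grid.
#' @param id identifier for the new subject.
#' @param params [registration_params()] for the label registration.
#' @param target_info optional list describing the shape-space coordinate,
#'   stored in the provenance.
#' @return an augmented [msk_subject()]; `provenance$field` is the
#'   `msk_field` that produced it.
#' @export
produce_subject <- function(reference, target_labels, id,
                            params = augmentation_params(),
                            target_info = NULL) {
  stopifnot(inherits(reference, "msk_subject"),
            inherits(target_labels, "msk_labelmap"))
  check_same_grid(reference$labels, target_labels)
  reg <- register(reference$labels, target_labels, params)
  msk_subject(id,
              warp_volume(reference$volume, reg$field),
              warp_labels(reference$labels, reg$field),
              provenance = list(type = "augmented",
                                reference = reference$id,
                                target = target_info,
                                field = reg$field))
}

#' Augment a cohort through its shape models
#'
#' Runs the full pipeline: per-label shape models, target synthesis at each
#' planned shape-space coordinate, and one deformable registration per
#' (target, reference) pair. Any failure in model building, target synthesis
#' or registration aborts the augmentation: a partially augmented cohort is
#' worse than none for downstream training.
#'
#' @param cohort list of [msk_subject()]s.
#' @param plan an [augmentation_plan()]; `NULL` uses the default
#'   mean / +1 SD / -1 SD plan.
#' @param ssms pre-built [build_ssms()] output, or `NULL` to build here.
#' @param params [registration_params()] used for every registration.
#' @param m particles per shape when building the models.
#' @param seed seed for the correspondence optimiser.
#' @return list of subjects: the originals followed by the augmented ones
#'   (N + T*(N-1) in total).
#' @export
augment_cohort <- function(cohort, plan = NULL, ssms = NULL,
                           params = augmentation_params(),
                           m = 256, seed = 1) {
  if (is.null(plan)) plan <- augmentation_plan(cohort)
  if (is.null(ssms)) ssms <- build_ssms(cohort, m = m, seed = seed)
  ids <- vapply(cohort, function(s) s$id, character(1))
  grid <- cohort[[1]]$labels
  tdefs <- unique(plan[, c("target_index", "mode_index", "s")])
  target_maps <- lapply(seq_len(nrow(tdefs)), function(i)
    build_target_labels(ssms, grid, mode_index = tdefs$mode_index[i],
                        s = tdefs$s[i]))
  names(target_maps) <- as.character(tdefs$target_index)
  augmented <- lapply(seq_len(nrow(plan)), function(r) {
    ref <- cohort[[match(plan$reference_id[r], ids)]]
    produce_subject(ref, target_maps[[as.character(plan$target_index[r])]],
                    id = plan$new_id[r], params = params,
                    target_info = list(target_index = plan$target_index[r],
                                       mode_index = plan$mode_index[r],
                                       s = plan$s[r]))
  })
  out <- c(cohort, augmented)
  attr(out, "plan") <- plan
  attr(out, "targets") <- target_maps
  out
}
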