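#' Specification for a synthetic lower-limb phantom
#'
#' Describes the geometry and intensity model of a seeded synthetic
#' "subject": elongated quasi-cylindrical muscle compartments arranged around
#' a central bone cylinder, wrapped in a bright fat rind, with per-compartment
#' mean intensities, a smooth multiplicative bias field and additive noise.
#' Phantoms emulate merged knee-to-hip MR volumes resampled to isotropic
#' 1 mm voxels; they make every downstream module testable without data.
#'
#' @param grid_shape integer length-3, voxels per axis; the third axis is the
#'   limb's long axis. All entries must be >= 16.
#' @param spacing_mm voxel size in mm per axis (default 1 mm isotropic).
#' @param n_muscles number of labelled compartments (default 16, the number
#'   of evaluated muscles).
#' @param fat_thickness_vox thickness of the subcutaneous fat rind in voxels.
#' @param noise_sigma additive Gaussian noise SD relative to the mean muscle
#'   intensity (default 0.05).
#' @param bias_field_amplitude peak relative amplitude of the smooth
#'   multiplicative intensity inhomogeneity (default 0.2).
#' @param seed integer; identical specs (including seed) generate
#'   bit-identical phantoms.
#' @param shape_family `"multi"` draws independent low-order shape
#'   coefficients per compartment; `"single_mode"` drives the whole
#'   cross-section with one scalar per subject, so cohort shape variation is
#'   genuinely one-dimensional (used by shape-model recovery checks).
#' @param shape_cv approximate coefficient of variation of compartment radii
#'   across a cohort at `morph_jitter = 1`.
#' @param rician logical; use Rician instead of additive Gaussian noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 96), spacing_mm = c(1, 1, 1),
                         n_muscles = 16, fat_thickness_vox = 3,
                         noise_sigma = 0.05, bias_field_amplitude = 0.2,
                         seed = 1, shape_family = c("multi", "single_mode"),
                         shape_cv = 0.08, rician = FALSE) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("grid_shape must have three entries, all >= 16")
  if (n_muscles < 1L) stop("n_muscles must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 n_muscles = as.integer(n_muscles),
                 fat_thickness_vox = fat_thickness_vox,
                 noise_sigma = noise_sigma,
                 bias_field_amplitude = bias_field_amplitude,
                 seed = as.integer(seed),
                 shape_family = match.arg(shape_family),
                 shape_cv = shape_cv, rician = rician),
            class = "phantom_spec")
}

# Draw the low-order shape coefficients for one subject. The cross-sectional
# radius of compartment k is scaled by s_k = 1 + jitter * cv * <low-order
# combination of the coefficients>, so a cohort's shape distribution is
# controlled by a handful of numbers per subject.
draw_shape_coeffs <- function(spec, morph_jitter) {
  n <- spec$n_muscles
  if (spec$shape_family == "single_mode") {
    list(c = rnorm(1), a = numeric(n), b = numeric(n),
         jitter = morph_jitter)
  } else {
    list(c = 0, a = rnorm(n), b = rnorm(n), jitter = morph_jitter)
  }
}

# Per-compartment, per-slice radial scale factors (n_muscles x nz matrix).
compartment_scales <- function(spec, coeffs) {
  n <- spec$n_muscles
  nz <- spec$grid_shape[3]
  zf <- cos(pi * seq_len(nz) / nz)  # one smooth axial pattern
  amp <- coeffs$jitter * spec$shape_cv
  if (spec$shape_family == "single_mode") {
    # fixed compartment weighting; variation spans exactly one direction
    w <- cos(2 * pi * seq_len(n) / max(n, 2)) * 0.5 + 1
    s <- 1 + amp * coeffs$c * outer(w, rep(1, nz))
  } else {
    s <- 1 + amp * (outer(coeffs$a, rep(1, nz)) + 0.5 * outer(coeffs$b, zf))
  }
  pmax(s, 0.5)
}

#' Generate one synthetic subject
#'
#' Builds a matched (image, label) pair. Compartments are pairwise-disjoint
#' angular sectors of an annulus between the bone and the fat rind; their
#' outer radii vary smoothly along the limb axis and across subjects via a
#' low-dimensional family of scale factors, so a cohort has a genuinely
#' low-rank shape distribution.
#'
#' @param spec a [phantom_spec()].
#' @param morph_jitter scale of the per-subject random deformation (0 =
#'   canonical anatomy; 1 = cohort default).
#' @param id subject identifier.
#' @param coeffs optional pre-drawn shape coefficients (used by
#'   [generate_cohort()] so cohort randomness is reproducible); when `NULL`
#'   they are drawn from `spec$seed`.
#' @return A [msk_subject()] with provenance type "original".
#' @export
generate_subject <- function(spec, morph_jitter = 1, id = "S1", coeffs = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  n <- spec$n_muscles
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  if (is.null(coeffs)) coeffs <- draw_shape_coeffs(spec, morph_jitter)

  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  rmin <- min(nx, ny)
  r_fat_out <- 0.47 * rmin
  r_fat_in <- r_fat_out - spec$fat_thickness_vox
  r_bone <- max(2, 0.10 * rmin)
  r_musc_in <- r_bone + 1
  # sizing check: every wedge needs >= 2 voxels of arc at its inner radius
  if (2 * pi * (r_musc_in + 1) / n < 2)
    stop("grid too small to fit ", n, " muscle compartments: ",
         "increase grid_shape or reduce n_muscles")

  x <- seq_len(nx) - cx
  y <- seq_len(ny) - cy
  r2d <- sqrt(outer(x^2, y^2, `+`))
  th <- atan2(outer(rep(1, nx), y), outer(x, rep(1, ny)))  # nx x ny
  wedge <- (floor(((th + pi) / (2 * pi)) * n) %% n) + 1L    # nx x ny in 1..n

  prof <- 0.85 + 0.15 * sin(pi * seq_len(nz) / (nz + 1))    # axial taper
  scl <- compartment_scales(spec, coeffs)                    # n x nz

  lab <- array(0L, dim = c(nx, ny, nz))
  mu <- array(15, dim = c(nx, ny, nz))                       # background
  mu_musc <- 90 + 30 * (seq_len(n) - 1) / max(1, n - 1)
  for (z in seq_len(nz)) {
    rz_fat_out <- r_fat_out * prof[z]
    rz_fat_in <- r_fat_in * prof[z]
    rz_musc_out <- (r_fat_in - 1) * prof[z] * scl[wedge, z]  # nx x ny
    dim(rz_musc_out) <- c(nx, ny)
    sl <- integer(nx * ny); dim(sl) <- c(nx, ny)
    in_musc <- r2d > r_musc_in & r2d <= rz_musc_out
    sl[in_musc] <- wedge[in_musc]
    lab[, , z] <- sl
    mz <- matrix(15, nx, ny)
    mz[r2d <= rz_fat_out] <- 190                             # fat disc first
    mz[r2d <= rz_fat_in] <- 60                               # unlabeled tissue
    mz[in_musc] <- mu_musc[wedge[in_musc]]
    mz[r2d <= r_bone] <- 40                                  # bone
    mu[, , z] <- mz
  }

  # smooth multiplicative bias: three random low-frequency cosine products
  if (spec$bias_field_amplitude > 0) {
    gx <- seq_len(nx) / nx; gy <- seq_len(ny) / ny; gz <- seq_len(nz) / nz
    f <- array(0, dim = c(nx, ny, nz))
    for (t in 1:3) {
      ph <- runif(3, 0, 2 * pi); wv <- runif(3, 0.5, 1.5); cf <- rnorm(1)
      f <- f + cf * (cos(pi * wv[1] * gx + ph[1]) %o%
                       cos(pi * wv[2] * gy + ph[2]) %o%
                       cos(pi * wv[3] * gz + ph[3]))
    }
    f <- f / max(abs(f))
    mu <- mu * (1 + spec$bias_field_amplitude * f)
  }

  sdn <- spec$noise_sigma * mean(mu_musc)
  img <- if (sdn > 0) {
    if (spec$rician) {
      sqrt((mu + rnorm(length(mu), 0, sdn))^2 + rnorm(length(mu), 0, sdn)^2)
    } else {
      mu + array(rnorm(length(mu), 0, sdn), dim = dim(mu))
    }
  } else mu

  msk_subject(id,
              msk_volume(img, spacing = spec$spacing_mm),
              msk_labelmap(lab, spacing = spec$spacing_mm))
}

#' Generate a cohort of synthetic subjects
#'
#' Subjects share topology (same label set, same compartment layout) and
#' differ smoothly in compartment shape and volume through the spec's shape
#' family.
#'
#' @param spec a [phantom_spec()].
#' @param n_subjects number of subjects (>= 1).
#' @param seed cohort-level seed (defaults to `spec$seed`); per-subject seeds
#'   are derived from it.
#' @param morph_jitter per-subject deformation scale passed through to
#'   [generate_subject()].
#' @return list of [msk_subject()]s with ids `S01`, `S02`, ...
#' @export
generate_cohort <- function(spec, n_subjects, seed = spec$seed,
                            morph_jitter = 1) {
  stopifnot(inherits(spec, "phantom_spec"), n_subjects >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  coeffs <- lapply(seq_len(n_subjects),
                   function(i) draw_shape_coeffs(spec, morph_jitter))
  lapply(seq_len(n_subjects), function(i) {
    sp <- spec
    sp$seed <- (seed + 7919L * i) %% .Machine$integer.max
    generate_subject(sp, morph_jitter = morph_jitter,
                     id = sprintf("S%02d", i), coeffs = coeffs[[i]])
  })
}

#' Write a cohort to disk as NIfTI pairs plus a JSON manifest
#'
#' @param cohort list of subjects.
#' @param dir output directory.
#' @return path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- lapply(cohort, function(s) {
    write_subject(s, dir)
    list(id = s$id, image = paste0(s$id, "_img.nii.gz"),
         labels = paste0(s$id, "_lab.nii.gz"),
         provenance = s$provenance[setdiff(names(s$provenance), "field")])
  })
  mp <- file.path(dir, "cohort.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing `cohort.json`.
#' @return list of subjects.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "cohort.json"))
  lapply(manifest, function(m) {
    msk_subject(m$id,
                read_nifti(file.path(dir, m$image)),
                read_nifti(file.path(dir, m$labels), labels = TRUE),
                provenance = m$provenance)
  })
}
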