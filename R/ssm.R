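# Statistical shape models: rigid Procrustes alignment of corresponded
# particle sets, PCA of the ensemble, and synthesis of new shapes along the
# principal modes.

# Kabsch rotation aligning pts onto ref (both centred), no scaling
kabsch_rotation <- function(pts, ref) {
  H <- t(pts) %*% ref
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

# Generalised Procrustes alignment (rigid: translation + rotation, no
# scaling, so volume differences survive into the model).
procrustes_align <- function(shapes, rotation = TRUE, iters = 3) {
  cent <- t(vapply(shapes, colMeans, numeric(3)))
  shapes <- lapply(seq_along(shapes), function(k)
    sweep(shapes[[k]], 2, cent[k, ]))
  rots <- rep(list(diag(3)), length(shapes))
  if (rotation) {
    for (it in seq_len(iters)) {
      mref <- Reduce(`+`, shapes) / length(shapes)
      for (k in seq_along(shapes)) {
        R <- kabsch_rotation(shapes[[k]], mref)
        shapes[[k]] <- shapes[[k]] %*% R
        rots[[k]] <- rots[[k]] %*% R
      }
    }
  }
  list(shapes = shapes, translations = cent, rotations = rots)
}

#' Fit a PCA shape-space model to a particle system
#'
#' Shapes are brought into a common frame by rigid generalised Procrustes
#' alignment (translation and rotation, no scaling), then the mean shape and
#' up to N - 1 orthonormal principal modes with their variances are extracted
#' from the ensemble covariance.
#'
#' @param ps a `particle_system` from [optimize_correspondence()], or a plain
#'   list of m x 3 particle matrices already in correspondence.
#' @param align logical; run Procrustes alignment first (default TRUE).
#' @param rotation logical; include rotations in the alignment. Defaults to
#'   FALSE because cohort surfaces extracted from a shared scanner frame are
#'   already co-oriented and a rotation-free model maps back onto the image
#'   grid exactly.
#' @return A `shape_space_model`: list with `mean` (3m vector), `modes`
#'   (3m x K orthonormal columns), `eigenvalues` (descending, >= 0),
#'   `n_input_shapes`, `m`, and `origin` (mm translation back to the source
#'   frame, the mean of the input centroids).
#' @export
fit_pca <- function(ps, align = TRUE, rotation = FALSE) {
  origin <- c(0, 0, 0)
  surface_area <- NULL
  if (inherits(ps, "particle_system")) {
    origin <- colMeans(ps$alignment$translations)
    surface_area <- mean(ps$surface_areas)
    shapes <- ps$shapes
  } else shapes <- ps
  N <- length(shapes)
  if (N < 2) stop("PCA needs at least 2 shapes")
  if (align) {
    al <- procrustes_align(shapes, rotation = rotation)
    origin <- origin + colMeans(al$translations)
    shapes <- al$shapes
  }
  X <- do.call(rbind, lapply(shapes, flatten_shape))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  k <- min(N - 1, ncol(X))
  eig <- (sv$d^2 / (N - 1))[seq_len(k)]
  structure(list(mean = mu, modes = sv$v[, seq_len(k), drop = FALSE],
                 eigenvalues = pmax(eig, 0), n_input_shapes = N,
                 m = nrow(shapes[[1]]), origin = origin,
                 surface_area = surface_area),
            class = "shape_space_model")
}

#' Number of modes of a shape-space model
#' @param model a `shape_space_model`.
#' @return integer mode count (at most N - 1).
#' @export
n_modes <- function(model) length(model$eigenvalues)

#' Synthesise a new shape from a shape-space model
#'
#' Returns the particle set at `mean + s * sqrt(eigenvalue[mode]) * mode`,
#' i.e. `s` is in standard-deviation units along the chosen mode (s = 0 gives
#' the mean shape; s = +/-1 the one-SD shapes used for augmentation).
#'
#' @param model a `shape_space_model`.
#' @param mode_index 1-based mode index.
#' @param s scale in SD units.
#' @return m x 3 matrix of particle positions in the model's (centred) frame;
#'   add `model$origin` to return to the source mm frame.
#' @export
synthesize_shape <- function(model, mode_index = 1, s = 0) {
  if (mode_index < 1 || mode_index > n_modes(model))
    stop("mode_index ", mode_index, " out of range (model has ",
         n_modes(model), " modes)")
  v <- model$mean +
    s * sqrt(model$eigenvalues[mode_index]) * model$modes[, mode_index]
  unflatten_shape(v)
}

#' @export
print.shape_space_model <- function(x, ...) {
  ev <- x$eigenvalues
  cat(sprintf(
    "<shape_space_model> m = %d particles, %d shapes, %d modes; mode 1 explains %.1f%% variance\n",
    x$m, x$n_input_shapes, n_modes(x),
    if (sum(ev) > 0) 100 * ev[1] / sum(ev) else NA_real_))
  invisible(x)
}

#' Save / load a shape-space model as JSON
#' @param model a `shape_space_model`.
#' @param path JSON file path.
#' @return `path` (write) or the model (read).
#' @export
write_shape_model <- function(model, path) {
  jsonlite::write_json(list(mean = model$mean,
                            modes = as.vector(model$modes),  # column-major
                            eigenvalues = model$eigenvalues,
                            n_input_shapes = model$n_input_shapes,
                            m = model$m, origin = model$origin,
                            surface_area = model$surface_area,
                            normals = if (!is.null(model$normals))
                              as.vector(model$normals)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(j$mean),
                 modes = matrix(as.numeric(j$modes), ncol = length(j$eigenvalues)),
                 eigenvalues = as.numeric(j$eigenvalues),
                 n_input_shapes = j$n_input_shapes, m = j$m,
                 origin = as.numeric(j$origin),
                 surface_area = j$surface_area,
                 normals = if (!is.null(j$normals))
                   matrix(as.numeric(j$normals), ncol = 3)),
            class = "shape_space_model")
}
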