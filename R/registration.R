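# Deformable registration with a coarse nodal displacement grid.
#
# Displacements live on a regular grid of control nodes with spacing NS
# voxels and are interpolated trilinearly to a dense per-voxel field (no
# B-spline kernels). The objective is
#
#   mean squared similarity residual  +  (lambda / 500) * nodal roughness
#
# where label maps are compared through per-label clamped signed distance
# transforms (SSD on raw integer labels carries no gradient), images through
# z-scored intensities, and the roughness is the mean squared forward
# difference of nodal displacements. Optimisation is gradient descent with a
# backtracking line search over a two-level multiresolution pyramid.

LAMBDA_SCALE <- 1 / 500  # maps the dimensionless smoothing coefficient to
                         # the normalised penalty; exposed via params

#' Parameters of the deformable registration
#'
#' @param nodal_spacing_vox spacing NS between displacement-grid nodes, in
#'   voxels (default 5).
#' @param smoothing_lambda dimensionless smoothness weight (default 50).
#' @param max_iters gradient iterations per pyramid level.
#' @param tolerance relative objective decrease below which iteration stops.
#' @param pyramid_levels multiresolution levels (default 2; level 2 works on
#'   a 2x downsampled grid to extend the capture range).
#' @param clamp_dist_vox clamp on the per-label signed distance maps, voxels.
#' @return list of class `registration_params`.
#' @export
registration_params <- function(nodal_spacing_vox = 5, smoothing_lambda = 50,
                                max_iters = 60, tolerance = 1e-5,
                                pyramid_levels = 2, clamp_dist_vox = 20) {
  if (nodal_spacing_vox < 2) stop("nodal spacing must be >= 2 voxels")
  if (smoothing_lambda < 0) stop("smoothing lambda must be >= 0")
  structure(list(nodal_spacing_vox = nodal_spacing_vox,
                 smoothing_lambda = smoothing_lambda,
                 max_iters = max_iters, tolerance = tolerance,
                 pyramid_levels = pyramid_levels,
                 clamp_dist_vox = clamp_dist_vox),
            class = "registration_params")
}

node_grid_dims <- function(dims, ns) {
  as.integer(ceiling((dims - 1) / ns) + 1)
}

#' Displacement field on a nodal grid
#'
#' @param nodes array (gx, gy, gz, 3) of nodal displacements in voxel units.
#' @param ns nodal spacing in voxels.
#' @param dim grid shape of the image domain.
#' @param spacing voxel spacing (mm) of the image domain.
#' @return object of class `msk_field`.
#' @export
displacement_field <- function(nodes, ns, dim, spacing = c(1, 1, 1)) {
  stopifnot(length(base::dim(nodes)) == 4L, base::dim(nodes)[4] == 3L)
  structure(list(nodes = nodes, ns = ns, dim = as.integer(dim),
                 spacing = as.numeric(spacing)),
            class = "msk_field")
}

#' Dense per-voxel displacement of a field (trilinear in node space)
#' @param field a `msk_field`.
#' @return array (nx, ny, nz, 3), displacements in voxel units.
#' @export
field_dense <- function(field) {
  cpp_field_from_nodes(field$nodes, field$dim, field$ns)
}

#' @export
print.msk_field <- function(x, ...) {
  cat(sprintf("<msk_field> %s voxels, NS = %g, max |u| = %.3f voxels\n",
              paste(x$dim, collapse = "x"), x$ns, max(abs(x$nodes))))
  invisible(x)
}

# mean squared forward difference of nodal displacements, and its gradient
node_roughness <- function(nodes, gradient = FALSE) {
  d <- dim(nodes)
  g <- if (gradient) array(0, d) else NULL
  tot <- 0
  nterm <- 0
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2) next
    lo <- function(a, take_first) {
      if (ax == 1) a[if (take_first) 1:(n - 1) else 2:n, , , , drop = FALSE]
      else if (ax == 2) a[, if (take_first) 1:(n - 1) else 2:n, , , drop = FALSE]
      else a[, , if (take_first) 1:(n - 1) else 2:n, , drop = FALSE]
    }
    df <- lo(nodes, FALSE) - lo(nodes, TRUE)
    tot <- tot + sum(df^2)
    nterm <- nterm + length(df)
    if (gradient) {
      if (ax == 1) {
        g[2:n, , , ] <- g[2:n, , , ] + 2 * df
        g[1:(n - 1), , , ] <- g[1:(n - 1), , , ] - 2 * df
      } else if (ax == 2) {
        g[, 2:n, , ] <- g[, 2:n, , ] + 2 * df
        g[, 1:(n - 1), , ] <- g[, 1:(n - 1), , ] - 2 * df
      } else {
        g[, , 2:n, ] <- g[, , 2:n, ] + 2 * df
        g[, , 1:(n - 1), ] <- g[, , 1:(n - 1), ] - 2 * df
      }
    }
  }
  nterm <- max(nterm, 1L)
  list(value = tot / nterm, grad = if (gradient) g / nterm else NULL)
}

# similarity representation: label maps become stacks of clamped per-label
# signed distance maps (voxel units); images a single z-scored channel
similarity_channels <- function(x, labels = NULL, clamp = 20) {
  d <- dim(x)
  if (inherits(x, "msk_labelmap")) {
    if (is.null(labels)) labels <- label_values(x)
    ch <- array(0, c(d, length(labels)))
    for (i in seq_along(labels)) {
      mask <- unclass(x) == labels[i]
      d_out <- cpp_edt(mask, c(1, 1, 1))
      d_in <- cpp_edt(!mask, c(1, 1, 1))
      ch[, , , i] <- pmin(d_out, clamp) - pmin(d_in, clamp)
    }
    ch
  } else {
    v <- unclass(x)
    array((v - mean(v)) / max(sd(v), 1e-12), c(d, 1))
  }
}

downsample2 <- function(x) {
  d <- dim(x)
  ix <- seq(1, d[1], 2); iy <- seq(1, d[2], 2); iz <- seq(1, d[3], 2)
  y <- unclass(x)[ix, iy, iz]
  if (inherits(x, "msk_labelmap")) msk_labelmap(y, msk_spacing(x) * 2)
  else msk_volume(y, msk_spacing(x) * 2)
}

# L-BFGS minimisation of similarity + roughness on one pyramid level. The
# trace records the best objective seen at each evaluation (including line
# searches), so it is non-increasing by construction.
optimize_nodes <- function(ref_ch, tgt_ch, nodes, ns, lambda, max_iters,
                           tol) {
  dims <- dim(ref_ch)[1:3]
  shape <- dim(nodes)
  gdims <- shape[1:3]
  lam <- lambda * LAMBDA_SCALE
  evals <- numeric(0)
  fn <- function(v) {
    nd <- array(v, shape)
    val <- cpp_reg_obj(ref_ch, tgt_ch, cpp_field_from_nodes(nd, dims, ns)) +
      lam * node_roughness(nd)$value
    evals[length(evals) + 1L] <<- val
    val
  }
  gr <- function(v) {
    nd <- array(v, shape)
    og <- cpp_reg_obj_grad(ref_ch, tgt_ch,
                           cpp_field_from_nodes(nd, dims, ns))
    g <- cpp_scatter_to_nodes(og$grad, gdims, ns)
    if (lam > 0) g <- g + lam * node_roughness(nd, gradient = TRUE)$grad
    as.vector(g)
  }
  # factr scales tol to L-BFGS-B's machine-epsilon convention
  o <- stats::optim(as.vector(nodes), fn, gr, method = "L-BFGS-B",
                    control = list(maxit = max_iters,
                                   factr = max(10, tol * 1e12)))
  list(nodes = array(o$par, shape), trace = cummin(evals))
}

#' Deformable registration of two label maps or volumes
#'
#' Estimates the displacement field phi that carries the reference onto the
#' target by minimising the similarity residual plus the lambda-weighted
#' nodal roughness penalty. The returned field maps reference voxels to the
#' locations they must sample from, and is applied to the reference's image
#' and labels alike by [warp_volume()] and [warp_labels()].
#'
#' @param reference,target two [msk_labelmap()]s (same label vocabulary) or
#'   two [msk_volume()]s on the same grid.
#' @param params a [registration_params()].
#' @return list with `field` (a `msk_field` on the full-resolution grid) and
#'   `trace` (best objective seen at each evaluation of the finest level;
#'   non-increasing), plus `traces` for all pyramid levels, coarse first.
#' @export
register <- function(reference, target, params = registration_params()) {
  check_same_grid(reference, target)
  if (!all(is.finite(reference)) || !all(is.finite(target)))
    stop("non-finite voxels in registration input")
  is_lab <- inherits(reference, "msk_labelmap")
  if (is_lab != inherits(target, "msk_labelmap"))
    stop("reference and target must both be label maps or both volumes")
  labels <- NULL
  if (is_lab) {
    labels <- sort(union(label_values(reference), label_values(target)))
    if (!setequal(label_values(reference), label_values(target)))
      stop("reference and target must share the same label vocabulary; ",
           "reference has {", paste(label_values(reference), collapse = ","),
           "}, target {", paste(label_values(target), collapse = ","), "}")
  }

  nlev <- max(1, params$pyramid_levels)
  nodes <- NULL
  ns_prev <- NULL
  traces <- list()
  for (lev in seq(nlev, 1)) {
    ref_l <- reference; tgt_l <- target
    for (s in seq_len(lev - 1)) {
      ref_l <- downsample2(ref_l)
      tgt_l <- downsample2(tgt_l)
    }
    dims_l <- dim(ref_l)
    f <- 2^(lev - 1)
    ns_l <- max(2, round(params$nodal_spacing_vox / f))
    clamp_l <- max(2, params$clamp_dist_vox / f)
    gdims <- node_grid_dims(dims_l, ns_l)
    ch_r <- similarity_channels(ref_l, labels, clamp_l)
    ch_t <- similarity_channels(tgt_l, labels, clamp_l)
    if (is.null(nodes)) {
      nodes_l <- array(0, c(gdims, 3))
    } else {
      # lift the coarser solution: displacements double, node grid refines
      dense <- cpp_field_from_nodes(2 * nodes, dims_l, 2 * ns_prev)
      nodes_l <- array(0, c(gdims, 3))
      px <- pmin((seq_len(gdims[1]) - 1) * ns_l + 1, dims_l[1])
      py <- pmin((seq_len(gdims[2]) - 1) * ns_l + 1, dims_l[2])
      pz <- pmin((seq_len(gdims[3]) - 1) * ns_l + 1, dims_l[3])
      nodes_l <- dense[px, py, pz, , drop = FALSE]
    }
    res <- optimize_nodes(ch_r, ch_t, nodes_l, ns_l,
                          params$smoothing_lambda, params$max_iters,
                          params$tolerance)
    nodes <- res$nodes
    ns_prev <- ns_l
    traces[[length(traces) + 1L]] <- res$trace
  }
  field <- displacement_field(nodes, ns_prev, dim(reference),
                              msk_spacing(reference))
  list(field = field, trace = traces[[length(traces)]], traces = traces)
}

check_field_domain <- function(x, field) {
  if (!identical(dim(x), field$dim))
    stop("field domain ", paste(field$dim, collapse = "x"),
         " does not match input grid ", paste(dim(x), collapse = "x"))
  invisible(TRUE)
}

#' Warp an image volume under a displacement field (trilinear)
#' @param volume a [msk_volume()].
#' @param field a `msk_field` whose domain matches the volume grid.
#' @return warped [msk_volume()]; samples outside the domain clamp to the
#'   nearest edge.
#' @export
warp_volume <- function(volume, field) {
  stopifnot(inherits(volume, "msk_volume"))
  check_field_domain(volume, field)
  out <- cpp_warp_trilinear(unclass(volume), field_dense(field))
  msk_volume(array(out, dim(volume)), msk_spacing(volume))
}

#' Warp a label map under a displacement field (nearest neighbour)
#' @param labels a [msk_labelmap()].
#' @param field a `msk_field` whose domain matches the label grid.
#' @return warped [msk_labelmap()]; the output label set is a subset of the
#'   input's, with background filled in where the field samples outside.
#' @export
warp_labels <- function(labels, field) {
  stopifnot(inherits(labels, "msk_labelmap"))
  check_field_domain(labels, field)
  out <- cpp_warp_nn(unclass(labels), field_dense(field))
  msk_labelmap(array(out, dim(labels)), msk_spacing(labels))
}

#' Serialise a displacement field (NIfTI vector field + JSON sidecar)
#'
#' Writes the dense field in mm as a 4D NIfTI (last dimension x/y/z) and a
#' JSON sidecar holding the nodal grid, NS and spacing so the field can be
#' reconstructed exactly.
#'
#' @param field a `msk_field`.
#' @param prefix output path prefix; writes `<prefix>_field.nii.gz` and
#'   `<prefix>_field.json`.
#' @return named vector of the two paths, invisibly.
#' @export
write_field <- function(field, prefix) {
  dense <- field_dense(field)
  for (c in 1:3) dense[, , , c] <- dense[, , , c] * field$spacing[c]
  img <- RNifti::asNifti(dense)
  RNifti::pixdim(img) <- field$spacing
  pn <- paste0(prefix, "_field.nii.gz")
  pj <- paste0(prefix, "_field.json")
  RNifti::writeNifti(img, pn)
  jsonlite::write_json(list(nodes = as.vector(field$nodes),
                            gdims = dim(field$nodes)[1:3], ns = field$ns,
                            dim = field$dim, spacing = field$spacing),
                       pj, digits = NA, auto_unbox = TRUE)
  invisible(c(nifti = pn, json = pj))
}

#' @rdname write_field
#' @param path path to the JSON sidecar written by `write_field`.
#' @export
read_field <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  displacement_field(array(as.numeric(j$nodes), c(j$gdims, 3)),
                     j$ns, j$dim, j$spacing)
}
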