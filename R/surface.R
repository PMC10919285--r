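# Surface extraction from binary label masks, and analytic surface samplers
# used by the shape-model tests and demos.

# voxels of `mask` with at least one background 6-neighbour (face adjacency)
boundary_mask <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  shift_and <- function(acc, src) acc & src
  nb <- array(TRUE, d)
  # a voxel is interior iff all six face neighbours are foreground;
  # edge-of-grid voxels are treated as boundary
  nb[] <- TRUE
  nb[2:d[1], , ] <- mask[1:(d[1] - 1), , ]; nb[1, , ] <- FALSE
  interior <- shift_and(interior, nb)
  nb[] <- TRUE
  nb[1:(d[1] - 1), , ] <- mask[2:d[1], , ]; nb[d[1], , ] <- FALSE
  interior <- shift_and(interior, nb)
  nb[] <- TRUE
  nb[, 2:d[2], ] <- mask[, 1:(d[2] - 1), ]; nb[, 1, ] <- FALSE
  interior <- shift_and(interior, nb)
  nb[] <- TRUE
  nb[, 1:(d[2] - 1), ] <- mask[, 2:d[2], ]; nb[, d[2], ] <- FALSE
  interior <- shift_and(interior, nb)
  nb[] <- TRUE
  nb[, , 2:d[3]] <- mask[, , 1:(d[3] - 1)]; nb[, , 1] <- FALSE
  interior <- shift_and(interior, nb)
  nb[] <- TRUE
  nb[, , 1:(d[3] - 1)] <- mask[, , 2:d[3]]; nb[, , d[3]] <- FALSE
  interior <- shift_and(interior, nb)
  mask & !interior
}

# voxel centre coordinates in mm for 1-based indices
voxel_centers_mm <- function(idx, spacing) {
  sweep(idx - 0.5, 2, spacing, `*`)
}

#' Extract the surface point cloud of one labelled compartment
#'
#' Returns the centres of the boundary voxels of the binary mask
#' `labels == label_id`, in physical mm coordinates (voxel centre of index i
#' is at (i - 0.5) * spacing).
#'
#' @param labels a [msk_labelmap()].
#' @param label_id label whose surface to extract; must be present.
#' @return numeric matrix with columns x, y, z (mm).
#' @export
extract_surface <- function(labels, label_id) {
  stopifnot(inherits(labels, "msk_labelmap"))
  mask <- unclass(labels) == label_id
  if (!any(mask))
    stop("label ", label_id, " is absent from the label map")
  bnd <- boundary_mask(mask)
  idx <- which(bnd, arr.ind = TRUE)
  voxel_centers_mm(idx, msk_spacing(labels))
}

#' Outward unit normals of a labelled compartment
#'
#' Normals are sampled at arbitrary mm positions as the gradient of the
#' mask's signed distance map (positive outside): central differences on the
#' grid, trilinear interpolation at the query points. More reliable than
#' local plane fits when the sampling of the surface is sparser than the
#' compartment is thick.
#'
#' @param labels a [msk_labelmap()].
#' @param label_id compartment label; must be present.
#' @param pts_mm n x 3 matrix of query positions (mm).
#' @return n x 3 matrix of outward unit normals.
#' @export
mask_surface_normals <- function(labels, label_id, pts_mm) {
  stopifnot(inherits(labels, "msk_labelmap"))
  sp <- msk_spacing(labels)
  mask <- unclass(labels) == label_id
  if (!any(mask)) stop("label ", label_id, " is absent from the label map")
  s <- cpp_edt(mask, sp) - cpp_edt(!mask, sp)
  d <- dim(s)
  g <- array(0, c(d, 3))
  g[2:(d[1] - 1), , , 1] <- (s[3:d[1], , ] - s[1:(d[1] - 2), , ]) / (2 * sp[1])
  g[, 2:(d[2] - 1), , 2] <- (s[, 3:d[2], ] - s[, 1:(d[2] - 2), ]) / (2 * sp[2])
  g[, , 2:(d[3] - 1), 3] <- (s[, , 3:d[3]] - s[, , 1:(d[3] - 2)]) / (2 * sp[3])
  # trilinear sample of each gradient component at the query points
  vox <- sweep(pts_mm, 2, sp, `/`) + 0.5       # 1-based fractional indices
  v0 <- pmin(pmax(floor(vox), 1), rep(d - 1, each = nrow(vox)))
  f <- vox - v0
  f <- pmin(pmax(f, 0), 1)
  out <- matrix(0, nrow(pts_mm), 3)
  for (c in 1:3) {
    gc <- g[, , , c]
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wgt <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
             (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
             (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
      acc <- acc + wgt * gc[cbind(v0[, 1] + dx, v0[, 2] + dy, v0[, 3] + dz)]
    }
    out[, c] <- acc
  }
  nn <- sqrt(rowSums(out^2))
  out / pmax(nn, 1e-12)
}

#' Sample points on an ellipsoid surface
#'
#' Deterministic quasi-uniform sampling via a Fibonacci sphere mapped onto the
#' ellipsoid. Useful as an analytic input to correspondence optimisation.
#'
#' @param center numeric length-3 (mm).
#' @param semiaxes numeric length-3 semi-axis lengths (mm).
#' @param n number of points.
#' @return n x 3 matrix of surface points.
#' @export
ellipsoid_surface <- function(center = c(0, 0, 0), semiaxes = c(10, 8, 14),
                              n = 1000) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  p <- cbind(semiaxes[1] * sin(phi) * cos(theta),
             semiaxes[2] * sin(phi) * sin(theta),
             semiaxes[3] * cos(phi))
  sweep(p, 2, center, `+`)
}
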