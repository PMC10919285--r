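# Particle-based surface correspondence across a cohort of shapes.
#
# A fixed number m of particles is placed on every shape's surface so that the
# k-th particle is homologous across shapes. Particle positions are found by
# minimising an ensemble energy
#
#     Q = H(Z) - sum_k H(x_k)
#
# where H(Z) is the Gaussian-model entropy of the shape-space distribution of
# the particle vectors x_k in R^{3m} (log-determinant of the regularised
# cross-shape covariance: favours a compact, well-corresponded ensemble) and
# H(x_k) is a Parzen kernel estimate of the particle entropy on shape k
# (favours uniform coverage of each surface). Minimising Q trades the two off.

flatten_shape <- function(pts) as.vector(t(pts))
unflatten_shape <- function(v) matrix(v, ncol = 3, byrow = TRUE)

# Gaussian-model entropy of the ensemble: 0.5 * sum log(lambda_i + alpha)
# over the min(N-1, 3m) leading eigenvalues of the cross-shape covariance.
ensemble_entropy <- function(X, alpha) {
  N <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 0)$d
  lam <- sv^2 / (N - 1)
  k <- min(N - 1, ncol(X))
  0.5 * sum(log(lam[seq_len(k)] + alpha))
}

# Gradient of ensemble_entropy with respect to each shape vector (3m x N),
# via the push-through identity so only an N x N system is solved.
ensemble_entropy_grad <- function(X, alpha) {
  N <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  M <- Xc %*% t(Xc) / (N - 1) + diag(alpha, N)
  G <- t(Xc) %*% solve(M) / (N - 1)        # 3m x N
  sweep(G, 1, rowMeans(G))                  # account for the ensemble mean
}

particle_sigma <- function(pts, sigma_factor = 1) {
  nn <- cpp_knn(pts, pts, 2L)$dist[, 2]
  max(mean(nn) * sigma_factor, 1e-3)
}

# surface area estimate of a dense point cloud: hexagonal packing carries
# ~0.866 d^2 of area per point, d the mean distance to the 6 nearest
surface_area_estimate <- function(pts) {
  k <- min(6L, nrow(pts) - 1L)
  nn <- cpp_knn(pts, pts, k + 1L)$dist[, -1, drop = FALSE]
  sum(sqrt(3) / 2 * rowMeans(nn)^2)
}

#' Correspondence energy of a particle system
#'
#' Reports the ensemble term H(Z), the per-shape Parzen entropies H(x_k) and
#' the total Q = H(Z) - sum_k H(x_k).
#'
#' @param shapes list of m x 3 particle matrices in a common frame, or a
#'   `particle_system`.
#' @param alpha regularisation added to the ensemble covariance eigenvalues;
#'   `NULL` derives it as `alpha_rel * trace / 3m`.
#' @param alpha_rel relative regularisation (default 1e-3).
#' @param sigma per-shape Parzen kernel widths; `NULL` adapts each to the
#'   shape's mean nearest-neighbour particle spacing.
#' @param sigma_factor multiplier on the adaptive kernel width.
#' @return list with `Q`, `ensemble_term`, `sample_terms`, `alpha`, `sigma`.
#' @export
correspondence_energy <- function(shapes, alpha = NULL, alpha_rel = 1e-3,
                                  sigma = NULL, sigma_factor = 1) {
  if (inherits(shapes, "particle_system")) shapes <- shapes$shapes
  X <- do.call(rbind, lapply(shapes, flatten_shape))
  N <- nrow(X)
  if (is.null(alpha)) {
    Xc <- sweep(X, 2, colMeans(X))
    alpha <- max(alpha_rel * sum(Xc^2) / ((N - 1) * ncol(X)), 1e-8)
  }
  if (is.null(sigma))
    sigma <- vapply(shapes, particle_sigma, numeric(1),
                    sigma_factor = sigma_factor)
  ens <- ensemble_entropy(X, alpha)
  samp <- vapply(seq_along(shapes), function(k)
    cpp_parzen_entropy(shapes[[k]], sigma[k])$H, numeric(1))
  list(Q = ens - sum(samp), ensemble_term = ens, sample_terms = samp,
       alpha = alpha, sigma = sigma)
}

# greedy farthest-point subsample of a point cloud (maxmin criterion)
farthest_point_sample <- function(pts, k, start = 1L) {
  n <- nrow(pts)
  sel <- integer(k)
  sel[1] <- start
  mind <- sqrt(rowSums(sweep(pts, 2, pts[start, ])^2))
  for (i in seq_len(k - 1L)) {
    nxt <- which.max(mind)
    sel[i + 1L] <- nxt
    d <- sqrt(rowSums(sweep(pts, 2, pts[nxt, ])^2))
    mind <- pmin(mind, d)
  }
  sel
}

# Project points onto the surface's local tangent plane at the nearest
# candidate point. Keeping positions continuous (rather than snapping to the
# discrete candidates) preserves sub-sample correspondence across shapes.
project_to_surface <- function(pts, candidates, normals = NULL,
                               max_lat = Inf) {
  idx <- cpp_knn(pts, candidates, 1L)$idx[, 1]
  near <- candidates[idx, , drop = FALSE]
  if (is.null(normals)) return(near)
  nrm <- normals[idx, , drop = FALSE]
  off <- rowSums((pts - near) * nrm)
  proj <- pts - off * nrm
  # don't let the tangent plane carry a particle away from the surface
  lat <- sqrt(rowSums((proj - near)^2))
  far <- lat > max_lat
  if (any(far)) proj[far, ] <- near[far, , drop = FALSE]
  proj
}

#' Optimise particle correspondence across a cohort of surfaces
#'
#' Places `m` corresponding particles on every surface by projected gradient
#' descent on the correspondence energy Q. Particles start as a farthest-point
#' sample of the first shape, matched by nearest neighbour on the others, and
#' are grown by splitting (each stage doubles the particle count, then
#' optimises) until `m` is reached; within every stage the Parzen kernel width
#' and covariance regularisation are frozen so accepted steps never increase
#' Q. After each gradient step particles are re-projected onto the nearest
#' surface point, so they lie exactly on their source surface throughout.
#'
#' @param surfaces list of point matrices (mm), one per shape (N >= 2).
#' @param m particles per shape (default 1024).
#' @param iters gradient iterations per stage.
#' @param seed integer seed for the initial sample and split jitter.
#' @param alpha_rel relative regularisation of the ensemble covariance
#'   (default 0.1: strong enough that near-null directions of the covariance
#'   do not pin the particles against the uniformity term).
#' @param sigma_factor multiplier on the Parzen kernel width, which is set to
#'   the target uniform particle spacing sqrt(area / m).
#' @param step_frac initial step length as a fraction of the mean particle
#'   spacing.
#' @param m0 particle count of the first stage.
#' @return a `particle_system`: list with `shapes` (m x 3 matrices, centred
#'   common frame), `alignment` (per-shape centroid translations), `m`, `N`,
#'   `trace` (data.frame of accepted energies per stage), `surface_areas`
#'   (per-shape area estimates from the candidate clouds) and `energy` (final
#'   decomposition from [correspondence_energy()]).
#' @export
optimize_correspondence <- function(surfaces, m = 1024, iters = 10, seed = 1,
                                    alpha_rel = 0.1, sigma_factor = 1,
                                    step_frac = 0.5, m0 = 16) {
  N <- length(surfaces)
  if (N < 2) stop("correspondence needs at least 2 shapes")
  if (m < 4) stop("m must be >= 4")
  surfaces <- lapply(surfaces, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    s
  })
  short <- vapply(surfaces, nrow, numeric(1)) < m
  if (any(short))
    stop("degenerate surface: shape(s) ", paste(which(short), collapse = ", "),
         " have fewer candidate points than m = ", m)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  centroids <- t(vapply(surfaces, colMeans, numeric(3)))
  cands <- lapply(seq_len(N), function(k)
    sweep(surfaces[[k]], 2, centroids[k, ]))
  normals <- lapply(cands, estimate_normals)
  spac <- vapply(cands, function(cc) mean(cpp_knn(cc, cc, 2L)$dist[, 2]),
                 numeric(1))
  areas <- vapply(cands, surface_area_estimate, numeric(1))
  proj <- function(pts, k)
    project_to_surface(pts, cands[[k]], normals[[k]], max_lat = 2 * spac[k])

  m_cur <- min(m0, m)
  sel <- farthest_point_sample(cands[[1]], m_cur)
  particles <- vector("list", N)
  particles[[1]] <- cands[[1]][sel, , drop = FALSE]
  for (k in seq_len(N)[-1])
    particles[[k]] <- proj(particles[[1]], k)

  trace <- list()
  stage <- 0L
  repeat {
    stage <- stage + 1L
    # Parzen width at the scale of the TARGET uniform particle spacing
    # sqrt(A/m), not the current nearest-neighbour distance: the latter
    # collapses after every split (freshly split pairs dominate it), which
    # would shrink the repulsion range and freeze the clusters in place.
    sigma <- sigma_factor * sqrt(areas / m_cur)
    X <- do.call(rbind, lapply(particles, flatten_shape))
    Xc <- sweep(X, 2, colMeans(X))
    alpha <- max(alpha_rel * sum(Xc^2) / ((N - 1) * ncol(X)), 1e-8)
    evalQ <- function(ps) {
      e <- correspondence_energy(ps, alpha = alpha, sigma = sigma)
      e$Q
    }
    Q <- evalQ(particles)
    trace[[stage]] <- list(Q = Q, m = m_cur)
    step <- step_frac * mean(sigma)
    for (it in seq_len(iters)) {
      X <- do.call(rbind, lapply(particles, flatten_shape))
      Gens <- ensemble_entropy_grad(X, alpha)      # 3m x N
      grads <- lapply(seq_len(N), function(k) {
        unflatten_shape(Gens[, k]) -
          cpp_parzen_entropy(particles[[k]], sigma[k])$grad
      })
      gmax <- max(vapply(grads, function(g) max(abs(g)), numeric(1)), 1e-12)
      accepted <- FALSE
      st <- min(step, mean(sigma) / gmax)
      for (bt in 1:8) {
        prop <- lapply(seq_len(N), function(k)
          proj(particles[[k]] - st * grads[[k]], k))
        Qp <- evalQ(prop)
        if (Qp < Q - 1e-12) {
          particles <- prop
          Q <- Qp
          step <- st * 1.3
          accepted <- TRUE
          break
        }
        st <- st / 2
      }
      if (!accepted) break
      trace[[stage]]$Q <- c(trace[[stage]]$Q, Q)
    }
    if (m_cur >= m) break
    # split: duplicate particles (same indices on every shape) with a small
    # jitter, then re-project, so correspondence survives the refinement
    n_new <- min(m_cur, m - m_cur)
    jit <- matrix(rnorm(3 * n_new, 0, 0.3 * mean(sigma)), ncol = 3)
    for (k in seq_len(N)) {
      src <- particles[[k]][seq_len(n_new), , drop = FALSE]
      particles[[k]] <- rbind(particles[[k]], proj(src + jit, k))
    }
    m_cur <- m_cur + n_new
  }

  trace_df <- do.call(rbind, lapply(seq_along(trace), function(s)
    data.frame(stage = s, m = trace[[s]]$m,
               iter = seq_along(trace[[s]]$Q) - 1L,
               Q = trace[[s]]$Q)))
  structure(list(shapes = particles,
                 alignment = list(translations = centroids),
                 m = m_cur, N = N, trace = trace_df,
                 surface_areas = areas,
                 energy = correspondence_energy(particles)),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("<particle_system> N = %d shapes, m = %d particles, Q = %.4g\n",
              x$N, x$m, x$energy$Q))
  invisible(x)
}
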