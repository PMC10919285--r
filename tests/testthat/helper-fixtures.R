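# Shared fixtures, built lazily once per test session and cached, so the
# expensive objects (cohorts, shape models, trained registrations) are paid
# for once no matter how many test files use them.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# small 4-compartment cohort on a compact grid: fast enough for unit tests
# of surfaces, correspondence, SSMs and augmentation plumbing
fx_small_cohort <- function() {
  fx("small_cohort", function() {
    spec <- phantom_spec(grid_shape = c(32, 32, 48), n_muscles = 4, seed = 101)
    generate_cohort(spec, 4)
  })
}

# shape models for the small cohort (coarse particle count keeps it quick)
fx_small_ssms <- function() {
  fx("small_ssms", function()
    build_ssms(fx_small_cohort(), m = 96, iters = 4, seed = 11))
}

# a rasterised ellipsoid mask + its extracted surface, reused by surface /
# rasterisation tests
fx_ellipsoid_mask <- function() {
  fx("ellipsoid_mask", function() {
    dims <- c(28, 28, 28)
    ctr <- (dims / 2)
    ax <- c(9, 7, 11)
    g <- expand.grid(x = seq_len(dims[1]) - 0.5, y = seq_len(dims[2]) - 0.5,
                     z = seq_len(dims[3]) - 0.5)
    r2 <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
      ((g$z - ctr[3]) / ax[3])^2
    msk_labelmap(array(as.integer(r2 <= 1), dims))
  })
}

# brute-force metric oracles, deliberately written as directly as possible
# (triple loops over voxel pairs) so they cannot share bugs with the
# EDT-based implementations
oracle_dsc <- function(a, b) {
  if (!any(a) && !any(b)) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}
oracle_rve <- function(a, b, spacing) {
  vv <- prod(spacing)
  abs(sum(a) * vv - sum(b) * vv) / (sum(b) * vv)
}
# Boundary voxels found by zero-padding and checking the six face
# neighbours at the index level; the distances are exhaustive pairwise
# Euclidean distances, so no distance transform is involved.
oracle_boundary_points <- function(m, spacing) {
  d <- dim(m)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  idx <- which(m, arr.ind = TRUE)
  p <- idx + 1   # position in the padded array
  interior <- pad[p + rep(c(1, 0, 0), each = nrow(p))] &
    pad[p - rep(c(1, 0, 0), each = nrow(p))] &
    pad[p + rep(c(0, 1, 0), each = nrow(p))] &
    pad[p - rep(c(0, 1, 0), each = nrow(p))] &
    pad[p + rep(c(0, 0, 1), each = nrow(p))] &
    pad[p - rep(c(0, 0, 1), each = nrow(p))]
  sweep(idx[!interior, , drop = FALSE], 2, spacing, `*`)
}

oracle_hausdorff <- function(a, b, spacing) {
  pa <- oracle_boundary_points(a, spacing)
  pb <- oracle_boundary_points(b, spacing)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  dmat <- sqrt(pmax(d2, 0))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

random_mask_pair <- function(seed, dims = c(16, 16, 16)) {
  set.seed(seed)
  blob <- function() {
    ctr <- runif(3, 5, dims - 5)
    ax <- runif(3, 2, 5)
    g <- expand.grid(x = seq_len(dims[1]) - 0.5, y = seq_len(dims[2]) - 0.5,
                     z = seq_len(dims[3]) - 0.5)
    r2 <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
      ((g$z - ctr[3]) / ax[3])^2
    array(r2 <= 1, dims)
  }
  list(a = blob(), b = blob())
}

# flatten an m x 3 particle matrix the way shape models store vectors
flat3 <- function(p) as.vector(t(p))

# analytic single-mode ellipsoid cohort: every shape shares one Fibonacci
# sphere parametrisation (exact correspondence by construction), and the only
# variation is a scalar factor on the z semi-axis -- one planted PCA mode
planted_ellipsoid_cohort <- function(n_shapes = 10, m = 128, seed = 5) {
  set.seed(seed)
  i <- seq_len(m) - 0.5
  phi <- acos(1 - 2 * i / m)
  theta <- pi * (1 + sqrt(5)) * i
  unit <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  ax <- c(10, 8, 14)
  cc <- rnorm(n_shapes, 0, 1.5)        # planted mode coefficients
  shapes <- lapply(cc, function(ck)
    cbind(unit[, 1] * ax[1], unit[, 2] * ax[2], unit[, 3] * (ax[3] + ck)))
  planted <- flat3(cbind(0 * unit[, 1], 0 * unit[, 2], unit[, 3]))
  list(shapes = shapes, planted_direction = planted / sqrt(sum(planted^2)),
       coefficients = cc)
}

# deterministic stub model for experiment bookkeeping tests: "predicts" a
# subject's own reference labels by recognising its volume among the
# registered subjects, so every label is evaluated (with perfect scores) and
# the bookkeeping is exercised without training anything
.stub <- new.env(parent = emptyenv())
stub_register <- function(subjects) assign("subjects", subjects, envir = .stub)
stub_trainer <- function(subjects, config, ...) {
  structure(list(n_train = length(subjects)), class = "stub_model")
}
stub_predictor <- function(model, volume) {
  for (s in get("subjects", envir = .stub))
    if (identical(dim(s$volume), dim(volume)) &&
        isTRUE(all.equal(as.vector(unclass(s$volume)),
                         as.vector(unclass(volume)))))
      return(s$labels)
  stop("volume not found among the registered stub subjects")
}
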