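# small configurations keep the forward/backward passes fast; the properties
# under test are architectural, not capacity-dependent
small_cfg <- function(arch, seed = 1)
  network_config(arch, n_classes = 3, base_width = 4, depth = 4,
                 aspp_rates = c(1, 2), seed = seed)

test_that("every architecture produces input-sized logits", {
  set.seed(1)
  x <- array(rnorm(33 * 29 * 2), c(33, 29, 1, 2))  # odd sizes force padding
  for (arch in c("unet", "unetpp", "ffu", "affu")) {
    net <- build_network(small_cfg(arch))
    out <- network_forward(net, x)
    expect_identical(dim(out$logits$value), c(33L, 29L, 3L, 2L))
    expect_true(all(is.finite(out$logits$value)))
  }
})

test_that("parameter counts grow unet < ffu < affu and FFU names nest in AFFU", {
  nets <- lapply(c("unet", "ffu", "affu"), function(a)
    build_network(small_cfg(a)))
  counts <- vapply(nets, count_params, numeric(1))
  expect_lt(counts[1], counts[2])
  expect_lt(counts[2], counts[3])
  expect_true(all(names(nets[[2]]$params) %in% names(nets[[3]]$params)))
})

test_that("network initialisation is deterministic in the seed", {
  n1 <- build_network(small_cfg("unet", seed = 7))
  n2 <- build_network(small_cfg("unet", seed = 7))
  expect_identical(n1$params, n2$params)
  n3 <- build_network(small_cfg("unet", seed = 8))
  expect_false(identical(n1$params, n3$params))
})

test_that("ablated AFFU reproduces the FFU forward pass under shared weights", {
  ffu <- build_network(small_cfg("ffu"))
  affu <- build_network(small_cfg("affu"))
  load_matching_weights(affu, ffu)
  set.seed(3)
  x <- array(rnorm(24 * 24 * 2), c(24, 24, 1, 2))
  out_f <- network_forward(ffu, x)
  out_a <- network_forward(affu, x, gate_passthrough = TRUE,
                           cbam_identity = TRUE)
  expect_equal(out_a$logits$value, out_f$logits$value, tolerance = 1e-12)
  # and without the ablation the outputs differ (the attention does something)
  out_full <- network_forward(affu, x)
  expect_false(isTRUE(all.equal(out_full$logits$value, out_f$logits$value)))
})

test_that("attention gates return per-pixel weights in [0, 1]", {
  set.seed(4)
  x <- array(rnorm(16 * 16 * 4 * 1), c(16, 16, 4, 1))
  gate <- array(rnorm(16 * 16 * 4 * 1), c(16, 16, 4, 1))
  wts <- list(theta_w = array(rnorm(1 * 1 * 4 * 2, 0, 0.5), c(1, 1, 4, 2)),
              theta_b = rep(0, 2),
              phi_w = array(rnorm(1 * 1 * 4 * 2, 0, 0.5), c(1, 1, 4, 2)),
              phi_b = rep(0, 2),
              psi_w = array(rnorm(1 * 1 * 2 * 1, 0, 0.5), c(1, 1, 2, 1)),
              psi_b = 0)
  ag <- attention_gate(x, gate, wts)
  expect_identical(dim(ag$output), dim(x))
  expect_true(all(ag$attention >= 0 & ag$attention <= 1))
  # gated output is the input scaled by the attention map
  expect_equal(ag$output[, , 1, 1], x[, , 1, 1] * ag$attention[, , 1, 1],
               tolerance = 1e-12)
})

test_that("ASPP fuses parallel dilated branches at full resolution", {
  set.seed(5)
  x <- array(rnorm(20 * 20 * 3 * 1), c(20, 20, 3, 1))
  rates <- c(1, 2, 4)
  wts <- list(branches = lapply(rates, function(r)
    list(w = array(rnorm(3 * 3 * 3 * 2, 0, 0.3), c(3, 3, 3, 2)),
         b = rep(0, 2))),
    project = list(w = array(rnorm(1 * 1 * 6 * 2, 0, 0.3), c(1, 1, 6, 2)),
                   b = rep(0, 2)))
  out <- aspp_block(x, wts, rates)
  expect_identical(dim(out$output)[1:2], dim(x)[1:2])
  expect_length(out$branches, 3)
  for (b in out$branches) expect_identical(dim(b)[1:2], dim(x)[1:2])
})

test_that("analytic gradients match finite differences through a training loss", {
  net <- build_network(network_config("unet", n_classes = 2, base_width = 2,
                                      depth = 4, seed = 2))
  set.seed(6)
  x <- array(rnorm(16 * 16), c(16, 16, 1, 1))
  y <- array(sample(0:1, 16 * 16, TRUE), c(16, 16, 1))
  fw <- network_forward(net, x, train = FALSE, labels = y)
  ag_backward(fw$loss)
  # probe a handful of parameters across layers
  nm_all <- names(fw$params)
  probes <- nm_all[round(seq(1, length(nm_all), length.out = 4))]
  eps <- 1e-5
  for (nm in probes) {
    g <- fw$params[[nm]]$grad
    i <- which.max(abs(g))
    fd_at <- function(delta) {
      net$params[[nm]][i] <- net$params[[nm]][i] + delta
      v <- network_forward(net, x, train = FALSE, labels = y)$loss$value
      net$params[[nm]][i] <- net$params[[nm]][i] - delta
      v
    }
    fd <- (fd_at(eps) - fd_at(-eps)) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-4)
  }
})

test_that("batch norm keeps separate training and inference statistics", {
  net <- build_network(small_cfg("unet"))
  set.seed(7)
  x <- array(rnorm(16 * 16 * 4, mean = 3), c(16, 16, 1, 4))
  # training passes update the running statistics
  bn_key <- names(net$bn)[1]
  before <- net$bn[[bn_key]]$mean
  invisible(network_forward(net, x, train = TRUE))
  after <- net$bn[[bn_key]]$mean
  expect_false(isTRUE(all.equal(before, after)))
  # inference is deterministic: same input, same logits
  o1 <- network_forward(net, x)$logits$value
  o2 <- network_forward(net, x)$logits$value
  expect_identical(o1, o2)
})

test_that("a few SGD steps reduce the training loss", {
  net <- build_network(network_config("unet", n_classes = 2, base_width = 4,
                                      depth = 4, seed = 4))
  set.seed(8)
  x <- array(rnorm(32 * 32 * 2), c(32, 32, 1, 2))
  y <- array(0L, c(32, 32, 2))
  y[9:24, 9:24, ] <- 1L
  losses <- numeric(8)
  vel <- list()
  for (it in 1:8) {
    fw <- network_forward(net, x, train = TRUE, labels = y)
    ag_backward(fw$loss)
    losses[it] <- fw$loss$value
    vel <- musclesegkit:::sgd_step(net, fw$params, vel, 0.05, 0.9)
  }
  expect_lt(losses[8], losses[1])
})

test_that("invalid configurations are rejected", {
  expect_error(network_config("unet", depth = 2), "depth")
  expect_error(network_config("unet", n_classes = 1), "n_classes")
  expect_error(network_config("resnet"), "arg")
})
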