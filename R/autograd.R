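# Minimal reverse-mode automatic differentiation over 4D feature tensors.
#
# Tensors are column-major R arrays with layout (H, W, C, B). A forward pass
# records operations on a tape; ag_backward() walks the tape in reverse and
# accumulates gradients into the leaf parameters. Heavy kernels (convolution,
# pooling) live in src/kernels.cpp; everything else is vectorised R.

.msk_ag <- new.env(parent = emptyenv())
.msk_ag$tape <- NULL
.msk_ag$tracing <- FALSE

ag_trace_on <- function() {
  .msk_ag$tape <- list()
  .msk_ag$tracing <- TRUE
}

ag_trace_off <- function() {
  .msk_ag$tape <- NULL
  .msk_ag$tracing <- FALSE
}

ag_node <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  class(e) <- "ag_node"
  if (.msk_ag$tracing && length(parents))
    .msk_ag$tape[[length(.msk_ag$tape) + 1L]] <- e
  e
}

ag_param <- function(value) {
  e <- ag_node(value)
  e$is_param <- TRUE
  e
}

ag_const <- function(value) ag_node(value)

ag_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Backpropagate from a scalar loss node through the recorded tape
#'
#' Walks the operations recorded since the last forward pass in reverse and
#' accumulates gradients into the parameter nodes, which
#' [network_forward()] returns in `$params`; each parameter node then carries
#' its gradient in `$grad`.
#'
#' @param loss the scalar loss node returned by [network_forward()].
#' @return NULL, invisibly; gradients are written into the parameter nodes.
#' @export
ag_backward <- function(loss) {
  loss$grad <- 1
  tape <- .msk_ag$tape
  for (i in rev(seq_along(tape))) {
    nd <- tape[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(gs))
      if (!is.null(gs[[j]])) ag_accum(nd$parents[[j]], gs[[j]])
    if (!isTRUE(nd$is_param)) nd$grad <- NULL  # free intermediate grads
  }
  invisible(NULL)
}

# ---- primitive ops --------------------------------------------------------

ag_conv2d <- function(x, w, b, dilation = 1L) {
  y <- cpp_conv2d_fwd(x$value, w$value, b$value, as.integer(dilation))
  ag_node(y, list(x, w, b), function(g) {
    bw <- cpp_conv2d_bwd(x$value, w$value, g, as.integer(dilation))
    list(bw$dx, bw$dw, bw$db)
  })
}

ag_relu <- function(x) {
  m <- x$value > 0
  ag_node(x$value * m, list(x), function(g) list(g * m))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_maxpool2 <- function(x) {
  d <- dim(x$value)
  fw <- cpp_maxpool2_fwd(x$value)
  ag_node(fw$y, list(x),
          function(g) list(cpp_maxpool2_bwd(fw$idx, g, d[1], d[2])))
}

ag_upsample <- function(x, f) {
  d <- dim(x$value)
  y <- x$value[rep(seq_len(d[1]), each = f),
               rep(seq_len(d[2]), each = f), , , drop = FALSE]
  ag_node(y, list(x), function(g) {
    t1 <- colSums(array(g, c(f, d[1], f * d[2] * d[3] * d[4])))
    dim(t1) <- c(d[1], f, d[2], d[3], d[4])
    t2 <- colSums(aperm(t1, c(2, 1, 3, 4, 5)))
    dim(t2) <- d
    list(t2)
  })
}

ag_concat <- function(xs) {
  d <- dim(xs[[1]]$value)
  cs <- vapply(xs, function(x) dim(x$value)[3], numeric(1))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (x in xs) {
    ci <- dim(x$value)[3]
    out[, , at + seq_len(ci), ] <- x$value
    at <- at + ci
  }
  offs <- cumsum(c(0, cs))
  ag_node(out, xs, function(g) {
    lapply(seq_along(xs), function(i)
      g[, , offs[i] + seq_len(cs[i]), , drop = FALSE])
  })
}

# multiply by a single-channel spatial map a with dims (H, W, 1, B)
ag_mul_spatial <- function(x, a) {
  C <- dim(x$value)[3]
  ae <- a$value[, , rep(1L, C), , drop = FALSE]
  ag_node(x$value * ae, list(x, a), function(g) {
    da <- colSums(aperm(g * x$value, c(3, 1, 2, 4)))
    dim(da) <- c(dim(x$value)[1], dim(x$value)[2], 1, dim(x$value)[4])
    list(g * ae, da)
  })
}

# multiply by a channel weighting s with dims (1, 1, C, B)
ag_mul_channel <- function(x, s) {
  d <- dim(x$value)
  se <- s$value[rep(1L, d[1]), rep(1L, d[2]), , , drop = FALSE]
  ag_node(x$value * se, list(x, s), function(g) {
    ds <- colSums(matrix(g * x$value, d[1] * d[2], d[3] * d[4]))
    dim(ds) <- c(1, 1, d[3], d[4])
    list(g * se, ds)
  })
}

ag_global_avgpool <- function(x) {
  d <- dim(x$value)
  v <- colSums(matrix(x$value, d[1] * d[2], d[3] * d[4])) / (d[1] * d[2])
  dim(v) <- c(1, 1, d[3], d[4])
  ag_node(v, list(x), function(g) {
    ge <- g[rep(1L, d[1]), rep(1L, d[2]), , , drop = FALSE] / (d[1] * d[2])
    list(ge)
  })
}

ag_global_maxpool <- function(x) {
  d <- dim(x$value)
  m <- matrix(x$value, d[1] * d[2], d[3] * d[4])
  idx <- max.col(t(m))
  v <- m[cbind(idx, seq_along(idx))]
  dim(v) <- c(1, 1, d[3], d[4])
  ag_node(v, list(x), function(g) {
    dm <- matrix(0, d[1] * d[2], d[3] * d[4])
    dm[cbind(idx, seq_along(idx))] <- as.vector(g)
    dim(dm) <- d
    list(dm)
  })
}

ag_channel_mean <- function(x) {
  d <- dim(x$value)
  v <- colSums(aperm(x$value, c(3, 1, 2, 4))) / d[3]
  dim(v) <- c(d[1], d[2], 1, d[4])
  ag_node(v, list(x), function(g)
    list(g[, , rep(1L, d[3]), , drop = FALSE] / d[3]))
}

ag_channel_max <- function(x) {
  d <- dim(x$value)
  xp <- aperm(x$value, c(3, 1, 2, 4))              # (C, H, W, B)
  m <- matrix(xp, d[3], d[1] * d[2] * d[4])
  idx <- max.col(t(m))
  v <- m[cbind(idx, seq_along(idx))]
  dim(v) <- c(d[1], d[2], 1, d[4])
  ag_node(v, list(x), function(g) {
    dm <- matrix(0, d[3], d[1] * d[2] * d[4])
    dm[cbind(idx, seq_along(idx))] <- as.vector(g)
    dim(dm) <- c(d[3], d[1], d[2], d[4])
    list(aperm(dm, c(2, 3, 1, 4)))
  })
}

# broadcast a (1, 1, C, B) tensor to (H, W, C, B)
ag_broadcast_hw <- function(x, H, W) {
  d <- dim(x$value)
  y <- x$value[rep(1L, H), rep(1L, W), , , drop = FALSE]
  ag_node(y, list(x), function(g) {
    ds <- colSums(matrix(g, H * W, d[3] * d[4]))
    dim(ds) <- d
    list(ds)
  })
}

# zero-pad H and W on the bottom/right; crop reverses it
ag_pad_hw <- function(x, H2, W2) {
  d <- dim(x$value)
  if (d[1] == H2 && d[2] == W2) return(x)
  y <- array(0, c(H2, W2, d[3], d[4]))
  y[seq_len(d[1]), seq_len(d[2]), , ] <- x$value
  ag_node(y, list(x), function(g)
    list(g[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE]))
}

ag_crop_hw <- function(x, H, W) {
  d <- dim(x$value)
  if (d[1] == H && d[2] == W) return(x)
  y <- x$value[seq_len(H), seq_len(W), , , drop = FALSE]
  ag_node(y, list(x), function(g) {
    dx <- array(0, d)
    dx[seq_len(H), seq_len(W), , ] <- g
    list(dx)
  })
}

# batch normalisation over (H, W, B) per channel
ag_batchnorm <- function(x, gamma, beta, state, training = FALSE,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  n <- d[1] * d[2] * d[4]
  xp <- aperm(x$value, c(1, 2, 4, 3))
  m <- matrix(xp, n, d[3])
  if (training) {
    mu <- colMeans(m)
    va <- colMeans(m^2) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va * n / max(n - 1, 1)
  } else {
    mu <- state$mean
    va <- state$var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (m - rep(mu, each = n)) * rep(istd, each = n)
  y <- xhat * rep(gamma$value, each = n) + rep(beta$value, each = n)
  dim(y) <- c(d[1], d[2], d[4], d[3])
  out <- aperm(y, c(1, 2, 4, 3))
  ag_node(out, list(x, gamma, beta), function(g) {
    gp <- matrix(aperm(g, c(1, 2, 4, 3)), n, d[3])
    dgamma <- colSums(gp * xhat)
    dbeta <- colSums(gp)
    if (training) {
      dxhat <- gp * rep(gamma$value, each = n)
      t1 <- colSums(dxhat)
      t2 <- colSums(dxhat * xhat)
      dx <- (dxhat - rep(t1 / n, each = n) -
               xhat * rep(t2 / n, each = n)) * rep(istd, each = n)
    } else {
      dx <- gp * rep(gamma$value * istd, each = n)
    }
    dim(dx) <- c(d[1], d[2], d[4], d[3])
    list(aperm(dx, c(1, 2, 4, 3)), dgamma, dbeta)
  })
}

# Combined softmax cross-entropy + soft multi-class Dice loss.
# logits: (H, W, C, B); labels: integer array (H, W, B) with values 0..C-1.
ag_ce_dice_loss <- function(logits, labels, mix = 0.5, smooth = 1) {
  d <- dim(logits$value)
  C <- d[3]
  z <- matrix(aperm(logits$value, c(1, 2, 4, 3)), ncol = C)   # N x C
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  N <- nrow(p)
  lab <- as.vector(labels) + 1L
  y <- matrix(0, N, C)
  y[cbind(seq_len(N), lab)] <- 1
  ce <- -mean(log(pmax(p[cbind(seq_len(N), lab)], 1e-12)))
  num <- 2 * colSums(p * y) + smooth
  den <- colSums(p) + colSums(y) + smooth
  dice <- num / den
  dl <- 1 - mean(dice)
  loss <- mix * ce + (1 - mix) * dl
  ag_node(loss, list(logits), function(g) {
    gz_ce <- (p - y) / N
    # d dice_c / d p_ic = (2 y_ic * den_c - num_c) / den_c^2
    ddice_dp <- 2 * y * rep(1 / den, each = N) - rep(num / den^2, each = N)
    gp <- -(1 / C) * ddice_dp                 # dLdice/dp
    gz_dice <- p * (gp - rowSums(gp * p))
    gz <- g * (mix * gz_ce + (1 - mix) * gz_dice)
    dim(gz) <- c(d[1], d[2], d[4], C)
    list(aperm(gz, c(1, 2, 4, 3)))
  })
}

softmax_probs <- function(logits_value) {
  d <- dim(logits_value)
  z <- matrix(aperm(logits_value, c(1, 2, 4, 3)), ncol = d[3])
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  dim(p) <- c(d[1], d[2], d[4], d[3])
  aperm(p, c(1, 2, 4, 3))
}
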