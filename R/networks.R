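# Segmentation network architectures over the package's reverse-mode
# autograd: a classic U-Net, a nested-skip U-Net ("unetpp"), a
# feature-fusion U-Net ("ffu") that carries ASPP-processed deep decoder
# features back to full resolution, and an attention variant ("affu") that
# adds additive attention gates on the skip connections and a CBAM module on
# the fused features. All operate on 2D slices with tensors laid out
# (H, W, C, B).

#' Configuration of a segmentation network
#'
#' @param arch architecture: "unet", "unetpp", "ffu" or "affu".
#' @param n_classes number of output classes including background (>= 2).
#' @param in_channels input image channels.
#' @param base_width channels of the first encoder level; each deeper level
#'   doubles it.
#' @param depth number of resolution levels (>= 4; the fusion architectures
#'   feed decoder levels 2..min(4, depth - 1) back to full resolution).
#' @param aspp_rates dilation rates of the ASPP branches.
#' @param seed integer seed for the deterministic weight initialisation.
#' @return list of class `network_config`.
#' @export
network_config <- function(arch = c("unet", "unetpp", "ffu", "affu"),
                           n_classes = 2, in_channels = 1, base_width = 64,
                           depth = 5, aspp_rates = c(1, 2, 4, 8), seed = 1) {
  arch <- match.arg(arch)
  if (depth < 4) stop("depth must be >= 4")
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (base_width < 1) stop("base_width must be >= 1")
  if (any(aspp_rates < 1) || anyDuplicated(aspp_rates))
    stop("aspp_rates must be distinct and >= 1")
  structure(list(arch = arch, n_classes = n_classes,
                 in_channels = in_channels, base_width = base_width,
                 depth = depth, aspp_rates = as.integer(aspp_rates),
                 seed = seed),
            class = "network_config")
}

# ---- parameter store ------------------------------------------------------

he_init <- function(dims) {
  fan_in <- prod(dims[seq_len(max(length(dims) - 1, 1))])
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

# parameter getter bound to a network: creates missing parameters (tracked
# in creation order for deterministic initialisation) and returns ag nodes,
# recording them so the trainer can read gradients by name
make_param_getter <- function(net) {
  function(name, dims, init = "he") {
    if (is.null(net$params[[name]])) {
      net$params[[name]] <- switch(init,
                                   he = he_init(dims),
                                   zero = array(0, dims),
                                   one = array(1, dims),
                                   stop("unknown init"))
      net$param_order <- c(net$param_order, name)
    }
    nd <- ag_param(net$params[[name]])
    net$touched[[name]] <- nd
    nd
  }
}

make_state_getter <- function(net) {
  function(name, C) {
    key <- paste0(name, ".bn")
    if (is.null(net$bn[[key]])) {
      e <- new.env(parent = emptyenv())
      e$mean <- numeric(C)
      e$var <- rep(1, C)
      net$bn[[key]] <- e
    }
    net$bn[[key]]
  }
}

conv_bn_relu <- function(G, S, name, x, cout, train, dilation = 1L) {
  cin <- dim(x$value)[3]
  y <- ag_conv2d(x, G(paste0(name, ".w"), c(3, 3, cin, cout)),
                 G(paste0(name, ".b"), cout, "zero"), dilation)
  y <- ag_batchnorm(y, G(paste0(name, ".g"), cout, "one"),
                    G(paste0(name, ".beta"), cout, "zero"),
                    S(name, cout), training = train)
  ag_relu(y)
}

conv1x1 <- function(G, name, x, cout) {
  cin <- dim(x$value)[3]
  ag_conv2d(x, G(paste0(name, ".w"), c(1, 1, cin, cout)),
            G(paste0(name, ".b"), cout, "zero"))
}

double_conv <- function(G, S, name, x, cout, train) {
  x <- conv_bn_relu(G, S, paste0(name, "a"), x, cout, train)
  conv_bn_relu(G, S, paste0(name, "b"), x, cout, train)
}

# ---- exported building blocks ---------------------------------------------

# node-level additive attention gate; wts supplies the projection nodes
ag_attention_gate <- function(x, gate, wts) {
  theta <- ag_conv2d(x, wts$theta_w, wts$theta_b)
  phi <- ag_conv2d(gate, wts$phi_w, wts$phi_b)
  a <- ag_relu(ag_add(theta, phi))
  psi <- ag_sigmoid(ag_conv2d(a, wts$psi_w, wts$psi_b))
  list(out = ag_mul_spatial(x, psi), attention = psi)
}

# node-level ASPP: parallel dilated conv + ReLU branches, concatenated and
# projected back by a 1x1 convolution
ag_aspp <- function(x, wts, rates) {
  H <- dim(x$value)[1]; W <- dim(x$value)[2]
  small <- rates[2 * rates + 1 > min(H, W)]
  if (length(small))
    warning("ASPP dilation rate(s) ", paste(small, collapse = ", "),
            " exceed the ", H, "x", W,
            " feature map; those branches degrade to border-dominated convolutions")
  branches <- lapply(seq_along(rates), function(i)
    ag_relu(ag_conv2d(x, wts$branches[[i]]$w, wts$branches[[i]]$b,
                      rates[i])))
  out <- ag_relu(ag_conv2d(ag_concat(branches), wts$project$w,
                           wts$project$b))
  list(out = out, branches = branches)
}

as_ag <- function(x) {
  if (inherits(x, "ag_node")) return(x)
  if (is.null(dim(x))) return(ag_const(as.numeric(x)))
  ag_const(x)
}

#' Additive attention gate
#'
#' Gates a feature map `x` by a spatial attention coefficient computed from
#' `x` and a gating signal `gate` of the same spatial size:
#' `psi = sigmoid(conv_psi(relu(conv_theta(x) + conv_phi(gate))))`, output
#' `x * psi`.
#'
#' @param x feature tensor (H, W, Cx, B).
#' @param gate gating tensor (H, W, Cg, B) on the same grid.
#' @param weights list with 1x1 convolution weights `theta_w` (1,1,Cx,Cm),
#'   `theta_b`, `phi_w` (1,1,Cg,Cm), `phi_b`, `psi_w` (1,1,Cm,1), `psi_b`.
#' @return list with `output` (gated features) and `attention` (the
#'   (H, W, 1, B) coefficient map in (0, 1)).
#' @export
attention_gate <- function(x, gate, weights) {
  wts <- lapply(weights, as_ag)
  r <- ag_attention_gate(as_ag(x), as_ag(gate), wts)
  list(output = r$out$value, attention = r$attention$value)
}

#' Atrous spatial pyramid pooling block
#'
#' Applies parallel 3x3 convolutions with the given dilation rates followed
#' by ReLU, concatenates the branches and projects back with a 1x1
#' convolution. Warns when a dilation rate reaches beyond the feature map,
#' where the branch degrades to a border-dominated convolution.
#'
#' @param x feature tensor (H, W, C, B).
#' @param weights list with `branches` (one `list(w, b)` of 3x3 kernels per
#'   rate) and `project` (`list(w, b)`, 1x1).
#' @param rates integer dilation rates, one per branch.
#' @return list with `output` and `branches` (each branch's activation).
#' @export
aspp_block <- function(x, weights, rates) {
  stopifnot(length(weights$branches) == length(rates))
  wts <- list(branches = lapply(weights$branches,
                                function(b) lapply(b, as_ag)),
              project = lapply(weights$project, as_ag))
  r <- ag_aspp(as_ag(x), wts, as.integer(rates))
  list(output = r$out$value,
       branches = lapply(r$branches, function(b) b$value))
}

# ---- architectures --------------------------------------------------------

# shared encoder: list of per-level features (level 1 = full resolution)
forward_encoder <- function(G, S, x, widths, depth, train) {
  enc <- vector("list", depth)
  h <- x
  for (l in seq_len(depth)) {
    if (l > 1) h <- ag_maxpool2(h)
    h <- double_conv(G, S, sprintf("enc%d", l), h, widths[l], train)
    enc[[l]] <- h
  }
  enc
}

# U-Net decoder; returns the per-level decoder features (level 1 full res).
# gate_fn, when given, gates the skip feature before concatenation.
forward_decoder <- function(G, S, enc, widths, depth, train,
                            gate_fn = NULL) {
  dec <- vector("list", depth)
  dec[[depth]] <- enc[[depth]]
  for (l in seq(depth - 1, 1)) {
    u <- ag_upsample(dec[[l + 1]], 2L)
    skip <- enc[[l]]
    if (!is.null(gate_fn)) skip <- gate_fn(l, skip, u)
    h <- ag_concat(list(u, skip))
    dec[[l]] <- double_conv(G, S, sprintf("dec%d", l), h, widths[l], train)
  }
  dec
}

forward_unet <- function(G, S, x, cfg, train, ...) {
  widths <- cfg$base_width * 2^(seq_len(cfg$depth) - 1)
  enc <- forward_encoder(G, S, x, widths, cfg$depth, train)
  dec <- forward_decoder(G, S, enc, widths, cfg$depth, train)
  conv1x1(G, "head", dec[[1]], cfg$n_classes)
}

forward_unetpp <- function(G, S, x, cfg, train, ...) {
  L <- cfg$depth
  widths <- cfg$base_width * 2^(seq_len(L) - 1)
  # grid of nodes X[[i]][[j + 1]], i the level (1 = full res), j the column
  X <- lapply(seq_len(L), function(i) vector("list", L - i + 1))
  h <- x
  for (i in seq_len(L)) {
    if (i > 1) h <- ag_maxpool2(h)
    h <- double_conv(G, S, sprintf("enc%d", i), h, widths[i], train)
    X[[i]][[1]] <- h
  }
  for (j in seq_len(L - 1))
    for (i in seq_len(L - j)) {
      up <- ag_upsample(X[[i + 1]][[j]], 2L)
      h <- ag_concat(c(X[[i]][seq_len(j)], list(up)))
      X[[i]][[j + 1]] <- double_conv(G, S, sprintf("x%d_%d", i, j), h,
                                     widths[i], train)
    }
  conv1x1(G, "head", X[[1]][[L]], cfg$n_classes)
}

# ASPP weight nodes for one fusion level
aspp_weights <- function(G, name, cin, cout, rates) {
  list(branches = lapply(seq_along(rates), function(i)
         list(w = G(sprintf("%s.r%d.w", name, rates[i]), c(3, 3, cin, cout)),
              b = G(sprintf("%s.r%d.b", name, rates[i]), cout, "zero"))),
       project = list(w = G(paste0(name, ".proj.w"),
                            c(1, 1, cout * length(rates), cout)),
                      b = G(paste0(name, ".proj.b"), cout, "zero")))
}

gate_weights <- function(G, name, cx, cg) {
  cm <- max(cx %/% 2, 1)
  list(theta_w = G(paste0(name, ".theta.w"), c(1, 1, cx, cm)),
       theta_b = G(paste0(name, ".theta.b"), cm, "zero"),
       phi_w = G(paste0(name, ".phi.w"), c(1, 1, cg, cm)),
       phi_b = G(paste0(name, ".phi.b"), cm, "zero"),
       psi_w = G(paste0(name, ".psi.w"), c(1, 1, cm, 1)),
       psi_b = G(paste0(name, ".psi.b"), 1, "zero"))
}

# CBAM: channel attention (shared MLP on global average and max pooling)
# followed by spatial attention (7x7 convolution of pooled channel maps)
ag_cbam <- function(G, name, x, train, reduction = 8) {
  C <- dim(x$value)[3]
  cr <- max(C %/% reduction, 1)
  w1 <- G(paste0(name, ".mlp1.w"), c(1, 1, C, cr))
  b1 <- G(paste0(name, ".mlp1.b"), cr, "zero")
  w2 <- G(paste0(name, ".mlp2.w"), c(1, 1, cr, C))
  b2 <- G(paste0(name, ".mlp2.b"), C, "zero")
  mlp <- function(v) ag_conv2d(ag_relu(ag_conv2d(v, w1, b1)), w2, b2)
  s <- ag_sigmoid(ag_add(mlp(ag_global_avgpool(x)),
                         mlp(ag_global_maxpool(x))))
  x <- ag_mul_channel(x, s)
  pooled <- ag_concat(list(ag_channel_mean(x), ag_channel_max(x)))
  m <- ag_sigmoid(ag_conv2d(pooled, G(paste0(name, ".sp.w"), c(7, 7, 2, 1)),
                            G(paste0(name, ".sp.b"), 1, "zero")))
  ag_mul_spatial(x, m)
}

forward_ffu <- function(G, S, x, cfg, train, gated = FALSE, use_cbam = FALSE,
                        gate_passthrough = FALSE, cbam_identity = FALSE) {
  widths <- cfg$base_width * 2^(seq_len(cfg$depth) - 1)
  enc <- forward_encoder(G, S, x, widths, cfg$depth, train)
  gate_fn <- NULL
  if (gated) {
    gate_fn <- function(l, skip, u) {
      wts <- gate_weights(G, sprintf("gate%d", l), dim(skip$value)[3],
                          dim(u$value)[3])
      if (gate_passthrough) return(skip)
      ag_attention_gate(skip, u, wts)$out
    }
  }
  dec <- forward_decoder(G, S, enc, widths, cfg$depth, train, gate_fn)
  fuse_levels <- 2:min(4, cfg$depth - 1)
  feats <- list(dec[[1]])
  for (lv in fuse_levels) {
    up <- ag_upsample(dec[[lv]], 2L^(lv - 1))
    wts <- aspp_weights(G, sprintf("aspp%d", lv), dim(up$value)[3],
                        cfg$base_width, cfg$aspp_rates)
    feats[[length(feats) + 1L]] <- ag_aspp(up, wts, cfg$aspp_rates)$out
  }
  fused <- ag_concat(feats)
  if (use_cbam) {
    cb <- function() ag_cbam(G, "cbam", fused, train)
    if (cbam_identity) {
      # instantiate the CBAM parameters without applying the module
      trc <- .msk_ag$tracing
      .msk_ag$tracing <- FALSE
      cb()
      .msk_ag$tracing <- trc
    } else fused <- cb()
  }
  merged <- conv_bn_relu(G, S, "fuse", fused, cfg$base_width, train)
  out <- ag_add(merged, dec[[1]])
  conv1x1(G, "head", out, cfg$n_classes)
}

# ---- network object -------------------------------------------------------

#' Build a segmentation network
#'
#' Instantiates all parameters deterministically from the configuration seed
#' (a dummy forward pass creates them in a fixed order) and returns the
#' network object. The "affu" architecture contains every "ffu" parameter
#' under the same name plus the attention-gate and CBAM parameters, so FFU
#' weights can be loaded into an AFFU for ablation.
#'
#' @param config a [network_config()].
#' @return object of class `msk_network` with elements `config`, `params`
#'   (named list of arrays), `bn` (running batch-norm statistics) and
#'   `forward` (see [network_forward()]).
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  net <- new.env(parent = emptyenv())
  net$params <- list()
  net$param_order <- character()
  net$bn <- list()
  net$touched <- list()
  net$config <- config
  class(net) <- "msk_network"
  fwd <- switch(config$arch,
                unet = forward_unet,
                unetpp = forward_unetpp,
                ffu = function(G, S, x, cfg, train, ...)
                  forward_ffu(G, S, x, cfg, train, gated = FALSE,
                              use_cbam = FALSE),
                affu = function(G, S, x, cfg, train, gate_passthrough = FALSE,
                                cbam_identity = FALSE, ...)
                  forward_ffu(G, S, x, cfg, train, gated = TRUE,
                              use_cbam = TRUE,
                              gate_passthrough = gate_passthrough,
                              cbam_identity = cbam_identity))
  net$fwd <- fwd
  # deterministic eager instantiation
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(config$seed)
  # large enough that no ASPP branch out-reaches the dummy feature maps
  side <- pad_multiple(2 * max(config$aspp_rates) + 2, 2^(config$depth - 1))
  dummy <- array(0, c(side, side, config$in_channels, 1))
  invisible(network_forward(net, dummy, train = FALSE))
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  net
}

pad_multiple <- function(n, m) as.integer(ceiling(n / m) * m)

#' Run a network forward pass
#'
#' Pads the input to a multiple of the network's total downsampling factor,
#' runs the graph and crops the logits back. With `labels` it also builds
#' the training loss (equal-weight mix of softmax cross-entropy and soft
#' Dice).
#'
#' @param net a [build_network()] object.
#' @param x input array (H, W, C, B) or (H, W, B) for single-channel input.
#' @param train logical; TRUE uses batch statistics (and updates the running
#'   ones) in batch norm.
#' @param labels optional integer array (H, W, B), values 0..n_classes-1.
#' @param gate_passthrough,cbam_identity "affu" ablation switches: force the
#'   attention gates to pass skip features unchanged / skip the CBAM module,
#'   reducing the forward pass to the "ffu" computation.
#' @return list with `logits` (ag node, input-sized), `loss` (ag node or
#'   NULL), `params` (named list of parameter nodes carrying gradients after
#'   [ag_backward()]).
#' @export
network_forward <- function(net, x, train = FALSE, labels = NULL,
                            gate_passthrough = FALSE,
                            cbam_identity = FALSE) {
  stopifnot(inherits(net, "msk_network"))
  cfg <- net$config
  if (length(dim(x)) == 3L)
    x <- array(x, c(dim(x)[1], dim(x)[2], 1, dim(x)[3]))
  stopifnot(length(dim(x)) == 4L, dim(x)[3] == cfg$in_channels)
  H <- dim(x)[1]; W <- dim(x)[2]
  mult <- 2^(cfg$depth - 1)
  net$touched <- list()
  G <- make_param_getter(net)
  S <- make_state_getter(net)
  ag_trace_on()
  xin <- ag_pad_hw(ag_const(x), pad_multiple(H, mult), pad_multiple(W, mult))
  logits <- net$fwd(G, S, xin, cfg, train,
                    gate_passthrough = gate_passthrough,
                    cbam_identity = cbam_identity)
  logits <- ag_crop_hw(logits, H, W)
  loss <- NULL
  if (!is.null(labels)) {
    stopifnot(identical(dim(labels), c(H, W, dim(x)[4])))
    loss <- ag_ce_dice_loss(logits, labels)
  }
  list(logits = logits, loss = loss, params = net$touched)
}

#' Number of trainable parameters of a network
#' @param net a `msk_network`.
#' @return integer parameter count.
#' @export
count_params <- function(net) {
  sum(vapply(net$params, length, numeric(1)))
}

#' @export
print.msk_network <- function(x, ...) {
  cat(sprintf("<msk_network %s> depth %d, base width %d, %d classes, %s parameters\n",
              x$config$arch, x$config$depth, x$config$base_width,
              x$config$n_classes, format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Copy matching weights from one network into another
#'
#' Every parameter of `from` whose name and shape exist in `to` is copied
#' (batch-norm running statistics included). Used to load FFU weights into
#' an AFFU for the attention ablation.
#'
#' @param to,from `msk_network` objects.
#' @return `to`, invisibly; modified in place.
#' @export
load_matching_weights <- function(to, from) {
  for (nm in names(from$params)) {
    if (!is.null(to$params[[nm]]) &&
        identical(dim(to$params[[nm]]), dim(from$params[[nm]])))
      to$params[[nm]] <- from$params[[nm]]
  }
  for (nm in names(from$bn)) {
    if (!is.null(to$bn[[nm]])) {
      to$bn[[nm]]$mean <- from$bn[[nm]]$mean
      to$bn[[nm]]$var <- from$bn[[nm]]$var
    }
  }
  invisible(to)
}
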