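# Lightweight attention and convolution building blocks.
#
# Three blocks are implemented with full forward passes and exact parameter
# accounting:
#   * ema_block()    — efficient multi-scale attention: grouped 1x1/3x3
#     branches with cross-spatial aggregation and no channel reduction.
#   * iema_block()   — the attention block wrapped in an inverted-residual
#     skeleton: input batch-norm -> attention -> depthwise 3x3 -> inner
#     residual -> pointwise 1x1 -> outer residual.
#   * gsconv_block() — group-shuffle convolution: half-width standard
#     convolution + depthwise convolution, concatenated and channel-shuffled.
#
# Parameter accounting distinguishes two conventions (see count_parameters()):
# "training" counts every trainable scalar including both batch-norm affine
# terms; "deployment" counts each fusable conv+BN pair as conv weights plus a
# single folded per-channel bias, the convention under which deployed model
# sizes are reported. Blocks assembled from explicit separate conv and norm
# primitives (the group-shuffle internals, the inverted-residual input norm)
# keep their full affine pairs in both conventions.

#' Block hyper-parameter specification
#'
#' @param in_channels,out_channels Channel counts (`C1`, `C2`).
#' @param kernel Kernel size, length 1 or 2 (`K1`, `K2`).
#' @param stride Stride (>= 1).
#' @param groups Convolution groups; `in_channels` must be divisible by it.
#' @param bias Whether convolutions carry an explicit bias term.
#' @return A `cm_block_spec` list.
#' @export
block_spec <- function(in_channels, out_channels, kernel = 1L, stride = 1L,
                       groups = 1L, bias = TRUE) {
  c1 <- check_count(in_channels, "in_channels")
  c2 <- check_count(out_channels, "out_channels")
  k <- vapply(rep(kernel, length.out = 2L), check_count, integer(1), name = "kernel")
  s <- check_count(stride, "stride")
  g <- check_count(groups, "groups")
  if (c1 %% g != 0L) stop_config("in_channels must be divisible by groups")
  structure(list(in_channels = c1, out_channels = c2, kernel = k, stride = s,
                 groups = g, bias = isTRUE(bias)),
            class = "cm_block_spec")
}

# ---- parameter tensor tables ------------------------------------------------

tt_row <- function(tensor, n_train, n_deploy = n_train) {
  tibble(tensor = tensor, n_train = as.numeric(n_train),
         n_deploy = as.numeric(n_deploy))
}

# Fusable conv + batch-norm pair: deployment folds the affine pair into the
# convolution, leaving one bias per output channel.
tt_conv_bn <- function(prefix, c1, c2, k, g = 1) {
  dplyr::bind_rows(
    tt_row(paste0(prefix, ".weight"), k * k * (c1 / g) * c2),
    tt_row(paste0(prefix, ".bn"), 2 * c2, c2)
  )
}

tt_conv2d <- function(prefix, c1, c2, k, g = 1, bias = TRUE) {
  out <- tt_row(paste0(prefix, ".weight"), k * k * (c1 / g) * c2)
  if (bias) out <- dplyr::bind_rows(out, tt_row(paste0(prefix, ".bias"), c2))
  out
}

tt_norm <- function(prefix, c) tt_row(paste0(prefix, ".affine"), 2 * c)

tt_ema <- function(prefix, channels, groups) {
  cg <- channels / groups
  dplyr::bind_rows(
    tt_norm(paste0(prefix, ".gn"), cg),
    tt_conv2d(paste0(prefix, ".conv1x1"), cg, cg, 1),
    tt_conv2d(paste0(prefix, ".conv3x3"), cg, cg, 3)
  )
}

tt_iema <- function(prefix, channels, groups) {
  dplyr::bind_rows(
    tt_norm(paste0(prefix, ".norm"), channels),
    tt_ema(paste0(prefix, ".ema"), channels, groups),
    tt_conv_bn(paste0(prefix, ".dw"), channels, channels, 3, g = channels),
    tt_conv_bn(paste0(prefix, ".pw"), channels, channels, 1)
  )
}

# Group-shuffle convolution internals use explicit conv + norm primitives, so
# both affine terms survive in either convention.
tt_gsconv <- function(prefix, c1, c2, k, dw_kernel = 5) {
  ch <- c2 / 2
  dplyr::bind_rows(
    tt_conv2d(paste0(prefix, ".cv1.conv"), c1, ch, k, bias = FALSE),
    tt_norm(paste0(prefix, ".cv1.bn"), ch),
    tt_conv2d(paste0(prefix, ".cv2.conv"), ch, ch, dw_kernel, g = ch, bias = FALSE),
    tt_norm(paste0(prefix, ".cv2.bn"), ch)
  )
}

#' Parameter tensor table of a block
#'
#' Enumerates every parameter tensor of a block with its size under the
#' training convention (all trainable scalars) and the deployment convention
#' (fusable conv+BN pairs folded to conv weights plus one bias per channel).
#'
#' @param block A block built by [ema_block()], [iema_block()] or
#'   [gsconv_block()].
#' @return A tibble with columns `tensor`, `n_train`, `n_deploy`.
#' @export
block_tensor_table <- function(block) {
  switch(class(block)[1],
    cm_ema = tt_ema("ema", block$channels, block$groups),
    cm_iema = tt_iema("iema", block$channels, block$groups),
    cm_gsconv = tt_gsconv("gsconv", block$in_channels, block$out_channels,
                          block$kernel, block$dw_kernel),
    stop_input("unknown block type")
  )
}

#' Total parameter count of a block
#'
#' @inheritParams block_tensor_table
#' @param convention `"deployment"` (batch-norm folded) or `"training"`.
#' @return A single number.
#' @export
block_parameters <- function(block, convention = c("deployment", "training")) {
  convention <- match.arg(convention)
  tt <- block_tensor_table(block)
  sum(if (convention == "deployment") tt$n_deploy else tt$n_train)
}

# ---- EMA --------------------------------------------------------------------

#' Construct an efficient multi-scale attention block
#'
#' Channel-grouped attention without dimensionality reduction: each group is
#' gated by horizontal/vertical pooled 1x1-convolution sigmoid maps, run in
#' parallel through a 3x3 convolution, and the two branch outputs are fused by
#' cross-spatial aggregation (instance-normalised descriptors, softmax
#' weights, pairwise aggregation, sigmoid) that re-weights the group features.
#'
#' @param channels Number of input (= output) channels.
#' @param groups Channel group factor; `channels` must be divisible by it.
#'   Default 32, the reference configuration.
#' @param seed Deterministic weight-initialisation seed.
#' @param init `"default"` for He-scaled weights, `"zeros"` for all-zero
#'   weights (identity-path testing).
#' @return A `cm_ema` block.
#' @export
ema_block <- function(channels, groups = 32L, seed = 1L, init = c("default", "zeros")) {
  channels <- check_count(channels, "channels")
  groups <- check_count(groups, "groups")
  init <- match.arg(init)
  if (channels %% groups != 0L) {
    stop_config("channels must be divisible by the group factor")
  }
  cg <- channels %/% groups
  zero <- init == "zeros"
  mk <- function(dims, fan_in, stream) {
    if (zero) array(0, dims) else init_weight(dims, fan_in, seed, stream)
  }
  structure(list(
    channels = channels, groups = groups,
    conv1x1 = list(w = mk(c(cg, cg, 1, 1), cg, 11L), b = rep(0, cg)),
    conv3x3 = list(w = mk(c(cg, cg, 3, 3), cg * 9, 12L), b = rep(0, cg)),
    gn_gamma = rep(1, cg), gn_beta = rep(0, cg)
  ), class = "cm_ema")
}

#' Forward pass of the efficient multi-scale attention block
#'
#' Output has exactly the shape of the input.
#'
#' @param x A feature map array `(batch, channels, height, width)`.
#' @param block A block from [ema_block()].
#' @return An array with the same dimensions as `x`.
#' @export
ema_forward <- function(x, block) {
  validate_feature_map(x)
  d <- dim(x)
  if (d[2] != block$channels) stop_config("input channels do not match the block")
  g <- block$groups
  cg <- d[2] %/% g
  b <- d[1]; h <- d[3]; w <- d[4]
  bg <- b * g

  gx <- array(0, c(bg, cg, h, w))
  for (bi in seq_len(b)) for (gi in seq_len(g)) {
    gx[(bi - 1L) * g + gi, , , ] <- x[bi, (gi - 1L) * cg + seq_len(cg), , ]
  }

  # 1x1 branch: pooled descriptors -> shared 1x1 conv -> sigmoid gates
  xh <- pool_width(gx)                        # (bg, cg, h, 1)
  xw <- aperm(pool_height(gx), c(1, 2, 4, 3)) # (bg, cg, w, 1)
  hw <- array(0, c(bg, cg, h + w, 1L))
  hw[, , seq_len(h), ] <- xh
  hw[, , h + seq_len(w), ] <- xw
  hw <- conv2d_forward(hw, block$conv1x1$w, block$conv1x1$b, padding = 0L)
  sh <- sigmoid(hw[, , seq_len(h), , drop = FALSE])                       # (bg,cg,h,1)
  sw <- sigmoid(aperm(hw[, , h + seq_len(w), , drop = FALSE], c(1, 2, 4, 3))) # (bg,cg,1,w)

  x1 <- gx
  sh3 <- array(sh, c(bg, cg, h))
  sw3 <- array(sw, c(bg, cg, w))
  for (wi in seq_len(w)) {
    x1[, , , wi] <- array(x1[, , , wi], c(bg, cg, h)) * sh3
  }
  for (hi in seq_len(h)) {
    x1[, , hi, ] <- array(x1[, , hi, ], c(bg, cg, w)) * sw3
  }
  x1 <- groupnorm_forward(x1, block$gn_gamma, block$gn_beta, n_groups = cg)

  # 3x3 branch
  x2 <- conv2d_forward(gx, block$conv3x3$w, block$conv3x3$b, padding = 1L)

  # cross-spatial aggregation
  a1 <- pool_global(x1)
  a2 <- pool_global(x2)
  wt <- array(0, c(bg, 1L, h, w))
  for (i in seq_len(bg)) {
    s1 <- softmax_vec(array(a1[i, , , ], cg))
    s2 <- softmax_vec(array(a2[i, , , ], cg))
    m1 <- matrix(x1[i, , , ], cg, h * w)
    m2 <- matrix(x2[i, , , ], cg, h * w)
    wt[i, 1L, , ] <- array(as.numeric(s1 %*% m2 + s2 %*% m1), c(h, w))
  }
  sg3 <- array(sigmoid(wt), c(bg, h, w))
  for (ci in seq_len(cg)) {
    gx[, ci, , ] <- array(gx[, ci, , ], c(bg, h, w)) * sg3
  }

  out <- array(0, d)
  for (bi in seq_len(b)) for (gi in seq_len(g)) {
    out[bi, (gi - 1L) * cg + seq_len(cg), , ] <- gx[(bi - 1L) * g + gi, , , ]
  }
  out
}

# ---- fusable conv+BN wrapper ------------------------------------------------

new_conv_bn <- function(c1, c2, k, s = 1L, g = 1L, seed = 1L, stream = 1L,
                        zero = FALSE) {
  w <- if (zero) array(0, c(c2, c1 %/% g, k, k)) else {
    init_weight(c(c2, c1 %/% g, k, k), k * k * c1 / g, seed, stream)
  }
  list(w = w, stride = s, groups = g, padding = k %/% 2L,
       gamma = rep(1, c2), beta = rep(0, c2), mean = rep(0, c2), var = rep(1, c2))
}

conv_bn_forward <- function(x, cb, act = silu) {
  y <- conv2d_forward(x, cb$w, bias = NULL, stride = cb$stride,
                      padding = cb$padding, groups = cb$groups)
  act(batchnorm_forward(y, cb$gamma, cb$beta, cb$mean, cb$var))
}

# ---- IEMA -------------------------------------------------------------------

#' Construct the inverted-residual attention block
#'
#' Wraps the multi-scale attention in an inverted-residual skeleton:
#' `y = EMA(BN(x)); z = DWConv3x3(y); s = y + z; w = PWConv1x1(s); out = w + x`.
#' The depthwise and pointwise stages are fusable conv+BN pairs; the input
#' normalisation is a standalone batch-norm.
#'
#' @inheritParams ema_block
#' @return A `cm_iema` block.
#' @export
iema_block <- function(channels, groups = 32L, seed = 1L,
                       init = c("default", "zeros")) {
  channels <- check_count(channels, "channels")
  init <- match.arg(init)
  zero <- init == "zeros"
  structure(list(
    channels = channels, groups = check_count(groups, "groups"),
    norm = list(gamma = rep(1, channels), beta = rep(0, channels),
                mean = rep(0, channels), var = rep(1, channels)),
    ema = ema_block(channels, groups, seed, init),
    dw = new_conv_bn(channels, channels, 3L, g = channels, seed = seed,
                     stream = 21L, zero = zero),
    pw = new_conv_bn(channels, channels, 1L, seed = seed, stream = 22L,
                     zero = zero)
  ), class = "cm_iema")
}

#' Forward pass of the inverted-residual attention block
#'
#' Shape-preserving; the outer residual guarantees that a block with all
#' convolution weights zeroed is the identity map.
#'
#' @param x A feature map array.
#' @param block A block from [iema_block()].
#' @return An array with the same dimensions as `x`.
#' @export
iema_forward <- function(x, block) {
  validate_feature_map(x)
  if (dim(x)[2] != block$channels) stop_config("input channels do not match the block")
  y <- ema_forward(batchnorm_forward(x, block$norm$gamma, block$norm$beta,
                                     block$norm$mean, block$norm$var),
                   block$ema)
  z <- conv_bn_forward(y, block$dw)
  s <- y + z
  conv_bn_forward(s, block$pw) + x
}

# ---- GSConv -----------------------------------------------------------------

#' Construct a group-shuffle convolution block
#'
#' A standard convolution maps `C1 -> C2/2` channels (kernel/stride per
#' arguments), a depthwise convolution (kernel `dw_kernel`) processes those
#' channels, the two maps are concatenated to `C2` channels, and a channel
#' shuffle interleaves them. Internal convolutions are explicit conv + BN
#' primitives.
#'
#' @param in_channels,out_channels Channel counts; `out_channels` must be even.
#' @param kernel,stride Standard-convolution kernel and stride.
#' @param dw_kernel Depthwise kernel size (default 5, the slim-neck reference).
#' @param seed,init As in [ema_block()].
#' @return A `cm_gsconv` block.
#' @export
gsconv_block <- function(in_channels, out_channels, kernel = 1L, stride = 1L,
                         dw_kernel = 5L, seed = 1L, init = c("default", "zeros")) {
  c1 <- check_count(in_channels, "in_channels")
  c2 <- check_count(out_channels, "out_channels")
  if (c2 %% 2L != 0L) stop_config("out_channels must be even")
  k <- check_count(kernel, "kernel")
  s <- check_count(stride, "stride")
  dk <- check_count(dw_kernel, "dw_kernel")
  init <- match.arg(init)
  zero <- init == "zeros"
  ch <- c2 %/% 2L
  structure(list(
    in_channels = c1, out_channels = c2, kernel = k, stride = s, dw_kernel = dk,
    cv1 = new_conv_bn(c1, ch, k, s = s, seed = seed, stream = 31L, zero = zero),
    cv2 = new_conv_bn(ch, ch, dk, g = ch, seed = seed, stream = 32L, zero = zero)
  ), class = "cm_gsconv")
}

#' Forward pass of the group-shuffle convolution block
#'
#' @param x A feature map array.
#' @param block A block from [gsconv_block()].
#' @return An array `(batch, out_channels, H/stride, W/stride)`.
#' @export
gsconv_forward <- function(x, block) {
  validate_feature_map(x)
  if (dim(x)[2] != block$in_channels) stop_config("input channels do not match the block")
  x1 <- conv_bn_forward(x, block$cv1)
  x2 <- conv_bn_forward(x1, block$cv2)
  d <- dim(x1)
  out <- array(0, c(d[1], 2L * d[2], d[3], d[4]))
  out[, seq_len(d[2]), , ] <- x1
  out[, d[2] + seq_len(d[2]), , ] <- x2
  channel_shuffle(out, groups = 2L)
}

#' Interleaving channel shuffle
#'
#' Reshapes the channel dimension to `(groups, C/groups)`, transposes and
#' flattens, so for two groups channels are interleaved
#' `1, C/2+1, 2, C/2+2, ...`. A pure permutation: no information is lost.
#'
#' @param x A feature map array.
#' @param groups Number of shuffle groups (channel count must divide evenly).
#' @return `x` with permuted channels.
#' @export
channel_shuffle <- function(x, groups = 2L) {
  validate_feature_map(x)
  cc <- dim(x)[2]
  if (cc %% groups != 0L) stop_config("channels must be divisible by shuffle groups")
  perm <- as.vector(t(matrix(seq_len(cc), ncol = groups)))
  x[, perm, , , drop = FALSE]
}

# ---- computational-cost accounting ------------------------------------------

check_cost_args <- function(...) {
  args <- c(...)
  if (any(!is.finite(args)) || any(args < 1) || any(args != round(args))) {
    stop_input("all cost arguments must be positive integers")
  }
  args
}

#' Multiply-accumulate cost of a dense standard convolution
#'
#' `W * H * K1 * K2 * C1 * C2`, the number of multiply-accumulate operations
#' of a dense convolution producing a `W x H` map with `C2` channels from
#' `C1` channels with a `K1 x K2` kernel.
#'
#' @param W,H Output feature-map width and height.
#' @param K1,K2 Kernel size.
#' @param C1,C2 Input and output channel counts.
#' @return The exact product as a double (exact integer arithmetic within
#'   2^53).
#' @export
conv_cost <- function(W, H, K1, K2, C1, C2) {
  check_cost_args(W, H, K1, K2, C1, C2)
  W * H * K1 * K2 * C1 * C2
}

#' Multiply-accumulate cost of the group-shuffle convolution
#'
#' `W * H * K1 * K2 * (C2/2) * (C1 + 1)`: the half-width standard convolution
#' costs `W*H*K1*K2*C1*C2/2` and the depthwise stage adds `W*H*K1*K2*C2/2`.
#' The ratio to [conv_cost()] is `(C1+1)/(2*C1)`, approaching one half as
#' `C1` grows.
#'
#' @inheritParams conv_cost
#' @return The exact product as a double.
#' @export
gsconv_cost <- function(W, H, K1, K2, C1, C2) {
  check_cost_args(W, H, K1, K2, C1, C2)
  if (C2 %% 2 != 0) stop_input("C2 must be even")
  W * H * K1 * K2 * (C2 / 2) * (C1 + 1)
}
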