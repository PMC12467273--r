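# Minimal deterministic neural-network primitives on 4-D activation arrays.
#
# A feature map is an ordinary R array with dim = c(batch, channels, height,
# width). Every primitive is evaluated in inference mode (normalisation layers
# use stored statistics), so outputs are bit-reproducible for fixed weights.

#' Validate a feature map
#'
#' Checks that `x` is a 4-D numeric array (batch, channels, height, width)
#' with all dimensions at least one and all values finite.
#'
#' @param x An array with `dim = c(batch, channels, height, width)`.
#' @return `x`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_feature_map <- function(x) {
  if (!is.array(x) || length(dim(x)) != 4L || !is.numeric(x)) {
    stop_input("feature map must be a 4-D numeric array (batch, channels, height, width)")
  }
  if (any(dim(x) < 1L)) stop_input("all feature-map dimensions must be >= 1")
  if (!all(is.finite(x))) stop_input("feature map contains non-finite values")
  invisible(x)
}

# Deterministic weight fill: He-scaled values from the counter stream, so
# constructing a block never touches the global RNG state.
init_weight <- function(dims, fan_in, seed, stream) {
  n <- prod(dims)
  vals <- (ch_unif(seed, stream, k1 = seq_len(n)) - 0.5) * 2 * sqrt(3 / fan_in)
  array(vals, dim = dims)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
silu <- function(x) x * sigmoid(x)

pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2], d[3] + 2 * p, d[4] + 2 * p))
  out[, , p + seq_len(d[3]), p + seq_len(d[4])] <- x
  out
}

# im2col over one padded sample (C, Hp, Wp) -> (C*k*k, Ho*Wo), row blocks
# ordered channel-fastest then kernel-row then kernel-column, matching the
# weight reshape in conv2d_forward().
im2col <- function(xp, k, s, ho, wo) {
  cc <- dim(xp)[1]
  out <- matrix(0, cc * k * k, ho * wo)
  blk <- 0L
  for (kj in seq_len(k)) {
    cols <- seq(kj, by = s, length.out = wo)
    for (ki in seq_len(k)) {
      rows <- seq(ki, by = s, length.out = ho)
      out[blk + seq_len(cc), ] <- matrix(xp[, rows, cols, drop = FALSE], cc, ho * wo)
      blk <- blk + cc
    }
  }
  out
}

# Grouped 2-D convolution. weight dims: (c2, c1/g, k, k); bias NULL or length c2.
conv2d_forward <- function(x, weight, bias = NULL, stride = 1L, padding = NULL,
                           groups = 1L) {
  d <- dim(x)
  c2 <- dim(weight)[1]
  c1g <- dim(weight)[2]
  k <- dim(weight)[3]
  if (is.null(padding)) padding <- k %/% 2L
  if (d[2] %% groups != 0L || c2 %% groups != 0L) {
    stop_config("channels not divisible by groups")
  }
  if (d[2] / groups != c1g) stop_config("weight shape does not match input channels")
  xp <- pad_hw(x, padding)
  hp <- dim(xp)[3]; wp <- dim(xp)[4]
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  out <- array(0, c(d[1], c2, ho, wo))
  c2g <- c2 %/% groups
  for (b in seq_len(d[1])) {
    for (g in seq_len(groups)) {
      in_ch <- (g - 1L) * c1g + seq_len(c1g)
      out_ch <- (g - 1L) * c2g + seq_len(c2g)
      wm <- matrix(weight[out_ch, , , , drop = FALSE], c2g, c1g * k * k)
      col <- im2col(array(xp[b, in_ch, , , drop = FALSE], c(c1g, hp, wp)),
                    k, stride, ho, wo)
      y <- wm %*% col
      if (!is.null(bias)) y <- y + bias[out_ch]
      out[b, out_ch, , ] <- array(y, c(c2g, ho, wo))
    }
  }
  out
}

# Inference-mode batch normalisation with stored statistics.
batchnorm_forward <- function(x, gamma, beta, mean = NULL, var = NULL, eps = 1e-5) {
  cc <- dim(x)[2]
  if (is.null(mean)) mean <- rep(0, cc)
  if (is.null(var)) var <- rep(1, cc)
  scale <- gamma / sqrt(var + eps)
  shift <- beta - mean * scale
  out <- x
  for (ch in seq_len(cc)) out[, ch, , ] <- x[, ch, , ] * scale[ch] + shift[ch]
  out
}

# Group normalisation (per-sample). With n_groups == channels this is
# channel-wise instance normalisation, the layout used inside the attention
# block's cross-spatial branch.
groupnorm_forward <- function(x, gamma, beta, n_groups, eps = 1e-5) {
  d <- dim(x)
  if (d[2] %% n_groups != 0L) stop_config("channels not divisible by norm groups")
  cg <- d[2] %/% n_groups
  out <- x
  for (b in seq_len(d[1])) {
    for (g in seq_len(n_groups)) {
      ch <- (g - 1L) * cg + seq_len(cg)
      v <- x[b, ch, , , drop = FALSE]
      mu <- mean(v)
      sd2 <- mean((v - mu)^2)
      out[b, ch, , ] <- (v - mu) / sqrt(sd2 + eps)
    }
  }
  for (ch in seq_len(d[2])) out[, ch, , ] <- out[, ch, , ] * gamma[ch] + beta[ch]
  out
}

# Average pooling helpers used by the attention block.
pool_width <- function(x) {
  d <- dim(x)
  array(apply(x, c(1, 2, 3), mean), c(d[1], d[2], d[3], 1L))
}

pool_height <- function(x) {
  d <- dim(x)
  array(apply(x, c(1, 2, 4), mean), c(d[1], d[2], 1L, d[4]))
}

pool_global <- function(x) {
  d <- dim(x)
  array(apply(x, c(1, 2), mean), c(d[1], d[2], 1L, 1L))
}

softmax_vec <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}
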