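# Attention and convolution building blocks: shape contracts, parameter
# accounting, shuffle permutation, cost formulas.

test_that("attention forward preserves shape and finiteness", {
  set.seed(41)
  shapes <- list(c(1, 64, 8, 8), c(2, 64, 6, 10), c(1, 32, 5, 5))
  for (sh in shapes) {
    x <- array(rnorm(prod(sh)), sh)
    blk <- ema_block(sh[2], groups = 32, seed = 3)
    y <- ema_forward(x, blk)
    expect_identical(dim(y), dim(x))
    expect_true(all(is.finite(y)))
  }
  # all-zeros input stays finite with identical shape
  x0 <- array(0, c(1, 64, 4, 4))
  y0 <- ema_forward(x0, ema_block(64, seed = 5))
  expect_identical(dim(y0), dim(x0))
  expect_true(all(is.finite(y0)))
})

test_that("attention forward handles the small-object branch shape (256ch, 80x80)", {
  x <- array(0.1, c(1, 256, 80, 80))
  y <- ema_forward(x, ema_block(256, groups = 32, seed = 1))
  expect_identical(dim(y), c(1L, 256L, 80L, 80L))
})

test_that("channel/group mismatch and non-finite input raise errors", {
  expect_error(ema_block(30, groups = 32), class = "cellmot_config_error")
  blk <- ema_block(64)
  x <- array(rnorm(64 * 16), c(1, 64, 4, 4))
  x[1] <- NA
  expect_error(ema_forward(x, blk), class = "cellmot_input_error")
  x[1] <- Inf
  expect_error(ema_forward(x, blk), class = "cellmot_input_error")
  xg <- array(0, c(1, 32, 4, 4))
  expect_error(ema_forward(xg, blk), class = "cellmot_config_error")
})

test_that("attention parameter count matches a per-layer enumeration", {
  # independent enumeration: instance-norm affine (2c) + 1x1 conv (c^2 + c)
  # + 3x3 conv (9c^2 + c), with c = channels / groups
  for (C in c(64, 256)) {
    g <- 32
    c <- C / g
    by_hand <- (2 * c) + (c^2 + c) + (9 * c^2 + c)
    expect_equal(block_parameters(ema_block(C, g)), by_hand)
    expect_equal(block_parameters(ema_block(C, g), "training"), by_hand)
  }
})

test_that("inverted-residual block preserves shape and the 80x80 contract", {
  set.seed(42)
  x <- array(rnorm(64 * 36), c(1, 64, 6, 6))
  blk <- iema_block(64, seed = 9)
  y <- iema_forward(x, blk)
  expect_identical(dim(y), dim(x))
  expect_true(all(is.finite(y)))
})

test_that("zeroed inverted-residual block is the exact identity", {
  set.seed(43)
  x <- array(rnorm(64 * 64), c(1, 64, 8, 8))
  blk <- iema_block(64, init = "zeros")
  expect_identical(iema_forward(x, blk), x)
})

test_that("inverted-residual block at 64 channels counts 4976 parameters", {
  blk <- iema_block(64, groups = 32)
  # per-layer enumeration under the folded convention: standalone norm 2C,
  # attention (2c + c^2+c + 9c^2+c with c = 2), depthwise 9C + C folded,
  # pointwise C^2 + C folded
  expect_equal(block_parameters(blk, "deployment"), 4976)
  by_hand <- 2 * 64 + (4 + 6 + 38) + (9 * 64 + 64) + (64 * 64 + 64)
  expect_equal(block_parameters(blk, "deployment"), by_hand)
})

test_that("group-shuffle convolution obeys the stride-2 shape contract", {
  set.seed(44)
  x <- array(rnorm(128 * 40 * 40), c(1, 128, 40, 40))
  blk <- gsconv_block(128, 128, kernel = 3, stride = 2)
  y <- gsconv_forward(x, blk)
  expect_identical(dim(y), c(1L, 128L, 20L, 20L))
  expect_error(gsconv_block(128, 127), class = "cellmot_config_error")
})

test_that("channel shuffle is a lossless interleaving permutation", {
  set.seed(45)
  x <- array(rnorm(2 * 8 * 3 * 3), c(2, 8, 3, 3))
  y <- channel_shuffle(x, 2)
  # interleave: output channels are 1, 5, 2, 6, 3, 7, 4, 8
  expect_equal(y[, 1, , ], x[, 1, , ])
  expect_equal(y[, 2, , ], x[, 5, , ])
  expect_equal(y[, 3, , ], x[, 2, , ])
  # permutation: the multiset of channel slices is preserved
  key <- function(a) sort(apply(a, 2, function(v) sum(v^2)))
  expect_equal(key(array(y, c(2, 8, 9))), key(array(x, c(2, 8, 9))))
})

test_that("shuffled block output is the union of the two branch outputs", {
  set.seed(46)
  x <- array(rnorm(64 * 100), c(1, 64, 10, 10))
  blk <- gsconv_block(64, 64, kernel = 3, stride = 1)
  x1 <- cellmot:::conv_bn_forward(x, blk$cv1)
  x2 <- cellmot:::conv_bn_forward(x1, blk$cv2)
  y <- gsconv_forward(x, blk)
  branch_norms <- sort(c(apply(x1[1, , , ], 1, function(v) sum(v^2)),
                         apply(x2[1, , , ], 1, function(v) sum(v^2))))
  out_norms <- sort(apply(y[1, , , ], 1, function(v) sum(v^2)))
  expect_equal(out_norms, branch_norms)
})

test_that("cost formulas match direct substitution and a counting oracle", {
  expect_equal(conv_cost(1, 1, 1, 1, 1, 2), 2)
  expect_equal(conv_cost(80, 80, 3, 3, 256, 256), 80 * 80 * 9 * 256 * 256)
  expect_equal(gsconv_cost(1, 1, 1, 1, 1, 2), 2)
  expect_error(conv_cost(0, 1, 1, 1, 1, 1), class = "cellmot_input_error")
  expect_error(gsconv_cost(1, 1, 1, 1, 1, 3), class = "cellmot_input_error")

  # naive loop count of multiply-accumulates on a tiny dense convolution
  W <- 3; H <- 2; K1 <- 2; K2 <- 2; C1 <- 3; C2 <- 2
  macs <- 0
  for (w in 1:W) for (h in 1:H) for (k1 in 1:K1) for (k2 in 1:K2) {
    for (ci in 1:C1) for (co in 1:C2) macs <- macs + 1
  }
  expect_equal(conv_cost(W, H, K1, K2, C1, C2), macs)
})

test_that("cost ratio follows (C1+1)/(2 C1) and approaches one half", {
  set.seed(47)
  for (i in 1:1000) {
    W <- sample(1:64, 1); H <- sample(1:64, 1)
    K1 <- sample(1:7, 1); K2 <- sample(1:7, 1)
    C1 <- sample(1:512, 1); C2 <- 2 * sample(1:256, 1)
    tc <- conv_cost(W, H, K1, K2, C1, C2)
    tg <- gsconv_cost(W, H, K1, K2, C1, C2)
    expect_identical(tc, W * H * K1 * K2 * C1 * C2)
    expect_identical(tg, W * H * K1 * K2 * (C2 / 2) * (C1 + 1))
    expect_equal(tg / tc, (C1 + 1) / (2 * C1))
  }
  ratios <- vapply(c(4, 16, 64, 256, 1024), function(C1) {
    gsconv_cost(8, 8, 3, 3, C1, 64) / conv_cost(8, 8, 3, 3, C1, 64)
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
  expect_lt(abs(ratios[5] - 0.5), 1e-3)
  expect_equal(gsconv_cost(1, 1, 1, 1, 256, 256) / conv_cost(1, 1, 1, 1, 256, 256),
               257 / 512)
})

test_that("group-shuffle block has fewer parameters than a standard convolution", {
  for (i in 1:20) {
    C1 <- 2 * sample(1:64, 1)
    C2 <- 2 * sample(1:64, 1)
    K <- sample(c(1, 3, 5), 1)
    gs <- block_parameters(gsconv_block(C1, C2, kernel = K, dw_kernel = K),
                           "training")
    std <- K * K * C1 * C2 + 2 * C2
    if (C1 > 1) expect_lt(gs, std)
  }
})

test_that("block forwards are deterministic for fixed weights", {
  set.seed(48)
  x <- array(rnorm(64 * 49), c(1, 64, 7, 7))
  blk <- ema_block(64, seed = 17)
  expect_identical(ema_forward(x, blk), ema_forward(x, blk))
  ib <- iema_block(64, seed = 17)
  expect_identical(iema_forward(x, ib), iema_forward(x, ib))
  gb <- gsconv_block(64, 64, kernel = 3, seed = 17)
  expect_identical(gsconv_forward(x, gb), gsconv_forward(x, gb))
})
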