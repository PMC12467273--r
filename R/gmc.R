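# Global (camera) motion compensation: a frame-to-frame transform applied to
# predicted track states before association. Detection boxes are never
# touched.

#' Estimate the translation between two frames
#'
#' Phase correlation via the 2-D FFT; the correlation peak gives the integer
#' displacement `(tx, ty)` mapping coordinates of `prev` into `cur`.
#'
#' @param prev,cur Numeric matrices (rows = y, columns = x) of equal size.
#' @return Numeric `c(tx, ty)` in pixels.
#' @export
estimate_translation <- function(prev, cur) {
  if (!is.matrix(prev) || !is.matrix(cur) || any(dim(prev) != dim(cur))) {
    stop_input("frames must be numeric matrices of equal size")
  }
  f1 <- fft(prev)
  f2 <- fft(cur)
  cross <- f2 * Conj(f1)
  denom <- Mod(cross)
  denom[denom < 1e-12] <- 1
  r <- Re(fft(cross / denom, inverse = TRUE))
  peak <- which(r == max(r), arr.ind = TRUE)[1, ]
  n <- nrow(prev); m <- ncol(prev)
  dy <- peak[1] - 1L
  dx <- peak[2] - 1L
  if (dy > n / 2) dy <- dy - n
  if (dx > m / 2) dx <- dx - m
  c(tx = as.numeric(dx), ty = as.numeric(dy))
}

# Affine estimation from a grid of local block translations. Returns a 2x3
# matrix A such that (x', y') = A %*% c(x, y, 1).
estimate_affine <- function(prev, cur, grid = 3L, block = NULL) {
  n <- nrow(prev); m <- ncol(prev)
  if (is.null(block)) block <- max(16L, min(n, m) %/% (grid + 1L))
  ys <- round(seq(1, n - block + 1, length.out = grid))
  xs <- round(seq(1, m - block + 1, length.out = grid))
  pts <- NULL
  for (y0 in ys) for (x0 in xs) {
    pb <- prev[y0:(y0 + block - 1L), x0:(x0 + block - 1L)]
    cb <- cur[y0:(y0 + block - 1L), x0:(x0 + block - 1L)]
    if (stats::sd(pb) < 1e-9) next
    sh <- estimate_translation(pb, cb)
    cx <- x0 + block / 2; cy <- y0 + block / 2
    pts <- rbind(pts, c(cx, cy, cx + sh[["tx"]], cy + sh[["ty"]]))
  }
  if (is.null(pts) || nrow(pts) < 3L) stop_numeric("too few blocks for affine estimation")
  X <- cbind(pts[, 1], pts[, 2], 1)
  ax <- solve(crossprod(X), crossprod(X, pts[, 3]))
  ay <- solve(crossprod(X), crossprod(X, pts[, 4]))
  rbind(as.numeric(ax), as.numeric(ay))
}

apply_affine_point <- function(A, x, y) {
  as.numeric(A %*% c(x, y, 1))
}

#' Compensate global frame motion in predicted track states
#'
#' Estimates a global 2-D transform between consecutive frames and applies it
#' to every predicted track mean (positions; and box corners in affine mode,
#' so box sizes follow the linear part). Detection boxes are untouched.
#' Returns tracks unchanged when compensation is disabled or frames are
#' absent; falls back to the identity transform (with a warning) when
#' estimation fails.
#'
#' @param tracks A list of track objects (as managed by [track_sequence()]).
#' @param prev_frame,cur_frame Numeric frame matrices.
#' @param cfg A [tracker_config()].
#' @return The track list with compensated state means.
#' @export
compensate_motion <- function(tracks, prev_frame, cur_frame, cfg) {
  mode <- cfg$motion_compensation
  if (mode == "off" || is.null(prev_frame) || is.null(cur_frame)) return(tracks)
  if (mode == "translation") {
    sh <- tryCatch(estimate_translation(prev_frame, cur_frame),
                   error = function(e) {
                     warn(paste0("motion estimation failed, using identity: ",
                                 conditionMessage(e)))
                     c(tx = 0, ty = 0)
                   })
    return(lapply(tracks, function(tr) {
      tr$state$mean[1] <- tr$state$mean[1] + sh[["tx"]]
      tr$state$mean[2] <- tr$state$mean[2] + sh[["ty"]]
      tr
    }))
  }
  A <- tryCatch(estimate_affine(prev_frame, cur_frame),
                error = function(e) {
                  warn(paste0("affine estimation failed, using identity: ",
                              conditionMessage(e)))
                  rbind(c(1, 0, 0), c(0, 1, 0))
                })
  lapply(tracks, function(tr) {
    m <- tr$state$mean
    tl <- apply_affine_point(A, m[1] - m[3] / 2, m[2] - m[4] / 2)
    br <- apply_affine_point(A, m[1] + m[3] / 2, m[2] + m[4] / 2)
    tr$state$mean[1] <- (tl[1] + br[1]) / 2
    tr$state$mean[2] <- (tl[2] + br[2]) / 2
    tr$state$mean[3] <- max(abs(br[1] - tl[1]), 1e-3)
    tr$state$mean[4] <- max(abs(br[2] - tl[2]), 1e-3)
    tr
  })
}
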