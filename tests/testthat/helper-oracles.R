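# Independent brute-force oracles and fixture builders used across the test
# files. Everything here is deliberately written with different machinery
# from the package internals: exhaustive enumeration instead of the
# Hungarian solver, plain loops instead of vectorised accumulation.

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Exhaustive gated assignment: maximise the number of feasible pairs, then
# minimise total cost; returns a 2-column matrix (row, col).
brute_assignment <- function(cost, gate = Inf) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L || nc == 0L) return(matrix(integer(), ncol = 2))
  n <- max(nr, nc)
  best <- NULL; best_k <- -1L; best_c <- Inf
  for (p in all_perms(n)) {
    k <- 0L; cst <- 0
    pairs <- matrix(integer(), ncol = 2)
    for (i in seq_len(nr)) {
      j <- p[i]
      if (j <= nc && is.finite(cost[i, j]) && cost[i, j] <= gate) {
        k <- k + 1L; cst <- cst + cost[i, j]
        pairs <- rbind(pairs, c(i, j))
      }
    }
    if (k > best_k || (k == best_k && cst < best_c - 1e-12)) {
      best <- pairs; best_k <- k; best_c <- cst
    }
  }
  best
}

oracle_iou <- function(a, b) {
  x1 <- max(a[1], b[1]); y1 <- max(a[2], b[2])
  x2 <- min(a[1] + a[3], b[1] + b[3]); y2 <- min(a[2] + a[4], b[2] + b[4])
  if (x2 <= x1 || y2 <= y1) return(0)
  inter <- (x2 - x1) * (y2 - y1)
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

oracle_iou_matrix <- function(g, p) {
  out <- matrix(0, nrow(g), nrow(p))
  for (i in seq_len(nrow(g))) for (j in seq_len(nrow(p))) {
    out[i, j] <- oracle_iou(as.numeric(g[i, c("left", "top", "width", "height")]),
                            as.numeric(p[j, c("left", "top", "width", "height")]))
  }
  out
}

# CLEAR-MOT with carry-over, brute-force per-frame assignment.
oracle_clear <- function(gt, pred, thresh = 0.5) {
  frames <- sort(unique(c(gt$frame, pred$frame)))
  fp <- 0L; fn <- 0L; idsw <- 0L; tp <- 0L
  prev <- NULL
  last <- list()
  for (f in frames) {
    g <- gt[gt$frame == f, ]; p <- pred[pred$frame == f, ]
    mg <- integer(0); mp <- integer(0); pairs <- NULL
    if (!is.null(prev)) {
      for (r in seq_len(nrow(prev))) {
        gi <- match(prev[r, 1], g$id); pi <- match(prev[r, 2], p$id)
        if (!is.na(gi) && !is.na(pi) && !(gi %in% mg) && !(pi %in% mp)) {
          v <- oracle_iou(as.numeric(g[gi, c("left", "top", "width", "height")]),
                          as.numeric(p[pi, c("left", "top", "width", "height")]))
          if (v >= thresh) {
            mg <- c(mg, gi); mp <- c(mp, pi)
            pairs <- rbind(pairs, c(g$id[gi], p$id[pi]))
          }
        }
      }
    }
    rg <- setdiff(seq_len(nrow(g)), mg); rp <- setdiff(seq_len(nrow(p)), mp)
    if (length(rg) > 0L && length(rp) > 0L) {
      sim <- oracle_iou_matrix(g[rg, ], p[rp, ])
      sel <- brute_assignment(1 - sim, gate = 1 - thresh)
      for (r in seq_len(nrow(sel))) {
        gi <- rg[sel[r, 1]]; pi <- rp[sel[r, 2]]
        mg <- c(mg, gi); mp <- c(mp, pi)
        pairs <- rbind(pairs, c(g$id[gi], p$id[pi]))
      }
    }
    tp <- tp + length(mg)
    fn <- fn + nrow(g) - length(mg)
    fp <- fp + nrow(p) - length(mg)
    for (r in seq_len(NROW(pairs))) {
      key <- as.character(pairs[r, 1])
      if (!is.null(last[[key]]) && last[[key]] != pairs[r, 2]) idsw <- idsw + 1L
      last[[key]] <- pairs[r, 2]
    }
    prev <- pairs
  }
  list(mota = 100 * (1 - (fn + fp + idsw) / nrow(gt)), fp = fp, fn = fn,
       idsw = idsw, tp = tp)
}

# IDF1 by exhaustive trajectory matching (dummy-padded permutations).
oracle_idf1 <- function(gt, pred, thresh = 0.5) {
  gids <- sort(unique(gt$id)); pids <- sort(unique(pred$id))
  ng <- length(gids); np <- length(pids)
  if (np == 0L) return(0)
  ov <- matrix(0, ng, np)
  for (f in sort(unique(c(gt$frame, pred$frame)))) {
    g <- gt[gt$frame == f, ]; p <- pred[pred$frame == f, ]
    if (nrow(g) == 0L || nrow(p) == 0L) next
    for (i in seq_len(nrow(g))) for (j in seq_len(nrow(p))) {
      v <- oracle_iou(as.numeric(g[i, c("left", "top", "width", "height")]),
                      as.numeric(p[j, c("left", "top", "width", "height")]))
      if (v >= thresh) {
        ov[match(g$id[i], gids), match(p$id[j], pids)] <-
          ov[match(g$id[i], gids), match(p$id[j], pids)] + 1
      }
    }
  }
  # maximise total overlap over injective gt -> pred maps (dummy allowed)
  n <- max(ng, np)
  best <- 0
  for (p in all_perms(n)) {
    tot <- 0
    for (i in seq_len(ng)) {
      j <- p[i]
      if (j <= np) tot <- tot + ov[i, j]
    }
    best <- max(best, tot)
  }
  idtp <- best
  100 * 2 * idtp / (nrow(gt) + nrow(pred))
}

# HOTA by direct definition: global alignment scores, one shared per-frame
# matching (exhaustively maximised), per-alpha thresholding.
oracle_hota <- function(gt, pred) {
  alphas <- seq(0.05, 0.95, by = 0.05)
  if (nrow(pred) == 0L) return(0)
  gids <- sort(unique(gt$id)); pids <- sort(unique(pred$id))
  ng <- length(gids); np <- length(pids)
  frames <- sort(unique(c(gt$frame, pred$frame)))
  pot <- matrix(0, ng, np); gc <- numeric(ng); pc <- numeric(np)
  sims <- list()
  for (f in frames) {
    g <- gt[gt$frame == f, ]; p <- pred[pred$frame == f, ]
    for (id in g$id) gc[match(id, gids)] <- gc[match(id, gids)] + 1
    for (id in p$id) pc[match(id, pids)] <- pc[match(id, pids)] + 1
    if (nrow(g) == 0L || nrow(p) == 0L) next
    sim <- oracle_iou_matrix(g, p)
    sims[[as.character(f)]] <- sim
    for (i in seq_len(nrow(g))) for (j in seq_len(nrow(p))) {
      den <- sum(sim[i, ]) + sum(sim[, j]) - sim[i, j]
      if (den > 1e-12) {
        ii <- match(g$id[i], gids); jj <- match(p$id[j], pids)
        pot[ii, jj] <- pot[ii, jj] + sim[i, j] / den
      }
    }
  }
  align <- pot / (outer(gc, pc, `+`) - pot)
  na <- length(alphas)
  tp <- numeric(na); fn <- numeric(na); fp <- numeric(na)
  mcs <- lapply(seq_len(na), function(a) matrix(0, ng, np))
  for (f in frames) {
    g <- gt[gt$frame == f, ]; p <- pred[pred$frame == f, ]
    if (nrow(g) == 0L || nrow(p) == 0L) {
      for (a in seq_len(na)) {
        fn[a] <- fn[a] + nrow(g); fp[a] <- fp[a] + nrow(p)
      }
      next
    }
    sim <- sims[[as.character(f)]]
    gi <- match(g$id, gids); pj <- match(p$id, pids)
    score <- align[gi, pj, drop = FALSE] * sim
    # exhaustive maximisation of total score
    n <- max(nrow(g), nrow(p))
    best <- NULL; best_s <- -Inf
    for (perm in all_perms(n)) {
      s <- 0; pairs <- matrix(integer(), ncol = 2)
      for (i in seq_len(nrow(g))) {
        j <- perm[i]
        if (j <= nrow(p)) {
          s <- s + score[i, j]
          pairs <- rbind(pairs, c(i, j))
        }
      }
      if (s > best_s + 1e-15) { best_s <- s; best <- pairs }
    }
    msim <- apply(best, 1, function(rc) sim[rc[1], rc[2]])
    for (a in seq_len(na)) {
      keep <- msim >= alphas[a] - 1e-9 & msim > 0
      nm <- sum(keep)
      tp[a] <- tp[a] + nm
      fn[a] <- fn[a] + nrow(g) - nm
      fp[a] <- fp[a] + nrow(p) - nm
      if (nm > 0L) {
        kk <- which(keep)
        for (r in kk) {
          ii <- gi[best[r, 1]]; jj <- pj[best[r, 2]]
          mcs[[a]][ii, jj] <- mcs[[a]][ii, jj] + 1
        }
      }
    }
  }
  hs <- numeric(na)
  for (a in seq_len(na)) {
    deta <- tp[a] / max(tp[a] + fn[a] + fp[a], 1e-12)
    assa <- 0
    if (tp[a] > 0) {
      mc <- mcs[[a]]
      ass <- mc / (outer(gc, pc, `+`) - mc)
      assa <- sum(ass * mc) / tp[a]
    }
    hs[a] <- sqrt(deta * assa)
  }
  100 * mean(hs)
}

# Dense-matrix Kalman oracle (direct evaluation of the filter equations).
oracle_kf_predict <- function(mean, P, Fm, Q) {
  list(mean = as.numeric(Fm %*% mean), P = Fm %*% P %*% t(Fm) + Q)
}

oracle_kf_update <- function(mean, P, z, H, R) {
  S <- H %*% P %*% t(H) + R
  K <- P %*% t(H) %*% solve(S)
  list(mean = as.numeric(mean + K %*% (z - H %*% mean)),
       P = P - K %*% H %*% P)
}

random_psd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) + diag(n) * 0.1
}

# Small randomized tracking fixture: ground truth plus a degraded prediction
# with box jitter, dropouts, one mid-sequence identity relabel and an
# optional false-positive trajectory.
random_metric_fixture <- function(seed, n_cells = 3, n_frames = 12) {
  set.seed(seed)
  cfg <- sim_config(n_frames = n_frames, n_cells = n_cells, seed = seed,
                    division_rate = 0, repulsion = TRUE, diffusion = 1,
                    axis_mean = 14)
  gt <- simulate_tracks(cfg)
  pred <- gt
  pred$left <- pred$left + rnorm(nrow(pred), 0, 1.5)
  pred$top <- pred$top + rnorm(nrow(pred), 0, 1.5)
  pred$conf <- 0.9
  pred <- pred[runif(nrow(pred)) > 0.1, ]
  # relabel one identity from the midpoint on
  ids <- unique(pred$id)
  if (length(ids) > 0) {
    tgt <- ids[1 + (seed %% length(ids))]
    mid <- floor(n_frames / 2)
    sel <- pred$id == tgt & pred$frame > mid
    pred$id[sel] <- max(gt$id) + 1L
  }
  if (seed %% 2 == 0) {
    fpf <- seq_len(min(4, n_frames))
    pred <- rbind(pred, tibble::tibble(
      frame = fpf, id = max(gt$id) + 10L,
      left = 5 + 2 * fpf, top = 5 + 2 * fpf, width = 18, height = 15,
      conf = 0.8, x = -1, y = -1, z = -1))
  }
  pred <- dplyr::arrange(pred, frame, id)
  list(gt = gt, pred = pred)
}

# Curved-motion fixture with a temporary confidence dip on one identity:
# used to probe the low-confidence second association round.
dip_fixture <- function(seed, dip_len = 8, dip_score = 0.3) {
  cfg <- sim_config(n_frames = 45, n_cells = 5, speed = 4, turn_rate = 12,
                    diffusion = 0.3, division_rate = 0, repulsion = TRUE,
                    axis_mean = 12, seed = seed)
  gt <- simulate_tracks(cfg)
  dets <- dplyr::transmute(gt, frame = frame, left = left, top = top,
                           width = width, height = height, score = 0.95)
  target <- unique(gt$id)[1 + (seed %% length(unique(gt$id)))]
  dip_frames <- 18:(18 + dip_len - 1)
  sel <- gt$id == target & gt$frame %in% dip_frames
  dets$score[sel] <- dip_score
  list(gt = gt, dets = dets)
}
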