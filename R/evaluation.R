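# Multi-object tracking evaluation: MOTChallenge CSV readers/writers and the
# CLEAR-MOT, identity (IDF1) and HOTA metric families.
#
# Conventions (MOTChallenge): frames are 1-based; boxes are
# (left, top, width, height) in pixels; ground-truth <-> prediction matching
# uses an IoU threshold (default 0.5); every prediction is evaluated
# regardless of confidence.

#' Read a MOTChallenge CSV file
#'
#' Lines are `frame,id,left,top,width,height,conf[,x,y,z]` with at least 7
#' comma-separated fields. Records are returned ordered by `(frame, id)`.
#'
#' @param path File path.
#' @param validate Check `frame >= 1` and positive box extents (default TRUE).
#' @return A tibble with columns `frame`, `id`, `left`, `top`, `width`,
#'   `height`, `conf`, `x`, `y`, `z`.
#' @export
read_mot <- function(path, validate = TRUE) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_mot())
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 7L)
  if (length(bad) > 0L) {
    stop_input(sprintf("line %d: expected at least 7 comma-separated fields, got %d",
                       bad[1], nf[bad[1]]))
  }
  parse_col <- function(i, default = -1) {
    vapply(parts, function(p) {
      v <- if (length(p) >= i) suppressWarnings(as.numeric(p[i])) else default
      if (is.na(v)) NA_real_ else v
    }, numeric(1))
  }
  m <- lapply(1:10, parse_col)
  if (any(is.na(unlist(m[1:7])))) {
    na_mat <- matrix(vapply(1:7, function(i) is.na(m[[i]]), logical(length(lines))),
                     nrow = length(lines))
    bad <- which(rowSums(na_mat) > 0)
    stop_input(sprintf("line %d: non-numeric field", bad[1]))
  }
  out <- tibble(frame = as.integer(m[[1]]), id = as.integer(m[[2]]),
                left = m[[3]], top = m[[4]], width = m[[5]], height = m[[6]],
                conf = m[[7]], x = m[[8]], y = m[[9]], z = m[[10]])
  out$x[is.na(out$x)] <- -1; out$y[is.na(out$y)] <- -1; out$z[is.na(out$z)] <- -1
  if (validate) {
    if (any(out$frame < 1L)) stop_input("frame indices must be >= 1")
    if (any(out$width <= 0 | out$height <= 0)) {
      stop_input("boxes must have positive width and height")
    }
  }
  dplyr::arrange(out, .data$frame, .data$id)
}

#' Write records as MOTChallenge CSV
#'
#' @param records A tibble with at least `frame`, `id`, `left`, `top`,
#'   `width`, `height`, `conf` (world coordinates default to -1). Values are
#'   written with enough digits for a lossless read-back.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mot <- function(records, path) {
  records <- as_tibble(records)
  for (col in c("x", "y", "z")) if (!col %in% names(records)) records[[col]] <- -1
  num <- function(v) formatC(v, format = "g", digits = 12)
  lines <- sprintf("%d,%d,%s,%s,%s,%s,%s,%s,%s,%s",
                   as.integer(records$frame), as.integer(records$id),
                   num(records$left), num(records$top), num(records$width),
                   num(records$height), num(records$conf), num(records$x),
                   num(records$y), num(records$z))
  writeLines(lines, path)
  invisible(path)
}

check_eval_inputs <- function(gt, pred) {
  gt <- as_tibble(gt); pred <- as_tibble(pred)
  if (nrow(gt) == 0L) stop_input("empty ground truth: metrics are undefined")
  list(gt = gt, pred = pred)
}

frame_split <- function(df, frames) {
  lapply(frames, function(f) df[df$frame == f, , drop = FALSE])
}

# ---- CLEAR-MOT --------------------------------------------------------------

#' CLEAR-MOT accuracy
#'
#' Per-frame ground-truth/prediction correspondence: matches from the
#' previous frame are carried over while still valid at the IoU threshold,
#' then the remainder is matched by optimal assignment on `1 - IoU`. An
#' identity switch is counted when a matched ground-truth object's assigned
#' prediction identity differs from its last assigned identity.
#' `MOTA = 100 * (1 - (FN + FP + IDSW) / |GT|)`.
#'
#' @param gt,pred MOT record tibbles (see [read_mot()]).
#' @param iou_thresh Minimum IoU for a valid correspondence (default 0.5).
#' @return A one-row tibble: `mota`, `fp`, `fn`, `idsw`, `tp`, `n_gt`.
#' @export
clear_mot <- function(gt, pred, iou_thresh = 0.5) {
  inp <- check_eval_inputs(gt, pred)
  gt <- inp$gt; pred <- inp$pred
  frames <- sort(unique(c(gt$frame, pred$frame)))
  gt_f <- frame_split(gt, frames)
  pr_f <- frame_split(pred, frames)
  fp <- 0L; fn <- 0L; idsw <- 0L; tp <- 0L
  prev_pairs <- NULL        # matrix of (gt_id, pred_id) matched in prev frame
  last_match <- list()      # gt_id -> last assigned pred id
  for (k in seq_along(frames)) {
    g <- gt_f[[k]]; p <- pr_f[[k]]
    ng <- nrow(g); np <- nrow(p)
    matched_g <- integer(0); matched_p <- integer(0)
    pairs <- NULL
    if (!is.null(prev_pairs) && ng > 0L && np > 0L) {
      for (r in seq_len(nrow(prev_pairs))) {
        gi <- match(prev_pairs[r, 1], g$id)
        pi <- match(prev_pairs[r, 2], p$id)
        if (!is.na(gi) && !is.na(pi) && !(gi %in% matched_g) && !(pi %in% matched_p)) {
          v <- box_iou(as.numeric(g[gi, c("left", "top", "width", "height")]),
                       as.numeric(p[pi, c("left", "top", "width", "height")]))
          if (v >= iou_thresh) {
            matched_g <- c(matched_g, gi); matched_p <- c(matched_p, pi)
            pairs <- rbind(pairs, c(g$id[gi], p$id[pi]))
          }
        }
      }
    }
    rem_g <- setdiff(seq_len(ng), matched_g)
    rem_p <- setdiff(seq_len(np), matched_p)
    if (length(rem_g) > 0L && length(rem_p) > 0L) {
      sim <- iou_matrix(g[rem_g, ], p[rem_p, ])
      sol <- solve_gated_assignment(1 - sim, gate = 1 - iou_thresh)
      if (nrow(sol) > 0L) {
        for (r in seq_len(nrow(sol))) {
          gi <- rem_g[sol$row[r]]; pi <- rem_p[sol$col[r]]
          if (sim[sol$row[r], sol$col[r]] >= iou_thresh) {
            matched_g <- c(matched_g, gi); matched_p <- c(matched_p, pi)
            pairs <- rbind(pairs, c(g$id[gi], p$id[pi]))
          }
        }
      }
    }
    nm <- length(matched_g)
    tp <- tp + nm
    fn <- fn + (ng - nm)
    fp <- fp + (np - nm)
    if (!is.null(pairs)) {
      for (r in seq_len(nrow(pairs))) {
        key <- as.character(pairs[r, 1])
        prev_id <- last_match[[key]]
        if (!is.null(prev_id) && prev_id != pairs[r, 2]) idsw <- idsw + 1L
        last_match[[key]] <- pairs[r, 2]
      }
    }
    prev_pairs <- pairs
  }
  n_gt <- nrow(gt)
  tibble(mota = 100 * (1 - (fn + fp + idsw) / n_gt),
         fp = fp, fn = fn, idsw = idsw, tp = tp, n_gt = n_gt)
}

# ---- identity metrics -------------------------------------------------------

#' Identity F1 (IDF1)
#'
#' A single bipartite assignment between whole ground-truth and predicted
#' trajectories minimising identity false positives plus false negatives;
#' `IDF1 = 100 * 2 IDTP / (2 IDTP + IDFP + IDFN)`.
#'
#' @inheritParams clear_mot
#' @return A one-row tibble: `idf1`, `idtp`, `idfp`, `idfn`.
#' @export
idf1 <- function(gt, pred, iou_thresh = 0.5) {
  inp <- check_eval_inputs(gt, pred)
  gt <- inp$gt; pred <- inp$pred
  n_gt <- nrow(gt); n_pr <- nrow(pred)
  if (n_pr == 0L) {
    return(tibble(idf1 = 0, idtp = 0L, idfp = 0L, idfn = n_gt))
  }
  gids <- sort(unique(gt$id)); pids <- sort(unique(pred$id))
  overlap <- id_overlap_matrix(gt, pred, gids, pids, iou_thresh)
  gt_len <- vapply(gids, function(i) sum(gt$id == i), numeric(1))
  pr_len <- vapply(pids, function(j) sum(pred$id == j), numeric(1))
  ng <- length(gids); np <- length(pids)
  n <- ng + np
  # pair cost = IDFN + IDFP for that pairing; dummies carry the full lengths
  cost <- matrix(0, n, n)
  cost[seq_len(ng), seq_len(np)] <- outer(gt_len, pr_len, `+`) - 2 * overlap
  cost[seq_len(ng), np + seq_len(ng)] <- 1e9
  for (i in seq_len(ng)) cost[i, np + i] <- gt_len[i]
  cost[ng + seq_len(np), seq_len(np)] <- 1e9
  for (j in seq_len(np)) cost[ng + j, j] <- pr_len[j]
  sol <- as.integer(clue::solve_LSAP(cost))
  idtp <- 0
  for (i in seq_len(ng)) {
    j <- sol[i]
    if (j <= np) idtp <- idtp + overlap[i, j]
  }
  idfn <- n_gt - idtp
  idfp <- n_pr - idtp
  tibble(idf1 = 100 * 2 * idtp / (2 * idtp + idfp + idfn),
         idtp = as.integer(idtp), idfp = as.integer(idfp), idfn = as.integer(idfn))
}

# Frames where trajectories i and j co-occur with IoU >= thresh.
id_overlap_matrix <- function(gt, pred, gids, pids, iou_thresh) {
  overlap <- matrix(0, length(gids), length(pids))
  frames <- sort(unique(c(gt$frame, pred$frame)))
  for (f in frames) {
    g <- gt[gt$frame == f, ]
    p <- pred[pred$frame == f, ]
    if (nrow(g) == 0L || nrow(p) == 0L) next
    sim <- iou_matrix(g, p)
    hit <- which(sim >= iou_thresh, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      gi <- match(g$id[hit[, 1]], gids)
      pj <- match(p$id[hit[, 2]], pids)
      for (r in seq_along(gi)) overlap[gi[r], pj[r]] <- overlap[gi[r], pj[r]] + 1
    }
  }
  overlap
}

# ---- HOTA -------------------------------------------------------------------

#' Higher-order tracking accuracy (HOTA)
#'
#' For each localisation threshold `alpha` in 0.05, 0.10, ..., 0.95,
#' `HOTA_alpha = sqrt(DetA_alpha * AssA_alpha)` with a single per-frame
#' matching that maximises globally-aligned similarity; the final score is
#' the average over the 19 thresholds, as a percentage.
#'
#' @inheritParams clear_mot
#' @return A one-row tibble `hota` plus a `detail` attribute holding the
#'   per-alpha components (`alpha`, `deta`, `assa`, `hota_alpha`).
#' @export
hota <- function(gt, pred) {
  inp <- check_eval_inputs(gt, pred)
  gt <- inp$gt; pred <- inp$pred
  alphas <- seq(0.05, 0.95, by = 0.05)
  na <- length(alphas)
  if (nrow(pred) == 0L) {
    detail <- tibble(alpha = alphas, deta = 0, assa = 0, hota_alpha = 0)
    out <- tibble(hota = 0)
    attr(out, "detail") <- detail
    return(out)
  }
  gids <- sort(unique(gt$id)); pids <- sort(unique(pred$id))
  ng <- length(gids); np <- length(pids)
  frames <- sort(unique(c(gt$frame, pred$frame)))
  gt_f <- frame_split(gt, frames)
  pr_f <- frame_split(pred, frames)
  sims <- vector("list", length(frames))

  # pass 1: global alignment scores
  potential <- matrix(0, ng, np)
  gcount <- numeric(ng); pcount <- numeric(np)
  for (k in seq_along(frames)) {
    g <- gt_f[[k]]; p <- pr_f[[k]]
    gi <- match(g$id, gids); pj <- match(p$id, pids)
    gcount[gi] <- gcount[gi] + 1
    pcount[pj] <- pcount[pj] + 1
    if (nrow(g) == 0L || nrow(p) == 0L) next
    sim <- iou_matrix(g, p)
    sims[[k]] <- sim
    denom <- outer(rowSums(sim), colSums(sim), `+`) - sim
    frac <- sim
    ok <- denom > 1e-12
    frac[ok] <- sim[ok] / denom[ok]
    frac[!ok] <- 0
    potential[gi, pj] <- potential[gi, pj] + frac
  }
  align <- potential / (outer(gcount, pcount, `+`) - potential)

  # pass 2: per-frame matching shared across alphas, thresholded per alpha
  tp <- numeric(na); fn <- numeric(na); fp <- numeric(na)
  match_counts <- lapply(seq_len(na), function(i) matrix(0, ng, np))
  for (k in seq_along(frames)) {
    g <- gt_f[[k]]; p <- pr_f[[k]]
    gi <- match(g$id, gids); pj <- match(p$id, pids)
    sim <- sims[[k]]
    if (nrow(g) > 0L && nrow(p) > 0L) {
      score <- align[gi, pj, drop = FALSE] * sim
      sol <- solve_gated_assignment(max(score) + 1e-9 - score, gate = Inf)
      msim <- sim[cbind(sol$row, sol$col)]
      for (a in seq_len(na)) {
        keep <- msim >= alphas[a] - 1e-9 & msim > 0
        nm <- sum(keep)
        tp[a] <- tp[a] + nm
        fn[a] <- fn[a] + nrow(g) - nm
        fp[a] <- fp[a] + nrow(p) - nm
        if (nm > 0L) {
          mc <- match_counts[[a]]
          idx <- cbind(gi[sol$row[keep]], pj[sol$col[keep]])
          mc[idx] <- mc[idx] + 1
          match_counts[[a]] <- mc
        }
      }
    } else {
      for (a in seq_len(na)) {
        fn[a] <- fn[a] + nrow(g)
        fp[a] <- fp[a] + nrow(p)
      }
    }
  }
  deta <- numeric(na); assa <- numeric(na)
  for (a in seq_len(na)) {
    deta[a] <- tp[a] / max(tp[a] + fn[a] + fp[a], 1e-12)
    if (tp[a] > 0) {
      mc <- match_counts[[a]]
      ass <- mc / (outer(gcount, pcount, `+`) - mc)
      assa[a] <- sum(ass * mc) / tp[a]
    }
  }
  hota_a <- sqrt(deta * assa)
  detail <- tibble(alpha = alphas, deta = 100 * deta, assa = 100 * assa,
                   hota_alpha = 100 * hota_a)
  out <- tibble(hota = 100 * mean(hota_a))
  attr(out, "detail") <- detail
  out
}

# ---- combined report --------------------------------------------------------

#' Evaluate tracking output against ground truth
#'
#' Computes the CLEAR-MOT, identity and HOTA families in one pass.
#'
#' @inheritParams clear_mot
#' @return A `cellmot_metrics` object; use [tidy()] for a long metric table,
#'   [glance()] for a one-row summary, and [autoplot()] for the per-alpha
#'   HOTA decomposition.
#' @export
evaluate_tracking <- function(gt, pred, iou_thresh = 0.5) {
  cm <- clear_mot(gt, pred, iou_thresh)
  idm <- idf1(gt, pred, iou_thresh)
  hm <- hota(gt, pred)
  structure(list(clear = cm, identity = idm, hota = hm,
                 hota_detail = attr(hm, "detail"), iou_thresh = iou_thresh),
            class = "cellmot_metrics")
}

#' @export
print.cellmot_metrics <- function(x, ...) {
  cat(sprintf("MOTA %.2f%%  HOTA %.2f%%  IDF1 %.2f%%  IDSW %d  (FP %d, FN %d, GT %d)\n",
              x$clear$mota, x$hota$hota, x$identity$idf1, x$clear$idsw,
              x$clear$fp, x$clear$fn, x$clear$n_gt))
  invisible(x)
}

#' @method tidy cellmot_metrics
#' @export
tidy.cellmot_metrics <- function(x, ...) {
  tibble(metric = c("MOTA", "HOTA", "IDF1", "IDSW", "FP", "FN", "TP", "IDTP"),
         value = c(x$clear$mota, x$hota$hota, x$identity$idf1,
                   x$clear$idsw, x$clear$fp, x$clear$fn, x$clear$tp,
                   x$identity$idtp))
}

#' @method glance cellmot_metrics
#' @export
glance.cellmot_metrics <- function(x, ...) {
  tibble(mota = x$clear$mota, hota = x$hota$hota, idf1 = x$identity$idf1,
         idsw = x$clear$idsw, fp = x$clear$fp, fn = x$clear$fn,
         tp = x$clear$tp, n_gt = x$clear$n_gt)
}

#' @method autoplot cellmot_metrics
#' @export
autoplot.cellmot_metrics <- function(object, ...) {
  d <- tidyr::pivot_longer(object$hota_detail, -"alpha",
                           names_to = "component", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$alpha, y = .data$value,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "localisation threshold α", y = "score (%)",
                  colour = NULL,
                  title = "HOTA decomposition across localisation thresholds") +
    ggplot2::theme_minimal()
}
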