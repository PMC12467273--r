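# BoT-SORT-style multi-object tracker: constant-velocity Kalman filtering on
# (cx, cy, w, h) boxes, two-round confidence-gated IoU association with
# optimal linear assignment, and tracklet lifecycle management.

#' Tracker configuration
#'
#' Defaults follow the confidence-gated two-round association scheme:
#' detections with score >= `tau_high` enter the first association round,
#' those in `[tau_low, tau_high)` the second; unmatched first-round
#' detections with score >= `tau_init` seed new tracks. `match_threshold` is
#' an IoU-distance cost gate (reject a pair when `1 - IoU > match_threshold`)
#' applied to both rounds.
#'
#' @param tau_high High-score gate (default 0.5).
#' @param tau_low Low-score gate (default 0.1).
#' @param tau_init New-track confidence threshold (default 0.6).
#' @param match_threshold IoU-distance cost gate (default 0.8).
#' @param lost_buffer Frames a lost track is retained before permanent
#'   removal (default 30).
#' @param motion_compensation `"off"`, `"translation"` or `"affine"`.
#' @param two_rounds Set `FALSE` to disable the low-score second round
#'   (ablation switch).
#' @param fuse_score Optionally multiply first-round IoU similarity by the
#'   detection score (off by default).
#' @return A `cellmot_tracker_config` list.
#' @export
tracker_config <- function(tau_high = 0.5, tau_low = 0.1, tau_init = 0.6,
                           match_threshold = 0.8, lost_buffer = 30L,
                           motion_compensation = c("off", "translation", "affine"),
                           two_rounds = TRUE, fuse_score = FALSE) {
  tau_high <- check_prob(tau_high, "tau_high")
  tau_low <- check_prob(tau_low, "tau_low")
  if (tau_low >= tau_high) stop_config("tau_low must be < tau_high")
  structure(list(
    tau_high = tau_high, tau_low = tau_low,
    tau_init = check_prob(tau_init, "tau_init"),
    match_threshold = check_prob(match_threshold, "match_threshold"),
    lost_buffer = check_count(lost_buffer, "lost_buffer", min = 0L),
    motion_compensation = match.arg(motion_compensation),
    two_rounds = isTRUE(two_rounds), fuse_score = isTRUE(fuse_score)
  ), class = "cellmot_tracker_config")
}

#' Constant-velocity Kalman model for bounding-box tracking
#'
#' State is the 8-vector `(cx, cy, w, h, vx, vy, vw, vh)` (pixels and
#' pixels/frame). The transition matrix advances positions and sizes by their
#' velocities over a unit time step; the observation matrix selects
#' `(cx, cy, w, h)`. Process and measurement noise are diagonal with standard
#' deviations proportional to the current box width/height.
#'
#' @param dt Time step in frames (default 1).
#' @param std_weight_position Position/size noise proportionality constant
#'   (default 1/20).
#' @param std_weight_velocity Velocity noise proportionality constant
#'   (default 1/160).
#' @return A `cellmot_kalman_model` with elements `F`, `H` and the noise
#'   weights.
#' @export
kalman_model <- function(dt = 1, std_weight_position = 1 / 20,
                         std_weight_velocity = 1 / 160) {
  F <- diag(8)
  for (i in 1:4) F[i, i + 4] <- dt
  H <- cbind(diag(4), matrix(0, 4, 4))
  structure(list(F = F, H = H, sp = std_weight_position,
                 sv = std_weight_velocity),
            class = "cellmot_kalman_model")
}

process_noise <- function(model, w, h) {
  std <- c(model$sp * w, model$sp * h, model$sp * w, model$sp * h,
           model$sv * w, model$sv * h, model$sv * w, model$sv * h)
  diag(std^2)
}

measurement_noise <- function(model, w, h) {
  std <- c(model$sp * w, model$sp * h, model$sp * w, model$sp * h)
  diag(std^2)
}

kf_state <- function(mean, cov) {
  structure(list(mean = as.numeric(mean), cov = cov), class = "cm_kf_state")
}

check_kf_state <- function(state) {
  if (!is.numeric(state$mean) || length(state$mean) != 8L ||
      !all(is.finite(state$mean))) {
    stop_input("Kalman state mean must be a finite 8-vector")
  }
  P <- state$cov
  if (!is.matrix(P) || any(dim(P) != 8L) || !all(is.finite(P))) {
    stop_input("Kalman covariance must be a finite 8x8 matrix")
  }
  if (max(abs(P - t(P))) > 1e-8) stop_input("Kalman covariance must be symmetric")
  if (min(eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values) < -1e-9) {
    stop_input("Kalman covariance must be positive semi-definite")
  }
  invisible(state)
}

#' Initialise a Kalman state from a measurement
#'
#' @param z Measurement 4-vector `(cx, cy, w, h)`.
#' @param model A [kalman_model()].
#' @return A `cm_kf_state` with zero initial velocity and a diagonal
#'   covariance scaled to the box size.
#' @export
kf_init <- function(z, model = kalman_model()) {
  z <- as.numeric(z)
  w <- z[3]; h <- z[4]
  std <- c(2 * model$sp * w, 2 * model$sp * h, 2 * model$sp * w, 2 * model$sp * h,
           10 * model$sv * w, 10 * model$sv * h, 10 * model$sv * w, 10 * model$sv * h)
  kf_state(c(z, 0, 0, 0, 0), diag(std^2))
}

#' Kalman prediction step
#'
#' `mean <- F mean`; `cov <- F P F' + Q`, exactly.
#'
#' @param state A `cm_kf_state` (see [kf_init()]).
#' @param model A [kalman_model()].
#' @param Q Optional explicit process-noise matrix; by default diagonal with
#'   standard deviations proportional to the state's current width/height.
#' @return The predicted `cm_kf_state`.
#' @export
kf_predict <- function(state, model = kalman_model(), Q = NULL) {
  check_kf_state(state)
  if (is.null(Q)) Q <- process_noise(model, state$mean[3], state$mean[4])
  mean <- as.numeric(model$F %*% state$mean)
  cov <- model$F %*% state$cov %*% t(model$F) + Q
  kf_state(mean, (cov + t(cov)) / 2)
}

#' Kalman update step
#'
#' Gain `K = P H' (H P H' + R)^-1`; `mean <- mean + K (z - H mean)`;
#' `cov <- P - K H P`, exactly. Width and height are clamped positive after
#' the update.
#'
#' @param state The predicted `cm_kf_state`.
#' @param z Measurement 4-vector `(cx, cy, w, h)`.
#' @param model A [kalman_model()].
#' @param R Optional explicit measurement-noise matrix; by default diagonal,
#'   proportional to the state's current width/height.
#' @return The posterior `cm_kf_state`.
#' @export
kf_update <- function(state, z, model = kalman_model(), R = NULL) {
  check_kf_state(state)
  z <- as.numeric(z)
  if (length(z) != 4L || !all(is.finite(z))) {
    stop_input("measurement must be a finite 4-vector (cx, cy, w, h)")
  }
  if (is.null(R)) R <- measurement_noise(model, state$mean[3], state$mean[4])
  H <- model$H
  P <- state$cov
  S <- H %*% P %*% t(H) + R
  K <- tryCatch(t(solve(S, H %*% P)),
                error = function(e) {
                  stop_numeric(paste0("innovation covariance is singular: ",
                                      conditionMessage(e)))
                })
  mean <- state$mean + as.numeric(K %*% (z - H %*% state$mean))
  cov <- P - K %*% H %*% P
  mean[3] <- max(mean[3], 1e-3)
  mean[4] <- max(mean[4], 1e-3)
  kf_state(mean, (cov + t(cov)) / 2)
}

# ---- boxes ------------------------------------------------------------------

#' Intersection over union of two boxes
#'
#' Boxes are `(left, top, width, height)`. Degenerate boxes yield 0.
#'
#' @param a,b Numeric length-4 vectors.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  if (a[3] <= 0 || a[4] <= 0 || b[3] <= 0 || b[4] <= 0) return(0)
  ix <- min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1])
  iy <- min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

#' Pairwise IoU matrix
#'
#' @param A,B Data frames (or matrices) with columns/order
#'   `left, top, width, height`.
#' @return A `nrow(A) x nrow(B)` matrix of IoU values.
#' @export
iou_matrix <- function(A, B) {
  A <- as.matrix(as.data.frame(A)[, c("left", "top", "width", "height")])
  B <- as.matrix(as.data.frame(B)[, c("left", "top", "width", "height")])
  na <- nrow(A); nb <- nrow(B)
  out <- matrix(0, na, nb)
  if (na == 0L || nb == 0L) return(out)
  ax2 <- A[, 1] + A[, 3]; ay2 <- A[, 2] + A[, 4]
  bx2 <- B[, 1] + B[, 3]; by2 <- B[, 2] + B[, 4]
  for (i in seq_len(na)) {
    ix <- pmin(ax2[i], bx2) - pmax(A[i, 1], B[, 1])
    iy <- pmin(ay2[i], by2) - pmax(A[i, 2], B[, 2])
    inter <- pmax(ix, 0) * pmax(iy, 0)
    union <- A[i, 3] * A[i, 4] + B[, 3] * B[, 4] - inter
    ok <- A[i, 3] > 0 & A[i, 4] > 0 & B[, 3] > 0 & B[, 4] > 0 & union > 0
    out[i, ok] <- inter[ok] / union[ok]
  }
  out
}

state_box <- function(mean) {
  c(mean[1] - mean[3] / 2, mean[2] - mean[4] / 2, mean[3], mean[4])
}

# ---- association ------------------------------------------------------------

#' Two-round confidence-gated IoU association
#'
#' Detections are split at the configured confidence gates into high-score
#' (`score >= tau_high`) and low-score (`tau_low <= score < tau_high`) sets.
#' Round 1 solves an optimal linear assignment on `1 - IoU` cost between all
#' tracks and the high-score set; pairs whose cost exceeds the match gate are
#' rejected. Round 2 repeats the procedure between the remaining tracks and
#' the low-score set.
#'
#' @param track_boxes A tibble of predicted track boxes with columns `left`,
#'   `top`, `width`, `height` (one row per track, in track order).
#' @param detections A tibble with columns `left`, `top`, `width`, `height`,
#'   `score`.
#' @param cfg A [tracker_config()].
#' @return A list with `matches` (tibble `track`, `det`, `round`, `iou` of
#'   row indices into the inputs), `unmatched_tracks`, `unmatched_high`,
#'   `unmatched_low` (integer row indices).
#' @export
associate <- function(track_boxes, detections, cfg = tracker_config()) {
  track_boxes <- as_tibble(track_boxes)
  detections <- as_tibble(detections)
  nt <- nrow(track_boxes)
  hi_idx <- which(detections$score >= cfg$tau_high)
  lo_idx <- which(detections$score >= cfg$tau_low & detections$score < cfg$tau_high)

  match_round <- function(trk_rows, det_rows, round) {
    if (length(trk_rows) == 0L || length(det_rows) == 0L) {
      return(tibble(track = integer(), det = integer(), round = integer(),
                    iou = numeric()))
    }
    sim <- iou_matrix(track_boxes[trk_rows, ], detections[det_rows, ])
    if (round == 1L && cfg$fuse_score) {
      sim <- sim * matrix(detections$score[det_rows], nrow(sim), ncol(sim),
                          byrow = TRUE)
    }
    sol <- solve_gated_assignment(1 - sim, gate = cfg$match_threshold)
    tibble(track = trk_rows[sol$row], det = det_rows[sol$col],
           round = rep(round, nrow(sol)),
           iou = sim[cbind(sol$row, sol$col)])
  }

  m1 <- match_round(seq_len(nt), hi_idx, 1L)
  remaining <- setdiff(seq_len(nt), m1$track)
  m2 <- if (cfg$two_rounds) match_round(remaining, lo_idx, 2L) else {
    tibble(track = integer(), det = integer(), round = integer(), iou = numeric())
  }
  matches <- dplyr::bind_rows(m1, m2)
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(nt), matches$track),
       unmatched_high = setdiff(hi_idx, matches$det),
       unmatched_low = setdiff(lo_idx, matches$det))
}

# ---- tracklet management ----------------------------------------------------

new_track <- function(id, det, model, frame) {
  z <- c(det$left + det$width / 2, det$top + det$height / 2, det$width, det$height)
  cls <- if ("class_id" %in% names(det)) det$class_id else 0L
  list(id = id, state = kf_init(z, model), status = "active",
       frames_since_update = 0L, class_id = cls,
       score = det$score, start_frame = frame)
}

#' Apply lifecycle rules after an association round
#'
#' Matched tracks are updated through the Kalman filter and marked active;
#' unmatched first-round detections at or above the initialisation threshold
#' become new tracks with fresh, never-reused identities; unmatched
#' second-round detections are discarded; unmatched tracks are marked lost
#' and removed permanently once lost longer than the buffer.
#'
#' @param tracks A list of track objects carrying predicted states.
#' @param assoc The result of [associate()] for this frame.
#' @param detections The frame's detection tibble (the one passed to
#'   [associate()]).
#' @param cfg A [tracker_config()].
#' @param model A [kalman_model()].
#' @param next_id Next fresh identity (integer).
#' @param frame Current frame index.
#' @return A list with `tracks` (updated list, removed tracks dropped),
#'   `records` (tibble of output rows for this frame) and `next_id`.
#' @export
manage_tracklets <- function(tracks, assoc, detections, cfg, model, next_id,
                             frame) {
  records <- list()
  if (nrow(assoc$matches) > 0L) {
    for (k in seq_len(nrow(assoc$matches))) {
      ti <- assoc$matches$track[k]
      di <- assoc$matches$det[k]
      det <- detections[di, ]
      z <- c(det$left + det$width / 2, det$top + det$height / 2,
             det$width, det$height)
      tr <- tracks[[ti]]
      tr$state <- kf_update(tr$state, z, model)
      tr$status <- "active"
      tr$frames_since_update <- 0L
      tr$score <- det$score
      tracks[[ti]] <- tr
      b <- state_box(tr$state$mean)
      records[[length(records) + 1L]] <- tibble(
        frame = frame, id = tr$id, left = b[1], top = b[2], width = b[3],
        height = b[4], conf = det$score)
    }
  }
  for (ti in assoc$unmatched_tracks) {
    tr <- tracks[[ti]]
    tr$status <- "lost"
    tr$frames_since_update <- tr$frames_since_update + 1L
    tracks[[ti]] <- tr
  }
  for (di in assoc$unmatched_high) {
    det <- detections[di, ]
    if (det$score >= cfg$tau_init) {
      tr <- new_track(next_id, det, model, frame)
      next_id <- next_id + 1L
      tracks[[length(tracks) + 1L]] <- tr
      records[[length(records) + 1L]] <- tibble(
        frame = frame, id = tr$id, left = det$left, top = det$top,
        width = det$width, height = det$height, conf = det$score)
    }
  }
  # unmatched second-round detections are discarded by omission
  keep <- vapply(tracks, function(tr) tr$frames_since_update <= cfg$lost_buffer,
                 logical(1))
  list(tracks = tracks[keep], records = dplyr::bind_rows(records),
       next_id = next_id)
}

# ---- full sequence ----------------------------------------------------------

empty_mot <- function() {
  tibble(frame = integer(), id = integer(), left = numeric(), top = numeric(),
         width = numeric(), height = numeric(), conf = numeric(),
         x = numeric(), y = numeric(), z = numeric())
}

#' Track a detection sequence
#'
#' Per frame: predict all live tracks, optionally compensate global frame
#' motion, run the two-round association, then update states and manage
#' lifecycles. Emits one output row per active track per frame. Fully
#' deterministic given inputs and configuration.
#'
#' @param detections A tibble with columns `frame` (1-based, non-decreasing),
#'   `left`, `top`, `width`, `height`, `score` and optionally `class_id`.
#' @param cfg A [tracker_config()].
#' @param frames Optional list of frame matrices (index = frame number) for
#'   camera-motion compensation.
#' @param model A [kalman_model()].
#' @return A tibble in MOTChallenge layout: `frame`, `id`, `left`, `top`,
#'   `width`, `height`, `conf`, `x`, `y`, `z` (world coordinates unused, -1),
#'   ordered by frame then identity.
#' @export
track_sequence <- function(detections, cfg = tracker_config(), frames = NULL,
                           model = kalman_model()) {
  detections <- as_tibble(detections)
  if (nrow(detections) == 0L) return(empty_mot())
  needed <- c("frame", "left", "top", "width", "height", "score")
  if (!all(needed %in% names(detections))) {
    stop_input("detections need columns frame/left/top/width/height/score")
  }
  if (is.unsorted(detections$frame)) {
    stop_input("detections must be ordered by frame (out-of-order frames)")
  }
  tracks <- list()
  next_id <- 1L
  out <- list()
  frame_range <- seq(min(detections$frame), max(detections$frame))
  for (f in frame_range) {
    dets_f <- detections[detections$frame == f, ]
    tracks <- lapply(tracks, function(tr) {
      tr$state <- kf_predict(tr$state, model)
      tr
    })
    if (cfg$motion_compensation != "off" && !is.null(frames) && f > 1 &&
        f <= length(frames) && !is.null(frames[[f - 1]]) && !is.null(frames[[f]])) {
      tracks <- compensate_motion(tracks, frames[[f - 1]], frames[[f]], cfg)
    }
    if (length(tracks) > 0L) {
      tb <- dplyr::bind_rows(lapply(tracks, function(tr) {
        b <- state_box(tr$state$mean)
        tibble(left = b[1], top = b[2], width = b[3], height = b[4])
      }))
    } else {
      tb <- tibble(left = numeric(), top = numeric(), width = numeric(),
                   height = numeric())
    }
    assoc <- associate(tb, dets_f, cfg)
    step <- manage_tracklets(tracks, assoc, dets_f, cfg, model, next_id, f)
    tracks <- step$tracks
    next_id <- step$next_id
    if (nrow(step$records) > 0L) out[[length(out) + 1L]] <- step$records
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) return(empty_mot())
  res$x <- -1; res$y <- -1; res$z <- -1
  dplyr::arrange(res, .data$frame, .data$id)
}
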