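# Seeded generator of synthetic cell sequences emulating small deformable
# cells in low-contrast microscopy video: ground-truth trajectories with
# division and boundary exit, detector-style corruption, and optional
# rendered grayscale frames.
#
# All randomness is drawn from counter-based streams keyed by
# (seed, component, cell id, frame), so toggling one component (e.g. turning
# corruption on) never shifts the draws of another, and output is
# byte-identical across runs for a fixed seed.

S_MOTION <- 1L; S_DEFORM <- 2L; S_DIVIDE <- 3L; S_ENTRY <- 4L
S_INIT <- 5L; S_MISS <- 6L; S_JITTER <- 7L; S_CONF <- 8L; S_FP <- 9L
S_RENDER <- 10L

#' Synthetic cell-sequence configuration
#'
#' Defaults emulate low-resolution time-lapse microscopy: a 400 x 320 pixel
#' field at 30 frames/s with many small deformable cells that divide, deform
#' and leave the field.
#'
#' @param width,height Frame size in pixels (default 400 x 320).
#' @param n_frames Number of frames (default 100).
#' @param fps Frame rate, carried as sequence metadata (default 30).
#' @param n_cells Initial cell count (default 10).
#' @param drift Per-frame deterministic drift `(dx, dy)` in pixels shared by
#'   all cells (default none).
#' @param speed Initial directed speed in pixels/frame (default 1), random
#'   heading per cell.
#' @param turn_rate Persistent heading change in degrees/frame (default 0);
#'   non-zero values give curved trajectories.
#' @param diffusion Random-walk standard deviation in pixels/frame
#'   (default 1.5).
#' @param axis_mean,axis_sd Mean and spread of cell semi-axes in pixels
#'   (default 12 and 2).
#' @param deformation Standard deviation of the per-frame log-axis
#'   fluctuation (default 0.02): slowly varying cell shape.
#' @param division_rate Per-cell per-frame division probability (default
#'   0.001).
#' @param entry_rate Expected new cells per frame entering the field
#'   (default 0).
#' @param repulsion If TRUE, overlapping cells are pushed apart each frame,
#'   keeping a no-occlusion regime for exact-recovery tests (default FALSE).
#' @param parent_keeps_id If TRUE a dividing cell keeps its identity and
#'   spawns one child; the default replaces the parent with two new
#'   identities (the identity-safe convention).
#' @param contrast,bg_level,bg_noise Rendering parameters of
#'   [render_frames()]: blob contrast over background level with additive
#'   texture noise.
#' @param seed Root seed; fixes every stream.
#' @return A `cellmot_sim_config` list.
#' @export
sim_config <- function(width = 400L, height = 320L, n_frames = 100L, fps = 30L,
                       n_cells = 10L, drift = c(0, 0), speed = 1, turn_rate = 0,
                       diffusion = 1.5, axis_mean = 12, axis_sd = 2,
                       deformation = 0.02, division_rate = 0.001,
                       entry_rate = 0, repulsion = FALSE,
                       parent_keeps_id = FALSE, contrast = 0.35,
                       bg_level = 0.25, bg_noise = 0.04, seed = 1L) {
  check_prob(division_rate, "division_rate")
  if (diffusion < 0 || axis_sd < 0 || deformation < 0 || entry_rate < 0) {
    stop_input("noise parameters must be non-negative")
  }
  structure(list(
    width = check_count(width, "width"), height = check_count(height, "height"),
    n_frames = check_count(n_frames, "n_frames"), fps = check_count(fps, "fps"),
    n_cells = check_count(n_cells, "n_cells", min = 0L),
    drift = as.numeric(drift), speed = as.numeric(speed),
    turn_rate = as.numeric(turn_rate), diffusion = as.numeric(diffusion),
    axis_mean = as.numeric(axis_mean), axis_sd = as.numeric(axis_sd),
    deformation = as.numeric(deformation),
    division_rate = as.numeric(division_rate),
    entry_rate = as.numeric(entry_rate), repulsion = isTRUE(repulsion),
    parent_keeps_id = isTRUE(parent_keeps_id),
    contrast = as.numeric(contrast), bg_level = as.numeric(bg_level),
    bg_noise = as.numeric(bg_noise), seed = check_count(seed, "seed", min = 0L)
  ), class = "cellmot_sim_config")
}

#' Detector-corruption configuration
#'
#' Emulates an imperfect detector: missed detections, localisation jitter,
#' confidence noise and low-confidence false positives.
#'
#' @param miss_rate Per-box drop probability (default 0.1).
#' @param fp_rate Expected false positives per frame (Poisson, default 0.5).
#' @param jitter_sd Box-coordinate jitter standard deviation in pixels
#'   (default 1).
#' @param conf_true_mean,conf_true_sd Truncated-normal confidence model for
#'   true detections (default 0.85, 0.08, truncated to `[0, 1]`).
#' @param conf_false_mean,conf_false_sd Confidence model for false positives
#'   (default 0.3, 0.1).
#' @param seed Stream seed (independent of the simulation seed).
#' @return A `cellmot_corruption_config` list.
#' @export
corruption_config <- function(miss_rate = 0.1, fp_rate = 0.5, jitter_sd = 1,
                              conf_true_mean = 0.85, conf_true_sd = 0.08,
                              conf_false_mean = 0.3, conf_false_sd = 0.1,
                              seed = 1L) {
  check_prob(miss_rate, "miss_rate")
  if (fp_rate < 0 || jitter_sd < 0) stop_input("rates must be non-negative")
  structure(list(miss_rate = miss_rate, fp_rate = fp_rate, jitter_sd = jitter_sd,
                 conf_true_mean = conf_true_mean, conf_true_sd = conf_true_sd,
                 conf_false_mean = conf_false_mean, conf_false_sd = conf_false_sd,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "cellmot_corruption_config")
}

cell_init <- function(id, cfg, frame) {
  margin <- 2 * cfg$axis_mean
  u <- ch_unif(cfg$seed, S_INIT, id, frame, 1:6)
  a <- max(3, cfg$axis_mean + cfg$axis_sd * ch_norm(cfg$seed, S_INIT, id, frame, 7))
  b <- max(3, cfg$axis_mean + cfg$axis_sd * ch_norm(cfg$seed, S_INIT, id, frame, 8))
  heading <- 2 * pi * u[3]
  list(id = id,
       x = margin + u[1] * (cfg$width - 2 * margin),
       y = margin + u[2] * (cfg$height - 2 * margin),
       heading = heading, a = a, b = b)
}

cell_box <- function(cell) {
  c(left = cell$x - cell$a, top = cell$y - cell$b,
    width = 2 * cell$a, height = 2 * cell$b)
}

fully_outside <- function(cell, cfg) {
  b <- cell_box(cell)
  b[1] + b[3] < 0 || b[2] + b[4] < 0 || b[1] > cfg$width || b[2] > cfg$height
}

#' Simulate ground-truth cell trajectories
#'
#' Each cell is the axis-aligned bounding box of an ellipse whose centre
#' follows a drift + persistent-heading + diffusion walk and whose axes
#' fluctuate slowly (deformation). A division replaces the parent identity
#' with two fresh identities (configurable); cells whose box leaves the
#' field terminate. Identities are globally unique and each identity's frame
#' set is one contiguous interval.
#'
#' @param cfg A [sim_config()].
#' @return A ground-truth tibble in MOTChallenge layout (`conf = 1`).
#' @export
simulate_tracks <- function(cfg = sim_config()) {
  if (!inherits(cfg, "cellmot_sim_config")) stop_config("`cfg` must be a sim_config()")
  cells <- lapply(seq_len(cfg$n_cells), function(i) cell_init(i, cfg, 0L))
  next_id <- cfg$n_cells + 1L
  rows <- vector("list", cfg$n_frames)
  for (f in seq_len(cfg$n_frames)) {
    # motion
    cells <- lapply(cells, function(cl) {
      cl$heading <- cl$heading + cfg$turn_rate * pi / 180
      step_x <- cfg$drift[1] + cfg$speed * cos(cl$heading) +
        cfg$diffusion * ch_norm(cfg$seed, S_MOTION, cl$id, f, 1)
      step_y <- cfg$drift[2] + cfg$speed * sin(cl$heading) +
        cfg$diffusion * ch_norm(cfg$seed, S_MOTION, cl$id, f, 2)
      cl$x <- cl$x + step_x
      cl$y <- cl$y + step_y
      cl$a <- max(3, cl$a * exp(cfg$deformation * ch_norm(cfg$seed, S_DEFORM, cl$id, f, 1)))
      cl$b <- max(3, cl$b * exp(cfg$deformation * ch_norm(cfg$seed, S_DEFORM, cl$id, f, 2)))
      cl
    })
    # division
    if (cfg$division_rate > 0 && length(cells) > 0L) {
      out <- list()
      for (cl in cells) {
        if (ch_unif(cfg$seed, S_DIVIDE, cl$id, f) < cfg$division_rate) {
          ang <- 2 * pi * ch_unif(cfg$seed, S_DIVIDE, cl$id, f, 1)
          off <- cl$a / 2
          mk_child <- function(id, sgn) {
            ch <- cl
            ch$id <- id
            ch$x <- cl$x + sgn * off * cos(ang)
            ch$y <- cl$y + sgn * off * sin(ang)
            ch$a <- max(3, cl$a / sqrt(2))
            ch$b <- max(3, cl$b / sqrt(2))
            ch
          }
          if (cfg$parent_keeps_id) {
            out[[length(out) + 1L]] <- mk_child(cl$id, -1)
            out[[length(out) + 1L]] <- mk_child(next_id, 1)
            next_id <- next_id + 1L
          } else {
            out[[length(out) + 1L]] <- mk_child(next_id, -1)
            out[[length(out) + 1L]] <- mk_child(next_id + 1L, 1)
            next_id <- next_id + 2L
          }
        } else {
          out[[length(out) + 1L]] <- cl
        }
      }
      cells <- out
    }
    # entries
    if (cfg$entry_rate > 0) {
      n_new <- qpois(ch_unif(cfg$seed, S_ENTRY, 0L, f), cfg$entry_rate)
      for (i in seq_len(n_new)) {
        cells[[length(cells) + 1L]] <- cell_init(next_id, cfg, f)
        next_id <- next_id + 1L
      }
    }
    # repulsion (single relaxation pass, deterministic order)
    if (cfg$repulsion && length(cells) > 1L) {
      for (i in seq_len(length(cells) - 1L)) {
        for (j in (i + 1L):length(cells)) {
          ci <- cells[[i]]; cj <- cells[[j]]
          dx <- cj$x - ci$x; dy <- cj$y - ci$y
          dist <- sqrt(dx^2 + dy^2)
          min_d <- max(ci$a, ci$b) + max(cj$a, cj$b)
          if (dist < min_d) {
            if (dist < 1e-6) { dx <- 1; dy <- 0; dist <- 1 }
            push <- (min_d - dist) / 2
            cells[[i]]$x <- ci$x - push * dx / dist
            cells[[i]]$y <- ci$y - push * dy / dist
            cells[[j]]$x <- cj$x + push * dx / dist
            cells[[j]]$y <- cj$y + push * dy / dist
          }
        }
      }
    }
    # exits
    cells <- Filter(function(cl) !fully_outside(cl, cfg), cells)
    if (length(cells) > 0L) {
      rows[[f]] <- dplyr::bind_rows(lapply(cells, function(cl) {
        b <- cell_box(cl)
        tibble(frame = f, id = cl$id, left = round(b[[1]], 2),
               top = round(b[[2]], 2), width = round(b[[3]], 2),
               height = round(b[[4]], 2), conf = 1, x = -1, y = -1, z = -1)
      }))
    }
  }
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0L) return(empty_mot())
  dplyr::arrange(res, .data$frame, .data$id)
}

#' Corrupt ground truth into detector-style detections
#'
#' Each ground-truth box is independently dropped at the miss rate; survivors
#' are jittered and scored from the true-detection confidence model; Poisson
#' false boxes with low-confidence scores are added per frame.
#'
#' @param gt A ground-truth tibble from [simulate_tracks()] (or [read_mot()]).
#' @param ccfg A [corruption_config()].
#' @param sim_cfg The [sim_config()] used for the ground truth (frame
#'   geometry and size prior of false positives); defaults to the package
#'   default.
#' @return A detection tibble with columns `frame`, `left`, `top`, `width`,
#'   `height`, `score`, `class_id`.
#' @export
corrupt_detections <- function(gt, ccfg = corruption_config(),
                               sim_cfg = sim_config()) {
  gt <- as_tibble(gt)
  if (nrow(gt) == 0L) {
    return(tibble(frame = integer(), left = numeric(), top = numeric(),
                  width = numeric(), height = numeric(), score = numeric(),
                  class_id = integer()))
  }
  s <- ccfg$seed
  keep <- ch_unif(s, S_MISS, gt$id, gt$frame) >= ccfg$miss_rate
  kept <- gt[keep, ]
  n <- nrow(kept)
  if (n > 0L) {
    jit <- function(k) ccfg$jitter_sd * ch_norm(s, S_JITTER, kept$id, kept$frame, k)
    det <- tibble(
      frame = kept$frame,
      left = kept$left + jit(1), top = kept$top + jit(2),
      width = pmax(kept$width + jit(3), 1),
      height = pmax(kept$height + jit(4), 1),
      score = ch_truncnorm(s, S_CONF, kept$id, kept$frame,
                           ccfg$conf_true_mean, ccfg$conf_true_sd),
      class_id = 0L)
  } else {
    det <- tibble(frame = integer(), left = numeric(), top = numeric(),
                  width = numeric(), height = numeric(), score = numeric(),
                  class_id = integer())
  }
  if (ccfg$fp_rate > 0) {
    fps <- list()
    for (f in sort(unique(gt$frame))) {
      n_fp <- qpois(ch_unif(s, S_FP, 0L, f), ccfg$fp_rate)
      if (n_fp > 0L) {
        k <- seq_len(n_fp)
        w <- pmax(2 * (sim_cfg$axis_mean + sim_cfg$axis_sd *
                         ch_norm(s, S_FP, k, f, 3)), 4)
        h <- pmax(2 * (sim_cfg$axis_mean + sim_cfg$axis_sd *
                         ch_norm(s, S_FP, k, f, 4)), 4)
        fps[[length(fps) + 1L]] <- tibble(
          frame = f,
          left = ch_unif(s, S_FP, k, f, 1) * (sim_cfg$width - w),
          top = ch_unif(s, S_FP, k, f, 2) * (sim_cfg$height - h),
          width = w, height = h,
          score = ch_truncnorm(s, S_FP, k + 1000L, f, ccfg$conf_false_mean,
                               ccfg$conf_false_sd),
          class_id = 0L)
      }
    }
    det <- dplyr::bind_rows(det, dplyr::bind_rows(fps))
  }
  det <- dplyr::arrange(det, .data$frame, .data$left)
  det$left <- round(det$left, 2); det$top <- round(det$top, 2)
  det$width <- round(det$width, 2); det$height <- round(det$height, 2)
  det$score <- round(det$score, 4)
  det
}

#' Render grayscale frames for a ground-truth sequence
#'
#' Textured background noise plus smooth elliptical intensity blobs with
#' Gaussian edges at the ground-truth locations; deterministic per seed.
#'
#' @param gt A ground-truth tibble.
#' @param cfg The [sim_config()] (frame geometry, contrast, noise level).
#' @param frames_idx Frames to render (default: all frames present in `gt`).
#' @return A named list of `height x width` matrices in `[0, 1]`.
#' @export
render_frames <- function(gt, cfg = sim_config(), frames_idx = NULL) {
  gt <- as_tibble(gt)
  if (is.null(frames_idx)) frames_idx <- sort(unique(gt$frame))
  h <- cfg$height; w <- cfg$width
  npx <- h * w
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  out <- lapply(frames_idx, function(f) {
    img <- cfg$bg_level +
      cfg$bg_noise * matrix(ch_norm(cfg$seed, S_RENDER, seq_len(npx), f), h, w)
    g <- gt[gt$frame == f, ]
    for (r in seq_len(nrow(g))) {
      cx <- g$left[r] + g$width[r] / 2
      cy <- g$top[r] + g$height[r] / 2
      sx <- g$width[r] / 4
      sy <- g$height[r] / 4
      blob <- cfg$contrast * exp(-0.5 * (((xs - cx) / sx)^2 + ((ys - cy) / sy)^2))
      img <- img + blob
    }
    pmin(pmax(img, 0), 1)
  })
  names(out) <- as.character(frames_idx)
  out
}

#' Plot simulated trajectories
#'
#' @param object A ground-truth tibble from [simulate_tracks()].
#' @param ... Unused.
#' @export
plot_trajectories <- function(object, ...) {
  d <- dplyr::mutate(as_tibble(object),
                     cx = .data$left + .data$width / 2,
                     cy = .data$top + .data$height / 2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cx, y = .data$cy,
                                  group = factor(.data$id),
                                  colour = factor(.data$id))) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = "Simulated cell trajectories") +
    ggplot2::theme_minimal()
}
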