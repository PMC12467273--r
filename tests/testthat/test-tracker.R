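# Kalman filter, IoU association, tracklet lifecycle, motion compensation
# and full-sequence tracking.

test_that("constant-velocity prediction advances the mean and covariance", {
  m <- kalman_model()
  s <- cellmot:::kf_state(c(0, 0, 10, 20, 1, 2, 0, 0), matrix(0, 8, 8))
  p <- kf_predict(s, m, Q = matrix(0, 8, 8))
  expect_equal(p$mean, c(1, 2, 10, 20, 1, 2, 0, 0))
  p2 <- kf_predict(s, m, Q = diag(8))
  expect_equal(p2$cov, diag(8))
})

test_that("prediction and update match the dense-matrix oracle", {
  m <- kalman_model()
  set.seed(101)
  for (i in 1:100) {
    mean <- c(runif(2, 0, 300), runif(2, 5, 60), rnorm(4))
    P <- random_psd(8)
    s <- cellmot:::kf_state(mean, P)
    Q <- cellmot:::process_noise(m, mean[3], mean[4])
    R <- cellmot:::measurement_noise(m, mean[3], mean[4])
    pred <- kf_predict(s, m)
    o <- oracle_kf_predict(mean, P, m$F, Q)
    expect_lt(max(abs(pred$mean - o$mean)) / max(abs(o$mean)), 1e-10)
    expect_lt(max(abs(pred$cov - o$P)) / max(abs(o$P)), 1e-10)
    z <- o$mean[1:4] + rnorm(4)
    upd <- kf_update(pred, z, m)
    Rp <- cellmot:::measurement_noise(m, o$mean[3], o$mean[4])
    ou <- oracle_kf_update(o$mean, o$P, z, m$H, Rp)
    expect_lt(max(abs(upd$mean - ou$mean)) / max(abs(ou$mean)), 1e-10)
    expect_lt(max(abs(upd$cov - (ou$P + t(ou$P)) / 2)) / max(abs(ou$P)), 1e-10)
  }
})

test_that("update leaves the mean unchanged at zero innovation and converges as R -> 0", {
  m <- kalman_model()
  s <- kf_init(c(100, 80, 30, 25), m)
  p <- kf_predict(s, m)
  z0 <- as.numeric(m$H %*% p$mean)
  u <- kf_update(p, z0, m)
  expect_equal(u$mean, p$mean, tolerance = 1e-12)
  z <- c(104, 84, 32, 27)
  u2 <- kf_update(p, z, m, R = diag(4) * 1e-12)
  expect_equal(u2$mean[1:4], z, tolerance = 1e-6)
})

test_that("covariances stay symmetric positive semi-definite through the filter", {
  m <- kalman_model()
  set.seed(102)
  s <- kf_init(c(50, 50, 20, 18), m)
  for (i in 1:50) {
    s <- kf_predict(s, m)
    s <- kf_update(s, s$mean[1:4] + rnorm(4), m)
    P <- s$cov
    expect_lt(max(abs(P - t(P))), 1e-9)
    expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  }
  bad <- cellmot:::kf_state(rep(1, 8), -diag(8))
  expect_error(kf_predict(bad, m), class = "cellmot_input_error")
})

test_that("IoU handles identical, disjoint and partially overlapping boxes", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 2, 2), c(5, 5, 2, 2)), 0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 0, 2, 2)), 1 / 3)
  expect_equal(box_iou(c(0, 0, 0, 2), c(0, 0, 2, 2)), 0)
  A <- tibble::tibble(left = c(0, 10), top = c(0, 10), width = c(2, 4), height = c(2, 4))
  expect_equal(iou_matrix(A, A), matrix(c(1, 0, 0, 1), 2))
})

test_that("two-round association gates by confidence and IoU distance", {
  cfg <- tracker_config()
  trk <- tibble::tibble(left = 0, top = 0, width = 10, height = 10)
  # high-confidence perfect overlap matches in round 1
  d1 <- tibble::tibble(left = 0, top = 0, width = 10, height = 10, score = 0.9)
  a1 <- associate(trk, d1, cfg)
  expect_equal(a1$matches$round, 1L)
  # low-confidence good overlap matches in round 2
  d2 <- tibble::tibble(left = 1, top = 0, width = 10, height = 10, score = 0.3)
  a2 <- associate(trk, d2, cfg)
  expect_equal(a2$matches$round, 2L)
  # empty detections leave all tracks unmatched
  a3 <- associate(trk, d1[0, ], cfg)
  expect_equal(nrow(a3$matches), 0)
  expect_equal(a3$unmatched_tracks, 1L)
  # second round disabled: the low-score detection is ignored
  a4 <- associate(trk, d2, tracker_config(two_rounds = FALSE))
  expect_equal(nrow(a4$matches), 0)
  # cost gate: distant high-confidence detection is rejected
  d5 <- tibble::tibble(left = 9.5, top = 9.5, width = 10, height = 10, score = 0.9)
  a5 <- associate(trk, d5, cfg)
  expect_equal(nrow(a5$matches), 0)
})

test_that("tracklet lifecycle: creation, discard and permanent removal", {
  cfg <- tracker_config(lost_buffer = 2)
  m <- kalman_model()
  # a fresh high-confidence unmatched detection becomes a new track
  det <- tibble::tibble(left = 5, top = 5, width = 10, height = 10,
                        score = 0.7, class_id = 0L)
  assoc <- list(matches = tibble::tibble(track = integer(), det = integer(),
                                         round = integer(), iou = numeric()),
                unmatched_tracks = integer(), unmatched_high = 1L,
                unmatched_low = integer())
  st <- manage_tracklets(list(), assoc, det, cfg, m, next_id = 7L, frame = 1L)
  expect_equal(length(st$tracks), 1)
  expect_equal(st$tracks[[1]]$id, 7L)
  expect_equal(st$next_id, 8L)
  # below the initiation threshold nothing is created
  det$score <- 0.55
  st2 <- manage_tracklets(list(), assoc, det, cfg, m, next_id = 8L, frame = 1L)
  expect_equal(length(st2$tracks), 0)
  # a second-round leftover is discarded
  assoc2 <- list(matches = assoc$matches, unmatched_tracks = integer(),
                 unmatched_high = integer(), unmatched_low = 1L)
  st3 <- manage_tracklets(list(), assoc2, det, cfg, m, next_id = 8L, frame = 1L)
  expect_equal(length(st3$tracks), 0)
  # a track lost beyond the buffer is removed permanently
  tr <- st$tracks[[1]]
  tracks <- list(tr)
  for (k in 1:3) {
    assoc_l <- list(matches = assoc$matches, unmatched_tracks = 1L,
                    unmatched_high = integer(), unmatched_low = integer())
    stk <- manage_tracklets(tracks, assoc_l, det[0, ], cfg, m, 8L, frame = 1L + k)
    tracks <- stk$tracks
  }
  expect_equal(length(tracks), 0)
})

test_that("noiseless constant-velocity input is tracked exactly in the limit", {
  m <- kalman_model()
  v <- c(2, -1)
  s <- cellmot:::kf_state(c(100, 100, 20, 20, v, 0, 0), diag(8) * 1e-4)
  for (f in 1:20) {
    s <- kf_predict(s, m, Q = matrix(0, 8, 8))
    truth <- c(100 + f * v[1], 100 + f * v[2], 20, 20)
    expect_equal(s$mean[1:4], truth, tolerance = 1e-9)
    s <- kf_update(s, truth, m, R = diag(4) * 1e-12)
    expect_equal(s$mean[1:4], truth, tolerance = 1e-9)
  }
})

test_that("motion compensation recovers pure translation and respects modes", {
  cfg_t <- tracker_config(motion_compensation = "translation")
  cfg_off <- tracker_config(motion_compensation = "off")
  sim <- sim_config(n_frames = 1, n_cells = 6, seed = 11)
  img <- render_frames(simulate_tracks(sim), sim)[[1]]
  shift <- function(mm, ty, tx) {
    n <- nrow(mm); k <- ncol(mm)
    mm[((seq_len(n) - 1 - ty) %% n) + 1, ((seq_len(k) - 1 - tx) %% k) + 1]
  }
  cur <- shift(img, -3, 5)
  tr <- list(list(id = 1L, state = kf_init(c(100, 90, 20, 20)), status = "active",
                  frames_since_update = 0L, class_id = 0L, score = 1,
                  start_frame = 1L))
  out <- compensate_motion(tr, img, cur, cfg_t)
  expect_equal(out[[1]]$state$mean[1:2], c(105, 87))
  # identity frames give the identity transform
  out_id <- compensate_motion(tr, img, img, cfg_t)
  expect_equal(out_id[[1]]$state$mean[1:2], c(100, 90))
  # disabled mode returns tracks unchanged
  expect_identical(compensate_motion(tr, img, cur, cfg_off), tr)
})

test_that("tracking a clean sequence recovers ground truth up to relabeling", {
  cfg <- sim_config(n_frames = 40, n_cells = 6, division_rate = 0,
                    repulsion = TRUE, seed = 21)
  gt <- simulate_tracks(cfg)
  dets <- dplyr::transmute(gt, frame = frame, left = left, top = top,
                           width = width, height = height, score = 1)
  res <- track_sequence(dets)
  ev <- glance(evaluate_tracking(gt, res))
  expect_equal(ev$mota, 100)
  expect_equal(ev$idsw, 0)
  expect_equal(ev$idf1, 100)
  # identities form a bijection onto ground-truth identities
  expect_equal(length(unique(res$id)), length(unique(gt$id)))
})

test_that("empty and malformed detection streams are handled", {
  expect_equal(nrow(track_sequence(tibble::tibble(
    frame = integer(), left = numeric(), top = numeric(), width = numeric(),
    height = numeric(), score = numeric()))), 0)
  bad <- tibble::tibble(frame = c(2L, 1L), left = 0, top = 0, width = 5,
                        height = 5, score = 1)
  expect_error(track_sequence(bad), class = "cellmot_input_error")
})

test_that("tracking output is byte-identical across repeated runs", {
  fx <- dip_fixture(3)
  r1 <- track_sequence(fx$dets)
  r2 <- track_sequence(fx$dets)
  expect_identical(r1, r2)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_mot(r1, p1); write_mot(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("a confidence dip splits the identity only without the second round", {
  fx <- dip_fixture(5)
  full <- track_sequence(fx$dets, tracker_config())
  ablated <- track_sequence(fx$dets, tracker_config(two_rounds = FALSE))
  idsw_full <- clear_mot(fx$gt, full)$idsw
  idsw_ablated <- clear_mot(fx$gt, ablated)$idsw
  expect_equal(idsw_full, 0)
  expect_gt(idsw_ablated, 0)
})

test_that("track identities are unique and never reused", {
  fx <- dip_fixture(9)
  res <- track_sequence(fx$dets)
  # each identity occupies one contiguous frame interval
  for (id in unique(res$id)) {
    fr <- sort(res$frame[res$id == id])
    expect_true(all(diff(fr) >= 1))
  }
  # identity start frames are ordered by identity number
  starts <- vapply(sort(unique(res$id)),
                   function(id) min(res$frame[res$id == id]), numeric(1))
  expect_true(all(diff(starts) >= 0))
})
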