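# MOT record IO and the CLEAR / identity / HOTA metric families.

test_that("MOT CSV files round-trip losslessly with stable ordering", {
  gt <- simulate_tracks(sim_config(n_frames = 15, n_cells = 5, seed = 31,
                                   division_rate = 0.01))
  path <- withr::local_tempfile(fileext = ".txt")
  write_mot(gt, path)
  back <- read_mot(path)
  expect_equal(back, gt)
})

test_that("single records parse to the documented fields", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines("1,1,100,50,20,20,0.9,-1,-1,-1", path)
  r <- read_mot(path)
  expect_equal(r$frame, 1L)
  expect_equal(r$id, 1L)
  expect_equal(c(r$left, r$top, r$width, r$height), c(100, 50, 20, 20))
  expect_equal(r$conf, 0.9)
})

test_that("malformed lines raise parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1,1,100,50,20,20,0.9", "2,1,100,50,20"), path)
  expect_error(read_mot(path), "line 2")
  writeLines("1,1,abc,50,20,20,0.9", path)
  expect_error(read_mot(path), "line 1")
})

test_that("perfect predictions score 100 on every metric", {
  gt <- simulate_tracks(sim_config(n_frames = 12, n_cells = 4, seed = 32))
  ev <- glance(evaluate_tracking(gt, gt))
  expect_equal(ev$mota, 100)
  expect_equal(ev$idf1, 100)
  expect_equal(ev$hota, 100)
  expect_equal(ev$idsw, 0)
  expect_error(clear_mot(gt[0, ], gt), class = "cellmot_input_error")
})

test_that("the accuracy formula matches hand-counted error components", {
  # 100 ground-truth boxes over 20 frames, 5 cells on a fixed grid
  gt <- tidyr::expand_grid(frame = 1:20, id = 1:5)
  gt <- dplyr::mutate(gt, left = 40 * id, top = 40 * id, width = 20,
                      height = 20, conf = 1, x = -1, y = -1, z = -1)
  pred <- gt
  # 5 missed boxes, 3 spurious boxes, and an identity swap on id 1 at frame 11
  pred <- pred[!(pred$frame %in% 1:5 & pred$id == 2), ]
  extra <- tibble::tibble(frame = 1:3, id = 99L, left = 300, top = 300,
                          width = 20, height = 20, conf = 1, x = -1, y = -1, z = -1)
  pred$id[pred$id == 1 & pred$frame >= 11] <- 50L
  pred <- dplyr::arrange(dplyr::bind_rows(pred, extra), frame, id)
  cm <- clear_mot(gt, pred)
  expect_equal(cm$fn, 5)
  expect_equal(cm$fp, 3)
  expect_equal(cm$idsw, 1)
  expect_equal(cm$mota, 100 * (1 - (5 + 3 + 1) / 100))
})

test_that("identity F1 under a clean mid-sequence split matches the brute-force value", {
  # every trajectory present for 10 frames with perfect boxes, each split in half
  gt <- tidyr::expand_grid(frame = 1:10, id = 1:3)
  gt <- dplyr::mutate(gt, left = 50 * id, top = 50 * id, width = 20,
                      height = 20, conf = 1, x = -1, y = -1, z = -1)
  pred <- dplyr::mutate(gt, id = ifelse(frame > 5, id + 10L, id))
  out <- idf1(gt, pred)
  # the best assignment keeps 5 of 10 frames per identity
  expect_equal(out$idtp, 15L)
  expect_equal(out$idf1, 100 * 2 * 15 / (30 + 30))
  expect_equal(out$idf1, oracle_idf1(gt, pred))
  expect_equal(idf1(gt, pred[0, ])$idf1, 0)
  expect_equal(hota(gt, pred[0, ])$hota, 0)
})

test_that("metrics are invariant to a global relabeling of prediction identities", {
  fx <- random_metric_fixture(7)
  relabel <- fx$pred
  ids <- unique(relabel$id)
  map <- setNames(sample(1000:2000, length(ids)), ids)
  relabel$id <- as.integer(map[as.character(relabel$id)])
  relabel <- dplyr::arrange(relabel, frame, id)
  a <- glance(evaluate_tracking(fx$gt, fx$pred))
  b <- glance(evaluate_tracking(fx$gt, relabel))
  expect_equal(a, b)
})

test_that("metrics agree with the brute-force oracles on random fixtures", {
  for (seed in 1:12) {
    fx <- random_metric_fixture(seed)
    cm <- clear_mot(fx$gt, fx$pred)
    oc <- oracle_clear(fx$gt, fx$pred)
    expect_equal(cm$mota, oc$mota, tolerance = 1e-6)
    expect_equal(cm$idsw, oc$idsw)
    expect_equal(idf1(fx$gt, fx$pred)$idf1, oracle_idf1(fx$gt, fx$pred),
                 tolerance = 1e-6)
    expect_equal(hota(fx$gt, fx$pred)$hota, oracle_hota(fx$gt, fx$pred),
                 tolerance = 1e-6)
  }
})

test_that("metrics degrade monotonically with increasing corruption", {
  cfg <- sim_config(n_frames = 20, n_cells = 6, seed = 33, repulsion = TRUE,
                    division_rate = 0)
  gt <- simulate_tracks(cfg)
  levels <- c(0, 0.1, 0.25)
  med <- vapply(levels, function(mr) {
    scores <- vapply(1:8, function(s) {
      d <- corrupt_detections(gt, corruption_config(miss_rate = mr, fp_rate = mr * 4,
                                                    jitter_sd = mr * 6, seed = s),
                              cfg)
      pred <- dplyr::mutate(d, id = dplyr::row_number(), conf = score)
      clear_mot(gt, pred)$mota
    }, numeric(1))
    stats::median(scores)
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})

test_that("the metric report tidies, summarises and plots", {
  fx <- random_metric_fixture(4)
  ev <- evaluate_tracking(fx$gt, fx$pred)
  td <- tidy(ev)
  expect_true(all(c("MOTA", "HOTA", "IDF1", "IDSW") %in% td$metric))
  gl <- glance(ev)
  expect_true(gl$mota <= 100)
  expect_gte(gl$idsw, 0)
  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
})
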