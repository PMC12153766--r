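test_that("confidence split partitions detections at the thresholds", {
  cfg <- cascade_config(tau_high = 0.6, tau_low = 0.1)
  d <- detections(rbind(c(0, 0, 10, 10), c(20, 0, 10, 10), c(40, 0, 10, 10),
                        c(60, 0, 10, 10)),
                  c(0.9, 0.3, 0.05, 0.6), frame = 1)
  sp <- split_by_confidence(d, cfg)
  expect_equal(sp$high_idx, c(1L, 4L))   # 0.6 goes high: >= convention
  expect_equal(sp$low_idx, 2L)
  expect_equal(sp$discarded_idx, 3L)
  expect_setequal(c(sp$high_idx, sp$low_idx, sp$discarded_idx), 1:4)
  expect_error(cascade_config(tau_high = 0.1, tau_low = 0.6), "tau_low")
})

test_that("stage 1 matches by IoU and equals the permutation oracle", {
  cfg <- cascade_config()
  tb <- rbind(c(0, 0, 20, 20), c(100, 100, 20, 20), c(45, 0, 20, 20))
  d <- detections(rbind(c(2, 2, 20, 20), c(101, 99, 20, 20), c(48, 3, 20, 20)),
                  rep(0.9, 3), frame = 1)
  r <- stage1_iou_match(tb, d, cfg)
  cost <- 1 - iou_matrix(tb, d$boxes)
  expect_equal(r$total_cost, perm_assignment_min(cost), tolerance = 1e-9)
  expect_equal(nrow(r$matches), 3L)
  # all-zero IoU is gated out entirely
  far <- detections(rbind(c(500, 500, 10, 10)), 0.9, frame = 1)
  expect_equal(nrow(stage1_iou_match(tb, far, cfg)$matches), 0L)
})

test_that("stage 2 recovers zero-IoU near-center pairs that stage 1 cannot", {
  cfg <- cascade_config(dist_gate_stage2 = 50)
  tracks <- list(list(box = bbox(0, 0, 10, 10), embedding = NULL),
                 list(box = bbox(400, 400, 10, 10), embedding = NULL))
  # disjoint from track 1 but 12 px away; 500+ px from track 2
  d <- detections(rbind(c(12, 0, 10, 10)), 0.9, frame = 1)
  expect_equal(box_iou(c(0, 0, 10, 10), c(12, 0, 10, 10)), 0)
  r <- run_cascade(tracks, d, cfg)
  expect_equal(nrow(r$matches), 1L)
  expect_equal(unname(r$matches[1, ]), c(1L, 1L, 2L))
  off <- run_cascade(tracks, d, cascade_config(dist_gate_stage2 = 50,
                                               enable_stage2 = FALSE))
  expect_equal(nrow(off$matches), 0L)
  # distances beyond the gate stay unmatched
  rfar <- run_cascade(list(tracks[[2]]), d, cfg)
  expect_equal(nrow(rfar$matches), 0L)
})

test_that("stage 3 fuses IoU with appearance and falls back without embeddings", {
  # two tracks with equal IoU to one low detection; appearance must decide
  tracks <- list(list(box = bbox(0, 0, 20, 20), embedding = c(1, 0)),
                 list(box = bbox(8, 0, 20, 20), embedding = c(0, 1)))
  d <- detections(rbind(c(4, 0, 20, 20)), 0.3, rbind(c(0, 1)), frame = 1)
  expect_equal(box_iou(tracks[[1]]$box, d$boxes[1, ]),
               box_iou(tracks[[2]]$box, d$boxes[1, ]))
  for (lam in c(0, 0.25, 0.5, 0.75, 0.99)) {
    r <- run_cascade(tracks, d, cascade_config(fuse_lambda = lam))
    expect_equal(unname(r$matches[1, "track"]), 2L)
    expect_equal(unname(r$matches[1, "stage"]), 3L)
  }
  # fuse_lambda = 1 degenerates to pure IoU (embedding ignored)
  r1 <- stage3_fused_match(rbind(c(0, 0, 20, 20)), list(c(1, 0)), d,
                           cascade_config(fuse_lambda = 1))
  riou <- solve_assignment(1 - iou_matrix(rbind(c(0, 0, 20, 20)), d$boxes),
                           gate = cascade_config()$fused_gate_stage3)
  expect_equal(r1$matches, riou$matches)
  # detection without embedding: cost falls back to pure IoU distance
  d_noemb <- detections(rbind(c(4, 0, 20, 20)), 0.3, frame = 1)
  r2 <- stage3_fused_match(rbind(c(0, 0, 20, 20)), list(c(1, 0)), d_noemb,
                           cascade_config(fuse_lambda = 0.5))
  expect_equal(nrow(r2$matches), 1L)
})

test_that("cascade output partitions tracks and detections", {
  set.seed(41)
  cfg <- cascade_config()
  for (k in 1:20) {
    n_tr <- sample(0:5, 1); n_d <- sample(0:7, 1)
    tracks <- lapply(seq_len(n_tr), function(i)
      list(box = random_box(), embedding = rnorm(4)))
    d <- detections(
      if (n_d) do.call(rbind, lapply(seq_len(n_d), function(i) random_box()))
      else matrix(numeric(0), ncol = 4),
      runif(n_d), if (n_d) matrix(rnorm(n_d * 4), n_d), frame = 1)
    r <- run_cascade(tracks, d, cfg)
    expect_setequal(c(r$matches[, "track"], r$unmatched_tracks), seq_len(n_tr))
    expect_false(anyDuplicated(r$matches[, "det"]) > 0)
    expect_length(intersect(r$matches[, "det"], r$unmatched_high), 0)
    expect_length(intersect(r$matches[, "det"], r$discarded), 0)
  }
})

test_that("admitting more low detections never hurts track matching", {
  set.seed(42)
  for (k in 1:15) {
    n_tr <- sample(2:5, 1); n_d <- sample(3:8, 1)
    tracks <- lapply(seq_len(n_tr), function(i)
      list(box = random_box(), embedding = rnorm(4)))
    d <- detections(do.call(rbind, lapply(seq_len(n_d), function(i) random_box())),
                    runif(n_d, 0.05, 0.95), matrix(rnorm(n_d * 4), n_d),
                    frame = 1)
    hi <- run_cascade(tracks, d, cascade_config(tau_low = 0.3))
    lo <- run_cascade(tracks, d, cascade_config(tau_low = 0.05))
    expect_lte(length(lo$unmatched_tracks), length(hi$unmatched_tracks))
  }
})

test_that("a low-confidence dip during contact is held only via stage 3", {
  stream <- make_bounce_stream()
  gt <- stream_to_gt(stream)
  on <- run_sequence(stream, tracker_config())
  off <- run_sequence(stream, tracker_config(
    cascade = cascade_config(enable_stage3 = FALSE)))
  expect_equal(clear_match(gt, on)$totals$IDSW, 0L)
  expect_gte(clear_match(gt, off)$totals$IDSW, 1L)
})
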