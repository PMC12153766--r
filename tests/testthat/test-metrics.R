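make_gt_two <- function(n_frames = 10) {
  rbind(data.frame(frame = 1:n_frames, id = 1L, left = 0, top = 0,
                   width = 10, height = 10),
        data.frame(frame = 1:n_frames, id = 2L, left = 200, top = 0,
                   width = 10, height = 10))
}

test_that("perfect hypotheses produce a clean event log and perfect scores", {
  gt <- make_gt_two()
  hyp <- cbind(gt, conf = 1)
  log <- clear_match(gt, hyp)
  expect_equal(log$totals$FP, 0L)
  expect_equal(log$totals$FN, 0L)
  expect_equal(log$totals$IDSW, 0L)
  expect_equal(log$frames$c, rep(2L, 10))
  expect_equal(mota(log), 1)
  expect_equal(motp(log), 1)
  expect_equal(idf1(gt, hyp)$idf1, 1)
  h <- hota(gt, hyp)
  expect_equal(h$hota, 1)
  expect_true(all(h$components$DetA == 1 & h$components$AssA == 1))
  expect_equal(mt_ml(log), list(MT = 2L, ML = 0L))
})

test_that("empty hypotheses count every ground-truth box as missed", {
  gt <- make_gt_two()
  hyp <- gt[0, ]
  log <- clear_match(gt, hyp)
  expect_equal(log$totals$FN, 20L)
  expect_equal(log$totals$FP, 0L)
  expect_equal(mota(log), 0)          # 1 - 20/20
  expect_equal(idf1(gt, hyp)$idf1, 0)
  expect_equal(hota(gt, hyp)$hota, 0)
  expect_equal(mt_ml(log), list(MT = 0L, ML = 2L))
  expect_error(motp(log), "undefined")
})

test_that("a mid-sequence identity swap logs exactly two switches", {
  gt <- make_gt_two(10)
  # hypothesis ids swap locations from frame 6 on
  hyp <- gt
  hyp$id <- ifelse(gt$frame <= 5, gt$id, 3L - gt$id)
  log <- clear_match(gt, hyp)
  expect_equal(log$totals$IDSW, 2L)
  expect_equal(log$frames$idsw, c(rep(0L, 5), 2L, rep(0L, 4)))
  expect_equal(log$totals$FP, 0L)
  expect_equal(log$totals$FN, 0L)
  expect_equal(mota(log), 1 - 2 / 20)
})

test_that("mota evaluates its closed form, including negative values", {
  # 10 single-object frames; one miss, one stray box
  gt <- data.frame(frame = 1:10, id = 1L, left = 0, top = 0,
                   width = 10, height = 10)
  hyp <- gt[-1, ]                      # frame 1 missed -> FN = 1
  hyp <- rbind(hyp, data.frame(frame = 2, id = 9L, left = 500, top = 500,
                               width = 10, height = 10))   # FP = 1
  log <- clear_match(gt, hyp)
  expect_equal(log$totals$FN, 1L)
  expect_equal(log$totals$FP, 1L)
  expect_equal(mota(log), 0.8)
  # all misses plus 2 strays per frame: 1 - (5 + 10)/5 = -2
  gt5 <- data.frame(frame = 1:5, id = 1L, left = 0, top = 0,
                    width = 10, height = 10)
  stray <- do.call(rbind, lapply(1:5, function(f)
    data.frame(frame = f, id = c(8L, 9L), left = c(400, 600), top = 400,
               width = 10, height = 10)))
  expect_equal(mota(clear_match(gt5, stray)), -2)
  expect_error(mota(clear_match(gt5[0, ], stray[0, ])), "undefined")
})

test_that("motp averages matched-pair overlap (or distance on request)", {
  gt <- data.frame(frame = 1:2, id = 1L, left = 0, top = 0,
                   width = 10, height = 10)
  hyp <- data.frame(frame = 1:2, id = 1L, left = c(2.5, 0),
                    top = c(0, 10 / 9), width = 10, height = 10)
  log <- clear_match(gt, hyp)
  expect_equal(log$matches$iou, c(0.6, 0.8), tolerance = 1e-12)
  expect_equal(motp(log), 0.7, tolerance = 1e-12)
  expect_equal(motp(log, as_distance = TRUE), (2.5 + 10 / 9) / 2,
               tolerance = 1e-12)
})

test_that("idf1 uses the best global identity bijection", {
  # one object tracked as two 5-frame fragments with perfect boxes
  gt <- data.frame(frame = 1:10, id = 1L, left = 0, top = 0,
                   width = 10, height = 10)
  hyp <- gt
  hyp$id <- ifelse(gt$frame <= 5, 7L, 8L)
  r <- idf1(gt, hyp)
  expect_equal(r$IDTP, 5L)
  expect_equal(r$IDFP, 5L)
  expect_equal(r$IDFN, 5L)
  expect_equal(r$idf1, 0.5)
})

test_that("identity metrics are invariant to hypothesis relabeling", {
  cfg <- small_noisy_config(3)
  sc <- simulate_scenario(cfg)
  hyp <- run_sequence(sc$stream, tracker_config())
  relabeled <- hyp
  relabeled$id <- hyp$id * 31L + 1000L
  expect_equal(idf1(sc$gt, hyp)$idf1, idf1(sc$gt, relabeled)$idf1)
  expect_equal(hota(sc$gt, hyp)$hota, hota(sc$gt, relabeled)$hota)
})

test_that("per-frame counts conserve boxes", {
  cfg <- small_noisy_config(4)
  sc <- simulate_scenario(cfg)
  hyp <- run_sequence(sc$stream, tracker_config())
  log <- clear_match(sc$gt, hyp)
  for (k in seq_len(nrow(log$frames))) {
    f <- log$frames$frame[k]
    expect_equal(log$frames$c[k] + log$frames$fn[k], sum(sc$gt$frame == f))
    expect_equal(log$frames$c[k] + log$frames$fp[k], sum(hyp$frame == f))
  }
})

test_that("duplicate ids within a frame are rejected", {
  gt <- data.frame(frame = c(1, 1), id = c(1L, 1L), left = c(0, 50),
                   top = 0, width = 10, height = 10)
  expect_error(clear_match(gt, gt), "duplicate")
})

test_that("the suite agrees with the independent reference evaluator", {
  for (seed in c(101, 102, 103)) {
    sc <- simulate_scenario(small_noisy_config(seed))
    hyp <- run_sequence(sc$stream, tracker_config())
    ours <- evaluate_tracking(sc$gt, hyp)
    ref <- run_mot_oracle(sc$gt, hyp)
    expect_equal(ours$MOTA, ref$MOTA, tolerance = 1e-6)
    expect_equal(ours$MOTP, ref$MOTP, tolerance = 1e-6)
    expect_equal(ours$IDF1, ref$IDF1, tolerance = 1e-6)
    expect_equal(ours$HOTA, ref$HOTA, tolerance = 1e-6)
    expect_equal(ours$IDS, ref$IDS)
    expect_equal(ours$FP, ref$FP)
    expect_equal(ours$FN, ref$FN)
    expect_equal(ours$MT, ref$MT)
    expect_equal(ours$ML, ref$ML)
  }
})

test_that("hota without the square root gives the plain product", {
  gt <- make_gt_two(6)
  hyp <- gt
  hyp$id <- ifelse(gt$frame <= 3, gt$id, 3L - gt$id)   # imperfect association
  a <- hota(gt, hyp, use_sqrt = TRUE)
  b <- hota(gt, hyp, use_sqrt = FALSE)
  expect_equal(b$components$score,
               a$components$DetA * a$components$AssA, tolerance = 1e-12)
  expect_lte(b$hota, a$hota)
})

test_that("metric deltas recover ablation arithmetic", {
  tab <- data.frame(method = c("a", "b"), MOTA = c(60, 70), IDS = c(100, 25))
  d <- metric_deltas(tab, "a", "b")
  expect_equal(d$mota_gain, 10)
  expect_equal(d$ids_reduction_pct, 75)
  expect_error(metric_deltas(tab, "a", "zzz"), "exactly one")
})
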