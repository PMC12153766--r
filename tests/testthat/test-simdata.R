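test_that("ground truth is deterministic, bounded and complete", {
  cfg <- scenario_config(n_identities = 6, n_frames = 80, seed = 9)
  a <- simulate_ground_truth(cfg)
  b <- simulate_ground_truth(cfg)
  expect_identical(a, b)
  gt <- a$gt
  expect_equal(nrow(gt), 6 * 80)
  expect_equal(as.integer(table(gt$frame)), rep(6L, 80))   # nobody leaves the pen
  expect_true(all(gt$left >= 0 & gt$left + gt$width <= cfg$pen_width))
  expect_true(all(gt$top >= 0 & gt$top + gt$height <= cfg$pen_height))
  expect_true(all(gt$visibility >= 0 & gt$visibility <= 1))
  # per-identity box size is fixed over time
  expect_true(all(tapply(gt$width, gt$id, function(w) diff(range(w))) == 0))
})

test_that("zero speed freezes every trajectory", {
  cfg <- scenario_config(n_identities = 4, n_frames = 30, speed_scale = 0,
                         occlusion_rate = 0, seed = 2)
  gt <- simulate_ground_truth(cfg)$gt
  expect_true(all(tapply(gt$left, gt$id, function(x) diff(range(x))) == 0))
  expect_true(all(tapply(gt$top, gt$id, function(x) diff(range(x))) == 0))
})

test_that("occlusion episodes land near the configured rate over 20 seeds", {
  pr <- day_night_presets(1)
  for (nm in names(pr)) {
    base <- pr[[nm]]
    rates <- vapply(1:20, function(s) {
      cfg <- base
      cfg$seed <- s
      count_occlusion_episodes(simulate_ground_truth(cfg))$per_100_frames
    }, numeric(1))
    expect_gte(mean(rates), 0.5 * base$occlusion_rate)
    expect_lte(mean(rates), 1.5 * base$occlusion_rate)
  }
})

test_that("a noiseless detector reproduces ground truth boxes", {
  cfg <- zero_noise_config(n_identities = 4, n_frames = 40, seed = 5)
  gts <- simulate_ground_truth(cfg)
  stream <- emulate_detector(gts)
  expect_length(stream, 40)
  for (f in seq_len(40)) {
    g <- gts$gt[gts$gt$frame == f, ]
    d <- stream[[f]]
    expect_equal(d$n, nrow(g))
    expect_equal(unname(d$boxes),
                 unname(as.matrix(g[, c("left", "top", "width", "height")])))
    fully_visible <- g$visibility == 1
    expect_equal(d$conf[fully_visible],
                 rep(cfg$confidence_mean_visible, sum(fully_visible)))
    expect_true(all(abs(sqrt(rowSums(d$embeddings^2)) - 1) < 1e-9))
  }
  # certain misses silence the stream entirely
  cfg2 <- scenario_config(detector_miss_base = 1, detector_miss_occluded = 1,
                          fp_rate = 0, n_identities = 4, n_frames = 10, seed = 5)
  stream2 <- emulate_detector(simulate_ground_truth(cfg2), cfg2)
  expect_true(all(vapply(stream2, function(d) d$n == 0L, logical(1))))
})

test_that("empirical miss rate matches detector_miss_base within 2 points", {
  misses <- 0L; total <- 0L
  for (s in 1:10) {
    cfg <- scenario_config(n_identities = 10, n_frames = 100,
                           occlusion_rate = 0, speed_scale = 2,
                           detector_miss_base = 0.3,
                           detector_miss_occluded = 0.3,
                           fp_rate = 0, seed = s)
    gts <- simulate_ground_truth(cfg)
    stream <- emulate_detector(gts, cfg)
    total <- total + nrow(gts$gt)
    misses <- misses + nrow(gts$gt) - sum(vapply(stream, function(d) d$n,
                                                 integer(1)))
  }
  expect_equal(misses / total, 0.3, tolerance = 0.02 / 0.3)
})

test_that("day and night presets encode the intended quality contrast", {
  pr <- day_night_presets(7)
  expect_gt(pr$night$detector_miss_base, pr$day$detector_miss_base)
  expect_gt(pr$night$occlusion_rate, pr$day$occlusion_rate)
  expect_lt(pr$night$confidence_mean_visible, pr$day$confidence_mean_visible)
  expect_s3_class(pr$day, "scenario_config")
  expect_s3_class(pr$night, "scenario_config")
})

test_that("the tracker scores better on day than on night scenes", {
  mota_day <- mota_night <- numeric(10)
  for (s in 1:10) {
    pr <- day_night_presets(s)
    scd <- simulate_scenario(pr$day)
    scn <- simulate_scenario(pr$night)
    mota_day[s] <- mota(clear_match(scd$gt, run_sequence(scd$stream,
                                                         tracker_config())))
    mota_night[s] <- mota(clear_match(scn$gt, run_sequence(scn$stream,
                                                           tracker_config())))
  }
  expect_gt(mean(mota_day), mean(mota_night))
})

test_that("scenario configs validate their invariants", {
  expect_error(scenario_config(n_identities = 1), "n_identities")
  expect_error(scenario_config(detector_miss_base = 0.5,
                               detector_miss_occluded = 0.1),
               "detector_miss_occluded")
  expect_error(scenario_config(embedding_noise_std = 0.5,
                               embedding_noise_occluded_std = 0.1),
               "embedding_noise_occluded_std")
  expect_error(scenario_config(n_identities = 20, pen_width = 200,
                               pen_height = 200), "packing")
})
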