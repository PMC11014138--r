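# Synthetic IMU generator: protocol structure, determinism, the zero-motion
# limit, and the execution-direction discrepancy that the flip augmentation
# is designed to repair.

quiet_profile <- function(noise_sd = 0) {
  subject_profile("p1", gait_frequency_hz = 1.8, noise_sd = noise_sd,
                  phase_offset = 0.3)
}

test_that("zero-motion limit: static posture gives pure gravity and silent gyro", {
  tpl <- activity_template("static", oscillation_amp = 0)
  blk <- synthesize_channels(tpl, quiet_profile(), duration_s = 2, seed = 1)
  expect_equal(nrow(blk$acc), 256L)
  expect_equal(unname(blk$acc[, "x"]), rep(0, 256))
  expect_equal(unname(blk$acc[, "y"]), rep(1, 256)) # gravity, upright
  expect_equal(unname(blk$gyro), matrix(0, 256, 3), ignore_attr = TRUE)
})

test_that("synthesis is deterministic under a fixed seed", {
  tpl <- activity_template("W")
  p <- quiet_profile(noise_sd = 0.05)
  a <- synthesize_channels(tpl, p, 2, seed = 7)
  b <- synthesize_channels(tpl, p, 2, seed = 7)
  d <- synthesize_channels(tpl, p, 2, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$acc, d$acc))

  s1 <- generate_separate_dataset(1, 1, seed = 5)
  s2 <- generate_separate_dataset(1, 1, seed = 5)
  expect_identical(s1$recordings[[1]]$sites, s2$recordings[[1]]$sites)
  expect_identical(s1$annotations, s2$annotations)
})

test_that("turn-direction reversal flips exactly the horizontal mag axes and the yaw rate", {
  p <- quiet_profile(noise_sd = 0)
  ccw <- synthesize_channels(activity_template("TN", direction = +1,
                                               oscillation_amp = 0), p, 2, 1)
  cw <- synthesize_channels(activity_template("TN", direction = -1,
                                              oscillation_amp = 0), p, 2, 1)
  expect_equal(cw$mag[, "x"], -ccw$mag[, "x"])
  expect_equal(cw$mag[, "z"], -ccw$mag[, "z"])
  expect_equal(cw$mag[, "y"], ccw$mag[, "y"])
  expect_equal(cw$gyro[, "y"], -ccw$gyro[, "y"]) # yaw rate sign
  expect_equal(cw$gyro[, c("x", "z")], ccw$gyro[, c("x", "z")])
  expect_equal(cw$acc, ccw$acc) # linear acceleration direction-independent
  expect_gt(max(abs(ccw$mag[, "x"])), 0.5) # the discrepancy is substantial

  # independent oracle: the x-axis hump is the horizontal field resolved
  # through the signed 180-degree heading program, evaluated point by point
  n <- 256; u <- (0:(n - 1)) / (n - 1)
  turn <- 180 * (3 * u^2 - 2 * u^3)
  expect_equal(unname(ccw$mag[, "x"]),
               1.0 * p$amplitude_scale["RP", "mag"] * sin(turn * pi / 180),
               tolerance = 1e-12)
})

test_that("sit-to-stand direction reversal flips the mag x and y axes only", {
  p <- quiet_profile(noise_sd = 0)
  fwd <- synthesize_channels(activity_template("S2S", direction = +1,
                                               oscillation_amp = 0), p, 2, 1)
  rev <- synthesize_channels(activity_template("S2S", direction = -1,
                                               oscillation_amp = 0), p, 2, 1)
  expect_equal(rev$mag[, "x"], -fwd$mag[, "x"])
  expect_equal(rev$mag[, "y"], -fwd$mag[, "y"])
  expect_equal(rev$mag[, "z"], fwd$mag[, "z"])
  expect_equal(rev$acc, fwd$acc)
  expect_equal(rev$gyro, fwd$gyro) # pitch motion identical either way
})

test_that("separate protocol has the documented shape and cohort arithmetic", {
  d <- generate_separate_dataset(1, 1, seed = 3)
  expect_length(d$recordings, 3L) # one per task
  expect_equal(nrow(d$annotations), 5L) # W, TN, W, S2S, LD
  expect_setequal(unique(d$annotations$label), activity_labels())
  wt_ann <- d$annotations[grepl("WT", d$annotations$recording_id), ]
  expect_equal(wt_ann$label, c("W", "TN", "W"))
  expect_true(all(vapply(d$recordings, function(r)
    identical(names(r$sites), sensor_sites()), TRUE)))
  # cohort arithmetic: 3 tasks x subjects x reps
  d2 <- generate_separate_dataset(3, 2, seed = 3)
  expect_length(d2$recordings, 18L)
})

test_that("continuous protocol yields ordered, disjoint, in-bounds circuits", {
  d <- generate_continuous_dataset(2, 2, seed = 9)
  expect_length(d$recordings, 4L)
  for (rid in names(d$recordings)) {
    a <- d$annotations[d$annotations$recording_id == rid, ]
    expect_equal(a$label, c("S2S", "W", "TN", "W", "LD"))
    expect_true(all(a$start_sample[-1] >= a$end_sample[-5]))
    expect_true(all(a$end_sample <= d$recordings[[rid]]$n_samples))
  }
})

test_that("profiles respect the duration ordering that causes class imbalance", {
  for (i in 1:20) {
    p <- draw_subject_profile("s", seed = i)
    expect_gt(p$activity_duration_s[["W"]], p$activity_duration_s[["S2S"]])
  }
  expect_error(subject_profile("x", activity_duration_s =
                                 c(W = 1.5, TN = 2, S2S = 2, LD = 4)),
               "duration")
})

test_that("classes are separable by a nearest-centroid sanity classifier", {
  # raw (unaugmented) windows: flip copies are deliberately bimodal in the
  # magnetometer and would defeat a single-centroid-per-class summary
  wt <- suppressWarnings(assemble(tiny_train(), "RW+RP+LP+S",
                                  augment = FALSE, stats = tiny_stats()))
  feats <- cbind(apply(wt$acc, c(1, 3), mean), apply(wt$gyro, c(1, 3), mean),
                 apply(wt$mag, c(1, 3), mean))
  labs <- as.character(wt$labels)
  half <- seq_len(nrow(feats)) %% 2 == 0
  cent <- sapply(activity_labels(), function(cl)
    colMeans(feats[half & labs == cl, , drop = FALSE]))
  pred <- activity_labels()[apply(feats[!half, ], 1, function(x)
    which.min(colSums((cent - x)^2)))]
  expect_gte(mean(pred == labs[!half]), 0.95)
})
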