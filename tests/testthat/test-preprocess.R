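# Preprocessing chain: normalization, segmentation, resampling, windowing,
# and the two augmentation techniques.

make_rec <- function(chan_x = c(0, 5, 10), site = "RW") {
  n <- length(chan_x)
  blk <- channel_block(cbind(chan_x, seq_len(n), -seq_len(n)),
                       matrix(rnorm(3 * n), n, 3),
                       matrix(rnorm(3 * n), n, 3))
  imu_recording("r", "s", "separate", setNames(list(blk), site))
}

test_that("min-max normalization pins endpoints, zeroes constants, and is idempotent", {
  rec <- make_rec(c(0, 5, 10))
  nr <- normalize(rec)
  expect_equal(unname(nr$sites$RW$acc[, "x"]), c(-1, 0, 1))
  expect_true(nr$sites$RW$normalized)
  # every non-degenerate channel attains exactly -1 and +1
  for (m in imu_modalities()) {
    expect_equal(unname(apply(nr$sites$RW[[m]], 2, min)), rep(-1, 3))
    expect_equal(unname(apply(nr$sites$RW[[m]], 2, max)), rep(1, 3))
  }
  expect_equal(normalize(nr)$sites$RW$acc, nr$sites$RW$acc)

  const <- make_rec(c(-3, -3, -3))
  expect_warning(nc <- normalize(const), "RW_acc_x")
  expect_equal(unname(nc$sites$RW$acc[, "x"]), c(0, 0, 0))
})

test_that("external statistics reproduce a shared affine map", {
  rec <- make_rec(c(2, 3, 4))
  st <- normalization_stats(list(make_rec(c(0, 5, 10))))
  nr <- normalize(rec, stats = st)
  expect_equal(unname(nr$sites$RW$acc[, "x"]), 2 * c(2, 3, 4) / 10 - 1)
})

test_that("extract_segments slices annotated half-open intervals only", {
  set.seed(4)
  n <- 1000
  blk <- channel_block(matrix(rnorm(3 * n), n, 3), matrix(rnorm(3 * n), n, 3),
                       matrix(rnorm(3 * n), n, 3))
  rec <- imu_recording("r", "s", "separate", list(RW = blk))
  ann <- data.frame(recording_id = "r", start_sample = 100L,
                    end_sample = 400L, label = "W", trial_id = "t1")
  segs <- extract_segments(rec, ann)
  expect_length(segs, 1L)
  expect_equal(segs[[1]]$n_samples, 300L)
  expect_equal(segs[[1]]$sites$RW$acc, blk$acc[101:400, ], tolerance = 0)

  expect_length(extract_segments(rec, ann[0, ]), 0L)
  bad <- transform(ann, end_sample = 2000L)
  expect_error(extract_segments(rec, bad), "exceeds")
})

test_that("resampling lands on multiples of 128 and preserves endpoints", {
  seg_of_length <- function(L) {
    ramp <- seq(0, 1, length.out = L)
    blk <- channel_block(cbind(ramp, ramp^2, rev(ramp)),
                         cbind(ramp, ramp, ramp), cbind(ramp, ramp, ramp))
    list(sites = list(RW = blk), label = "W", trial_id = "t", n_samples = L)
  }
  expect_equal(resample_to_window_multiple(seg_of_length(300))$n_samples, 256L)
  expect_equal(resample_to_window_multiple(seg_of_length(64))$n_samples, 128L)
  s256 <- seg_of_length(256)
  expect_identical(resample_to_window_multiple(s256)$sites$RW$acc,
                   s256$sites$RW$acc) # already a multiple: untouched
  for (L in c(130, 200, 500, 1234)) {
    out <- resample_to_window_multiple(seg_of_length(L))
    expect_equal(out$n_samples %% 128L, 0L)
    src <- seg_of_length(L)$sites$RW$acc
    expect_equal(out$sites$RW$acc[1, ], src[1, ])                    # first
    expect_equal(out$sites$RW$acc[out$n_samples, ], src[L, ])        # last
    # a linear ramp must stay exactly linear under linear interpolation
    expect_equal(unname(out$sites$RW$acc[, 1]),
                 seq(0, 1, length.out = out$n_samples), tolerance = 1e-12)
  }
})

test_that("windowing yields Nw = (L-128)/64 + 1 contiguous half-overlapping windows", {
  seg_of_length <- function(L) {
    vals <- seq_len(L) # window content = sample index, for coverage checks
    blk <- channel_block(cbind(vals, vals, vals), cbind(vals, vals, vals),
                         cbind(vals, vals, vals))
    list(sites = list(RW = blk), label = "TN", trial_id = "tr", n_samples = L)
  }
  expect_equal(n_windows(make_windows(seg_of_length(128))), 1L)
  expect_equal(n_windows(make_windows(seg_of_length(256))), 3L)

  wt <- make_windows(seg_of_length(640))
  expect_equal(n_windows(wt), 9L)
  # brute-force enumeration oracle: window i covers samples [64 i, 64 i+128)
  for (i in 0:8) {
    expect_equal(unname(wt$acc[i + 1, , 1]), (64 * i + 1):(64 * i + 128))
  }
  expect_equal(unname(wt$acc[5, 1, 1]), 257) # window 4 starts at sample 256 (0-based)
  expect_true(all(wt$labels == "TN") && all(wt$trial_ids == "tr"))

  for (L in 128L * c(1:6, 10)) {
    expect_equal(n_windows(make_windows(seg_of_length(L))), 2L * L / 128L - 1L)
  }
  expect_error(make_windows(seg_of_length(129)), "multiple")
  expect_error(make_windows(seg_of_length(100)), "shorter")
})

test_that("flip augmentation inverts only the listed mag axes and is an involution", {
  wt <- tiny_train_tensor()
  plain <- suppressWarnings(assemble(tiny_train(), "RW+RP+LP+S",
                                     augment = FALSE, stats = tiny_stats()))
  rep1 <- augment_flip(plain, mode = "replace")
  rep2 <- augment_flip(rep1, mode = "replace")
  expect_equal(rep2$mag, plain$mag)               # involution
  expect_identical(rep1$acc, plain$acc)           # acc untouched
  expect_identical(rep1$gyro, plain$gyro)         # gyro untouched

  tn <- which(as.character(plain$labels) == "TN")
  w <- which(as.character(plain$labels) == "W")
  # mag x (channels 1,4,7,10) and z (3,6,9,12) inverted for TN; y untouched
  expect_equal(rep1$mag[tn, , c(1, 3)], -plain$mag[tn, , c(1, 3)])
  expect_equal(rep1$mag[tn, , 2], plain$mag[tn, , 2])
  expect_equal(rep1$mag[w, , ], plain$mag[w, , ]) # no rule for W

  app <- augment_flip(plain, mode = "append")
  n_rule <- sum(as.character(plain$labels) %in% c("TN", "S2S"))
  expect_equal(n_windows(app), n_windows(plain) + n_rule)
  expect_true(any(grepl("#flip$", app$trial_ids)))

  expect_error(augment_flip(plain, rules = list(TN = c("x", "q"))), "axis")
})

test_that("scale balancing equalizes the class histogram with per-trial factors", {
  plain <- suppressWarnings(assemble(tiny_train(), "RW+RP+LP+S",
                                     augment = FALSE, stats = tiny_stats()))
  counts <- table(plain$labels)
  expect_gt(max(counts), min(counts)) # imbalance present by construction

  bal <- augment_scale_balance(plain, seed = 3)
  expect_true(all(table(bal$labels) == max(counts)))

  # duplicates are elementwise scalings of their source trial windows
  dup_ids <- unique(bal$trial_ids[grepl("#s", bal$trial_ids)])
  src_id <- sub("#s.*$", "", dup_ids[1])
  d_rows <- which(bal$trial_ids == dup_ids[1])
  s_rows <- which(bal$trial_ids == src_id)[seq_along(d_rows)]
  ratio <- bal$acc[d_rows[1], , ] / bal$acc[s_rows[1], , ]
  f <- stats::median(ratio, na.rm = TRUE)
  expect_gte(f, 0.8); expect_lte(f, 1.2)
  expect_equal(bal$acc[d_rows, , ], bal$acc[s_rows, , ] * f, tolerance = 1e-12)
  expect_equal(bal$mag[d_rows, , ], bal$mag[s_rows, , ] * f, tolerance = 1e-12)

  # already balanced input returns unchanged
  expect_identical(augment_scale_balance(bal, seed = 4), bal)
  # determinism
  expect_identical(augment_scale_balance(plain, seed = 3)$acc, bal$acc)
})

test_that("assemble restricts channels per combination and counts windows exactly", {
  pair <- suppressWarnings(assemble(tiny_test(), "RW+LP", augment = FALSE))
  expect_equal(pair$Nc, 6L)
  quad <- tiny_test_tensor()
  expect_equal(quad$Nc, 12L)
  expect_true(all(as.character(quad$labels) %in% activity_labels()))

  # brute-force window count over annotated, resampled segments
  ann <- tiny_test()$annotations
  expected <- sum(vapply(seq_len(nrow(ann)), function(i) {
    L <- ann$end_sample[i] - ann$start_sample[i]
    Lp <- max(128, 128 * round(L / 128))
    2 * Lp / 128 - 1
  }, 1))
  expect_equal(n_windows(quad), expected)
})

test_that("flip augmentation repairs the protocol discrepancy on noiseless data", {
  tr0 <- generate_separate_dataset(1, 1, seed = 2, noise_sd = 0)
  te0 <- generate_continuous_dataset(1, 1, seed = 2, noise_sd = 0)
  st0 <- normalization_stats(tr0$recordings)
  wtr <- suppressWarnings(assemble(tr0, "RW+RP+LP+S", augment = TRUE,
                                   seed = 1, stats = st0))
  wte <- suppressWarnings(assemble(te0, "RW+RP+LP+S", augment = FALSE,
                                   stats = st0))
  for (lab in c("TN", "S2S")) {
    # the flipped copies are the ones that emulate the circuit's direction
    i_tr <- which(as.character(wtr$labels) == lab & grepl("#flip", wtr$trial_ids))
    i_te <- which(as.character(wte$labels) == lab)
    m_tr <- apply(wtr$mag[i_tr, , , drop = FALSE], 3, mean)
    m_te <- apply(wte$mag[i_te, , , drop = FALSE], 3, mean)
    big <- abs(m_te) > 0.1 # axes where the discrepancy is material
    expect_true(all(sign(m_tr[big]) == sign(m_te[big])),
                label = paste("sign agreement for", lab))
  }
})
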