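test_that("drive equations reproduce direct substitution of the weights", {
  cfg <- default_config_cached()
  # area 1: white -> w1 = 10, black -> 0
  expect_identical(area1_drive(c(1, 0, 1), cfg$w1), c(10, 0, 10))
  # area 2 with uniform presynaptic activity: 400 - 750 everywhere
  x1 <- matrix(1, 4L, 4L)
  expect_true(all(area2_drive(x1, cfg$w2e, cfg$w2i) == -350))
  expect_true(all(area2_drive(matrix(0, 4L, 4L), cfg$w2e, cfg$w2i) == 0))
  # 29.78 % active sites: global term -223.35, net on-site +176.65
  n_on <- round(0.2978 * 10000)
  x <- c(rep(1, n_on), rep(0, 10000 - n_on))
  d <- area2_drive(x, cfg$w2e, cfg$w2i)
  expect_equal(unique(d[x == 0]), -750 * 0.2978)
  expect_equal(unique(d[x == 1]), 400 - 750 * 0.2978)
  # area 3: w3 at detections
  det <- matrix(c(0L, 1L, 0L, 0L), 2L, 2L)
  expect_identical(sum(area3_drive(det, cfg$w3)), 500)
  # area 4: mean over N^2 sites, with and without the gain
  x3 <- numeric(76 * 76); x3[1:250] <- 0.5
  expect_equal(area4_drive(x3, cfg$w4, kappa4 = 1), 5 * 125 / 5776)
  expect_equal(area4_drive(x3, cfg$w4, kappa4 = 250), 250 * 5 * 125 / 5776)
  # area 5: read-out against both rows of w5
  x4 <- matrix(0, 2L, 4L); x4[1L, c(2L, 4L)] <- 0.5
  w5 <- default_w5(100, 5)
  expect_equal(area5_drive(x4, w5$w5_1), 100)
  x4b <- matrix(0, 2L, 4L); x4b[2L, c(2L, 4L)] <- 0.5
  expect_equal(area5_drive(x4b, w5$w5_1), 5)
  expect_equal(area5_drive(matrix(0, 2L, 4L), w5$w5_1), 0)
})

test_that("output weight matrices have the printed sparsity and fail for B >= A", {
  w5 <- default_w5(100, 5)
  expect_equal(unname(w5$w5_1), rbind(c(0, 100, 0, 100), c(0, 5, 0, 5)))
  expect_equal(unname(w5$w5_2), rbind(c(100, 0, 100, 0), c(5, 0, 5, 0)))
  expect_identical(sum(w5$w5_1 != 0), 4L)
  expect_identical(sum(w5$w5_2 != 0), 4L)
  # disjoint, exhaustive column support
  sup1 <- which(colSums(w5$w5_1) > 0); sup2 <- which(colSums(w5$w5_2) > 0)
  expect_identical(unname(sort(c(sup1, sup2))), 1:4)
  expect_length(intersect(sup1, sup2), 0L)
  expect_error(default_w5(100, 200), "smaller")
  expect_error(network_config(A = 100, B = 100), "smaller")
})

test_that("channel construction pairs every stimulus with its negative", {
  fx <- fixtures_cached()
  img <- fx$set1$original
  ch <- make_channels(img)
  expect_identical(ch$T1$pixels, img$pixels)
  expect_identical(ch$T2$pixels, 1L - img$pixels)
  # swapping polarity swaps the channels
  ch_rev <- make_channels(contrast_reverse(img))
  expect_identical(ch_rev$T1$pixels, ch$T2$pixels)
  expect_identical(ch_rev$T2$pixels, ch$T1$pixels)
})

test_that("binarize_map thresholds against the saturation level", {
  expect_identical(binarize_map(matrix(0, 2L, 2L), 0.9, 2.5),
                   matrix(0L, 2L, 2L))
  x <- matrix(c(0.1, 2.3, 2.25, 3.0), 2L, 2L)
  expect_identical(binarize_map(x, 0.9, 2.5),
                   matrix(as.integer(x >= 2.25), 2L, 2L))
  expect_identical(binarize_map(matrix(5, 3L, 3L), 0.9, 2.5),
                   matrix(1L, 3L, 3L))
})

test_that("network runs are deterministic and causally ordered", {
  img <- small_stimulus()
  cfg <- short_config()
  run1 <- run_network(img, cfg)
  run2 <- run_network(img, cfg)
  expect_identical(run1$rasters, run2$rasters)
  expect_identical(run1$drive_log, run2$drive_log)
  # area-5 drive stays zero until area 4 has first spiked
  a4_first <- suppressWarnings(min(first_spike_times(run1$rasters$area4),
                                   na.rm = TRUE))
  if (is.finite(a4_first)) {
    pre <- run1$drive_log$I5[seq_len(round(a4_first / cfg$dt)), , drop = FALSE]
    expect_true(all(pre == 0))
  }
  # an all-black stimulus drives only channel F = 2 in area 1
  black <- binary_image(matrix(0L, 16L, 16L), 8L, 4L)
  runb <- run_network(black, short_config(duration = 20))
  expect_identical(sum(lengths(runb$rasters$area1[[1L]]$spikes)), 0L)
  expect_gt(sum(lengths(runb$rasters$area1[[2L]]$spikes)), 0L)
})

test_that("contrast reversal exactly exchanges the two channels", {
  img <- small_stimulus()
  cfg <- short_config()
  run <- run_network(img, cfg)
  run_rev <- run_network(contrast_reverse(img), cfg)
  for (F in 1:2) {
    G <- 3L - F
    expect_identical(run_rev$rasters$area1[[F]]$spikes,
                     run$rasters$area1[[G]]$spikes)
    expect_identical(run_rev$rasters$area2[[F]]$spikes,
                     run$rasters$area2[[G]]$spikes)
    for (j in 1:4)
      expect_identical(run_rev$rasters$area3[[F]][[j]]$spikes,
                       run$rasters$area3[[G]][[j]]$spikes)
  }
})

test_that("mirror reversal leaves the integrated drives exactly invariant", {
  run0 <- member_run("set1", "original")
  runm <- member_run("set1", "mirror")
  # drives agree to float summation order (mirroring permutes the sites
  # inside the spatial means); the spike outputs are bit-identical
  expect_equal(runm$drive_log$I4[, c(2L, 4L, 6L, 8L)],
               run0$drive_log$I4[, c(4L, 2L, 8L, 6L)], tolerance = 1e-9)
  expect_equal(runm$drive_log$I5, run0$drive_log$I5, tolerance = 1e-9)
  expect_identical(spike_counts(runm$rasters$area5),
                   spike_counts(run0$rasters$area5))
  expect_identical(first_spike_times(runm$rasters$area5),
                   first_spike_times(run0$rasters$area5))
})

test_that("area 2 segregates the figure in both channels on the reference stimulus", {
  run <- member_run("set1", "original")
  fig <- figure_mask(run$stimulus)
  for (F in 1:2) {
    spiking <- spike_counts(run$rasters$area2[[F]]) > 0
    expect_gte(dice_coefficient(spiking, as.vector(fig)), 0.9)
  }
})

test_that("initial-voltage jitter is seeded, bounded and reproducible", {
  img <- small_stimulus()
  cfg1 <- network_config(duration = 20, jitter_mv = 1, jitter_seed = 11L)
  r1 <- run_network(img, cfg1)
  r2 <- run_network(img, cfg1)
  expect_identical(r1$rasters, r2$rasters)
  cfg2 <- network_config(duration = 20, jitter_mv = 1, jitter_seed = 12L)
  r3 <- run_network(img, cfg2)
  expect_false(identical(r1$rasters, r3$rasters))
  expect_error(run_network(img, network_config(jitter_mv = 1)), "seed")
})
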