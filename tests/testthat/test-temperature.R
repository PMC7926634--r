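test_that("head temperature is the crop maximum and is monotone", {
  v <- matrix(30, 20, 20)
  v[8, 9] <- 37.2
  box <- bounding_box("head", 4, 4, 14, 14)
  expect_equal(head_temperature(v, box), 37.2)
  expect_equal(head_temperature(matrix(30, 10, 10),
                                bounding_box("head", 0, 0, 10, 10)), 30)
  # raising any pixel cannot lower the result
  v2 <- v; v2[10, 10] <- 36
  expect_gte(head_temperature(v2, box), head_temperature(v, box))
})

test_that("head max under noise follows extreme-value statistics", {
  # synthetic head ellipse, core 36.8, noise sd 0.04: the max over ~1e3
  # noisy plateau pixels sits a couple sigma above the core
  sc <- generate_scene(scene_config(width = 140, height = 110, duration = 1,
                                    fps = 4, noise_sigma = 0.04, seed = 21))
  hb <- sc$truth$boxes[[1]]
  hb <- hb[hb$label == "head", ]
  mx <- head_temperature(sc$sequence$frames[[1]], hb)
  expect_equal(mx, 36.8, tolerance = 0.15)
})

test_that("ambient estimate is the corner ROI mean", {
  v <- matrix(25, 20, 20)
  v[1:5, 1:5] <- 22
  expect_equal(ambient_estimate(v), 22)
  v[1:5, 1:2] <- 21; v[1:5, 3] <- 22; v[1:5, 4:5] <- 23
  expect_equal(ambient_estimate(v), 22)
  # noise sd 0.04 -> estimate sd ~ 0.008 over the 25-pixel ROI
  set.seed(4)
  ests <- vapply(1:400, function(i) {
    v[1:5, 1:5] <- 22 + rnorm(25, sd = 0.04)
    ambient_estimate(v)
  }, numeric(1))
  expect_equal(sd(ests), 0.04 / 5, tolerance = 0.15)
})

make_point_seq <- function(head_series, ambient_series, agg = 4) {
  # one synthetic frame per sample: head pixel block + corner ambient block
  n <- length(head_series)
  frames <- lapply(seq_len(n), function(i) {
    v <- matrix(ambient_series[i], 30, 30)
    v[15:20, 15:20] <- head_series[i]
    thermal_frame(v, timestamp = i - 1, index = i)
  })
  seqq <- thermal_sequence(frames, fps = 1)
  track <- roi_track(lapply(seq_len(n), function(i)
    bounding_box("head", 12, 12, 24, 24)), n)
  list(seq = seqq, track = track,
       cfg = temperature_config(aggregation_frames = agg))
}

test_that("trend: raw deviations and exact ambient cancellation", {
  # three measurement points of one frame each
  s <- make_point_seq(c(36.0, 36.5, 35.8), rep(21, 3), agg = 1)
  tr <- trend(s$seq, s$track, s$cfg)
  expect_equal(tr$deviation_raw, c(0, 0.5, -0.2))
  expect_equal(tr$deviation_corrected, c(0, 0.5, -0.2))

  # common linear drift on head AND ambient cancels exactly
  drift <- seq(0, 1, length.out = 12)
  s2 <- make_point_seq(36 + drift, 21 + drift, agg = 3)
  tr2 <- trend(s2$seq, s2$track, s2$cfg)
  expect_equal(tr2$deviation_corrected, rep(0, 4), tolerance = 1e-12)
  expect_gt(max(tr2$deviation_raw), 0.5)

  # missing points are reported, not interpolated
  s3 <- make_point_seq(c(36, 36.2, 36.4), rep(21, 3), agg = 1)
  s3$track[[2]] <- s3$track[[2]][0, ]
  tr3 <- trend(s3$seq, s3$track, s3$cfg)
  expect_true(tr3$missing[2])
  expect_true(is.na(tr3$deviation_raw[2]))
  expect_equal(tr3$deviation_corrected[3], 0.4, tolerance = 1e-12)
})

test_that("trend is invariant to re-partitioning for constant series", {
  s <- make_point_seq(rep(36.4, 12), rep(21.5, 12), agg = 3)
  tr_a <- trend(s$seq, s$track, temperature_config(aggregation_frames = 3))
  tr_b <- trend(s$seq, s$track, temperature_config(aggregation_frames = 4))
  expect_true(all(tr_a$deviation_corrected == 0))
  expect_true(all(tr_b$deviation_corrected == 0))
  expect_equal(unique(tr_a$head_max), 36.4)
})

test_that("trend recovery on a generated scene with drifting ambient", {
  # +0.8 K/h head trend with +0.5 K/h ambient drift over 2 h of sparse frames
  cfg <- scene_config(width = 100, height = 76, fps = 1 / 30, duration = 7200,
                      ambient_drift = 0.5, noise_sigma = 0.04,
                      head = list(trend = 0.8),
                      chest = list(amplitude = 0), seed = 17)
  sc <- generate_scene(cfg)
  tr <- trend(sc$sequence, sc$truth$boxes,
              temperature_config(aggregation_frames = 10L))
  hours <- (tr$time - tr$time[1]) / 3600
  fit_c <- lm(tr$deviation_corrected ~ hours)
  fit_r <- lm(tr$deviation_raw ~ hours)
  expect_equal(unname(coef(fit_c)[2]), 0.8, tolerance = 0.1)
  # raw trend is biased up by the ambient drift
  expect_gt(unname(coef(fit_r)[2]), 1.0)
})

test_that("trend regression diagnostics", {
  x <- c(35.1, 35.8, 36.2, 36.9, 37.4)
  r <- suppressWarnings(trend_regression(x, x))   # perfect-fit lm warning
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$mse, 0, tolerance = 1e-20)
  expect_equal(r$r_squared, 1)

  r2 <- suppressWarnings(trend_regression(x, x + 1.75))
  expect_equal(r2$slope, 1)
  expect_equal(r2$intercept, 1.75)
  expect_equal(r2$r, 1)

  # known-noise simulation: MSE ~ sigma^2
  set.seed(44)
  est <- runif(200, 34, 38)
  ref <- est + rnorm(200, sd = 0.3)
  r3 <- trend_regression(est, ref)
  expect_equal(r3$mse, 0.09, tolerance = 0.25)
  expect_equal(r3$slope, 1, tolerance = 0.1)

  expect_error(trend_regression(rep(1, 5), 1:5), "zero-variance")
})
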