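test_that("temporal filter: identity, forced means, variance reduction", {
  c4 <- replicate(4, matrix(2.5, 6, 6), simplify = FALSE)
  tf <- temporal_filter(c4)
  expect_equal(tf$prev_avg, matrix(2.5, 6, 6))
  expect_equal(tf$next_avg, matrix(2.5, 6, 6))

  scalars <- lapply(1:4, function(i) matrix(i, 1, 1))
  tf <- temporal_filter(scalars)
  expect_equal(tf$prev_avg[1, 1], 2)
  expect_equal(tf$next_avg[1, 1], 3)

  set.seed(8)
  noise <- replicate(4, matrix(rnorm(1e4, sd = 0.04), 100, 100),
                     simplify = FALSE)
  tf <- temporal_filter(noise)
  expect_equal(var(as.vector(tf$prev_avg)), 0.04^2 / 3, tolerance = 0.1)

  expect_error(temporal_filter(noise[1:3]), "exactly 4")
  expect_error(temporal_filter(c(noise[1:3], list(matrix(0, 2, 2)))),
               "shape mismatch")
})

test_that("bandpass design matches the independent scipy oracle", {
  # frozen from scipy.signal.butter(2, [0.15, 0.44], btype='band', fs=4)
  b_ref <- c(0.03888859392236640, 0, -0.07777718784473280, 0,
             0.03888859392236640)
  a_ref <- c(1, -3.09444587063294, 3.81127045659295, -2.22293486968722,
             0.52545530666502)
  f <- butter_bandpass(0.15, 0.44, 4, 2)
  expect_equal(f$b, b_ref, tolerance = 1e-12)
  expect_equal(f$a, a_ref, tolerance = 1e-12)
})

test_that("bandpass behaviour on signals", {
  cfg <- respiration_config()
  n <- 960; t <- (0:(n - 1)) / 4
  expect_equal(bandpass(rep(0, n), cfg), rep(0, n))

  # in-band sine passes within 3 dB (two passes accounted)
  x <- sin(2 * pi * 0.25 * t)
  y <- bandpass(x, cfg)
  expect_gt(max(abs(y[100:860])), 10^(-3 / 20))

  # unit DC offset: residual mean attenuated by >= 40 dB (finite-length
  # boundary transients keep it from being exactly zero)
  y <- bandpass(rep(1, n) + 0.5 * sin(2 * pi * 0.25 * t), cfg)
  expect_lt(abs(mean(y)), 10^(-40 / 20))

  expect_error(bandpass(rep(0, 10), cfg), "too short")
})

test_that("autocorrelation: normalization, sine peaks, noise bound", {
  set.seed(10)
  x <- rnorm(400)
  ac <- autocorrelation(x)
  expect_equal(ac$r[1], 1)

  t <- (0:959) / 4
  ac <- autocorrelation(sin(2 * pi * t / 5))    # period 5 s = 20 samples
  peaks <- which(diff(sign(diff(ac$r))) == -2)  # interior maxima (lag idx)
  expect_true(any(abs(ac$lag[peaks + 1] - 20) <= 1))
  expect_true(any(abs(ac$lag[peaks + 1] - 40) <= 1))

  # white-noise ACF stays within 3/sqrt(n) in the respiratory search band
  # for >= 95% of seeds (biased estimator under the null)
  n <- 960
  band <- 10:26
  cover <- vapply(1:100, function(s) {
    set.seed(s)
    r <- autocorrelation(rnorm(n))$r
    all(abs(r[band + 1]) < 3 / sqrt(n))
  }, logical(1))
  expect_gte(mean(cover), 0.95)

  expect_true(autocorrelation(rep(1, 100))$undefined)
})

test_that("estimate_rr recovers clean sine rates within 0.5 bpm", {
  cfg <- respiration_config()
  t <- (0:959) / 4
  for (rr in c(15, 20)) {
    x <- sin(2 * pi * rr / 60 * t)
    est <- estimate_rr(autocorrelation(bandpass(x, cfg)), cfg)
    expect_true(est$valid)
    expect_equal(est$rr_bpm, rr, tolerance = 0.5)
    expect_equal(60 / est$peak_lag, est$rr_bpm)
  }
  # 1/3 Hz -> 20 bpm
  x <- sin(2 * pi * t / 3)
  est <- estimate_rr(autocorrelation(bandpass(x, cfg)), cfg)
  expect_equal(est$rr_bpm, 20, tolerance = 0.5)

  # noise-only input falls below the peak floor
  set.seed(3)
  est <- estimate_rr(autocorrelation(bandpass(rnorm(960), cfg)), cfg)
  expect_false(est$valid)
  expect_match(est$exclusion_reason, "peak_floor|no_peak")
})

test_that("chest motion signal carries the breathing frequency and flags", {
  sc <- tiny_scene(seed = 6, duration = 60, rr_bpm = 15)
  sig <- chest_motion_signal(sc$sequence, sc$truth$boxes)
  expect_s3_class(sig, "motion_signal")
  expect_equal(nrow(sig), length(sc$sequence) - 3L)
  expect_true(all(sig$valid))
  # dominant FFT component of the y-signal at 0.25 Hz
  v <- sig$dy - mean(sig$dy)
  sp <- Mod(fft(v))[1:(length(v) %/% 2)]
  freqs <- (seq_along(sp) - 1) * 4 / length(v)
  expect_equal(freqs[which.max(sp)], 0.25, tolerance = 0.02)

  # static chest: signal ~ 0
  sc0 <- tiny_scene(seed = 6, duration = 20, amplitude = 0, noise_sigma = 0)
  sig0 <- chest_motion_signal(sc0$sequence, sc0$truth$boxes)
  expect_lt(sd(sig0$value), 0.05)
})

test_that("detection gaps are bridged or invalidated; overlaps flagged", {
  sc <- tiny_scene(seed = 9, duration = 20)
  tr <- sc$truth$boxes
  # short gap (2 frames): bridged, flagged
  for (i in 30:31) tr[[i]] <- tr[[i]][tr[[i]]$label != "chest", ]
  # long gap (5 frames): invalidated
  for (i in 50:54) tr[[i]] <- tr[[i]][tr[[i]]$label != "chest", ]
  cfg <- respiration_config()
  sig <- chest_motion_signal(sc$sequence, tr, cfg)
  # sample index of buffer centre frame t: i = t - 2
  expect_true(all(sig$detection_gap[c(28, 29)]))
  expect_true(all(sig$valid[c(28, 29)]))
  gap_samples <- 50:54 - 2
  expect_true(any(!sig$valid[gap_samples]))

  # clinician overlapping the chest box
  ch <- scene_config(width = 140, height = 110)$chest
  ev <- clinician_event(5, 10, cx = ch$x0 + 5, cy = ch$y0 + 5,
                        ax = 8, ay = 8)
  sc2 <- tiny_scene(seed = 9, duration = 20, clinician_events = list(ev))
  sig2 <- chest_motion_signal(sc2$sequence, sc2$truth$boxes, cfg)
  on_frames <- which(sc2$truth$presence == 1)
  expect_true(all(sig2$clinician_overlap[on_frames - 2]))
  expect_false(any(sig2$clinician_overlap[1:10]))
})

test_that("extract_rr end-to-end contracts", {
  sc <- tiny_scene(seed = 12, duration = 240)
  est <- extract_rr(sc$sequence, sc$truth$boxes)
  expect_true(est$valid)
  expect_equal(est$rr_bpm, 15, tolerance = 1)

  # amplitude invariance: halving/doubling moves the estimate < 0.2 bpm
  ests <- vapply(c(0.5, 1, 2), function(a) {
    s <- accept_scene(seed = 5, rr_bpm = 15, amplitude = a)
    extract_rr(s$sequence, s$truth$boxes)$rr_bpm
  }, numeric(1))
  expect_lt(max(ests) - min(ests), 0.2)

  # clinician occlusion over most of the window -> excluded
  ch <- scene_config(width = 140, height = 110)$chest
  ev <- clinician_event(0, 160, cx = ch$x0 + 5, cy = ch$y0 + 5,
                        ax = 8, ay = 8)
  sc3 <- tiny_scene(seed = 12, duration = 240,
                    clinician_events = list(ev))
  est3 <- extract_rr(sc3$sequence, sc3$truth$boxes)
  expect_false(est3$valid)
  expect_equal(est3$exclusion_reason, "clinician_overlap")
  expect_gt(est3$overlap_fraction, 0.6)
})
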