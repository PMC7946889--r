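test_that("spatial smoothing preserves constant and affine depth profiles", {
  const <- matrix(5, 32, 10)
  expect_equal(spatial_smooth(const), const, tolerance = 1e-12)
  affine <- outer(seq_len(32), rep(1, 10)) * 3 + 2
  expect_equal(spatial_smooth(affine), affine, tolerance = 1e-10)
  expect_error(spatial_smooth(const, window_len = 4), "odd")
})

test_that("smoothing an impulse reproduces the normalized Hamming weights", {
  x <- matrix(0, 32, 1); x[16, 1] <- 1
  out <- spatial_smooth(x, 7)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:6) / 6)
  w <- w / sum(w)
  expect_equal(out[13:19, 1], w, tolerance = 1e-12)
  expect_equal(sum(out[, 1]), 1, tolerance = 1e-12)
})

test_that("the CSD operator is exact on quadratics and annihilates affine profiles", {
  z <- seq_len(32)
  theta <- array(0, c(1, 32, 5))
  for (s in 1:5) theta[1, , s] <- z^2
  rec <- laminar_recording(theta, fs = 2000, dz = 1)
  csd <- compute_csd(rec, grid_n = 1, window_len = NULL)
  expect_equal(csd$csd[1, 2:31, ], matrix(2, 30, 5), tolerance = 1e-10)
  csd_sm <- compute_csd(rec, grid_n = 1, window_len = 7)
  expect_equal(csd_sm$csd[1, 8:25, ], matrix(2, 18, 5), tolerance = 1e-10)
  # affine profile maps to zero everywhere, smoothed or not
  for (s in 1:5) theta[1, , s] <- 3 * z + 7
  rec_a <- laminar_recording(theta, fs = 2000, dz = 1)
  expect_lt(max(abs(compute_csd(rec_a, window_len = NULL)$csd)), 1e-10)
  expect_lt(max(abs(compute_csd(rec_a, window_len = 7)$csd)), 1e-10)
})

test_that("the pipeline recovers a designed CSD from its double-integrated LFP", {
  p0 <- quiet_params()
  rec <- generate_evoked(p0, freqs = 2000, n_trials_per_freq = 1, seed = 1)
  truth <- evoked_design(p0, 2000, "pre")$csd
  est <- compute_csd(rec, window_len = NULL)$csd[1, , ]
  interior <- 2:31
  r <- cor(as.vector(est[interior, ]), as.vector(truth[interior, ]))
  expect_gt(r, 0.99)
})

test_that("AVREC and RelResCSD reproduce the hand-worked channel cases", {
  ct <- avrec_relres(csd_of(matrix(c(1, -1), 2, 1)))
  expect_equal(ct$avrec[1, 1], 1)
  expect_equal(ct$relres[1, 1], 0)
  ct <- avrec_relres(csd_of(matrix(c(-1, -1), 2, 1)))
  expect_equal(ct$avrec[1, 1], 1)
  expect_equal(ct$relres[1, 1], -1)
  ct <- avrec_relres(csd_of(matrix(c(1, -1, 2), 3, 1)))
  expect_equal(ct$avrec[1, 1], 4 / 3)
  expect_equal(ct$relres[1, 1], 1 / 2)
})

test_that("AVREC is nonnegative and RelResCSD bounded on random profiles", {
  set.seed(99)
  x <- array(rnorm(10 * 16 * 625), c(10, 16, 625))   # 10^4 profiles
  x[1, , 1] <- 0                                     # an all-zero sample
  ct <- avrec_relres(csd_of(x))
  expect_true(all(ct$avrec >= 0))
  expect_true(all(abs(ct$relres) <= 1 + 1e-12))
  expect_identical(ct$relres[1, 1], 0)               # defined as 0 when AVREC 0
  expect_identical(ct$avrec[1, 1], 0)
})

test_that("layer RMS is channel-wise-then-average and homogeneous of degree 1", {
  m <- layer_map(list(A = 1:2, B = 3:8))
  x <- matrix(0, 8, 50); x[1, ] <- 1; x[2, ] <- -1
  csd <- csd_of(x)
  r <- layer_rms(csd, m)
  expect_equal(unname(r["A", 1]), 1)            # average-then-RMS would give 0
  csd2 <- csd_of(2 * x)
  expect_equal(layer_rms(csd2, m), 2 * r, tolerance = 1e-12)
  # constant value c over the window gives |c|
  xc <- matrix(-3, 8, 50)
  expect_equal(unname(layer_rms(csd_of(xc), m, window = 11:40)["B", 1]), 3)
  expect_error(layer_rms(csd, m, window = 45:60), "window")
})

test_that("onset latency recovers the designed latencies and their laminar ordering", {
  p0 <- quiet_params()
  rec <- generate_evoked(p0, freqs = 2000, n_trials_per_freq = 2, seed = 1)
  csd <- compute_csd(rec)
  map <- default_layer_map(32)
  ol <- onset_latency(csd, map, baseline = 201:400)
  lat <- setNames(ol$latency_ms, ol$layer)
  expect_true(all(ol$detected))
  rise <- p0$kernel$rise_ms
  expect_lt(abs(lat["III/IV"] - p0$latency_ms[["III/IV"]]), rise)
  expect_lt(abs(lat["Vb"] - p0$latency_ms[["Vb"]]), rise)
  expect_gt(lat["I/II"], lat["III/IV"])       # intracortical follows afferent
  expect_gt(lat["VI"], lat["Vb"])
  # flat recording: nothing detected
  flat <- csd_of(array(0, c(1, 32, 1600)))
  flat$stim_onset <- 400L
  ol0 <- onset_latency(flat, map, baseline = 201:400)
  expect_true(all(is.na(ol0$latency_ms)))
})

test_that("stability cross-correlogram finds constructed shifts and amplitude invariance", {
  p0 <- quiet_params()
  csd1 <- generate_evoked(p0, freqs = 2000, n_trials_per_freq = 1, seed = 1,
                          emit = "csd")
  win <- 401:500                                 # first 50 ms post onset
  s <- stability_xcorr(csd1, csd1, win, max_lag = 5)
  expect_identical(s$peak_lag, 0L)
  expect_equal(max(s$correlation), 1)
  expect_true(all(abs(s$correlation) <= 1 + 1e-12))
  # profile displaced 3 channels deeper peaks at +3
  shifted <- csd1
  arr <- csd1$csd
  arr2 <- array(0, dim(arr))
  arr2[, 4:32, ] <- arr[, 1:29, ]
  shifted$csd <- arr2
  expect_identical(stability_xcorr(csd1, shifted, win, max_lag = 5)$peak_lag, 3L)
  # per-layer amplitude rescaling without displacement stays at zero lag
  ph <- hyase_effect(quiet_params())
  post <- generate_evoked(ph, freqs = 2000, n_trials_per_freq = 1,
                          condition = "post", seed = 1, emit = "csd")
  pre <- generate_evoked(ph, freqs = 2000, n_trials_per_freq = 1,
                         condition = "pre", seed = 1, emit = "csd")
  expect_identical(stability_xcorr(pre, post, win, max_lag = 5)$peak_lag, 0L)
  expect_error(stability_xcorr(csd1, csd1, win, max_lag = 32), "max_lag")
})
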