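test_that("generators are deterministic under a fixed seed", {
  p <- synth_params()
  a <- generate_evoked(p, freqs = 2000, n_trials_per_freq = 2, seed = 7)
  b <- generate_evoked(p, freqs = 2000, n_trials_per_freq = 2, seed = 7)
  expect_identical(a$lfp, b$lfp)
  g1 <- generate_spontaneous(p, duration = 5, seed = 3)
  g2 <- generate_spontaneous(p, duration = 5, seed = 3)
  expect_identical(g1$recording$lfp, g2$recording$lfp)
  expect_identical(g1$events, g2$events)
  t1 <- generate_var_traces(p$var_coupling, p$var_noise_cov, 2, 200, seed = 5)
  t2 <- generate_var_traces(p$var_coupling, p$var_noise_cov, 2, 200, seed = 5)
  expect_identical(t1, t2)
})

test_that("noise-free evoked output is monotone and linear in layer gain", {
  p0 <- quiet_params()
  p0$lateral$gain[] <- 0
  map <- default_layer_map(32)
  p_off <- p0; p_off$gain["Vb", ] <- 0
  d_on <- evoked_design(p0, 2000, "pre")$csd
  d_off <- evoked_design(p_off, 2000, "pre")$csd
  rms <- function(x, ch) sqrt(mean(x[ch, ]^2))
  expect_lt(rms(d_off, map[["Vb"]]), rms(d_on, map[["Vb"]]))
  # linearity: doubling the gain doubles that layer's kernel contribution
  p2 <- p0; p2$gain["Vb", ] <- 2 * p0$gain["Vb", ]
  comp1 <- evoked_design(p0, 2000, "pre")$by_layer[["Vb"]]
  comp2 <- evoked_design(p2, 2000, "pre")$by_layer[["Vb"]]
  expect_equal(comp2, 2 * comp1, tolerance = 1e-14)
})

test_that("frequency tuning of the noise-free kernel follows the Gaussian octave law", {
  p0 <- quiet_params()
  p0$lateral$gain[] <- 0
  p0$gain[, ] <- 0; p0$gain["III/IV", ] <- 1   # isolate one layer
  bf <- p0$best_freq; sig <- p0$tuning_width_oct
  d_bf <- evoked_design(p0, bf, "pre")$csd
  d_off <- evoked_design(p0, bf * 16, "pre")$csd   # 4 octaves off
  ratio <- sqrt(mean(d_off^2)) / sqrt(mean(d_bf^2))
  expect_equal(ratio, exp(-16 / (2 * sig^2)), tolerance = 1e-12)
})

test_that("layer kernels are charge balanced and the lateral kernel is not", {
  p0 <- quiet_params()
  p0$lateral$gain[] <- 0
  d <- evoked_design(p0, 2000, "pre")$csd
  expect_lt(max(abs(colSums(d))), 1e-10)      # column sums ~ 0 at every sample
  ct0 <- avrec_relres(csd_of(d))
  resp <- 401:800
  expect_lt(max(abs(ct0$relres[1, resp])), 1e-10)
  p1 <- quiet_params()   # default lateral present
  d1 <- evoked_design(p1, 2000, "pre")$csd
  ct1 <- avrec_relres(csd_of(d1))
  expect_gt(sqrt(mean(ct1$relres[1, resp]^2)),
            sqrt(mean(ct0$relres[1, resp]^2)))
})

test_that("spontaneous events respect the minimum separation and Poisson rate", {
  p <- synth_params()
  g <- generate_spontaneous(p, duration = 60, condition = "pre", seed = 11)
  if (nrow(g$events) > 1L)
    expect_true(all(diff(g$events$onset_s) > 0.150))
  # rate 0 gives pure noise and an empty truth list
  p0 <- synth_params(); p0$sce$rate[] <- 0
  g0 <- generate_spontaneous(p0, duration = 5, seed = 1)
  expect_identical(nrow(g0$events), 0L)
  # Monte-Carlo mean event count matches the thinning-corrected Poisson mean
  rate <- 1; dur <- 60; min_sep <- 0.15; margin <- 0.5
  counts <- vapply(1:100, function(s) {
    set.seed(s)
    length(lamcsd:::.sample_onsets(rate, dur, min_sep, margin))
  }, numeric(1))
  expected <- (dur - margin) * rate / (1 + rate * min_sep)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("VAR trace generator matches the Lyapunov covariance and reports truth edges", {
  # bivariate VAR(1) with x -> y coupling 0.5
  A <- array(0, c(2, 2, 1)); A[1, 1, 1] <- 0.3; A[2, 2, 1] <- 0.3
  A[2, 1, 1] <- 0.5
  tr <- generate_var_traces(A, diag(2), n_trials = 1, n_samples = 1e5, seed = 2)
  truth <- attr(tr, "truth_edges")
  expect_true(truth[2, 1]); expect_false(truth[1, 2])
  # stationary covariance from the discrete Lyapunov equation
  A1 <- A[, , 1]
  vecP <- solve(diag(4) - kronecker(A1, A1), as.vector(diag(2)))
  P <- matrix(vecP, 2, 2)
  G1 <- A1 %*% P                      # lag-1 autocovariance Cov(X_t, X_{t-1})
  x <- tr[1, 1, ]; y <- tr[1, 2, ]
  n <- length(x)
  emp <- mean((y[-1] - mean(y)) * (x[-n] - mean(x)))
  expect_gt(emp, 0)
  expect_lt(abs(emp - G1[2, 1]), 4 * sqrt(2 / n) * sqrt(P[1, 1] * P[2, 2]))
  # diagonal coupling only: empty truth edge set
  Ad <- array(0, c(3, 3, 1)); diag(Ad[, , 1]) <- 0.4
  trd <- generate_var_traces(Ad, diag(3), 1, 100, seed = 1)
  expect_false(any(attr(trd, "truth_edges")))
})

test_that("parameter validation rejects unstable or negative settings", {
  p <- synth_params()
  p$gain[1, 1] <- -1
  expect_error(validate_synth_params(p), "negative layer gain")
  Abad <- array(0, c(4, 4, 1)); diag(Abad[, , 1]) <- 1.05
  expect_error(synth_params(var_coupling = Abad), "unstable")
  expect_error(generate_var_traces(Abad, diag(4), 1, 100), "unstable")
  expect_error(generate_var_traces(array(0.1, c(2, 2, 1)),
                                   matrix(c(1, 2, 2, 1), 2), 1, 100),
               "positive definite")
})

test_that("treatment effect presets encode the reported direction of change", {
  p <- synth_params()
  ph <- hyase_effect(p)
  expect_lt(ph$sce$rate[["post"]], ph$sce$rate[["pre"]])
  expect_lt(ph$sce$dur_scale[["post"]], ph$sce$dur_scale[["pre"]])
  expect_lt(ph$var_coupling_post["III/IV", "Vb", 1],
            ph$var_coupling["III/IV", "Vb", 1])
  expect_gt(ph$var_coupling_post["VI", "I/II", 1],
            ph$var_coupling["VI", "I/II", 1])
  expect_gt(ph$var_coupling_post["Vb", "VI", 1],
            ph$var_coupling["Vb", "VI", 1])
  expect_gt(ph$osc$gain[["post"]], 0)
  expect_identical(ph$osc$gain[["pre"]], 0)
  # layer-symmetry of the noise-free kernels rises from pre to post
  pq <- quiet_params(); pq <- hyase_effect(pq)
  map <- default_layer_map(32)
  lsi_of <- function(cond) {
    d <- evoked_design(pq, 2000, cond)$csd
    r <- layer_rms(csd_of(d), map)
    lsi(r["I/II", 1], r["Vb", 1])
  }
  expect_gt(lsi_of("post"), lsi_of("pre"))
})
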