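test_that("the ADF test separates unit roots from stationary series", {
  set.seed(21)
  rw <- cumsum(rnorm(600))
  expect_gt(adf_test(rw)$p_value, 0.1)
  expect_lt(adf_test(diff(rw))$p_value, 0.05)
  ar1 <- as.numeric(stats::arima.sim(list(ar = 0.5), 600))
  expect_lt(adf_test(diff(ar1))$p_value, 0.05)
})

test_that("stationarization differences once and reports per-series diagnostics", {
  set.seed(22)
  tr <- array(rnorm(3 * 2 * 200), c(3, 2, 200))
  tr[, 2, ] <- aperm(apply(tr[, 2, ], 1, cumsum), c(2, 1))   # random walks
  st <- stationarize(tr)
  expect_identical(dim(st$traces), c(3L, 2L, 199L))          # exactly one sample fewer
  expect_identical(nrow(st$adf), 2L)
  expect_true(all(st$adf$stationary))                        # differenced walks pass
  expect_error(stationarize(array(0, c(2, 2, 30))), "50 samples")
})

test_that("VAR fitting identifies noise-free recursions exactly", {
  # deterministic rotation with an integer period: exactly zero-mean input
  th <- 2 * pi / 8
  A <- array(matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2),
             c(2, 2, 1))
  x <- matrix(0, 2, 200)
  x[, 1] <- c(1, -1)
  for (t in 2:200) x[, t] <- A[, , 1] %*% x[, t - 1]
  tr <- array(0, c(1, 2, 200)); tr[1, , ] <- x
  m <- fit_var(tr, 1)
  expect_lt(max(abs(m$A - A)), 1e-8)
  expect_lt(max(abs(m$sigma)), 1e-16)
})

test_that("VAR estimates are consistent on long simulations", {
  p <- synth_params()
  tr <- generate_var_traces(p$var_coupling, p$var_noise_cov,
                            n_trials = 2, n_samples = 5e4, seed = 30)
  m <- fit_var(tr, 2)
  expect_lt(sqrt(mean((m$A - p$var_coupling)^2)), 0.01)
  expect_lt(m$spectral_radius, 1)
})

test_that("trial boundaries are respected in the pooled fit", {
  set.seed(23)
  # two trials with very different means; a naive concatenation would
  # regress across the seam and see the jump
  t1 <- matrix(rnorm(1 * 100), 1, 100)
  t2 <- matrix(rnorm(1 * 100) + 50, 1, 100)
  tr <- array(0, c(2, 1, 100)); tr[1, 1, ] <- t1; tr[2, 1, ] <- t2
  m_joint <- fit_var(tr, 1)
  cat_tr <- array(0, c(1, 1, 200)); cat_tr[1, 1, ] <- c(t1, t2)
  m_cat <- fit_var(cat_tr, 1)
  expect_gt(abs(m_cat$A[1, 1, 1] - m_joint$A[1, 1, 1]), 0.05)
  expect_lt(abs(m_joint$A[1, 1, 1]), 0.3)   # white noise: near zero
})

test_that("order selection recovers the generative order of a clear VAR(2)", {
  p <- synth_params()
  hits <- vapply(1:20, function(s) {
    tr <- generate_var_traces(p$var_coupling, p$var_noise_cov, 10, 1000, seed = 400 + s)
    select_order(tr, max_order = 5) == 2L
  }, logical(1))
  expect_gte(sum(hits), 17)               # >= 90% of seeded runs
  tr1 <- generate_var_traces(p$var_coupling, p$var_noise_cov, 2, 300, seed = 1)
  expect_identical(as.integer(select_order(tr1, max_order = 1)), 1L)
})

test_that("the model-implied autocovariance matches closed forms and simulations", {
  phi <- 0.6; s2 <- 1.7
  mod <- list(A = array(phi, c(1, 1, 1)), sigma = matrix(s2, 1, 1), p = 1L)
  G <- autocov_sequence(mod, 6)
  expect_equal(G[, 1, 1], s2 * phi^(0:6) / (1 - phi^2), tolerance = 1e-12)
  # multivariate: Gamma(0) symmetric positive definite, and close to the
  # empirical autocovariance of a long realization
  p <- synth_params()
  tr <- generate_var_traces(p$var_coupling, p$var_noise_cov, 1, 2e5, seed = 31)
  m <- fit_var(tr, 2)
  G2 <- autocov_sequence(m, 10)
  expect_equal(G2[1, , ], t(G2[1, , ]), tolerance = 1e-10)
  expect_true(all(eigen(G2[1, , ], symmetric = TRUE)$values > 0))
  x <- matrix(tr[1, , ], 4); x <- x - rowMeans(x)
  emp <- tcrossprod(x) / ncol(x)
  expect_lt(max(abs(G2[1, , ] - emp)), 0.05)
  expect_error(autocov_sequence(list(A = array(1.01, c(1, 1, 1)),
                                     sigma = matrix(1, 1, 1), p = 1L), 5),
               "unstable")
})

test_that("reducing nothing returns the full model's residual variance", {
  p <- synth_params()
  tr <- generate_var_traces(p$var_coupling, p$var_noise_cov, 5, 400, seed = 32)
  m <- fit_var(tr, 2)
  G <- autocov_sequence(m, 40)
  for (i in 1:4) {
    red <- reduced_model(G, target = i, conditioning = 1:4, order = 2)
    expect_lt(abs(red$residual_var - m$sigma[i, i]), 1e-10)
  }
})

test_that("independent series yield near-zero causality and F is never negative", {
  A <- array(0, c(4, 4, 1)); diag(A[, , 1]) <- 0.4
  tr <- generate_var_traces(A, diag(4), 8, 500, seed = 33)
  gc <- conditional_gc(tr, p = 1)
  off <- gc$F[row(gc$F) != col(gc$F)]
  expect_true(all(off >= 0))
  expect_lt(max(off), 0.01)
})

test_that("autocovariance-route causality agrees with the direct OLS oracle", {
  p <- synth_params()
  for (s in 1:3) {
    tr <- generate_var_traces(p$var_coupling, p$var_noise_cov, 10, 600, seed = 40 + s)
    Fa <- conditional_gc(tr, p = 2)$F
    Fo <- gc_ols_oracle(tr, 2)
    d <- abs(Fa - Fo)
    expect_lt(max(d, na.rm = TRUE), max(1e-3, 1e-3 * max(abs(Fo), na.rm = TRUE)))
  }
})

test_that("a perfectly predictive conditioning series drives all causality to zero", {
  set.seed(34)
  base <- generate_var_traces(synth_params()$var_coupling, diag(4), 5, 400, seed = 35)
  # without the copy, the Vb -> III/IV drive registers strongly
  expect_gt(conditional_gc(base, p = 2)$F[2, 3], 0.05)
  tr <- array(0, c(5, 5, 400))
  tr[, 1:4, ] <- base
  # a one-step-leading near-copy of series 2: its past contains the
  # target present, so it predicts series 2 perfectly
  tr[, 5, 1:399] <- base[, 2, 2:400] + 1e-4 * rnorm(5 * 399)
  tr[, 5, 400] <- tr[, 5, 399]
  gc <- conditional_gc(tr, p = 2)
  # no other source can add predictive power once the copy is conditioned on
  expect_lt(max(gc$F[2, c(1, 3, 4)]), 5e-3)
})

test_that("causality is invariant under rescaling any series", {
  p <- synth_params()
  tr <- generate_var_traces(p$var_coupling, p$var_noise_cov, 6, 500, seed = 36)
  tr2 <- tr
  tr2[, 3, ] <- 100 * tr2[, 3, ]
  F1 <- conditional_gc(tr, p = 2)$F
  F2 <- conditional_gc(tr2, p = 2)$F
  expect_equal(F1, F2, tolerance = 1e-8)
})

test_that("group comparison flags nothing for identical conditions", {
  p <- synth_params()
  gcs <- lapply(1:4, function(s) {
    tr <- generate_var_traces(p$var_coupling, p$var_noise_cov, 5, 400, seed = 60 + s)
    conditional_gc(tr, p = 2)
  })
  cmp <- compare_gc(gcs, gcs, fdr_q = 0.05)
  expect_false(any(cmp$significant))
  expect_identical(nrow(cmp), 12L)        # all ordered off-diagonal edges
  expect_error(compare_gc(gcs[1:2], gcs[1:2]), "3 matched")
})
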