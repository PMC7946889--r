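# Shared helpers: deterministic parameter sets and small constructors.

# Noise-free, jitter-free parameters for closed-form checks.
quiet_params <- function(...) {
  p <- synth_params(...)
  p$noise_sd <- 0
  p$trial_jitter$latency_sd_ms <- 0
  p$trial_jitter$gain_sd <- 0
  p
}

# Wrap a channels x samples matrix (or trials x channels x samples array)
# as a csd_profile for unit tests of the columnar measures.
csd_of <- function(x, fs = 2000, dz = 0.05) {
  if (is.matrix(x)) {
    arr <- array(0, c(1L, nrow(x), ncol(x)))
    arr[1L, , ] <- x
  } else arr <- x
  lamcsd:::as_csd_profile(arr, fs = fs, dz = dz)
}

# Independent pooled-OLS conditional-GC oracle: direct least-squares fits of
# the full and reduced regressions (Eqs. of the two-model construction),
# sharing no code with the package's autocovariance route.
ols_sigma <- function(traces, p, vars) {
  d <- dim(traces); k <- length(vars)
  Xs <- NULL; Ys <- NULL
  for (trl in seq_len(d[1])) {
    x <- matrix(traces[trl, vars, ], k, d[3])
    x <- x - rowMeans(x)
    n <- ncol(x)
    Y <- t(x[, (p + 1):n, drop = FALSE])
    X <- NULL
    for (l in 1:p) X <- cbind(X, t(x[, (p + 1 - l):(n - l), drop = FALSE]))
    Xs <- rbind(Xs, X); Ys <- rbind(Ys, Y)
  }
  B <- solve(crossprod(Xs), crossprod(Xs, Ys))
  E <- Ys - Xs %*% B
  crossprod(E) / nrow(Ys)
}

gc_ols_oracle <- function(traces, p) {
  k <- dim(traces)[2]
  Sfull <- ols_sigma(traces, p, 1:k)
  Fm <- matrix(NA_real_, k, k)
  for (j in 1:k) {
    keep <- setdiff(1:k, j)
    Sred <- ols_sigma(traces, p, keep)
    for (i in keep)
      Fm[i, j] <- log(Sred[match(i, keep), match(i, keep)] / Sfull[i, i])
  }
  Fm
}

# Session-level variability for paired-design analyses: small independent
# perturbation of gains, latencies and kernel shape per recording session.
session_variant <- function(params, seed) {
  jitter_params(params, seed = seed, gain_sd = 0.05, latency_sd = 2,
                shape_sd = 0.15)
}
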