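## Time-domain pairwise-conditional Granger causality between layer CSD
## traces.
##
## Full model: X(t) = sum_k A_k X(t-k) + e(t) over all layer traces, fit
## jointly across trials by pooled least squares (per-trial demeaning, no
## regression across trial boundaries). For a source series j and target i,
## the reduced model omits j and is derived from the autocovariance sequence
## implied by the full model via the Yule-Walker equations; the causality
## estimate is F(j -> i | rest) = ln(var(e'_i) / var(e_i)), the log ratio of
## the target's reduced and full residual variances.

# ---- stationarity -----------------------------------------------------------

# Dickey-Fuller response-surface table for the constant+trend regression
# (Banerjee, Dolado, Galbraith & Hendry 1993, Table 4.2), interpolated over
# sample size and statistic; the standard table used by ADF implementations.
.adf_table <- local({
  tbl <- -rbind(
    c(4.38, 4.15, 4.04, 3.99, 3.98, 3.96),
    c(3.95, 3.80, 3.73, 3.69, 3.68, 3.66),
    c(3.60, 3.50, 3.45, 3.43, 3.42, 3.41),
    c(3.24, 3.18, 3.15, 3.13, 3.13, 3.12),
    c(1.14, 1.19, 1.22, 1.23, 1.24, 1.25),
    c(0.80, 0.87, 0.90, 0.92, 0.93, 0.94),
    c(0.50, 0.58, 0.62, 0.64, 0.65, 0.66),
    c(0.15, 0.24, 0.28, 0.31, 0.32, 0.33))
  list(stat = t(tbl), p = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
       n = c(25, 50, 100, 250, 500, 1e5))
})

#' Augmented Dickey-Fuller unit-root test
#'
#' Tests the null of a unit root against trend-stationarity using the
#' standard constant + trend ADF regression
#' `dx_t = a + b t + g x_{t-1} + sum_i d_i dx_{t-i} + e_t`; the test
#' statistic is the t-ratio on `g`, with the p-value interpolated from the
#' published Dickey-Fuller response-surface table. Small p-values reject
#' the unit root (i.e. support stationarity).
#'
#' @param x numeric series (length >= 25 recommended).
#' @param lags number of lagged differences; default
#'   `trunc((length(x) - 1)^(1/3))`.
#' @return list with `statistic`, `p_value` (clamped to `[0.01, 0.99]`),
#'   and `lags`.
#' @export
adf_test <- function(x, lags = trunc((length(x) - 1)^(1/3))) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < lags + 10L) stop("series too short for the ADF regression", call. = FALSE)
  dx <- diff(x)
  k <- lags
  nn <- length(dx) - k
  y <- dx[(k + 1L):length(dx)]
  xlag <- x[(k + 1L):(n - 1L)]
  X <- cbind(1, seq_len(nn), xlag)
  if (k > 0L) {
    for (i in seq_len(k)) X <- cbind(X, dx[(k + 1L - i):(length(dx) - i)])
  }
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  s2 <- sum(res^2) / (nn - ncol(X))
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * XtXinv[3L, 3L])
  stat <- fit$coefficients[3L] / se
  tb <- .adf_table
  row <- vapply(seq_along(tb$p), function(j)
    stats::approx(tb$n, tb$stat[, j], xout = n, rule = 2)$y, numeric(1))
  p <- stats::approx(row, tb$p, xout = stat, rule = 2)$y
  list(statistic = unname(stat), p_value = p, lags = k)
}

#' First-derivative stationarization with ADF diagnostics
#'
#' Takes the first time difference of each series in each trial (removing
#' slow nonstationary trends in CSD traces) and runs an augmented
#' Dickey-Fuller test per series on the concatenated, per-trial demeaned
#' segments. Series that still fail at `alpha` are flagged, not fatal: the
#' protocol differences once and proceeds.
#'
#' @param traces array `trials x k x samples` of layer traces (samples
#'   >= 50).
#' @param alpha significance level for the ADF flag (default 0.05).
#' @return list with `traces` (differenced, one sample shorter) and `adf`
#'   (`data.frame(series, statistic, p_value, stationary)`).
#' @export
stationarize <- function(traces, alpha = 0.05) {
  d <- dim(traces)
  if (is.null(d) || length(d) != 3L)
    stop("traces must be a trials x k x samples array", call. = FALSE)
  if (d[3] < 50L) stop("need at least 50 samples per trial", call. = FALSE)
  dtr <- traces[, , -1L, drop = FALSE] - traces[, , -d[3], drop = FALSE]
  nms <- dimnames(traces)[[2]]
  if (is.null(nms)) nms <- paste0("series", seq_len(d[2]))
  rep_df <- data.frame(series = nms, statistic = NA_real_, p_value = NA_real_,
                       stationary = NA)
  for (s in seq_len(d[2])) {
    segs <- lapply(seq_len(d[1]), function(tr) {
      v <- dtr[tr, s, ]; v - mean(v)
    })
    a <- adf_test(unlist(segs))
    rep_df$statistic[s] <- a$statistic
    rep_df$p_value[s] <- a$p_value
    rep_df$stationary[s] <- a$p_value <= alpha
  }
  list(traces = dtr, adf = rep_df)
}

# ---- VAR fitting ------------------------------------------------------------

# Pooled lagged design matrix across trials (per-trial demeaned, no lags
# across trial boundaries). Returns list(X, Y): X is N x (k*p) with columns
# ordered lag-major (lag 1 series 1..k, lag 2 series 1..k, ...).
.pooled_design <- function(traces, p) {
  d <- dim(traces)
  k <- d[2]; n <- d[3]
  if (n <= p) stop("trials shorter than the model order", call. = FALSE)
  Xs <- vector("list", d[1]); Ys <- vector("list", d[1])
  for (tr in seq_len(d[1])) {
    x <- matrix(traces[tr, , ], k, n)
    x <- x - rowMeans(x)
    Y <- t(x[, (p + 1L):n, drop = FALSE])
    X <- matrix(0, n - p, k * p)
    for (l in seq_len(p))
      X[, ((l - 1L) * k + 1L):(l * k)] <- t(x[, (p + 1L - l):(n - l), drop = FALSE])
    Xs[[tr]] <- X; Ys[[tr]] <- Y
  }
  list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys))
}

#' Fit a vector autoregressive model across trials
#'
#' Estimates a VAR(p) jointly from all trials by pooled least squares:
#' each trial is demeaned per series, lagged regressors never cross trial
#' boundaries, and the residual covariance is the maximum-likelihood
#' estimate (sum of squared residuals over the number of pooled
#' observations).
#'
#' @param traces array `trials x k x samples`.
#' @param p model order (>= 1).
#' @return An object of class `var_model`: coefficient array `A`
#'   (`k x k x p`), residual covariance `sigma`, order `p`, pooled
#'   observation count `n_obs`, log-likelihood, and the companion-matrix
#'   `spectral_radius`.
#' @export
fit_var <- function(traces, p) {
  d <- dim(traces)
  if (is.null(d) || length(d) != 3L)
    stop("traces must be a trials x k x samples array", call. = FALSE)
  k <- d[2]
  nms <- dimnames(traces)[[2]]
  if (is.null(nms)) nms <- paste0("series", seq_len(k))
  pd <- .pooled_design(traces, p)
  N <- nrow(pd$X)
  if (N <= k * p)
    stop("not enough pooled samples for order ", p, call. = FALSE)
  G <- crossprod(pd$X)
  sv <- svd(G, nu = 0, nv = 0)$d
  if (min(sv) <= max(sv) * 1e-12) {
    # identify the offending series from near-zero variance columns
    vars <- apply(pd$X[, seq_len(k), drop = FALSE], 2L, stats::var)
    bad <- nms[which.min(vars)]
    stop("singular lagged covariance (series '", bad, "')", call. = FALSE)
  }
  B <- solve(G, crossprod(pd$X, pd$Y))    # (k*p) x k
  E <- pd$Y - pd$X %*% B
  sigma <- crossprod(E) / N
  A <- array(0, c(k, k, p), dimnames = list(nms, nms, NULL))
  for (l in seq_len(p))
    A[, , l] <- t(B[((l - 1L) * k + 1L):(l * k), , drop = FALSE])
  sr <- .companion_radius(A)
  ld <- determinant(sigma, logarithm = TRUE)$modulus
  structure(list(A = A, sigma = sigma, p = p, k = k, n_obs = N,
                 loglik = -N / 2 * (as.numeric(ld) + k * (1 + log(2 * pi))),
                 spectral_radius = sr, series = nms),
            class = "var_model")
}

.companion_radius <- function(A) {
  k <- dim(A)[1]; p <- dim(A)[3]
  C <- matrix(0, k * p, k * p)
  for (l in seq_len(p)) C[seq_len(k), ((l - 1L) * k + 1L):(l * k)] <- A[, , l]
  if (p > 1L)
    C[(k + 1L):(k * p), seq_len(k * (p - 1L))] <- diag(k * (p - 1L))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' @export
print.var_model <- function(x, ...) {
  cat("<var_model> k = ", x$k, ", p = ", x$p, ", N = ", x$n_obs,
      ", spectral radius = ", round(x$spectral_radius, 3), "\n", sep = "")
  invisible(x)
}

#' Select the VAR model order by AIC
#'
#' Fits VAR(p) for `p = 1..max_order` on the pooled trials and returns the
#' order minimizing `AIC(p) = log det(Sigma_p) + 2 p k^2 / N_p`, the
#' residual generalized variance with the standard parameter-count
#' penalty. Unstable fits (companion spectral radius >= 1) are excluded.
#'
#' @param traces array `trials x k x samples`.
#' @param max_order largest order to consider (default 20, i.e. 10 ms of
#'   history at 2 kHz).
#' @return Selected order (integer); attribute `aic` carries the full
#'   criterion curve.
#' @export
select_order <- function(traces, max_order = 20L) {
  if (max_order < 1L) stop("max_order must be >= 1", call. = FALSE)
  k <- dim(traces)[2]
  # all candidate orders are scored on the same effective sample (the first
  # max_order samples of each trial are excluded throughout), so the
  # criteria are properly nested
  pd <- .pooled_design(traces, max_order)
  N <- nrow(pd$X)
  aic <- rep(NA_real_, max_order)
  for (p in seq_len(max_order)) {
    Xp <- pd$X[, seq_len(k * p), drop = FALSE]
    fit <- tryCatch({
      B <- solve(crossprod(Xp), crossprod(Xp, pd$Y))
      E <- pd$Y - Xp %*% B
      sigma <- crossprod(E) / N
      A <- array(0, c(k, k, p))
      for (l in seq_len(p)) A[, , l] <- t(B[((l - 1L) * k + 1L):(l * k), ,
                                            drop = FALSE])
      list(sigma = sigma, sr = .companion_radius(A))
    }, error = function(e) NULL)
    if (is.null(fit) || fit$sr >= 1) next
    ld <- as.numeric(determinant(fit$sigma, logarithm = TRUE)$modulus)
    aic[p] <- ld + 2 * p * k^2 / N
  }
  if (all(is.na(aic))) stop("no stable VAR fit at any order", call. = FALSE)
  p_sel <- which.min(aic)
  attr(p_sel, "aic") <- aic
  p_sel
}

# ---- autocovariance and reduced models --------------------------------------

#' Model-implied autocovariance sequence
#'
#' Solves the discrete Lyapunov equation of the companion form of a stable
#' VAR(p) (by doubling iteration) for the contemporaneous covariance and
#' extends to `Gamma(0..n_lags)` with the Yule-Walker recursion
#' `Gamma(h) = sum_l A_l Gamma(h - l)`. `Gamma(h) = Cov(X_t, X_{t-h})`.
#'
#' @param model a [fit_var()] model (or any list with `A`, `sigma`, `p`).
#' @param n_lags number of lags (default `max(4 p, 40)`).
#' @return Array `(n_lags + 1) x k x k`; entry `[h + 1, , ]` is `Gamma(h)`.
#' @export
autocov_sequence <- function(model, n_lags = max(4L * model$p, 40L)) {
  A <- model$A; sigma <- model$sigma
  k <- dim(A)[1]; p <- dim(A)[3]
  sr <- .companion_radius(A)
  if (sr >= 1) stop("unstable model (spectral radius ", round(sr, 3), ")",
                    call. = FALSE)
  kp <- k * p
  C <- matrix(0, kp, kp)
  for (l in seq_len(p)) C[seq_len(k), ((l - 1L) * k + 1L):(l * k)] <- A[, , l]
  if (p > 1L) C[(k + 1L):kp, seq_len(k * (p - 1L))] <- diag(k * (p - 1L))
  Q <- matrix(0, kp, kp); Q[seq_len(k), seq_len(k)] <- sigma
  # doubling iteration for P = sum_j C^j Q C^j'
  P <- Q; M <- C
  for (it in seq_len(100L)) {
    P <- P + M %*% P %*% t(M)
    M <- M %*% M
    if (max(abs(M)) < 1e-300 ||
        max(abs(M)) * max(abs(P)) < 1e-14 * max(abs(P))) break
  }
  P <- (P + t(P)) / 2
  G <- array(0, c(n_lags + 1L, k, k))
  for (h in 0:min(p - 1L, n_lags))
    G[h + 1L, , ] <- P[seq_len(k), (h * k + 1L):((h + 1L) * k)]
  if (n_lags >= p) {
    for (h in p:n_lags) {
      acc <- matrix(0, k, k)
      for (l in seq_len(p)) {
        hl <- h - l
        Ghl <- if (hl >= 0) G[hl + 1L, , ] else t(G[-hl + 1L, , ])
        acc <- acc + A[, , l] %*% Ghl
      }
      G[h + 1L, , ] <- acc
    }
  }
  G
}

#' Reduced model from the autocovariance sequence
#'
#' Solves the multivariate Yule-Walker equations of the sub-autocovariance
#' over `{target} + conditioning` for a reduced VAR of order `order`
#' (default: the order of the full model that produced the
#' autocovariance), and extracts the residual covariance
#' `Sigma_red = Gamma(0) - sum_l A'_l Gamma(l)'`. Omitting nothing returns
#' the full model's residuals exactly, since the model-implied
#' autocovariance satisfies the full model's own Yule-Walker relations.
#'
#' @param autocov array from [autocov_sequence()].
#' @param target index of the target series within the original ordering.
#' @param conditioning indices of the retained conditioning series.
#' @param order reduced model order (lags used).
#' @return list with `A` (`m x m x order` coefficients over the reduced
#'   variable set), `sigma` (`m x m` residual covariance),
#'   `target_pos` (row of the target within the reduced set), and
#'   `residual_var` (the target's reduced residual variance).
#' @export
reduced_model <- function(autocov, target, conditioning,
                          order = NULL) {
  vs <- sort(unique(c(target, conditioning)))
  m <- length(vs)
  n_lags <- dim(autocov)[1] - 1L
  if (is.null(order)) order <- n_lags
  if (order > n_lags)
    stop("autocovariance available to ", n_lags, " lags only", call. = FALSE)
  q <- order
  Gs <- function(h) {
    if (h >= 0) autocov[h + 1L, vs, vs, drop = TRUE]
    else t(autocov[-h + 1L, vs, vs, drop = TRUE])
  }
  if (m == 1L) Gs <- function(h) matrix(autocov[abs(h) + 1L, vs, vs], 1L, 1L)
  # block-Toeplitz system: [A_1 ... A_q] T = [Gamma(1) ... Gamma(q)],
  # T[(j),(i)] = Gamma(i - j)
  Tm <- matrix(0, m * q, m * q)
  Cm <- matrix(0, m, m * q)
  for (i in seq_len(q)) {
    Cm[, ((i - 1L) * m + 1L):(i * m)] <- Gs(i)
    for (j in seq_len(q))
      Tm[((j - 1L) * m + 1L):(j * m), ((i - 1L) * m + 1L):(i * m)] <- Gs(i - j)
  }
  rc <- rcond(Tm)
  if (rc < 1e-12)
    stop("ill-conditioned Yule-Walker system (rcond = ",
         format(rc, digits = 3), ")", call. = FALSE)
  Aall <- t(solve(Tm, t(Cm)))             # m x (m*q)
  sig <- Gs(0)
  for (l in seq_len(q))
    sig <- sig - Aall[, ((l - 1L) * m + 1L):(l * m), drop = FALSE] %*% t(Gs(l))
  sig <- (sig + t(sig)) / 2
  A <- array(Aall, c(m, m, q))
  tp <- match(target, vs)
  list(A = A, sigma = sig, target_pos = tp, vars = vs,
       residual_var = sig[tp, tp])
}

# ---- conditional GC ---------------------------------------------------------

#' Pairwise-conditional Granger causality matrix
#'
#' For every ordered pair of series `(j -> i)`, fits the full VAR over all
#' `k` series (pooled across trials) and a reduced model omitting `j`
#' (derived from the full model's autocovariance sequence via Yule-Walker,
#' same order), conditioning on the remaining series, and computes
#' `F[i, j] = ln(var(e'_i) / var(e_i))`. Negative estimates (a
#' finite-sample artifact) are clipped to 0 and flagged.
#'
#' @param traces array `trials x k x samples` of (stationarized) layer
#'   traces.
#' @param p model order; `NULL` selects by AIC via [select_order()].
#' @param max_order passed to [select_order()] when `p` is `NULL`.
#' @param n_lags autocovariance lags (default `max(4 p, 40)`).
#' @return An object of class `gc_matrix`: list with `F` (`k x k`,
#'   `F[i, j]` = causality j -> i, diagonal `NA`), `clipped` logical
#'   matrix, order `p`, and the full `model`.
#' @export
conditional_gc <- function(traces, p = NULL, max_order = 20L, n_lags = NULL) {
  if (is.null(p)) p <- as.integer(select_order(traces, max_order))
  model <- fit_var(traces, p)
  k <- model$k
  if (is.null(n_lags)) n_lags <- max(4L * p, 40L)
  G <- autocov_sequence(model, n_lags)
  Fm <- matrix(NA_real_, k, k, dimnames = list(model$series, model$series))
  clipped <- matrix(FALSE, k, k, dimnames = dimnames(Fm))
  for (j in seq_len(k)) {
    # one reduced model without series j serves every target i != j
    keep <- setdiff(seq_len(k), j)
    red <- tryCatch(
      reduced_model(G, target = keep[1L], conditioning = keep, order = p),
      error = function(e) e)
    for (i in keep) {
      if (inherits(red, "error")) { next }
      pos <- match(i, red$vars)
      f <- log(red$sigma[pos, pos] / model$sigma[i, i])
      if (is.finite(f) && f < 0) { clipped[i, j] <- TRUE; f <- 0 }
      Fm[i, j] <- f
    }
  }
  structure(list(F = Fm, clipped = clipped, p = p, model = model,
                 subject_id = attr(traces, "subject_id"),
                 condition = attr(traces, "condition")),
            class = "gc_matrix")
}

#' @export
print.gc_matrix <- function(x, ...) {
  cat("<gc_matrix> k = ", ncol(x$F), ", order p = ", x$p,
      " (column = source, row = target)\n", sep = "")
  print(round(x$F, 4))
  invisible(x)
}

#' Group comparison of Granger-causality matrices
#'
#' Per directed edge, a paired t-test across subjects on the
#' log-transformed causality estimates, corrected over the off-diagonal
#' edges by the Benjamini-Hochberg rule at `fdr_q` (default 0.05).
#' Subjects with a clipped (zero) estimate on an edge are excluded
#' pairwise from that edge's log-domain test; edges with fewer than 3
#' usable pairs are flagged untestable.
#'
#' @param pre,post lists of [conditional_gc()] results (one per subject),
#'   matched by position.
#' @param fdr_q false discovery rate.
#' @return An object of class `gc_comparison`:
#'   `data.frame(from, to, n_pairs, t, p, significant, direction)` with
#'   attributes `critical_p` and `fdr_q`. `direction` is
#'   `"increase"`/`"decrease"` of post relative to pre for significant
#'   edges.
#' @export
compare_gc <- function(pre, post, fdr_q = 0.05) {
  if (length(pre) != length(post) || length(pre) < 3L)
    stop("need >= 3 matched subjects", call. = FALSE)
  k <- ncol(pre[[1L]]$F)
  nms <- colnames(pre[[1L]]$F)
  if (is.null(nms)) nms <- paste0("series", seq_len(k))
  rows <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    a <- vapply(pre, function(g) g$F[i, j], numeric(1))
    b <- vapply(post, function(g) g$F[i, j], numeric(1))
    ok <- is.finite(a) & is.finite(b) & a > 0 & b > 0
    n_ok <- sum(ok)
    if (n_ok >= 3L) {
      r <- paired_t(log(a[ok]), log(b[ok]))
      tt <- r$t; pp <- if (is.na(r$p)) 1 else r$p
    } else {
      tt <- NA_real_; pp <- NA_real_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      from = nms[j], to = nms[i], n_pairs = n_ok, t = tt, p = pp,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  testable <- !is.na(out$p)
  mask <- logical(nrow(out)); crit <- 0
  if (any(testable)) {
    bh <- bh_correct(out$p[testable], fdr_q)
    mask[testable] <- bh$mask
    crit <- bh$critical_p
  }
  out$significant <- mask
  out$direction <- ifelse(!mask, "", ifelse(out$t < 0, "increase", "decrease"))
  attr(out, "critical_p") <- crit
  attr(out, "fdr_q") <- fdr_q
  class(out) <- c("gc_comparison", "data.frame")
  out
}
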