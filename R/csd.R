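## CSD estimation and columnar current-flow measures.
##
## The estimator is the standard one-dimensional second spatial difference of
## the laminar LFP,
##   CSD(z) ~ d^2 theta / dz^2
##          = [theta(z + n dz) - 2 theta(z) + theta(z - n dz)] / (n dz)^2,
## applied after Hamming-window smoothing along depth. Sinks (current influx,
## depolarizing synaptic activity) come out negative.

# Linearly extend a channels x samples matrix by n_ext virtual channels on
# each end, using the exact line through the outermost two channels.
.extend_linear <- function(x, n_ext = 4L) {
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 channels to extrapolate", call. = FALSE)
  top_slope <- x[1L, ] - x[2L, ]
  bot_slope <- x[n, ] - x[n - 1L, ]
  top <- outer(seq.int(n_ext, 1L), top_slope) +
    matrix(x[1L, ], n_ext, ncol(x), byrow = TRUE)
  bot <- outer(seq.int(1L, n_ext), bot_slope) +
    matrix(x[n, ], n_ext, ncol(x), byrow = TRUE)
  rbind(top, x, bot)
}

#' Hamming-window spatial smoothing of a laminar profile
#'
#' Replaces each channel by a Hamming-weighted average over `window_len`
#' neighbouring channels at every time sample (the default 7 channels on a
#' 50-um probe correspond to a 300-um spatial kernel). Boundaries are
#' handled by first extending the profile with 4 virtual channels on each
#' end via linear extrapolation from the outermost channel pair, then
#' trimming back. Weights are normalized to sum 1, so constant and affine
#' depth profiles pass through unchanged.
#'
#' @param x numeric matrix `channels x samples` (one trial).
#' @param window_len odd window length, `3 <= window_len <= n_channels`.
#' @return Matrix of the same dimensions as `x`.
#' @export
spatial_smooth <- function(x, window_len = 7L) {
  if (window_len %% 2L == 0L)
    stop("window_len must be odd", call. = FALSE)
  if (window_len < 3L || window_len > nrow(x))
    stop("window_len must be in [3, n_channels]", call. = FALSE)
  half <- (window_len - 1L) %/% 2L
  w <- signal::hamming(window_len)
  w <- w / sum(w)
  ext <- .extend_linear(x, n_ext = max(4L, half))
  n_ext <- max(4L, half)
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  for (j in seq_len(window_len)) {
    off <- j - half - 1L
    out <- out + w[j] * ext[(n_ext + 1L + off):(n_ext + n + off), , drop = FALSE]
  }
  dimnames(out) <- dimnames(x)
  out
}

#' Compute the current-source density profile
#'
#' Applies the second spatial difference with differentiation grid `grid_n`
#' and spacing `dz` to each trial of a laminar recording, after optional
#' Hamming-window spatial smoothing. The same 4-channel linear boundary
#' extrapolation used for smoothing is applied before differencing, so all
#' `n_channels` get a CSD value. Sinks are negative.
#'
#' Layer-resolved measures (RMS, latency) conventionally use the smoothed
#' CSD; the columnar AVREC / relative-residual measures are defined on the
#' CSD of the unsmoothed single-trial LFP — pass `window_len = NULL` for
#' that path.
#'
#' @param rec a [laminar_recording()].
#' @param grid_n differentiation grid (number of channel steps), default 1.
#' @param window_len odd Hamming window length for spatial smoothing, or
#'   `NULL` to skip smoothing.
#' @return An object of class `csd_profile`: list with `csd`
#'   (`trials x channels x samples` array, sinks negative), the recording
#'   metadata, and a `provenance` record (smoothing window, grid, boundary
#'   policy).
#' @export
compute_csd <- function(rec, grid_n = 1L, window_len = 7L) {
  validate_recording(rec)
  d <- dim(rec$lfp)
  n_ch <- d[2]
  if (grid_n < 1L) stop("grid_n must be >= 1", call. = FALSE)
  n_ext <- 4L
  if (!is.null(window_len)) n_ext <- max(4L, (window_len - 1L) %/% 2L)
  if (grid_n > n_ext)
    stop("grid_n = ", grid_n, " too large for the ", n_ext,
         "-channel boundary extrapolation", call. = FALSE)
  if (n_ch < 2L * grid_n + 1L)
    stop("grid_n too large for the channel count", call. = FALSE)
  denom <- (grid_n * rec$dz)^2
  csd <- array(0, dim = d)
  for (tr in seq_len(d[1])) {
    theta <- rec$lfp[tr, , ]
    if (!is.null(window_len)) theta <- spatial_smooth(theta, window_len)
    ext <- .extend_linear(theta, n_ext = n_ext)
    idx <- (n_ext + 1L):(n_ext + n_ch)
    csd[tr, , ] <- (ext[idx + grid_n, , drop = FALSE] -
                      2 * ext[idx, , drop = FALSE] +
                      ext[idx - grid_n, , drop = FALSE]) / denom
  }
  structure(
    list(csd = csd, fs = rec$fs, dz = rec$dz, condition = rec$condition,
         subject_id = rec$subject_id, stim_freq = rec$stim_freq,
         stim_onset = rec$stim_onset,
         provenance = list(window_len = window_len, grid_n = grid_n,
                           boundary = "4-channel linear extrapolation")),
    class = "csd_profile")
}

# Wrap a bare CSD array (e.g. generator output) as a csd_profile.
as_csd_profile <- function(csd, fs, dz, condition = "pre", subject_id = "s01",
                           stim_freq = NULL, stim_onset = NULL,
                           provenance = list(window_len = NULL, grid_n = NA,
                                             boundary = "designed")) {
  structure(list(csd = csd, fs = fs, dz = dz, condition = condition,
                 subject_id = subject_id, stim_freq = stim_freq,
                 stim_onset = stim_onset, provenance = provenance),
            class = "csd_profile")
}

#' @export
print.csd_profile <- function(x, ...) {
  d <- dim(x$csd)
  cat("<csd_profile> ", x$subject_id, " [", x$condition, "] ",
      d[1], " trials x ", d[2], " channels x ", d[3], " samples\n", sep = "")
  cat("  smoothing: ",
      if (is.null(x$provenance$window_len)) "none" else
        paste0(x$provenance$window_len, "-channel Hamming"),
      ", grid_n = ", x$provenance$grid_n, "\n", sep = "")
  invisible(x)
}

#' AVREC and relative-residual CSD traces
#'
#' For each trial and time sample computes the averaged rectified CSD,
#' `AVREC(t) = sum_i |CSD_i(t)| / n`, an overall measure of columnar
#' current flow, and the relative residual,
#' `RelResCSD(t) = sum_i CSD_i(t) / sum_i |CSD_i(t)|`, the signed imbalance
#' of sinks and sources that indexes lateral (cross-columnar) synaptic
#' input. RelResCSD is defined as 0 wherever the rectified sum is 0.
#' Both are conventionally computed on the CSD of the unsmoothed
#' single-trial LFP (`compute_csd(..., window_len = NULL)`).
#'
#' @param csd a `csd_profile`.
#' @return An object of class `columnar_traces`: list with matrices `avrec`
#'   and `relres` (`trials x samples`) and `n_channels_used`.
#' @export
avrec_relres <- function(csd) {
  stopifnot(inherits(csd, "csd_profile"))
  x <- csd$csd
  d <- dim(x)
  # mean over the channel dimension, kept as trials x samples matrices
  absmean <- colMeans(aperm(abs(x), c(2L, 1L, 3L)))
  sigmean <- colMeans(aperm(x, c(2L, 1L, 3L)))
  relres <- ifelse(absmean > 0, sigmean / absmean, 0)
  structure(list(avrec = absmean, relres = relres, n_channels_used = d[2],
                 fs = csd$fs, stim_onset = csd$stim_onset),
            class = "columnar_traces")
}

#' Layer root-mean-square amplitudes
#'
#' RMS is computed per channel over the analysis window and then averaged
#' across the channels of each layer (channel-wise RMS first, average
#' second — the two orders differ and this one is the convention used
#' throughout).
#'
#' @param csd a `csd_profile`.
#' @param map a [layer_map()].
#' @param window integer vector of sample indices (e.g. the 200-ms stimulus
#'   period); defaults to the whole trial.
#' @return Numeric matrix `layers x trials` of RMS amplitudes.
#' @export
layer_rms <- function(csd, map, window = NULL) {
  stopifnot(inherits(csd, "csd_profile"), inherits(map, "layer_map"))
  d <- dim(csd$csd)
  if (is.null(window)) window <- seq_len(d[3])
  if (min(window) < 1L || max(window) > d[3])
    stop("window outside the trace", call. = FALSE)
  out <- matrix(NA_real_, length(map), d[1],
                dimnames = list(names(map), NULL))
  for (nm in names(map)) {
    ch <- map[[nm]]
    if (length(ch) == 0L) stop("empty layer range '", nm, "'", call. = FALSE)
    if (max(ch) > d[2]) stop("layer '", nm, "' outside channel range", call. = FALSE)
    seg <- csd$csd[, ch, window, drop = FALSE]
    rms_ch <- sqrt(apply(seg^2, c(1L, 2L), mean))   # trials x channels
    out[nm, ] <- rowMeans(rms_ch)
  }
  out
}

# Layer-averaged CSD traces: trials x layers x samples array.
#' Layer-averaged CSD traces
#'
#' Averages the CSD across the channels of each layer, yielding one trace
#' per layer and trial — the input representation for the Granger-causality
#' stage.
#'
#' @param csd a `csd_profile`.
#' @param map a [layer_map()].
#' @param window optional sample-index window to crop (e.g. an evoked
#'   analysis window).
#' @return Array `trials x layers x samples` with layer dimnames.
#' @export
layer_traces <- function(csd, map, window = NULL) {
  stopifnot(inherits(csd, "csd_profile"), inherits(map, "layer_map"))
  d <- dim(csd$csd)
  if (is.null(window)) window <- seq_len(d[3])
  out <- array(NA_real_, c(d[1], length(map), length(window)),
               dimnames = list(NULL, names(map), NULL))
  for (li in seq_along(map)) {
    ch <- map[[li]]
    seg <- csd$csd[, ch, window, drop = FALSE]
    out[, li, ] <- apply(seg, c(1L, 3L), mean)
  }
  out
}

# First run of `flag` lasting strictly more than min_len samples; returns the
# starting index or NA. Shared by response detection and onset latency.
.first_sustained <- function(flag, min_len) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths > min_len)
  if (length(hit) == 0L) return(NA_integer_)
  starts[hit[1L]]
}

#' Sink onset latency per layer
#'
#' On the trial-averaged, layer-averaged CSD trace, the onset latency is the
#' first post-onset time at which the trace falls below
#' `baseline mean - k_sd * baseline SD` (sinks are negative) continuously
#' for more than `min_dur_ms`. The threshold criterion is the same
#' 2 SD / >5 ms rule used by [detect_response()]. Layers without a
#' detectable sink are flagged missing (`NA`).
#'
#' @param csd a `csd_profile` (smoothed path).
#' @param map a [layer_map()].
#' @param baseline integer vector of baseline sample indices (pre-stimulus).
#' @param onset stimulus onset as number of pre-stimulus samples; defaults
#'   to the profile's `stim_onset`.
#' @param k_sd threshold factor in baseline SDs (default 2).
#' @param min_dur_ms minimum supra-threshold duration in ms (default 5).
#' @return `data.frame(layer, latency_ms, detected)`.
#' @export
onset_latency <- function(csd, map, baseline, onset = csd$stim_onset,
                          k_sd = 2, min_dur_ms = 5) {
  stopifnot(inherits(csd, "csd_profile"), inherits(map, "layer_map"))
  if (is.null(onset)) stop("no stimulus onset available", call. = FALSE)
  if (max(baseline) > onset)
    stop("baseline must precede the stimulus onset", call. = FALSE)
  fs <- csd$fs
  min_len <- as.integer(min_dur_ms * fs / 1000)
  tr <- layer_traces(csd, map)
  n_samp <- dim(tr)[3]
  res <- data.frame(layer = names(map), latency_ms = NA_real_,
                    detected = FALSE, stringsAsFactors = FALSE)
  for (li in seq_along(map)) {
    trace <- colMeans(matrix(tr[, li, , drop = FALSE], dim(tr)[1], n_samp))
    mu <- mean(trace[baseline]); sdv <- stats::sd(trace[baseline])
    thr <- mu - k_sd * sdv
    post <- trace[(onset + 1L):n_samp]
    idx <- .first_sustained(post < thr, min_len)
    if (!is.na(idx)) {
      res$latency_ms[li] <- (idx - 1L) / fs * 1000
      res$detected[li] <- TRUE
    }
  }
  res
}

#' Electrode-stability cross-correlogram
#'
#' Reduces each condition to a depth profile (per-channel mean of the CSD
#' over the early post-onset window, averaged across trials) and Pearson
#' cross-correlates the two profiles over integer channel shifts in
#' `[-max_lag, +max_lag]` using the overlapping channels. A stable
#' penetration with only amplitude changes between conditions peaks at zero
#' lag; a physical displacement of the electrode shows up as a shifted
#' peak.
#'
#' @param csd_pre,csd_post `csd_profile`s with equal channel counts.
#' @param onset_window sample indices of the early evoked window (e.g. the
#'   first 50 ms after onset).
#' @param max_lag maximum channel shift (default 5 channels, i.e. 250 um).
#' @return An object of class `stability_result`: list with `lags`,
#'   `correlation` and `peak_lag`.
#' @export
stability_xcorr <- function(csd_pre, csd_post, onset_window, max_lag = 5L) {
  stopifnot(inherits(csd_pre, "csd_profile"), inherits(csd_post, "csd_profile"))
  n <- dim(csd_pre$csd)[2]
  if (dim(csd_post$csd)[2] != n)
    stop("channel counts differ between conditions", call. = FALSE)
  if (max_lag >= n) stop("max_lag must be < n_channels", call. = FALSE)
  depth_profile <- function(csd) {
    seg <- csd$csd[, , onset_window, drop = FALSE]
    colMeans(apply(seg, c(1L, 2L), mean))  # length n_channels
  }
  a <- depth_profile(csd_pre)
  b <- depth_profile(csd_post)
  lags <- seq.int(-max_lag, max_lag)
  rr <- vapply(lags, function(l) {
    t_idx <- seq_len(n)
    keep <- t_idx + l >= 1L & t_idx + l <= n
    stats::cor(a[t_idx[keep]], b[t_idx[keep] + l])
  }, numeric(1))
  structure(list(lags = lags, correlation = rr,
                 peak_lag = lags[which.max(rr)]),
            class = "stability_result")
}
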