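## Frequency-response analysis: response detection, best frequency, octave
## binning, Q40dB bandwidth, and the layer symmetry index.

#' Threshold-criterion response detection
#'
#' A trace contains a significant evoked response if its absolute deviation
#' from the baseline mean exceeds `k_sd` baseline standard deviations
#' continuously for more than `min_dur_ms` (defaults: 2 SD, >5 ms). The
#' same criterion is shared with the sink onset-latency estimator. A trace
#' with zero baseline SD and zero excursion is not a response.
#'
#' @param trace numeric vector (one trace, typically trial-averaged).
#' @param baseline integer vector of baseline sample indices (nonempty).
#' @param fs sampling rate in Hz.
#' @param k_sd threshold factor in baseline SDs.
#' @param min_dur_ms minimum supra-threshold duration in ms.
#' @return list with `response` (logical) and `onset` (sample index of the
#'   first crossing of the detected run, or `NA`).
#' @export
detect_response <- function(trace, baseline, fs, k_sd = 2, min_dur_ms = 5) {
  if (length(baseline) == 0L) stop("baseline must be nonempty", call. = FALSE)
  mu <- mean(trace[baseline])
  sdv <- stats::sd(trace[baseline])
  if (!is.finite(sdv)) sdv <- 0
  min_len <- as.integer(min_dur_ms * fs / 1000)
  above <- abs(trace - mu) > k_sd * sdv
  if (sdv == 0) above <- abs(trace - mu) > 0
  idx <- .first_sustained(above, min_len)
  list(response = !is.na(idx), onset = idx)
}

#' Best frequency from granular-layer responses
#'
#' The best frequency (BF) is the tone frequency evoking the highest RMS
#' amplitude in granular layer III/IV. Ties are broken toward the lower
#' frequency.
#'
#' @param freq numeric vector of tone frequencies (Hz).
#' @param rms matching RMS amplitudes.
#' @return The best frequency (Hz).
#' @export
best_frequency <- function(freq, rms) {
  if (length(freq) == 0L || length(freq) != length(rms))
    stop("freq and rms must be matching nonempty vectors", call. = FALSE)
  min(freq[rms == max(rms)])
}

#' Octave-distance binning around the best frequency
#'
#' Assigns each tone to one of five bins by its octave distance
#' `d = round(log2(f / bf))` from the best frequency: `-3-4` for
#' `d in {-4,-3}`, `-1-2` for `d in {-2,-1}`, `BF` for `d = 0`, and the
#' mirrored positive bins. Tones more than 4 octaves away are excluded
#' (`NA`).
#'
#' @param freqs tone frequencies (Hz), > 0.
#' @param bf best frequency (Hz), > 0.
#' @return Factor of length `length(freqs)` with levels
#'   `c("-3-4","-1-2","BF","+1-2","+3-4")`.
#' @export
bin_by_octave <- function(freqs, bf) {
  if (bf <= 0 || any(freqs <= 0))
    stop("frequencies must be positive", call. = FALSE)
  d <- round(log2(freqs / bf))
  lv <- c("-3-4", "-1-2", "BF", "+1-2", "+3-4")
  bin <- rep(NA_character_, length(freqs))
  bin[d %in% c(-4, -3)] <- "-3-4"
  bin[d %in% c(-2, -1)] <- "-1-2"
  bin[d == 0]           <- "BF"
  bin[d %in% c(1, 2)]   <- "+1-2"
  bin[d %in% c(3, 4)]   <- "+3-4"
  factor(bin, levels = lv)
}

#' Octave-binned tuning curve
#'
#' Averages a per-frequency measure (layer RMS, AVREC RMS, RelResCSD RMS)
#' into the five octave-distance bins around the best frequency, with SEM
#' and per-bin counts.
#'
#' @param freq tone frequencies (Hz).
#' @param value matching per-frequency values.
#' @param bf best frequency (Hz).
#' @return `data.frame(bin, mean, sem, n)` with one row per octave bin.
#' @export
tuning_curve <- function(freq, value, bf) {
  bin <- bin_by_octave(freq, bf)
  lv <- levels(bin)
  out <- data.frame(bin = factor(lv, levels = lv), mean = NA_real_,
                    sem = NA_real_, n = 0L)
  for (i in seq_along(lv)) {
    v <- value[!is.na(bin) & bin == lv[i]]
    out$n[i] <- length(v)
    if (length(v) > 0L) out$mean[i] <- mean(v)
    if (length(v) > 1L) out$sem[i] <- stats::sd(v) / sqrt(length(v))
  }
  out
}

#' Q40dB response bandwidth
#'
#' Response bandwidth in octaves at 40 dB above threshold: the number of
#' stimulus frequencies whose trace passes the [detect_response()]
#' criterion, times the octave spacing of the stimulus grid. Passing
#' frequencies are counted globally (contiguity around BF is not required;
#' the two readings coincide for unimodal tuning).
#'
#' @param traces numeric matrix `frequencies x samples` of (typically
#'   trial-averaged) response traces, one row per stimulus frequency.
#' @param baseline baseline sample indices.
#' @param fs sampling rate in Hz.
#' @param octave_spacing spacing of the stimulus grid in octaves.
#' @param k_sd,min_dur_ms detection criterion, see [detect_response()].
#' @return Bandwidth in octaves.
#' @export
q40_bandwidth <- function(traces, baseline, fs, octave_spacing = 1,
                          k_sd = 2, min_dur_ms = 5) {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1L)
  pass <- vapply(seq_len(nrow(traces)), function(i)
    detect_response(traces[i, ], baseline, fs, k_sd, min_dur_ms)$response,
    logical(1))
  sum(pass) * octave_spacing
}

#' Layer symmetry index
#'
#' `LSI = (I/II - Vb) / (I/II + Vb)` on layer RMS amplitudes. Positive
#' values indicate stronger activation of supragranular layers, negative
#' values stronger infragranular recruitment; the index is bounded in
#' `[-1, 1]`. Undefined (NA, with a warning) when both inputs are zero.
#'
#' @param rms_supra supragranular (I/II) RMS, >= 0. Vectorized.
#' @param rms_vb infragranular (Vb) RMS, >= 0.
#' @return LSI value(s) in `[-1, 1]`.
#' @export
lsi <- function(rms_supra, rms_vb) {
  if (any(rms_supra < 0, na.rm = TRUE) || any(rms_vb < 0, na.rm = TRUE))
    stop("RMS inputs must be nonnegative", call. = FALSE)
  den <- rms_supra + rms_vb
  out <- ifelse(den > 0, (rms_supra - rms_vb) / den, NA_real_)
  if (any(den == 0, na.rm = TRUE))
    warning("LSI undefined where both RMS values are zero", call. = FALSE)
  out
}
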