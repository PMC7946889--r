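## Spontaneous columnar events (SCE): transient translaminar activations in
## the absence of a stimulus, detected as peaks of the single-trial AVREC
## trace.

#' Detect spontaneous columnar events on an AVREC trace
#'
#' Peak detection with threshold `T = median(trace) + k_sd * SD(trace)`:
#' the baseline is the median of the whole spontaneous trace and the SD is
#' computed over the whole trace. Candidate peaks are local maxima above
#' `T`; peaks closer than `min_sep_ms` are merged keeping the larger. The
#' event duration is the width of the contiguous supra-threshold excursion
#' containing the peak. A constant trace (zero SD) yields no events.
#' Because both the median and the SD shift with the trace, the detector is
#' invariant to adding a constant.
#'
#' @param trace single-trial AVREC trace (numeric vector).
#' @param fs sampling rate in Hz.
#' @param k_sd threshold factor (default 3 SD).
#' @param min_sep_ms minimum separation between peaks in ms (default 150).
#' @return `data.frame(time_s, amplitude, duration_ms)`, one row per event,
#'   ordered by time. `time_s` is the peak time ((index-1)/fs).
#' @export
detect_sce <- function(trace, fs, k_sd = 3, min_sep_ms = 150) {
  n <- length(trace)
  min_sep <- as.integer(round(min_sep_ms * fs / 1000))
  if (n <= min_sep) stop("trace shorter than the minimum separation", call. = FALSE)
  sdv <- stats::sd(trace)
  empty <- data.frame(time_s = numeric(0), amplitude = numeric(0),
                      duration_ms = numeric(0))
  if (!is.finite(sdv) || sdv == 0) return(empty)
  thr <- stats::median(trace) + k_sd * sdv
  above <- trace > thr
  if (!any(above)) return(empty)
  # local maxima above threshold (plateaus keep their first sample)
  d1 <- diff(trace)
  is_peak <- c(FALSE, d1 > 0) & c(d1 <= 0, FALSE) & above
  cand <- which(is_peak)
  if (length(cand) == 0L) return(empty)
  # greedy merge: keep the taller of any pair closer than min_sep
  ord <- cand[order(trace[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(i - kept) >= min_sep)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  # duration of the supra-threshold excursion containing each peak
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_of <- function(i) which(starts <= i & ends >= i)
  dur <- vapply(kept, function(i) {
    k <- run_of(i)
    r$lengths[k] / fs * 1000
  }, numeric(1))
  data.frame(time_s = (kept - 1L) / fs, amplitude = trace[kept],
             duration_ms = dur)
}

#' Spontaneous-event rate
#'
#' Event count divided by total recorded duration, in events per second.
#' Counts are conventionally aggregated across a subject's 6-s spontaneous
#' traces.
#'
#' @param events event table from [detect_sce()] (or a bare count).
#' @param duration total duration in seconds, > 0.
#' @return Events per second.
#' @export
sce_rate <- function(events, duration) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  n / duration
}

#' Spontaneous activity metrics per trace
#'
#' For each spontaneous trace (trial) computes the RMS over the full trace
#' of: the layer-averaged CSD per layer (channel-wise RMS averaged across
#' the layer), the AVREC, and the RelResCSD.
#'
#' @param csd a `csd_profile` of spontaneous traces.
#' @param map a [layer_map()].
#' @return data.frame with one row per trace: `trial`, one column per
#'   layer, `avrec_rms`, `relres_rms`.
#' @export
spontaneous_metrics <- function(csd, map) {
  stopifnot(inherits(csd, "csd_profile"), inherits(map, "layer_map"))
  lr <- layer_rms(csd, map)           # layers x trials
  ct <- avrec_relres(csd)
  rms_rows <- function(m) sqrt(rowMeans(m^2))
  out <- data.frame(trial = seq_len(ncol(lr)))
  for (nm in rownames(lr)) out[[nm]] <- lr[nm, ]
  out$avrec_rms <- rms_rows(ct$avrec)
  out$relres_rms <- rms_rows(ct$relres)
  out
}
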