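#' Construct a laminar recording
#'
#' Bundles a multi-trial laminar local field potential (LFP) array with its
#' acquisition metadata. The LFP is stored as a 3-d numeric array
#' `trials x channels x samples`; channel 1 is the most superficial contact
#' and depth increases with channel index.
#'
#' @param lfp numeric array `[n_trials x n_channels x n_samples]`, microvolts
#'   (or any consistent amplitude unit).
#' @param fs sampling rate in Hz.
#' @param dz inter-channel spacing in mm (0.05 mm for a 50 um probe).
#' @param condition condition label, `"pre"` or `"post"`.
#' @param subject_id subject identifier string.
#' @param stim_freq optional per-trial tone frequency in Hz (length
#'   `n_trials`); omit for spontaneous recordings.
#' @param stim_onset optional number of pre-stimulus samples; the first
#'   stimulus sample is index `stim_onset + 1`.
#' @return An object of class `laminar_recording`.
#' @export
laminar_recording <- function(lfp, fs, dz, condition = c("pre", "post"),
                              subject_id = "s01", stim_freq = NULL,
                              stim_onset = NULL) {
  condition <- match.arg(condition)
  rec <- structure(
    list(lfp = lfp, fs = fs, dz = dz, condition = condition,
         subject_id = subject_id, stim_freq = stim_freq,
         stim_onset = stim_onset),
    class = "laminar_recording")
  validate_recording(rec)
}

#' Validate a laminar recording
#'
#' Checks the field and shape invariants of a [laminar_recording()]:
#' a 3-d finite LFP array with at least 7 channels (the spatial filter
#' length), positive sampling rate and channel spacing, per-trial stimulus
#' frequencies of matching length, and a stimulus onset inside the trial.
#'
#' @param rec object to validate.
#' @return `rec`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_recording <- function(rec) {
  required <- c("lfp", "fs", "dz", "condition", "subject_id")
  for (f in required) {
    if (is.null(rec[[f]]))
      stop("format error: missing field '", f, "'", call. = FALSE)
  }
  lfp <- rec$lfp
  if (!is.numeric(lfp) || length(dim(lfp)) != 3L)
    stop("format error: 'lfp' must be a numeric trials x channels x samples array",
         call. = FALSE)
  if (anyNA(lfp) || any(!is.finite(lfp)))
    stop("data error: non-finite values in 'lfp'", call. = FALSE)
  if (dim(lfp)[2] < 7L)
    stop("format error: need at least 7 channels, got ", dim(lfp)[2],
         call. = FALSE)
  if (!is.numeric(rec$fs) || rec$fs <= 0)
    stop("format error: 'fs' must be > 0", call. = FALSE)
  if (!is.numeric(rec$dz) || rec$dz <= 0)
    stop("format error: 'dz' must be > 0", call. = FALSE)
  if (!rec$condition %in% c("pre", "post"))
    stop("format error: 'condition' must be 'pre' or 'post'", call. = FALSE)
  if (!is.null(rec$stim_freq) && length(rec$stim_freq) != dim(lfp)[1])
    stop("format error: 'stim_freq' length must equal the number of trials",
         call. = FALSE)
  if (!is.null(rec$stim_onset)) {
    if (rec$stim_onset < 0 || rec$stim_onset >= dim(lfp)[3])
      stop("format error: 'stim_onset' must lie within the trial", call. = FALSE)
  }
  invisible(rec)
}

#' @export
print.laminar_recording <- function(x, ...) {
  d <- dim(x$lfp)
  cat("<laminar_recording> ", x$subject_id, " [", x$condition, "]\n", sep = "")
  cat("  ", d[1], " trials x ", d[2], " channels x ", d[3], " samples @ ",
      x$fs, " Hz, dz = ", x$dz, " mm\n", sep = "")
  if (!is.null(x$stim_freq))
    cat("  tones: ", length(unique(x$stim_freq)), " frequencies, onset at ",
        x$stim_onset, " samples\n", sep = "")
  invisible(x)
}

#' Write a laminar recording to disk
#'
#' Serializes the recording to a single self-contained file using R's native
#' serialization, preserving every field bit-exactly. The companion reader is
#' [read_recording()].
#'
#' @param rec a validated [laminar_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  ok <- tryCatch({ saveRDS(unclass(rec), path); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    stop("I/O error: cannot write '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

#' Read a laminar recording from disk
#'
#' Reads a file produced by [write_recording()] and revalidates it. Missing
#' fields raise a format error naming the missing key; non-finite LFP values
#' raise a data error.
#'
#' @param path file path.
#' @return A validated [laminar_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path))
    stop("I/O error: no such file '", path, "'", call. = FALSE)
  raw <- readRDS(path)
  if (!is.list(raw))
    stop("format error: '", path, "' does not contain a recording", call. = FALSE)
  rec <- structure(raw, class = "laminar_recording")
  validate_recording(rec)
  rec
}

#' Construct a cortical layer map
#'
#' A layer map partitions the channel axis into named, contiguous,
#' non-overlapping ranges ordered from superficial to deep. Layer assignment
#' is configuration, not inference: the default split encodes the usual
#' depth extent of each layer on a 32-channel, 50-um probe and should be
#' overridden per penetration when the sink pattern says otherwise.
#'
#' @param ranges named list of integer vectors of channel indices; names are
#'   layer labels ordered superficial to deep.
#' @param n_channels optional channel count used to range-check indices.
#' @return An object of class `layer_map`.
#' @export
layer_map <- function(ranges, n_channels = NULL) {
  if (!is.list(ranges) || is.null(names(ranges)) || any(names(ranges) == ""))
    stop("layer map must be a named list of channel index vectors", call. = FALSE)
  idx_all <- integer(0)
  last_max <- 0L
  for (nm in names(ranges)) {
    idx <- as.integer(ranges[[nm]])
    if (length(idx) == 0L)
      stop("layer '", nm, "' has an empty channel range", call. = FALSE)
    if (any(idx < 1L))
      stop("layer '", nm, "' has channel indices < 1", call. = FALSE)
    if (!all(diff(idx) == 1L))
      stop("layer '", nm, "' is not a contiguous channel range", call. = FALSE)
    if (min(idx) <= last_max)
      stop("layer ranges overlap or are out of superficial-to-deep order at '",
           nm, "'", call. = FALSE)
    if (!is.null(n_channels) && max(idx) > n_channels)
      stop("layer '", nm, "' exceeds n_channels = ", n_channels, call. = FALSE)
    last_max <- max(idx)
    idx_all <- c(idx_all, idx)
    ranges[[nm]] <- idx
  }
  structure(ranges, class = "layer_map")
}

#' Default four-layer map
#'
#' Splits the channel axis into the four laminar compartments used
#' throughout the analysis: supragranular I/II, granular III/IV, and
#' infragranular Vb and VI. On 32 channels the default is I/II 1-6,
#' III/IV 10-15, Vb 18-23, VI 26-30; the channels between ranges are
#' laminar transition zones left unassigned (their laminar identity is
#' ambiguous and they carry the return currents of both neighbours), and
#' the deepest channels are presumptive white matter. Other channel counts
#' scale these boundaries proportionally. Pass `config` to override any
#' range.
#'
#' @param n_channels number of channels (>= 8).
#' @param config optional named list of channel ranges overriding the
#'   default split (validated through [layer_map()]).
#' @return A [layer_map()] with layers `I/II`, `III/IV`, `Vb`, `VI`.
#' @export
default_layer_map <- function(n_channels = 32L, config = NULL) {
  if (n_channels < 8L)
    stop("need at least 8 channels for a four-layer split", call. = FALSE)
  if (!is.null(config))
    return(layer_map(config, n_channels = n_channels))
  starts <- pmax(1L, round(c(1, 10, 18, 26) * n_channels / 32))
  ends <- pmin(n_channels, round(c(6, 15, 23, 30) * n_channels / 32))
  for (i in 2:4) {
    starts[i] <- max(starts[i], ends[i - 1] + 1L)
    ends[i] <- max(ends[i], starts[i])
  }
  if (ends[4] > n_channels)
    stop("cannot fit four non-empty layers into ", n_channels, " channels",
         call. = FALSE)
  layer_map(list(
    "I/II"   = seq.int(starts[1], ends[1]),
    "III/IV" = seq.int(starts[2], ends[2]),
    "Vb"     = seq.int(starts[3], ends[3]),
    "VI"     = seq.int(starts[4], ends[4])),
    n_channels = n_channels)
}

#' @export
print.layer_map <- function(x, ...) {
  cat("<layer_map>\n")
  for (nm in names(x))
    cat(sprintf("  %-7s channels %d-%d\n", nm, min(x[[nm]]), max(x[[nm]])))
  invisible(x)
}
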