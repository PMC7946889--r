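## Synthetic laminar-recording generator.
##
## Emulates the statistical structure the analysis assumes: a canonical
## feedforward evoked CSD pattern (early sinks in granular III/IV and
## infragranular Vb, later sinks in I/II and VI), Gaussian-in-octaves
## frequency tuning, condition-dependent layer gains, a band-limited
## oscillation, spontaneous columnar events initiated in layer Vb, and layer
## traces with known directed VAR coupling. Kernels are phenomenological
## (no biophysical forward model): each layer contributes a charge-balanced
## spatial profile (sink flanked by return sources within the layer's
## channel range) times a delayed, smoothed biphasic temporal transient.
## LFP output is produced by spatially double-integrating the designed CSD,
## so the analysis pipeline - not the generator - recovers the pattern.

.synth_layers <- c("I/II", "III/IV", "Vb", "VI")

.default_coupling <- function() {
  # VAR(2) layer-trace dynamics; layer order I/II, III/IV, Vb, VI.
  # Directed edges restricted to the three the treatment is defined on
  # (Vb->III/IV, I/II->VI, VI->Vb) so that condition contrasts cannot leak
  # into nominally untouched edges through variance propagation.
  k <- 4L
  A <- array(0, c(k, k, 2L), dimnames = list(.synth_layers, .synth_layers, NULL))
  diag(A[, , 1L]) <- 0.35
  diag(A[, , 2L]) <- -0.15
  A["III/IV", "Vb", 1L] <- 0.40   # Vb -> III/IV
  A["VI", "I/II", 1L]   <- 0.12   # I/II -> VI
  A["Vb", "VI", 1L]     <- 0.12   # VI -> Vb
  A
}

.post_coupling <- function() {
  A <- .default_coupling()
  A["III/IV", "Vb", 1L] <- 0.12   # weakened
  A["VI", "I/II", 1L]   <- 0.40   # strengthened
  A["Vb", "VI", 1L]     <- 0.40   # strengthened
  A
}

#' Ground-truth parameters for the synthetic generator
#'
#' Holds all generative parameters: per-layer gains for the pre and post
#' conditions, onset latencies, temporal-kernel time constants, frequency
#' tuning, the unbalanced lateral-input kernel, noise level, the
#' beta-band oscillation, spontaneous-event statistics, and the directed
#' VAR coupling between layer traces. The defaults describe an untreated
#' (pre) cortex in both condition slots; [hyase_effect()] fills the post
#' slots with the enzyme-treatment effect fingerprint.
#'
#' @param n_channels,fs,dz,n_samples,stim_onset recording geometry: 32
#'   channels at 50-um spacing sampled at 2 kHz; 1600-sample (800 ms)
#'   trials with 400 pre-stimulus samples (200 ms) and a 200-ms tone.
#' @param gain 4 x 2 matrix of layer gains (rows `I/II, III/IV, Vb, VI`,
#'   columns `pre, post`), in CSD amplitude units.
#' @param latency_ms per-layer sink onset latency.
#' @param kernel temporal-kernel time constants (ms): sink rise/decay plus
#'   a slower rebound source lobe.
#' @param best_freq,tuning_width_oct Gaussian tuning in octave distance.
#' @param lateral unbalanced supragranular sink modelling lateral
#'   (cross-columnar) input: per-condition gain and tuning width.
#' @param noise_sd SD of the additive white noise on the designed CSD.
#' @param trial_jitter trial-to-trial response variability: SD of a common
#'   latency shift (ms, applied to the whole columnar response of a trial)
#'   and lognormal sigma of a common amplitude factor. Both are universal
#'   features of evoked responses and give single-subject spectra their
#'   sampling variance; set to 0 for exactly repeated trials.
#' @param osc band-limited oscillation injected during the evoked epoch:
#'   centre frequency, target layer, per-condition gain, duration.
#' @param sce spontaneous columnar events: rate (events/s), amplitude,
#'   duration scale, lateral gain per condition, minimum separation, and
#'   the translaminar latencies (layer Vb leads).
#' @param var_coupling,var_coupling_post,var_noise_cov VAR(p) coefficient
#'   tensors (`k x k x p`) for the pre/post layer-trace dynamics and the
#'   innovation covariance.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(n_channels = 32L, fs = 2000, dz = 0.05,
                         n_samples = 1600L, stim_onset = 400L,
                         gain = cbind(pre = c(1.15, 2.0, 1.0, 0.8),
                                      post = c(1.15, 2.0, 1.0, 0.8)),
                         latency_ms = c(30, 20, 20, 35),
                         kernel = list(rise_ms = 5, decay_ms = 30,
                                       rebound = 0.25, rebound_rise_ms = 25,
                                       rebound_decay_ms = 80),
                         best_freq = 2000, tuning_width_oct = 1.5,
                         lateral = list(gain = c(pre = 0.5, post = 0.5),
                                        width_oct = c(pre = 1.0, post = 1.0)),
                         noise_sd = 0.1,
                         trial_jitter = list(latency_sd_ms = 1.5,
                                             gain_sd = 0.15),
                         osc = list(freq = 30.5, layer = "Vb",
                                    gain = c(pre = 0, post = 0), dur_ms = 600),
                         sce = list(rate = c(pre = 1.0, post = 1.0),
                                    amp = c(pre = 1.0, post = 1.0),
                                    dur_scale = c(pre = 1.0, post = 1.0),
                                    lateral = c(pre = 0.2, post = 0.2),
                                    min_sep_ms = 150,
                                    latency_ms = c(20, 10, 0, 20)),
                         var_coupling = .default_coupling(),
                         var_coupling_post = .default_coupling(),
                         var_noise_cov = diag(4)) {
  rownames(gain) <- .synth_layers
  names(latency_ms) <- .synth_layers
  names(sce$latency_ms) <- .synth_layers
  p <- structure(
    list(n_channels = as.integer(n_channels), fs = fs, dz = dz,
         n_samples = as.integer(n_samples), stim_onset = as.integer(stim_onset),
         gain = gain, latency_ms = latency_ms, kernel = kernel,
         best_freq = best_freq, tuning_width_oct = tuning_width_oct,
         lateral = lateral, noise_sd = noise_sd, trial_jitter = trial_jitter,
         osc = osc, sce = sce,
         var_coupling = var_coupling, var_coupling_post = var_coupling_post,
         var_noise_cov = var_noise_cov,
         layer_map = default_layer_map(n_channels)),
    class = "synth_params")
  validate_synth_params(p)
}

#' Validate synthetic-generator parameters
#'
#' Checks nonnegative gains and latencies, positive noise SD bound,
#' spectral stability of both VAR coupling tensors (companion spectral
#' radius < 1) and positive-definiteness of the innovation covariance.
#'
#' @param p a [synth_params()] object.
#' @return `p` invisibly if valid, otherwise an error.
#' @export
validate_synth_params <- function(p) {
  if (any(p$gain < 0)) stop("parameter error: negative layer gain", call. = FALSE)
  if (any(p$latency_ms < 0)) stop("parameter error: negative latency", call. = FALSE)
  if (p$noise_sd < 0) stop("parameter error: negative noise SD", call. = FALSE)
  if (any(p$lateral$gain < 0)) stop("parameter error: negative lateral gain", call. = FALSE)
  if (any(p$osc$gain < 0)) stop("parameter error: negative oscillation gain", call. = FALSE)
  if (any(p$sce$rate < 0)) stop("parameter error: negative SCE rate", call. = FALSE)
  for (cp in list(p$var_coupling, p$var_coupling_post)) {
    sr <- .companion_radius(cp)
    if (sr >= 1)
      stop("parameter error: unstable VAR coupling (spectral radius ",
           round(sr, 3), ")", call. = FALSE)
  }
  ev <- eigen(p$var_noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("parameter error: VAR noise covariance not positive definite",
         call. = FALSE)
  invisible(p)
}

#' @export
print.synth_params <- function(x, ...) {
  cat("<synth_params> ", x$n_channels, " channels @ ", x$fs, " Hz, ",
      x$n_samples, " samples/trial\n", sep = "")
  cat("  gains (pre/post):\n")
  print(round(x$gain, 3))
  invisible(x)
}

#' Apply the enzyme-treatment effect fingerprint
#'
#' Returns a parameter set whose post-condition slots encode the treated
#' cortex: reduced infragranular Vb gain, moderately increased
#' supragranular I/II gain, a beta-band oscillation added to layer Vb
#' during evoked epochs, doubled and broadened lateral (cross-columnar)
#' input, fewer / smaller / shorter spontaneous events, and rebalanced
#' directed coupling (I/II to VI and VI to Vb strengthened, Vb to III/IV
#' weakened). Pre-condition slots are untouched, so the same object
#' generates both conditions of a paired design.
#'
#' @param params_pre a [synth_params()] object describing the untreated
#'   cortex.
#' @param vb_factor,supra_factor multiplicative post gains for layers Vb
#'   and I/II.
#' @param lateral_factor,lateral_width_factor scaling of the lateral-input
#'   gain and tuning width.
#' @param osc_gain amplitude of the injected beta oscillation (CSD units).
#' @param sce_rate_factor,sce_amp_factor,sce_dur_factor scaling of the
#'   spontaneous-event rate, amplitude, and duration.
#' @return A [synth_params()] object with post-condition slots filled.
#' @export
hyase_effect <- function(params_pre, vb_factor = 0.6, supra_factor = 1.2,
                         lateral_factor = 2.0, lateral_width_factor = 2.0,
                         osc_gain = 0.04, sce_rate_factor = 0.6,
                         sce_amp_factor = 0.7, sce_dur_factor = 0.6) {
  p <- params_pre
  p$gain[, "post"] <- p$gain[, "pre"] *
    c(supra_factor, 1, vb_factor, 1)
  p$lateral$gain[["post"]] <- p$lateral$gain[["pre"]] * lateral_factor
  p$lateral$width_oct[["post"]] <- p$lateral$width_oct[["pre"]] *
    lateral_width_factor
  p$osc$gain[["post"]] <- osc_gain
  p$sce$rate[["post"]] <- p$sce$rate[["pre"]] * sce_rate_factor
  p$sce$amp[["post"]] <- p$sce$amp[["pre"]] * sce_amp_factor
  p$sce$dur_scale[["post"]] <- p$sce$dur_scale[["pre"]] * sce_dur_factor
  p$sce$lateral[["post"]] <- p$sce$lateral[["pre"]] * 2.25
  p$var_coupling_post <- .post_coupling()
  validate_synth_params(p)
}

#' Per-subject parameter jitter
#'
#' Draws one subject's variant of a parameter set: lognormal multiplicative
#' jitter on the layer gains (applied to both condition columns, so paired
#' pre/post ratios are preserved), additive latency jitter, and lognormal
#' jitter on the tuning width, kernel decay, and lateral gain. This is what
#' makes synthetic subjects exchangeable-but-distinct for group-level
#' statistics.
#'
#' @param params a [synth_params()] object.
#' @param seed integer seed for this subject.
#' @param gain_sd lognormal sigma of the gain jitter.
#' @param latency_sd SD of the additive latency jitter (ms).
#' @param shape_sd lognormal sigma of the kernel/tuning shape jitter.
#' @return A jittered [synth_params()] object.
#' @export
jitter_params <- function(params, seed, gain_sd = 0.1, latency_sd = 2,
                          shape_sd = 0.1) {
  set.seed(seed)
  p <- params
  g <- exp(stats::rnorm(4, 0, gain_sd))
  p$gain <- p$gain * g
  p$latency_ms <- pmax(p$latency_ms + stats::rnorm(4, 0, latency_sd), 5)
  p$tuning_width_oct <- p$tuning_width_oct * exp(stats::rnorm(1, 0, shape_sd))
  p$kernel$decay_ms <- p$kernel$decay_ms * exp(stats::rnorm(1, 0, shape_sd))
  p$kernel$rise_ms <- p$kernel$rise_ms * exp(stats::rnorm(1, 0, shape_sd))
  p$lateral$gain <- p$lateral$gain * exp(stats::rnorm(1, 0, gain_sd))
  validate_synth_params(p)
}

# ---- kernels ----------------------------------------------------------------

# Fraction of the return current placed in the superficial source lobe for
# each layer. Granular cells return current mainly above the sink (classic
# granular dipole); supragranular synaptic input returns at the soma below;
# infragranular layers are intermediate.
.source_asym <- c("I/II" = 0.4, "III/IV" = 0.75, "Vb" = 0.85, "VI" = 0.15)

# Charge-balanced spatial kernel on the full channel axis: a Gaussian sink
# centred in the layer's channel range, with tight return-current source
# lobes straddling the layer borders (return currents spill into adjacent
# laminae, as they do physiologically); `w_sup` sets the superficial lobe's
# share of the charge. The profile sums to 0 exactly across the column, so
# a single-column event leaves the relative residual near zero; peak sink
# amplitude is -1.
.spatial_kernel <- function(range_idx, n_channels, w_sup = 0.5,
                            lobe_offset = 1.5, lobe_sd = 0.8) {
  L <- length(range_idx)
  ctr <- mean(range_idx)
  ch <- seq_len(n_channels)
  sink <- exp(-(ch - ctr)^2 / (2 * (L / 4)^2))
  sink[abs(ch - ctr) > L / 2] <- 0           # sink confined to the layer
  src1 <- exp(-(ch - (min(range_idx) - lobe_offset))^2 / (2 * lobe_sd^2))
  src2 <- exp(-(ch - (max(range_idx) + lobe_offset))^2 / (2 * lobe_sd^2))
  src1[ch > ctr] <- 0
  src2[ch < ctr] <- 0
  src <- w_sup * src1 / sum(src1) + (1 - w_sup) * src2 / sum(src2)
  prof <- -sink + src * sum(sink)             # exact charge balance
  prof / max(abs(prof))
}

# Unbalanced supragranular sink: models lateral input relayed through
# horizontal corticocortical projections (return currents outside the
# recorded cylinder), so it deliberately does NOT sum to zero.
.lateral_kernel <- function(n_channels) {
  centre <- max(2L, round(n_channels * 0.16))
  x <- seq_len(n_channels) - centre
  g <- exp(-x^2 / (2 * (n_channels / 16)^2))
  -g / max(g)
}

# Biphasic temporal transient: fast sink lobe (rise ~5 ms, decay ~30 ms)
# followed by a slower rebound of opposite sign; peak magnitude 1.
.temporal_kernel <- function(n_samples, fs, latency_ms, kernel,
                             dur_scale = 1) {
  t_ms <- (seq_len(n_samples) - 1) / fs * 1000 - latency_ms
  lobe <- function(rise, decay) {
    h <- ifelse(t_ms > 0, (1 - exp(-t_ms / rise)) * exp(-t_ms / decay), 0)
    h
  }
  h <- lobe(kernel$rise_ms, kernel$decay_ms * dur_scale) -
    kernel$rebound * lobe(kernel$rebound_rise_ms,
                          kernel$rebound_decay_ms * dur_scale)
  h / max(abs(h))
}

.octave_tuning <- function(freq, bf, width_oct) {
  d <- log2(freq / bf)
  exp(-d^2 / (2 * width_oct^2))
}

#' Noise-free evoked CSD design for one tone
#'
#' The deterministic (noise-free) component of an evoked trial: the sum
#' over layers of spatial kernel x temporal kernel x layer gain x Gaussian
#' octave tuning, plus the unbalanced lateral-input kernel and, in the post
#' condition, the injected oscillation. Exposed so the closed-form
#' relations between gains, tuning and the derived measures can be tested
#' exactly.
#'
#' @param params a [synth_params()] object.
#' @param freq tone frequency (Hz).
#' @param condition `"pre"` or `"post"`.
#' @return list with `csd` (`channels x samples`), `by_layer` (list of the
#'   per-layer components), `lateral`, and `osc`.
#' @export
evoked_design <- function(params, freq, condition = c("pre", "post")) {
  condition <- match.arg(condition)
  p <- params
  n_ch <- p$n_channels; n_s <- p$n_samples
  onset_ms <- p$stim_onset / p$fs * 1000
  tune <- .octave_tuning(freq, p$best_freq, p$tuning_width_oct)
  by_layer <- list()
  total <- matrix(0, n_ch, n_s)
  for (li in seq_along(.synth_layers)) {
    nm <- .synth_layers[li]
    sk <- .spatial_kernel(p$layer_map[[nm]], n_ch, .source_asym[[nm]])
    tk <- .temporal_kernel(n_s, p$fs, onset_ms + p$latency_ms[nm], p$kernel)
    comp <- p$gain[nm, condition] * tune * outer(sk, tk)
    by_layer[[nm]] <- comp
    total <- total + comp
  }
  lat_tune <- .octave_tuning(freq, p$best_freq,
                             p$lateral$width_oct[[condition]])
  lk <- .lateral_kernel(n_ch)
  # lateral input is relayed through supragranular horizontal projections,
  # so it shares the supragranular latency
  ltk <- .temporal_kernel(n_s, p$fs, onset_ms + p$latency_ms[["I/II"]],
                          p$kernel)
  lateral <- p$lateral$gain[[condition]] * lat_tune * outer(lk, ltk)
  total <- total + lateral
  osc <- matrix(0, n_ch, n_s)
  og <- p$osc$gain[[condition]]
  if (og > 0) {
    nm <- p$osc$layer
    # oscillation dipole: return lobes kept tight inside the transition
    # zones so the injected rhythm stays confined to its target layer
    sk <- .spatial_kernel(p$layer_map[[nm]], n_ch, 0.5,
                          lobe_offset = 1.1, lobe_sd = 0.7)
    t_rel <- (seq_len(n_s) - 1) / p$fs - p$stim_onset / p$fs
    dur <- p$osc$dur_ms / 1000
    env <- ifelse(t_rel >= 0 & t_rel < dur,
                  0.5 * (1 - cos(2 * pi * t_rel / dur)), 0)
    carrier <- sin(2 * pi * p$osc$freq * t_rel)
    osc <- og * outer(sk, env * carrier)
    total <- total + osc
  }
  list(csd = total, by_layer = by_layer, lateral = lateral, osc = osc)
}

# Double spatial integration of a designed CSD (channels x samples) into an
# LFP profile; integration constants removed as a per-sample affine depth
# trend (the CSD operator annihilates affine profiles, so this is the
# canonical representative).
.csd_to_lfp <- function(csd, dz) {
  n <- nrow(csd)
  theta <- matrix(0, n, ncol(csd))
  for (ch in 2:(n - 1L))
    theta[ch + 1L, ] <- 2 * theta[ch, ] - theta[ch - 1L, ] + csd[ch, ] * dz^2
  X <- cbind(1, seq_len(n))
  Q <- qr.Q(qr(X))
  theta - Q %*% crossprod(Q, theta)
}

#' Generate a tone-evoked laminar recording
#'
#' For each tone frequency and trial, the noise-free design of
#' [evoked_design()] plus white Gaussian noise (SD `params$noise_sd`, CSD
#' units) is either returned directly as a CSD array (`emit = "csd"`) or
#' double-integrated along depth into an LFP recording (`emit = "lfp"`,
#' the default), which is what the estimation pipeline consumes.
#'
#' @param params a [synth_params()] object.
#' @param freqs tone frequencies (Hz); default the 8-tone, octave-spaced
#'   series 250 Hz - 32 kHz.
#' @param n_trials_per_freq trials per tone.
#' @param condition `"pre"` or `"post"`.
#' @param seed integer seed (trials are independent given the seed).
#' @param emit `"lfp"` for a [laminar_recording()], `"csd"` for a
#'   `csd_profile` of the designed (noisy) CSD.
#' @param subject_id subject label.
#' @return A [laminar_recording()] or `csd_profile` with per-trial
#'   `stim_freq` metadata.
#' @export
generate_evoked <- function(params, freqs = 250 * 2^(0:7),
                            n_trials_per_freq = 5L,
                            condition = c("pre", "post"), seed = 1L,
                            emit = c("lfp", "csd"), subject_id = "s01") {
  condition <- match.arg(condition)
  emit <- match.arg(emit)
  validate_synth_params(params)
  if (length(freqs) == 0L) stop("freqs must be nonempty", call. = FALSE)
  set.seed(seed)
  p <- params
  n_trials <- length(freqs) * n_trials_per_freq
  out <- array(0, c(n_trials, p$n_channels, p$n_samples))
  stim <- rep(freqs, each = n_trials_per_freq)
  designs <- lapply(freqs, function(f) evoked_design(p, f, condition)$csd)
  names(designs) <- as.character(freqs)
  lat_sd <- p$trial_jitter$latency_sd_ms
  amp_sd <- p$trial_jitter$gain_sd
  for (tr in seq_len(n_trials)) {
    csd <- designs[[as.character(stim[tr])]]
    if (amp_sd > 0) csd <- csd * exp(stats::rnorm(1, 0, amp_sd))
    if (lat_sd > 0) {
      # common latency shift of the whole columnar response, in samples
      sh <- as.integer(round(stats::rnorm(1, 0, lat_sd) * p$fs / 1000))
      if (sh != 0) {
        shifted <- matrix(0, nrow(csd), ncol(csd))
        src <- seq_len(ncol(csd)) - sh
        ok <- src >= 1 & src <= ncol(csd)
        shifted[, which(ok)] <- csd[, src[ok]]
        csd <- shifted
      }
    }
    if (p$noise_sd > 0)
      csd <- csd + matrix(stats::rnorm(length(csd), 0, p$noise_sd),
                          nrow(csd), ncol(csd))
    out[tr, , ] <- if (emit == "lfp") .csd_to_lfp(csd, p$dz) else csd
  }
  if (emit == "lfp")
    return(laminar_recording(out, fs = p$fs, dz = p$dz, condition = condition,
                             subject_id = subject_id, stim_freq = stim,
                             stim_onset = p$stim_onset))
  as_csd_profile(out, fs = p$fs, dz = p$dz, condition = condition,
                 subject_id = subject_id, stim_freq = stim,
                 stim_onset = p$stim_onset)
}

# Poisson event onsets with a minimum separation enforced by thinning
# (later event dropped). The kept process is a renewal process with mean
# interval min_sep + 1/rate, so the observed rate is rate/(1 + rate*min_sep).
.sample_onsets <- function(rate, duration, min_sep_s, margin_s = 0.5) {
  if (rate <= 0) return(numeric(0))
  horizon <- duration - margin_s
  if (horizon <= 0) return(numeric(0))
  if (rate * min_sep_s > 20)
    stop("parameter error: rate and minimum separation are inconsistent",
         call. = FALSE)
  n <- stats::rpois(1L, rate * horizon)
  if (n == 0L) return(numeric(0))
  t0 <- sort(stats::runif(n, 0, horizon))
  kept <- t0[1L]
  last <- t0[1L]
  for (ti in t0[-1L]) {
    if (ti - last > min_sep_s) { kept <- c(kept, ti); last <- ti }
  }
  kept
}

#' Generate a spontaneous laminar recording with ground-truth events
#'
#' Spontaneous columnar events are drawn from a Poisson process at the
#' condition's rate with a minimum separation (> 150 ms) enforced by
#' thinning (the later event is dropped, so the realized rate is
#' `rate / (1 + rate * min_sep)`). Each event is a translaminar kernel
#' sequence initiated in layer Vb (granular and supragranular layers
#' follow), with per-event lognormal amplitude jitter, an unbalanced
#' lateral component, and the condition's amplitude and duration scaling.
#' Returns the true event times for detector validation.
#'
#' @param params a [synth_params()] object.
#' @param duration recording duration in seconds (> 0).
#' @param condition `"pre"` or `"post"`.
#' @param seed integer seed.
#' @param emit `"lfp"` or `"csd"` as in [generate_evoked()].
#' @param subject_id subject label.
#' @return list with `recording` (single-trial [laminar_recording()] or
#'   `csd_profile`) and `events`
#'   (`data.frame(onset_s, peak_s, amplitude)`).
#' @export
generate_spontaneous <- function(params, duration, condition = c("pre", "post"),
                                 seed = 1L, emit = c("lfp", "csd"),
                                 subject_id = "s01") {
  condition <- match.arg(condition)
  emit <- match.arg(emit)
  validate_synth_params(params)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  set.seed(seed)
  p <- params
  n_s <- as.integer(round(duration * p$fs))
  n_ch <- p$n_channels
  rate <- p$sce$rate[[condition]]
  onsets <- .sample_onsets(rate, duration, p$sce$min_sep_ms / 1000)
  csd <- matrix(0, n_ch, n_s)
  ev_len <- as.integer(round(0.4 * p$fs))   # 400-ms event support
  amp0 <- p$sce$amp[[condition]]
  dsc <- p$sce$dur_scale[[condition]]
  # per-layer building blocks of one unit event
  kernels <- lapply(.synth_layers, function(nm) {
    sk <- .spatial_kernel(p$layer_map[[nm]], n_ch, .source_asym[[nm]])
    tk <- .temporal_kernel(ev_len, p$fs, p$sce$latency_ms[nm], p$kernel,
                           dur_scale = dsc)
    outer(sk, tk)
  })
  unit_event <- Reduce(`+`, kernels)
  lat_ev <- p$sce$lateral[[condition]] *
    outer(.lateral_kernel(n_ch),
          .temporal_kernel(ev_len, p$fs, 15, p$kernel, dur_scale = dsc))
  amps <- amp0 * exp(stats::rnorm(length(onsets), 0, 0.2))
  for (ei in seq_along(onsets)) {
    i0 <- as.integer(round(onsets[ei] * p$fs)) + 1L
    idx <- i0:min(i0 + ev_len - 1L, n_s)
    csd[, idx] <- csd[, idx] + amps[ei] * unit_event[, seq_along(idx)] +
      lat_ev[, seq_along(idx)]
  }
  if (p$noise_sd > 0)
    csd <- csd + matrix(stats::rnorm(length(csd), 0, p$noise_sd), n_ch, n_s)
  # peak offset of the unit event's AVREC, for detector matching
  peak_off <- (which.max(colMeans(abs(unit_event))) - 1L) / p$fs
  events <- data.frame(onset_s = onsets, peak_s = onsets + peak_off,
                       amplitude = amps)
  arr <- array(0, c(1L, n_ch, n_s))
  if (emit == "lfp") {
    arr[1L, , ] <- .csd_to_lfp(csd, p$dz)
    rec <- laminar_recording(arr, fs = p$fs, dz = p$dz, condition = condition,
                             subject_id = subject_id)
  } else {
    arr[1L, , ] <- csd
    rec <- as_csd_profile(arr, fs = p$fs, dz = p$dz, condition = condition,
                          subject_id = subject_id)
  }
  list(recording = rec, events = events)
}

#' Generate stationary VAR layer traces with known coupling
#'
#' Simulates `n_trials` independent realizations of a stable VAR(p) with
#' the given coefficient tensor and innovation covariance, discarding a
#' 500-sample burn-in. The ground-truth directed edge set
#' `{(j -> i) : any coupling[i, j, ] != 0, i != j}` is attached as
#' attribute `truth_edges`.
#'
#' @param coupling `k x k x p` coefficient tensor (companion spectral
#'   radius < 1).
#' @param noise_cov `k x k` positive-definite innovation covariance.
#' @param n_trials,n_samples output dimensions.
#' @param seed integer seed.
#' @return Array `n_trials x k x n_samples` with layer dimnames taken from
#'   `coupling`, and attribute `truth_edges` (logical `k x k`,
#'   `[i, j]` = edge j -> i).
#' @export
generate_var_traces <- function(coupling, noise_cov, n_trials, n_samples,
                                seed = 1L) {
  k <- dim(coupling)[1]; p <- dim(coupling)[3]
  sr <- .companion_radius(coupling)
  if (sr >= 1)
    stop("parameter error: unstable coupling (spectral radius ",
         round(sr, 3), ")", call. = FALSE)
  L <- tryCatch(chol(noise_cov), error = function(e)
    stop("parameter error: noise covariance not positive definite",
         call. = FALSE))
  set.seed(seed)
  burn <- 500L
  total <- n_samples + burn
  out <- array(0, c(n_trials, k, n_samples),
               dimnames = list(NULL, dimnames(coupling)[[1]], NULL))
  for (tr in seq_len(n_trials)) {
    x <- matrix(0, k, total)
    z <- t(L) %*% matrix(stats::rnorm(k * total), k, total)
    for (t in (p + 1L):total) {
      acc <- z[, t]
      for (l in seq_len(p)) acc <- acc + coupling[, , l] %*% x[, t - l]
      x[, t] <- acc
    }
    out[tr, , ] <- x[, (burn + 1L):total]
  }
  truth <- matrix(FALSE, k, k, dimnames = dimnames(coupling)[1:2])
  for (i in seq_len(k)) for (j in seq_len(k))
    if (i != j && any(coupling[i, j, ] != 0)) truth[i, j] <- TRUE
  attr(out, "truth_edges") <- truth
  out
}
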