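---
title: "Laminar CSD analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar CSD analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamcsd)
```

## What this package computes

`lamcsd` analyses multi-trial laminar local field potential (LFP)
recordings from linear multielectrode penetrations of sensory cortex —
the standard preparation for studying how a cortical column distributes
synaptic activity across its layers. The pipeline has five analysis
stages and one synthesis stage:

1. **Current-source density (CSD)**: the one-dimensional second spatial
   derivative of the LFP along depth,
   $\mathrm{CSD}(z) \approx \frac{\theta(z+n\Delta z) - 2\theta(z) +
   \theta(z-n\Delta z)}{(n\Delta z)^2},$
   which localizes transmembrane current sinks (influx, plotted negative)
   and sources (return currents). Columnar summary measures are the
   averaged rectified CSD, $\mathrm{AVREC}(t) = \sum_i |CSD_i(t)|/n$, and
   the relative residual, $\mathrm{RelRes}(t) = \sum_i CSD_i(t) /
   \sum_i |CSD_i(t)|$, whose departure from zero indexes charge imbalance
   attributable to lateral, cross-columnar synaptic input.
2. **Frequency tuning**: response detection (2 baseline SD sustained for
   more than 5 ms), best frequency (granular-layer RMS argmax), octave
   binning around the best frequency, Q40dB bandwidth, and the layer
   symmetry index $\mathrm{LSI} = (\mathrm{I/II} - \mathrm{Vb}) /
   (\mathrm{I/II} + \mathrm{Vb})$.
3. **Spontaneous columnar events (SCE)**: peaks of the single-trial AVREC
   exceeding the trace median by 3 SD, separated by at least 150 ms.
4. **Multitaper spectra**: evoked (complex trial averaging before power)
   and spontaneous (power before averaging) spectra with 5 Slepian tapers
   on 600-ms epochs (time-bandwidth product 3, no padding), normalized to
   unit sum over 1–100 Hz, compared per frequency bin with paired t
   statistics under Benjamini–Hochberg control (Q = 0.1).
5. **Conditional Granger causality (GC)**: for layer traces
   $X_1,\dots,X_k$, the causality of $j$ on $i$ given the rest is
   $F_{j \to i \mid \cdot} = \ln\big(\mathrm{var}(\varepsilon_i') /
   \mathrm{var}(\varepsilon_i)\big)$, the log ratio of the target's
   residual variance in a reduced model omitting $j$ versus the full
   vector autoregression (VAR). Group contrasts use paired t tests on
   $\ln F$ with Benjamini–Hochberg control at Q = 0.05 over the 12
   directed edges.

The synthesis stage (`synth_params()`, `generate_evoked()`,
`generate_spontaneous()`, `generate_var_traces()`, `hyase_effect()`)
produces recordings with known ground truth so that every stage above is
testable end to end.

## The CSD estimator

The estimator follows the classical second-difference scheme on a
2 kHz / 32-channel / 50-µm grid. Two numerical choices matter:

* **Spatial smoothing.** The LFP profile is smoothed along depth with a
  7-channel Hamming window (a 300-µm kernel) before differencing.
  Because the differentiation grid and the smoothing kernel set the same
  spatial scale, the differentiation grid defaults to `grid_n = 1`;
  both are configurable.
* **Boundary policy.** Both smoothing and differencing first extend the
  profile by 4 virtual channels on each end, linearly extrapolated from
  the outermost channel pair (the minimal reading of a linear
  extrapolation rule; a least-squares line through two points is the
  line through them). Every recorded channel therefore receives a CSD
  estimate; the extrapolation is exact for locally affine profiles and
  the operator annihilates affine depth profiles identically.

AVREC and RelRes are computed from the CSD of the *unsmoothed*
single-trial LFP: smoothing redistributes charge along depth and would
bias the residual ratio. Layer-resolved RMS amplitudes and onset
latencies use the smoothed CSD. Both paths share `compute_csd()`
(`window_len = NULL` disables smoothing).

Layer RMS is computed per channel over the analysis window and then
averaged across the layer's channels. The two orders of operations
differ (for channels carrying +c and −c, channel-wise RMS averages to
|c| while the layer-average trace is 0); the channel-wise-first
convention is used everywhere.

## Layer maps are configuration

Layers are assigned by the analyst, not inferred: `default_layer_map()`
encodes a documented convention for a 32-channel probe — I/II 1–6,
III/IV 10–15, Vb 18–23, VI 26–30 — with the channels between ranges
treated as laminar transition zones. Those zones are deliberately left
unassigned: the borders carry the return currents of both neighbouring
layers, so their laminar attribution is ambiguous, and excluding them
keeps layer-averaged traces interpretable. The deepest channels are
presumptive white matter. Any range can be overridden per penetration
(`config =`), which is the expected workflow when the sink pattern says
the probe sits deeper or shallower than the convention assumes.

## Onset latency and response detection

A single threshold rule serves both response detection and latency
estimation: a deviation beyond `k_sd = 2` baseline standard deviations
sustained for more than 5 ms. For latencies the rule is applied
one-sidedly (sinks are negative) to the trial-averaged, layer-averaged
CSD, with the baseline taken from the final 100–200 ms of the
pre-stimulus period. Whether the latency criterion should differ from
the detection criterion is not determinable from first principles; using
one implementation for both is the package's documented choice, and the
factor and duration are arguments.

## Electrode stability

`stability_xcorr()` reduces each condition to a depth profile (mean CSD
over the first 50 ms post onset, averaged over trials) and Pearson
cross-correlates the profiles over integer channel shifts (default ±5
channels, i.e. ±250 µm). A stable penetration with purely amplitude
changes peaks at lag 0; a mechanical displacement shows up as a shifted
peak. `scripts/acceptance.R` reruns exactly this check on a synthetic
pair whose only difference is per-layer amplitude rescaling.

## Multitaper choices

Tapers are discrete prolate spheroidal sequences computed from the
standard symmetric tridiagonal eigenproblem; with a 600-ms epoch and
NW = 3 the half-bandwidth is W = 5 Hz and the grid spacing
1/0.6 s ≈ 1.667 Hz (no padding). Two averaging orders are exposed
deliberately:

* `evoked_spectrum()` averages the complex spectra across trials within
  each taper before squaring — non-phase-locked energy cancels.
* `spontaneous_spectrum()` averages power per trial and taper — it
  retains induced (non-phase-locked) energy. By the triangle inequality
  the evoked estimate never exceeds the total-power estimate bin-wise.

The per-bin group statistic is a paired t across subjects on the
normalized power (sign convention: negative t means more power in the
post condition). An alternative that pools subject × taper samples would
inflate the effective n and is not offered.

## Granger causality: fitting and the reduced model

The full VAR is fit by pooled least squares across trials: each trial is
demeaned per series and lagged regressors never cross trial boundaries.
The model order is selected by AIC with all candidate orders scored on a
common effective sample (so likelihood ratios between orders are
properly nested); the default ceiling is 20 lags (10 ms at 2 kHz).
Stationarity is addressed as in standard practice for slow CSD traces:
first differencing followed by an augmented Dickey–Fuller check per
series (constant + trend regression, p-values interpolated from the
published Dickey–Fuller response-surface table). A series that still
fails is flagged, not fatal; an optional second differencing exists but
single differencing is the default protocol.

The reduced model for edge $j \to i$ is *not* refit to data. The
autocovariance sequence implied by the fitted full model is computed
(companion-form Lyapunov equation solved by a doubling iteration, then
the Yule–Walker recursion, to `max(4p, 40)` lags), the sub-block for the
retained series is extracted, and the reduced VAR solves the
block-Toeplitz Yule–Walker system of the same order p as the full model.
Using the same order keeps the full/reduced pair interpretable as the
classical two-regression construction, and makes the estimate
numerically equivalent (to ~1e-3 and better on the scales tested) to
direct OLS refits of the reduced regression — an equivalence the test
suite checks edge by edge against an independent OLS oracle. Omitting
nothing reproduces the full model's residual variance exactly, because
the model-implied autocovariance satisfies the model's own Yule–Walker
relations.

Negative causality estimates, a finite-sample artifact, are clipped to
zero and flagged; clipped values are excluded pairwise from log-domain
group tests, and edges left with fewer than 3 usable pairs are reported
untestable rather than silently dropped.

## The synthetic generator: what it emulates

The generator is phenomenological, not biophysical. Each layer
contributes a spatial kernel times a temporal kernel:

* **Spatial**: a Gaussian sink confined to the layer's channel range,
  flanked by two tight return-source lobes straddling the layer borders.
  The profile sums to zero across the column exactly, so a single-column
  event leaves RelRes at machine zero — which is what makes the
  unbalanced "lateral input" kernel (a supragranular sink whose return
  currents lie outside the recorded cylinder) informative. The
  superficial/deep split of the return charge is layer-dependent
  (granular cells return current mostly above the sink, supragranular
  synapses mostly at the soma below), which keeps each layer's own sink
  visible in its layer-averaged trace.
* **Temporal**: a smoothed biphasic transient (≈5 ms rise, ≈30 ms decay,
  with a slower rebound of opposite sign), delayed by the layer's onset
  latency. Defaults are III/IV ≈ Vb ≈ 20 ms (afferent thalamocortical
  input) and I/II ≈ 30 ms, VI ≈ 35 ms (intracortical relay) — the
  ordering is the modeled fact; the exact values are presets.

Tone trials scale each kernel by the layer gain and a Gaussian tuning
factor in octave distance from the best frequency (default width 1.5
octaves over the 8-tone, octave-spaced 250 Hz–32 kHz series). Trials
receive a common lognormal amplitude factor (σ = 0.15) and a common
latency shift (SD 1.5 ms) — ubiquitous features of evoked responses that
give single-subject spectra realistic sampling variance — plus white
CSD-domain noise (SD 0.1 relative to a unit sink). The LFP is produced
by double spatial integration of the designed CSD, so the analysis
pipeline, not the generator, is what recovers the pattern; a `csd` emit
mode bypasses integration for unit tests.

`hyase_effect()` writes the treated-cortex fingerprint into the
post-condition slots: Vb gain × 0.6, I/II gain × 1.2 (a moderate,
sub-significance increase), lateral gain and width doubled, a 30.5-Hz
phase-locked oscillation (Hann envelope over the 600-ms evoked epoch,
amplitude 0.04) added to layer Vb, spontaneous event rate × 0.6,
amplitude × 0.7, duration × 0.6, and the directed coupling rebalanced
(I/II→VI and VI→Vb strengthened from 0.12 to 0.40, Vb→III/IV weakened
from 0.40 to 0.12). With these presets the population LSI sits near
+0.2 before and above +0.4 (at best-frequency stimulation) after
treatment, which is the calibration the generator is built to.

The VAR preset for layer-trace dynamics carries exactly the three
directed edges that the treatment modifies, plus within-layer AR(2)
terms. This is a deliberate design restriction: any additional fixed
cross-edge would let condition-dependent variance propagate into a
nominally untouched edge and shift its causality estimate for reasons
unrelated to the detection method under test.

Spontaneous events are drawn from a Poisson process thinned to a minimum
separation of 150 ms (the later event is dropped), so the realized rate
is $\lambda / (1 + \lambda\,\tau_{\min})$ — the correction used by the
rate-recovery tests. Each event is a translaminar kernel sequence led by
layer Vb (III/IV at +10 ms, I/II and VI at +20 ms), with lognormal
amplitude jitter and an unbalanced lateral component.

### What the generator does not emulate

No volume-conductor forward model, no spikes, no 1/f background, no
slow anesthesia state drift within a session, no tonotopic gradient
along the probe, and no truly laminar-continuous sources — kernels are
low-dimensional and the layer map used for analysis coincides with the
one used for synthesis. Passing tests therefore demonstrate that the
estimators recover the structure they are defined on, with correct
calibration under realistic noise; they do not certify performance on
real recordings, where layer assignment, electrode drift and
non-stationarity are harder.

## Paired-design conventions in the tests

Group-level checks simulate 9 subjects. Subject identity is a lognormal
gain jitter (σ = 0.1), latency jitter (SD 2 ms) and kernel-shape jitter
(σ = 0.1) applied to both conditions of a pair, so treatment ratios are
preserved within subject; each recording session additionally receives a
smaller independent jitter (gains σ = 0.05, latency SD 2 ms, shape
σ = 0.15), reflecting that the two conditions are recorded hours apart.
Spectral layer traces are taken from the unsmoothed CSD: layer averaging
already integrates over ~6 channels, and smoothing first would smear
each layer's content into its neighbours' ranges. The spectral
fingerprint check asks the precise layer-specific question the analysis
is designed for: significant beta-band (25–36 Hz) bins must appear in
layer Vb and in no other layer. Broadband normalized-power differences
between conditions do occur outside that band — gain changes alter the
mixing ratios of kernel components with different latencies, and
normalization couples all bins — and are an acknowledged property of the
generator rather than of the method.

Problem sizes used by the end-to-end checks — 9 subjects, 8 tones × 6
trials for tuning, 24 s of spontaneous data per condition, 10 trials ×
600 samples for each subject's VAR, 20 seeded replicates with
majority-vote criteria — were chosen as the smallest sizes at which the
paired effects are comfortably resolved by the statistics involved.

## Known limitations

* The second-difference estimator is the classical one; no inverse
  methods (iCSD/kCSD) are provided, so conductivity inhomogeneities and
  finite-diameter effects are not modeled.
* The Q40dB bandwidth counts supra-threshold frequencies globally rather
  than requiring contiguity around the best frequency; the readings
  coincide for unimodal tuning, which the generator guarantees.
* SCE duration is defined as the width of the supra-threshold excursion
  containing the peak — a package definition, since duration has no
  canonical definition in this analysis tradition.
* The ADF p-value is interpolated from the standard response-surface
  table and clamped to [0.01, 0.99]; it is a diagnostic flag here, not
  an inferential endpoint.
* Repeated-measures ANOVA tables for layer × frequency designs are out
  of scope; `layer_rms()` output (layers × trials) is already tidy
  enough to feed any standard rmANOVA routine.
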