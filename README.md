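# lamcsd

Laminar current-source density (CSD), spectral, and Granger-causality
analysis of cortical multielectrode recordings — plus a ground-truth
synthetic generator that makes the whole pipeline testable end to end.

## The problem

Linear multichannel probes inserted perpendicular to the cortical surface
record the local field potential (LFP) at tens of depths spanning all
cortical layers. The scientific questions asked of such recordings are
laminar: which layers receive early afferent input, how strongly, how is
columnar activity balanced between supragranular and infragranular
circuits, what oscillatory structure does each layer carry, and which
layer drives which. `lamcsd` is for electrophysiologists running paired
designs on such data — for example comparing a cortical column before and
after a pharmacological manipulation — who need the standard laminar
toolchain in one tested package.

## The methods

**CSD.** The one-dimensional second spatial derivative of the LFP,

    CSD(z) ≈ [θ(z + nΔz) − 2 θ(z) + θ(z − nΔz)] / (nΔz)²,

computed after 7-channel Hamming smoothing along depth, with a 4-channel
linear boundary extrapolation so every contact gets an estimate. Sinks
(current influx, synaptic depolarization) are negative. Columnar
summaries per time point: the averaged rectified CSD,
`AVREC = Σᵢ|CSDᵢ|/n` (overall current flow), and the relative residual,
`RelRes = ΣᵢCSDᵢ / Σᵢ|CSDᵢ|` (charge imbalance, an index of lateral
cross-columnar input), both computed on unsmoothed single-trial CSD.

**Tuning.** Response detection (2 baseline SD sustained > 5 ms), best
frequency (granular-layer RMS argmax), octave-distance binning, Q40dB
bandwidth, and the layer symmetry index
`LSI = (I/II − Vb)/(I/II + Vb)`.

**Spontaneous events.** AVREC peaks over median + 3 SD with ≥ 150 ms
separation, with rates, amplitudes, durations and per-trace RMS tables.

**Spectra.** Multitaper estimates (5 Slepian tapers, 600-ms epochs,
NW = 3, no padding, 1–100 Hz, unit-sum normalization); evoked spectra
average complex spectra across trials before squaring, spontaneous
spectra average power. Per-bin paired t statistics across subjects with
Benjamini–Hochberg FDR control.

**Granger causality.** Pairwise-conditional time-domain GC between layer
CSD traces: a pooled multi-trial VAR (AIC order selection, first
differencing with ADF diagnostics), reduced models derived from the
full model's autocovariance sequence via block-Toeplitz Yule–Walker
solves, `F(j→i|rest) = ln(var ε′ᵢ / var εᵢ)`, and paired-t /
FDR-corrected group comparison of the 12 directed edges.

**Synthesis.** `synth_params()` + `generate_evoked()` /
`generate_spontaneous()` / `generate_var_traces()` produce recordings
with known layer gains, latencies, tuning, event statistics, and
directed VAR coupling; `hyase_effect()` encodes an
extracellular-matrix-digestion treatment fingerprint (reduced
infragranular Vb input, moderately increased supragranular flow, added
beta-band oscillation in Vb, fewer/shorter spontaneous events,
rebalanced translaminar drive) for paired-design testing.

## Worked example

```r
library(lamcsd)

params <- hyase_effect(synth_params())     # pre + treated-post presets
map <- default_layer_map(32)

pre  <- generate_evoked(params, n_trials_per_freq = 6,
                        condition = "pre",  seed = 42)
post <- generate_evoked(params, n_trials_per_freq = 6,
                        condition = "post", seed = 43)

csd_pre  <- compute_csd(pre)               # smoothed path
csd_post <- compute_csd(post)

tone <- 401:800                            # 200-ms tone period
rms_pre  <- rowMeans(layer_rms(csd_pre,  map, tone)[, pre$stim_freq  == 2000])
rms_post <- rowMeans(layer_rms(csd_post, map, tone)[, post$stim_freq == 2000])
round(rbind(pre = rms_pre, post = rms_post), 4)
#>        I/II III/IV     Vb     VI
#> pre  0.1799 0.2076 0.1146 0.0911
#> post 0.3038 0.2347 0.0889 0.0987

lsi(rms_pre["I/II"], rms_pre["Vb"])        # 0.221
lsi(rms_post["I/II"], rms_post["Vb"])      # 0.547

onset_latency(csd_pre, map, baseline = 201:400)
#>    layer latency_ms detected
#> 1   I/II       30.0     TRUE
#> 2 III/IV       18.5     TRUE
#> 3     Vb       19.5     TRUE
#> 4     VI       35.0     TRUE

stability_xcorr(csd_pre, csd_post, 401:500)$peak_lag
#> [1] 0
```

Reading: at best-frequency stimulation the treated column loses early
infragranular Vb current flow (RMS 0.115 → 0.089) and gains
supragranular flow (0.180 → 0.304), shifting the layer symmetry index
from ≈ +0.2 to ≈ +0.5 — a supragranular-dominated columnar profile —
while the afferent layers III/IV and Vb keep their short (~20 ms) onset
latencies and the electrode-stability cross-correlogram peaks at zero
channel shift (amplitude changes, no displacement). Spontaneous
activity: `detect_sce()` on a 30-s pre-condition trace recovers 28/28
ground-truth events (rate 0.93 events/s).

## Layout

- `R/` — recording container and layer maps, CSD and columnar measures,
  tuning, SCE detection, multitaper spectra, VAR/GC, shared statistics,
  synthetic generator.
- `tests/testthat/` — unit, property, and end-to-end suites (all fixtures
  generated in code).
- `vignettes/laminar-csd-analysis.Rmd` — the methods vignette: models,
  parameter choices, generator design, limitations.
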