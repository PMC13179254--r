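---
title: "Gastric band-power analysis and biofeedback: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gastric band-power analysis and biofeedback: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastroEGG)
```

## The measurement problem

Cutaneous electrogastrography records the stomach's slow myoelectrical
rhythm from abdominal electrodes. The signal of interest lives between 1 and
10 cycles per minute (0.016–0.16 Hz), orders of magnitude below the
acquisition rate of a typical 1000 Hz, 16-bit biosignal amplifier, and is
buried under electrode drift, motion artifact and broadband noise. The
quantity clinicians and biofeedback paradigms work with is not the raw
voltage but the *distribution of spectral power* across three bands:
bradygastria (1–2 cpm), normogastria (2–4 cpm, centred on the normal 3 cpm
pacemaker rhythm) and tachygastria (4–10 cpm), each as a percentage of total
1–10 cpm power.

`gastroEGG` implements this computation twice, deliberately: an *offline*
pipeline for resting recordings, where non-causal (zero-phase) filtering is
allowed and the whole recording forms one spectral estimate; and a *causal
streaming* engine, where every feedback frame may use only samples from the
past, as a live biofeedback display must.

## The offline pipeline

`analyze_recording()` composes five stages:

1. **Downsampling to 10 Hz.** Decimation is preceded by an 8th-order
   Butterworth low-pass at 0.8× the target Nyquist frequency, so that mains
   and motion energy above 5 Hz cannot fold into the gastric band. A 100×
   rate reduction in one step would put the filter's normalized cutoff at
   0.008, where the transfer-function form of an 8th-order Butterworth is
   numerically ill-conditioned (we measured a passband gain error of 9% at
   0.05 Hz); decimation therefore proceeds in cascaded stages of at most 10×
   each (1000 → 100 → 10 Hz), each stage with its own anti-alias filter.
   With zero-phase application the stopband attenuation doubles; a 6 Hz tone
   survives 1000 → 10 Hz decimation at 0.13% of its amplitude. Tones just
   above the target Nyquist (within ~10% of 5 Hz) are attenuated by ~30 dB
   rather than 40 dB — they alias to just below Nyquist, far outside the
   gastric band, so they cannot bias band percentages.
2. **Linear detrending.** A least-squares straight line is removed. First
   -order detrending suffices for slow electrode drift and, unlike high-order
   polynomial or moving-average detrending, cannot eat into 1 cpm content.
3. **Butterworth bandpass, 0.016–0.16 Hz.** 4th order, applied forward then
   backward (`signal::filtfilt`), so the passband is effectively 8th order
   with exactly zero phase shift. Passband gain at 0.05 Hz is within 0.1% of
   unity; a 0.5 Hz tone is attenuated by more than 20 dB; DC is removed.
   The detrend → bandpass stage order is the offline default and is exposed
   as the `stage_order` argument, since the reverse order is equally
   defensible (and is what the streaming path uses); for stationary signals
   the two differ negligibly.
4. **Hann window, zero-padding, FFT.** The windowed signal is padded to the
   next power of 2 and transformed; squared magnitudes are scaled to a
   one-sided density with the window's power normalization
   (`fs · Σw²`). Only *ratios* of band power enter the output, so the
   scaling convention is immaterial to percentages — a property the test
   suite asserts by scaling inputs 50-fold.
5. **Band integration.** Power is integrated per band by the trapezoidal
   rule over the bins whose centre frequency falls in the band. Band edges
   at exactly 2 and 4 cpm are assigned half-open, `[lo, hi)`, with the last
   band closed at 10 cpm, so the three bands tile 1–10 cpm without double
   counting. The total is the sum over 1–10 cpm only; energy outside the
   gastric range never enters the denominator. A recording with zero
   in-range power raises a classed error rather than returning percentages
   of nothing.

A 15-minute recording — the standard rest-measurement length — yields 9000
samples at 10 Hz, padded to 16384 points: a frequency resolution of
0.037 cpm, ample for the 1 cpm-wide bradygastric band.

## The streaming engine

`stream_process()` reproduces the offline quantities causally. The input is
decimated with *single-pass* anti-alias filters and bandpassed with a
*single-pass* Butterworth (the zero-phase variant would need future
samples), then three feedback channels are computed per hop:

- **Pacemaker** — a raised cosine `(1 − cos(2π·cpm·t/60))/2` at 3 cpm: a
  reference sphere filling and draining every 20 s, independent of the
  participant.
- **Direct feedback** — the newest bandpassed sample mapped to [0, 1] by
  min–max normalization over the trailing 60 s. This self-calibrates across
  participants and electrode gains without any per-participant setup; a flat
  window (dead channel) maps to the neutral 0.5. Whether the original
  paradigm normalized per participant, per session or with fixed gain is not
  determinable, so the trailing-window horizon is a configuration field.
- **Dimensional FFT feedback** — the trailing analysis window is detrended,
  Hann-windowed and transformed exactly as offline, and the normogastric
  fraction drives four environment parameters linearly:
  `cloud_density = 1 − x`, `water_clarity = x`, `wind_gain = 1 − x`,
  `water_sound_gain = 0.25 + 0.75·x`. The forms are linear defaults; the
  directionality (sunnier with higher normogastria) is the contract, and the
  sound floor of 0.25 keeps the scene audible even at zero normogastria.
  No temporal smoothing is applied to the fraction by default: the window
  average is already a heavy smoother, and additional exponential smoothing
  would be a second, confounded time constant.

**Window length.** Resolving the 1 cpm lower band edge requires at least a
60 s window. But the window also sets spectral leakage between bands: a
Hann window of length `T` has a main lobe extending `±2/T` Hz around a tone,
so at `T = 120` s a 1.5 cpm bradygastric tone leaks up to 2.5 cpm — about 5
points of its power land in the normogastric band, biasing the streamed
estimate relative to the offline one. At `T = 180` s the lobe half-width is
0.67 cpm and the cross-band leakage falls below 3 points, which is why 180 s
is the default `window_s`; at 240 s leakage is negligible but warm-up
consumes 40% of a 10-minute training block. The update cadence (`hop_s`,
default 1 s) only affects display smoothness, not the estimate.

Before the first full window, frames are flagged `warmed_up = FALSE`, the
normogastric fraction is undefined (`NA`) and the environment is held
neutral at 0.5 — showing a partial-spectrum estimate would give actively
misleading feedback during the first minutes.

**Causality** is a tested invariant: truncating the input at time `t` leaves
every emitted state up to `t − hop_s` bit-identical, so replaying a file is
equivalent to live operation.

## The synthetic-data generator

No public EGG recording ships with the package; `simulate_egg()` generates
test material from a transparent model: a sum of sinusoids at gastric
frequencies, linear drift, white Gaussian noise, and optional quantization
to integer ADC codes (0…2¹⁶−1 over the signal range, as the 16-bit
digitizer would emit). The sinusoid-mixture model was chosen over
autoregressive noise shaping because band targets become analytically
solvable: `simulate_scenario()` places one tone at the centre of each band
(1.5, 3, 7 cpm) with amplitude `√(target %)`, so power ratios match the
requested mixture by construction.

Scenario presets encode the expected ordering of gastric states across a
biofeedback session — `fasted` 40/35/25 (normo/brady/tachy), `post_water`
70/20/10, `fullness` 50/20/30 — low normogastria after fasting, a rise
after water intake and training, and a partial fall with elevated
tachygastria after drinking to fullness. These targets are *illustrative*
of that ordering, not published group means.

What the generator does **not** emulate: respiratory and cardiac artifact,
colonic co-activity overlapping the tachygastric band, nonstationary
frequency drift of the gastric rhythm, movement transients, and the
amplitude scale of real abdominal-surface recordings (samples carry an
arbitrary-unit scale factor in metadata; every pipeline quantity is
scale-invariant). Passing tests therefore demonstrate that the *computation*
is correct on signals with known ground truth — not that the pipeline is
robust to every artifact class of real recordings, which is what the
artifact flagger and visual inspection are for in practice.

## Session summaries and winsorization

`summarize_session()` applies the offline pipeline to the baseline (15 min),
training (10 min) and post (15 min) recordings of a session and reports the
successive differences (during − pre, post − during) per band — the
structure in which training effects are examined. The same offline pipeline
is used for all three timepoints (the streaming aggregate is available as an
alternative); group-level inference (mixed-effects models, post-hoc
contrasts, effect sizes) is out of scope and served by the tidy
`session_table()` export instead.

`winsorize_by_group()` implements the 3-SD outlier rule applied before
group statistics: values beyond `mean ± k·SD` of the group are set to the
boundary, with mean and SD computed *once* from the input. The operation is
intentionally not iterated, and is applied per band × timepoint × group
cell. Note the finite-sample geometry: a single outlier among `n` values can
be at most `(n−1)/√n` SDs from the mean, so with `n = 5` nothing can ever
exceed 3 SDs — the rule only bites in group-sized samples.

`artifact_flag()` replaces human visual inspection with two conservative
automated checks — windows with more than 1% of samples at the recording's
range extremes (ADC saturation), and sample-to-sample jumps beyond 6 robust
SDs (scaled MAD of the first difference; electrode pops). Both thresholds
are configurable defaults; the flagger never modifies data.

## Numerical choices and degenerate inputs

- Dominant-frequency ties resolve to the lower frequency, deterministically.
- A constant signal detrends to exactly zero; a zero signal yields an
  all-zero spectrum, and band percentages on it raise
  `egg_undefined_result_error` rather than `NaN`s.
- The streaming engine holds the environment neutral whenever the window's
  in-band power is zero, so environment parameters stay in [0, 1] for
  arbitrary inputs (tested against rail-to-rail, Cauchy-tailed and dead
  inputs).
- All randomness flows through a single integer seed; the generator restores
  the caller's RNG state, and fixed seeds give bit-identical recordings.
- Filtering uses `signal` (Butterworth design, `filtfilt`); spectra use
  `stats::fft`. The test suite cross-checks the whole windowed-FFT path
  against a brute-force O(n²) DFT oracle to 10⁻⁹ relative error per bin.

## Problem sizes in the test suite

Tests generate recordings of 120–900 s at 1000 Hz (or directly at the 10 Hz
analysis rate where only the spectral stages are exercised): long enough
that a 15-minute pipeline run, 20-seed parameter-recovery and
session-direction sweeps, and four streaming replays all execute in well
under a minute each. Spectral oracle comparisons use 700–1500-sample inputs
(padded to 1024/2048), the largest sizes at which a dense DFT matrix is
cheap.

## Known limitations

- The percent-of-total summary is blind to absolute amplitude; a flat-noise
  recording still sums to 100%. Check `total_power` and the artifact flags
  before interpreting percentages.
- Windowed-FFT band power cannot see wave-by-wave rhythm irregularities;
  cycle-detection methods are a complement, not implemented here.
- Single-channel only; multi-channel electrode arrays and propagation
  analysis are out of scope.
- The streaming normalization makes the direct-feedback sphere's excursion
  relative by design: it shows rhythm, not amplitude.
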