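# gastroEGG

Signal-processing tools for cutaneous electrogastrography (EGG) and gastric
biofeedback research.

The stomach's pacemaker cells (interstitial cells of Cajal) drive a slow
myoelectrical rhythm of about 3 cycles per minute (cpm) that can be recorded
non-invasively from abdominal surface electrodes. Clinically, spectral power
is summarized in three bands: bradygastria (1–2 cpm), normogastria (2–4 cpm)
and tachygastria (4–10 cpm), each expressed as a percentage of the total
1–10 cpm power. Biofeedback paradigms additionally need this computation in
real time, so that a participant can watch their own gastric rhythm and try
to steer it toward the normal 3 cpm.

`gastroEGG` provides, for researchers building or evaluating such paradigms:

- **`simulate_egg()` / `simulate_scenario()`** — a seeded synthetic EGG
  generator (sinusoid mixture + drift + noise + 16-bit ADC quantization) at
  the 1000 Hz acquisition rate, including scenario presets for the fasted,
  post-water and fullness gastric states with solvable band-power targets.
- **`analyze_recording()`** — the offline pipeline for rest recordings:
  anti-aliased downsampling to 10 Hz, linear detrending, zero-phase 4th-order
  Butterworth bandpass over 0.016–0.16 Hz, Hann-windowed FFT with zero-padding
  to the next power of 2, and percent power per gastric band,

  `pct_b = 100 · ∫_b P(f) df / ∫_{1–10 cpm} P(f) df`.
- **`stream_process()`** — a causal real-time engine emitting one feedback
  state per hop: a 3 cpm raised-cosine *pacemaker* fill, a *direct feedback*
  fill tracking the bandpassed signal (trailing min–max normalization), and
  *dimensional FFT feedback* mapping the normogastric power fraction of a
  sliding spectral window to environment parameters (cloud density, water
  clarity, wind and water sounds — sunnier weather when normogastria is high).
- **`summarize_session()` / `winsorize_by_group()`** — per-session
  baseline/training/post band-power summaries and the 3-SD group
  winsorization rule used before group statistics.
- **`read_recording()` / `write_recording()`** — plain delimited and
  OpenSignals-style (`#`-header) text recordings, plus a small CLI
  (`exec/gastroEGG`) with `simulate`, `analyze`, `stream` and `session`
  subcommands.

## Worked example

```r
library(gastroEGG)

rec <- simulate_scenario("post_water", duration_s = 600, seed = 7)
rec
#> <egg_recording> EGG(sim:post_water): 600000 samples @ 1000 Hz (600.0 s)

bp <- analyze_recording(rec)
bp
#> <band_power_summary> brady 19.9% | normo 70.7% | tachy 9.4% (total 1.56e+08)
attr(bp, "dominant_cpm")
#> [1] 3.00293
```

The `post_water` scenario targets 70/20/10 percent
normogastria/bradygastria/tachygastria; the analyzed summary lands within a
point of each target, and the dominant rhythm is the 3 cpm tone the scenario
placed at the centre of the normogastric band (the 0.003 cpm offset is one
frequency bin of the zero-padded FFT).

The same recording replayed through the real-time engine:

```r
st <- stream_process(rec, stream_config())
head(st[st$warmed_up, c("t", "pacemaker_fill", "user_fill",
                        "normo_fraction", "cloud_density")], 3)
#>       t pacemaker_fill user_fill normo_fraction cloud_density
#> 180 180     0.00000000 0.5078542      0.7266203     0.2733797
#> 181 181     0.02447174 0.6246571      0.7276580     0.2723420
#> 182 182     0.09549150 0.6774360      0.7286411     0.2713589
mean(st$normo_fraction[st$warmed_up])
#> [1] 0.7353135
```

One row per second: the pacemaker fill cycles at exactly 3 cpm, the user
sphere follows the participant's filtered EGG, and the streamed normogastric
fraction (73.5% on average here) agrees with the offline estimate to within a
few points. `cloud_density = 1 − normo_fraction`, so the sky clears as the
gastric rhythm normalizes.

From the shell:

```sh
gastroEGG simulate --scenario fasted --duration 900 --seed 1 --out baseline.txt
gastroEGG analyze --in baseline.txt
```

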