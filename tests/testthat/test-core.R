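test_that("cpm/Hz conversion is exact and rejects negative frequencies", {
  expect_equal(cpm_to_hz(3), 0.05)
  expect_equal(cpm_to_hz(0), 0)
  expect_equal(cpm_to_hz(60), 1)
  expect_equal(hz_to_cpm(0.05), 3)
  expect_error(cpm_to_hz(-1), class = "egg_domain_error")
  expect_error(hz_to_cpm(-0.1), class = "egg_domain_error")
  # duality: cpm axis is exactly 60x the Hz axis on a real spectrum
  sp <- egg_spectrum(tone_cpm(3, 120, 10), fs = 10)
  expect_identical(sp$freqs_cpm, sp$freqs_hz * 60)
})

test_that("canonical bands tile 1-10 cpm without overlap", {
  b <- gastric_bands()
  expect_identical(b$name, c("bradygastria", "normogastria", "tachygastria"))
  expect_equal(b$lo_cpm, c(1, 2, 4))
  expect_equal(b$hi_cpm, c(2, 4, 10))
  expect_equal(b$lo_cpm[-1], b$hi_cpm[-3]) # adjacent edges meet
})

test_that("downsampling preserves duration and in-band amplitude, rejects in-band aliases", {
  rec <- egg_recording(stats::rnorm(10 * 1000), fs = 1000)
  out <- downsample(rec, 10)
  expect_equal(out$fs, 10)
  expect_equal(length(out$samples), 100) # 10 s at 10 Hz

  # 0.05 Hz tone survives 1000 -> 10 Hz decimation within 1%
  slow <- egg_recording(tone_cpm(3, 120, 1000), fs = 1000)
  a <- fit_amplitude(downsample(slow, 10)$samples, 0.05, 10)
  expect_gt(a, 0.99)
  expect_lt(a, 1.01)

  # 6 Hz tone (above the 5 Hz target Nyquist) is suppressed to <= 1%
  fast <- egg_recording(sin(2 * pi * 6 * (0:(120 * 1000 - 1)) / 1000),
                        fs = 1000)
  ds <- downsample(fast, 10)$samples
  o <- oracle_psd(ds[101:1100], 10) # interior segment, away from edges
  expect_lt(sqrt(max(o$power)) / sqrt(max(oracle_psd(
    tone_cpm(3, 100, 10), 10)$power)), 0.01)

  expect_error(downsample(rec, 3), class = "egg_config_error") # 1000/3 not integer
  expect_error(downsample(rec, 2000), class = "egg_config_error")
})

test_that("linear detrending removes lines exactly and recovers a sinusoid on a ramp", {
  t <- seq(0, 10, by = 0.01)
  expect_lt(max(abs(detrend(5 + 2 * t))), 1e-9)
  expect_identical(detrend(numeric(100) + 0), numeric(100))
  expect_identical(detrend(rep(3.7, 50)), rep(0, 50))

  s <- sin(2 * pi * 0.5 * t)
  recovered <- detrend(s + 1.5 + 0.3 * t)
  # the ramp removal also strips the (tiny) line best fitting the sinusoid
  reference <- detrend(s)
  expect_lt(sqrt(mean((recovered - reference)^2)) / sqrt(mean(s^2)), 1e-6)

  expect_error(detrend(1), class = "egg_length_error")
})

test_that("gastric bandpass passes 0.05 Hz, rejects DC and out-of-band tones", {
  fs <- 10
  dur <- 900
  # DC rejection
  dc <- bandpass(rep(7, dur * fs), fs)
  expect_lt(max(abs(dc[(300 * fs):(600 * fs)])), 1e-3)
  # passband gain within 5% of unity
  a_pass <- fit_amplitude(bandpass(tone_cpm(3, dur, fs), fs), 0.05, fs)
  expect_gt(a_pass, 0.95)
  expect_lt(a_pass, 1.05)
  # 1 Hz stopband
  a_stop <- fit_amplitude(bandpass(sin(2 * pi * 1 * (0:(dur * fs - 1)) / fs),
                                   fs), 1, fs)
  expect_lt(a_stop, 0.1)
  # 0.5 Hz attenuated by >= 20 dB
  a_half <- fit_amplitude(bandpass(sin(2 * pi * 0.5 * (0:(dur * fs - 1)) / fs),
                                   fs), 0.5, fs)
  expect_lt(a_half, 10^(-20 / 20))
  # attenuation non-decreasing over 0.3, 0.5, 1.0 Hz
  atten <- vapply(c(0.3, 0.5, 1.0), function(f) {
    fit_amplitude(bandpass(sin(2 * pi * f * (0:(dur * fs - 1)) / fs), fs), f, fs)
  }, numeric(1))
  expect_true(all(diff(atten) <= 0))
  # zero-phase: 0.05 Hz peak positions shift by < 1 sample
  x <- tone_cpm(3, dur, fs)
  y <- bandpass(x, fs)
  mid <- (200 * fs):(700 * fs)
  px <- mid[which(diff(sign(diff(x[mid]))) == -2) + 1]
  py <- mid[which(diff(sign(diff(y[mid]))) == -2) + 1]
  shift <- vapply(px, function(p) min(abs(py - p)), numeric(1))
  expect_lt(max(shift), 1)

  expect_error(bandpass(x, fs = 0.2), class = "egg_config_error") # hi >= Nyquist
  expect_error(bandpass(x[1:10], fs), class = "egg_length_error")
})

test_that("Hann-windowed spectrum matches the brute-force DFT oracle bin by bin", {
  set.seed(11)
  for (n in c(700, 1500)) { # pad to 1024 and 2048
    x <- tone_cpm(3, n / 10, 10) + 0.3 * tone_cpm(7.3, n / 10, 10) +
      stats::rnorm(n, sd = 0.1)
    x <- x[1:n]
    sp <- egg_spectrum(x, 10)
    o <- oracle_psd(x, 10)
    expect_equal(sp$n_fft, 2^ceiling(log2(n)))
    expect_equal(sp$freqs_hz, o$freqs_hz)
    floor_p <- max(o$power) * 1e-12
    rel <- abs(sp$power - o$power) / pmax(o$power, floor_p)
    expect_lt(max(rel), 1e-9)
  }
})

test_that("spectrum locates pure tones and handles degenerate signals", {
  sp <- egg_spectrum(tone_cpm(3, 900, 10), fs = 10)
  bin <- diff(sp$freqs_hz[1:2])
  expect_lt(abs(sp$freqs_hz[which.max(sp$power)] - 0.05), bin + 1e-12)

  expect_true(all(egg_spectrum(rep(0, 512), 10)$power == 0))

  # two equal tones give two near-equal local maxima
  x <- tone_cpm(1.5, 900, 10) + tone_cpm(6, 900, 10) # 0.025 and 0.1 Hz
  sp2 <- egg_spectrum(x, 10)
  p1 <- max(sp2$power[abs(sp2$freqs_hz - 0.025) < 0.01])
  p2 <- max(sp2$power[abs(sp2$freqs_hz - 0.1) < 0.01])
  expect_lt(abs(p1 - p2) / max(p1, p2), 0.05)

  expect_error(egg_spectrum(numeric(0), 10), class = "egg_length_error")
  expect_error(egg_spectrum(1, 10), class = "egg_length_error")
})

test_that("band percentages integrate per band, sum to 100 and are scale-invariant", {
  sp <- egg_spectrum(tone_cpm(3, 900, 10), 10)
  bp <- band_powers(sp)
  expect_gte(bp$pct_normo, 95)
  expect_equal(bp$pct_brady + bp$pct_normo + bp$pct_tachy, 100,
               tolerance = 1e-6)

  # equal-amplitude brady + tachy tones split roughly evenly
  x <- tone_cpm(1.5, 900, 10) + tone_cpm(7, 900, 10)
  bp2 <- band_powers(egg_spectrum(x, 10))
  expect_gt(bp2$pct_brady, 45)
  expect_lt(bp2$pct_brady, 55)
  expect_gt(bp2$pct_tachy, 45)
  expect_lt(bp2$pct_tachy, 55)
  expect_lt(bp2$pct_normo, 10)

  # PSD scaling convention cannot move percentages: amplitude scaling drops out
  bp50 <- band_powers(egg_spectrum(50 * x, 10))
  expect_equal(bp50$pct_brady, bp2$pct_brady, tolerance = 1e-12)
  expect_equal(bp50$pct_normo, bp2$pct_normo, tolerance = 1e-12)

  expect_error(band_powers(egg_spectrum(rep(0, 512), 10)),
               class = "egg_undefined_result_error")
})

test_that("percent conservation holds across random mixtures", {
  set.seed(21)
  for (i in 1:10) {
    k <- sample(1:4, 1)
    x <- rowSums(vapply(seq_len(k), function(j) {
      tone_cpm(stats::runif(1, 1.1, 9.5), 300, 10,
               amplitude = stats::runif(1, 0.2, 3),
               phase = stats::runif(1, 0, 2 * pi))
    }, numeric(3000))) + stats::rnorm(3000, sd = 0.05)
    bp <- band_powers(egg_spectrum(x, 10))
    expect_equal(bp$pct_brady + bp$pct_normo + bp$pct_tachy, 100,
                 tolerance = 1e-6)
    expect_true(all(c(bp$pct_brady, bp$pct_normo, bp$pct_tachy) >= 0))
  }
})

test_that("noiseless tones place >= 90% of in-range power in their own band", {
  grid <- c(1.2, 1.8, 2.5, 3.0, 3.8, 5, 9)
  bands <- gastric_bands()
  for (cpm in grid) {
    bp <- band_powers(egg_spectrum(tone_cpm(cpm, 600, 10), 10))
    own <- bands$name[cpm >= bands$lo_cpm &
                        (cpm < bands$hi_cpm | bands$hi_cpm == 10)][1]
    pct <- switch(own, bradygastria = bp$pct_brady,
                  normogastria = bp$pct_normo, tachygastria = bp$pct_tachy)
    expect_gte(pct, 90)
  }
})

test_that("dominant frequency finds the strongest in-range bin, ties to the lower", {
  sp <- egg_spectrum(tone_cpm(3, 900, 10), 10)
  bin_cpm <- diff(sp$freqs_cpm[1:2])
  expect_lt(abs(dominant_frequency(sp) - 3), bin_cpm + 1e-12)
  sp15 <- egg_spectrum(tone_cpm(1.5, 900, 10), 10)
  expect_lt(abs(dominant_frequency(sp15) - 1.5), bin_cpm + 1e-12)

  # constructed flat two-bin tie resolves to the lower frequency
  flat <- structure(list(
    freqs_hz = c(0, 0.04, 0.08), freqs_cpm = c(0, 2.4, 4.8),
    power = c(0, 1, 1), n_fft = 4L, window = "hann"),
    class = "egg_spectrum")
  expect_equal(dominant_frequency(flat), 2.4)

  zero <- structure(list(
    freqs_hz = c(0, 0.04, 0.08), freqs_cpm = c(0, 2.4, 4.8),
    power = c(1, 0, 0), n_fft = 4L, window = "hann"),
    class = "egg_spectrum")
  expect_error(dominant_frequency(zero), class = "egg_undefined_result_error")
})

test_that("recording constructor enforces its invariants", {
  expect_error(egg_recording(numeric(0)), class = "egg_length_error")
  expect_error(egg_recording(1:10, fs = -5), class = "egg_config_error")
  mk <- data.frame(time = c(5, 2), label = c("a", "b"))
  expect_error(egg_recording(1:100, fs = 10, markers = mk),
               class = "egg_config_error")
  late <- data.frame(time = 99, label = "x")
  expect_error(egg_recording(1:100, fs = 10, markers = late),
               class = "egg_config_error")
  ok <- egg_recording(1:100, fs = 10,
                      markers = data.frame(time = c(1, 9), label = c("a", "b")))
  expect_equal(duration(ok), 10)
})
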