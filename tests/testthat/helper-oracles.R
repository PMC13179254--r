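# Shared fixtures and independent oracles for the spectral tests.

# A sampled tone: frequency in cpm, at rate fs, for dur seconds.
tone_cpm <- function(cpm, dur, fs, amplitude = 1, phase = 0) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  amplitude * sin(2 * pi * cpm / 60 * t + phase)
}

# Brute-force O(n^2) discrete Fourier transform oracle for the one-sided
# PSD: same Hann window and zero-padding convention as the implementation,
# but the transform itself is a dense complex matrix product, independent
# of stats::fft.
oracle_psd <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  nfft <- 2^ceiling(log2(n))
  xw <- c(x * w, rep(0, nfft - n))
  k <- 0:(nfft / 2)
  j <- 0:(nfft - 1)
  E <- exp(-2i * pi * outer(k, j) / nfft)
  X <- as.vector(E %*% xw)
  p <- Mod(X)^2 / (fs * sum(w^2))
  p[2:(nfft / 2)] <- 2 * p[2:(nfft / 2)]
  list(freqs_hz = k * fs / nfft, power = p)
}

# Least-squares amplitude of a known-frequency sinusoid in a signal;
# independent check of filter gains.
fit_amplitude <- function(x, f_hz, fs) {
  t <- (seq_along(x) - 1) / fs
  X <- cbind(sin(2 * pi * f_hz * t), cos(2 * pi * f_hz * t))
  cf <- stats::coef(stats::lm.fit(X, x))
  sqrt(sum(cf^2))
}

# Count complete oscillation cycles of a [0, 1] fill signal by zero
# crossings of (fill - 0.5); each cycle crosses twice.
count_cycles <- function(fill) {
  s <- sign(fill - 0.5)
  s <- s[s != 0]
  sum(s[-1] != s[-length(s)]) / 2
}

# Single-tone recording at the acquisition rate with mild noise, used where
# tests need a realistic simulated EGG rather than a bare vector.
sim_tone_recording <- function(cpm, dur = 600, seed = 1, noise_sd = 0.2,
                               fs = 1000) {
  simulate_egg(simulation_config(
    duration_s = dur, fs = fs,
    components = data.frame(freq_cpm = cpm, amplitude = 1, phase = 0),
    noise_sd = noise_sd, seed = seed))
}
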