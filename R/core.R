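#' Canonical gastric frequency bands
#'
#' The three bands of the clinical EGG taxonomy, in cycles per minute:
#' bradygastria 1-2 cpm, normogastria 2-4 cpm (centred on the 3 cpm gastric
#' pacemaker rhythm) and tachygastria 4-10 cpm. Bands are treated as
#' half-open `[lo, hi)` except the last, which is closed at 10 cpm, so the
#' three tile 1-10 cpm with no double counting.
#'
#' @return Data frame with columns `name`, `lo_cpm`, `hi_cpm`.
#' @export
#' @examples
#' gastric_bands()
gastric_bands <- function() {
  data.frame(
    name = c("bradygastria", "normogastria", "tachygastria"),
    lo_cpm = c(1, 2, 4),
    hi_cpm = c(2, 4, 10),
    stringsAsFactors = FALSE
  )
}

#' Convert cycles per minute to Hz
#'
#' The EGG literature quotes gastric frequencies in cycles per minute (cpm);
#' spectral code works in Hz. 3 cpm, the normal gastric rhythm, is 0.05 Hz.
#'
#' @param f_cpm Frequency in cycles per minute; must be non-negative.
#' @return Frequency in Hz (`f_cpm / 60`).
#' @export
#' @examples
#' cpm_to_hz(3) # 0.05
cpm_to_hz <- function(f_cpm) {
  if (any(!is.finite(f_cpm)) || any(f_cpm < 0)) {
    abort_domain("frequencies in cpm must be finite and non-negative")
  }
  f_cpm / 60
}

#' Convert Hz to cycles per minute
#'
#' @param f_hz Frequency in Hz; must be non-negative.
#' @return Frequency in cycles per minute (`f_hz * 60`).
#' @export
hz_to_cpm <- function(f_hz) {
  if (any(!is.finite(f_hz)) || any(f_hz < 0)) {
    abort_domain("frequencies in Hz must be finite and non-negative")
  }
  f_hz * 60
}

#' Bandpass filter specification
#'
#' Defaults describe the gastric passband used throughout: 0.016-0.16 Hz
#' (about 1-10 cpm), 4th-order Butterworth, applied forward-backward
#' (zero-phase) so the filter adds no phase distortion to the slow waves.
#'
#' @param lo_hz Lower cutoff in Hz.
#' @param hi_hz Upper cutoff in Hz.
#' @param order Butterworth order (of the underlying low/high-pass prototype).
#' @param zero_phase Apply forward-backward (`TRUE`, offline) or single-pass
#'   causal (`FALSE`, real-time).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(lo_hz = 0.016, hi_hz = 0.16, order = 4L,
                        zero_phase = TRUE) {
  if (!(lo_hz > 0 && hi_hz > lo_hz)) {
    abort_config("need 0 < lo_hz < hi_hz")
  }
  if (order < 1 || order != round(order)) {
    abort_config("`order` must be a positive integer")
  }
  structure(list(lo_hz = lo_hz, hi_hz = hi_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Split an integer decimation factor into a cascade of stages <= 10.
# Large single-stage Butterworth decimators are numerically ill-conditioned
# in transfer-function form; cascading keeps each stage's normalized cutoff
# sane. A prime factor > 10 is accepted as its own stage.
decimation_stages <- function(factor) {
  stages <- integer(0)
  m <- factor
  while (m > 10L) {
    d <- 0L
    for (cand in 10L:2L) {
      if (m %% cand == 0L) {
        d <- cand
        break
      }
    }
    if (d == 0L) break # prime > 10: single big stage
    stages <- c(stages, d)
    m <- m %/% d
  }
  c(stages, m)
}

#' Downsample a recording with anti-alias filtering
#'
#' Reduces the sampling rate by an integer factor. Before each decimation an
#' 8th-order Butterworth low-pass at 0.8x the target Nyquist frequency is
#' applied so that energy above the new Nyquist (mains interference, motion
#' artifact) does not fold back into the gastric band. Decimation by large
#' factors (e.g. 1000 Hz to 10 Hz) is performed in cascaded stages of at most
#' 10x each.
#'
#' @param rec An `egg_recording`.
#' @param target_fs Target sampling rate in Hz; must divide `rec$fs` evenly.
#' @param zero_phase Apply the anti-alias filter forward-backward (default,
#'   offline use) or single-pass causal (streaming use).
#' @return An `egg_recording` at `target_fs`.
#' @export
#' @examples
#' rec <- simulate_egg(simulation_config(duration_s = 30, seed = 1))
#' downsample(rec, 10)
downsample <- function(rec, target_fs, zero_phase = TRUE) {
  stopifnot(inherits(rec, "egg_recording"))
  if (target_fs >= rec$fs) {
    abort_config("`target_fs` must be below the recording's sampling rate")
  }
  ratio <- rec$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort_config(sprintf(
      "decimation ratio %g Hz -> %g Hz is not an integer", rec$fs, target_fs))
  }
  x <- rec$samples
  fs <- rec$fs
  for (d in decimation_stages(as.integer(round(ratio)))) {
    if (d == 1L) next
    stage_fs <- fs / d
    lp <- signal::butter(8, 0.8 * (stage_fs / 2) / (fs / 2), type = "low")
    x <- if (zero_phase) signal::filtfilt(lp, x)
         else as.numeric(signal::filter(lp, x))
    x <- x[seq(1L, length(x), by = d)]
    fs <- stage_fs
  }
  egg_recording(x, fs = target_fs, start_time = rec$start_time,
                markers = rec$markers, channel_label = rec$channel_label,
                scale = rec$scale)
}

#' Remove a best-fit straight line
#'
#' Linear least-squares detrending, the standard EGG step for removing slow
#' electrode drift without attacking the 1 cpm end of the gastric band. A
#' constant signal detrends to all zeros.
#'
#' @param x Numeric vector, length >= 2.
#' @return Detrended vector with (numerically) zero mean.
#' @export
detrend <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) {
    abort_length("detrending needs at least 2 samples")
  }
  t <- seq_len(n) - (n + 1) / 2 # centred time axis: slope and mean decouple
  slope <- sum(t * x) / sum(t * t)
  x - mean(x) - slope * t
}

#' Butterworth bandpass filter
#'
#' Applies the gastric bandpass of a `filter_spec` to a sampled signal.
#' With `zero_phase = TRUE` the filter runs forward then backward
#' (`signal::filtfilt`), doubling the attenuation and cancelling phase;
#' otherwise a single causal pass (`signal::filter`) is used, as required
#' when the output drives real-time feedback.
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @param spec A `filter_spec`; defaults to the 0.016-0.16 Hz gastric band.
#' @return Filtered numeric vector, same length as `x`.
#' @export
bandpass <- function(x, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  x <- as.numeric(x)
  if (spec$hi_hz >= fs / 2) {
    abort_config(sprintf(
      "upper cutoff %g Hz must be below the Nyquist frequency %g Hz",
      spec$hi_hz, fs / 2))
  }
  if (length(x) <= 3L * spec$order) {
    abort_length(sprintf(
      "signal too short to filter: need more than %d samples", 3L * spec$order))
  }
  bf <- signal::butter(spec$order, c(spec$lo_hz, spec$hi_hz) / (fs / 2),
                       type = "pass")
  if (spec$zero_phase) signal::filtfilt(bf, x)
  else as.numeric(signal::filter(bf, x))
}

next_pow2 <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

#' One-sided power spectral density via Hann-windowed FFT
#'
#' The signal is Hann-windowed, zero-padded to the nearest power of 2, and
#' Fourier transformed; the squared magnitudes are scaled to a one-sided
#' density (units^2 / Hz) with the window's power normalization. Only power
#' ratios enter band percentages, so the scaling convention cannot affect
#' downstream summaries.
#'
#' @param x Numeric vector of samples, length >= 2.
#' @param fs Sampling rate in Hz.
#' @return An object of class `egg_spectrum` with fields `freqs_hz`,
#'   `freqs_cpm` (`= freqs_hz * 60`), `power`, `n_fft`, `window`.
#' @export
#' @examples
#' sp <- egg_spectrum(sin(2 * pi * 0.05 * seq(0, 900, by = 0.1)), fs = 10)
#' sp$freqs_hz[which.max(sp$power)] # ~0.05 Hz
egg_spectrum <- function(x, fs) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) {
    abort_length("spectral estimation needs at least 2 samples")
  }
  if (!is.finite(fs) || fs <= 0) {
    abort_config("`fs` must be positive")
  }
  w <- hann_window(n)
  nfft <- next_pow2(n)
  xw <- c(x * w, rep(0, nfft - n))
  X <- stats::fft(xw)
  half <- nfft / 2L
  idx <- seq_len(half + 1L) # DC .. Nyquist
  # density scaling: /(fs * sum(w^2)); double interior bins for one-sidedness
  p <- Mod(X[idx])^2 / (fs * sum(w^2))
  p[2:half] <- 2 * p[2:half]
  freqs <- (idx - 1L) * fs / nfft
  structure(
    list(freqs_hz = freqs, freqs_cpm = freqs * 60, power = p,
         n_fft = nfft, window = "hann"),
    class = "egg_spectrum"
  )
}

#' Hann window
#'
#' Periodic-symmetric ("symmetric") Hann window of length `n`.
#' @param n Window length.
#' @return Numeric vector of window coefficients.
#' @export
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

#' @export
print.egg_spectrum <- function(x, ...) {
  cat(sprintf("<egg_spectrum> %d bins to %.3g Hz (n_fft = %d, %s window)\n",
              length(x$freqs_hz), max(x$freqs_hz), x$n_fft, x$window))
  invisible(x)
}

# Trapezoidal integral of spectrum bins whose centre frequency falls in
# [lo, hi) cpm (closed at hi when `closed`); single-bin bands degenerate to
# the bin value.
band_integral <- function(spec, lo_cpm, hi_cpm, closed = FALSE) {
  cpm <- spec$freqs_cpm
  sel <- if (closed) cpm >= lo_cpm & cpm <= hi_cpm
         else cpm >= lo_cpm & cpm < hi_cpm
  f <- spec$freqs_hz[sel]
  p <- spec$power[sel]
  if (length(p) == 0L) return(0)
  if (length(p) == 1L) return(p)
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' Percent power per gastric band
#'
#' Integrates the spectral density over each band (trapezoidal rule over the
#' bins whose centre frequency falls in the band; bands half-open `[lo, hi)`
#' except the last, closed) and expresses each as a percentage of the total
#' power over 1-10 cpm. Power outside 1-10 cpm is ignored entirely.
#'
#' @param spec An `egg_spectrum`.
#' @param bands Band definition data frame; defaults to [gastric_bands()].
#' @return An object of class `band_power_summary` with fields `pct_brady`,
#'   `pct_normo`, `pct_tachy` (percent, summing to 100) and `total_power`
#'   (the integrated 1-10 cpm power in the spectrum's units).
#' @export
#' @examples
#' sp <- egg_spectrum(sin(2 * pi * 0.05 * seq(0, 900, by = 0.1)), fs = 10)
#' band_powers(sp)
band_powers <- function(spec, bands = gastric_bands()) {
  stopifnot(inherits(spec, "egg_spectrum"))
  if (max(spec$freqs_cpm) < max(bands$hi_cpm)) {
    abort_config("spectrum does not cover the gastric band (up to 10 cpm)")
  }
  nb <- nrow(bands)
  pows <- vapply(seq_len(nb), function(i) {
    band_integral(spec, bands$lo_cpm[i], bands$hi_cpm[i], closed = i == nb)
  }, numeric(1))
  names(pows) <- bands$name
  total <- sum(pows)
  if (total <= 0) {
    abort_undefined("total in-band (1-10 cpm) power is zero; band percentages undefined")
  }
  pct <- 100 * pows / total
  structure(
    list(pct_brady = unname(pct["bradygastria"]),
         pct_normo = unname(pct["normogastria"]),
         pct_tachy = unname(pct["tachygastria"]),
         total_power = total),
    class = "band_power_summary"
  )
}

#' @export
print.band_power_summary <- function(x, ...) {
  cat(sprintf(
    "<band_power_summary> brady %.1f%% | normo %.1f%% | tachy %.1f%% (total %.3g)\n",
    x$pct_brady, x$pct_normo, x$pct_tachy, x$total_power))
  invisible(x)
}

#' @export
as.data.frame.band_power_summary <- function(x, ...) {
  data.frame(pct_brady = x$pct_brady, pct_normo = x$pct_normo,
             pct_tachy = x$pct_tachy, total_power = x$total_power)
}

#' Dominant gastric frequency
#'
#' Frequency, in cpm, of the maximal power bin within the 1-10 cpm gastric
#' range. Ties are broken toward the lower frequency.
#'
#' @param spec An `egg_spectrum`.
#' @return Dominant frequency in cycles per minute.
#' @export
dominant_frequency <- function(spec) {
  stopifnot(inherits(spec, "egg_spectrum"))
  sel <- which(spec$freqs_cpm >= 1 & spec$freqs_cpm <= 10)
  if (length(sel) == 0L || all(spec$power[sel] <= 0)) {
    abort_undefined("no power in the 1-10 cpm range; dominant frequency undefined")
  }
  p <- spec$power[sel]
  spec$freqs_cpm[sel[which.max(p)]] # which.max: first (lowest-frequency) max
}
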