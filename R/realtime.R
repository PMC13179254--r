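#' Streaming engine configuration
#'
#' Parameters of the real-time feedback loop: the spectral branch analyzes a
#' sliding window of `window_s` seconds (>= 60 s is required to resolve
#' 1 cpm), emitting one feedback state every `hop_s` seconds. The 180 s
#' default keeps the Hann main lobe (half-width `2/window_s` Hz, i.e.
#' 0.67 cpm) narrow enough that a bradygastric tone leaks under 3 points of
#' power into the normogastric band, so streamed and offline normogastria
#' agree within a few points; shorter windows react faster but blur the
#' band boundaries. The direct
#' branch normalizes the bandpassed signal against its trailing
#' `direct_norm_s` seconds, self-calibrating across electrode gains. The
#' pacemaker sphere oscillates at `pacemaker_cpm` (default 3 cpm, the
#' normogastric rhythm).
#'
#' @param window_s Sliding-window length in seconds (>= 60).
#' @param hop_s Seconds between feedback updates (> 0).
#' @param direct_norm_s Trailing normalization horizon in seconds.
#' @param pacemaker_cpm Pacemaker rhythm in cycles per minute (> 0).
#' @return An object of class `stream_config`.
#' @export
stream_config <- function(window_s = 180, hop_s = 1, direct_norm_s = 60,
                          pacemaker_cpm = 3) {
  if (window_s < 60) abort_config("`window_s` must be at least 60 s to resolve 1 cpm")
  if (hop_s <= 0) abort_config("`hop_s` must be positive")
  if (direct_norm_s <= 0) abort_config("`direct_norm_s` must be positive")
  if (pacemaker_cpm <= 0) abort_config("`pacemaker_cpm` must be positive")
  structure(list(window_s = window_s, hop_s = hop_s,
                 direct_norm_s = direct_norm_s, pacemaker_cpm = pacemaker_cpm),
            class = "stream_config")
}

#' Pacemaker sphere fill level
#'
#' Raised-cosine fill of the pacemaker sphere: `(1 - cos(2*pi*cpm*t/60))/2`,
#' starting empty at `t = 0` and completing one fill-drain cycle every
#' `60/cpm` seconds (20 s at the default 3 cpm).
#'
#' @param t Time in seconds (>= 0); vectorized.
#' @param cpm Pacemaker rhythm in cycles per minute (> 0).
#' @return Fill level(s) in `[0, 1]`.
#' @export
#' @examples
#' pacemaker_fill(c(0, 10, 20)) # 0, 1, 0 at 3 cpm
pacemaker_fill <- function(t, cpm = 3) {
  if (any(t < 0)) abort_domain("`t` must be non-negative")
  if (cpm <= 0) abort_domain("`cpm` must be positive")
  (1 - cos(2 * pi * cpm * t / 60)) / 2
}

#' Direct-feedback fill level
#'
#' Maps the latest bandpassed sample to `[0, 1]` by min-max normalization
#' over a trailing window, driving the user's sphere. A constant window
#' (zero dynamic range) maps to the neutral 0.5.
#'
#' @param filtered_window Numeric vector: the trailing bandpassed samples,
#'   newest last; length >= 2.
#' @return Fill level in `[0, 1]`.
#' @export
direct_feedback <- function(filtered_window) {
  n <- length(filtered_window)
  if (n < 2L) abort_state("direct feedback needs at least 2 samples of history")
  lo <- min(filtered_window)
  hi <- max(filtered_window)
  if (hi <= lo) return(0.5)
  (filtered_window[n] - lo) / (hi - lo)
}

#' Dimensional FFT feedback: environment parameters
#'
#' Maps the fraction of normogastric power to the virtual environment:
#' higher normogastria gives sunnier weather — cloud density and wind fall
#' linearly, water clarity rises linearly, and the water-sound gain rises
#' from a 0.25 floor. All mappings are linear by convention and clamped
#' nowhere because the input is range-checked.
#'
#' @param normo_fraction Normogastric power fraction in `[0, 1]`.
#' @return An `environment_params` list with `cloud_density`,
#'   `water_clarity`, `wind_gain`, `water_sound_gain`, all in `[0, 1]`.
#' @export
#' @examples
#' fft_feedback(1) # clear sky
fft_feedback <- function(normo_fraction) {
  if (length(normo_fraction) != 1L || !is.finite(normo_fraction) ||
      normo_fraction < 0 || normo_fraction > 1) {
    abort_domain("`normo_fraction` must be a single value in [0, 1]")
  }
  structure(
    list(cloud_density = 1 - normo_fraction,
         water_clarity = normo_fraction,
         wind_gain = 1 - normo_fraction,
         water_sound_gain = 0.25 + 0.75 * normo_fraction),
    class = "environment_params"
  )
}

neutral_env <- function() {
  structure(
    list(cloud_density = 0.5, water_clarity = 0.5, wind_gain = 0.5,
         water_sound_gain = 0.5),
    class = "environment_params"
  )
}

#' Run the streaming feedback engine over a recording
#'
#' Replays a recording through the causal real-time chain: downsample to
#' 10 Hz (single-pass anti-alias filters), causal Butterworth bandpass
#' (0.016-0.16 Hz), then one feedback state per hop. Each state carries the
#' pacemaker fill, the direct-feedback fill (trailing min-max normalization),
#' and — once a full analysis window has elapsed — the normogastric power
#' fraction of the trailing window (detrended, Hann-windowed, zero-padded
#' FFT) with the environment parameters it implies. Before warm-up, and
#' whenever the window has no in-band power, the environment is held neutral
#' (all parameters 0.5) and `normo_fraction` is `NA`.
#'
#' Processing is causal: the state emitted at time `t` depends only on
#' samples at or before `t`, so replay is equivalent to live operation.
#'
#' @param rec An `egg_recording` at 1000 Hz (downsampled internally) or
#'   already at 10 Hz.
#' @param cfg A `stream_config`.
#' @return A data frame of class `feedback_stream`, one row per hop, with
#'   columns `t`, `pacemaker_fill`, `user_fill`, `normo_fraction`,
#'   `cloud_density`, `water_clarity`, `wind_gain`, `water_sound_gain`,
#'   `warmed_up`.
#' @export
#' @examples
#' rec <- simulate_scenario("post_water", duration_s = 200, seed = 1)
#' head(stream_process(rec, stream_config(window_s = 60)))
stream_process <- function(rec, cfg = stream_config()) {
  stopifnot(inherits(rec, "egg_recording"), inherits(cfg, "stream_config"))
  proc_fs <- 10
  if (rec$fs == proc_fs) {
    rec10 <- rec
  } else if (rec$fs > proc_fs && abs(rec$fs / proc_fs -
                                     round(rec$fs / proc_fs)) < 1e-9) {
    rec10 <- downsample(rec, proc_fs, zero_phase = FALSE)
  } else {
    abort_config(sprintf(
      "stream input must be at 10 Hz or an integer multiple; got %g Hz", rec$fs))
  }
  dur <- duration(rec10)
  hops <- seq_len(floor(dur / cfg$hop_s)) * cfg$hop_s
  if (length(hops) == 0L) {
    return(empty_stream())
  }
  filt <- bandpass(rec10$samples, proc_fs,
                   filter_spec(zero_phase = FALSE))
  win_n <- round(cfg$window_s * proc_fs)
  norm_n <- round(cfg$direct_norm_s * proc_fs)
  states <- lapply(hops, function(t) {
    i <- min(length(filt), floor(t * proc_fs)) # last sample index at time <= t
    norm_win <- filt[max(1L, i - norm_n + 1L):i]
    user <- if (length(norm_win) >= 2L) direct_feedback(norm_win) else 0.5
    warmed <- i >= win_n
    normo <- NA_real_
    env <- neutral_env()
    if (warmed) {
      win <- filt[(i - win_n + 1L):i]
      sp <- egg_spectrum(detrend(win), proc_fs)
      bp <- tryCatch(band_powers(sp), egg_undefined_result_error = function(e) NULL)
      if (!is.null(bp)) {
        normo <- bp$pct_normo / 100
        env <- fft_feedback(normo)
      }
    }
    data.frame(t = t,
               pacemaker_fill = pacemaker_fill(t, cfg$pacemaker_cpm),
               user_fill = user,
               normo_fraction = normo,
               cloud_density = env$cloud_density,
               water_clarity = env$water_clarity,
               wind_gain = env$wind_gain,
               water_sound_gain = env$water_sound_gain,
               warmed_up = warmed)
  })
  out <- do.call(rbind, states)
  class(out) <- c("feedback_stream", "data.frame")
  out
}

empty_stream <- function() {
  out <- data.frame(t = numeric(0), pacemaker_fill = numeric(0),
                    user_fill = numeric(0), normo_fraction = numeric(0),
                    cloud_density = numeric(0), water_clarity = numeric(0),
                    wind_gain = numeric(0), water_sound_gain = numeric(0),
                    warmed_up = logical(0))
  class(out) <- c("feedback_stream", "data.frame")
  out
}

#' Write a feedback stream as JSON lines
#'
#' One JSON object per hop, the format a renderer would consume.
#'
#' @param stream A `feedback_stream` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stream_jsonl <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(stream))) {
    writeLines(jsonlite::toJSON(as.list(stream[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA, na = "null"),
               con)
  }
  invisible(path)
}
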