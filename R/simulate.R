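#' Simulation configuration for synthetic EGG
#'
#' Describes a sinusoid-mixture model of a single-channel abdominal EGG:
#' a sum of gastric oscillations (each a `(freq_cpm, amplitude, phase)`
#' triple), a linear electrode-drift term, additive white Gaussian noise, and
#' optional uniform quantization emulating a 16-bit ADC over the signal
#' range. The model is deliberately simple so that band-power targets can be
#' solved for analytically.
#'
#' @param duration_s Recording length in seconds; must be positive.
#' @param fs Sampling rate in Hz (default 1000, the acquisition rate).
#' @param components Data frame with columns `freq_cpm` (in (0, 30)),
#'   `amplitude`, `phase` (radians); or `NULL` for none.
#' @param drift_slope Linear drift in units per second.
#' @param noise_sd Standard deviation of the white Gaussian noise; >= 0.
#' @param quantize_bits Integer number of ADC bits, or `NULL` to skip
#'   quantization.
#' @param seed Integer RNG seed; a fixed seed makes the output bit-identical.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(duration_s, fs = 1000,
                              components = NULL,
                              drift_slope = 0, noise_sd = 0,
                              quantize_bits = NULL, seed = NULL) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort_config("`duration_s` must be positive")
  }
  if (fs <= 0) abort_config("`fs` must be positive")
  if (is.null(components)) {
    components <- data.frame(freq_cpm = numeric(0), amplitude = numeric(0),
                             phase = numeric(0))
  }
  if (!is.data.frame(components) ||
      !all(c("freq_cpm", "amplitude") %in% names(components))) {
    abort_config("`components` must have columns `freq_cpm` and `amplitude`")
  }
  if (is.null(components$phase)) components$phase <- 0
  if (nrow(components) &&
      (any(components$freq_cpm <= 0) || any(components$freq_cpm >= 30))) {
    abort_config("component frequencies must lie in (0, 30) cpm")
  }
  if (noise_sd < 0) abort_config("`noise_sd` must be >= 0")
  if (!is.null(quantize_bits) &&
      (quantize_bits < 1 || quantize_bits != round(quantize_bits))) {
    abort_config("`quantize_bits` must be a positive integer or NULL")
  }
  structure(
    list(duration_s = duration_s, fs = fs, components = components,
         drift_slope = drift_slope, noise_sd = noise_sd,
         quantize_bits = if (is.null(quantize_bits)) NULL
                         else as.integer(quantize_bits),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "simulation_config"
  )
}

# Evaluate a closure with a locally seeded RNG, leaving the caller's RNG
# state untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Map a signal to integer ADC codes: 0 .. 2^bits - 1 over the signal range,
# as a real acquisition front end would emit. The affine code mapping leaves
# band percentages untouched (gain scales all power equally; the offset is
# removed by detrending); only the rounding step loses information.
quantize_signal <- function(x, bits) {
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) return(x) # constant signal: nothing to quantize
  levels <- 2^bits - 1
  round((x - lo) / (hi - lo) * levels)
}

#' Simulate a synthetic EGG recording
#'
#' Generates samples from the sinusoid-mixture model of a
#' [simulation_config()]: for each component `a * sin(2*pi*f*t + phase)`
#' with `f` converted from cpm to Hz, plus `drift_slope * t` and Gaussian
#' noise. With `quantize_bits` set, samples are mapped to integer ADC codes
#' (`0 .. 2^bits - 1` over the generated range), emulating the digitizer;
#' band percentages are invariant under this affine code mapping up to
#' rounding. Output is bit-identical for a fixed seed.
#'
#' @param config A `simulation_config`.
#' @return An `egg_recording` at `config$fs`.
#' @export
#' @examples
#' cfg <- simulation_config(duration_s = 120, components = data.frame(
#'   freq_cpm = 3, amplitude = 1, phase = 0), noise_sd = 0.1, seed = 42)
#' rec <- simulate_egg(cfg)
simulate_egg <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- round(config$duration_s * config$fs)
  t <- (seq_len(n) - 1L) / config$fs
  x <- numeric(n)
  cmp <- config$components
  for (i in seq_len(nrow(cmp))) {
    x <- x + cmp$amplitude[i] *
      sin(2 * pi * cpm_to_hz(cmp$freq_cpm[i]) * t + cmp$phase[i])
  }
  x <- x + config$drift_slope * t
  if (config$noise_sd > 0) {
    x <- x + with_seed(config$seed, stats::rnorm(n, 0, config$noise_sd))
  }
  if (!is.null(config$quantize_bits)) {
    x <- quantize_signal(x, config$quantize_bits)
  }
  egg_recording(x, fs = config$fs, channel_label = "EGG(sim)")
}

#' Gastric state scenario
#'
#' A named gastric state with target percentages of band power, used to
#' generate recordings emulating the phases of a biofeedback session:
#' `fasted` (baseline after a >= 3 h fast, low normogastria), `post_water`
#' (after moderate water intake and training, elevated normogastria) and
#' `fullness` (after drinking to fullness, reduced normogastria with more
#' dysrhythmic power). The default targets are illustrative of the expected
#' ordering between states, not published group means.
#'
#' @param name One of `"fasted"`, `"post_water"`, `"fullness"`, or
#'   `"custom"` with explicit targets.
#' @param target_normo_pct,target_brady_pct,target_tachy_pct Target percent
#'   power per band; must be non-negative and sum to 100. Defaults depend on
#'   `name`.
#' @return An object of class `scenario_label`.
#' @export
#' @examples
#' scenario_label("post_water")
scenario_label <- function(name = c("fasted", "post_water", "fullness", "custom"),
                           target_normo_pct = NULL, target_brady_pct = NULL,
                           target_tachy_pct = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    fasted     = c(normo = 40, brady = 35, tachy = 25),
    post_water = c(normo = 70, brady = 20, tachy = 10),
    fullness   = c(normo = 50, brady = 20, tachy = 30),
    custom     = c(normo = NA, brady = NA, tachy = NA)
  )
  normo <- if (is.null(target_normo_pct)) defaults[["normo"]] else target_normo_pct
  brady <- if (is.null(target_brady_pct)) defaults[["brady"]] else target_brady_pct
  tachy <- if (is.null(target_tachy_pct)) defaults[["tachy"]] else target_tachy_pct
  if (anyNA(c(normo, brady, tachy))) {
    abort_config("custom scenarios need all three target percentages")
  }
  if (any(c(normo, brady, tachy) < 0)) {
    abort_config("target percentages must be non-negative")
  }
  if (abs(normo + brady + tachy - 100) > 1e-6) {
    abort_config("target percentages must sum to 100")
  }
  structure(list(name = name, target_normo_pct = normo,
                 target_brady_pct = brady, target_tachy_pct = tachy),
            class = "scenario_label")
}

#' Simulate a recording for a gastric scenario
#'
#' Places one tone at the centre of each gastric band (1.5, 3 and 7 cpm) and
#' solves the component amplitudes from the scenario's target percentages
#' (power scales with amplitude squared, so `a_band = sqrt(target_pct)`), on
#' top of mild drift and measurement noise. The analyzed band percentages of
#' the result track the targets to within a few points.
#'
#' @param label A `scenario_label` (or a scenario name passed to
#'   [scenario_label()]).
#' @param duration_s Recording length in seconds.
#' @param seed Integer RNG seed.
#' @param fs Sampling rate in Hz.
#' @param noise_sd Measurement noise SD relative to unit tone scale.
#' @return An `egg_recording`.
#' @export
#' @examples
#' rec <- simulate_scenario("post_water", duration_s = 300, seed = 7)
#' analyze_recording(rec)
simulate_scenario <- function(label, duration_s = 900, seed = NULL,
                              fs = 1000, noise_sd = 0.5) {
  if (is.character(label)) label <- scenario_label(label)
  stopifnot(inherits(label, "scenario_label"))
  targets <- c(label$target_brady_pct, label$target_normo_pct,
               label$target_tachy_pct)
  comp <- data.frame(
    freq_cpm = c(1.5, 3, 7),
    amplitude = sqrt(targets),
    phase = c(0, pi / 3, 2 * pi / 3)
  )
  comp <- comp[comp$amplitude > 0, , drop = FALSE]
  cfg <- simulation_config(
    duration_s = duration_s, fs = fs, components = comp,
    drift_slope = 0.01, noise_sd = noise_sd, quantize_bits = 16L, seed = seed
  )
  rec <- simulate_egg(cfg)
  rec$channel_label <- sprintf("EGG(sim:%s)", label$name)
  rec
}
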