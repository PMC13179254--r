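#' Session plan
#'
#' Durations and mode of one biofeedback session: a 15-min baseline rest
#' recording, 250 ml of water, a 10-min training block (VR, 2D screen, or
#' relaxation control), a water-load test to fullness, and a 15-min post
#' recording.
#'
#' @param baseline_s,training_s,post_s Timepoint durations in seconds.
#' @param mode One of `"vr"`, `"2d"`, `"control"`.
#' @return An object of class `session_plan`.
#' @export
session_plan <- function(baseline_s = 900, training_s = 600, post_s = 900,
                         mode = c("vr", "2d", "control")) {
  mode <- match.arg(mode)
  if (any(c(baseline_s, training_s, post_s) <= 0)) {
    abort_config("all session durations must be positive")
  }
  structure(list(baseline_s = baseline_s, training_s = training_s,
                 post_s = post_s, mode = mode,
                 markers = c("water_intake", "wlt_start")),
            class = "session_plan")
}

#' Offline band-power analysis of one recording
#'
#' The full offline pipeline for a rest EGG recording: anti-aliased
#' downsampling to 10 Hz, linear detrending and zero-phase Butterworth
#' bandpass (0.016-0.16 Hz; order of the two stages configurable), then a
#' Hann-windowed, zero-padded FFT and percent power per gastric band.
#' Deterministic: repeated calls on the same input are bit-identical.
#'
#' @param rec An `egg_recording` of at least 120 s.
#' @param spec `filter_spec` for the bandpass stage.
#' @param stage_order Character vector giving the order of the detrend and
#'   bandpass stages. The default (detrend first) matches offline practice;
#'   the streaming path uses the reverse.
#' @param target_fs Analysis rate in Hz after downsampling.
#' @return A `band_power_summary`; the spectrum is attached as attribute
#'   `"spectrum"` and the dominant frequency (cpm) as `"dominant_cpm"`.
#' @export
#' @examples
#' rec <- simulate_scenario("fasted", duration_s = 300, seed = 2)
#' analyze_recording(rec)
analyze_recording <- function(rec, spec = filter_spec(),
                              stage_order = c("detrend", "bandpass"),
                              target_fs = 10) {
  stopifnot(inherits(rec, "egg_recording"))
  if (duration(rec) < 120) {
    abort_length("offline analysis needs at least 120 s of signal")
  }
  if (!identical(sort(stage_order), c("bandpass", "detrend"))) {
    abort_config("`stage_order` must be a permutation of c('detrend', 'bandpass')")
  }
  rec10 <- if (rec$fs == target_fs) rec else downsample(rec, target_fs)
  x <- rec10$samples
  for (stage in stage_order) {
    x <- switch(stage,
                detrend = detrend(x),
                bandpass = bandpass(x, target_fs, spec))
  }
  sp <- egg_spectrum(x, target_fs)
  bp <- band_powers(sp)
  attr(bp, "spectrum") <- sp
  attr(bp, "dominant_cpm") <- dominant_frequency(sp)
  bp
}

#' Flag likely artifacts in a recording
#'
#' An automated stand-in for visual quality inspection. Two checks, both
#' non-destructive: (1) clipping — windows in which more than
#' `clip_fraction` of samples sit at the recording's range extremes
#' (saturated ADC); (2) jumps — sample-to-sample steps larger than
#' `jump_sds` robust standard deviations (median absolute deviation, scaled)
#' of the first difference, catching electrode pops and motion spikes.
#'
#' @param rec An `egg_recording`.
#' @param clip_fraction Fraction of at-extreme samples within a window above
#'   which the window is flagged.
#' @param window_s Inspection window length in seconds.
#' @param jump_sds Robust-SD multiplier for the jump detector.
#' @return Data frame of warnings with columns `type` (`"clipping"` or
#'   `"jump"`), `t_start`, `t_end` (seconds); zero rows when clean.
#' @export
artifact_flag <- function(rec, clip_fraction = 0.01, window_s = 10,
                          jump_sds = 6) {
  stopifnot(inherits(rec, "egg_recording"))
  x <- rec$samples
  fs <- rec$fs
  warnings <- list()
  rng <- range(x)
  tol <- max(diff(rng) * 1e-9, .Machine$double.eps)
  at_extreme <- x >= rng[2] - tol | x <= rng[1] + tol
  win_n <- max(2L, round(window_s * fs))
  starts <- seq(1L, length(x), by = win_n)
  for (s in starts) {
    e <- min(s + win_n - 1L, length(x))
    frac <- mean(at_extreme[s:e])
    if (frac > clip_fraction) {
      warnings[[length(warnings) + 1L]] <- data.frame(
        type = "clipping", t_start = (s - 1L) / fs, t_end = e / fs)
    }
  }
  d <- diff(x)
  rsd <- stats::mad(d)
  if (rsd > 0) {
    big <- which(abs(d) > jump_sds * rsd)
    for (i in big) {
      warnings[[length(warnings) + 1L]] <- data.frame(
        type = "jump", t_start = (i - 1L) / fs, t_end = i / fs)
    }
  }
  if (length(warnings) == 0L) {
    return(data.frame(type = character(0), t_start = numeric(0),
                      t_end = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, warnings)
  rownames(out) <- NULL
  out
}

#' Winsorize values against the group distribution
#'
#' Clamps outliers to `k` standard deviations from the group mean: values
#' above `mean + k*SD` are set to `mean + k*SD`, values below `mean - k*SD`
#' to `mean - k*SD`. Mean and SD are computed once from the input and not
#' re-estimated after clamping.
#'
#' @param values Numeric vector of per-participant values; length >= 2.
#' @param k SD multiplier (default 3).
#' @return Numeric vector of the same length with outliers clamped.
#' @export
#' @examples
#' winsorize_by_group(c(0, 0, 0, 0, 100))
winsorize_by_group <- function(values, k = 3) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    abort_length("winsorization needs at least 2 values")
  }
  m <- mean(values)
  s <- stats::sd(values)
  pmin(pmax(values, m - k * s), m + k * s)
}

#' Summarize a baseline/training/post session
#'
#' Runs [analyze_recording()] on each available timepoint and reports the
#' per-band percentages plus the successive differences (during - pre,
#' post - during) that carry the training effect. A missing timepoint yields
#' a partial result with a flag; differences touching it are `NA`.
#'
#' @param recordings Named list with elements `pre`, `during`, `post`, each
#'   an `egg_recording` or `NULL` if unusable.
#' @param plan A `session_plan`; recording durations must match it to
#'   within 5 percent.
#' @param session_index Session number (1-4) stored in the result.
#' @return An object of class `session_result`: per-timepoint
#'   `band_power_summary` (or `NULL`), a `differences` data frame, `mode`,
#'   `session_index` and character `flags`.
#' @export
summarize_session <- function(recordings, plan = session_plan(),
                              session_index = 1L) {
  stopifnot(is.list(recordings), inherits(plan, "session_plan"))
  tps <- c("pre", "during", "post")
  if (!all(tps %in% names(recordings))) {
    abort_config("`recordings` must have elements `pre`, `during`, `post`")
  }
  planned <- c(pre = plan$baseline_s, during = plan$training_s,
               post = plan$post_s)
  flags <- character(0)
  summaries <- stats::setNames(vector("list", 3L), tps)
  for (tp in tps) {
    rec <- recordings[[tp]]
    if (is.null(rec)) {
      flags <- c(flags, sprintf("missing %s recording", tp))
      next
    }
    if (abs(duration(rec) - planned[[tp]]) > 0.05 * planned[[tp]]) {
      abort_config(sprintf(
        "%s recording is %.0f s, plan expects %.0f s (+/- 5%%)",
        tp, duration(rec), planned[[tp]]))
    }
    summaries[[tp]] <- analyze_recording(rec)
  }
  diff_row <- function(a, b) { # b - a, per band
    if (is.null(a) || is.null(b)) {
      return(c(pct_brady = NA_real_, pct_normo = NA_real_,
               pct_tachy = NA_real_))
    }
    c(pct_brady = b$pct_brady - a$pct_brady,
      pct_normo = b$pct_normo - a$pct_normo,
      pct_tachy = b$pct_tachy - a$pct_tachy)
  }
  differences <- rbind(
    during_minus_pre = diff_row(summaries$pre, summaries$during),
    post_minus_during = diff_row(summaries$during, summaries$post)
  )
  differences <- as.data.frame(differences)
  differences$contrast <- rownames(differences)
  rownames(differences) <- NULL
  structure(
    list(timepoints = summaries, differences = differences,
         mode = plan$mode, session_index = as.integer(session_index),
         flags = flags),
    class = "session_result"
  )
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> mode %s, session %d\n", x$mode,
              x$session_index))
  for (tp in names(x$timepoints)) {
    s <- x$timepoints[[tp]]
    if (is.null(s)) {
      cat(sprintf("  %-6s: (missing)\n", tp))
    } else {
      cat(sprintf("  %-6s: brady %.1f%% | normo %.1f%% | tachy %.1f%%\n",
                  tp, s$pct_brady, s$pct_normo, s$pct_tachy))
    }
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy per-band table for a set of session results
#'
#' Long format suitable for external statistics packages: one row per
#' participant x session x timepoint x band.
#'
#' @param results List of `session_result` objects.
#' @param participant_ids Optional vector of ids, recycled over `results`.
#' @return Data frame with columns `participant`, `session`, `mode`,
#'   `timepoint`, `band`, `pct`.
#' @export
session_table <- function(results, participant_ids = seq_along(results)) {
  rows <- list()
  ids <- rep_len(participant_ids, length(results))
  for (i in seq_along(results)) {
    res <- results[[i]]
    for (tp in names(res$timepoints)) {
      s <- res$timepoints[[tp]]
      if (is.null(s)) next
      rows[[length(rows) + 1L]] <- data.frame(
        participant = ids[i], session = res$session_index, mode = res$mode,
        timepoint = tp,
        band = c("bradygastria", "normogastria", "tachygastria"),
        pct = c(s$pct_brady, s$pct_normo, s$pct_tachy),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(participant = integer(0), session = integer(0),
                      mode = character(0), timepoint = character(0),
                      band = character(0), pct = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
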