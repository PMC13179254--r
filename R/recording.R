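#' Construct an EGG recording
#'
#' A uniformly sampled single-channel electrogastrogram trace. Sample values
#' carry arbitrary acquisition units; a configurable `scale` field records the
#' conversion to millivolts without being applied to the data (the band-power
#' pipeline is scale-invariant).
#'
#' @param samples Numeric vector of voltage samples (arbitrary units).
#' @param fs Sampling rate in Hz. Defaults to 1000, the acquisition rate of a
#'   16-bit cutaneous EGG amplifier.
#' @param start_time Recording start, in seconds.
#' @param markers Data frame of session events with columns `time` (seconds
#'   from recording start) and `label`, or `NULL` for none. Markers must be
#'   sorted by time and fall within the recording.
#' @param channel_label Channel name stored in metadata.
#' @param scale Multiplicative factor mapping raw units to mV (metadata only).
#'
#' @return An object of class `egg_recording`.
#' @export
#' @examples
#' rec <- egg_recording(sin(2 * pi * 0.05 * seq(0, 60, by = 0.1)), fs = 10)
#' duration(rec)
egg_recording <- function(samples, fs = 1000, start_time = 0, markers = NULL,
                          channel_label = "EGG", scale = 1) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    abort_length("an EGG recording needs at least one sample")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort_config("`fs` must be a single positive number (Hz)")
  }
  if (is.null(markers)) {
    markers <- data.frame(time = numeric(0), label = character(0),
                          stringsAsFactors = FALSE)
  }
  if (!is.data.frame(markers) || !all(c("time", "label") %in% names(markers))) {
    abort_config("`markers` must be a data frame with columns `time` and `label`")
  }
  markers$time <- as.numeric(markers$time)
  markers$label <- as.character(markers$label)
  if (is.unsorted(markers$time)) {
    abort_config("markers must be sorted by time")
  }
  dur <- length(samples) / fs
  if (nrow(markers) && (any(markers$time < 0) || any(markers$time > dur))) {
    abort_config("marker times must lie within [0, duration]")
  }
  structure(
    list(samples = samples, fs = fs, start_time = as.numeric(start_time),
         markers = markers, channel_label = as.character(channel_label),
         scale = as.numeric(scale)),
    class = "egg_recording"
  )
}

#' Duration of a recording in seconds
#'
#' @param rec An `egg_recording`.
#' @return Duration in seconds (`length(samples) / fs`).
#' @export
duration <- function(rec) {
  stopifnot(inherits(rec, "egg_recording"))
  length(rec$samples) / rec$fs
}

#' @export
print.egg_recording <- function(x, ...) {
  cat(sprintf("<egg_recording> %s: %d samples @ %g Hz (%.1f s)\n",
              x$channel_label, length(x$samples), x$fs, duration(x)))
  if (nrow(x$markers)) {
    cat(sprintf("  markers: %s\n",
                paste(sprintf("%s@%.1fs", x$markers$label, x$markers$time),
                      collapse = ", ")))
  }
  invisible(x)
}
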