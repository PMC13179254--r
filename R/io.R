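#' Write a recording to a text file
#'
#' Two dialects: `"plain"` writes one sample per row at full double
#' precision (lossless round-trip; the sampling rate travels out-of-band),
#' and `"opensignals"` writes an OpenSignals-style text file with a
#' `#`-prefixed header carrying a JSON metadata line (sampling rate,
#' resolution, column labels) and an `# EndOfHeader` marker, followed by
#' `nSeq<TAB>value` rows. Markers, when present, are written to a JSON
#' sidecar at `<path>.markers.json` together with the recording metadata;
#' marker-free recordings emit no sidecar.
#'
#' @param rec An `egg_recording`.
#' @param path Output file path.
#' @param dialect `"plain"` or `"opensignals"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = c("plain", "opensignals")) {
  stopifnot(inherits(rec, "egg_recording"))
  dialect <- match.arg(dialect)
  fmt <- function(x) sprintf("%.17g", x)
  ok <- tryCatch({
    if (dialect == "plain") {
      writeLines(fmt(rec$samples), path)
    } else {
      header <- c(
        "# OpenSignals Text File Format",
        paste0("# ", jsonlite::toJSON(list(device = list(
          "sampling rate" = rec$fs,
          resolution = 16,
          column = c("nSeq", rec$channel_label),
          label = rec$channel_label,
          "start time" = rec$start_time,
          scale = rec$scale
        )), auto_unbox = TRUE, digits = NA)),
        "# EndOfHeader"
      )
      body <- paste(seq_along(rec$samples) - 1L, fmt(rec$samples), sep = "\t")
      writeLines(c(header, body), path)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort_data(sprintf("failed to write %s: %s", path, conditionMessage(ok)))
  }
  if (nrow(rec$markers)) {
    jsonlite::write_json(
      list(fs = rec$fs, start_time = rec$start_time,
           channel_label = rec$channel_label, scale = rec$scale,
           markers = rec$markers),
      paste0(path, ".markers.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

parse_opensignals_header <- function(lines) {
  meta <- NULL
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    if (startsWith(body, "{")) {
      meta <- tryCatch(jsonlite::fromJSON(body), error = function(e) NULL)
      if (!is.null(meta)) break
    }
  }
  meta
}

#' Read a recording from a text file
#'
#' Auto-detects the dialect: a leading `#` means an OpenSignals-style text
#' file whose JSON header supplies the sampling rate and metadata; anything
#' else is read as plain delimited samples, for which the sampling rate must
#' come from `fs_override` or a markers sidecar. Non-numeric sample values
#' are reported with their file line numbers. A `<path>.markers.json`
#' sidecar, if present, restores markers and metadata.
#'
#' @param path Input file path.
#' @param dialect `"auto"` (default), `"plain"` or `"opensignals"`.
#' @param fs_override Sampling rate in Hz, overriding any header value.
#' @param column_index 1-based index of the sample column; default is the
#'   last column (OpenSignals devices append the signal after counters).
#' @param delimiter Field delimiter; default splits on any whitespace.
#' @return An `egg_recording`.
#' @export
read_recording <- function(path, dialect = c("auto", "plain", "opensignals"),
                           fs_override = NULL, column_index = NULL,
                           delimiter = "auto") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_data(sprintf("file not found: %s", path))
  }
  first <- readLines(path, n = 1L)
  if (dialect == "auto") {
    dialect <- if (length(first) && startsWith(first, "#")) "opensignals"
               else "plain"
  }
  n_header <- 0L
  meta <- NULL
  if (dialect == "opensignals") {
    head_lines <- character(0)
    con <- file(path, "r")
    repeat {
      ln <- readLines(con, n = 1L)
      if (length(ln) == 0L || !startsWith(ln, "#")) break
      head_lines <- c(head_lines, ln)
      if (grepl("EndOfHeader", ln)) break
    }
    close(con)
    n_header <- length(head_lines)
    meta <- parse_opensignals_header(head_lines)
  }
  dt <- tryCatch(
    data.table::fread(path, skip = n_header, header = FALSE,
                      sep = if (identical(delimiter, "auto")) "auto" else delimiter,
                      colClasses = "character", data.table = FALSE),
    error = function(e) abort_data(sprintf("cannot parse %s: %s", path,
                                           conditionMessage(e))))
  if (nrow(dt) == 0L) abort_data(sprintf("no sample rows in %s", path))
  col <- if (!is.null(column_index)) column_index else ncol(dt)
  if (col < 1L || col > ncol(dt)) {
    abort_config(sprintf("column_index %d out of range (file has %d columns)",
                         col, ncol(dt)))
  }
  samples <- suppressWarnings(as.numeric(dt[[col]]))
  bad <- which(!is.finite(samples) & !(dt[[col]] %in% c("Inf", "-Inf", "NaN")))
  if (length(bad)) {
    abort_data(sprintf(
      "non-numeric sample value%s at line%s %s of %s",
      if (length(bad) > 1) "s" else "", if (length(bad) > 1) "s" else "",
      paste(utils::head(bad + n_header, 5L), collapse = ", "), path))
  }
  sidecar_path <- paste0(path, ".markers.json")
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::fromJSON(sidecar_path)
  } else NULL
  device <- meta$device
  fs <- fs_override %||% device[["sampling rate"]] %||% sidecar$fs
  if (is.null(fs)) {
    abort_config(sprintf(
      "sampling rate for %s not in header or sidecar; pass `fs_override`", path))
  }
  markers <- if (!is.null(sidecar$markers) && length(sidecar$markers)) {
    as.data.frame(sidecar$markers)
  } else NULL
  egg_recording(
    samples, fs = fs,
    start_time = (sidecar$start_time %||% device[["start time"]] %||% 0),
    markers = markers,
    channel_label = as.character(
      sidecar$channel_label %||% device$label %||% "EGG")[1],
    scale = (sidecar$scale %||% device$scale %||% 1)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a band-power summary or session result to JSON
#'
#' @param x A `band_power_summary` or `session_result`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
to_json <- function(x, path = NULL) {
  payload <- if (inherits(x, "band_power_summary")) {
    list(pct_brady = x$pct_brady, pct_normo = x$pct_normo,
         pct_tachy = x$pct_tachy, total_power = x$total_power)
  } else if (inherits(x, "session_result")) {
    list(
      mode = x$mode, session_index = x$session_index,
      timepoints = lapply(x$timepoints, function(s) {
        if (is.null(s)) NULL
        else list(pct_brady = s$pct_brady, pct_normo = s$pct_normo,
                  pct_tachy = s$pct_tachy, total_power = s$total_power)
      }),
      differences = x$differences, flags = x$flags)
  } else {
    unclass(x)
  }
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
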