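#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

#' Recognized event types
#'
#' The five-value event vocabulary used throughout the package: gamma-band
#' events, ripples (80-250 Hz), fast ripples (250-500 Hz), ultrafast
#' oscillations (> 500 Hz), and interictal spikes.
#'
#' @export
hfo_event_types <- c("gamma", "ripple", "fastripple", "ultrafast", "spike")

#' Construct a table of HFO events
#'
#' Events are stored as a tibble with one row per event. Sample indices are
#' 0-based and intervals are half-open `[start_sample, end_sample)`, so the
#' event duration in seconds is `(end_sample - start_sample) / srate`.
#'
#' @param channel Character, channel label per event.
#' @param start_sample,end_sample Integer sample indices (0-based, half-open).
#' @param type Event type, one of [hfo_event_types].
#' @param avg_freq Average oscillation frequency (Hz).
#' @param n_cycles Number of oscillatory cycles (may be fractional).
#' @param peak_zscore Maximal envelope z-score of the event (SD units).
#' @param bp_low,bp_high Bandpass band used for detection (Hz); `NA` for
#'   events not produced by a bandpass detector (e.g. simulated ground truth).
#'
#' @return A tibble of class `hfo_events`.
#' @export
hfo_events <- function(channel = character(), start_sample = integer(),
                       end_sample = integer(), type = character(),
                       avg_freq = double(), n_cycles = double(),
                       peak_zscore = double(), bp_low = double(),
                       bp_high = double()) {
  ev <- tibble::tibble(
    channel = as.character(channel),
    start_sample = as.integer(start_sample),
    end_sample = as.integer(end_sample),
    type = as.character(type),
    avg_freq = as.double(avg_freq),
    n_cycles = as.double(n_cycles),
    peak_zscore = as.double(peak_zscore),
    bp_low = as.double(bp_low),
    bp_high = as.double(bp_high)
  )
  validate_events(ev)
  class(ev) <- c("hfo_events", class(ev))
  ev
}

#' Validate an event table
#'
#' Checks the structural invariants of an event table: required columns,
#' start before end, known types, positive cycle counts and ordered bands.
#'
#' @param events An event tibble as built by [hfo_events()].
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_events <- function(events) {
  req <- c("channel", "start_sample", "end_sample", "type", "avg_freq",
           "n_cycles", "peak_zscore", "bp_low", "bp_high")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols) > 0) {
    abort(paste("event table lacks columns:", paste(missing_cols, collapse = ", ")),
          class = "hfotools_format_error")
  }
  if (nrow(events) == 0) return(invisible(events))
  if (any(events$start_sample >= events$end_sample)) {
    abort("event intervals must satisfy start_sample < end_sample",
          class = "hfotools_format_error")
  }
  bad_type <- setdiff(unique(events$type), hfo_event_types)
  if (length(bad_type) > 0) {
    abort(paste("unknown event type(s):", paste(bad_type, collapse = ", ")),
          class = "hfotools_format_error")
  }
  if (any(!is.na(events$n_cycles) & events$n_cycles <= 0)) {
    abort("n_cycles must be positive", class = "hfotools_format_error")
  }
  ok_band <- is.na(events$bp_low) | is.na(events$bp_high) |
    events$bp_low < events$bp_high
  if (!all(ok_band)) {
    abort("bp_low must be below bp_high", class = "hfotools_format_error")
  }
  invisible(events)
}

as_hfo_events <- function(df) {
  ev <- hfo_events(
    channel = df$channel, start_sample = df$start_sample,
    end_sample = df$end_sample, type = df$type, avg_freq = df$avg_freq,
    n_cycles = df$n_cycles, peak_zscore = df$peak_zscore,
    bp_low = df$bp_low, bp_high = df$bp_high
  )
  ev
}

events_table_header <- c("channel", "start_clock", "start_s", "end_s",
                         "start_sample", "end_sample", "type", "avg_freq",
                         "n_cycles", "peak_zscore", "bp_low", "bp_high")

#' Write an event table to a tab-separated text file
#'
#' One row per event with the channel, wall-clock and relative start/end
#' times, sample indices, event type, average frequency, cycle count, peak
#' z-score and bandpass band. Relative times are seconds from recording start
#' with 4 decimals; the wall-clock column is derived from `start_clock`.
#'
#' @param events An [hfo_events()] tibble.
#' @param path Output file path.
#' @param srate Sampling rate (samples/s) used to convert samples to seconds.
#' @param start_clock POSIXct wall-clock time of the first sample, or `NA`.
#' @return `path`, invisibly.
#' @seealso [read_events_table()] for the inverse, [write_summary()] for the
#'   per-channel summary file.
#' @export
write_events_table <- function(events, path, srate, start_clock = NA) {
  validate_events(events)
  start_s <- events$start_sample / srate
  end_s <- events$end_sample / srate
  clock <- if (inherits(start_clock, "POSIXct")) {
    format(start_clock + start_s, "%Y-%m-%d %H:%M:%OS3")
  } else {
    rep(NA_character_, nrow(events))
  }
  out <- data.frame(
    channel = events$channel,
    start_clock = clock,
    start_s = sprintf("%.4f", start_s),
    end_s = sprintf("%.4f", end_s),
    start_sample = events$start_sample,
    end_sample = events$end_sample,
    type = events$type,
    avg_freq = fmt_num(events$avg_freq),
    n_cycles = fmt_num(events$n_cycles),
    peak_zscore = fmt_num(events$peak_zscore),
    bp_low = fmt_num(events$bp_low),
    bp_high = fmt_num(events$bp_high),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(events_table_header, collapse = "\t"), con)
  if (nrow(out) > 0) {
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, na = "NA")
  }
  invisible(path)
}

fmt_num <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.9g", x))

#' Read an event table written by [write_events_table()]
#'
#' @param path Path to a tab-separated event table.
#' @return An [hfo_events()] tibble. Malformed rows raise a parse error that
#'   names the offending line.
#' @export
read_events_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste("no such file:", path), class = "hfotools_io_error")
  }
  lines <- readLines(path)
  if (length(lines) == 0 ||
      !identical(strsplit(lines[1], "\t", fixed = TRUE)[[1]], events_table_header)) {
    abort("not an event table: bad or missing header",
          class = "hfotools_parse_error")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) return(hfo_events())
  fields <- strsplit(body, "\t", fixed = TRUE)
  parse_row <- function(parts, lineno) {
    if (length(parts) != length(events_table_header)) {
      abort(sprintf("line %d: expected %d fields, got %d", lineno,
                    length(events_table_header), length(parts)),
            class = "hfotools_parse_error")
    }
    num <- function(x, nm) {
      if (identical(x, "NA")) return(NA_real_)
      v <- suppressWarnings(as.numeric(x))
      if (is.na(v)) {
        abort(sprintf("line %d: field '%s' is not numeric: '%s'", lineno, nm, x),
              class = "hfotools_parse_error")
      }
      v
    }
    list(
      channel = parts[1],
      start_sample = as.integer(num(parts[5], "start_sample")),
      end_sample = as.integer(num(parts[6], "end_sample")),
      type = parts[7],
      avg_freq = num(parts[8], "avg_freq"),
      n_cycles = num(parts[9], "n_cycles"),
      peak_zscore = num(parts[10], "peak_zscore"),
      bp_low = num(parts[11], "bp_low"),
      bp_high = num(parts[12], "bp_high")
    )
  }
  rows <- purrr::imap(fields, function(p, i) parse_row(p, i + 1L))
  df <- dplyr::bind_rows(rows)
  as_hfo_events(df)
}

#' Summarize events per channel
#'
#' Counts each event type and sums its duration per channel. Channels with no
#' events get a zero row, so every label passed in appears exactly once.
#'
#' @param events An [hfo_events()] tibble.
#' @param labels Channel labels to report (typically `recording$labels`).
#' @param srate Sampling rate, to express total durations in seconds.
#' @return A tibble with one row per channel: `n_<type>` counts and
#'   `dur_<type>` total durations (s) for each of the five event types.
#' @export
summarize_events <- function(events, labels, srate) {
  validate_events(events)
  base <- tidyr::expand_grid(channel = labels, type = hfo_event_types)
  tallies <- events %>%
    tibble::as_tibble() %>%
    dplyr::mutate(dur = (.data$end_sample - .data$start_sample) / srate) %>%
    dplyr::group_by(.data$channel, .data$type) %>%
    dplyr::summarise(n = dplyr::n(), dur = sum(.data$dur), .groups = "drop")
  base %>%
    dplyr::left_join(tallies, by = c("channel", "type")) %>%
    dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
                  dur = ifelse(is.na(.data$dur), 0, .data$dur)) %>%
    tidyr::pivot_wider(names_from = "type", values_from = c("n", "dur"),
                       names_sep = "_") %>%
    dplyr::arrange(match(.data$channel, labels))
}

#' Write the per-channel summary file
#'
#' The second of the two text outputs: per channel, the number of occurrences
#' and total duration of each event type.
#'
#' @inheritParams summarize_events
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(events, labels, path, srate) {
  smry <- summarize_events(events, labels, srate)
  utils::write.table(smry, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify a frequency into an event type
#'
#' Conventional bands: gamma below 80 Hz, ripple 80-250 Hz, fast ripple
#' 250-500 Hz, ultrafast above 500 Hz.
#'
#' @param freq Frequency in Hz.
#' @return One of `"gamma"`, `"ripple"`, `"fastripple"`, `"ultrafast"`.
#' @export
classify_frequency <- function(freq) {
  dplyr::case_when(
    freq < 80 ~ "gamma",
    freq < 250 ~ "ripple",
    freq < 500 ~ "fastripple",
    TRUE ~ "ultrafast"
  )
}
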