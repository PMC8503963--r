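#' Construct a multichannel iEEG recording
#'
#' A recording is a channels x samples matrix in microvolts plus its sampling
#' rate, ordered channel labels, the wall-clock time of the first sample and
#' (optionally) the path it was loaded from.
#'
#' @param mat Numeric matrix, channels x samples (microvolts).
#' @param labels Character vector of unique channel names, one per row.
#' @param srate Sampling rate in samples/s.
#' @param start_clock POSIXct time of the first sample; defaults to `NA`.
#' @param file Source file path or `NA`.
#' @return An object of class `hfo_recording`.
#' @export
new_recording <- function(mat, labels, srate, start_clock = NA, file = NA) {
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = 1)
  if (length(labels) != nrow(mat)) {
    abort("number of labels must equal number of matrix rows",
          class = "hfotools_format_error")
  }
  if (anyDuplicated(labels)) {
    abort("channel labels must be unique", class = "hfotools_format_error")
  }
  if (!is.numeric(srate) || length(srate) != 1 || srate <= 0) {
    abort("srate must be a positive scalar", class = "hfotools_domain_error")
  }
  structure(
    list(mat = mat, labels = as.character(labels), srate = srate,
         start_clock = start_clock, file = file),
    class = "hfo_recording"
  )
}

#' @export
print.hfo_recording <- function(x, ...) {
  cat(sprintf("<hfo_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$mat), ncol(x$mat), x$srate, ncol(x$mat) / x$srate))
  cat("  channels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  if (inherits(x$start_clock, "POSIXct")) {
    cat("  start:", format(x$start_clock, "%Y-%m-%d %H:%M:%S"), "\n")
  }
  invisible(x)
}

# Round outward (with `floor` or `ceiling`) to a decimal that prints within
# 8 characters, the width of EDF physical-range header fields.
fit8 <- function(x, outward) {
  vapply(x, function(v) {
    for (digits in 6:0) {
      s <- sprintf("%.*f", digits, outward(v * 10^digits) / 10^digits)
      if (nchar(s) <= 8) return(s)
    }
    stop("physical range too wide for an EDF header field")
  }, character(1))
}

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to a European Data Format (EDF) file
#'
#' Writes standard EDF: a 256-byte fixed header, one 256-byte header block
#' per signal, then 1-second data records of little-endian 16-bit integers
#' scaled between each channel's physical min/max. The sampling rate must be
#' a whole number; recordings whose length is not a whole number of seconds
#' are zero-padded to the next full record (with a warning).
#'
#' @param recording An [new_recording()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  mat <- recording$mat
  srate <- recording$srate
  if (srate != round(srate)) {
    abort("EDF writer requires an integer sampling rate",
          class = "hfotools_domain_error")
  }
  ns <- nrow(mat)
  n <- ncol(mat)
  n_rec <- ceiling(n / srate)
  if (n_rec * srate != n) {
    warn("recording padded with zeros to a whole number of 1 s records")
    pad <- matrix(0, ns, n_rec * srate - n)
    mat <- cbind(mat, pad)
    n <- ncol(mat)
  }
  phys_min <- apply(mat, 1, min)
  phys_max <- apply(mat, 1, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  # the header stores these in 8 ASCII chars; widen to the printed values so
  # the scaling used for quantization matches what a reader will parse
  phys_min_s <- fit8(phys_min, floor)
  phys_max_s <- fit8(phys_max, ceiling)
  phys_min <- as.numeric(phys_min_s)
  phys_max <- as.numeric(phys_max_s)
  dig_min <- -32768
  dig_max <- 32767

  clock <- recording$start_clock
  if (!inherits(clock, "POSIXct")) clock <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8),
    pad_ascii("X X X X", 80),
    pad_ascii("Startdate X X X X", 80),
    pad_ascii(format(clock, "%d.%m.%y"), 8),
    pad_ascii(format(clock, "%H.%M.%S"), 8),
    pad_ascii(256 * (ns + 1), 8),
    pad_ascii("", 44),
    pad_ascii(n_rec, 8),
    pad_ascii("1", 8),
    pad_ascii(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  sig_hdr <- paste0(
    paste(pad_ascii(recording$labels, 16), collapse = ""),
    paste(pad_ascii(rep("", ns), 80), collapse = ""),
    paste(pad_ascii(rep("uV", ns), 8), collapse = ""),
    paste(pad_ascii(phys_min_s, 8), collapse = ""),
    paste(pad_ascii(phys_max_s, 8), collapse = ""),
    paste(pad_ascii(rep(dig_min, ns), 8), collapse = ""),
    paste(pad_ascii(rep(dig_max, ns), 8), collapse = ""),
    paste(pad_ascii(rep("", ns), 80), collapse = ""),
    paste(pad_ascii(rep(srate, ns), 8), collapse = ""),
    paste(pad_ascii(rep("", ns), 32), collapse = "")
  )
  writeChar(sig_hdr, con, eos = NULL)

  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * srate + 1):(r * srate)
    for (ch in seq_len(ns)) {
      dig <- round((mat[ch, idx] - phys_min[ch]) * gain[ch] + dig_min)
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_ascii <- function(con, width) {
  trimws(readChar(con, width, useBytes = TRUE))
}

#' Load a recording from a European Data Format (EDF) file
#'
#' Reads all signals in file order and rescales 16-bit samples to physical
#' units. Duplicate channel labels are de-duplicated with a numeric suffix
#' (with a warning). All signals must share one sampling rate.
#'
#' @param path Path to an EDF file.
#' @return An [new_recording()] object.
#' @export
load_recording <- function(path) {
  if (!file.exists(path)) {
    abort(paste("no such file:", path), class = "hfotools_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii(con, 8)
  if (version != "0") {
    abort("not an EDF file (bad version field)", class = "hfotools_format_error")
  }
  readChar(con, 160, useBytes = TRUE)   # patient + recording id
  date_s <- read_ascii(con, 8)
  time_s <- read_ascii(con, 8)
  readChar(con, 8, useBytes = TRUE)     # header length
  readChar(con, 44, useBytes = TRUE)    # reserved
  n_rec <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  if (is.na(ns) || ns < 1) {
    abort("EDF file declares zero signals", class = "hfotools_format_error")
  }
  labels <- vapply(seq_len(ns), function(i) read_ascii(con, 16), character(1))
  readChar(con, 80 * ns, useBytes = TRUE)  # transducer
  readChar(con, 8 * ns, useBytes = TRUE)   # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), double(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), double(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), double(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), double(1))
  readChar(con, 80 * ns, useBytes = TRUE)  # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(read_ascii(con, 8)), integer(1))
  readChar(con, 32 * ns, useBytes = TRUE)  # reserved

  if (length(unique(spr)) != 1) {
    abort("signals with differing sampling rates are not supported",
          class = "hfotools_format_error")
  }
  srate <- spr[1] / rec_dur
  if (anyDuplicated(labels)) {
    warn("duplicate channel labels de-duplicated with a suffix")
    labels <- make.unique(labels, sep = "_")
  }

  mat <- matrix(0, ns, n_rec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      mat[ch, idx] <- (dig - dig_min[ch]) * gain[ch] + phys_min[ch]
    }
  }

  start_clock <- parse_edf_clock(date_s, time_s)
  new_recording(mat, labels, srate, start_clock = start_clock, file = path)
}

parse_edf_clock <- function(date_s, time_s) {
  tryCatch({
    yy <- as.integer(substr(date_s, 7, 8))
    century <- if (!is.na(yy) && yy >= 85) "19" else "20"
    as.POSIXct(paste0(substr(date_s, 1, 6), century, substr(date_s, 7, 8),
                      " ", gsub(".", ":", time_s, fixed = TRUE)),
               format = "%d.%m.%Y %H:%M:%S", tz = "UTC")
  }, error = function(e) NA)
}
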