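#' FIR filter order for a given band
#'
#' The window-based FIR bandpass uses an order of three times the sampling
#' rate divided by the low cutoff frequency, floored to an integer. This ties
#' the filter length to roughly three periods of the slowest passband
#' component.
#'
#' @param srate Sampling rate (samples/s).
#' @param low_cutoff Low cutoff frequency (Hz).
#' @return Integer filter order.
#' @export
fir_order <- function(srate, low_cutoff) {
  if (!is.numeric(low_cutoff) || low_cutoff <= 0) {
    abort("low_cutoff must be positive", class = "hfotools_domain_error")
  }
  if (!is.numeric(srate) || srate <= 0) {
    abort("srate must be positive", class = "hfotools_domain_error")
  }
  as.integer(floor(3 * srate / low_cutoff))
}

# Zero-phase (forward-backward) filtering with odd-reflection padding.
# Padding suppresses the startup transient that would otherwise appear as a
# spurious high-envelope cluster at the series edges; odd reflection keeps
# the padded series continuous in value. Effective stopband attenuation is
# doubled relative to a single pass.
zero_phase <- function(b, a, x) {
  flen <- max(length(b), length(a))
  pad <- min(3L * flen, length(x) - 1L)
  if (pad < 1) {
    abort("signal too short for zero-phase filtering",
          class = "hfotools_length_error")
  }
  head_pad <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_pad <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - pad)]
  xx <- c(head_pad, x, tail_pad)
  y <- signal::filter(b, a, xx)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(pad + 1):(pad + length(x))]
}

design_bandpass <- function(srate, band, kind) {
  if (band[1] <= 0 || band[1] >= band[2] || band[2] >= srate / 2) {
    abort(sprintf("invalid band (%g, %g) Hz for srate %g", band[1], band[2], srate),
          class = "hfotools_domain_error")
  }
  w <- band / (srate / 2)
  if (kind == "butterworth4") {
    f <- signal::butter(4, w, type = "pass")
    list(b = f$b, a = f$a)
  } else if (kind == "fir_window") {
    ord <- fir_order(srate, band[1])
    if (ord %% 2 == 1) ord <- ord + 1L  # even order => odd length, type-I FIR
    # strip the Ma class so signal::filter dispatches on (b, a, x)
    list(b = as.numeric(signal::fir1(ord, w, type = "pass")), a = 1)
  } else {
    abort(paste("unknown filter kind:", kind), class = "hfotools_domain_error")
  }
}

#' Bandpass filter a signal
#'
#' Zero-phase bandpass filtering with either a fourth-order Butterworth (IIR)
#' filter or a window-based FIR filter whose order is [fir_order()]. Both are
#' applied forward and backward with odd-reflection padding, so the output
#' has no phase delay and edge transients are suppressed.
#'
#' @param x Numeric vector, one channel.
#' @param srate Sampling rate (samples/s).
#' @param band Length-2 numeric, (low, high) cutoff in Hz; must lie inside
#'   (0, srate/2).
#' @param kind `"butterworth4"` (default) or `"fir_window"`.
#' @return Filtered vector of the same length.
#' @export
bandpass <- function(x, srate, band, kind = c("butterworth4", "fir_window")) {
  kind <- match.arg(kind)
  f <- design_bandpass(srate, band, kind)
  if (kind == "fir_window" && length(x) <= 3 * length(f$b)) {
    abort("signal shorter than three FIR filter lengths",
          class = "hfotools_length_error")
  }
  zero_phase(f$b, f$a, x)
}

#' Notch out power-line interference
#'
#' Removes a 50 or 60 Hz line component with a zero-phase second-order IIR
#' notch (narrow band-stop Butterworth, +-2 Hz around the line frequency).
#'
#' @param x Numeric vector.
#' @param srate Sampling rate (samples/s).
#' @param line_freq 50 or 60 (Hz).
#' @return Filtered vector of the same length.
#' @export
notch_filter <- function(x, srate, line_freq) {
  if (!line_freq %in% c(50, 60)) {
    abort("line_freq must be 50 or 60 Hz", class = "hfotools_domain_error")
  }
  if (line_freq >= srate / 2) {
    abort("line frequency above Nyquist", class = "hfotools_domain_error")
  }
  w <- c(line_freq - 2, line_freq + 2) / (srate / 2)
  f <- signal::butter(2, w, type = "stop")
  zero_phase(f$b, f$a, x)
}
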