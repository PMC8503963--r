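#' Locate oscillatory peaks in a bandpassed segment
#'
#' Strict local maxima (greater than both neighbours); on a plateau the first
#' sample is taken. No prominence filter is applied: segments reaching this
#' stage are already bandpass filtered and threshold selected.
#'
#' @param x Numeric vector, a bandpass-filtered event segment.
#' @return Integer vector of 1-based peak indices, strictly increasing.
#' @export
oscillation_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  # collapse plateaus to their first sample, then compare run-level values
  r <- rle(x)
  vals <- r$values
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  k <- length(vals)
  if (k < 3) return(integer(0))
  mid <- 2:(k - 1)
  is_peak <- vals[mid] > vals[mid - 1] & vals[mid] > vals[mid + 1]
  starts[mid][is_peak]
}

#' Average oscillation frequency from peak positions
#'
#' The sampling rate divided by the mean peak-to-peak distance (in samples).
#'
#' @param peaks Integer peak indices from [oscillation_peaks()].
#' @param srate Sampling rate (samples/s).
#' @return Frequency in Hz.
#' @export
average_frequency <- function(peaks, srate) {
  if (length(peaks) < 2) {
    abort("need at least two peaks to estimate a frequency",
          class = "hfotools_insufficient_peaks")
  }
  srate / mean(diff(peaks))
}

#' Number of oscillatory cycles in an event
#'
#' The event duration divided by the mean peak-to-peak interval; may be
#' fractional. Algebraically `duration_s * average_frequency`.
#'
#' @param duration_s Event duration in seconds.
#' @param peaks Integer peak indices from [oscillation_peaks()].
#' @param srate Sampling rate (samples/s).
#' @return Dimensionless cycle count.
#' @export
cycle_count <- function(duration_s, peaks, srate) {
  duration_s * average_frequency(peaks, srate)
}

#' Peak z-score over an event interval
#'
#' @param z Numeric vector of envelope z-scores.
#' @param start_sample,end_sample 0-based half-open interval into `z`.
#' @return Maximum z-score in the interval.
#' @export
peak_zscore <- function(z, start_sample, end_sample) {
  if (end_sample <= start_sample) {
    abort("empty interval", class = "hfotools_domain_error")
  }
  max(z[(start_sample + 1):end_sample])
}

# Characterize a cluster interval: features of Fig-style event panels.
# Returns NULL when fewer than two oscillatory peaks exist (no frequency
# estimate is possible, so the event cannot satisfy a cycle criterion).
characterize_interval <- function(start_sample, end_sample, z, bp, srate,
                                  channel = "ch", band = c(NA_real_, NA_real_)) {
  seg <- bp[(start_sample + 1):end_sample]
  pk <- oscillation_peaks(seg)
  if (length(pk) < 2) return(NULL)
  dur <- (end_sample - start_sample) / srate
  avg_f <- average_frequency(pk, srate)
  hfo_events(
    channel = channel,
    start_sample = start_sample,
    end_sample = end_sample,
    type = classify_frequency(avg_f),
    avg_freq = avg_f,
    n_cycles = cycle_count(dur, pk, srate),
    peak_zscore = peak_zscore(z, start_sample, end_sample),
    bp_low = band[1],
    bp_high = band[2]
  )
}
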