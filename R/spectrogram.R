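#' Spectrogram configuration
#'
#' Parameters of the Gabor-wavelet time-frequency map and of click-guided
#' narrow-band detection. The Gaussian window SD in time at frequency `f` is
#' `sigma_factor / (2 * pi * f)` seconds; the default factor of 6 gives a
#' wavelet of roughly two cycles per standard deviation width, favouring
#' temporal resolution as is usual for transient HFO inspection.
#'
#' @param freqs Frequency grid in Hz, strictly increasing.
#' @param sigma_factor Dimensionless; `sigma = sigma_factor / (2 pi f)`.
#' @param time_window Seconds of spectrogram averaged around a click.
#' @param bandwidth Fixed bandwidth in Hz, or a percentage in (0, 100) when
#'   `percentage_mode` is set.
#' @param percentage_mode If `TRUE`, `bandwidth` is read as a percentage of
#'   the spectral peak at which the band cutoffs are placed.
#' @return A list of class `spectrogram_config`.
#' @export
spectrogram_config <- function(freqs = seq(60, 500, by = 5), sigma_factor = 6,
                               time_window = 0.2, bandwidth = 20,
                               percentage_mode = FALSE) {
  if (any(diff(freqs) <= 0) || any(freqs <= 0)) {
    abort("freqs must be positive and strictly increasing",
          class = "hfotools_domain_error")
  }
  if (time_window <= 0) {
    abort("time_window must be positive", class = "hfotools_domain_error")
  }
  if (percentage_mode && (bandwidth <= 0 || bandwidth > 100)) {
    abort("percentage bandwidth must lie in (0, 100]",
          class = "hfotools_domain_error")
  }
  structure(
    list(freqs = freqs, sigma_factor = sigma_factor,
         time_window = time_window, bandwidth = bandwidth,
         percentage_mode = percentage_mode),
    class = "spectrogram_config"
  )
}

#' Continuous Gabor-wavelet transform
#'
#' Time-frequency magnitude map from a Gaussian-windowed complex exponential
#' (Gabor/Morlet-type) wavelet with `1/sqrt(scale)` normalization, evaluated
#' by frequency-domain convolution per frequency row.
#'
#' @param x Numeric signal.
#' @param srate Sampling rate (samples/s).
#' @param cfg A [spectrogram_config()].
#' @return An object of class `hfo_tfm`: list with `mag` (frequencies x
#'   samples, nonnegative), `freqs`, and `srate`.
#' @export
gabor_cwt <- function(x, srate, cfg = spectrogram_config()) {
  if (any(cfg$freqs >= srate / 2)) {
    abort("requested frequencies reach the Nyquist frequency",
          class = "hfotools_domain_error")
  }
  n <- length(x)
  X <- stats::fft(x)
  # angular frequency of each FFT bin (rad/s), with negative upper half
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  omega <- 2 * pi * k * srate / n
  mag <- matrix(0, length(cfg$freqs), n)
  for (i in seq_along(cfg$freqs)) {
    f <- cfg$freqs[i]
    sigma <- cfg$sigma_factor / (2 * pi * f)      # seconds
    scale <- 1 / f
    # FT of the unit-energy Gaussian-windowed exponential, centred at 2*pi*f
    psi <- (4 * pi * sigma^2)^(1 / 4) * exp(-sigma^2 * (omega - 2 * pi * f)^2 / 2)
    coef <- stats::fft(X * psi, inverse = TRUE) / n
    mag[i, ] <- Mod(coef) / sqrt(scale)
  }
  structure(list(mag = mag, freqs = cfg$freqs, srate = srate),
            class = "hfo_tfm")
}

#' @export
print.hfo_tfm <- function(x, ...) {
  cat(sprintf("<hfo_tfm> %d frequencies (%g-%g Hz) x %d samples @ %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs), ncol(x$mag),
              x$srate))
  invisible(x)
}

# Time-averaged spectrum around a click, window clipped at the series edges.
average_spectrum_at <- function(tfm, click_sample, time_window_s) {
  n <- ncol(tfm$mag)
  if (click_sample < 0 || click_sample >= n) {
    abort("click outside the series", class = "hfotools_domain_error")
  }
  half <- round(time_window_s / 2 * tfm$srate)
  lo <- max(0, click_sample - half)
  hi <- min(n - 1, click_sample + half)
  tibble::tibble(
    freq = tfm$freqs,
    mag = rowMeans(tfm$mag[, (lo + 1):(hi + 1), drop = FALSE])
  )
}

#' Peak frequency of the spectrogram at a click
#'
#' Averages the magnitude map over a small time window centred at the click
#' (clipped at the series edges) and returns the frequency of maximal
#' average magnitude.
#'
#' @param tfm An `hfo_tfm` from [gabor_cwt()].
#' @param click_sample 0-based sample index of the click.
#' @param time_window_s Averaging window in seconds.
#' @return Peak frequency in Hz (a grid point).
#' @export
peak_frequency_at <- function(tfm, click_sample, time_window_s = 0.2) {
  spec <- average_spectrum_at(tfm, click_sample, time_window_s)
  spec$freq[which.max(spec$mag)]
}

#' Narrow band around a spectral peak
#'
#' In fixed mode the band is `peak +- bandwidth/2`. In percentage mode the
#' cutoffs are the nearest frequencies on each side of the peak at which the
#' averaged spectrum drops to `bandwidth`% of its maximum; if the spectrum
#' never drops below the cutoff on a side, the grid edge is used.
#'
#' @param avg_spectrum Tibble with columns `freq`, `mag` (e.g. from the
#'   spectrogram averaged around a click).
#' @param peak_freq Peak frequency; must be a grid point of `avg_spectrum`.
#' @param cfg A [spectrogram_config()] (uses `bandwidth`/`percentage_mode`).
#' @param nyquist Optional Nyquist frequency for validity checking (Hz).
#' @return Numeric `(low, high)` band in Hz.
#' @export
band_from_peak <- function(avg_spectrum, peak_freq, cfg, nyquist = Inf) {
  if (!cfg$percentage_mode) {
    band <- c(peak_freq - cfg$bandwidth / 2, peak_freq + cfg$bandwidth / 2)
  } else {
    i_pk <- match(peak_freq, avg_spectrum$freq)
    if (is.na(i_pk)) {
      abort("peak_freq is not on the spectrum grid",
            class = "hfotools_domain_error")
    }
    cutoff <- cfg$bandwidth / 100 * max(avg_spectrum$mag)
    if (cutoff >= avg_spectrum$mag[i_pk]) {
      abort("cutoff percentage leaves no band around the peak",
            class = "hfotools_degenerate_band")
    }
    below <- avg_spectrum$mag <= cutoff
    lo_idx <- which(below & seq_along(below) < i_pk)
    hi_idx <- which(below & seq_along(below) > i_pk)
    low <- if (length(lo_idx)) avg_spectrum$freq[max(lo_idx)] else avg_spectrum$freq[1]
    high <- if (length(hi_idx)) avg_spectrum$freq[min(hi_idx)] else avg_spectrum$freq[nrow(avg_spectrum)]
    band <- c(low, high)
  }
  if (band[1] >= band[2] || band[1] <= 0 || band[2] >= nyquist) {
    abort(sprintf("degenerate band (%g, %g) Hz", band[1], band[2]),
          class = "hfotools_degenerate_band")
  }
  band
}

#' Spectrogram-guided narrow-band detection at a click
#'
#' Composes [peak_frequency_at()], [band_from_peak()], a narrow [bandpass()]
#' of the raw series, and [detect_at_cursor()] at the click. The returned
#' event's band columns record the narrow band actually used.
#'
#' @param x Raw signal (one channel).
#' @param srate Sampling rate.
#' @param click_sample 0-based click position.
#' @param spec_cfg A [spectrogram_config()].
#' @param det_cfg A [hilbert_config()] providing thresholds, cycle criterion,
#'   baseline and search range.
#' @param channel Channel label for the resulting event.
#' @return An [hfo_events()] row, or `NULL` (quiet background or degenerate
#'   band; the reason is reported as a message).
#' @export
spectrogram_guided_detect <- function(x, srate, click_sample,
                                      spec_cfg = spectrogram_config(),
                                      det_cfg = hilbert_config(),
                                      channel = "ch") {
  tfm <- gabor_cwt(x, srate, spec_cfg)
  spec <- average_spectrum_at(tfm, click_sample, spec_cfg$time_window)
  peak <- spec$freq[which.max(spec$mag)]
  band <- tryCatch(
    band_from_peak(spec, peak, spec_cfg, nyquist = srate / 2),
    hfotools_degenerate_band = function(e) {
      rlang::inform(paste("no detection:", conditionMessage(e)))
      NULL
    }
  )
  if (is.null(band)) return(NULL)
  cfg <- det_cfg
  cfg$band <- band
  bp <- bandpass(x, srate, band, kind = cfg$filter_kind)
  env <- hilbert_envelope(bp)
  z <- zscore_envelope(env, baseline = cfg$baseline, srate = srate)
  detect_at_cursor(z, bp, srate, click_sample, cfg, channel = channel)
}

#' Plot a time-frequency map
#'
#' @param object An `hfo_tfm` from [gabor_cwt()].
#' @param max_cols Maximum number of time columns drawn (the map is thinned
#'   by an integer stride above this).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hfo_tfm <- function(object, max_cols = 2000, ...) {
  n <- ncol(object$mag)
  stride <- max(1L, ceiling(n / max_cols))
  cols <- seq(1L, n, by = stride)
  df <- tidyr::expand_grid(time = (cols - 1) / object$srate,
                           freq = object$freqs)
  df$mag <- as.vector(object$mag[, cols])  # column-major: freq fastest
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$mag)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "|C|") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}
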