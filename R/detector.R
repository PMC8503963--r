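#' Configuration for the two-threshold Hilbert detector
#'
#' The detector bandpass filters the raw series, takes the Hilbert envelope,
#' z-scores it against a baseline (the whole series or fixed-length epochs),
#' cuts clusters at the onset threshold and accepts a cluster as an event if
#' (1) its maximal z-score reaches the inclusion threshold and (2) its cycle
#' count reaches `min_cycles`.
#'
#' @param band Bandpass band (low, high) in Hz.
#' @param onset_threshold Lower SD threshold that defines cluster boundaries.
#' @param inclusion_threshold Higher SD threshold the cluster peak must reach.
#' @param min_cycles Minimum number of oscillatory cycles (may be fractional).
#' @param baseline `"whole"` or a baseline epoch length in seconds; the
#'   envelope is z-scored (and clusters are cut) per epoch.
#' @param notch `NULL`, 50 or 60: optional power-line notch before detection.
#' @param filter_kind `"butterworth4"` or `"fir_window"`.
#' @param search_range Search range in seconds for cursor-guided detection.
#' @return A list of class `hilbert_config`.
#' @export
hilbert_config <- function(band = c(80, 250), onset_threshold = 1,
                           inclusion_threshold = 5, min_cycles = 2.4,
                           baseline = 600, notch = NULL,
                           filter_kind = c("butterworth4", "fir_window"),
                           search_range = 0.2) {
  filter_kind <- match.arg(filter_kind)
  if (onset_threshold > inclusion_threshold) {
    abort("onset_threshold must not exceed inclusion_threshold",
          class = "hfotools_domain_error")
  }
  if (min_cycles <= 0) {
    abort("min_cycles must be positive", class = "hfotools_domain_error")
  }
  if (!(identical(baseline, "whole") ||
        (is.numeric(baseline) && baseline > 0))) {
    abort("baseline must be \"whole\" or a positive epoch length in seconds",
          class = "hfotools_domain_error")
  }
  structure(
    list(band = band, onset_threshold = onset_threshold,
         inclusion_threshold = inclusion_threshold, min_cycles = min_cycles,
         baseline = baseline, notch = notch, filter_kind = filter_kind,
         search_range = search_range),
    class = "hilbert_config"
  )
}

#' Hilbert envelope of a bandpassed signal
#'
#' Magnitude of the analytic signal, computed by the FFT construction
#' (positive frequencies doubled, negative zeroed).
#'
#' @param x Numeric vector (typically bandpass filtered).
#' @return Nonnegative vector of the same length.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# Start indices (1-based) of baseline epochs for a series of length n.
epoch_bounds <- function(n, baseline, srate) {
  if (identical(baseline, "whole")) return(cbind(start = 1L, end = n))
  len <- as.integer(round(baseline * srate))
  starts <- seq(1L, n, by = len)
  cbind(start = starts, end = pmin(starts + len - 1L, n))
}

#' Z-score an envelope against a baseline
#'
#' Subtracts the baseline mean and divides by the baseline SD. The baseline
#' is either the whole series or consecutive epochs of fixed length, each
#' normalized independently (a trailing partial epoch is its own baseline).
#'
#' @param env Envelope vector.
#' @param baseline `"whole"` or epoch length in seconds.
#' @param srate Sampling rate (samples/s).
#' @return Vector of z-scores, same length as `env`.
#' @export
zscore_envelope <- function(env, baseline = "whole", srate = NULL) {
  if (!identical(baseline, "whole") && is.null(srate)) {
    abort("srate is required for epoch baselines", class = "hfotools_domain_error")
  }
  eb <- epoch_bounds(length(env), baseline, srate)
  z <- env
  for (i in seq_len(nrow(eb))) {
    seg <- env[eb[i, 1]:eb[i, 2]]
    s <- stats::sd(seg)
    if (!is.finite(s) || s == 0) {
      abort("degenerate baseline: zero variance", class = "hfotools_degenerate_baseline")
    }
    z[eb[i, 1]:eb[i, 2]] <- (seg - mean(seg)) / s
  }
  z
}

#' Find supra-threshold clusters
#'
#' Maximal runs of `z >= onset_threshold`, returned in temporal order as a
#' tibble of 0-based half-open intervals with each cluster's peak z-score.
#'
#' @param z Z-scored envelope.
#' @param onset_threshold Onset threshold in SD units.
#' @return Tibble with columns `start_sample`, `end_sample`, `peak_z`.
#' @export
find_clusters <- function(z, onset_threshold) {
  above <- z >= onset_threshold
  if (!any(above)) {
    return(tibble::tibble(start_sample = integer(0), end_sample = integer(0),
                          peak_z = double(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  s <- starts[keep]
  e <- ends[keep]
  tibble::tibble(
    start_sample = s - 1L,
    end_sample = e,
    peak_z = purrr::map2_dbl(s, e, function(a, b) max(z[a:b]))
  )
}

#' Qualify a cluster as an HFO event
#'
#' A cluster becomes an event iff its maximal z-score reaches the inclusion
#' threshold and its cycle count (duration over mean peak-to-peak interval of
#' the bandpassed series, measured inside the onset-threshold boundaries)
#' reaches `min_cycles`. Event boundaries are the onset-threshold crossings;
#' no padding is applied.
#'
#' @param start_sample,end_sample Cluster interval (0-based, half-open).
#' @param z Z-scored envelope.
#' @param bp Bandpass-filtered signal.
#' @param srate Sampling rate.
#' @param cfg A [hilbert_config()].
#' @param channel Channel label for the resulting event.
#' @return An [hfo_events()] row, or `NULL` if the cluster does not qualify.
#' @export
qualify_cluster <- function(start_sample, end_sample, z, bp, srate, cfg,
                            channel = "ch") {
  if (max(z[(start_sample + 1):end_sample]) < cfg$inclusion_threshold) {
    return(NULL)
  }
  ev <- characterize_interval(start_sample, end_sample, z, bp, srate,
                              channel = channel, band = cfg$band)
  if (is.null(ev) || ev$n_cycles < cfg$min_cycles) return(NULL)
  ev
}

# Shared pipeline: filter, envelope, per-epoch z-score. Returns bp and z.
prepare_channel <- function(x, srate, cfg) {
  if (!is.null(cfg$notch)) x <- notch_filter(x, srate, cfg$notch)
  bp <- bandpass(x, srate, cfg$band, kind = cfg$filter_kind)
  env <- hilbert_envelope(bp)
  z <- zscore_envelope(env, baseline = cfg$baseline, srate = srate)
  list(bp = bp, z = z)
}

# Clusters cut independently within each baseline epoch (a cluster abutting
# an epoch edge is kept as-is, never merged across epochs).
epochwise_clusters <- function(z, onset_threshold, baseline, srate) {
  eb <- epoch_bounds(length(z), baseline, srate)
  cl <- purrr::map(seq_len(nrow(eb)), function(i) {
    ci <- find_clusters(z[eb[i, 1]:eb[i, 2]], onset_threshold)
    ci$start_sample <- ci$start_sample + eb[i, 1] - 1L
    ci$end_sample <- ci$end_sample + eb[i, 1] - 1L
    ci
  })
  dplyr::bind_rows(cl)
}

#' Detect HFO events on one channel
#'
#' Runs the full two-threshold Hilbert pipeline on a single channel:
#' optional notch, bandpass, Hilbert envelope, per-epoch z-scoring, onset
#' clustering and two-criterion qualification.
#'
#' @param recording An [new_recording()] object.
#' @param channel Channel label.
#' @param cfg A [hilbert_config()].
#' @return An [hfo_events()] tibble sorted by start sample.
#' @export
detect_channel <- function(recording, channel, cfg = hilbert_config()) {
  ch <- match(channel, recording$labels)
  if (is.na(ch)) {
    abort(paste("no such channel:", channel), class = "hfotools_domain_error")
  }
  x <- recording$mat[ch, ]
  srate <- recording$srate
  if (stats::sd(x) == 0) return(hfo_events())
  p <- prepare_channel(x, srate, cfg)
  cl <- epochwise_clusters(p$z, cfg$onset_threshold, cfg$baseline, srate)
  evs <- purrr::map2(cl$start_sample, cl$end_sample, function(s, e) {
    qualify_cluster(s, e, p$z, p$bp, srate, cfg, channel = channel)
  })
  evs <- purrr::compact(evs)
  if (length(evs) == 0) return(hfo_events())
  dplyr::bind_rows(evs) %>% dplyr::arrange(.data$start_sample) %>% as_hfo_events()
}

#' Detect HFO events on all (or selected) channels
#'
#' @inheritParams detect_channel
#' @param channels Channel labels to run on; defaults to all.
#' @return An [hfo_events()] tibble, events sorted within channel.
#' @export
detect_events <- function(recording, cfg = hilbert_config(),
                          channels = recording$labels) {
  out <- purrr::map(channels, function(ch) detect_channel(recording, ch, cfg))
  df <- dplyr::bind_rows(out)
  if (nrow(df) == 0) return(hfo_events())
  as_hfo_events(df)
}

#' Cursor-guided detection
#'
#' Among clusters having any sample within `cfg$search_range` seconds of the
#' cursor, the nearest one is qualified (an exact tie goes to the earlier
#' cluster). Returns `NULL` when no cluster is in range or qualification
#' fails.
#'
#' @param z Z-scored envelope.
#' @param bp Bandpass-filtered signal.
#' @param srate Sampling rate.
#' @param cursor_sample 0-based cursor position.
#' @param cfg A [hilbert_config()].
#' @param channel Channel label for the resulting event.
#' @return An [hfo_events()] row or `NULL`.
#' @export
detect_at_cursor <- function(z, bp, srate, cursor_sample,
                             cfg = hilbert_config(), channel = "ch") {
  cl <- find_clusters(z, cfg$onset_threshold)
  if (nrow(cl) == 0) return(NULL)
  # distance from cursor to the closed sample set of each cluster
  dist <- pmax(cl$start_sample - cursor_sample,
               cursor_sample - (cl$end_sample - 1L), 0L)
  in_range <- dist <= cfg$search_range * srate
  if (!any(in_range)) return(NULL)
  cand <- which(in_range)
  best <- cand[order(dist[cand], cl$start_sample[cand])][1]
  qualify_cluster(cl$start_sample[best], cl$end_sample[best], z, bp, srate,
                  cfg, channel = channel)
}

#' Single-threshold duration-based Hilbert detector
#'
#' The comparator detector: the envelope is z-scored per epoch, maximal runs
#' of `z >= sd_threshold` lasting at least `min_duration_ms` become events,
#' characterized with the same feature set as the two-threshold detector.
#'
#' @param x Numeric vector, one channel.
#' @param srate Sampling rate (samples/s).
#' @param band Bandpass band (low, high) Hz.
#' @param sd_threshold Single SD threshold.
#' @param min_duration_ms Minimal event duration in milliseconds.
#' @param epoch_s Baseline epoch length in seconds (or `"whole"`).
#' @param filter_kind Passed to [bandpass()].
#' @param channel Channel label for resulting events.
#' @return An [hfo_events()] tibble.
#' @export
ripplelab_hilbert <- function(x, srate, band = c(80, 250), sd_threshold = 3.5,
                              min_duration_ms = 10, epoch_s = 600,
                              filter_kind = "butterworth4", channel = "ch") {
  if (stats::sd(x) == 0) return(hfo_events())
  cfg <- hilbert_config(band = band, onset_threshold = sd_threshold,
                        inclusion_threshold = sd_threshold, min_cycles = 1e-9,
                        baseline = epoch_s, filter_kind = filter_kind)
  p <- prepare_channel(x, srate, cfg)
  cl <- epochwise_clusters(p$z, sd_threshold, cfg$baseline, srate)
  min_len <- min_duration_ms / 1000 * srate
  cl <- cl[cl$end_sample - cl$start_sample >= min_len, , drop = FALSE]
  evs <- purrr::map2(cl$start_sample, cl$end_sample, function(s, e) {
    characterize_interval(s, e, p$z, p$bp, srate, channel = channel,
                          band = band)
  })
  evs <- purrr::compact(evs)
  if (length(evs) == 0) return(hfo_events())
  dplyr::bind_rows(evs) %>% dplyr::arrange(.data$start_sample) %>% as_hfo_events()
}
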