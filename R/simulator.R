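# Evaluate code under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Parameters of the synthetic iEEG generator. The background is a sum of
#' unit-amplitude sinusoids at `base_freqs`; HFO bursts are Hann-tapered
#' sinusoids at `hfo_freqs`, `events_per_freq` of each, with an integer cycle
#' count drawn uniformly from `cycle_range`, inserted at uniformly random
#' non-overlapping onsets. Burst amplitude is `hfo_amp_factor` times the RMS
#' of the background.
#'
#' @param base_freqs Background sinusoid frequencies (Hz).
#' @param srate Sampling rate (samples/s).
#' @param duration Recording length in seconds.
#' @param hfo_freqs HFO burst frequencies (Hz).
#' @param events_per_freq Number of bursts inserted per HFO frequency.
#' @param cycle_range Integer (low, high) range of cycles per burst.
#' @param hfo_amp_factor Burst amplitude as a multiple of background RMS.
#'   The default of 6 puts bursts clearly above the background, so that on
#'   noise-free data detection is essentially at ceiling (see the methods
#'   vignette for the calibration).
#' @param min_separation Minimum spacing in seconds between inserted bursts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(base_freqs = c(2.5, 6.0, 10.0, 16.0, 32.5, 67.5, 165.0,
                                      250.0, 425.0, 500.0, 800.0, 1500.0),
                       srate = 2000, duration = 600,
                       hfo_freqs = c(100, 140, 180, 220),
                       events_per_freq = 20, cycle_range = c(3L, 10L),
                       hfo_amp_factor = 6, min_separation = 0.5) {
  if (any(hfo_freqs >= srate / 2)) {
    abort("hfo_freqs must lie below the Nyquist frequency",
          class = "hfotools_domain_error")
  }
  if (events_per_freq < 0 || cycle_range[1] > cycle_range[2]) {
    abort("invalid event count or cycle range", class = "hfotools_domain_error")
  }
  structure(
    list(base_freqs = base_freqs, srate = srate, duration = duration,
         hfo_freqs = hfo_freqs, events_per_freq = events_per_freq,
         cycle_range = as.integer(cycle_range),
         hfo_amp_factor = hfo_amp_factor, min_separation = min_separation),
    class = "sim_config"
  )
}

#' Simulate a clean (noise-free) dataset with ground truth
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return A list of class `hfo_simdata`: `recording` (one channel), `truth`
#'   (an [hfo_events()] tibble with the exact insertion intervals; the band
#'   columns and peak z-scores are `NA`), `config`, `snr` (`NULL`), `seed`.
#' @export
simulate_clean <- function(cfg = sim_config(), seed = 1) {
  with_seed(seed, {
    n <- round(cfg$duration * cfg$srate)
    t <- (0:(n - 1)) / cfg$srate
    x <- numeric(n)
    for (f in cfg$base_freqs) x <- x + sin(2 * pi * f * t)
    bg_rms <- sqrt(mean(x^2))
    amp <- cfg$hfo_amp_factor * bg_rms

    freqs <- rep(cfg$hfo_freqs, each = cfg$events_per_freq)
    cycles <- sample(seq(cfg$cycle_range[1], cfg$cycle_range[2]),
                     length(freqs), replace = TRUE)
    lens <- round(cycles / freqs * cfg$srate)

    sep <- round(cfg$min_separation * cfg$srate)
    starts <- integer(length(freqs))
    placed_s <- integer(0)
    placed_e <- integer(0)
    for (i in seq_along(freqs)) {
      ok <- FALSE
      for (try in 1:10000) {
        s <- sample.int(n - lens[i] - 2L * sep, 1) + sep
        e <- s + lens[i]
        if (!any(s - sep < placed_e & e + sep > placed_s)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort("could not place events without overlap",
              class = "hfotools_placement_error")
      }
      starts[i] <- s
      placed_s <- c(placed_s, s)
      placed_e <- c(placed_e, e)
    }

    for (i in seq_along(freqs)) {
      idx <- starts[i]:(starts[i] + lens[i] - 1L)
      tt <- (0:(lens[i] - 1L)) / cfg$srate
      taper <- 0.5 * (1 - cos(2 * pi * (0:(lens[i] - 1L)) / (lens[i] - 1L)))
      x[idx + 1L] <- x[idx + 1L] + amp * taper * sin(2 * pi * freqs[i] * tt)
    }

    ord <- order(starts)
    truth <- hfo_events(
      channel = "sim1",
      start_sample = starts[ord],
      end_sample = (starts + lens)[ord],
      type = classify_frequency(freqs[ord]),
      avg_freq = freqs[ord],
      n_cycles = cycles[ord],
      peak_zscore = NA_real_,
      bp_low = NA_real_,
      bp_high = NA_real_
    )
    rec <- new_recording(matrix(x, nrow = 1), labels = "sim1",
                         srate = cfg$srate,
                         start_clock = as.POSIXct("2021-01-01 00:00:00",
                                                  tz = "UTC"))
    structure(list(recording = rec, truth = truth, config = cfg,
                   snr = NULL, seed = seed),
              class = "hfo_simdata")
  })
}

#' Add white Gaussian noise at a given signal-to-noise ratio
#'
#' SNR is defined as the power ratio of the clean signal to the added noise:
#' the noise SD is `sqrt(mean(x^2) / snr)`.
#'
#' @param x Clean signal.
#' @param snr Positive power ratio, or `NULL` for no noise.
#' @param seed Integer seed; the same seed reproduces the same noise.
#' @return Noisy signal of the same length.
#' @export
add_noise <- function(x, snr, seed = 1) {
  if (is.null(snr)) return(x)
  if (!is.numeric(snr) || snr <= 0) {
    abort("snr must be positive", class = "hfotools_domain_error")
  }
  with_seed(seed, x + stats::rnorm(length(x), sd = sqrt(mean(x^2) / snr)))
}

#' Simulate one dataset at a given noise level
#'
#' @param cfg A [sim_config()].
#' @param snr Signal-to-noise power ratio, or `NULL` for the noise-free
#'   condition.
#' @param seed Integer seed for both burst placement and noise.
#' @return An `hfo_simdata` (see [simulate_clean()]) with `snr` recorded.
#' @export
simulate_dataset <- function(cfg = sim_config(), snr = NULL, seed = 1) {
  ds <- simulate_clean(cfg, seed = seed)
  if (!is.null(snr)) {
    ds$recording$mat[1, ] <- add_noise(ds$recording$mat[1, ], snr,
                                       seed = seed + 499979L)
    ds$snr <- snr
  }
  ds
}

suite_seed <- function(master_seed, condition_index, replicate) {
  master_seed + 1009L * (condition_index * 100L + replicate)
}

#' Generate the full validation suite
#'
#' Eleven conditions — noise-free plus SNR 1 through 10 — with a fixed
#' number of replicate datasets per condition (defaults: 10 replicates, 110
#' datasets in total). Deterministic given the master seed.
#'
#' @param cfg A [sim_config()].
#' @param master_seed Integer master seed; per-dataset seeds are derived
#'   from it.
#' @param conditions Numeric vector of SNR levels, with `NA` denoting the
#'   noise-free condition.
#' @param replicates Replicate datasets per condition.
#' @return A list of `hfo_simdata` objects, conditions in order, replicates
#'   within condition.
#' @export
generate_suite <- function(cfg = sim_config(), master_seed = 1,
                           conditions = c(NA, 1:10), replicates = 10) {
  out <- list()
  for (k in seq_along(conditions)) {
    for (r in seq_len(replicates)) {
      snr <- if (is.na(conditions[k])) NULL else conditions[k]
      out[[length(out) + 1L]] <-
        simulate_dataset(cfg, snr = snr,
                         seed = suite_seed(master_seed, k, r))
    }
  }
  out
}

#' @export
print.hfo_simdata <- function(x, ...) {
  cat(sprintf("<hfo_simdata> %.0f s @ %g Hz, %d truth events, %s\n",
              ncol(x$recording$mat) / x$recording$srate, x$recording$srate,
              nrow(x$truth),
              if (is.null(x$snr)) "noise-free" else paste("SNR", x$snr)))
  invisible(x)
}
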