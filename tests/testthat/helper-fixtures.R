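# Shared fixtures: small signals and recordings built in code.

tone <- function(freq, srate = 2000, duration = 1, amp = 1, phase = 0) {
  t <- seq(0, duration - 1 / srate, by = 1 / srate)
  amp * sin(2 * pi * freq * t + phase)
}

# 2-channel test recording: a ripple-band tone plus a slow wave
tiny_recording <- function(srate = 2000, duration = 2) {
  mat <- rbind(tone(100, srate, duration),
               tone(7, srate, duration, amp = 50))
  new_recording(mat, labels = c("chA", "chB"), srate = srate,
                start_clock = as.POSIXct("2021-06-01 12:00:00", tz = "UTC"))
}

random_events <- function(n, channels = c("A", "B", "C"), seed = 1) {
  set.seed(seed)
  start <- sort(sample.int(100000, n)) * 10L
  hfo_events(
    channel = sample(channels, n, replace = TRUE),
    start_sample = start,
    end_sample = start + sample(20:400, n, replace = TRUE),
    type = sample(hfo_event_types, n, replace = TRUE),
    avg_freq = runif(n, 80, 500),
    n_cycles = runif(n, 1, 12),
    peak_zscore = runif(n, 3, 30),
    bp_low = 80,
    bp_high = 500
  )
}

# small simulated dataset for fast end-to-end tests
small_simdata <- function(seed = 7, snr = NULL, events_per_freq = 5,
                          duration = 60) {
  simulate_dataset(sim_config(duration = duration,
                              events_per_freq = events_per_freq),
                   snr = snr, seed = seed)
}

small_hilbert_cfg <- function(duration = 60) {
  hilbert_config(baseline = duration)
}
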