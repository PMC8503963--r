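# hfotools

Detection, characterization and simulation of high-frequency oscillations
(HFOs) in intracranial EEG.

HFOs are brief oscillatory bursts (roughly 80–500 Hz, a few cycles long)
recorded with intracranial electrodes and studied as a biomarker of
epileptogenic tissue. `hfotools` is aimed at researchers who need a
scriptable detection pipeline and a controlled benchmark for it: it detects
HFOs, characterizes them, writes the standard tabular outputs, and — because
ground truth is unobtainable in patient data — ships a synthetic iEEG
generator and a validation harness for measuring detector performance.

## What is in the box

* **Two-threshold Hilbert detector.** The signal is bandpass filtered
  (zero-phase fourth-order Butterworth or window FIR), its Hilbert envelope
  is z-scored against a baseline (whole series or fixed epochs, e.g. 600 s),
  and maximal runs with *z* ≥ onset threshold (default 1 SD) become
  candidate clusters whose crossings define the event boundaries. A cluster
  is accepted iff its peak *z* reaches the inclusion threshold (default
  5 SD) **and** its cycle count — duration divided by the mean peak-to-peak
  interval — reaches `min_cycles` (default 2.4). Fully automatic
  (`detect_events()`), cursor-guided (`detect_at_cursor()`) and
  spectrogram-guided (`spectrogram_guided_detect()`) modes share this core.
* **Single-threshold comparator** (`ripplelab_hilbert()`): one SD threshold
  plus a minimal duration in ms, for benchmarking against the classic
  design.
* **Gabor-wavelet spectrogram** (`gabor_cwt()`): Gaussian-windowed complex
  exponential with σ = 6/(2πf) by default, used to pick a peak frequency at
  a clicked time and derive a narrow detection band (fixed width or
  percentage-of-peak cutoffs).
* **Event characterization:** average frequency, cycle count, peak z-score,
  band; five-type vocabulary (gamma, ripple, fastripple, ultrafast, spike).
* **Synthetic iEEG** (`simulate_dataset()`, `generate_suite()`): twelve
  background sinusoids at 2000 Hz, Hann-tapered HFO bursts at
  100/140/180/220 Hz (20 each, 3–10 cycles), white noise at SNR 1–10 by
  power ratio, exact ground-truth event records.
* **Validation** (`run_validation()`): sensitivity, false-detection
  proportion and relative duration per noise condition, with SE across
  replicate datasets; `tidy()`, `glance()` and `autoplot()` methods.
* **I/O:** EDF read/write (`load_recording()`, `write_edf()`), tab-separated
  event tables and per-channel summaries (`write_events_table()`,
  `read_events_table()`, `write_summary()`).
* **CLI:** `inst/cli/hfoscan.R` with `simulate`, `detect` and `validate`
  subcommands for shell use.

## Worked example

```r
library(hfotools)

# one synthetic 10-min iEEG channel with 80 inserted HFO bursts, SNR 5
ds <- simulate_dataset(sim_config(), snr = 5, seed = 42)
ds
#> <hfo_simdata> 600 s @ 2000 Hz, 80 truth events, SNR 5

cfg <- hilbert_config(band = c(80, 250), onset_threshold = 1,
                      inclusion_threshold = 5, min_cycles = 2.4,
                      baseline = 600)
events <- detect_channel(ds$recording, "sim1", cfg)
print(events, n = 3)
#> # A tibble: 80 × 9
#>   channel start_sample end_sample type   avg_freq n_cycles peak_zscore bp_low
#>   <chr>          <int>      <int> <chr>     <dbl>    <dbl>       <dbl>  <dbl>
#> 1 sim1            6264       6345 ripple     105.     4.26        15.6     80
#> 2 sim1            9087       9140 ripple     182.     4.82        18.8     80
#> 3 sim1           17109      17201 ripple     182.     8.36        16.8     80
#> # ℹ 77 more rows
#> # ℹ 1 more variable: bp_high <dbl>

score_detections(events, ds$truth)
#> # A tibble: 1 × 6
#>   sensitivity false_rate mean_relative_duration n_truth n_detected n_matched
#>         <dbl>      <dbl>                  <dbl>   <int>      <int>     <int>
#> 1           1          0                  0.855      80         80        80
```

Each detected event reports where it is (0-based half-open sample
interval), what it is (all fall in the ripple band here), its average
frequency in Hz, how many oscillatory cycles it spans, and how far its
envelope rose above baseline in SD units. The score line says all 80
inserted bursts were recovered with no false detections; matched detections
cover ~86% of the inserted durations because event boundaries sit at the
onset-threshold crossings of the tapered bursts.

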