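#' Match detected events to ground truth
#'
#' Greedy one-to-one matching by start time: truth events are visited in
#' start order and each is matched to the earliest-starting unused detected
#' event whose interval overlaps it by at least one sample. Detected events
#' left unmatched are false detections.
#'
#' @param detected,truth [hfo_events()] tibbles, non-overlapping within
#'   themselves.
#' @return Tibble with columns `truth` and `detected`: row indices of the
#'   matched pairs.
#' @export
match_events <- function(detected, truth) {
  ot <- order(truth$start_sample)
  od <- order(detected$start_sample)
  used <- rep(FALSE, nrow(detected))
  pairs_t <- integer(0)
  pairs_d <- integer(0)
  for (i in ot) {
    ts <- truth$start_sample[i]
    te <- truth$end_sample[i]
    for (j in od) {
      if (used[j]) next
      if (detected$start_sample[j] >= te) break
      if (detected$end_sample[j] > ts) {  # >= 1 sample overlap
        used[j] <- TRUE
        pairs_t <- c(pairs_t, i)
        pairs_d <- c(pairs_d, j)
        break
      }
    }
  }
  tibble::tibble(truth = pairs_t, detected = pairs_d)
}

#' Score a detection run against ground truth
#'
#' Sensitivity is the proportion of truth events matched; the false rate is
#' the number of unmatched (nonsimulated) detections divided by the total
#' number of detections (0 when nothing was detected); the relative duration
#' is the detected/truth duration ratio averaged over matched pairs.
#'
#' @inheritParams match_events
#' @return One-row tibble: `sensitivity`, `false_rate`,
#'   `mean_relative_duration`, `n_truth`, `n_detected`, `n_matched`.
#' @export
score_detections <- function(detected, truth) {
  m <- match_events(detected, truth)
  n_match <- nrow(m)
  n_det <- nrow(detected)
  rel <- if (n_match > 0) {
    dd <- detected$end_sample[m$detected] - detected$start_sample[m$detected]
    td <- truth$end_sample[m$truth] - truth$start_sample[m$truth]
    mean(dd / td)
  } else {
    NA_real_
  }
  tibble::tibble(
    sensitivity = if (nrow(truth) > 0) n_match / nrow(truth) else NA_real_,
    false_rate = if (n_det > 0) (n_det - n_match) / n_det else 0,
    mean_relative_duration = rel,
    n_truth = nrow(truth),
    n_detected = n_det,
    n_matched = n_match
  )
}

#' Run the simulation validation experiment
#'
#' Generates replicate synthetic datasets per noise condition and scores the
#' two-threshold Hilbert detector and the single-threshold duration-based
#' comparator against the inserted ground truth, mirroring the benchmark
#' design: 11 conditions (noise-free plus SNR 1-10), 10 replicates each,
#' sensitivity / false-detection proportion / relative duration per dataset.
#'
#' @param cfg A [sim_config()] describing the datasets.
#' @param conditions SNR levels (`NA` = noise-free).
#' @param replicates Replicate datasets per condition.
#' @param master_seed Master seed for the suite.
#' @param hilbert_cfg A [hilbert_config()] for the two-threshold detector.
#' @param comparator List of comparator parameters:
#'   `sd_threshold`, `min_duration_ms`, `epoch_s`.
#' @param detectors Which detectors to run (subset of
#'   `c("hilbert", "comparator")`).
#' @return An object of class `hfo_validation`: per-dataset scores plus the
#'   run configuration. Use [tidy()][generics::tidy] for per-condition
#'   summaries with standard errors, `glance()` for a one-row-per-detector
#'   overview and [ggplot2::autoplot()] for the three-panel figure.
#' @export
run_validation <- function(cfg = sim_config(), conditions = c(NA, 1:10),
                           replicates = 10, master_seed = 1,
                           hilbert_cfg = hilbert_config(),
                           comparator = list(sd_threshold = 3.5,
                                             min_duration_ms = 10,
                                             epoch_s = 600),
                           detectors = c("hilbert", "comparator")) {
  detectors <- match.arg(detectors, several.ok = TRUE)
  rows <- list()
  for (k in seq_along(conditions)) {
    for (r in seq_len(replicates)) {
      snr <- if (is.na(conditions[k])) NULL else conditions[k]
      ds <- simulate_dataset(cfg, snr = snr,
                             seed = suite_seed(master_seed, k, r))
      x <- ds$recording$mat[1, ]
      for (det in detectors) {
        ev <- if (det == "hilbert") {
          detect_channel(ds$recording, ds$recording$labels[1], hilbert_cfg)
        } else {
          ripplelab_hilbert(x, ds$recording$srate, band = hilbert_cfg$band,
                            sd_threshold = comparator$sd_threshold,
                            min_duration_ms = comparator$min_duration_ms,
                            epoch_s = comparator$epoch_s,
                            filter_kind = hilbert_cfg$filter_kind,
                            channel = ds$recording$labels[1])
        }
        sc <- score_detections(ev, ds$truth)
        sc$condition <- if (is.null(snr)) "noise-free" else sprintf("snr%02d", snr)
        sc$snr <- if (is.null(snr)) NA_real_ else snr
        sc$replicate <- r
        sc$detector <- det
        rows[[length(rows) + 1L]] <- sc
      }
    }
  }
  structure(
    list(scores = dplyr::bind_rows(rows),
         conditions = conditions, replicates = replicates,
         master_seed = master_seed, cfg = cfg,
         hilbert_cfg = hilbert_cfg, comparator = comparator),
    class = "hfo_validation"
  )
}

#' @export
print.hfo_validation <- function(x, ...) {
  cat(sprintf("<hfo_validation> %d condition(s) x %d replicate(s), detectors: %s\n",
              length(x$conditions), x$replicates,
              paste(unique(x$scores$detector), collapse = ", ")))
  print(tidy(x))
  invisible(x)
}

#' Tidy per-condition validation summaries
#'
#' One row per condition x detector with the mean and standard error (across
#' replicate datasets) of sensitivity, false-detection proportion and mean
#' relative duration.
#'
#' @param x An `hfo_validation` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hfo_validation <- function(x, ...) {
  se <- function(v) stats::sd(v) / sqrt(length(v))
  x$scores %>%
    dplyr::group_by(.data$detector, .data$condition, .data$snr) %>%
    dplyr::summarise(
      n_datasets = dplyr::n(),
      sensitivity_mean = mean(.data$sensitivity),
      sensitivity_se = se(.data$sensitivity),
      false_rate_mean = mean(.data$false_rate),
      false_rate_se = se(.data$false_rate),
      rel_duration_mean = mean(.data$mean_relative_duration, na.rm = TRUE),
      rel_duration_se = se(stats::na.omit(.data$mean_relative_duration)),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$detector, .data$snr, .data$condition)
}

#' One-row-per-detector overview of a validation run
#'
#' @param x An `hfo_validation` object.
#' @param ... Unused.
#' @return A tibble with overall means across all datasets.
#' @export
glance.hfo_validation <- function(x, ...) {
  x$scores %>%
    dplyr::group_by(.data$detector) %>%
    dplyr::summarise(
      n_datasets = dplyr::n(),
      sensitivity = mean(.data$sensitivity),
      false_rate = mean(.data$false_rate),
      rel_duration = mean(.data$mean_relative_duration, na.rm = TRUE),
      .groups = "drop"
    )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a validation run
#'
#' Three panels against noise level: proportion of simulated HFOs detected,
#' proportion of detections that were not simulated HFOs, and detected
#' duration relative to truth. Error bars are the SE across replicate
#' datasets.
#'
#' @param object An `hfo_validation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hfo_validation <- function(object, ...) {
  td <- tidy(object) %>%
    tidyr::pivot_longer(
      cols = c("sensitivity_mean", "false_rate_mean", "rel_duration_mean"),
      names_to = "metric", values_to = "mean"
    ) %>%
    dplyr::mutate(
      se = dplyr::case_when(
        .data$metric == "sensitivity_mean" ~ .data$sensitivity_se,
        .data$metric == "false_rate_mean" ~ .data$false_rate_se,
        TRUE ~ .data$rel_duration_se
      ),
      metric = dplyr::recode(.data$metric,
                             sensitivity_mean = "proportion detected",
                             false_rate_mean = "false-detection proportion",
                             rel_duration_mean = "relative duration")
    )
  ggplot2::ggplot(td, ggplot2::aes(x = .data$condition, y = .data$mean,
                                   group = .data$detector,
                                   colour = .data$detector)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "condition", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write a tab-separated validation report
#'
#' @param x An `hfo_validation` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(x, path) {
  utils::write.table(tidy(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
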