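mk_events <- function(starts, ends, channel = "c") {
  hfo_events(channel = channel, start_sample = starts, end_sample = ends,
             type = "ripple", avg_freq = 120, n_cycles = 5, peak_zscore = 8,
             bp_low = 80, bp_high = 250)
}

test_that("perfect and disjoint detections score as expected", {
  tr <- mk_events(c(100, 300, 500), c(150, 360, 580))
  expect_equal(unlist(score_detections(tr, tr)[1:3]),
               c(sensitivity = 1, false_rate = 0, mean_relative_duration = 1))
  far <- mk_events(c(1000, 2000), c(1100, 2100))
  sc <- score_detections(far, tr)
  expect_equal(sc$sensitivity, 0)
  expect_equal(sc$false_rate, 1)
  empty <- mk_events(integer(0), integer(0))
  expect_equal(score_detections(empty, tr)$false_rate, 0)
})

test_that("score arithmetic matches an independent tally", {
  # 60 of 80 truth matched, 15 of 75 detections false
  set.seed(31)
  tr <- mk_events(seq(0, by = 1000, length.out = 80),
                  seq(0, by = 1000, length.out = 80) + 200)
  matched_idx <- sort(sample.int(80, 60))
  det_start <- tr$start_sample[matched_idx] + 50L
  det_end <- tr$end_sample[matched_idx] - 50L
  false_start <- seq(80000, by = 1000, length.out = 15) + 300L
  det <- mk_events(c(det_start, false_start), c(det_end, false_start + 100L))
  sc <- score_detections(det, tr)
  expect_equal(sc$sensitivity, 0.75)
  expect_equal(sc$false_rate, 0.20)
  expect_equal(sc$n_matched, 60)
})

test_that("greedy matching agrees with an exhaustive overlap oracle", {
  overlap <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1
  oracle_match <- function(det, tr) {
    used <- rep(FALSE, nrow(det))
    n <- 0L
    for (i in order(tr$start_sample)) {
      js <- order(det$start_sample)
      js <- js[!used[js]]
      hit <- js[vapply(js, function(j) {
        overlap(det$start_sample[j], det$end_sample[j],
                tr$start_sample[i], tr$end_sample[i])
      }, logical(1))]
      if (length(hit) > 0) {
        used[hit[1]] <- TRUE
        n <- n + 1L
      }
    }
    n
  }
  set.seed(77)
  for (rep in 1:50) {
    nt <- sample(1:12, 1)
    nd <- sample(0:12, 1)
    ts <- sort(sample.int(5000, nt)) * 20L
    tr <- mk_events(ts, ts + sample(10:200, nt, replace = TRUE))
    if (nd == 0) {
      det <- mk_events(integer(0), integer(0))
    } else {
      dss <- sort(sample.int(5000, nd)) * 20L
      det <- mk_events(dss, dss + sample(10:200, nd, replace = TRUE))
    }
    m <- match_events(det, tr)
    expect_equal(nrow(m), oracle_match(det, tr))
    # one-to-one: no index reused
    expect_false(any(duplicated(m$truth)))
    expect_false(any(duplicated(m$detected)))
    # every matched pair overlaps by at least one sample
    if (nrow(m) > 0) {
      expect_true(all(det$start_sample[m$detected] < tr$end_sample[m$truth] &
                        tr$start_sample[m$truth] < det$end_sample[m$detected]))
    }
  }
})

test_that("scores are invariant to event-list order", {
  set.seed(19)
  ts <- sort(sample.int(3000, 10)) * 30L
  tr <- mk_events(ts, ts + 120L)
  det <- mk_events(ts[c(2, 5, 7)] + 20L, ts[c(2, 5, 7)] + 90L)
  sc <- score_detections(det, tr)
  perm_d <- det[sample.int(nrow(det)), ]
  perm_t <- tr[sample.int(nrow(tr)), ]
  expect_equal(score_detections(perm_d, perm_t)[1:3], sc[1:3])
})

test_that("spurious detections cannot raise sensitivity or lower false rate", {
  ts <- c(100L, 400L, 900L)
  tr <- mk_events(ts, ts + 100L)
  det <- mk_events(c(110L, 410L), c(190L, 480L))
  base <- score_detections(det, tr)
  spurious <- dplyr::bind_rows(det, mk_events(5000L, 5100L))
  with_sp <- score_detections(spurious, tr)
  expect_equal(with_sp$sensitivity, base$sensitivity)
  expect_gte(with_sp$false_rate, base$false_rate)
})

test_that("the validation harness summarizes per condition with SE", {
  v <- run_validation(sim_config(duration = 30, events_per_freq = 3),
                      conditions = c(NA, 5), replicates = 2, master_seed = 2,
                      hilbert_cfg = hilbert_config(baseline = 30),
                      comparator = list(sd_threshold = 3.5,
                                        min_duration_ms = 10, epoch_s = 30))
  td <- tidy(v)
  expect_equal(nrow(td), 4)  # 2 conditions x 2 detectors
  expect_true(all(td$sensitivity_mean >= 0 & td$sensitivity_mean <= 1))
  expect_true(all(td$false_rate_mean >= 0 & td$false_rate_mean <= 1))
  expect_equal(unique(td$n_datasets), 2)
  # SE equals sd/sqrt(n) recomputed from the per-dataset scores
  one <- v$scores[v$scores$detector == "hilbert" &
                    v$scores$condition == "snr05", ]
  expect_equal(td$sensitivity_se[td$detector == "hilbert" &
                                   td$condition == "snr05"],
               stats::sd(one$sensitivity) / sqrt(nrow(one)))
  gl <- glance(v)
  expect_equal(nrow(gl), 2)
  # report writes and re-reads
  path <- withr::local_tempfile(fileext = ".tsv")
  write_validation_report(v, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), 4)
  # parameter recovery on the noise-free condition
  ds <- simulate_dataset(sim_config(duration = 30, events_per_freq = 3),
                         seed = 11)
  ev <- detect_channel(ds$recording, "sim1", hilbert_config(baseline = 30))
  m <- match_events(ev, ds$truth)
  expect_gt(nrow(m), 0)
  rel_err <- abs(ev$avg_freq[m$detected] - ds$truth$avg_freq[m$truth]) /
    ds$truth$avg_freq[m$truth]
  # event boundaries sit at the onset threshold, where the burst is no
  # stronger than the background, so individual estimates can pick up
  # background peaks; the typical event recovers its frequency closely
  expect_lte(stats::median(rel_err), 0.05)
  expect_true(all(ev$avg_freq >= 80 & ev$avg_freq <= 250))
})

test_that("validation plot builds without error", {
  v <- run_validation(sim_config(duration = 30, events_per_freq = 3),
                      conditions = c(2, 8), replicates = 2, master_seed = 3,
                      hilbert_cfg = hilbert_config(baseline = 30),
                      comparator = list(sd_threshold = 3.5,
                                        min_duration_ms = 10, epoch_s = 30))
  p <- ggplot2::autoplot(v)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(length(built$data), 0)
})
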