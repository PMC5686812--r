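flat_ts <- function(values, fs = 2, n_trials = 1, roi = "d1") {
  nfr <- length(values)
  trace_set(matrix(values, ncol = 1),
            data.frame(roi_id = roi, role = "dendrite", parent_id = ""),
            fs, rep(seq_len(n_trials), each = nfr / n_trials),
            rep("running", n_trials), background = 0)
}

test_that("constant fluorescence gives F0 = level, dff = 0, baseline SD = 0", {
  d <- compute_dff(flat_ts(rep(100, 120)))
  expect_equal(d$windows$f0, 100)
  expect_equal(unname(d$dff[, 1]), rep(0, 120))
  expect_equal(d$windows$baseline_sd, 0)
  expect_equal(d$windows$threshold, d$threshold_floor)
})

test_that("F0 is the mean of the lowest 10% of samples in the window", {
  # 110 frames at 100 and 10 at 200: the lowest 12 samples are all 100
  x <- c(rep(100, 110), rep(200, 10))
  d <- compute_dff(flat_ts(x))
  expect_equal(d$windows$f0, 100)
  expect_equal(unname(d$dff[111:120, 1]), rep(1.0, 10))
})

test_that("windows shorter than 10 samples and F0 <= 0 are errors", {
  expect_error(compute_dff(flat_ts(rep(100, 16), fs = 2), window_s = 4),
               "fewer than 10")
  expect_error(compute_dff(flat_ts(rep(-5, 120))), "F0")
})

test_that("threshold equals the SD multiplier times baseline SD above the floor", {
  cfg <- trace_gen_config(event_rate_per_min = 1, noise_sd = 3, seed = 8)
  g <- generate_trace_set(cfg, n_dendrites = 4)
  d <- compute_dff(subtract_background(g$traces))
  above_floor <- d$windows$threshold > d$threshold_floor + 1e-12
  expect_gt(sum(above_floor), 0)
  expect_equal(d$windows$threshold[above_floor],
               3 * d$windows$baseline_sd[above_floor])
})

test_that("zero-noise event amplitude is recovered exactly through dff", {
  sched <- data.frame(roi_id = "dend001", trial = 1, onset_s = 20,
                      duration_s = 4, amplitude = 2.0)
  cfg <- trace_gen_config(n_trials = 1, trial_states = "running", noise_sd = 0)
  g <- generate_trace_set(cfg, n_dendrites = 1, dendrite_events = sched)
  d <- compute_dff(subtract_background(g$traces))
  expect_equal(max(d$dff), 2.0, tolerance = 1e-9)
})

test_that("dff and detection are invariant under raw-F rescaling", {
  cfg <- trace_gen_config(event_rate_per_min = 2, noise_sd = 2,
                          background_level = 0, seed = 13)
  g <- generate_trace_set(cfg, n_dendrites = 3)
  ts <- subtract_background(g$traces)
  ts_scaled <- ts; ts_scaled$F <- 7.3 * ts$F
  d1 <- compute_dff(ts); d2 <- compute_dff(ts_scaled)
  expect_equal(d1$dff, d2$dff, tolerance = 1e-12)
  expect_equal(detect_transients(d1), detect_transients(d2))
})

test_that("supra-threshold runs become transients with the documented metrics", {
  expect_equal(nrow(detect_transients(make_dff_trace(rep(0, 40), 0.15))), 0)

  dff <- rep(0, 40); dff[10:15] <- c(0.2, 0.5, 0.9, 0.6, 0.3, 0.16)
  ev <- detect_transients(make_dff_trace(dff, 0.15))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 3.0)      # 6 samples at 2 Hz
  expect_equal(ev$onset_frame, 9)       # 0-based
  expect_equal(ev$peak_dff, 0.9)
  expect_equal(ev$integrated, sum(dff[10:15]) / 2)
  expect_false(ev$prolonged)
  expect_false(ev$large_amplitude)
})

test_that("events spanning a trial boundary split at the boundary", {
  dff <- rep(0, 40); dff[18:24] <- 1
  tr <- rep(1:2, each = 20)
  ev <- detect_transients(make_dff_trace(dff, 0.15, trial = tr))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$trial, c(1L, 2L))
  expect_equal(ev$onset_frame, c(17L, 0L))
  expect_equal(ev$duration_s, c(1.5, 2.0))
})

test_that("prolonged and large-amplitude flags use strict cutoffs", {
  # 16 samples = 8.0 s exactly: not prolonged; 17 samples = 8.5 s: prolonged
  d8 <- rep(0, 60); d8[10:25] <- 1
  expect_false(detect_transients(make_dff_trace(d8, 0.15))$prolonged)
  d85 <- rep(0, 60); d85[10:26] <- 1
  expect_true(detect_transients(make_dff_trace(d85, 0.15))$prolonged)
  # peak exactly 4.0 is not "large"; above it is
  p4 <- rep(0, 60); p4[10:12] <- 4.0
  expect_false(detect_transients(make_dff_trace(p4, 0.15))$large_amplitude)
  p4b <- rep(0, 60); p4b[10:12] <- 4.01
  expect_true(detect_transients(make_dff_trace(p4b, 0.15))$large_amplitude)
})

test_that("detection is idempotent on its own output", {
  cfg <- trace_gen_config(event_rate_per_min = 2, noise_sd = 2, seed = 17)
  g <- generate_trace_set(cfg, n_dendrites = 3)
  d <- compute_dff(subtract_background(g$traces))
  expect_identical(detect_transients(d), detect_transients(d))
})

test_that("ROI summaries match a brute-force recount", {
  expect_equal(summarize_roi(detect_transients(make_dff_trace(rep(0, 10), 1)),
                             5, roi_id = "x")$frequency_per_min, 0)

  set.seed(33)
  ev <- data.frame(roi_id = "d1", trial = 1L,
                   onset_frame = 1:10 * 20L, offset_frame = 1:10 * 20L + 3L,
                   onset_s = 0, duration_s = runif(10, 0.5, 9),
                   peak_dff = runif(10, 0.1, 3),
                   integrated = runif(10, 0.1, 5),
                   prolonged = FALSE, large_amplitude = FALSE)
  s <- summarize_roi(ev, minutes_observed = 5)
  expect_equal(s$frequency_per_min, 10 / 5)
  expect_equal(s$total_duration_s, sum(ev$duration_s))
  expect_equal(s$mean_peak, mean(ev$peak_dff))
  expect_equal(s$total_integrated, sum(ev$integrated))
  expect_equal(s$integrated_per_min, sum(ev$integrated) / 5)
  expect_error(summarize_roi(rbind(ev, transform(ev, roi_id = "d2")), 5),
               "one ROI")
})

test_that("per-event integrated activity sums to the summary total", {
  cfg <- trace_gen_config(event_rate_per_min = 2, noise_sd = 2, seed = 19)
  g <- generate_trace_set(cfg, n_dendrites = 2)
  d <- compute_dff(subtract_background(g$traces))
  ev <- detect_transients(d)
  s <- summarize_activity(ev, d)
  for (roi in unique(s$roi_id)) {
    tot <- sum(ev$integrated[ev$roi_id == roi])
    expect_equal(sum(s$total_integrated[s$roi_id == roi]), tot)
  }
})

test_that("dendrite fractions count event-bearing dendrites with a qualifying event", {
  ev <- data.frame(roi_id = c("a", "b", "c"), prolonged = c(TRUE, TRUE, TRUE),
                   large_amplitude = FALSE)
  expect_equal(dendrite_fraction_with(ev, "prolonged"), 1.0)
  ev$prolonged <- FALSE
  expect_equal(dendrite_fraction_with(ev, "prolonged"), 0.0)
  expect_equal(dendrite_fraction_with(ev, "large_amplitude"), 0.0)
  expect_error(dendrite_fraction_with(ev[0, ], "prolonged"), "empty")
})

test_that("duration-amplitude correlation behaves at the extremes", {
  ev <- data.frame(duration_s = 1:20, peak_dff = (1:20) * 0.1)
  expect_equal(duration_amplitude_correlation(ev)$r, 1.0)

  set.seed(7)
  n <- 2000
  ev0 <- data.frame(duration_s = rlnorm(n), peak_dff = rlnorm(n))
  r0 <- duration_amplitude_correlation(ev0)$r
  expect_lt(abs(r0), 3 / sqrt(n))

  expect_error(duration_amplitude_correlation(ev[1:2, ]), "3 events")
  expect_error(duration_amplitude_correlation(
    data.frame(duration_s = rep(1, 5), peak_dff = 1:5)), "constant")
})

test_that("events CSV round-trips through the writer", {
  cfg <- trace_gen_config(event_rate_per_min = 2, noise_sd = 2, seed = 23)
  g <- generate_trace_set(cfg, n_dendrites = 2)
  ev <- detect_transients(compute_dff(subtract_background(g$traces)))
  f <- tempfile(fileext = ".csv")
  write_events_csv(ev, f)
  back <- read_events_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(ev), tolerance = 1e-12)
})
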