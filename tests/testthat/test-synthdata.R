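test_that("config validation rejects impossible parameter sets", {
  expect_error(trace_gen_config(f_rest = 0), "f_rest")
  expect_error(trace_gen_config(f_rest = 50, background_level = 60),
               "background")
  expect_error(trace_gen_config(duration_dist = list(
    meanlog_short = 0, sdlog_short = 1, meanlog_long = 2, sdlog_long = 1,
    p_long = 1.2)), "p_long")
  expect_error(trace_gen_config(noise_sd = -1), "noise_sd")
})

test_that("zero event rate and zero noise give flat traces and no ground truth", {
  cfg <- trace_gen_config(event_rate_per_min = 0,
                          spine_event_rate_per_min = 0, noise_sd = 0)
  g <- generate_trace_set(cfg, n_somas = 1, n_dendrites = 2,
                          n_spines_per_dendrite = 2)
  expect_equal(nrow(g$events), 0)
  expect_true(all(g$traces$F == cfg$f_rest + cfg$background_level))
})

test_that("pure plateau mixture with 12 s median flags every event prolonged", {
  # p_long = 1 with a tight spread around a 12 s median keeps every drawn
  # duration above the 8 s cutoff
  cfg <- trace_gen_config(event_rate_per_min = 1, noise_sd = 0,
                          duration_dist = list(meanlog_short = log(2),
                                               sdlog_short = 0.5,
                                               meanlog_long = log(12),
                                               sdlog_long = 0.05,
                                               p_long = 1),
                          seed = 11)
  g <- generate_trace_set(cfg, n_dendrites = 50)
  ev <- g$events[g$events$role == "dendrite", ]
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$prolonged))
})

test_that("duration-amplitude coupling is recovered from the ground truth", {
  cfg <- trace_gen_config(event_rate_per_min = 4, noise_sd = 0,
                          amp_coupling = list(intercept = 0.3, slope = 0.08,
                                              sd = 0.1, min = 0.05, max = 10),
                          duration_dist = list(meanlog_short = log(2),
                                               sdlog_short = 0.5,
                                               meanlog_long = log(12),
                                               sdlog_long = 0.4,
                                               p_long = 0.3),
                          seed = 21)
  g <- generate_trace_set(cfg, n_dendrites = 40)
  ev <- g$events
  expect_gt(nrow(ev), 500)
  expect_gt(cor(ev$duration_s, ev$amplitude), 0.5)
})

test_that("identical configuration and seed give bit-identical output", {
  cfg <- trace_gen_config(seed = 99)
  g1 <- generate_trace_set(cfg, n_dendrites = 3, n_spines_per_dendrite = 2)
  g2 <- generate_trace_set(cfg, n_dendrites = 3, n_spines_per_dendrite = 2)
  expect_identical(g1$traces$F, g2$traces$F)
  expect_identical(g1$events, g2$events)
  cfg2 <- trace_gen_config(seed = 100)
  g3 <- generate_trace_set(cfg2, n_dendrites = 3, n_spines_per_dendrite = 2)
  expect_false(identical(g1$traces$F, g3$traces$F))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(42); before <- runif(1)
  set.seed(42); invisible(generate_trace_set(trace_gen_config(), n_dendrites = 1))
  expect_identical(runif(1), before)
})

test_that("prolonged-dendrite fraction in ground truth matches the analytic value", {
  cfg <- regime_config("AD", noise_sd = 0, seed = 31)
  minutes <- 5
  expected <- expected_dendrite_fraction(cfg, minutes)
  expect_equal(expected, 0.47, tolerance = 1e-6)
  g <- generate_trace_set(cfg, n_dendrites = 500)
  ev <- g$events[g$events$role == "dendrite" &
                   g$events$trial <= 5, ]   # running trials only
  per_dend <- tapply(ev$prolonged, ev$roi_id, any)
  frac <- mean(per_dend)
  se <- sqrt(expected * (1 - expected) / length(per_dend))
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("event rate, duration quantiles and plateau weight are recovered from detected events", {
  dd <- list(meanlog_short = log(2), sdlog_short = 0.5,
             meanlog_long = log(12), sdlog_long = 0.4, p_long = 0.25)
  cfg <- trace_gen_config(event_rate_per_min = 1.2, noise_sd = 1,
                          duration_dist = dd, seed = 55)
  n_dend <- 200
  g <- generate_trace_set(cfg, n_dendrites = n_dend)
  d <- compute_dff(subtract_background(g$traces))
  ev <- detect_transients(d)
  run <- ev[ev$trial <= 5, ]

  # rate: Poisson counting error over n_dend x 5 observed minutes
  minutes <- n_dend * 5
  rate_hat <- nrow(run) / minutes
  se_rate <- sqrt(cfg$event_rate_per_min / minutes)
  expect_lt(abs(rate_hat - cfg$event_rate_per_min), 3 * se_rate)

  # median duration: solve the mixture CDF independently of the generator
  mix_cdf <- function(x)
    dd$p_long * plnorm(x, dd$meanlog_long, dd$sdlog_long) +
      (1 - dd$p_long) * plnorm(x, dd$meanlog_short, dd$sdlog_short)
  med_true <- uniroot(function(x) mix_cdf(x) - 0.5, c(0.1, 20))$root
  expect_lt(abs(median(run$duration_s) - med_true), 0.5)

  # plateau weight via the prolonged-event fraction
  q_true <- prolonged_prob_per_event(cfg)
  q_hat <- mean(run$prolonged)
  expect_lt(abs(q_hat - q_true), 3 * sqrt(q_true * (1 - q_true) / nrow(run)))
})

test_that("spine image pair reproduces the configured intensity ratio", {
  cfg <- image_gen_config(intensities = list(structural = c(S = 200, D = 150, B = 50),
                                             functional = c(S = 100, D = 80, B = 20)))
  img <- generate_spine_image_pair(cfg)
  expect_equal(img$true_ratio, 1.5)
  m <- measure_spine_size(img$structural, img$rois$spine, img$rois$shaft,
                          img$rois$background)
  expect_equal(m$size_ratio, 1.5, tolerance = 1e-12)

  # equal spine and shaft brightness: ratio 1 exactly
  cfg1 <- image_gen_config(intensities = list(structural = c(S = 150, D = 150, B = 0),
                                              functional = c(S = 100, D = 100, B = 0)))
  expect_equal(generate_spine_image_pair(cfg1)$true_ratio, 1.0)

  # affine re-rendering (2 I + 10 everywhere) leaves the ratio unchanged
  v <- c(S = 2 * 200 + 10, D = 2 * 150 + 10, B = 2 * 50 + 10)
  cfg2 <- image_gen_config(intensities = list(structural = v,
                                              functional = v))
  expect_equal(generate_spine_image_pair(cfg2)$true_ratio, 1.5)
})

test_that("a spine that would fall outside the image is rejected", {
  expect_error(image_gen_config(image_size_px = 32, spine_offset_px = 14,
                                spine_radius_px = 6), "fit inside")
})
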