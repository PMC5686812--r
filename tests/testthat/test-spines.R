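test_that("scaled subtraction obeys its algebraic identities", {
  set.seed(1)
  d <- rnorm(200)
  expect_equal(spine_specific_series(0.7 * d, d, scale = 0.7), rep(0, 200))
  s <- rnorm(200)
  expect_equal(spine_specific_series(s, rep(0, 200)), s)
  # linearity in both arguments
  a <- 3.7
  expect_equal(spine_specific_series(a * s, a * d), a * spine_specific_series(s, d))
  expect_error(spine_specific_series(s, d[1:100]), "length")
})

test_that("spine isolation recovers the injected synaptic signal at zero noise", {
  cfg <- trace_gen_config(event_rate_per_min = 1.5, spine_event_rate_per_min = 1.5,
                          noise_sd = 0, seed = 41)
  g <- generate_trace_set(cfg, n_dendrites = 2, n_spines_per_dendrite = 2)
  d <- compute_dff(subtract_background(g$traces))
  for (sp in g$traces$rois$roi_id[g$traces$rois$role == "spine"]) {
    sst <- spine_specific(d, sp, scale = cfg$bap_scale)
    det <- detect_transients(sst)
    gt <- g$events[g$events$roi_id == sp, ]
    expect_equal(nrow(det), nrow(gt))
    if (nrow(gt)) {
      expect_equal(det$peak_dff, gt$amplitude, tolerance = 1e-9)
      expect_lt(max(abs(det$duration_s - gt$n_samples / 2)), 0.5 + 1e-12)
    }
  }
})

test_that("spine isolation validates parentage and records its scale", {
  cfg <- trace_gen_config(noise_sd = 0, seed = 2)
  g <- generate_trace_set(cfg, n_dendrites = 2, n_spines_per_dendrite = 1)
  d <- compute_dff(subtract_background(g$traces))
  expect_error(spine_specific(d, "dend001"), "not a spine")
  expect_error(spine_specific(d, "dend001_sp01", dendrite_id = "dend002"),
               "parent")
  sst <- spine_specific(d, "dend001_sp01")
  expect_equal(sst$scale, 0.7)
  expect_equal(sst$dendrite_id, "dend001")
})

test_that("with scale 0 the pipeline reduces to raw spine analysis", {
  cfg <- trace_gen_config(event_rate_per_min = 1, noise_sd = 2, seed = 43)
  g <- generate_trace_set(cfg, n_dendrites = 1, n_spines_per_dendrite = 1)
  d <- compute_dff(subtract_background(g$traces))
  sst <- spine_specific(d, "dend001_sp01", scale = 0)
  expect_equal(sst$dff, unname(d$dff[, "dend001_sp01"]))
})

test_that("activity calls follow the threshold rule and are monotone in amplitude", {
  base <- structure(list(spine_id = "s", dendrite_id = "d",
                         dff = rep(0, 40), threshold = rep(0.1, 40),
                         windows = NULL, scale = 0.7, sampling_rate_hz = 2,
                         trial = rep(1L, 40), states = "running"),
                    class = "spine_specific_trace")
  expect_false(classify_active(base, c(10, 20))$active)

  ev <- base; ev$dff[15:18] <- 1.0
  expect_true(classify_active(ev, c(10, 20))$active)
  # scaling a supra-threshold event up never flips the call
  ev2 <- ev; ev2$dff <- ev$dff * 5
  expect_true(classify_active(ev2, c(10, 20))$active)
  expect_error(classify_active(base, integer(0)), "window")

  # ratio rule with the published-midpoint cutoff
  expect_true(classify_active(base, c(10, 20), rule = "ratio",
                              head_shaft_ratio = 1.56)$active)
  expect_false(classify_active(base, c(10, 20), rule = "ratio",
                               head_shaft_ratio = 0.46)$active)
})

test_that("activity calls match a scripted per-spine schedule exactly at zero noise", {
  n_sp <- 40
  sp_ids <- sprintf("dend001_sp%02d", seq_len(n_sp))
  active_truth <- seq_len(n_sp) %% 2 == 1
  dend_sched <- data.frame(roi_id = "dend001", trial = 1, onset_s = 20,
                           duration_s = 6, amplitude = 1.2)
  sp_sched <- data.frame(roi_id = sp_ids[active_truth], trial = 1,
                         onset_s = 21, duration_s = 2, amplitude = 1)
  cfg <- trace_gen_config(n_trials = 1, trial_states = "running", noise_sd = 0)
  g <- generate_trace_set(cfg, n_dendrites = 1, n_spines_per_dendrite = n_sp,
                          dendrite_events = dend_sched, spine_events = sp_sched)
  d <- compute_dff(subtract_background(g$traces))
  window <- c(40L, 55L)   # frames of the dendritic event
  calls <- vapply(sp_ids, function(sp)
    classify_active(spine_specific(d, sp), window)$active, TRUE)
  expect_equal(unname(calls), active_truth)
})

test_that("first-vs-third comparison stratifies by the middle transient duration", {
  s <- simulate_depotentiation_session(n_spines = 10, attenuation = 0,
                                       middle_duration_s = 8.5, noise_sd = 0,
                                       seed = 6)
  d <- compute_dff(subtract_background(s$traces))
  dev <- detect_transients(d)
  dev <- dev[dev$roi_id == "dend001", ]
  ft <- first_third_comparison(dev, d)
  expect_equal(nrow(ft), 10)
  expect_true(all(ft$middle_duration_class == ">8 s"))

  s2 <- simulate_depotentiation_session(n_spines = 10, attenuation = 0,
                                        middle_duration_s = 7.5, noise_sd = 0,
                                        seed = 6)
  d2 <- compute_dff(subtract_background(s2$traces))
  dev2 <- detect_transients(d2)
  ft2 <- first_third_comparison(dev2[dev2$roi_id == "dend001", ], d2)
  expect_true(all(ft2$middle_duration_class == "0-8 s"))
})

test_that("fewer than three dendritic transients yields no comparison rows", {
  dend_sched <- data.frame(roi_id = "dend001", trial = 1,
                           onset_s = c(10, 30), duration_s = c(3, 3),
                           amplitude = c(1, 1))
  cfg <- trace_gen_config(n_trials = 1, trial_states = "running",
                          noise_sd = 0, spine_event_rate_per_min = 0)
  g <- generate_trace_set(cfg, n_dendrites = 1, n_spines_per_dendrite = 3,
                          dendrite_events = dend_sched)
  d <- compute_dff(subtract_background(g$traces))
  dev <- detect_transients(d)
  ft <- first_third_comparison(dev[dev$roi_id == "dend001", ], d)
  expect_equal(nrow(ft), 0)
})

test_that("unchanged spine peaks give a null paired comparison", {
  s <- simulate_depotentiation_session(n_spines = 40, attenuation = 0,
                                       middle_duration_s = 10, noise_sd = 0,
                                       seed = 11)
  d <- compute_dff(subtract_background(s$traces))
  dev <- detect_transients(d)
  ft <- first_third_comparison(dev[dev$roi_id == "dend001", ], d)
  # amplitudes at the 3rd transient carry only mean-one per-event jitter;
  # the paired comparison must not report a systematic change
  rt <- route_and_test(ft$peak_post, ft$peak_pre, paired = TRUE)
  expect_gt(rt$p_value, 0.05)
  expect_equal(mean(ft$peak_post / ft$peak_pre), 1, tolerance = 0.05)
})
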