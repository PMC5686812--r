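#' Simulate a running trial with three dendritic transients for the
#' first-vs-third spine-peak comparison
#'
#' Builds a scripted single-trial session: one dendrite carrying exactly
#' three calcium transients (the middle one of configurable duration) and
#' `n_spines` child spines, each with one intrinsic synaptic event inside the
#' window of the 1st dendritic transient and one inside the 3rd. Spine event
#' amplitudes are a spine-level lognormal base times a small event-level
#' jitter, so the 1st/3rd pairing is genuinely paired. When
#' `middle_duration_s` exceeds the prolonged cutoff and `attenuation > 0`,
#' the generator multiplies every post-event spine amplitude by
#' `1 - attenuation`, injecting a depotentiation effect of known size.
#'
#' @param n_spines number of spines on the dendrite.
#' @param attenuation fractional attenuation of spine events following a
#'   prolonged dendritic transient.
#' @param middle_duration_s duration of the 2nd dendritic transient, seconds
#'   (10 = prolonged stratum, 3 = control stratum).
#' @param noise_sd raw-fluorescence noise SD passed to the generator.
#' @param seed RNG seed.
#' @return list `traces`, `events` (ground truth), `dendrite_id`.
#' @export
simulate_depotentiation_session <- function(n_spines = 50, attenuation = 0.2,
                                            middle_duration_s = 10,
                                            noise_sd = 2, seed = 1L) {
  cfg <- trace_gen_config(n_trials = 1, trial_states = "running",
                          noise_sd = noise_sd,
                          depot_attenuation = attenuation,
                          seed = seed)
  dend_sched <- data.frame(roi_id = "dend001", trial = 1L,
                           onset_s = c(5, 20, 45),
                           duration_s = c(3, middle_duration_s, 3),
                           amplitude = c(1.0, 1.5, 1.0))
  sp_ids <- sprintf("dend001_sp%02d", seq_len(n_spines))
  sp_sched <- with_seed(seed + 1L, {
    base <- stats::rlnorm(n_spines, 0, 0.3)
    # mean-one lognormal jitter so the null (no attenuation) scenario has no
    # systematic 1st-to-3rd drift
    jit <- stats::rlnorm(n_spines, -0.15^2 / 2, 0.15)
    rbind(
      data.frame(roi_id = sp_ids, trial = 1L, onset_s = 5.5, duration_s = 1.5,
                 amplitude = base),
      data.frame(roi_id = sp_ids, trial = 1L, onset_s = 45.5, duration_s = 1.5,
                 amplitude = base * jit))
  })
  g <- generate_trace_set(cfg, n_dendrites = 1,
                          n_spines_per_dendrite = n_spines,
                          dendrite_events = dend_sched, spine_events = sp_sched)
  c(g, list(dendrite_id = "dend001"))
}

#' Simulate a two-session spine-size experiment with a known shrink effect
#'
#' Renders a structural/functional image pair per spine and session for four
#' groups (active / inactive crossed with parent-dendrite transient duration
#' class). Session-0 size ratios are drawn uniformly; session-1 ratios equal
#' session-0 times a lognormal session jitter, additionally multiplied by
#' `1 - shrink` for active spines on long-duration dendrites -- the group
#' the depotentiation hypothesis predicts should shrink. Images are degraded
#' with the configured blur and pixel noise before measurement, so recovered
#' ratios carry realistic measurement error.
#'
#' @param n_spines total number of spines, split as evenly as possible
#'   across the four groups.
#' @param shrink fractional size reduction injected into the active / long
#'   group.
#' @param session_jitter_sdlog lognormal SD of the biological session-to-
#'   session ratio jitter.
#' @param blur_sigma_px,noise_sd image degradation settings.
#' @param seed RNG seed.
#' @return list with `meas0`, `meas1` ([measure_spine_size()] tables),
#'   `groups` (spine_id, active, duration_class), and `truth` (per-spine
#'   true ratios per session).
#' @export
simulate_size_change_session <- function(n_spines = 50, shrink = 0.15,
                                         session_jitter_sdlog = 0.05,
                                         blur_sigma_px = 0.8, noise_sd = 2,
                                         seed = 1L) {
  groups <- expand.grid(active = c(TRUE, FALSE),
                        duration_class = c("<8 s", ">8 s"),
                        stringsAsFactors = FALSE)
  gidx <- rep(seq_len(4), length.out = n_spines)
  ids <- sprintf("sp%03d", seq_len(n_spines))
  with_seed(seed, {
    ratio0 <- stats::runif(n_spines, 0.8, 1.6)
    jit <- stats::rlnorm(n_spines, 0, session_jitter_sdlog)
    effect <- ifelse(groups$active[gidx] & groups$duration_class[gidx] == ">8 s",
                     1 - shrink, 1)
    ratio1 <- ratio0 * jit * effect
    D <- 150; B <- 50
    render_measure <- function(ratio, id, session, sd) {
      cfg <- image_gen_config(
        intensities = list(structural = c(S = B + ratio * (D - B), D = D, B = B),
                           functional = c(S = 100, D = 100, B = 20)),
        blur_sigma_px = blur_sigma_px, noise_sd = noise_sd, seed = sd)
      img <- generate_spine_image_pair(cfg)
      measure_spine_size(img$structural, img$rois$spine, img$rois$shaft,
                         img$rois$background, spine_id = id, session = session)
    }
    meas0 <- do.call(rbind, lapply(seq_len(n_spines), function(i)
      render_measure(ratio0[i], ids[i], "0h", seed + 1000L + i)))
    meas1 <- do.call(rbind, lapply(seq_len(n_spines), function(i)
      render_measure(ratio1[i], ids[i], "1.5h", seed + 2000L + i)))
    list(meas0 = meas0, meas1 = meas1,
         groups = data.frame(spine_id = ids, active = groups$active[gidx],
                             duration_class = groups$duration_class[gidx],
                             stringsAsFactors = FALSE),
         truth = data.frame(spine_id = ids, ratio_0 = ratio0, ratio_1 = ratio1,
                            stringsAsFactors = FALSE))
  })
}
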