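#' Configuration for the synthetic fluorescence-trace generator
#'
#' Builds the parameter set for [generate_trace_set()]. Defaults emulate slow
#' genetically encoded calcium-indicator (GCaMP6s-class) recordings sampled at
#' 2 Hz in 60 s trials, five treadmill-running trials plus one quiet-resting
#' trial per session. Dendritic event durations are drawn from a two-component
#' lognormal mixture (brief events plus a heavy-tailed plateau component) and
#' peak amplitudes are linearly coupled to duration, so that long plateau
#' events tend to be large -- the statistical structure the downstream
#' transient analysis assumes.
#'
#' @param sampling_rate_hz imaging frame rate in frames/s.
#' @param trial_length_s length of one acquisition trial, seconds.
#' @param n_trials number of trials per session.
#' @param trial_states character vector of length `n_trials`, each
#'   `"running"` or `"resting"`.
#' @param event_rate_per_min expected somatic/dendritic event rate per ROI per
#'   minute during running trials.
#' @param resting_rate_factor multiplier applied to `event_rate_per_min` in
#'   resting trials.
#' @param duration_dist list with `meanlog_short`, `sdlog_short`,
#'   `meanlog_long`, `sdlog_long` (lognormal parameters, seconds) and
#'   `p_long`, the mixture weight of the long plateau component.
#' @param amp_coupling list `intercept`, `slope` (per second), `sd`, `min`,
#'   `max`: event peak amplitude (fractional dF/F0) is
#'   `intercept + slope * duration + Normal(0, sd)`, clipped to `[min, max]`.
#' @param spine_event_rate_per_min rate of spine-intrinsic synaptic events.
#' @param spine_amp list `meanlog`, `sdlog`, `jitter_sdlog`: each spine gets a
#'   lognormal base amplitude; individual events multiply it by a lognormal
#'   jitter. Keeping amplitude a spine-level property makes paired
#'   before/after comparisons realistic.
#' @param bap_scale coupling of the parent-dendrite fractional signal into
#'   spine traces (back-propagating action-potential contamination). The
#'   spine-isolation stage removes exactly this component when its scale
#'   matches.
#' @param tau_decay_s exponential decay constant of the event waveform after
#'   the plateau, seconds. Default 0.2 s: short relative to the 0.5 s frame
#'   interval, so the supra-threshold duration of a rendered event coincides
#'   with its plateau duration at the default frame rate.
#' @param min_gap_s minimum enforced gap between consecutive events on one
#'   ROI, seconds (keeps rendered events separable by the detector).
#' @param noise_sd additive Gaussian noise SD on raw fluorescence, in the same
#'   arbitrary units as `f_rest`.
#' @param noise_model `"additive"` (default) or `"multiplicative"`
#'   (shot-noise-like: SD scales with instantaneous brightness).
#' @param f_rest baseline fluorescence level, arbitrary units, > 0.
#' @param background_level vessel background fluorescence added to every
#'   trace and recorded as the background series.
#' @param depot_attenuation fraction in `[0, 1)`: spine-intrinsic events whose
#'   onset falls after the end of a prolonged (> `prolonged_cutoff_s`)
#'   dendritic event in the same trial have their amplitude multiplied by
#'   `1 - depot_attenuation`. 0 disables the effect. Used to emulate
#'   depotentiation of synaptic calcium following dendritic plateau events.
#' @param prolonged_cutoff_s duration cutoff, seconds, defining a prolonged
#'   event (strict inequality).
#' @param seed integer RNG seed; identical configuration and seed give
#'   bit-identical output.
#' @return a list of class `trace_gen_config`.
#' @seealso [generate_trace_set()], [regime_config()]
#' @export
trace_gen_config <- function(sampling_rate_hz = 2,
                             trial_length_s = 60,
                             n_trials = 6,
                             trial_states = c(rep("running", 5), "resting"),
                             event_rate_per_min = 0.6,
                             resting_rate_factor = 0.5,
                             duration_dist = list(meanlog_short = log(2),
                                                  sdlog_short = 0.5,
                                                  meanlog_long = log(12),
                                                  sdlog_long = 0.4,
                                                  p_long = 0.1),
                             amp_coupling = list(intercept = 0.3, slope = 0.08,
                                                 sd = 0.25, min = 0.2, max = 5),
                             spine_event_rate_per_min = 1,
                             spine_amp = list(meanlog = 0, sdlog = 0.3,
                                              jitter_sdlog = 0.15),
                             bap_scale = 0.7,
                             tau_decay_s = 0.2,
                             min_gap_s = 1.5,
                             noise_sd = 2,
                             noise_model = c("additive", "multiplicative"),
                             f_rest = 100,
                             background_level = 10,
                             depot_attenuation = 0,
                             prolonged_cutoff_s = 8,
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (sampling_rate_hz <= 0) stopf("sampling_rate_hz must be > 0")
  if (trial_length_s <= 0) stopf("trial_length_s must be > 0")
  p <- duration_dist$p_long
  if (is.null(p) || p < 0 || p > 1) stopf("duration_dist$p_long must lie in [0, 1]")
  if (f_rest <= 0) stopf("f_rest must be > 0")
  if (background_level < 0 || f_rest <= background_level)
    stopf("need f_rest > background_level >= 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (depot_attenuation < 0 || depot_attenuation >= 1)
    stopf("depot_attenuation must lie in [0, 1)")
  if (length(trial_states) != n_trials)
    stopf("trial_states must have length n_trials")
  if (!all(trial_states %in% c("running", "resting")))
    stopf("trial_states must be 'running' or 'resting'")
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 trial_length_s = trial_length_s,
                 n_trials = n_trials, trial_states = trial_states,
                 event_rate_per_min = event_rate_per_min,
                 resting_rate_factor = resting_rate_factor,
                 duration_dist = duration_dist, amp_coupling = amp_coupling,
                 spine_event_rate_per_min = spine_event_rate_per_min,
                 spine_amp = spine_amp, bap_scale = bap_scale,
                 tau_decay_s = tau_decay_s, min_gap_s = min_gap_s,
                 noise_sd = noise_sd, noise_model = noise_model,
                 f_rest = f_rest, background_level = background_level,
                 depot_attenuation = depot_attenuation,
                 prolonged_cutoff_s = prolonged_cutoff_s,
                 seed = seed),
            class = "trace_gen_config")
}

#' Per-event probability that a drawn duration exceeds the prolonged cutoff
#' @param cfg a `trace_gen_config`.
#' @param cutoff_s duration cutoff in seconds.
#' @export
prolonged_prob_per_event <- function(cfg, cutoff_s = cfg$prolonged_cutoff_s) {
  d <- cfg$duration_dist
  d$p_long * stats::plnorm(cutoff_s, d$meanlog_long, d$sdlog_long, lower.tail = FALSE) +
    (1 - d$p_long) * stats::plnorm(cutoff_s, d$meanlog_short, d$sdlog_short,
                                   lower.tail = FALSE)
}

#' Per-event probability that the drawn peak amplitude exceeds a cutoff
#'
#' Integrates the Gaussian amplitude-given-duration model over the duration
#' mixture. Amplitude clipping does not affect the tail as long as the clip
#' bounds straddle the cutoff.
#' @param cfg a `trace_gen_config`.
#' @param cutoff fractional dF/F0 cutoff (4 = 400%).
#' @export
large_amp_prob_per_event <- function(cfg, cutoff = 4) {
  d <- cfg$duration_dist; a <- cfg$amp_coupling
  tail_given_dur <- function(dur)
    stats::pnorm(cutoff, mean = a$intercept + a$slope * dur, sd = a$sd,
                 lower.tail = FALSE)
  comp <- function(ml, sl)
    stats::integrate(function(x) stats::dlnorm(x, ml, sl) * tail_given_dur(x),
                     0, Inf, rel.tol = 1e-9)$value
  d$p_long * comp(d$meanlog_long, d$sdlog_long) +
    (1 - d$p_long) * comp(d$meanlog_short, d$sdlog_short)
}

#' Analytic expected fraction of event-bearing dendrites with a qualifying event
#'
#' With events arriving as a Poisson process (expected count `m` over the
#' observation) and each event independently "qualifying" with probability
#' `q`, the fraction of dendrites with at least one qualifying event among
#' dendrites with at least one event of any kind is
#' `(1 - exp(-m q)) / (1 - exp(-m))`.
#'
#' @param cfg a `trace_gen_config`.
#' @param minutes observation time in minutes (running-state minutes).
#' @param q per-event qualifying probability; defaults to the prolonged
#'   probability implied by `cfg`'s duration mixture.
#' @export
expected_dendrite_fraction <- function(cfg, minutes,
                                       q = prolonged_prob_per_event(cfg)) {
  m <- cfg$event_rate_per_min * minutes
  (1 - exp(-m * q)) / (1 - exp(-m))
}

#' Calibrate the plateau mixture weight to a target prolonged-dendrite fraction
#'
#' Solves for `p_long` such that [expected_dendrite_fraction()] equals
#' `target` over `minutes` of observation, holding everything else in `cfg`
#' fixed.
#' @param cfg a `trace_gen_config`.
#' @param target target fraction in (0, 1).
#' @param minutes observation minutes.
#' @return the calibrated `trace_gen_config`.
#' @export
calibrate_p_long <- function(cfg, target, minutes) {
  f <- function(p) {
    cfg$duration_dist$p_long <- p
    expected_dendrite_fraction(cfg, minutes) - target
  }
  p <- stats::uniroot(f, c(1e-6, 1 - 1e-6), tol = 1e-10)$root
  cfg$duration_dist$p_long <- p
  cfg
}

# expected fractional shortfall of the lowest-10% baseline below the true
# resting level, for additive noise: F0 ~ f_rest (1 - c sigma_rel) where c is
# the expected mean of the lowest 10% order statistics of a standard normal
# window (Blom approximation)
f0_percentile_bias <- function(cfg) {
  n <- as.integer(round(cfg$trial_length_s * cfg$sampling_rate_hz))
  k <- max(1L, ceiling(0.1 * n))
  c_n <- -mean(stats::qnorm(((1:k) - 0.375) / (n + 0.25)))
  c_n * cfg$noise_sd / cfg$f_rest
}

#' Calibrate the amplitude intercept to a target large-amplitude fraction
#'
#' Solves for the amplitude-model intercept such that the analytic expected
#' fraction of event-bearing dendrites with at least one event whose
#' *measured* peak exceeds `cutoff` equals `target`. Because the percentile
#' baseline sits slightly below the true resting level under noise, measured
#' peaks are inflated by a known factor; the calibration converts `cutoff`
#' to the equivalent cutoff on true amplitudes
#' (`cutoff - (cutoff + 1) * bias`) before solving.
#' @inheritParams calibrate_p_long
#' @param cutoff peak cutoff on measured dF/F0 (4 = 400%).
#' @export
calibrate_amp_intercept <- function(cfg, target, minutes, cutoff = 4) {
  cut_eff <- cutoff - (cutoff + 1) * f0_percentile_bias(cfg)
  f <- function(a0) {
    cfg$amp_coupling$intercept <- a0
    q <- large_amp_prob_per_event(cfg, cut_eff)
    expected_dendrite_fraction(cfg, minutes, q = q) - target
  }
  a0 <- stats::uniroot(f, c(-5, cutoff), tol = 1e-9)$root
  cfg$amp_coupling$intercept <- a0
  cfg
}

#' Preset generator regimes calibrated to the two experimental groups
#'
#' `"AD"` (amyloid-model-like) and `"WT"` (wild-type-like) presets share the
#' acquisition parameters and differ in the plateau mixture weight and
#' amplitude level, calibrated analytically so that over a 5-minute running
#' observation the expected fraction of event-bearing dendrites with at least
#' one prolonged (> 8 s) transient is 0.47 (AD) or 0.18 (WT), and with at
#' least one large-amplitude (> 400%) transient is 0.372 (AD) or 0.250 (WT).
#'
#' @param regime `"AD"` or `"WT"`.
#' @param ... overrides passed to [trace_gen_config()] before calibration.
#' @return calibrated `trace_gen_config`.
#' @export
regime_config <- function(regime = c("AD", "WT"), ...) {
  regime <- match.arg(regime)
  cfg <- trace_gen_config(...)
  minutes <- sum(cfg$trial_states == "running") * cfg$trial_length_s / 60
  targets <- switch(regime,
                    AD = c(prolonged = 0.47, large = 0.372),
                    WT = c(prolonged = 0.18, large = 0.250))
  cfg <- calibrate_p_long(cfg, targets[["prolonged"]], minutes)
  cfg <- calibrate_amp_intercept(cfg, targets[["large"]], minutes)
  cfg$regime <- regime
  cfg
}

# draw a non-overlapping event schedule for one ROI over one trial.
# Durations are continuous (seconds); onsets are snapped to the frame grid.
# A decay clearance of 2 frames plus min_gap_s separates consecutive events.
draw_trial_events <- function(cfg, rate_per_min, amp_fun) {
  fs <- cfg$sampling_rate_hz; T_s <- cfg$trial_length_s
  n <- stats::rpois(1, rate_per_min * T_s / 60)
  empty <- data.frame(onset_s = numeric(0), onset_frame = integer(0),
                      duration_s = numeric(0), n_samples = integer(0),
                      amplitude = numeric(0))
  if (n == 0) return(empty)
  d <- cfg$duration_dist
  long <- stats::runif(n) < d$p_long
  dur <- ifelse(long,
                stats::rlnorm(n, d$meanlog_long, d$sdlog_long),
                stats::rlnorm(n, d$meanlog_short, d$sdlog_short))
  # clearance covers the rendered decay (truncated at 0.1% of amplitude)
  pad <- ceiling(cfg$tau_decay_s * log(1000) * fs) / fs + cfg$min_gap_s
  dur <- pmin(dur, T_s - pad - 1 / fs)   # an event must fit inside its trial
  amp <- amp_fun(n, dur)
  for (try in seq_len(200)) {
    onset <- stats::runif(n, 0, T_s - dur - pad)
    o <- order(onset)
    onset <- onset[o]; dur_o <- dur[o]; amp_o <- amp[o]
    if (n == 1 || all(onset[-1] >= (onset + dur_o + pad)[-n])) {
      onset_frame <- as.integer(floor(onset * fs))
      return(data.frame(onset_s = onset_frame / fs, onset_frame = onset_frame,
                        duration_s = dur_o,
                        n_samples = pmax(1L, as.integer(round(dur_o * fs))),
                        amplitude = amp_o))
    }
  }
  # dense draw that never spaced out: keep a greedy non-overlapping subset
  o <- order(onset)
  keep <- logical(n); last_end <- -Inf
  for (i in o) {
    if (onset[i] >= last_end) { keep[i] <- TRUE; last_end <- onset[i] + dur[i] + pad }
  }
  onset_frame <- as.integer(floor(onset[keep] * fs))
  ord <- order(onset_frame)
  data.frame(onset_s = (onset_frame / fs)[ord], onset_frame = onset_frame[ord],
             duration_s = dur[keep][ord],
             n_samples = pmax(1L, as.integer(round(dur[keep] * fs)))[ord],
             amplitude = amp[keep][ord])
}

# render the fractional-activity waveform A(t) for one trial:
# step to full amplitude at the onset frame (the rise occupies the preceding
# inter-frame interval), flat plateau, then exponential decay with tau,
# truncated below 0.1% of the event amplitude so that events separated by
# the enforced gap are exactly non-interacting.
render_waveform <- function(events, n_frames, fs, tau) {
  A <- numeric(n_frames)
  dt <- 1 / fs
  for (i in seq_len(nrow(events))) {
    on <- events$onset_frame[i] + 1L           # to 1-based
    top <- seq.int(on, min(on + events$n_samples[i] - 1L, n_frames))
    A[top] <- A[top] + events$amplitude[i]
    k <- 1L
    repeat {
      fr <- on + events$n_samples[i] - 1L + k
      val <- events$amplitude[i] * exp(-k * dt / tau)
      if (fr > n_frames || val < 1e-3 * events$amplitude[i]) break
      A[fr] <- A[fr] + val
      k <- k + 1L
    }
  }
  A
}

#' Generate a synthetic fluorescence trace set with known ground truth
#'
#' Simulates raw per-ROI fluorescence for somata, dendrites and spines over
#' the trial structure in `cfg`. Raw fluorescence is
#' `F(t) = background_level + f_rest * (1 + A(t)) + noise`, where `A(t)` sums
#' plateau event waveforms. Spine activity is composed in fractional space as
#' `bap_scale` times the parent dendrite's fractional signal plus
#' spine-intrinsic synaptic events, then mapped back to raw fluorescence on
#' the spine's own baseline -- so scaled-subtraction spine isolation is
#' exactly invertible at zero noise.
#'
#' Event schedules are drawn per ROI and trial as a Poisson process with
#' non-overlap enforced, or supplied explicitly via `dendrite_events` /
#' `spine_events` (data frames with columns `roi_id`, `trial`, `onset_s`,
#' `duration_s`, `amplitude`) for scripted experiments.
#'
#' If `cfg$depot_attenuation > 0`, spine-intrinsic events starting after the
#' offset of a prolonged dendritic event in the same trial are attenuated by
#' that fraction, emulating depotentiation.
#'
#' @param cfg a [trace_gen_config()].
#' @param n_somas,n_dendrites number of somatic and dendritic ROIs.
#' @param n_spines_per_dendrite number of spine ROIs per dendrite.
#' @param dendrite_events,spine_events optional explicit event schedules.
#' @return list with `traces` (a [trace_set()]) and `events`, the
#'   ground-truth table: one row per injected event with `roi_id`, `role`,
#'   `parent_id`, `trial`, `onset_s`, `onset_frame`, `duration_s`,
#'   `n_samples`, `amplitude` and `prolonged` flag.
#' @export
generate_trace_set <- function(cfg, n_somas = 0, n_dendrites = 1,
                               n_spines_per_dendrite = 0,
                               dendrite_events = NULL, spine_events = NULL) {
  stopifnot(inherits(cfg, "trace_gen_config"),
            n_somas >= 0, n_dendrites >= 0, n_spines_per_dendrite >= 0)
  fs <- cfg$sampling_rate_hz
  nft <- as.integer(round(cfg$trial_length_s * fs))
  n_frames <- nft * cfg$n_trials
  soma_ids <- if (n_somas > 0) sprintf("soma%02d", seq_len(n_somas)) else character(0)
  dend_ids <- if (n_dendrites > 0) sprintf("dend%03d", seq_len(n_dendrites)) else character(0)
  spine_ids <- character(0); spine_parent <- character(0)
  for (d in dend_ids) {
    if (n_spines_per_dendrite > 0) {
      sid <- sprintf("%s_sp%02d", d, seq_len(n_spines_per_dendrite))
      spine_ids <- c(spine_ids, sid)
      spine_parent <- c(spine_parent, rep(d, n_spines_per_dendrite))
    }
  }
  rois <- data.frame(
    roi_id = c(soma_ids, dend_ids, spine_ids),
    role = c(rep("soma", length(soma_ids)), rep("dendrite", length(dend_ids)),
             rep("spine", length(spine_ids))),
    parent_id = c(rep("", length(soma_ids) + length(dend_ids)), spine_parent),
    stringsAsFactors = FALSE)

  with_seed(cfg$seed, {
    amp_fun <- function(n, dur) {
      a <- cfg$amp_coupling
      pmin(pmax(a$intercept + a$slope * dur + stats::rnorm(n, 0, a$sd), a$min), a$max)
    }
    rate_for <- function(state)
      cfg$event_rate_per_min *
        if (state == "resting") cfg$resting_rate_factor else 1

    sched_for <- function(cfg_use, roi, trial, supplied, rate, amp_fun) {
      if (!is.null(supplied)) {
        ev <- supplied[supplied$roi_id == roi & supplied$trial == trial, ,
                       drop = FALSE]
        if (nrow(ev) == 0)
          return(draw_trial_events(cfg_use, 0, amp_fun))
        onset_frame <- as.integer(floor(ev$onset_s * fs))
        ord <- order(onset_frame)
        return(data.frame(onset_s = (onset_frame / fs)[ord],
                          onset_frame = onset_frame[ord],
                          duration_s = ev$duration_s[ord],
                          n_samples = pmax(1L, as.integer(round(ev$duration_s * fs)))[ord],
                          amplitude = ev$amplitude[ord]))
      }
      draw_trial_events(cfg_use, rate, amp_fun)
    }

    Fmat <- matrix(NA_real_, n_frames, nrow(rois),
                   dimnames = list(NULL, rois$roi_id))
    gt <- list()
    dend_frac <- list()  # per dendrite: fractional waveform, full session
    dend_prolonged_offset <- list()  # per dendrite per trial: earliest offset time

    # somata and dendrites
    for (roi in c(soma_ids, dend_ids)) {
      role <- if (roi %in% soma_ids) "soma" else "dendrite"
      A <- numeric(n_frames)
      for (tr in seq_len(cfg$n_trials)) {
        ev <- sched_for(cfg, roi, tr,
                        if (role == "dendrite") dendrite_events else NULL,
                        rate_for(cfg$trial_states[tr]), amp_fun)
        idx <- (tr - 1L) * nft
        A[idx + seq_len(nft)] <- render_waveform(ev, nft, fs, cfg$tau_decay_s)
        if (nrow(ev)) {
          gt[[length(gt) + 1L]] <- cbind(
            data.frame(roi_id = roi, role = role, parent_id = "", trial = tr,
                       stringsAsFactors = FALSE), ev)
          if (role == "dendrite") {
            prol <- ev$duration_s > cfg$prolonged_cutoff_s
            if (any(prol)) {
              off <- min(ev$onset_s[prol] + ev$n_samples[prol] / fs)
              dend_prolonged_offset[[roi]][[tr]] <- off
            }
          }
        }
      }
      if (role == "dendrite") dend_frac[[roi]] <- A
      Fmat[, roi] <- cfg$f_rest * (1 + A)
    }

    # spines: bAP-coupled dendritic component + intrinsic synaptic events
    if (length(spine_ids)) {
      for (si in seq_along(spine_ids)) {
        roi <- spine_ids[si]; parent <- spine_parent[si]
        base_amp <- stats::rlnorm(1, cfg$spine_amp$meanlog, cfg$spine_amp$sdlog)
        spine_amp_fun <- function(n, dur)
          base_amp * stats::rlnorm(n, 0, cfg$spine_amp$jitter_sdlog)
        A_syn <- numeric(n_frames)
        scfg <- cfg
        scfg$duration_dist$p_long <- 0   # synaptic events are brief
        for (tr in seq_len(cfg$n_trials)) {
          ev <- sched_for(scfg, roi, tr, spine_events,
                          cfg$spine_event_rate_per_min *
                            if (cfg$trial_states[tr] == "resting") cfg$resting_rate_factor else 1,
                          spine_amp_fun)
          if (!is.null(spine_events)) {
            # supplied schedules carry their own amplitudes
          }
          if (cfg$depot_attenuation > 0 && nrow(ev)) {
            po <- dend_prolonged_offset[[parent]]
            off <- if (!is.null(po) && length(po) >= tr) po[[tr]] else NULL
            if (!is.null(off)) {
              late <- ev$onset_s > off
              ev$amplitude[late] <- ev$amplitude[late] * (1 - cfg$depot_attenuation)
            }
          }
          idx <- (tr - 1L) * nft
          if (nrow(ev)) {
            A_syn[idx + seq_len(nft)] <-
              render_waveform(ev, nft, fs, cfg$tau_decay_s)
            gt[[length(gt) + 1L]] <- cbind(
              data.frame(roi_id = roi, role = "spine", parent_id = parent,
                         trial = tr, stringsAsFactors = FALSE), ev)
          }
        }
        A <- cfg$bap_scale * dend_frac[[parent]] + A_syn
        Fmat[, roi] <- cfg$f_rest * (1 + A)
      }
    }

    # background and noise
    Fmat <- Fmat + cfg$background_level
    if (cfg$noise_sd > 0) {
      eps <- matrix(stats::rnorm(length(Fmat)), nrow(Fmat), ncol(Fmat))
      Fmat <- Fmat + if (cfg$noise_model == "additive") cfg$noise_sd * eps
                     else cfg$noise_sd * eps * Fmat / cfg$f_rest
    }

    events <- if (length(gt)) do.call(rbind, gt) else
      data.frame(roi_id = character(0), role = character(0),
                 parent_id = character(0), trial = integer(0),
                 onset_s = numeric(0), onset_frame = integer(0),
                 duration_s = numeric(0), n_samples = integer(0),
                 amplitude = numeric(0))
    events$prolonged <- events$duration_s > cfg$prolonged_cutoff_s
    events <- events[order(events$roi_id, events$trial, events$onset_frame), ]
    rownames(events) <- NULL

    ts <- trace_set(F = Fmat, rois = rois, sampling_rate_hz = fs,
                    trial = rep(seq_len(cfg$n_trials), each = nft),
                    states = cfg$trial_states,
                    background = rep(cfg$background_level, n_frames))
    list(traces = ts, events = events)
  })
}

#' Configuration for the two-channel spine-image generator
#'
#' @param image_size_px side length of the square image, pixels.
#' @param shaft_width_px width of the vertical dendritic shaft band.
#' @param spine_radius_px radius of the circular spine head.
#' @param spine_offset_px distance from the shaft centre column to the spine
#'   head centre, pixels.
#' @param intensities list with numeric vectors `structural` and `functional`,
#'   each `c(S = spine, D = dendrite, B = background)` brightness.
#' @param blur_sigma_px Gaussian blur sigma (0 = none).
#' @param noise_sd additive Gaussian pixel noise SD.
#' @param seed RNG seed.
#' @export
image_gen_config <- function(image_size_px = 64, shaft_width_px = 8,
                             spine_radius_px = 6, spine_offset_px = 14,
                             intensities = list(
                               structural = c(S = 200, D = 150, B = 50),
                               functional = c(S = 120, D = 100, B = 20)),
                             blur_sigma_px = 0, noise_sd = 0, seed = 1L) {
  for (ch in c("structural", "functional")) {
    v <- intensities[[ch]]
    if (!(v[["S"]] > v[["B"]] && v[["D"]] > v[["B"]] && v[["B"]] >= 0))
      stopf("%s intensities must satisfy S, D > B >= 0", ch)
  }
  cc <- floor(image_size_px / 2)
  if (cc + spine_offset_px + spine_radius_px >= image_size_px ||
      spine_offset_px - spine_radius_px <= shaft_width_px / 2)
    stopf("spine head must fit inside the image, clear of the shaft")
  structure(list(image_size_px = image_size_px, shaft_width_px = shaft_width_px,
                 spine_radius_px = spine_radius_px,
                 spine_offset_px = spine_offset_px, intensities = intensities,
                 blur_sigma_px = blur_sigma_px, noise_sd = noise_sd,
                 seed = seed),
            class = "image_gen_config")
}

#' Render a two-channel (structural + functional) spine image pair
#'
#' Paints a vertical dendritic shaft and a circular spine head on a uniform
#' background in both channels, optionally blurs and adds pixel noise, and
#' returns the images together with the ground-truth structural intensity
#' ratio `(S - B) / (D - B)` (computed from the configured intensities before
#' blur and noise) and measurement ROI masks for the spine head, an adjacent
#' shaft sample and a background patch.
#'
#' @param cfg an [image_gen_config()].
#' @return list `structural`, `functional` (matrices), `true_ratio`, and
#'   `rois` (logical masks `spine`, `shaft`, `background`).
#' @export
generate_spine_image_pair <- function(cfg) {
  stopifnot(inherits(cfg, "image_gen_config"))
  n <- cfg$image_size_px
  cc <- floor(n / 2)                       # 0-based centre column
  half_w <- cfg$shaft_width_px / 2
  col0 <- matrix(rep(0:(n - 1), each = n), n, n)   # 0-based column of pixel centre
  row0 <- matrix(rep(0:(n - 1), times = n), n, n)
  shaft <- abs(col0 - cc) <= half_w
  sp_c <- c(row = cc, col = cc + cfg$spine_offset_px)
  spine <- (row0 - sp_c[["row"]])^2 + (col0 - sp_c[["col"]])^2 <=
    cfg$spine_radius_px^2

  paint <- function(v) {
    img <- matrix(v[["B"]], n, n)
    img[shaft] <- v[["D"]]
    img[spine] <- v[["S"]]
    img
  }
  degrade <- function(img) {
    if (cfg$blur_sigma_px > 0)
      img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                               sigma = cfg$blur_sigma_px))
    if (cfg$noise_sd > 0)
      img <- img + matrix(stats::rnorm(n * n, 0, cfg$noise_sd), n, n)
    pmax(img, 0)
  }
  vs <- cfg$intensities$structural
  out <- with_seed(cfg$seed, list(
    structural = degrade(paint(vs)),
    functional = degrade(paint(cfg$intensities$functional))))
  out$true_ratio <- (vs[["S"]] - vs[["B"]]) / (vs[["D"]] - vs[["B"]])

  # measurement masks, eroded well inside their regions so that moderate
  # blur (sigma around 1 px) does not bleed neighbouring intensities in:
  # spine core 3 px inside the head, shaft sample on the band axis,
  # background patch in the far corner
  shaft_samp <- shaft & abs(row0 - cc) <= 4 & abs(col0 - cc) <= 2
  bg <- row0 <= 7 & col0 <= 7
  spine_core <- (row0 - sp_c[["row"]])^2 + (col0 - sp_c[["col"]])^2 <=
    max(cfg$spine_radius_px - 3, 1)^2
  out$rois <- list(spine = spine_core, shaft = shaft_samp, background = bg)
  out
}
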