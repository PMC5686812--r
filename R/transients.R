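#' @section Baseline and threshold estimation:
#' The baseline SD that sets the detection threshold is estimated per
#' analysis window as the root-mean-square dF/F0 of the baseline sample set
#' (deviation from the window baseline F0, which is a low-percentile
#' statistic, so baseline dF/F0 sits slightly above zero). Two sample-set
#' modes exist. `"two_pass"` (default): pass 1 uses samples whose reference
#' trace lies below the window median and forms a provisional threshold;
#' pass 2 recomputes over all samples outside provisional supra-threshold
#' runs. This avoids the systematic underestimate that comes from using only
#' the lowest-intensity samples. `"f0_set"`: the same lowest-10% samples
#' that define F0 (for sensitivity analysis). A small absolute floor on the
#' threshold guards degenerate zero-noise traces where the baseline SD is
#' exactly 0.
#' @name baseline-threshold
#' @keywords internal
NULL

# Baseline SD is the root-mean-square dF/F0 of the baseline sample set --
# deviation from the window baseline F0 (dff = 0), not from the baseline
# samples' own mean. Because F0 is a low-percentile statistic, baseline dff
# sits slightly above 0; an SD about the baseline mean would put a 3x
# threshold barely above the baseline band and fire on noise.
rms0 <- function(x) if (length(x) >= 2) sqrt(mean(x^2)) else 0

baseline_threshold <- function(dff, ref = dff, mode = "two_pass",
                               mult = 3, floor_dff = 0.05) {
  if (mode == "f0_set") {
    k <- max(1L, ceiling(0.1 * length(ref)))
    s <- rms0(dff[order(ref)[seq_len(k)]])
  } else {
    below <- ref < stats::median(ref)
    s1 <- rms0(dff[below])
    thr1 <- max(mult * s1, floor_dff)
    runs <- logical_runs(dff >= thr1)
    keep <- rep(TRUE, length(dff))
    for (i in seq_len(nrow(runs))) keep[runs$start[i]:runs$end[i]] <- FALSE
    s <- rms0(dff[keep])
  }
  if (is.na(s)) s <- 0
  list(baseline_sd = s, threshold = max(mult * s, floor_dff))
}

#' Compute dF/F0 with percentile baseline and per-window detection thresholds
#'
#' For every ROI and every analysis window (default one 60 s window per
#' trial, matching the acquisition block length), the baseline `F0` is the
#' mean of the lowest 10% of raw fluorescence samples in that window
#' (`ceiling(0.1 n)` samples, at least one), and
#' `dF/F0 = (F - F0) / F0` using that window's `F0`. The detection threshold
#' is `sd_multiplier` (default 3) times the baseline SD of dF/F0, estimated
#' as described under `baseline_threshold`, with an absolute floor for
#' zero-noise degenerate traces.
#'
#' Background must already have been subtracted (see
#' [subtract_background()]); an `F0 <= 0` in any window signals background
#' over-subtraction and is an error.
#'
#' @param ts a background-subtracted [trace_set()].
#' @param window_s analysis-window length in seconds; must divide into trials
#'   with at least 10 samples per window.
#' @param sd_mode `"two_pass"` (default) or `"f0_set"`; see Details.
#' @param sd_multiplier threshold multiplier on the baseline SD.
#' @param threshold_floor absolute lower bound on the detection threshold
#'   (fractional dF/F0).
#' @return an object of class `dff_set`: list with `dff` and `threshold`
#'   matrices (frames x ROIs), a `windows` table (`roi_id`, `trial`,
#'   `window`, `f0`, `baseline_sd`, `threshold`), and the session metadata.
#' @export
compute_dff <- function(ts, window_s = 60, sd_mode = c("two_pass", "f0_set"),
                        sd_multiplier = 3, threshold_floor = 0.05) {
  stopifnot(inherits(ts, "trace_set"))
  sd_mode <- match.arg(sd_mode)
  fs <- ts$sampling_rate_hz
  wlen <- as.integer(round(window_s * fs))
  dff <- ts$F * NA_real_
  thr <- ts$F * NA_real_
  wins <- list()
  for (tr in unique(ts$trial)) {
    fr <- which(ts$trial == tr)
    if (wlen > length(fr)) stopf("window_s exceeds trial %d length", tr)
    starts <- seq(1L, length(fr), by = wlen)
    for (wi in seq_along(starts)) {
      idx <- fr[starts[wi]:min(starts[wi] + wlen - 1L, length(fr))]
      if (length(idx) < 10) stopf("analysis window with fewer than 10 samples")
      for (roi in colnames(ts$F)) {
        x <- ts$F[idx, roi]
        k <- max(1L, ceiling(0.1 * length(x)))
        f0 <- mean(sort(x)[seq_len(k)])
        if (f0 <= 0)
          stopf("F0 <= 0 for ROI '%s' in trial %d (background over-subtraction?)",
                roi, tr)
        d <- (x - f0) / f0
        bt <- baseline_threshold(d, ref = x, mode = sd_mode,
                                 mult = sd_multiplier,
                                 floor_dff = threshold_floor)
        dff[idx, roi] <- d
        thr[idx, roi] <- bt$threshold
        wins[[length(wins) + 1L]] <-
          data.frame(roi_id = roi, trial = tr, window = wi, f0 = f0,
                     baseline_sd = bt$baseline_sd, threshold = bt$threshold,
                     stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(dff = dff, threshold = thr, windows = do.call(rbind, wins),
                 sampling_rate_hz = fs, trial = ts$trial, states = ts$states,
                 rois = ts$rois, sd_multiplier = sd_multiplier,
                 sd_mode = sd_mode, threshold_floor = threshold_floor),
            class = "dff_set")
}

#' Extract one ROI's dF/F0 trace from a `dff_set`
#' @param dset a [compute_dff()] result.
#' @param roi_id ROI identifier.
#' @return list of class `dff_trace` with `dff`, per-frame `threshold`,
#'   the ROI's window table and session metadata.
#' @export
get_dff_trace <- function(dset, roi_id) {
  stopifnot(inherits(dset, "dff_set"))
  if (!roi_id %in% colnames(dset$dff)) stopf("unknown ROI '%s'", roi_id)
  structure(list(roi_id = roi_id, dff = dset$dff[, roi_id],
                 threshold = dset$threshold[, roi_id],
                 windows = dset$windows[dset$windows$roi_id == roi_id, ],
                 sampling_rate_hz = dset$sampling_rate_hz,
                 trial = dset$trial, states = dset$states),
            class = "dff_trace")
}

empty_transients <- function() {
  data.frame(roi_id = character(0), trial = integer(0),
             onset_frame = integer(0), offset_frame = integer(0),
             onset_s = numeric(0), duration_s = numeric(0),
             peak_dff = numeric(0), integrated = numeric(0),
             prolonged = logical(0), large_amplitude = logical(0))
}

detect_one <- function(dff, thr, trial, fs, roi_id,
                       prolonged_cutoff_s, large_amp_cutoff) {
  out <- list()
  for (tr in unique(trial)) {
    fr <- which(trial == tr)
    runs <- logical_runs(dff[fr] >= thr[fr])
    if (!nrow(runs)) next
    n <- runs$end - runs$start + 1L
    seg <- function(i) dff[fr[runs$start[i]:runs$end[i]]]
    out[[length(out) + 1L]] <- data.frame(
      roi_id = roi_id, trial = tr,
      onset_frame = runs$start - 1L, offset_frame = runs$end - 1L,
      onset_s = (runs$start - 1L) / fs,
      duration_s = n / fs,
      peak_dff = vapply(seq_len(nrow(runs)), function(i) max(seg(i)), 0),
      integrated = vapply(seq_len(nrow(runs)), function(i) sum(seg(i)), 0) / fs,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_transients())
  ev <- do.call(rbind, out)
  ev$prolonged <- ev$duration_s > prolonged_cutoff_s
  ev$large_amplitude <- ev$peak_dff > large_amp_cutoff
  ev
}

#' Detect calcium transients as supra-threshold runs of dF/F0
#'
#' A transient is a maximal run of consecutive samples with
#' `dff >= threshold`; runs are computed within trials, so an excursion
#' spanning a trial boundary splits at the boundary. Per event the duration
#' is the supra-threshold time `(offset - onset + 1) / rate`, the peak is the
#' highest dF/F0 in the run, and the integrated activity is the sum of
#' supra-threshold dF/F0 times the frame interval. Events with duration
#' strictly greater than `prolonged_cutoff_s` are flagged `prolonged`; events
#' whose peak strictly exceeds `large_amp_cutoff` (fractional units, 4 =
#' 400%) are flagged `large_amplitude`. Frames are 0-based within trial.
#'
#' @param x a `dff_set`, `dff_trace` or `spine_specific_trace`.
#' @param prolonged_cutoff_s duration cutoff, seconds (strict).
#' @param large_amp_cutoff peak cutoff, fractional dF/F0 (strict).
#' @return a `transient_table` data.frame sorted by ROI, trial, onset.
#' @export
detect_transients <- function(x, prolonged_cutoff_s = 8, large_amp_cutoff = 4) {
  ev <- if (inherits(x, "dff_set")) {
    do.call(rbind, lapply(colnames(x$dff), function(roi)
      detect_one(x$dff[, roi], x$threshold[, roi], x$trial,
                 x$sampling_rate_hz, roi, prolonged_cutoff_s, large_amp_cutoff)))
  } else if (inherits(x, c("dff_trace", "spine_specific_trace"))) {
    detect_one(x$dff, x$threshold, x$trial, x$sampling_rate_hz,
               x$roi_id %||% x$spine_id, prolonged_cutoff_s, large_amp_cutoff)
  } else stopf("x must be a dff_set, dff_trace or spine_specific_trace")
  ev <- ev[order(ev$roi_id, ev$trial, ev$onset_frame), ]
  rownames(ev) <- NULL
  class(ev) <- c("transient_table", "data.frame")
  ev
}

#' Summarize transient activity for one ROI
#'
#' Frequency is events per minute observed; total integrated activity is
#' normalized per minute (accumulated supra-threshold dF/F0 x dt / minutes).
#'
#' @param events `transient_table` rows from a single ROI (any state mix the
#'   caller chose).
#' @param minutes_observed observation time in minutes, > 0.
#' @param roi_id ROI id (required when `events` is empty).
#' @param state optional state label carried through.
#' @return one-row data.frame.
#' @export
summarize_roi <- function(events, minutes_observed, roi_id = NULL,
                          state = NA_character_) {
  if (minutes_observed <= 0) stopf("minutes_observed must be > 0")
  if (nrow(events)) {
    ids <- unique(events$roi_id)
    if (length(ids) > 1) stopf("summarize_roi expects events from one ROI")
    roi_id <- ids
  }
  if (is.null(roi_id)) stopf("roi_id required for an empty event table")
  data.frame(
    roi_id = roi_id, state = state, n_events = nrow(events),
    minutes_observed = minutes_observed,
    frequency_per_min = nrow(events) / minutes_observed,
    mean_duration_s = if (nrow(events)) mean(events$duration_s) else 0,
    total_duration_s = sum(events$duration_s),
    mean_peak = if (nrow(events)) mean(events$peak_dff) else 0,
    max_peak = if (nrow(events)) max(events$peak_dff) else 0,
    total_integrated = sum(events$integrated),
    integrated_per_min = sum(events$integrated) / minutes_observed,
    stringsAsFactors = FALSE)
}

#' Summarize activity for every ROI by behavioural state
#'
#' @param events a `transient_table`.
#' @param dset the `dff_set` the events came from (supplies trial states and
#'   observation times).
#' @return data.frame, one row per ROI x state present in the session.
#' @export
summarize_activity <- function(events, dset) {
  stopifnot(inherits(dset, "dff_set"))
  trial_state <- dset$states
  fs <- dset$sampling_rate_hz
  out <- list()
  for (roi in colnames(dset$dff)) {
    for (st in unique(trial_state)) {
      trs <- which(trial_state == st)
      minutes <- sum(dset$trial %in% trs) / fs / 60
      ev <- events[events$roi_id == roi & events$trial %in% trs, , drop = FALSE]
      out[[length(out) + 1L]] <- summarize_roi(ev, minutes, roi_id = roi,
                                               state = st)
    }
  }
  do.call(rbind, out)
}

#' Fraction of event-bearing dendrites with a qualifying transient
#'
#' The denominator is the set of dendrites exhibiting at least one detected
#' transient in `events` (ROIs with no events never enter); the numerator
#' counts those with at least one event satisfying the predicate flag.
#'
#' @param events `transient_table` restricted to dendritic ROIs.
#' @param predicate `"prolonged"` or `"large_amplitude"`.
#' @return fraction in `[0, 1]`.
#' @export
dendrite_fraction_with <- function(events,
                                   predicate = c("prolonged", "large_amplitude")) {
  predicate <- match.arg(predicate)
  if (!nrow(events)) stopf("no event-bearing dendrites (empty denominator)")
  hit <- tapply(events[[predicate]], events$roi_id, any)
  mean(hit)
}

#' Correlation between transient duration and peak amplitude
#'
#' @param events a `transient_table` with at least 3 events.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `r`, `p`, `n`, `method`.
#' @export
duration_amplitude_correlation <- function(events,
                                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(events) < 3) stopf("need at least 3 events")
  if (stats::sd(events$duration_s) == 0 || stats::sd(events$peak_dff) == 0)
    stopf("constant input vector")
  ct <- stats::cor.test(events$duration_s, events$peak_dff, method = method,
                        exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(events),
       method = method)
}

#' Write a transient table to CSV with provenance header
#' @param events a `transient_table`.
#' @param path output file.
#' @param config optional configuration hashed into the header.
#' @export
write_events_csv <- function(events, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  utils::write.csv(as.data.frame(events), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path, comment.char = "#")
  class(ev) <- c("transient_table", "data.frame")
  ev
}
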