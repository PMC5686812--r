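#' Scaled subtraction of the dendritic shaft signal from a spine trace
#'
#' Back-propagating action potentials invade spines together with their
#' parent dendrite, so the raw spine dF/F0 contains a dendritic component.
#' The spine-specific signal removes it by elementwise subtraction of a
#' scaled copy of the shaft trace:
#' `dff_specific = dff_spine - scale * dff_dendrite`, with `scale = 0.7` by
#' default. [spine_specific_series()] is the bare vector operation;
#' [spine_specific()] operates on a [compute_dff()] result, checks
#' spine-to-dendrite parentage, and recomputes per-window detection
#' thresholds on the resulting trace with the same baseline rule used for
#' raw traces (median split and event exclusion applied to the
#' spine-specific trace itself).
#'
#' @param dff_spine,dff_dendrite aligned numeric dF/F0 vectors.
#' @param scale subtraction coefficient.
#' @return `spine_specific_series`: the subtracted numeric vector.
#' @export
spine_specific_series <- function(dff_spine, dff_dendrite, scale = 0.7) {
  if (length(dff_spine) != length(dff_dendrite))
    stopf("spine and dendrite traces have different lengths")
  dff_spine - scale * dff_dendrite
}

#' @rdname spine_specific_series
#' @param dset a `dff_set` containing both ROIs.
#' @param spine_id spine ROI id.
#' @param dendrite_id parent dendrite id; defaults to the spine's registered
#'   parent, and must match it.
#' @param sd_mode,sd_multiplier,threshold_floor threshold-estimation settings,
#'   as in [compute_dff()].
#' @return `spine_specific()`: object of class `spine_specific_trace` with
#'   `dff`, per-frame `threshold`, `windows`, the ids, `scale` and session
#'   metadata.
#' @export
spine_specific <- function(dset, spine_id, dendrite_id = NULL, scale = 0.7,
                           sd_mode = c("two_pass", "f0_set"),
                           sd_multiplier = 3, threshold_floor = 0.05) {
  stopifnot(inherits(dset, "dff_set"))
  sd_mode <- match.arg(sd_mode)
  info <- dset$rois[dset$rois$roi_id == spine_id, ]
  if (!nrow(info) || info$role != "spine") stopf("'%s' is not a spine ROI", spine_id)
  parent <- info$parent_id
  if (is.null(dendrite_id)) dendrite_id <- parent
  if (!identical(dendrite_id, parent))
    stopf("'%s' is not the parent dendrite of '%s'", dendrite_id, spine_id)
  d <- spine_specific_series(dset$dff[, spine_id], dset$dff[, dendrite_id],
                             scale)
  thr <- numeric(length(d))
  wins <- list()
  wtab <- dset$windows[dset$windows$roi_id == spine_id, ]
  for (tr in unique(dset$trial)) {
    fr <- which(dset$trial == tr)
    bt <- baseline_threshold(d[fr], ref = d[fr], mode = sd_mode,
                             mult = sd_multiplier, floor_dff = threshold_floor)
    thr[fr] <- bt$threshold
    wins[[length(wins) + 1L]] <-
      data.frame(roi_id = spine_id, trial = tr, window = 1L, f0 = NA_real_,
                 baseline_sd = bt$baseline_sd, threshold = bt$threshold,
                 stringsAsFactors = FALSE)
  }
  structure(list(spine_id = spine_id, dendrite_id = dendrite_id, dff = d,
                 threshold = thr, windows = do.call(rbind, wins),
                 scale = scale, sampling_rate_hz = dset$sampling_rate_hz,
                 trial = dset$trial, states = dset$states),
            class = "spine_specific_trace")
}

#' Classify a spine as active or inactive at a dendritic event
#'
#' Two interchangeable rules. `"threshold"` (default): the spine is active
#' iff its spine-specific trace reaches its 3-SD detection threshold inside
#' the event window. `"ratio"`: the spine is active iff the functional-channel
#' intensity ratio between spine head and adjacent shaft at the event is at
#' least `ratio_cutoff`; the default cutoff 1.0 is the midpoint between
#' published mean head/shaft ratios for active (1.56) and inactive (0.46)
#' spines.
#'
#' @param sst a [spine_specific()] trace.
#' @param window integer frame window `c(onset, offset)` (0-based, inclusive,
#'   session frames) or a vector of frame indices.
#' @param rule `"threshold"` or `"ratio"`.
#' @param head_shaft_ratio measured head/shaft intensity ratio (required for
#'   the ratio rule, reported alongside otherwise).
#' @param ratio_cutoff decision cutoff for the ratio rule.
#' @return one-row data.frame: `spine_id`, `active`, `rule`, `peak_in_window`,
#'   `threshold`, `head_shaft_ratio`.
#' @export
classify_active <- function(sst, window, rule = c("threshold", "ratio"),
                            head_shaft_ratio = NA_real_, ratio_cutoff = 1.0) {
  stopifnot(inherits(sst, "spine_specific_trace"))
  rule <- match.arg(rule)
  idx <- if (length(window) == 2) (window[1]:window[2]) + 1L else window + 1L
  if (!length(idx) || any(idx < 1 | idx > length(sst$dff)))
    stopf("empty or out-of-range event window")
  peak <- max(sst$dff[idx])
  active <- if (rule == "threshold") any(sst$dff[idx] >= sst$threshold[idx])
            else {
              if (is.na(head_shaft_ratio)) stopf("ratio rule needs head_shaft_ratio")
              head_shaft_ratio >= ratio_cutoff
            }
  data.frame(spine_id = sst$spine_id, active = active, rule = rule,
             peak_in_window = peak,
             threshold = max(sst$threshold[idx]),
             head_shaft_ratio = head_shaft_ratio, stringsAsFactors = FALSE)
}

#' Paired spine peaks around the first and third dendritic transients
#'
#' For every (dendrite, trial) with at least three detected dendritic
#' transients, measures each child spine's peak dF/F0 inside the windows of
#' the 1st and 3rd transients of a triplet, stratified by the duration of
#' the 2nd ("middle") transient: class `"0-8 s"` versus `">8 s"` (strict
#' cutoff). The change between the two peaks probes depotentiation of
#' synaptic calcium by the intervening dendritic event; paired statistics
#' are left to [route_and_test()].
#'
#' When more than three transients occur, all sliding triplets
#' `(k, k+1, k+2)` are emitted and flagged; only the first (`primary`) is
#' independent, and callers doing inference should filter on it.
#'
#' @param dend_events `transient_table` of dendritic events (frames 0-based
#'   within trial).
#' @param dset the `dff_set` holding spine and dendrite traces.
#' @param scale subtraction coefficient for spine isolation.
#' @param measure `"specific"` (peaks on spine-specific traces, default) or
#'   `"raw"` (peaks on raw spine dF/F0).
#' @param duration_cutoff_s stratification cutoff for the middle transient.
#' @param sliding emit all sliding triplets (`TRUE`) or the first only.
#' @return data.frame of class `first_third_table`: `spine_id`,
#'   `dendrite_id`, `trial`, `triplet`, `primary`, `peak_pre`, `peak_post`,
#'   `middle_duration_s`, `middle_duration_class`.
#' @export
first_third_comparison <- function(dend_events, dset, scale = 0.7,
                                   measure = c("specific", "raw"),
                                   duration_cutoff_s = 8, sliding = TRUE) {
  stopifnot(inherits(dset, "dff_set"))
  measure <- match.arg(measure)
  out <- list()
  spines <- dset$rois[dset$rois$role == "spine", ]
  for (dend in unique(dend_events$roi_id)) {
    kids <- spines$roi_id[spines$parent_id == dend]
    if (!length(kids)) next
    traces <- lapply(kids, function(s) {
      if (measure == "specific") spine_specific(dset, s, scale = scale)$dff
      else dset$dff[, s]
    })
    names(traces) <- kids
    for (tr in unique(dend_events$trial[dend_events$roi_id == dend])) {
      ev <- dend_events[dend_events$roi_id == dend & dend_events$trial == tr, ]
      ev <- ev[order(ev$onset_frame), ]
      if (nrow(ev) < 3) next
      frame0 <- which(dset$trial == tr)[1] - 1L   # session frame of trial frame 0
      triplets <- if (sliding) seq_len(nrow(ev) - 2L) else 1L
      for (k in triplets) {
        w1 <- (ev$onset_frame[k]:ev$offset_frame[k]) + frame0 + 1L
        w3 <- (ev$onset_frame[k + 2L]:ev$offset_frame[k + 2L]) + frame0 + 1L
        mid_dur <- ev$duration_s[k + 1L]
        for (s in kids) {
          x <- traces[[s]]
          out[[length(out) + 1L]] <- data.frame(
            spine_id = s, dendrite_id = dend, trial = tr, triplet = k,
            primary = k == 1L,
            peak_pre = max(x[w1]), peak_post = max(x[w3]),
            middle_duration_s = mid_dur,
            middle_duration_class = if (mid_dur > duration_cutoff_s) ">8 s"
                                    else "0-8 s",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(spine_id = character(0), dendrite_id = character(0),
               trial = integer(0), triplet = integer(0), primary = logical(0),
               peak_pre = numeric(0), peak_post = numeric(0),
               middle_duration_s = numeric(0),
               middle_duration_class = character(0))
  class(res) <- c("first_third_table", "data.frame")
  res
}
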