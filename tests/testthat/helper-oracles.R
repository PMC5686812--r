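# Independent oracles, deliberately written as naive per-sample scans and
# brute-force recounts so they share no code with the package internals.

# event boundaries by a stateful per-sample scan (1-based frames, split at
# trial boundaries); returns trial/onset/offset rows in scan order
naive_event_scan <- function(dff, thr, trial) {
  rows <- list()
  in_ev <- FALSE
  st <- NA_integer_
  for (i in seq_along(dff)) {
    new_trial <- i > 1 && trial[i] != trial[i - 1]
    if (in_ev && new_trial) {
      rows[[length(rows) + 1]] <- c(trial[i - 1], st, i - 1)
      in_ev <- FALSE
    }
    above <- dff[i] >= thr[i]
    if (!in_ev && above) {
      in_ev <- TRUE
      st <- i
    } else if (in_ev && !above) {
      rows[[length(rows) + 1]] <- c(trial[i - 1], st, i - 1)
      in_ev <- FALSE
    }
  }
  if (in_ev)
    rows[[length(rows) + 1]] <- c(trial[length(dff)], st, length(dff))
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(trial = integer(0), onset = integer(0),
                      offset = integer(0)))
  data.frame(trial = as.integer(out[, 1]), onset = as.integer(out[, 2]),
             offset = as.integer(out[, 3]))
}

# detected events of one ROI expressed in the same 1-based session-frame
# coordinates as the naive scan
events_as_session_frames <- function(ev, trial_vec) {
  if (!nrow(ev)) return(data.frame(trial = integer(0), onset = integer(0),
                                   offset = integer(0)))
  frame0 <- vapply(ev$trial, function(tr) which(trial_vec == tr)[1] - 1L, 1L)
  data.frame(trial = ev$trial, onset = ev$onset_frame + frame0 + 1L,
             offset = ev$offset_frame + frame0 + 1L)
}

# a hand-built dff trace object for direct detector tests
make_dff_trace <- function(dff, threshold, fs = 2, trial = NULL) {
  structure(list(roi_id = "test", dff = dff,
                 threshold = rep_len(threshold, length(dff)),
                 trial = trial %||% rep(1L, length(dff)),
                 sampling_rate_hz = fs, states = "running"),
            class = "dff_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
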