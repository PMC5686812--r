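#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d frames x %d ROIs @ %g Hz, %d trials (%s)\n",
              nrow(x$F), ncol(x$F), x$sampling_rate_hz, length(x$states),
              paste(x$states, collapse = ", ")))
  tab <- table(x$rois$role)
  cat("  ROIs:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  background:",
      if (is.null(x$background)) "undefined"
      else sprintf("per-frame (mean %.3g)", mean(x$background)), "\n")
  invisible(x)
}

#' @export
summary.trace_set <- function(object, ...) {
  rng <- range(object$F)
  cat(sprintf("trace_set: F range [%.3g, %.3g], %.1f min total\n",
              rng[1], rng[2],
              nrow(object$F) / object$sampling_rate_hz / 60))
  print(object)
  invisible(object)
}

#' @export
print.dff_set <- function(x, ...) {
  cat(sprintf("<dff_set> %d frames x %d ROIs, thresholds = %g x baseline SD (%s mode)\n",
              nrow(x$dff), ncol(x$dff), x$sd_multiplier, x$sd_mode))
  cat(sprintf("  median threshold %.3g dF/F0 across %d ROI-windows\n",
              stats::median(x$windows$threshold), nrow(x$windows)))
  invisible(x)
}

#' Plot one ROI's dF/F0 trace with threshold and detected transients
#'
#' @param x a `dff_set`.
#' @param roi_id ROI to plot (default: first column).
#' @param events optional `transient_table` whose events for this ROI are
#'   shaded.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dff_set <- function(x, roi_id = colnames(x$dff)[1], events = NULL, ...) {
  t_s <- (seq_len(nrow(x$dff)) - 1) / x$sampling_rate_hz
  graphics::plot(t_s, x$dff[, roi_id], type = "l", xlab = "time (s)",
                 ylab = expression(Delta * F / F[0]), main = roi_id, ...)
  graphics::lines(t_s, x$threshold[, roi_id], lty = 2, col = "red")
  bounds <- which(diff(x$trial) != 0)
  graphics::abline(v = t_s[bounds], col = "grey80")
  if (!is.null(events)) {
    ev <- events[events$roi_id == roi_id, ]
    nft <- sum(x$trial == x$trial[1])
    for (i in seq_len(nrow(ev))) {
      off <- (ev$trial[i] - 1) * nft
      graphics::rect((off + ev$onset_frame[i]) / x$sampling_rate_hz,
                     graphics::par("usr")[3],
                     (off + ev$offset_frame[i] + 1) / x$sampling_rate_hz,
                     graphics::par("usr")[4],
                     col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
    }
  }
  invisible(x)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s%s vs %s (n = %d, %d)\n",
              if (nzchar(x$metric)) paste0(x$metric, ": ") else "",
              x$groups[1], x$groups[2], x$n[1], x$n[2]))
  cat(sprintf("  %s = %.4g +/- %.3g, %s = %.4g +/- %.3g\n",
              x$groups[1], x$means[1], x$sems[1],
              x$groups[2], x$means[2], x$sems[2]))
  cat(sprintf("  normality p = %.3g, %.3g -> %s: statistic = %s, p = %.4g %s\n",
              x$normality_p[1], x$normality_p[2], x$test_used,
              format(x$statistic, digits = 4), x$p_value,
              if (x$p_value <= x$alpha) "*" else "n.s."))
  invisible(x)
}

#' @export
print.spine_turnover <- function(x, ...) {
  cat(sprintf("<spine_turnover> %d -> %d spines: stable %.1f%%, eliminated %.1f%%, formed %.1f%%\n",
              x$n_session0, x$n_session1, 100 * x$stable_rate,
              100 * x$elimination_rate, 100 * x$formation_rate))
  invisible(x)
}

#' @export
print.trace_gen_config <- function(x, ...) {
  cat(sprintf("<trace_gen_config>%s %g Hz, %d x %g s trials, rate %.3g/min, p_long %.3g, bAP scale %g, noise sd %g\n",
              if (!is.null(x$regime)) paste0(" [", x$regime, "]") else "",
              x$sampling_rate_hz, x$n_trials, x$trial_length_s,
              x$event_rate_per_min, x$duration_dist$p_long, x$bap_scale,
              x$noise_sd))
  invisible(x)
}
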