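#' Normality-routed two-group comparison
#'
#' Mirrors the conventional routing used in imaging papers: each sample is
#' screened for normality with a Kolmogorov-Smirnov test; if both pass
#' (p > alpha) the groups are compared with a two-tailed Student's t test
#' (paired or unpaired), otherwise with the Mann-Whitney U test (unpaired)
#' or the Wilcoxon signed-rank test (paired). Means and standard errors are
#' always reported.
#'
#' Because the plain KS test against a normal distribution with parameters
#' estimated from the same sample is anticonservative, the default normality
#' screen is the Lilliefors-corrected KS test (`ks_mode = "lilliefors"`);
#' `ks_mode = "plain"` gives the uncorrected version for fidelity with
#' SPSS-style analyses. Zero-variance samples cannot be screened and are
#' routed nonparametric with a warning. Rank tests use mid-ranks for ties
#' with the normal approximation and continuity correction when exact
#' p-values are unavailable.
#'
#' @param a,b numeric samples (each n >= 3; equal length when paired).
#' @param paired paired design flag.
#' @param alpha significance level for both the normality screen and the
#'   reported decision.
#' @param ks_mode `"lilliefors"` (default) or `"plain"`.
#' @param metric label carried into the result.
#' @param group_labels length-2 character vector naming the groups.
#' @return object of class `comparison_result`: metric, group labels and
#'   sizes, per-group normality p, `test_used`, `statistic`, `p_value`,
#'   per-group `means` and `sems`, `effect` (mean difference, a - b, or mean
#'   paired difference) and `direction`.
#' @export
route_and_test <- function(a, b, paired = FALSE, alpha = 0.05,
                           ks_mode = c("lilliefors", "plain"),
                           metric = "", group_labels = c("a", "b")) {
  ks_mode <- match.arg(ks_mode)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) stopf("each sample needs n >= 3")
  if (paired && length(a) != length(b))
    stopf("paired samples must have equal length")

  norm_p <- function(x) {
    if (stats::sd(x) == 0) {
      warning("zero-variance sample; routing nonparametric", call. = FALSE)
      return(0)
    }
    if (ks_mode == "lilliefors") {
      if (length(x) < 4) return(0)          # lillie.test needs n >= 4
      nortest::lillie.test(x)$p.value
    } else {
      suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
    }
  }
  pa <- norm_p(a); pb <- norm_p(b)
  normal <- pa > alpha && pb > alpha

  if (paired && all(a - b == 0)) {
    # degenerate: no difference anywhere; every routed test is null
    warning("all paired differences are zero", call. = FALSE)
    ht <- list(statistic = NA_real_, p.value = 1)
    test_used <- if (normal) "paired t-test" else "Wilcoxon signed-rank"
  } else if (normal) {
    ht <- stats::t.test(a, b, paired = paired, var.equal = FALSE)
    test_used <- if (paired) "paired t-test" else "t-test"
  } else if (paired) {
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              correct = TRUE))
    test_used <- "Wilcoxon signed-rank"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
    test_used <- "Mann-Whitney"
  }
  effect <- if (paired) mean(a - b) else mean(a) - mean(b)
  structure(list(metric = metric, groups = group_labels,
                 n = c(length(a), length(b)), normality_p = c(pa, pb),
                 ks_mode = ks_mode, test_used = test_used, paired = paired,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 means = c(mean(a), mean(b)), sems = c(sem(a), sem(b)),
                 effect = effect,
                 direction = if (effect > 0) ">" else if (effect < 0) "<" else "=",
                 alpha = alpha),
            class = "comparison_result")
}

comparison_row <- function(cr) {
  data.frame(metric = cr$metric, group_a = cr$groups[1], group_b = cr$groups[2],
             n_a = cr$n[1], n_b = cr$n[2],
             normality_p_a = cr$normality_p[1], normality_p_b = cr$normality_p[2],
             test_used = cr$test_used, statistic = cr$statistic %||% NA_real_,
             p_value = cr$p_value,
             mean_a = cr$means[1], sem_a = cr$sems[1],
             mean_b = cr$means[2], sem_b = cr$sems[2],
             effect = cr$effect, direction = cr$direction,
             stringsAsFactors = FALSE)
}

#' Assemble tidy per-figure-panel tables from pipeline outputs
#'
#' Packages the pipeline's distributed outputs into a consistent report
#' bundle: per-event transient metrics and per-ROI activity summaries split
#' by group and behavioural state, dendrite fractions with
#' prolonged / large-amplitude transients per group, paired first-vs-third
#' spine-peak deltas by middle-transient duration class, spine size-change
#' group summaries, flattened comparison results, and a manifest recording
#' package version, configuration hash and seed. Every element is a plain
#' data.frame with a fixed schema, empty but schema-valid when the
#' corresponding input is absent.
#'
#' @param events `transient_table` with an additional `group` column (and
#'   optionally `state`), or `NULL`.
#' @param summaries [summarize_activity()] output with a `group` column, or
#'   `NULL`.
#' @param first_third [first_third_comparison()] output, or `NULL`.
#' @param size_changes [size_change()] output list, or `NULL`.
#' @param comparisons list of `comparison_result` objects, or `NULL`.
#' @param config,seed recorded in the manifest.
#' @return list of class `report_bundle`.
#' @export
figure_tables <- function(events = NULL, summaries = NULL, first_third = NULL,
                          size_changes = NULL, comparisons = NULL,
                          config = NULL, seed = NULL) {
  grp <- function(df) if ("group" %in% names(df)) df$group else "all"

  event_metrics <- if (!is.null(events) && nrow(events)) {
    data.frame(group = grp(events), roi_id = events$roi_id,
               trial = events$trial, duration_s = events$duration_s,
               peak_dff = events$peak_dff, integrated = events$integrated,
               prolonged = events$prolonged,
               large_amplitude = events$large_amplitude,
               stringsAsFactors = FALSE)
  } else data.frame(group = character(0), roi_id = character(0),
                    trial = integer(0), duration_s = numeric(0),
                    peak_dff = numeric(0), integrated = numeric(0),
                    prolonged = logical(0), large_amplitude = logical(0))

  fractions <- if (!is.null(events) && nrow(events)) {
    do.call(rbind, lapply(split(events, grp(events)), function(ev) {
      data.frame(group = grp(ev)[1],
                 n_dendrites = length(unique(ev$roi_id)),
                 frac_prolonged = dendrite_fraction_with(ev, "prolonged"),
                 frac_large_amplitude = dendrite_fraction_with(ev, "large_amplitude"),
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(group = character(0), n_dendrites = integer(0),
                    frac_prolonged = numeric(0),
                    frac_large_amplitude = numeric(0))

  ft_deltas <- if (!is.null(first_third) && nrow(first_third)) {
    data.frame(first_third[, c("spine_id", "dendrite_id", "trial", "primary",
                               "middle_duration_class")],
               delta_peak = first_third$peak_post - first_third$peak_pre,
               change_ratio = first_third$peak_post / first_third$peak_pre,
               stringsAsFactors = FALSE)
  } else data.frame(spine_id = character(0), dendrite_id = character(0),
                    trial = integer(0), primary = logical(0),
                    middle_duration_class = character(0),
                    delta_peak = numeric(0), change_ratio = numeric(0))

  size_groups <- if (!is.null(size_changes) && !is.null(size_changes$group_summary))
    size_changes$group_summary
  else data.frame(active = logical(0), duration_class = character(0),
                  n = integer(0), mean_change = numeric(0),
                  sem_change = numeric(0))

  comp_tab <- if (!is.null(comparisons) && length(comparisons))
    do.call(rbind, lapply(comparisons, comparison_row))
  else data.frame(metric = character(0), group_a = character(0),
                  group_b = character(0), n_a = integer(0), n_b = integer(0),
                  normality_p_a = numeric(0), normality_p_b = numeric(0),
                  test_used = character(0), statistic = numeric(0),
                  p_value = numeric(0), mean_a = numeric(0), sem_a = numeric(0),
                  mean_b = numeric(0), sem_b = numeric(0), effect = numeric(0),
                  direction = character(0))

  structure(list(
    event_metrics = event_metrics,
    roi_summaries = summaries %||% data.frame(),
    dendrite_fractions = fractions,
    first_third_deltas = ft_deltas,
    size_change_groups = size_groups,
    comparisons = comp_tab,
    manifest = list(package = "dendrocalc",
                    version = as.character(utils::packageVersion("dendrocalc")),
                    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    config_md5 = if (is.null(config)) "none" else config_hash(config),
                    seed = seed)),
    class = "report_bundle")
}

#' Distribution plots for a report bundle
#'
#' Draws box plots of per-event duration, peak and integrated activity by
#' group, and a bar chart of the dendrite fractions -- the basic
#' distribution graphics that accompany the tables.
#'
#' @param x a [figure_tables()] result with a non-empty `event_metrics`.
#' @param ... unused.
#' @export
plot.report_bundle <- function(x, ...) {
  em <- x$event_metrics
  if (!nrow(em)) {
    warning("empty report bundle; nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::boxplot(duration_s ~ group, em, main = "event duration",
                    ylab = "s", xlab = "")
  graphics::boxplot(peak_dff ~ group, em, main = "peak",
                    ylab = expression(Delta * F / F[0]), xlab = "")
  graphics::boxplot(integrated ~ group, em, main = "integrated activity",
                    ylab = expression(Delta * F / F[0] %.% s), xlab = "")
  fr <- x$dendrite_fractions
  if (nrow(fr)) {
    graphics::barplot(rbind(fr$frac_prolonged, fr$frac_large_amplitude),
                      beside = TRUE, names.arg = fr$group,
                      legend.text = c("prolonged > 8 s", "peak > 400%"),
                      ylab = "fraction of dendrites", ylim = c(0, 1))
  }
  invisible(x)
}

#' Write a report bundle to a directory (CSVs + manifest JSON)
#' @param bundle a [figure_tables()] result.
#' @param dir output directory, created if needed.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in setdiff(names(bundle), "manifest"))
    utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
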