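#' Spine-head size as a background-corrected intensity ratio
#'
#' Spine-head size is scored on the structural (red, tdTomato-like) channel
#' as the ratio of background-corrected mean brightness ("Mean OD") of the
#' spine head to that of the adjacent dendritic shaft:
#' `size_ratio = (OD_spine - OD_background) / (OD_dendrite - OD_background)`.
#' The published form of the formula multiplies every Mean OD by the spine
#' area in pixels; the area factor cancels algebraically, so the reduced
#' form is computed. [spine_size_ratio_full()] keeps the literal
#' area-carrying expression for verification.
#'
#' @param od_spine,od_dendrite,od_background mean pixel brightness of the
#'   spine-head, adjacent-shaft and background ROIs (arbitrary units).
#' @return the dimensionless size ratio.
#' @export
spine_size_ratio <- function(od_spine, od_dendrite, od_background) {
  if (any(od_dendrite <= od_background))
    stopf("dendrite Mean OD must exceed background Mean OD (bad ROI placement?)")
  (od_spine - od_background) / (od_dendrite - od_background)
}

#' @rdname spine_size_ratio
#' @param area_px spine-head ROI area in pixels (>= 1); cancels from the
#'   result.
#' @export
spine_size_ratio_full <- function(area_px, od_spine, od_dendrite,
                                  od_background) {
  if (any(area_px < 1)) stopf("area_px must be >= 1")
  if (any(od_dendrite <= od_background))
    stopf("dendrite Mean OD must exceed background Mean OD (bad ROI placement?)")
  (area_px * od_spine - area_px * od_background) /
    (area_px * od_dendrite - area_px * od_background)
}

#' Measure spine-head size on a structural-channel image
#'
#' @param image numeric matrix, structural channel.
#' @param spine_roi,shaft_roi,background_roi logical masks or [roi_def()]
#'   geometries for the oval spine head, the adjacent shaft sample and a
#'   nearby background patch. Masks must be pairwise disjoint.
#' @param spine_id identifier carried into the output.
#' @param session session label (e.g. `"0h"`, `"1.5h"`).
#' @return one-row data.frame: `spine_id`, `session`, `area_px`,
#'   `mean_od_spine`, `mean_od_dendrite`, `mean_od_background`, `size_ratio`.
#' @export
measure_spine_size <- function(image, spine_roi, shaft_roi, background_roi,
                               spine_id = "spine", session = "0h") {
  as_mask <- function(m) if (is.logical(m)) m else rasterize_roi(m, dim(image))
  sp <- as_mask(spine_roi); sh <- as_mask(shaft_roi); bg <- as_mask(background_roi)
  if (any(sp & sh) || any(sp & bg) || any(sh & bg))
    stopf("measurement ROIs must be disjoint")
  ods <- mean(image[sp]); odd <- mean(image[sh]); odb <- mean(image[bg])
  data.frame(spine_id = spine_id, session = session, area_px = sum(sp),
             mean_od_spine = ods, mean_od_dendrite = odd,
             mean_od_background = odb,
             size_ratio = spine_size_ratio(ods, odd, odb),
             stringsAsFactors = FALSE)
}

#' Spine size change between two imaging sessions
#'
#' Joins per-spine measurements from two sessions on `spine_id` and reports
#' `size_change = ratio_session1 / ratio_session0` for spines present in
#' both. Unmatched spines are dropped here (they are the business of
#' [turnover()]). An optional grouping table (`spine_id`, `active`,
#' `duration_class`) attaches the activity call and the parent dendrite's
#' transient-duration class, and a per-group summary (n, mean, sem) is
#' returned alongside.
#'
#' @param meas0,meas1 measurement tables from [measure_spine_size()] at the
#'   first and second session.
#' @param groups optional data.frame `spine_id`, `active` (logical),
#'   `duration_class` (e.g. `"<8 s"` / `">8 s"`).
#' @return list with `changes` (per spine) and `group_summary` (or `NULL`).
#' @export
size_change <- function(meas0, meas1, groups = NULL) {
  m <- merge(meas0[, c("spine_id", "size_ratio")],
             meas1[, c("spine_id", "size_ratio")],
             by = "spine_id", suffixes = c("_0", "_1"))
  changes <- data.frame(spine_id = m$spine_id,
                        ratio_0 = m$size_ratio_0, ratio_1 = m$size_ratio_1,
                        size_change = m$size_ratio_1 / m$size_ratio_0,
                        stringsAsFactors = FALSE)
  summary <- NULL
  if (!is.null(groups)) {
    changes <- merge(changes, groups, by = "spine_id")
    agg <- split(changes$size_change,
                 list(active = changes$active,
                      duration_class = changes$duration_class), drop = TRUE)
    summary <- do.call(rbind, lapply(names(agg), function(k) {
      v <- agg[[k]]
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      data.frame(active = as.logical(parts[1]), duration_class = parts[2],
                 n = length(v), mean_change = mean(v), sem_change = sem(v),
                 stringsAsFactors = FALSE)
    }))
  }
  list(changes = changes, group_summary = summary)
}

#' Call spine presence from a structural measurement
#'
#' A spine counts as present when its structural size ratio reaches
#' `cutoff` (default 0.2) -- a spine head indistinguishable from background
#' scores near 0, one as bright as the shaft scores near 1.
#'
#' @param measurements a [measure_spine_size()] table.
#' @param cutoff minimum size ratio counted as present.
#' @return data.frame `spine_id`, `present`.
#' @export
spine_presence <- function(measurements, cutoff = 0.2) {
  data.frame(spine_id = measurements$spine_id,
             present = measurements$size_ratio >= cutoff,
             stringsAsFactors = FALSE)
}

#' Spine turnover between two sessions
#'
#' Stable and eliminated rates are relative to the session-0 spine count
#' (and sum to 1 over session-0 spines); the formation rate is the number of
#' new session-1 spines, also expressed relative to the session-0 count.
#'
#' @param present0,present1 character vectors of spine ids present at each
#'   session, or presence data.frames from [spine_presence()].
#' @return object of class `spine_turnover`: list with `stable_rate`,
#'   `formation_rate`, `elimination_rate`, counts and a per-spine `fates`
#'   table (`stable` / `eliminated` / `formed`).
#' @export
turnover <- function(present0, present1) {
  as_ids <- function(x) if (is.data.frame(x)) x$spine_id[x$present] else x
  ids0 <- unique(as_ids(present0)); ids1 <- unique(as_ids(present1))
  if (!length(ids0)) stopf("no spines present at session 0")
  stable <- intersect(ids0, ids1)
  eliminated <- setdiff(ids0, ids1)
  formed <- setdiff(ids1, ids0)
  fates <- data.frame(
    spine_id = c(stable, eliminated, formed),
    fate = rep(c("stable", "eliminated", "formed"),
               c(length(stable), length(eliminated), length(formed))),
    stringsAsFactors = FALSE)
  structure(list(stable_rate = length(stable) / length(ids0),
                 elimination_rate = length(eliminated) / length(ids0),
                 formation_rate = length(formed) / length(ids0),
                 n_session0 = length(ids0), n_session1 = length(ids1),
                 fates = fates),
            class = "spine_turnover")
}

#' Write a turnover result to JSON
#' @param tv a [turnover()] result.
#' @param path output file.
#' @export
write_turnover_json <- function(tv, path) {
  jsonlite::write_json(unclass(tv), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
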