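#' Construct a raw fluorescence trace set
#'
#' Container for per-ROI raw mean-fluorescence time series plus the session
#' metadata every downstream stage needs: sampling rate, contiguous trial
#' blocks with their behavioural state, and the per-frame vessel-background
#' series used for background subtraction.
#'
#' @param F numeric matrix, frames x ROIs, column names = ROI ids.
#' @param rois data.frame with columns `roi_id`, `role` (one of `soma`,
#'   `dendrite`, `spine`, `background_vessel`), `parent_id` (dendrite id for
#'   spines, `""` otherwise).
#' @param sampling_rate_hz frames per second.
#' @param trial integer vector, one trial index per frame; blocks must be
#'   contiguous.
#' @param states character vector, one of `"running"`/`"resting"` per trial.
#' @param background numeric scalar or per-frame vector of vessel background
#'   fluorescence, or `NULL` when unknown.
#' @return an object of class `trace_set`.
#' @export
trace_set <- function(F, rois, sampling_rate_hz, trial, states,
                      background = NULL) {
  F <- as.matrix(F)
  if (!all(is.finite(F))) stopf("all fluorescence values must be finite")
  if (nrow(rois) != ncol(F)) stopf("rois rows must match F columns")
  if (anyDuplicated(rois$roi_id)) stopf("roi_id values must be unique")
  colnames(F) <- rois$roi_id
  trial <- as.integer(trial)
  if (length(trial) != nrow(F)) stopf("trial must have one entry per frame")
  if (any(diff(trial) < 0)) stopf("trial blocks must be contiguous and ordered")
  if (length(states) != length(unique(trial)))
    stopf("states must have one entry per trial")
  sp <- rois$parent_id[rois$role == "spine"]
  if (length(sp) && !all(sp %in% rois$roi_id[rois$role == "dendrite"]))
    stopf("every spine must reference an existing dendrite parent")
  if (!is.null(background)) {
    if (length(background) == 1) background <- rep(background, nrow(F))
    if (length(background) != nrow(F))
      stopf("background must be scalar or per-frame")
  }
  structure(list(F = F, rois = rois, sampling_rate_hz = sampling_rate_hz,
                 trial = trial, states = as.character(states),
                 background = background),
            class = "trace_set")
}

#' Define a region of interest
#'
#' @param roi_id unique identifier.
#' @param role `soma`, `dendrite`, `spine` or `background_vessel`.
#' @param geometry list describing pixel support, one of:
#'   `list(type = "mask", mask = <logical matrix>)`,
#'   `list(type = "rect", x0=, y0=, w=, h=)`,
#'   `list(type = "ellipse", cx=, cy=, rx=, ry=)`,
#'   `list(type = "polygon", x = <vec>, y = <vec>)`.
#'   Coordinates are 0-based; `x` is the column, `y` the row; a pixel belongs
#'   to a region iff its centre does (centre-of-pixel inclusion).
#' @param parent_id parent dendrite id (spines only).
#' @param channel image channel the ROI is measured on (1-based).
#' @export
roi_def <- function(roi_id, role, geometry, parent_id = "", channel = 1L) {
  role <- match.arg(role, c("soma", "dendrite", "spine", "background_vessel"))
  structure(list(roi_id = roi_id, role = role, geometry = geometry,
                 parent_id = parent_id, channel = as.integer(channel)),
            class = "roi_def")
}

# even-odd ray-casting point-in-polygon on pixel centres
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Rasterize an ROI geometry to a logical pixel mask
#'
#' @param geometry geometry list as in [roi_def()].
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return logical matrix of the given dimensions.
#' @export
rasterize_roi <- function(geometry, dim) {
  nr <- dim[1]; nc <- dim[2]
  g <- geometry
  mask <- switch(g$type,
    mask = {
      m <- g$mask
      if (is.list(m)) m <- do.call(cbind, m)   # from JSON round-trip
      storage.mode(m) <- "logical"
      m
    },
    rect = {
      col0 <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
      row0 <- matrix(rep(0:(nr - 1), times = nc), nr, nc)
      col0 >= g$x0 & col0 < g$x0 + g$w & row0 >= g$y0 & row0 < g$y0 + g$h
    },
    ellipse = {
      col0 <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
      row0 <- matrix(rep(0:(nr - 1), times = nc), nr, nc)
      ((col0 - g$cx) / g$rx)^2 + ((row0 - g$cy) / g$ry)^2 <= 1
    },
    polygon = {
      col0 <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
      row0 <- matrix(rep(0:(nr - 1), times = nc), nr, nc)
      matrix(points_in_polygon(as.vector(col0), as.vector(row0),
                               g$x, g$y), nr, nc)
    },
    stopf("unknown geometry type '%s'", g$type))
  if (!identical(dim(mask), as.integer(dim)))
    stopf("ROI mask dimensions do not match image")
  if (!any(mask)) stopf("ROI rasterizes to an empty mask")
  mask
}

#' Extract per-ROI mean-fluorescence traces from an image stack
#'
#' Each trace value is the mean pixel intensity inside the ROI on its channel.
#' The vessel-background series is the per-frame mean over all
#' `background_vessel` ROIs (on their channels) and is stored in the returned
#' [trace_set()] for later [subtract_background()]. Frames containing pixels
#' at or above `sat_level` inside an ROI are flagged in the `saturated`
#' attribute, not dropped.
#'
#' @param stack numeric array `nrow x ncol x nframes` (single channel) or a
#'   list of such arrays, one per channel.
#' @param rois list of [roi_def()] objects.
#' @param sampling_rate_hz frames per second.
#' @param trial per-frame trial index (default: a single trial).
#' @param states per-trial behavioural state (default `"running"`).
#' @param sat_level saturation threshold in raw intensity units.
#' @return a [trace_set()]; background ROIs are retained as columns.
#' @export
extract_traces <- function(stack, rois, sampling_rate_hz = 2, trial = NULL,
                           states = NULL, sat_level = Inf) {
  channels <- if (is.list(stack)) stack else list(stack)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3))
    stopf("stack must be nrow x ncol x nframes")
  nframes <- dims[[1]][3]
  ids <- vapply(rois, function(r) r$roi_id, "")
  if (anyDuplicated(ids)) stopf("roi_id values must be unique")

  Fmat <- matrix(NA_real_, nframes, length(rois), dimnames = list(NULL, ids))
  satm <- matrix(FALSE, nframes, length(rois), dimnames = list(NULL, ids))
  for (j in seq_along(rois)) {
    r <- rois[[j]]
    if (r$channel > length(channels)) stopf("ROI '%s' references a missing channel", r$roi_id)
    ch <- channels[[r$channel]]
    mask <- rasterize_roi(r$geometry, dim(ch)[1:2])
    idx <- which(mask)
    flat <- matrix(ch, prod(dim(ch)[1:2]), nframes)
    px <- flat[idx, , drop = FALSE]
    Fmat[, j] <- colMeans(px)
    if (is.finite(sat_level)) satm[, j] <- apply(px >= sat_level, 2, any)
  }
  roi_tab <- data.frame(
    roi_id = ids,
    role = vapply(rois, function(r) r$role, ""),
    parent_id = vapply(rois, function(r) r$parent_id, ""),
    stringsAsFactors = FALSE)
  bg_cols <- roi_tab$role == "background_vessel"
  background <- if (any(bg_cols))
    rowMeans(Fmat[, bg_cols, drop = FALSE]) else NULL
  trial <- trial %||% rep(1L, nframes)
  states <- states %||% rep("running", length(unique(trial)))
  ts <- trace_set(Fmat, roi_tab, sampling_rate_hz, trial, states, background)
  attr(ts, "saturated") <- satm
  ts
}

#' Subtract the vessel background from every trace
#'
#' Subtracts the per-frame background series from every ROI column and zeroes
#' the background field. Negative values are permitted and preserved.
#'
#' @param ts a [trace_set()] with a defined background.
#' @return the background-subtracted `trace_set`.
#' @export
subtract_background <- function(ts) {
  stopifnot(inherits(ts, "trace_set"))
  if (is.null(ts$background))
    stopf("background subtraction requested but no background is defined")
  ts$F <- ts$F - ts$background
  ts$background <- rep(0, nrow(ts$F))
  ts
}

# ---- plain-text I/O ---------------------------------------------------------

provenance_header <- function(config = NULL) {
  c(sprintf("# dendrocalc %s  %s",
            as.character(utils::packageVersion("dendrocalc")),
            format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("# config_md5: %s", if (is.null(config)) "none" else config_hash(config)))
}

#' Write a trace set to CSV
#'
#' Long format, columns `trial`, `frame` (0-based), `roi_id`, `F`,
#' `background`, preceded by `#` comment lines carrying provenance (package
#' version, config hash) and the session metadata as a one-line JSON header so
#' the file round-trips losslessly through [read_trace_csv()].
#'
#' @param ts a [trace_set()].
#' @param path output file.
#' @param config optional configuration object hashed into the header.
#' @export
write_trace_csv <- function(ts, path, config = NULL) {
  stopifnot(inherits(ts, "trace_set"))
  meta <- list(sampling_rate_hz = ts$sampling_rate_hz, states = ts$states,
               rois = ts$rois)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  writeLines(sprintf("# meta: %s", jsonlite::toJSON(meta, digits = NA)), con)
  nfr <- nrow(ts$F)
  df <- data.frame(trial = rep(ts$trial, times = ncol(ts$F)),
                   frame = rep(0:(nfr - 1), times = ncol(ts$F)),
                   roi_id = rep(colnames(ts$F), each = nfr),
                   F = as.vector(ts$F),
                   background = rep(ts$background %||% rep(NA_real_, nfr),
                                    times = ncol(ts$F)))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a trace set written by [write_trace_csv()]
#' @param path CSV file path.
#' @return a [trace_set()].
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  meta_line <- grep("^# meta: ", hdr, value = TRUE)
  if (!length(meta_line)) stopf("not a dendrocalc trace CSV (no meta header)")
  meta <- jsonlite::fromJSON(sub("^# meta: ", "", meta_line[1]))
  df <- utils::read.csv(path, comment.char = "#")
  ids <- meta$rois$roi_id
  nfr <- max(df$frame) + 1L
  Fmat <- matrix(NA_real_, nfr, length(ids), dimnames = list(NULL, ids))
  for (id in ids) {
    sub <- df[df$roi_id == id, ]
    Fmat[sub$frame + 1L, id] <- sub$F
  }
  first <- df[df$roi_id == ids[1], ]
  bg <- if (all(is.na(first$background))) NULL else first$background
  trace_set(Fmat, as.data.frame(meta$rois), meta$sampling_rate_hz,
            first$trial, meta$states, bg)
}

#' Write / read ROI definitions as JSON
#'
#' @param rois list of [roi_def()] objects.
#' @param path file path.
#' @param config optional configuration hashed into the provenance field.
#' @export
write_rois_json <- function(rois, path, config = NULL) {
  payload <- list(
    provenance = list(package = "dendrocalc",
                      version = as.character(utils::packageVersion("dendrocalc")),
                      config_md5 = if (is.null(config)) "none" else config_hash(config)),
    rois = lapply(rois, unclass))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois_json
#' @export
read_rois_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(payload$rois, function(r) {
    g <- r$geometry
    if (g$type == "mask") {
      rows <- g$mask   # serialized row-wise
      g$mask <- matrix(as.logical(unlist(rows)), nrow = length(rows),
                       byrow = TRUE)
    } else {
      for (k in setdiff(names(g), "type")) g[[k]] <- unlist(g[[k]])
    }
    roi_def(r$roi_id, r$role, g, r$parent_id %||% "", r$channel %||% 1L)
  })
}

#' Write / read ground-truth event tables as JSON
#' @param events ground-truth event data.frame from [generate_trace_set()].
#' @param path file path.
#' @param config optional configuration hashed into the provenance field.
#' @export
write_ground_truth_json <- function(events, path, config = NULL) {
  jsonlite::write_json(list(
    provenance = list(package = "dendrocalc",
                      config_md5 = if (is.null(config)) "none" else config_hash(config)),
    events = events), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  jsonlite::fromJSON(path)$events
}

#' Write / read a multi-page TIFF image stack
#'
#' Pages are stored 16-bit, scaled by `scale`; a two-channel image pair is
#' written as two pages per frame (channel-major).
#'
#' @param images list of numeric matrices (pages).
#' @param path file path.
#' @param scale intensity corresponding to the 16-bit full scale.
#' @export
write_image_tiff <- function(images, path, scale = 4096) {
  if (!is.list(images)) images <- list(images)
  pages <- lapply(images, function(m) pmin(pmax(m / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, scale = 4096) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(m) m * scale)
}
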