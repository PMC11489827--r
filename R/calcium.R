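#' Fluorescence trace set
#'
#' Container for somatic fluorescence time series: a cells x frames matrix
#' of raw fluorescence, the shared frame timestamps, an optional
#' missing-value mask (frames with residual z-drift etc.), and - once
#' [compute_dff()] has run - the oversmoothed baseline `F0` and the
#' relative change `dff = (F - F0)/F0`.
#'
#' @param F numeric matrix, cells x frames, arbitrary units
#' @param frame_times numeric vector of frame times in seconds
#' @param missing_mask logical vector per frame; `TRUE` marks frames to be
#'   excluded from all downstream counts and durations
#' @param F0,dff optional baseline and dF/F0 matrices of the same shape
#' @return object of class `fluorescence_traces`
#' @export
fluorescence_traces <- function(F, frame_times, missing_mask = NULL,
                                F0 = NULL, dff = NULL) {
  F <- as.matrix(F)
  stopifnot(ncol(F) == length(frame_times),
            !is.unsorted(frame_times, strictly = TRUE))
  if (is.null(missing_mask)) missing_mask <- rep(FALSE, ncol(F))
  stopifnot(length(missing_mask) == ncol(F))
  structure(list(F = F, frame_times = as.numeric(frame_times),
                 missing_mask = as.logical(missing_mask), F0 = F0, dff = dff),
            class = "fluorescence_traces")
}

#' @export
print.fluorescence_traces <- function(x, ...) {
  cat(sprintf("<fluorescence_traces: %d cells x %d frames, %.1f s, %d masked%s>\n",
              nrow(x$F), ncol(x$F), diff(range(x$frame_times)),
              sum(x$missing_mask),
              if (is.null(x$dff)) ", dF/F0 not computed" else ""))
  invisible(x)
}

# Duration covered by unmasked frames, in seconds.
analyzed_duration <- function(frame_times, missing_mask) {
  dt <- median(diff(frame_times))
  sum(!missing_mask) * dt
}

#' Compute dF/F0 with a Savitzky-Golay oversmoothed baseline
#'
#' The baseline `F0(t)` is obtained by oversmoothing each cell's raw
#' fluorescence with a second-order Savitzky-Golay filter whose window is
#' far longer than any transient (default 1,500 frames, adjusted down to
#' the nearest odd integer), so that transients are averaged away while
#' slow drifts of indicator brightness are tracked. The relative change
#' `dff = (F - F0)/F0` is then computed elementwise; masked frames are
#' linearly interpolated before smoothing and propagate to `dff` as `NA`.
#'
#' @param x a [fluorescence_traces()] object, or a numeric matrix
#'   (cells x frames) together with `frame_times`
#' @param frame_times frame times in seconds (ignored when `x` is a
#'   `fluorescence_traces`)
#' @param window_frames Savitzky-Golay window length in frames; even values
#'   are reduced by one
#' @param polyorder polynomial order of the filter (default 2)
#' @return the input `fluorescence_traces` with `F0` and `dff` filled in
#' @export
compute_dff <- function(x, frame_times = NULL, window_frames = 1500,
                        polyorder = 2) {
  if (!inherits(x, "fluorescence_traces")) {
    x <- fluorescence_traces(x, frame_times)
  }
  n <- ncol(x$F)
  win <- as.integer(window_frames)
  if (win %% 2L == 0L) win <- win - 1L
  if (n <= win) {
    stop(sprintf(paste("trace length (%d frames) must exceed the baseline",
                       "window (%d frames); pass a smaller `window_frames`",
                       "explicitly for short recordings"), n, win),
         call. = FALSE)
  }
  mask <- x$missing_mask
  F0 <- t(apply(x$F, 1L, function(f) {
    if (any(mask)) {
      f[mask] <- approx(which(!mask), f[!mask], xout = which(mask),
                        rule = 2)$y
    }
    signal::sgolayfilt(f, p = polyorder, n = win)
  }))
  if (any(F0 <= 0)) {
    warning("non-positive baseline F0 encountered; dF/F0 undefined there")
  }
  dff <- (x$F - F0) / F0
  dff[, mask] <- NA_real_
  x$F0 <- F0
  x$dff <- dff
  x
}

#' Calcium-transient raster
#'
#' Per-cell sorted onset times of detected somatic Ca2+ transients, plus
#' the mask-corrected duration over which detection was possible.
#'
#' @param onsets list of numeric vectors (seconds), one per cell
#' @param analyzed_duration unmasked recording duration in seconds
#' @return object of class `cat_raster`
#' @export
cat_raster <- function(onsets, analyzed_duration) {
  onsets <- lapply(onsets, function(o) sort(as.numeric(o)))
  stopifnot(analyzed_duration >= 0)
  structure(list(onsets = onsets, n_cells = length(onsets),
                 analyzed_duration = analyzed_duration),
            class = "cat_raster")
}

#' @export
print.cat_raster <- function(x, ...) {
  cat(sprintf("<cat_raster: %d cells, %d onsets in %.1f s analyzed>\n",
              x$n_cells, sum(lengths(x$onsets)), x$analyzed_duration))
  invisible(x)
}

# Robust noise SD of a dF/F trace from the MAD of its first difference.
robust_noise_sd <- function(v) {
  d <- diff(v[is.finite(v)])
  if (!length(d)) return(NA_real_)
  mad(d) / sqrt(2)
}

#' Detect calcium-transient onsets from dF/F0 traces
#'
#' Threshold detector: each cell's dF/F0 trace is lightly smoothed
#' (second-order Savitzky-Golay, `smooth_window` frames) and a transient
#' onset is the first frame of each suprathreshold excursion, with the
#' threshold set per cell to the larger of `threshold_sd` robust noise
#' SDs (MAD of the first difference divided by sqrt(2), measured on the
#' smoothed trace) and an absolute floor `min_amplitude_dff`. An
#' excursion ends only once the trace has fallen below
#' `release_frac * threshold` (hysteresis), so a noisy decay is not split
#' into spurious re-triggers. Onsets closer than `refractory_s` are
#' merged into the earlier event. Masked frames terminate excursions and
#' are excluded from the analyzed duration.
#'
#' @param x a [fluorescence_traces()] with `dff` computed, or a dF/F0
#'   matrix plus `frame_times`
#' @param frame_times frame times in seconds (matrix input only)
#' @param threshold_sd threshold in robust noise SDs (default 5)
#' @param min_amplitude_dff absolute dF/F floor for the threshold
#' @param refractory_s minimum separation of onsets in seconds
#' @param smooth_window Savitzky-Golay pre-smoothing window (frames,
#'   default 5; 1 disables smoothing)
#' @param release_frac hysteresis release level as a fraction of the
#'   threshold (default 0.5)
#' @return a [cat_raster()]
#' @export
detect_cats <- function(x, frame_times = NULL, threshold_sd = 5,
                        min_amplitude_dff = 0.05, refractory_s = 0.5,
                        smooth_window = 5, release_frac = 0.5) {
  if (inherits(x, "fluorescence_traces")) {
    if (is.null(x$dff)) stop("run compute_dff() first")
    dff <- x$dff; times <- x$frame_times; mask <- x$missing_mask
  } else {
    dff <- as.matrix(x); times <- frame_times
    mask <- rep(FALSE, ncol(dff))
  }
  dur <- analyzed_duration(times, mask)
  onsets <- apply(dff, 1L, function(v) {
    ok <- is.finite(v) & !mask
    if (!any(ok)) return(numeric(0))
    # noise SD from the raw trace: the first-difference MAD is only a
    # consistent estimator on (near-)white noise, not after smoothing
    thr <- max(threshold_sd * robust_noise_sd(v[ok]), min_amplitude_dff)
    if (any(!ok)) { # interpolate gaps so the smoother stays defined
      v[!ok] <- approx(which(ok), v[ok], xout = which(!ok), rule = 2)$y
    }
    if (smooth_window > 1) {
      w <- smooth_window + (1 - smooth_window %% 2)
      v <- signal::sgolayfilt(v, p = 2, n = w)
    }
    v[!ok] <- -Inf # masked frames break excursions and cannot trigger
    on <- numeric(0)
    armed <- TRUE
    for (i in seq_along(v)) {
      if (armed && v[i] >= thr) {
        on <- c(on, times[i]); armed <- FALSE
      } else if (!armed && v[i] < release_frac * thr) {
        armed <- TRUE
      }
    }
    keep <- c(TRUE, diff(on) >= refractory_s)
    # merge any chain of onsets closer than the refractory period
    while (any(!keep)) {
      on <- on[keep]
      keep <- c(TRUE, diff(on) >= refractory_s)
    }
    on
  }, simplify = FALSE)
  cat_raster(onsets, dur)
}

# Number of distinct cells with >=1 onset inside [t0, t0 + window]
# (closed interval), vectorized over candidate window starts t0.
count_active_cells <- function(onsets, t0, window) {
  counts <- integer(length(t0))
  for (o in onsets) {
    if (!length(o)) next
    # onset o_i is inside [t0, t0+w]  <=>  t0 in [o_i - w, o_i]
    n_before <- findInterval(t0 + window, o)   # onsets <= t0 + w
    n_lt <- findInterval(t0, o, left.open = TRUE) # onsets < t0
    counts <- counts + as.integer(n_before - n_lt >= 1L)
  }
  counts
}

#' Detect network events (GDPs) from a calcium-transient raster
#'
#' Implements the two-rule definition of a giant depolarizing potential:
#' (1) a transient is network-related if it falls inside some interval of
#' length `window_s` during which at least `fraction` of all recorded
#' cells are active (have >= 1 onset inside the interval); (2) two
#' network-related transients belong to the same event if they share such
#' a qualifying interval. Rule (2) is applied transitively and events
#' whose spans still overlap afterwards are merged. The candidate window
#' search is exact: the active-cell count only changes at onset times, so
#' evaluating all windows starting at an onset or ending at an onset is
#' equivalent to the exhaustive continuous search.
#'
#' @param raster a [cat_raster()]
#' @param window_s interval length in seconds (default 0.5)
#' @param fraction minimum fraction of all cells active (default 0.20,
#'   attained inclusively)
#' @return data.frame with one row per event: `start`, `end` (seconds,
#'   first to last member onset), `n_members`, `member_cells`
#'   (comma-separated ids), `peak_participation`
#' @export
detect_gdps <- function(raster, window_s = 0.5, fraction = 0.20) {
  stopifnot(inherits(raster, "cat_raster"), raster$n_cells >= 1)
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_members = integer(0), member_cells = character(0),
                      peak_participation = numeric(0))
  ev <- data.frame(
    cell = rep(seq_along(raster$onsets), lengths(raster$onsets)),
    t = unlist(raster$onsets, use.names = FALSE)
  )
  if (!nrow(ev)) return(empty)
  ev <- ev[order(ev$t), , drop = FALSE]
  need <- fraction * raster$n_cells
  w <- window_s
  # candidate window starts: every onset and every onset minus the window
  cand <- sort(unique(c(ev$t, ev$t - w)))
  counts <- count_active_cells(raster$onsets, cand, w)
  qualifying <- counts >= need
  # rule (1): onset o is network-related iff some qualifying window start
  # lies in [o - w, o]
  related <- vapply(ev$t, function(o) {
    idx <- which(cand >= o - w & cand <= o)
    any(qualifying[idx])
  }, logical(1))
  if (!any(related)) return(empty)
  rel <- ev[related, , drop = FALSE]
  # rule (2): union-find over pairs sharing a qualifying window
  parent <- seq_len(nrow(rel))
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(rel) - 1L)) {
    for (j in (i + 1L):nrow(rel)) {
      if (rel$t[j] - rel$t[i] > w) break
      idx <- which(cand >= rel$t[j] - w & cand <= rel$t[i])
      if (length(idx) && any(qualifying[idx])) {
        parent[find_root(j)] <- find_root(i)
      }
    }
  }
  group <- vapply(seq_len(nrow(rel)), find_root, integer(1))
  out <- do.call(rbind, lapply(split(seq_len(nrow(rel)), group), function(ii) {
    span <- range(rel$t[ii])
    idx <- which(cand >= span[1] - w & cand <= span[2])
    data.frame(start = span[1], end = span[2],
               n_members = length(unique(rel$cell[ii])),
               member_cells = paste(sort(unique(rel$cell[ii])),
                                    collapse = ","),
               peak_participation = max(counts[idx]) / raster$n_cells)
  }))
  out <- out[order(out$start), , drop = FALSE]
  merge_overlapping_events(out)
}

# Merge events whose [start, end] spans overlap (closed intervals).
merge_overlapping_events <- function(ev) {
  if (nrow(ev) <= 1L) { rownames(ev) <- NULL; return(ev) }
  merged <- ev[1, , drop = FALSE]
  for (i in 2:nrow(ev)) {
    last <- nrow(merged)
    if (ev$start[i] <= merged$end[last]) {
      merged$end[last] <- max(merged$end[last], ev$end[i])
      cells <- sort(unique(as.integer(c(
        strsplit(merged$member_cells[last], ",")[[1]],
        strsplit(ev$member_cells[i], ",")[[1]]))))
      merged$member_cells[last] <- paste(cells, collapse = ",")
      merged$n_members[last] <- length(cells)
      merged$peak_participation[last] <-
        max(merged$peak_participation[last], ev$peak_participation[i])
    } else {
      merged <- rbind(merged, ev[i, , drop = FALSE])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Calcium-transient frequency per cell and mean
#'
#' Onset counts divided by the mask-corrected analyzed duration, scaled to
#' events per minute.
#'
#' @param raster a [cat_raster()]
#' @return list with `per_cell` (min^-1, one entry per cell) and `mean`
#' @export
cat_frequency <- function(raster) {
  stopifnot(inherits(raster, "cat_raster"))
  if (raster$analyzed_duration <= 0) stop("analyzed duration is zero")
  per_cell <- lengths(raster$onsets) / raster$analyzed_duration * 60
  list(per_cell = per_cell, mean = mean(per_cell))
}

#' Network-event (GDP) frequency
#'
#' @param gdps data.frame from [detect_gdps()]
#' @param analyzed_duration mask-corrected duration in seconds
#' @return events per minute
#' @export
gdp_frequency <- function(gdps, analyzed_duration) {
  if (analyzed_duration <= 0) stop("analyzed duration is zero")
  nrow(gdps) / analyzed_duration * 60
}
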