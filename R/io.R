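# Plain-text readers/writers for the package's containers. All tables are
# TSV with a header; time is seconds, intervals are half-open [start, end).

#' Read fluorescence traces from a wide CSV
#'
#' Expected columns: `frame_time_s`, then one column per cell
#' (`cell_0`, `cell_1`, ...). An optional mask TSV with columns
#' `start_s`, `end_s` marks frames to treat as missing.
#'
#' @param path CSV file
#' @param mask_path optional TSV of masked intervals
#' @return a [fluorescence_traces()]
#' @export
read_traces_csv <- function(path, mask_path = NULL) {
  d <- read.csv(path, check.names = FALSE)
  stopifnot("frame_time_s" %in% names(d))
  times <- d$frame_time_s
  F <- t(as.matrix(d[, setdiff(names(d), "frame_time_s"), drop = FALSE]))
  mask <- rep(FALSE, length(times))
  if (!is.null(mask_path)) {
    mv <- read.delim(mask_path)
    for (i in seq_len(nrow(mv))) {
      mask[times >= mv$start_s[i] & times < mv$end_s[i]] <- TRUE
    }
  }
  fluorescence_traces(F, times, mask)
}

#' Write fluorescence traces to a wide CSV
#' @param x a [fluorescence_traces()]
#' @param path output CSV file
#' @export
write_traces_csv <- function(x, path) {
  d <- data.frame(frame_time_s = x$frame_times, t(x$F))
  names(d) <- c("frame_time_s", paste0("cell_", seq_len(nrow(x$F)) - 1L))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a calcium-transient raster as TSV (columns `cell`, `onset_s`)
#' @param raster a [cat_raster()]
#' @param path output TSV file
#' @export
write_raster_tsv <- function(raster, path) {
  d <- data.frame(cell = rep(seq_len(raster$n_cells),
                             lengths(raster$onsets)),
                  onset_s = unlist(raster$onsets, use.names = FALSE))
  utils::write.table(d, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a calcium-transient raster from TSV
#' @param path TSV with columns `cell`, `onset_s`
#' @param n_cells total number of recorded cells (the raster may contain
#'   silent cells absent from the table)
#' @param analyzed_duration mask-corrected duration (s)
#' @return a [cat_raster()]
#' @export
read_raster_tsv <- function(path, n_cells, analyzed_duration) {
  d <- read.delim(path)
  onsets <- lapply(seq_len(n_cells), function(i) d$onset_s[d$cell == i])
  cat_raster(onsets, analyzed_duration)
}

#' Write a generic event table as TSV
#' @param events data.frame of events
#' @param path output TSV file
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read current-clamp sweeps from a long CSV plus a protocol sidecar
#'
#' The CSV has columns `sweep_id`, `t_s`, `Vm_mV`, `I_pA`; the JSON or
#' YAML sidecar provides `sampling_rate`, `protocol` and any protocol
#' metadata (test-pulse or step tables).
#'
#' @param path long CSV file
#' @param sidecar_path JSON/YAML protocol file
#' @return a [sweep_set()]
#' @export
read_sweeps_csv <- function(path, sidecar_path) {
  d <- read.csv(path)
  meta <- if (grepl("\\.json$", sidecar_path, ignore.case = TRUE)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else yaml::read_yaml(sidecar_path)
  sweeps <- lapply(split(d, d$sweep_id), function(s) {
    out <- data.frame(t = s$t_s)
    if ("Vm_mV" %in% names(s)) out$Vm <- s$Vm_mV
    if ("I_pA" %in% names(s)) out$I <- s$I_pA
    out
  })
  sweep_set(unname(sweeps), meta$sampling_rate, meta$protocol,
            meta = meta[setdiff(names(meta),
                                c("sampling_rate", "protocol"))])
}

#' Write a sweep set to a long CSV plus a JSON protocol sidecar
#' @param x a [sweep_set()]
#' @param path output CSV file
#' @param sidecar_path output JSON file
#' @export
write_sweeps_csv <- function(x, path, sidecar_path) {
  long <- do.call(rbind, lapply(seq_along(x$sweeps), function(i) {
    s <- x$sweeps[[i]]
    out <- data.frame(sweep_id = i, t_s = s$t)
    if (!is.null(s$Vm)) out$Vm_mV <- s$Vm
    if (!is.null(s$I)) out$I_pA <- s$I
    out
  }))
  write.csv(long, path, row.names = FALSE)
  jsonlite::write_json(c(list(sampling_rate = x$sampling_rate,
                              protocol = x$protocol), x$meta),
                       sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an LFP recording from single-column CSVs plus a JSON sidecar
#'
#' @param signal_path single-column CSV (header `lfp_mV`) of the signal
#' @param reference_path single-column CSV of the noise reference
#' @param sidecar_path JSON with `sampling_rate`, optional
#'   `injection_time` and `mask` (list of `start`/`end` intervals, s)
#' @return an [lfp_recording()]
#' @export
read_lfp_csv <- function(signal_path, reference_path, sidecar_path) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  mask <- NULL
  if (!is.null(meta$mask) && length(meta$mask)) {
    mask <- as.data.frame(meta$mask)
  }
  lfp_recording(read.csv(signal_path)[[1]],
                read.csv(reference_path)[[1]],
                meta$sampling_rate, mask,
                meta$injection_time %||% NA_real_)
}
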