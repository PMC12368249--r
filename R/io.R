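#' Write a calcium movie as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 32-bit TIFF pages scaled to `[0, 1]`; the scaling
#' (`offset`, `scale`), frame rate, stimulation schedule and any seed are
#' stored in `<path>.json`. Values round-trip to within 32-bit
#' quantisation (~2^-32 of the data range).
#'
#' @param movie a [calcium_movie()].
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @param seed optional integer recorded in the sidecar for provenance.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, seed = NULL) {
  d <- dim(movie$data)
  lo <- min(movie$data); hi <- max(movie$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[1L]), function(f)
    (movie$data[f, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(frame_rate = movie$frame_rate, stim_times = movie$stim_times,
               offset = lo, scale = scale,
               n_frames = d[1L], height = d[2L], width = d[3L])
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a calcium movie written by [write_movie()]
#'
#' @param path TIFF path; metadata is read from `<path>.json` unless
#'   `frame_rate` is supplied, which takes precedence over a missing
#'   sidecar.
#' @param frame_rate optional frame rate (Hz) used when no sidecar exists.
#' @return a [calcium_movie()].
#' @export
read_movie <- function(path, frame_rate = NULL) {
  if (!file.exists(path)) stop_param("no such file: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop_param("cannot parse TIFF %s: %s", path,
                                 conditionMessage(e)))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  } else {
    if (is.null(frame_rate))
      stop_param(paste("missing sidecar %s and no `frame_rate` given;",
                       "pass frame_rate= or restore the sidecar"), side)
    meta <- list(frame_rate = frame_rate, stim_times = numeric(0),
                 offset = 0, scale = 1)
  }
  arr <- array(NA_real_, c(length(pages), dim(pages[[1L]])[1:2]))
  for (f in seq_along(pages)) arr[f, , ] <- pages[[f]] * meta$scale + meta$offset
  calcium_movie(arr, meta$frame_rate,
                if (is.null(meta$stim_times)) numeric(0)
                else as.numeric(meta$stim_times))
}

#' Write spike trains as a two-column CSV
#'
#' Columns `electrode,time_s`, one row per spike.
#'
#' @param trains a [spike_train_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(trains, path) {
  df <- data.frame(
    electrode = rep(names(trains$trains), lengths(trains$trains)),
    time_s = unlist(trains$trains, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spike table CSV into a spike-train set
#'
#' Accepts header `electrode,time_s`; rows may be unsorted. Duplicate
#' timestamps on one electrode are collapsed with a warning; negative times
#' are an error.
#'
#' @param path CSV path.
#' @param duration recording duration in seconds; required when it cannot be
#'   inferred (empty table), otherwise defaults to the last spike time
#'   rounded up to the next second.
#' @param electrodes optional electrode ids to include even when silent.
#' @return a [spike_train_set()].
#' @export
read_spike_table <- function(path, duration = NULL, electrodes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("electrode", "time_s") %in% names(df)))
    stop_param("spike table must have columns electrode,time_s")
  if (nrow(df) && any(df$time_s < 0)) stop_param("negative spike times")
  if (is.null(duration)) {
    if (!nrow(df)) stop_param("empty table: `duration` must be supplied")
    duration <- ceiling(max(df$time_s) + 1e-9)
  }
  ids <- unique(c(as.character(df$electrode), electrodes))
  trains <- lapply(ids, function(e) {
    t <- sort(df$time_s[df$electrode == e])
    if (anyDuplicated(t)) {
      warning(sprintf("duplicate spike times on electrode %s collapsed", e))
      t <- unique(t)
    }
    t
  })
  names(trains) <- ids
  spike_train_set(trains, duration)
}

#' Write an MEA recording as CSV traces plus a JSON sidecar
#'
#' Raw traces go to `<path>.csv` (one column per electrode); sampling rate,
#' stimulation times and layout go to `<path>.json`.
#'
#' @param recording an [mea_recording()] with raw traces.
#' @param path base path (no extension).
#' @return `path`, invisibly.
#' @export
write_mea_recording <- function(recording, path) {
  if (is.null(recording$raw)) stop_param("recording carries no raw traces")
  df <- as.data.frame(t(recording$raw))
  names(df) <- recording$layout$electrode[seq_len(nrow(recording$raw))]
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(fs_hz = recording$fs, stim_times_s = recording$stim_times,
         layout = recording$layout),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an MEA recording written by [write_mea_recording()]
#'
#' @param path base path used at write time.
#' @return an [mea_recording()].
#' @export
read_mea_recording <- function(path) {
  csv <- paste0(path, ".csv"); side <- paste0(path, ".json")
  if (!file.exists(csv) || !file.exists(side))
    stop_param("expected %s and %s", csv, side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  df <- utils::read.csv(csv, check.names = FALSE)
  mea_recording(t(as.matrix(df)), meta$fs_hz,
                as.numeric(meta$stim_times_s),
                layout = as.data.frame(meta$layout))
}
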