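# File I/O: per-channel CSV signals with a JSON layout, annotation CSVs,
# and feature tables.

#' Read event annotations from CSV
#'
#' Reference dialect: a CSV with header `label,start_s,end_s`.
#'
#' @param path file path.
#' @return an `event_annotations` table.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "start_s", "end_s")
  if (!all(need %in% names(df))) {
    stopf("annotation CSV must have columns %s (found: %s)",
          paste(need, collapse = ","), paste(names(df), collapse = ","))
  }
  event_annotations(df$label, df$start_s, df$end_s)
}

#' Write event annotations to CSV
#'
#' @param ann an `event_annotations` table.
#' @param path file path.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(as.data.frame(ann)[, c("label", "start_s", "end_s")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multi-channel PSG record from per-channel CSV files
#'
#' The layout configuration (a JSON file or an equivalent list) maps the
#' file signal labels to canonical channel names and carries each
#' channel's sampling rate:
#' ```
#' {"patient_id": "p01",
#'  "channels": {"sao2": {"file": "sao2.csv", "fs": 1, "units": "%"}, ...}}
#' ```
#' Each channel CSV holds one numeric column (with header).
#'
#' @param layout path to a layout JSON file, or a list with the same shape.
#' @param dir directory the channel files are relative to; defaults to the
#'   layout file's directory.
#' @return a `psg_record`.
#' @export
read_record <- function(layout, dir = NULL) {
  if (is.character(layout)) {
    if (is.null(dir)) dir <- dirname(layout)
    layout <- jsonlite::read_json(layout, simplifyVector = TRUE)
  }
  if (is.null(dir)) dir <- "."
  chans <- layout$channels
  unknown <- setdiff(names(chans), names(CANONICAL_CHANNELS))
  if (length(unknown) > 0L) {
    stopf("unknown channel label(s) %s; available canonical names: %s",
          paste(unknown, collapse = ", "),
          paste(names(CANONICAL_CHANNELS), collapse = ", "))
  }
  channels <- lapply(names(chans), function(nm) {
    spec <- chans[[nm]]
    path <- file.path(dir, spec$file)
    if (!file.exists(path)) stopf("channel file not found: %s", path)
    df <- utils::read.csv(path)
    channel_series(nm, fs = spec$fs, samples = df[[1L]],
                   units = spec$units %||% "a.u.")
  })
  psg_record(layout$patient_id %||% "unknown", channels)
}

#' Write a PSG record as per-channel CSV files plus a layout JSON
#'
#' @param record a `psg_record`.
#' @param dir output directory (created if missing).
#' @return path of the written layout file.
#' @export
write_record <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chans <- lapply(record$channels, function(ch) {
    fn <- paste0(ch$name, ".csv")
    df <- stats::setNames(data.frame(ch$samples), ch$name)
    utils::write.csv(df, file.path(dir, fn), row.names = FALSE)
    list(file = fn, fs = ch$fs, units = ch$units)
  })
  layout <- list(patient_id = record$patient_id, channels = chans)
  path <- file.path(dir, "layout.json")
  jsonlite::write_json(layout, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write labelled segments to a directory
#'
#' Writes an index CSV (`segments.csv`: patient, label, interval) plus one
#' CSV per segment and channel under `seg<k>/<channel>.csv`.
#'
#' @param segs list of `psg_segment` from [segment_by_events()] or
#'   [segment_by_windows()].
#' @param dir output directory (created if missing).
#' @return the index file path.
#' @export
write_segments <- function(segs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- data.frame(
    segment = sprintf("seg%04d", seq_along(segs)),
    patient_id = vapply(segs, `[[`, character(1), "patient_id"),
    label = vapply(segs, `[[`, character(1), "label"),
    start_s = vapply(segs, `[[`, numeric(1), "start_s"),
    end_s = vapply(segs, `[[`, numeric(1), "end_s"))
  for (i in seq_along(segs)) {
    sd_ <- file.path(dir, idx$segment[i])
    dir.create(sd_, showWarnings = FALSE)
    for (nm in names(segs[[i]]$channels)) {
      ch <- segs[[i]]$channels[[nm]]
      utils::write.csv(stats::setNames(data.frame(ch$samples), nm),
                       file.path(sd_, paste0(nm, ".csv")), row.names = FALSE)
    }
  }
  path <- file.path(dir, "segments.csv")
  utils::write.csv(idx, path, row.names = FALSE)
  invisible(path)
}

#' Write a feature table to CSV
#'
#' Feature names (which contain `.` and `/`) are preserved verbatim.
#'
#' @param table feature data.frame (`patient_id`, `label`, 66 features).
#' @param path file path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path file path.
#' @return data.frame with verbatim column names.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
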