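# Data model for multi-rate polysomnography records, event annotations
# and labelled segments.

CANONICAL_CHANNELS <- c(sao2 = 1, airflow = 10, thoracic = 10,
                        abdominal = 10, ecg = 125)

#' Construct a single PSG channel
#'
#' @param name canonical channel id: one of `sao2`, `airflow`, `thoracic`,
#'   `abdominal`, `ecg`.
#' @param fs sampling rate in Hz (> 0). Non-canonical rates are accepted
#'   with a warning.
#' @param samples numeric sample vector (non-empty).
#' @param units free-text units (`"%"`, `"a.u."`, `"mV"`).
#' @return object of class `channel_series`.
#' @export
channel_series <- function(name, fs, samples, units = "a.u.") {
  name <- match.arg(name, names(CANONICAL_CHANNELS))
  if (!is.numeric(fs) || fs <= 0) stopf("fs must be > 0")
  if (length(samples) == 0L) stopf("channel '%s' has no samples", name)
  if (abs(fs - CANONICAL_CHANNELS[[name]]) > 1e-9) {
    warnf("channel '%s' at %g Hz (canonical rate is %g Hz)",
          name, fs, CANONICAL_CHANNELS[[name]])
  }
  structure(list(name = name, fs = fs, samples = as.numeric(samples),
                 units = units),
            class = "channel_series")
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series> %s: %d samples @ %g Hz (%s), %.1f s\n",
              x$name, length(x$samples), x$fs, x$units,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Construct a multi-rate PSG record
#'
#' All channels must span the same duration to within one sample period of
#' the slowest channel involved.
#'
#' @param patient_id string identifier.
#' @param channels list of `channel_series`, keyed (or keyable) by name.
#' @return object of class `psg_record`.
#' @export
psg_record <- function(patient_id, channels) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  if (length(channels) == 0L) stopf("record needs at least one channel")
  ok <- vapply(channels, inherits, logical(1), "channel_series")
  if (!all(ok)) stopf("all channels must be channel_series objects")
  names(channels) <- vapply(channels, `[[`, character(1), "name")
  if (anyDuplicated(names(channels))) stopf("duplicate channel names")
  durs <- vapply(channels, function(ch) length(ch$samples) / ch$fs, numeric(1))
  dur <- max(durs)
  tol <- vapply(channels, function(ch) 1 / ch$fs, numeric(1))
  if (any(dur - durs > tol + 1e-9)) {
    stopf("channel durations disagree beyond one sample period: %s",
          paste(sprintf("%s=%.3fs", names(durs), durs), collapse = ", "))
  }
  structure(list(patient_id = patient_id, channels = channels,
                 duration_s = min(durs)),
            class = "psg_record")
}

#' @export
print.psg_record <- function(x, ...) {
  cat(sprintf("<psg_record> patient %s, %.1f s, channels: %s\n",
              x$patient_id, x$duration_s,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Build an event annotation table
#'
#' @param label character vector of `"apnea"` / `"normal"` labels.
#' @param start_s,end_s event bounds in seconds from record start;
#'   intervals are half-open `[start_s, end_s)`.
#' @return data.frame of class `event_annotations`.
#' @export
event_annotations <- function(label, start_s, end_s) {
  label <- as.character(label)
  if (!all(label %in% c("apnea", "normal"))) {
    stopf("labels must be 'apnea' or 'normal'")
  }
  if (any(end_s <= start_s)) stopf("end_s must exceed start_s for every event")
  out <- data.frame(label = label, start_s = as.numeric(start_s),
                    end_s = as.numeric(end_s), stringsAsFactors = FALSE)
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_annotations", "data.frame")
  out
}

#' Normalize annotations against a record
#'
#' Sorts by start time and checks that the intervals are non-overlapping
#' and within the record bounds.
#'
#' @param ann an `event_annotations` table.
#' @param duration_s record duration in seconds.
#' @return the normalized table.
#' @export
normalize_annotations <- function(ann, duration_s) {
  ann <- event_annotations(ann$label, ann$start_s, ann$end_s)
  if (nrow(ann) == 0L) return(ann)
  bad <- which(ann$start_s < 0 | ann$end_s > duration_s + 1e-9)
  if (length(bad) > 0L) {
    stopf("annotation outside record [0, %g s]: %s [%g, %g)",
          duration_s, ann$label[bad[1L]], ann$start_s[bad[1L]],
          ann$end_s[bad[1L]])
  }
  if (nrow(ann) > 1L &&
      any(ann$start_s[-1L] < ann$end_s[-nrow(ann)] - 1e-9)) {
    stopf("annotations overlap after sorting")
  }
  ann
}

#' Infer normal-period annotations from inter-event gaps
#'
#' Records annotated only with apnea events get explicit `normal` rows for
#' every gap of at least `min_len_s` seconds.
#'
#' @param ann apnea annotations.
#' @param duration_s record duration.
#' @param min_len_s minimum gap length to annotate (default 10 s).
#' @return combined `event_annotations`.
#' @export
infer_normal_annotations <- function(ann, duration_s, min_len_s = 10) {
  ann <- normalize_annotations(ann, duration_s)
  ap <- ann[ann$label == "apnea", , drop = FALSE]
  bounds <- c(0, as.vector(rbind(ap$start_s, ap$end_s)), duration_s)
  starts <- bounds[seq(1, length(bounds), by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  keep <- (ends - starts) >= min_len_s
  normals <- event_annotations(rep("normal", sum(keep)),
                               starts[keep], ends[keep])
  out <- rbind(as.data.frame(ap), as.data.frame(normals))
  event_annotations(out$label, out$start_s, out$end_s)
}

# slice one channel over [start_s, end_s): sample index = floor(t * fs),
# 0-based; slice length is exactly round(duration * fs)
slice_channel <- function(ch, start_s, end_s) {
  i0 <- floor(start_s * ch$fs)          # 0-based first sample
  len <- round((end_s - start_s) * ch$fs)
  if (i0 < 0 || i0 + len > length(ch$samples)) {
    stopf("interval [%g, %g) outside channel '%s'", start_s, end_s, ch$name)
  }
  ch$samples[(i0 + 1L):(i0 + len)]
}

new_segment <- function(record, label, start_s, end_s) {
  chans <- lapply(record$channels, function(ch) {
    list(fs = ch$fs, samples = slice_channel(ch, start_s, end_s))
  })
  structure(list(patient_id = record$patient_id, label = label,
                 start_s = start_s, end_s = end_s, channels = chans),
            class = "psg_segment")
}

#' @export
print.psg_segment <- function(x, ...) {
  cat(sprintf("<psg_segment> %s [%g, %g) s, label=%s\n",
              x$patient_id, x$start_s, x$end_s, x$label))
  invisible(x)
}

#' Segment a record by annotated event durations
#'
#' One segment per annotation; the segment interval equals the annotation
#' interval exactly and the label is copied.
#'
#' @param record a `psg_record`.
#' @param annotations an `event_annotations` table.
#' @return list of `psg_segment`.
#' @export
segment_by_events <- function(record, annotations) {
  annotations <- normalize_annotations(annotations, record$duration_s)
  lapply(seq_len(nrow(annotations)), function(i) {
    new_segment(record, annotations$label[i],
                annotations$start_s[i], annotations$end_s[i])
  })
}

#' Segment a record into fixed-length windows
#'
#' Contiguous non-overlapping windows of `window_s` seconds from the
#' record start; the trailing partial window is dropped. A window is
#' labelled `apnea` when its total overlap with apnea annotations is at
#' least `overlap_min_s` seconds (the clinical 10 s minimum by default),
#' otherwise `normal`.
#'
#' @param record a `psg_record`.
#' @param annotations an `event_annotations` table (apnea rows are used
#'   for labelling; explicit normal rows are allowed and ignored here).
#' @param window_s window length in seconds (default 60).
#' @param overlap_min_s apnea-overlap threshold in seconds (default 10).
#' @return list of `psg_segment`.
#' @export
segment_by_windows <- function(record, annotations, window_s = 60,
                               overlap_min_s = 10) {
  if (window_s <= 0) stopf("window_s must be > 0")
  if (window_s > record$duration_s) {
    stopf("window_s (%g) exceeds record duration (%g s)",
          window_s, record$duration_s)
  }
  annotations <- normalize_annotations(annotations, record$duration_s)
  ap <- annotations[annotations$label == "apnea", , drop = FALSE]
  k <- floor(record$duration_s / window_s)
  lapply(seq_len(k), function(i) {
    w0 <- (i - 1) * window_s
    w1 <- i * window_s
    ov <- 0
    if (nrow(ap) > 0L) {
      ov <- sum(pmax(0, pmin(ap$end_s, w1) - pmax(ap$start_s, w0)))
    }
    lab <- if (ov >= overlap_min_s) "apnea" else "normal"
    new_segment(record, lab, w0, w1)
  })
}
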