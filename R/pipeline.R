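# Record-level orchestration: preprocess once per record, slice prepared
# channels and derived series per segment, assemble feature tables. The
# event-duration and fixed-window protocols share this single code path;
# only the segmentation rule differs.

#' Preprocess a full PSG record
#'
#' Runs every channel-specific preprocessing step once per record: SaO2
#' artifact removal, airflow baseline/low-pass/decimation to 1 Hz, effort
#' band-pass, ECG band-pass, Pan-Tompkins R-peak detection, RR
#' correction, QRS matrix extraction and EDR derivation.
#'
#' @param record a `psg_record` with all five canonical channels.
#' @param config a `preprocess_config`.
#' @return object of class `prepared_psg`.
#' @export
prepare_record <- function(record, config = preprocess_config()) {
  need <- names(CANONICAL_CHANNELS)
  missing <- setdiff(need, names(record$channels))
  if (length(missing) > 0L) {
    stopf("record is missing channel(s): %s", paste(missing, collapse = ", "))
  }
  ch <- record$channels
  sao2 <- clean_sao2(ch$sao2$samples, config$sao2_jump_max)
  airflow <- preprocess_airflow(ch$airflow$samples, ch$airflow$fs, config)
  thoracic <- preprocess_effort(ch$thoracic$samples, ch$thoracic$fs, config)
  abdominal <- preprocess_effort(ch$abdominal$samples, ch$abdominal$fs, config)
  ecg <- preprocess_ecg(ch$ecg$samples, ch$ecg$fs, config)
  fs_ecg <- ch$ecg$fs

  rpeaks <- detect_r_peaks(ecg, fs_ecg, config)
  rtimes <- (rpeaks - 1L) / fs_ecg
  rr <- if (length(rtimes) >= 2L) correct_rr(rr_series(rtimes), config) else
    structure(list(times_s = rtimes, intervals_s = numeric(0)),
              class = "rr_series")
  qrs <- extract_qrs(ecg, rpeaks, fs_ecg)
  edr <- if (length(rpeaks) >= 2L) derive_edr(ecg, rpeaks, fs_ecg) else
    numeric(floor(length(ecg) / fs_ecg))

  structure(list(
    patient_id = record$patient_id,
    duration_s = record$duration_s,
    channels = list(
      sao2 = list(fs = 1, samples = sao2),
      airflow = list(fs = 1, samples = airflow),
      thoracic = list(fs = ch$thoracic$fs, samples = thoracic),
      abdominal = list(fs = ch$abdominal$fs, samples = abdominal),
      ecg = list(fs = fs_ecg, samples = ecg)
    ),
    rpeaks_s = rtimes, rr = rr, qrs = qrs,
    qrs_times_s = (attr(qrs, "rpeaks") - 1L) / fs_ecg,
    edr = list(fs = 1, samples = edr)
  ), class = "prepared_psg")
}

#' @export
print.prepared_psg <- function(x, ...) {
  cat(sprintf("<prepared_psg> patient %s, %.0f s, %d beats\n",
              x$patient_id, x$duration_s, length(x$rpeaks_s)))
  invisible(x)
}

slice_prepared <- function(ch, start_s, end_s) {
  i0 <- floor(start_s * ch$fs)
  len <- round((end_s - start_s) * ch$fs)
  len <- min(len, length(ch$samples) - i0)
  ch$samples[(i0 + 1L):(i0 + len)]
}

make_prepared_segment <- function(prep, label, start_s, end_s) {
  sel_rr <- prep$rr$times_s >= start_s & prep$rr$times_s < end_s
  rt <- prep$rr$times_s[sel_rr]
  # intervals whose bounding peaks both lie in the segment
  iv <- if (sum(sel_rr) >= 2L) {
    idx <- which(sel_rr)
    prep$rr$intervals_s[idx[-length(idx)]]
  } else numeric(0)
  rr <- structure(list(times_s = rt, intervals_s = iv), class = "rr_series")
  qsel <- prep$qrs_times_s >= start_s & prep$qrs_times_s < end_s
  structure(list(
    patient_id = prep$patient_id, label = label,
    start_s = start_s, end_s = end_s,
    sao2 = slice_prepared(prep$channels$sao2, start_s, end_s),
    airflow = slice_prepared(prep$channels$airflow, start_s, end_s),
    thoracic = slice_prepared(prep$channels$thoracic, start_s, end_s),
    abdominal = slice_prepared(prep$channels$abdominal, start_s, end_s),
    ecg = slice_prepared(prep$channels$ecg, start_s, end_s),
    fs_ecg = prep$channels$ecg$fs,
    fs_effort = prep$channels$thoracic$fs,
    rr = rr,
    edr = slice_prepared(prep$edr, start_s, end_s),
    qrs = prep$qrs[qsel, , drop = FALSE]
  ), class = "prepared_segment")
}

#' Segment a prepared record
#'
#' Applies either the event-duration rule (one segment per annotation) or
#' the fixed-window rule (non-overlapping windows, apnea iff apnea
#' overlap >= `overlap_min_s`), carrying the preprocessed channel slices
#' and the derived RR / EDR / QRS slices into each segment.
#'
#' @param prep a `prepared_psg`.
#' @param annotations an `event_annotations` table.
#' @param mode `"events"` or `"windows"`.
#' @param window_s window length for `"windows"` (default 60 s).
#' @param overlap_min_s apnea-overlap labelling threshold (default 10 s).
#' @return list of `prepared_segment`.
#' @export
segment_prepared <- function(prep, annotations, mode = c("windows", "events"),
                             window_s = 60, overlap_min_s = 10) {
  mode <- match.arg(mode)
  annotations <- normalize_annotations(annotations, prep$duration_s)
  if (mode == "events") {
    iv <- annotations
  } else {
    if (window_s > prep$duration_s) {
      stopf("window_s (%g) exceeds record duration (%g s)",
            window_s, prep$duration_s)
    }
    ap <- annotations[annotations$label == "apnea", , drop = FALSE]
    k <- floor(prep$duration_s / window_s)
    w0 <- (seq_len(k) - 1) * window_s
    ov <- vapply(seq_len(k), function(i) {
      if (nrow(ap) == 0L) return(0)
      sum(pmax(0, pmin(ap$end_s, w0[i] + window_s) - pmax(ap$start_s, w0[i])))
    }, numeric(1))
    iv <- data.frame(label = ifelse(ov >= overlap_min_s, "apnea", "normal"),
                     start_s = w0, end_s = w0 + window_s)
  }
  lapply(seq_len(nrow(iv)), function(i) {
    make_prepared_segment(prep, iv$label[i], iv$start_s[i], iv$end_s[i])
  })
}

#' Extract the feature table of one record
#'
#' Preprocesses the record, segments it and computes the 66-feature
#' vector of every segment.
#'
#' @param record a `psg_record`.
#' @param annotations an `event_annotations` table. For `mode = "events"`
#'   normal periods must be annotated explicitly or inferred first with
#'   [infer_normal_annotations()].
#' @inheritParams segment_prepared
#' @param config a `preprocess_config`.
#' @return data.frame: `patient_id`, `label`, then the 66 schema columns.
#' @export
extract_feature_table <- function(record, annotations,
                                  mode = c("windows", "events"),
                                  window_s = 60, overlap_min_s = 10,
                                  config = preprocess_config()) {
  mode <- match.arg(mode)
  prep <- prepare_record(record, config)
  segs <- segment_prepared(prep, annotations, mode, window_s, overlap_min_s)
  feature_table_from_segments(segs)
}

#' Assemble a feature table from prepared segments
#'
#' @param segs list of `prepared_segment`.
#' @return data.frame: `patient_id`, `label`, 66 feature columns.
#' @export
feature_table_from_segments <- function(segs) {
  rows <- lapply(segs, function(s) suppressWarnings(extract_all(s)))
  mat <- do.call(rbind, rows)
  out <- data.frame(
    patient_id = vapply(segs, `[[`, character(1), "patient_id"),
    label = vapply(segs, `[[`, character(1), "label"),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  out[feature_schema()] <- as.data.frame(mat, check.names = FALSE)
  out
}

#' Extract feature tables for a whole cohort
#'
#' @param cohort list as returned by [generate_cohort()] (elements with
#'   `record` and `annotations`), or a list of such pairs from files.
#' @inheritParams extract_feature_table
#' @return row-bound feature data.frame over all records.
#' @export
extract_cohort_features <- function(cohort, mode = c("windows", "events"),
                                    window_s = 60, overlap_min_s = 10,
                                    config = preprocess_config()) {
  mode <- match.arg(mode)
  tabs <- lapply(cohort, function(el) {
    ann <- el$annotations
    if (mode == "events") {
      ann <- infer_normal_annotations(ann, el$record$duration_s)
    }
    extract_feature_table(el$record, ann, mode, window_s, overlap_min_s,
                          config)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
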