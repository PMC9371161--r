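# Channel-specific preprocessing: SaO2 artifact removal, airflow/effort/
# ECG filtering, Pan-Tompkins R-peak detection, RR correction, QRS
# extraction and ECG-derived respiration.

#' Preprocessing configuration
#'
#' All tunables of the preprocessing stage with their defaults; the list
#' round-trips through JSON.
#'
#' @param sao2_jump_max maximum physiological point-to-point SaO2 change in
#'   percentage points (default 8; larger jumps are artifacts).
#' @param airflow_lp_hz airflow low-pass cutoff (default 3 Hz, order 3).
#' @param airflow_baseline_s airflow running-median baseline window (10 s).
#' @param effort_band_hz effort band-pass edges (default 0.05-4 Hz).
#' @param effort_baseline_s effort running-median baseline window (60 s).
#' @param ecg_band_hz ECG band-pass edges (default 0.05-40 Hz).
#' @param butter_order Butterworth order per direction (default 3).
#' @param refractory_s R-peak refractory period (default 0.2 s).
#' @param rr_range_s physiological RR range (default 0.3-2.0 s).
#' @param rr_dev_frac RR deviation fraction versus the local median that
#'   triggers replacement (default 0.2).
#' @return named list of class `preprocess_config`.
#' @export
preprocess_config <- function(sao2_jump_max = 8,
                              airflow_lp_hz = 3, airflow_baseline_s = 10,
                              effort_band_hz = c(0.05, 4),
                              effort_baseline_s = 60,
                              ecg_band_hz = c(0.05, 40),
                              butter_order = 3,
                              refractory_s = 0.2,
                              rr_range_s = c(0.3, 2.0),
                              rr_dev_frac = 0.2) {
  structure(list(sao2_jump_max = sao2_jump_max,
                 airflow_lp_hz = airflow_lp_hz,
                 airflow_baseline_s = airflow_baseline_s,
                 effort_band_hz = effort_band_hz,
                 effort_baseline_s = effort_baseline_s,
                 ecg_band_hz = ecg_band_hz,
                 butter_order = butter_order,
                 refractory_s = refractory_s,
                 rr_range_s = rr_range_s,
                 rr_dev_frac = rr_dev_frac),
            class = "preprocess_config")
}

#' Remove non-physiological jumps from an SaO2 series
#'
#' Scanning left to right, any sample differing from its (corrected)
#' predecessor by strictly more than `jump_max` percentage points is
#' replaced by the median of the first 10 s of the original series.
#' Because the replacement value is fixed, the operation is idempotent.
#'
#' @param x SaO2 series at 1 Hz, values in `[0, 100]`.
#' @param jump_max artifact threshold in percentage points (default 8).
#' @return cleaned series, same length.
#' @export
clean_sao2 <- function(x, jump_max = 8) {
  n <- length(x)
  if (n < 10L) stopf("SaO2 series shorter than 10 samples")
  if (any(x < 0 | x > 100)) stopf("SaO2 values must lie in [0, 100]")
  m <- stats::median(x[1:10])
  out <- x
  for (i in 2:n) {
    if (abs(out[i] - out[i - 1L]) > jump_max) out[i] <- m
  }
  out
}

#' Preprocess an airflow channel
#'
#' Baseline correction by a 10 s running median, zero-phase 3rd-order
#' Butterworth low-pass at 3 Hz, then decimation from 10 Hz to 1 Hz.
#'
#' @param x airflow series at 10 Hz.
#' @param fs input sampling rate (10 Hz).
#' @param config a `preprocess_config`.
#' @return series at 1 Hz of length `length(x) / fs` (floored).
#' @export
preprocess_airflow <- function(x, fs = 10, config = preprocess_config()) {
  if (length(x) < config$airflow_baseline_s * fs) {
    stopf("airflow record shorter than the %g s baseline window",
          config$airflow_baseline_s)
  }
  base <- running_median(x, as.integer(config$airflow_baseline_s * fs))
  y <- zero_phase_butter(x - base, fs, order = config$butter_order,
                         hi = config$airflow_lp_hz, type = "low")
  dec <- as.integer(round(fs))  # to 1 Hz
  y[seq(1L, (length(y) %/% dec) * dec, by = dec)]
}

#' Preprocess a respiratory-effort channel (thoracic or abdominal)
#'
#' Baseline correction by a 60 s running median and a zero-phase
#' Butterworth band-pass 0.05-4 Hz (order 3 per direction). The rate is
#' unchanged.
#'
#' @inheritParams preprocess_airflow
#' @return filtered series at the input rate.
#' @export
preprocess_effort <- function(x, fs = 10, config = preprocess_config()) {
  if (length(x) < config$effort_baseline_s * fs) {
    stopf("effort record shorter than the %g s baseline window",
          config$effort_baseline_s)
  }
  base <- running_median(x, as.integer(config$effort_baseline_s * fs))
  zero_phase_butter(x - base, fs, order = config$butter_order,
                    lo = config$effort_band_hz[1], hi = config$effort_band_hz[2],
                    type = "pass")
}

#' Preprocess an ECG channel
#'
#' Zero-phase 3rd-order Butterworth band-pass 0.05-40 Hz (noise removal
#' and baseline correction in one step).
#'
#' @param x ECG series.
#' @param fs sampling rate (125 Hz canonical).
#' @param config a `preprocess_config`.
#' @return filtered ECG, same length and rate.
#' @export
preprocess_ecg <- function(x, fs = 125, config = preprocess_config()) {
  zero_phase_butter(x, fs, order = config$butter_order,
                    lo = config$ecg_band_hz[1], hi = config$ecg_band_hz[2],
                    type = "pass")
}

#' Detect R peaks with a modified Pan-Tompkins algorithm
#'
#' Stages: 5-15 Hz band-pass (re-filtering the already band-passed ECG),
#' five-point derivative, squaring, 150 ms moving-window integration, and
#' adaptive signal/noise thresholds with a 200 ms refractory period. The
#' modifications over the textbook detector: a 2 s learning phase
#' initialises the thresholds, and a search-back pass at half threshold
#' recovers beats missed for more than 1.66 times the running RR average.
#' Peak positions are refined to the local ECG maximum.
#'
#' @param ecg preprocessed ECG series.
#' @param fs sampling rate in Hz (>= 100).
#' @param config a `preprocess_config`.
#' @return strictly increasing integer sample indices of R peaks (1-based),
#'   empty for a flat signal.
#' @export
detect_r_peaks <- function(ecg, fs, config = preprocess_config()) {
  if (fs < 100) stopf("detect_r_peaks requires fs >= 100 Hz")
  n <- length(ecg)
  if (n < 2 * fs) stopf("record shorter than 2 s")
  if (max(abs(ecg)) < 1e-12) return(integer(0))

  bp <- zero_phase_butter(ecg, fs, order = 2, lo = 5, hi = 15, type = "pass")
  # five-point derivative (causal, delay 2 samples)
  dk <- c(-1, -2, 0, 2, 1) / 8
  der <- as.numeric(stats::filter(bp, rev(dk), method = "convolution",
                                  sides = 1))
  der[is.na(der)] <- 0
  sq <- der^2
  win <- max(1L, as.integer(round(0.15 * fs)))
  mwi <- as.numeric(stats::filter(sq, rep(1 / win, win), method = "convolution",
                                  sides = 1))
  mwi[is.na(mwi)] <- 0
  # group delay of derivative + integrator
  delay <- 2L + (win - 1L) %/% 2L

  # candidate peaks: local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[mwi[cand] > 0]
  if (length(cand) == 0L) return(integer(0))

  learn <- seq_len(min(n, 2L * as.integer(fs)))
  spki <- 0.25 * max(mwi[learn])
  npki <- 0.5 * mean(mwi[learn])
  thr <- function() npki + 0.25 * (spki - npki)

  refr <- config$refractory_s * fs
  beats <- integer(0)
  rr_avg <- fs  # running RR average in samples, init 1 s
  last <- -Inf
  for (p in cand) {
    v <- mwi[p]
    if (v > thr() && p - last >= refr) {
      # search-back before accepting a very late beat is handled below
      beats <- c(beats, p)
      if (length(beats) > 1L) {
        rr <- diff(utils::tail(beats, 9L))
        if (length(rr) > 0L) rr_avg <- mean(rr)
      }
      last <- p
      spki <- 0.125 * v + 0.875 * spki
    } else {
      # search-back: if a long gap elapsed, accept the best candidate
      # above half threshold inside the gap
      if (is.finite(last) && p - last > 1.66 * rr_avg &&
          v > 0.5 * thr() && p - last >= refr) {
        beats <- c(beats, p)
        last <- p
        spki <- 0.25 * v + 0.75 * spki
      } else {
        npki <- 0.125 * v + 0.875 * npki
      }
    }
  }
  if (length(beats) == 0L) return(integer(0))

  # refine to the ECG maximum around the delay-corrected position
  half <- as.integer(round(0.10 * fs))
  ref <- vapply(beats, function(p) {
    c0 <- max(1L, p - delay - half)
    c1 <- min(n, p - delay + half)
    if (c1 < c0) c1 <- c0
    c0 + which.max(ecg[c0:c1]) - 1L
  }, integer(1))
  ref <- sort(unique(ref))
  # enforce refractory spacing after refinement, keeping the larger peak
  if (length(ref) > 1L) {
    keep <- ref[1L]
    for (r in ref[-1L]) {
      lastk <- keep[length(keep)]
      if (r - lastk >= refr) {
        keep <- c(keep, r)
      } else if (ecg[r] > ecg[lastk]) {
        keep[length(keep)] <- r
      }
    }
    ref <- keep
  }
  as.integer(ref)
}

#' Construct an RR interval series from R-peak times
#'
#' @param times_s R-peak times in seconds (strictly increasing).
#' @return object of class `rr_series` with fields `times_s` and
#'   `intervals_s` (length one less).
#' @export
rr_series <- function(times_s) {
  if (is.unsorted(times_s, strictly = TRUE)) {
    stopf("R-peak times must be strictly increasing")
  }
  structure(list(times_s = as.numeric(times_s),
                 intervals_s = diff(as.numeric(times_s))),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats, mean RR %.3f s\n",
              length(x$times_s),
              if (length(x$intervals_s)) mean(x$intervals_s) else NA))
  invisible(x)
}

#' Correct an RR interval series
#'
#' Intervals outside the physiological range (0.3-2.0 s by default), or
#' deviating by more than 20% from the median of the five surrounding
#' intervals, are replaced by that local median (clamped to the range).
#' Length is preserved; peak times are kept as detected.
#'
#' @param rr an `rr_series`.
#' @param config a `preprocess_config` (fields `rr_range_s`, `rr_dev_frac`).
#' @return corrected `rr_series`.
#' @export
correct_rr <- function(rr, config = preprocess_config()) {
  iv <- rr$intervals_s
  if (length(iv) == 0L) return(rr)
  lo <- config$rr_range_s[1]; hi <- config$rr_range_s[2]
  locmed <- running_median(iv, 5L)
  bad <- iv < lo | iv > hi | abs(iv - locmed) > config$rr_dev_frac * locmed
  iv[bad] <- pmin(pmax(locmed[bad], lo), hi)
  rr$intervals_s <- iv
  rr
}

#' Extract the QRS morphology matrix
#'
#' One row per beat: a symmetric 120 ms window around each R peak
#' (15 samples at 125 Hz). Peaks too close to a record edge are dropped.
#'
#' @param ecg preprocessed ECG series.
#' @param rpeaks R-peak sample indices (1-based).
#' @param fs sampling rate (default 125).
#' @return matrix with `2*floor(0.12*fs/2) + 1` columns; attribute
#'   `rpeaks` holds the retained peak indices.
#' @export
extract_qrs <- function(ecg, rpeaks, fs = 125) {
  half <- floor(0.12 * fs / 2)
  keep <- rpeaks[rpeaks - half >= 1L & rpeaks + half <= length(ecg)]
  m <- t(vapply(keep, function(p) ecg[(p - half):(p + half)],
                numeric(2L * half + 1L)))
  if (length(keep) == 0L) m <- matrix(numeric(0), 0L, 2L * half + 1L)
  attr(m, "rpeaks") <- keep
  m
}

#' ECG-derived respiration at 1 Hz
#'
#' R-wave-area style EDR: for each beat the mean amplitude of its 120 ms
#' QRS window after subtracting the window's first/last-sample baseline,
#' linearly interpolated from beat times to a 1 Hz grid.
#'
#' @param ecg preprocessed ECG series.
#' @param rpeaks R-peak sample indices.
#' @param fs sampling rate.
#' @return numeric EDR series at 1 Hz spanning the record.
#' @export
derive_edr <- function(ecg, rpeaks, fs) {
  if (length(rpeaks) < 2L) stopf("derive_edr needs at least 2 R peaks")
  q <- extract_qrs(ecg, rpeaks, fs)
  keep <- attr(q, "rpeaks")
  if (length(keep) < 2L) stopf("too few interior QRS windows for EDR")
  ncol_ <- ncol(q)
  baseline <- (q[, 1L] + q[, ncol_]) / 2
  vals <- rowMeans(q) - baseline
  tbeat <- (keep - 1L) / fs
  tgrid <- seq(0, floor(length(ecg) / fs) - 1)
  stats::approx(tbeat, vals, xout = tgrid, rule = 2)$y
}
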