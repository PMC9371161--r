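# The 66-feature multi-domain battery: 12 SaO2, 10 airflow, 6 abdominal,
# 6 thoracic and 32 ECG features per segment.

.sao2_names <- c("med", "MM2", "kur", "var", "min", "mean", "NumZC", "comp",
                 "SD1", "Bel98", "Abo98", "mean_PSD0.016/0.05")
.airflow_names <- c("mean", "med", "std", "mean_PSD0/0.1", "mean_PSD0.4/0.5",
                    "mean_D1", "mean_D2", "mean_D3", "mean_A3", "comp")
.abd_names <- c("sum_abs", "std_abs", "mean", "mean_PSD80/100",
                "mean_D2", "mean_D1")
.thor_names <- c("sum", "med", "std", "mean", "var", "sum_PSD80/100")
.ecg_names <- c("NN50_RR", "SDSD_RR", "tSD_RR", "std_RR", "var", "kur",
                "mean_RR", "CV_EDR", "SS", "SD",
                paste0("entropy_D", 1:7), paste0("var_D", 1:7),
                "WSD_RR", "max_PSD0.03/0.5", "mean_PSD10/20",
                "mean_PSD80/100", "SCrC_3_RR", "SCrC_4_RR",
                "max_dia_kPCA", "RP_2_PC")

#' Canonical 66-feature name schema
#'
#' Family-prefixed feature names in their fixed order: 12 SaO2, 10
#' airflow, 6 abdominal, 6 thoracic and 32 ECG features.
#'
#' @return character vector of length 66.
#' @export
feature_schema <- function() {
  c(paste0("sao2.", .sao2_names),
    paste0("airflow.", .airflow_names),
    paste0("abd.", .abd_names),
    paste0("thor.", .thor_names),
    paste0("ecg.", .ecg_names))
}

# alternating local-extrema values of a series (plateaus collapsed,
# endpoints included)
local_extrema_values <- function(x) {
  r <- rle(x)$values
  n <- length(r)
  if (n < 3L) return(r)
  d <- sign(diff(r))
  keep <- c(TRUE, d[-1L] != d[-(n - 1L)], TRUE)
  r[keep]
}

#' SaO2 features (12)
#'
#' Median, count of adjacent local-extremum excursions larger than 2
#' percentage points (MM2), kurtosis (Pearson), variance, minimum, mean,
#' mean-crossing count, normalized Lempel-Ziv complexity, Poincare SD1,
#' seconds spent strictly below / at-or-above 98% of the window maximum
#' (Bel98 / Abo98), and the mean Yule-Walker PSD in 0.016-0.05 Hz.
#'
#' @param w cleaned SaO2 window at 1 Hz, length >= 10.
#' @return named numeric vector of 12 values.
#' @export
sao2_features <- function(w) {
  if (length(w) < 10L) stopf("SaO2 window shorter than 10 samples")
  assert_finite(w, "SaO2 window")
  ext <- local_extrema_values(w)
  thr <- 0.98 * max(w)
  psd <- yule_walker_psd(w, order = 5, fs = 1)
  vals <- c(
    stats::median(w),
    sum(abs(diff(ext)) > 2),
    pearson_kurtosis(w),
    stats::var(w),
    min(w),
    mean(w),
    zero_crossings(w),
    lz_complexity(w),
    poincare_sd1(w),
    sum(w < thr),
    sum(w >= thr),
    band_stat(psd, 0.016, 0.05, "mean")
  )
  stats::setNames(vals, paste0("sao2.", .sao2_names))
}

#' Airflow features (10)
#'
#' Time-domain statistics, Welch-PSD band means in 0-0.1 Hz and
#' 0.4-0.5 Hz (5-sample segments, 2 overlapped), db3 depth-3 wavelet
#' coefficient means, and normalized Lempel-Ziv complexity.
#'
#' @param w preprocessed airflow window at 1 Hz.
#' @return named numeric vector of 10 values.
#' @export
airflow_features <- function(w) {
  assert_finite(w, "airflow window")
  psd <- welch_psd(w, segment_len = 5, overlap = 2, fs = 1)
  ws <- wavelet_stats(w, "db3", 3)$stats
  m <- stats::setNames(ws$mean, ws$level)
  vals <- c(
    mean(w), stats::median(w), stats::sd(w),
    band_stat(psd, 0, 0.1, "mean"),
    band_stat(psd, 0.4, 0.5, "mean"),
    m[["D1"]], m[["D2"]], m[["D3"]], m[[paste0("A", nrow(ws) - 1L)]],
    lz_complexity(w)
  )
  stats::setNames(vals, paste0("airflow.", .airflow_names))
}

# Yule-Walker PSD shared by the two effort families: order 5, averaged
# over 40-sample segments; the 80-100 band is read under the
# normalized-band convention (uppermost fifth of the spectrum).
effort_psd <- function(w, fs = 10) {
  yule_walker_psd(w, order = 5, fs = fs, segment_len = 40)
}

#' Abdominal effort features (6)
#'
#' @param w preprocessed abdominal window at 10 Hz.
#' @param fs sampling rate (default 10).
#' @return named numeric vector of 6 values.
#' @export
abdominal_features <- function(w, fs = 10) {
  assert_finite(w, "abdominal window")
  psd <- effort_psd(w, fs)
  ws <- wavelet_stats(w, "db2", 2)$stats
  m <- stats::setNames(ws$mean, ws$level)
  vals <- c(
    sum(abs(w)), stats::sd(abs(w)), mean(w),
    band_stat(psd, 80, 100, "mean"),
    m[["D2"]], m[["D1"]]
  )
  stats::setNames(vals, paste0("abd.", .abd_names))
}

#' Thoracic effort features (6)
#'
#' @param w preprocessed thoracic window at 10 Hz.
#' @param fs sampling rate (default 10).
#' @return named numeric vector of 6 values.
#' @export
thoracic_features <- function(w, fs = 10) {
  assert_finite(w, "thoracic window")
  psd <- effort_psd(w, fs)
  vals <- c(
    sum(w), stats::median(w), stats::sd(w), mean(w), stats::var(w),
    band_stat(psd, 80, 100, "sum")
  )
  stats::setNames(vals, paste0("thor.", .thor_names))
}

#' ECG-block features (32)
#'
#' Heart-rate-variability statistics from the corrected RR intervals
#' (NN50 one-sided, SDSD, half-window SD difference, SD, mean, serial
#' correlations at lags 3 and 4, dominant RR frequency in 0.03-0.5 Hz,
#' wavelet spectral density), ECG-sample statistics and spectral shape
#' (variance, kurtosis, spectral spread/decrease, band means), sym3
#' depth-7 detail entropies and variances, EDR coefficient of variation,
#' and the kernel-PCA QRS morphology summary.
#'
#' Degenerate segments (< 2 RR intervals, < 3 QRS complexes) set the
#' affected features to 0 with a warning.
#'
#' @param ecg preprocessed ECG samples of the segment.
#' @param fs_ecg ECG sampling rate.
#' @param rr an `rr_series` restricted to the segment (times relative to
#'   the record; only intervals inside the segment).
#' @param edr EDR samples (1 Hz) of the segment.
#' @param qrs QRS matrix rows of the segment.
#' @param t0,t1 segment bounds in seconds (for the half-window split).
#' @return named numeric vector of 32 values.
#' @export
ecg_features <- function(ecg, fs_ecg, rr, edr, qrs, t0 = 0,
                         t1 = length(ecg) / fs_ecg) {
  assert_finite(ecg, "ECG window")
  iv <- rr$intervals_s
  ivt <- if (length(rr$times_s) > 1L) rr$times_s[-1L] else numeric(0)
  rr_ok <- length(iv) >= 2L
  if (!rr_ok) warnf("fewer than 2 RR intervals in segment: RR features set to 0")

  nn50 <- if (rr_ok) sum(diff(iv) > 0.05) else 0
  sdsd <- if (rr_ok && length(iv) >= 3L) stats::sd(diff(iv)) else 0
  mid <- (t0 + t1) / 2
  iv1 <- iv[ivt < mid]; iv2 <- iv[ivt >= mid]
  tsd <- if (length(iv1) >= 2L && length(iv2) >= 2L) {
    abs(stats::sd(iv1) - stats::sd(iv2))
  } else 0
  std_rr <- if (rr_ok) stats::sd(iv) else 0
  mean_rr <- if (rr_ok) mean(iv) else 0

  cv_edr <- if (length(edr) >= 2L && abs(mean(edr)) > 1e-12) {
    stats::sd(edr) / mean(edr)
  } else 0

  seg_len <- min(length(ecg), as.integer(2 * fs_ecg))
  psd_ecg <- welch_psd(ecg, segment_len = seg_len, overlap = seg_len %/% 2L,
                       fs = fs_ecg, nfft = 256)
  dec <- dwt_periodized(ecg, "sym3", 7)
  ent <- vapply(1:7, function(j) {
    if (j <= dec$level) shannon_entropy_coeffs(dec$details[[j]]) else 0
  }, numeric(1))
  vard <- vapply(1:7, function(j) {
    d <- if (j <= dec$level) dec$details[[j]] else numeric(0)
    if (length(d) > 1L) stats::var(d) else 0
  }, numeric(1))

  wsd_rr <- if (rr_ok && length(iv) >= 4L) {
    dd <- dwt_periodized(iv, "sym3", 7)
    sum(vapply(dd$details, function(d) sum(d^2), numeric(1))) / length(iv)
  } else 0

  max_psd_rr <- 0
  if (rr_ok) {
    grid <- seq(floor(t0), ceiling(t1) - 1)
    rr1 <- stats::approx(ivt, iv, xout = grid, rule = 2)$y
    if (stats::var(rr1) > 1e-18) {
      psd_rr <- welch_psd(rr1, segment_len = min(length(rr1), 30L),
                          overlap = min(length(rr1), 30L) %/% 2L,
                          fs = 1, nfft = 256)
      max_psd_rr <- band_stat(psd_rr, 0.03, 0.5, "argmax_freq")
    }
  }

  scrc3 <- if (rr_ok && length(iv) >= 6L && stats::sd(iv) > 0) {
    serial_corr(iv, 3L)
  } else 0
  scrc4 <- if (rr_ok && length(iv) >= 7L && stats::sd(iv) > 0) {
    serial_corr(iv, 4L)
  } else 0

  if (nrow(qrs) >= 3L) {
    kp <- kpca_qrs(qrs)
  } else {
    warnf("fewer than 3 QRS complexes in segment: kPCA features set to 0")
    kp <- c(max_dia_kpca = 0, rp_2_pc = 0)
  }

  vals <- c(nn50, sdsd, tsd, std_rr, stats::var(ecg), pearson_kurtosis(ecg),
            mean_rr, cv_edr, spectral_spread(psd_ecg),
            spectral_decrease(psd_ecg), ent, vard, wsd_rr, max_psd_rr,
            band_stat(psd_ecg, 10, 20, "mean"),
            band_stat(psd_ecg, 80, 100, "mean"),
            scrc3, scrc4, kp[["max_dia_kpca"]], kp[["rp_2_pc"]])
  stats::setNames(vals, paste0("ecg.", .ecg_names))
}

#' Extract the full 66-feature vector from a prepared segment
#'
#' Concatenates the five family extractors in schema order. The segment
#' must come from [segment_prepared()] so that all five preprocessed
#' channels and the derived RR / EDR / QRS slices are present.
#'
#' @param seg a `prepared_segment`.
#' @return named numeric vector of 66 features, plus attributes `label`
#'   and `patient_id`.
#' @export
extract_all <- function(seg) {
  stopifnot(inherits(seg, "prepared_segment"))
  out <- c(
    sao2_features(seg$sao2),
    airflow_features(seg$airflow),
    abdominal_features(seg$abdominal, fs = seg$fs_effort),
    thoracic_features(seg$thoracic, fs = seg$fs_effort),
    ecg_features(seg$ecg, seg$fs_ecg, seg$rr, seg$edr, seg$qrs,
                 t0 = seg$start_s, t1 = seg$end_s)
  )
  stopifnot(identical(names(out), feature_schema()))
  attr(out, "label") <- seg$label
  attr(out, "patient_id") <- seg$patient_id
  out
}
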