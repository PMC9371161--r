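# Seeded generator of five-channel synthetic PSG records with ground-truth
# apnea annotations. The generator reproduces the physiological signatures
# the feature battery targets: airflow amplitude collapse (to at most 10%
# of basal for at least 10 s), delayed SaO2 desaturation dips, attenuated
# (but persisting) respiratory effort, and cyclic RR lengthening during
# events with post-event shortening.

#' Synthetic cohort configuration
#'
#' @param n_patients number of records (default 40).
#' @param record_s record length in seconds (default 3600).
#' @param apnea_rate_per_h mean apnea events per hour (default 30).
#' @param apnea_duration_s event duration range in seconds (default 10-60;
#'   the clinical minimum of 10 s is enforced).
#' @param desat_depth SaO2 desaturation depth range in percentage points
#'   (default 3-10).
#' @param desat_delay_s circulation delay from apnea onset to the start of
#'   the desaturation (default 15 s).
#' @param airflow_reduction fraction of the basal airflow amplitude removed
#'   during events (default 0.9, i.e. collapse to 10% of basal).
#' @param breathing_freq_hz respiratory frequency (default 0.25 Hz).
#' @param rr_base_s basal RR interval (default 1.0 s).
#' @param noise per-channel additive Gaussian noise SDs.
#' @param sao2_spike_rate_per_h rate of oximeter spike artifacts (> 8-point
#'   jumps) per hour (default 6).
#' @param central if `TRUE`, effort collapses with airflow (central-apnea
#'   morphology); default `FALSE` (obstructive: effort persists attenuated
#'   and counter-phased).
#' @param seed integer master seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 40, record_s = 3600,
                             apnea_rate_per_h = 30,
                             apnea_duration_s = c(10, 60),
                             desat_depth = c(3, 10),
                             desat_delay_s = 15,
                             airflow_reduction = 0.9,
                             breathing_freq_hz = 0.25,
                             rr_base_s = 1.0,
                             noise = list(sao2 = 0.1, airflow = 0.05,
                                          effort = 0.05, ecg = 0.02),
                             sao2_spike_rate_per_h = 6,
                             central = FALSE,
                             seed = 1L) {
  if (record_s <= 0 || any(apnea_duration_s <= 0)) {
    stopf("durations must be positive")
  }
  if (apnea_duration_s[1] < 10) stopf("apnea durations must be >= 10 s")
  if (airflow_reduction <= 0 || airflow_reduction > 1) {
    stopf("airflow_reduction must lie in (0, 1]")
  }
  structure(list(n_patients = n_patients, record_s = record_s,
                 apnea_rate_per_h = apnea_rate_per_h,
                 apnea_duration_s = apnea_duration_s,
                 desat_depth = desat_depth, desat_delay_s = desat_delay_s,
                 airflow_reduction = airflow_reduction,
                 breathing_freq_hz = breathing_freq_hz,
                 rr_base_s = rr_base_s, noise = noise,
                 sao2_spike_rate_per_h = sao2_spike_rate_per_h,
                 central = central, seed = as.integer(seed)),
            class = "synthetic_config")
}

# smooth 0/1 event indicator sampled at times t, with raised-cosine
# transitions of width w seconds at each event edge
event_indicator <- function(t, events, w = 2) {
  ind <- numeric(length(t))
  for (i in seq_len(nrow(events))) {
    s <- events$start_s[i]; e <- events$end_s[i]
    ramp_in <- pmin(pmax((t - s) / w, 0), 1)
    ramp_out <- pmin(pmax((e - t) / w, 0), 1)
    ind <- pmax(ind, pmin(ramp_in, ramp_out))
  }
  ind
}

draw_events <- function(record_s, rate_per_h, dur_range, margin = 30,
                        max_tries = 200) {
  n_target <- stats::rpois(1, rate_per_h * record_s / 3600)
  # head margin (lead-in) and tail margin (desaturation recovery room),
  # shrunk proportionally for short records
  lead <- min(60, 0.1 * record_s)
  starts <- numeric(0); ends <- numeric(0)
  tries <- 0
  while (length(starts) < n_target && tries < max_tries * max(1, n_target)) {
    tries <- tries + 1
    d <- stats::runif(1, dur_range[1], dur_range[2])
    hi <- record_s - d - 2 * lead
    if (hi <= lead) next
    s <- stats::runif(1, lead, hi)
    if (all(s > ends + margin | s + d < starts - margin)) {
      starts <- c(starts, s); ends <- c(ends, s + d)
    }
  }
  o <- order(starts)
  data.frame(start_s = starts[o], end_s = ends[o])
}

#' Generate one synthetic PSG record
#'
#' @param config a `synthetic_config`.
#' @param patient_index 1-based patient index; determines the child seed.
#' @return list with `record` (a `psg_record`), `annotations` (apnea
#'   `event_annotations`) and `truth` (ground truth: R-peak times, events,
#'   programmed breathing frequency, basal SaO2).
#' @export
generate_record <- function(config, patient_index = 1L) {
  set.seed(child_seed(config$seed, patient_index))
  dur <- config$record_s
  fbr <- config$breathing_freq_hz

  # per-patient variability
  basal_sao2 <- stats::runif(1, 96, 98)
  rate_mult <- stats::runif(1, 0.7, 1.3)
  depth_lo <- config$desat_depth[1]
  depth_hi <- config$desat_depth[2]

  events <- draw_events(dur, config$apnea_rate_per_h * rate_mult,
                        config$apnea_duration_s)
  nev <- nrow(events)

  # ---- airflow (10 Hz): breathing sinusoid with collapsing envelope ----
  t10 <- (0:(dur * 10 - 1)) / 10
  ind10 <- event_indicator(t10, events)
  env_air <- 1 - config$airflow_reduction * ind10
  airflow <- env_air * sin(2 * pi * fbr * t10) +
    stats::rnorm(length(t10), 0, config$noise$airflow)

  # ---- effort (10 Hz): attenuated, phase-shifted analogues ----
  eff_drop <- if (config$central) config$airflow_reduction else 0.5
  env_eff <- 1 - eff_drop * ind10
  thoracic <- 0.8 * env_eff * sin(2 * pi * fbr * t10 + pi / 6) +
    stats::rnorm(length(t10), 0, config$noise$effort)
  # obstructive paradox: abdominal excursion counter-phases during events
  abd_phase <- if (config$central) pi / 6 else pi / 6 + pi * ind10
  abdominal <- 0.7 * env_eff * sin(2 * pi * fbr * t10 + abd_phase) +
    stats::rnorm(length(t10), 0, config$noise$effort)

  # ---- SaO2 (1 Hz): delayed desaturation ramps, exponential recovery ----
  t1 <- 0:(dur - 1)
  desat <- numeric(length(t1))
  if (nev > 0) {
    for (i in seq_len(nev)) {
      depth <- stats::runif(1, depth_lo, depth_hi)
      on <- events$start_s[i] + config$desat_delay_s
      off <- events$end_s[i] + config$desat_delay_s
      ramp <- pmin(pmax((t1 - on) / max(off - on, 1), 0), 1)
      rec <- ifelse(t1 > off, exp(-(t1 - off) / 15), 1)
      desat <- desat - depth * ramp * rec
    }
  }
  sao2 <- basal_sao2 + desat + stats::rnorm(length(t1), 0, config$noise$sao2)
  # oximeter spike artifacts (> 8-point jumps) on event-free samples
  nspk <- stats::rpois(1, config$sao2_spike_rate_per_h * dur / 3600)
  if (nspk > 0) {
    free <- which(event_indicator(t1, events) == 0 & t1 > 20 & t1 < dur - 20)
    if (length(free) >= nspk) {
      at <- sample(free, nspk)
      sao2[at] <- sao2[at] - stats::runif(nspk, 12, 25)
    }
  }
  sao2 <- round(pmin(pmax(sao2, 50), 100), 1)  # oximeter quantization

  # ---- RR / ECG (125 Hz) ----
  rtimes <- numeric(0)
  tcur <- stats::runif(1, 0, config$rr_base_s)
  brady <- function(tt) {
    if (nev == 0) return(0)
    b <- 0
    for (i in seq_len(nev)) {
      s <- events$start_s[i]; e <- events$end_s[i]
      if (tt >= s && tt < e) b <- b + 0.12 * (tt - s) / (e - s)
      if (tt >= e && tt < e + 10) b <- b - 0.08
    }
    b
  }
  while (tcur < dur) {
    rtimes <- c(rtimes, tcur)
    rr <- config$rr_base_s + 0.04 * sin(2 * pi * fbr * tcur) + brady(tcur) +
      stats::rnorm(1, 0, 0.01)
    tcur <- tcur + max(rr, 0.4)
  }
  n125 <- dur * 125L
  ecg <- numeric(n125)
  k <- -7:7
  tpl <- 1.2 * exp(-(k / 1.5)^2) -
    0.30 * exp(-((k - 3) / 1.5)^2) - 0.25 * exp(-((k + 3) / 1.5)^2)
  amp <- 1 + 0.15 * sin(2 * pi * fbr * rtimes)   # respiratory modulation
  for (i in seq_along(rtimes)) {
    c0 <- as.integer(round(rtimes[i] * 125)) + 1L
    lo <- c0 - 7L; hi <- c0 + 7L
    if (lo >= 1L && hi <= n125) ecg[lo:hi] <- ecg[lo:hi] + amp[i] * tpl
  }
  t125 <- (0:(n125 - 1)) / 125
  ecg <- ecg + 0.05 * sin(2 * pi * 0.05 * t125 + stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(n125, 0, config$noise$ecg)

  record <- psg_record(sprintf("synth%03d", patient_index), list(
    channel_series("sao2", 1, sao2, "%"),
    channel_series("airflow", 10, airflow, "a.u."),
    channel_series("thoracic", 10, thoracic, "a.u."),
    channel_series("abdominal", 10, abdominal, "a.u."),
    channel_series("ecg", 125, ecg, "mV")
  ))
  ann <- event_annotations(rep("apnea", nev), events$start_s, events$end_s)
  truth <- list(r_times_s = rtimes, events = events,
                breathing_freq_hz = fbr, basal_sao2 = basal_sao2)
  list(record = record, annotations = ann, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Child seeds are derived deterministically from the master seed, so the
#' same configuration reproduces the cohort bitwise.
#'
#' @param config a `synthetic_config`.
#' @return list of `n_patients` elements as returned by [generate_record()].
#' @export
generate_cohort <- function(config) {
  lapply(seq_len(config$n_patients), function(i) generate_record(config, i))
}

#' Simulate a feature-level cohort with known informative features
#'
#' Builds a feature table directly (no signals): the informative columns
#' carry a per-patient class-mean separation of `effect_sd` standard
#' deviations between apnea and normal segments, the remaining columns are
#' pure noise. Used to measure selection recovery.
#'
#' @param n_patients number of patients (default 40).
#' @param segments_per_class labelled segments per class per patient.
#' @param n_features total feature count (default 66).
#' @param informative indices of informative features (default 1:10).
#' @param effect_sd class separation in SD units (default 1).
#' @param seed integer seed.
#' @return data.frame with `patient_id`, `label` and feature columns
#'   `feat_01..`; attribute `informative` holds the informative names.
#' @export
simulate_feature_cohort <- function(n_patients = 40, segments_per_class = 30,
                                    n_features = 66, informative = 1:10,
                                    effect_sd = 1, seed = 1L) {
  set.seed(as.integer(seed))
  informative <- informative[informative <= n_features]
  fnames <- sprintf("feat_%02d", seq_len(n_features))
  rows <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    lab <- rep(c("apnea", "normal"), each = segments_per_class)
    X <- matrix(stats::rnorm(length(lab) * n_features), nrow = length(lab))
    if (length(informative) > 0L) {
      X[lab == "apnea", informative] <-
        X[lab == "apnea", informative] + effect_sd
    }
    df <- data.frame(patient_id = sprintf("p%03d", p), label = lab,
                     stringsAsFactors = FALSE)
    df[fnames] <- X
    rows[[p]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "informative") <- fnames[informative]
  out
}
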