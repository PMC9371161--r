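# Power spectral density estimators and band statistics.

new_psd <- function(freqs_hz, power, method, params) {
  structure(list(freqs_hz = freqs_hz, power = pmax(power, 0),
                 method = method, params = params),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> method=%s, %d bins, f in [%.4g, %.4g] Hz\n",
              x$method, length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz)))
  invisible(x)
}

flat_psd <- function(fs, nfft, method, params) {
  freqs <- seq(0, fs / 2, length.out = nfft %/% 2 + 1L)
  new_psd(freqs, rep(0, length(freqs)), method, params)
}

#' Yule-Walker autoregressive PSD estimate
#'
#' Fits an AR model by the autocorrelation (Yule-Walker) method and
#' evaluates its one-sided power spectral density on a regular grid. When
#' `segment_len` is given, the series is cut into consecutive
#' non-overlapping segments of that length and the per-segment spectra
#' are averaged.
#'
#' @param x numeric series.
#' @param order AR model order (default 5).
#' @param fs sampling rate in Hz.
#' @param nfft grid size; the PSD is returned on `nfft/2 + 1` frequencies.
#' @param segment_len optional segment length in samples.
#' @return a `psd_estimate` whose integral over frequency approximates the
#'   series variance.
#' @export
yule_walker_psd <- function(x, order = 5, fs, nfft = 256, segment_len = NULL) {
  params <- list(order = order, segment_len = segment_len, nfft = nfft)
  if (length(x) <= order) stopf("series length (%d) must exceed AR order (%d)",
                                length(x), order)
  if (!is.null(segment_len)) {
    nseg <- length(x) %/% segment_len
    if (nseg < 1L) {
      segs <- list(x)
    } else {
      segs <- lapply(seq_len(nseg), function(i) {
        x[((i - 1L) * segment_len + 1L):(i * segment_len)]
      })
    }
    psds <- lapply(segs, function(s) {
      if (length(s) <= order) NULL else ar_psd_one(s, order, fs, nfft, params)
    })
    psds <- Filter(Negate(is.null), psds)
    if (length(psds) == 0L) return(flat_psd(fs, nfft, "yule_walker", params))
    pw <- rowMeans(do.call(cbind, lapply(psds, `[[`, "power")))
    return(new_psd(psds[[1L]]$freqs_hz, pw, "yule_walker", params))
  }
  ar_psd_one(x, order, fs, nfft, params)
}

ar_psd_one <- function(x, order, fs, nfft, params) {
  if (stats::var(x) < 1e-24) {
    warnf("constant input to yule_walker_psd: returning flat near-zero PSD")
    return(flat_psd(fs, nfft, "yule_walker", params))
  }
  fit <- tryCatch(
    stats::ar(x, aic = FALSE, order.max = order, method = "yule-walker",
              demean = TRUE),
    error = function(e) NULL)
  if (is.null(fit)) {
    warnf("Yule-Walker fit failed: returning flat near-zero PSD")
    return(flat_psd(fs, nfft, "yule_walker", params))
  }
  a <- fit$ar
  sig2 <- fit$var.pred
  freqs <- seq(0, fs / 2, length.out = nfft %/% 2 + 1L)
  w <- 2 * pi * freqs / fs
  A <- 1 + 0i
  if (length(a) > 0) {
    A <- 1 - vapply(w, function(wk) sum(a * exp(-1i * wk * seq_along(a))),
                    complex(1))
  }
  # one-sided density: integrates to the process variance over [0, fs/2]
  p <- 2 * sig2 / fs / Mod(A)^2
  p[c(1L, length(p))] <- p[c(1L, length(p))] / 2
  new_psd(freqs, p, "yule_walker", params)
}

#' Welch averaged-periodogram PSD estimate
#'
#' Hann-windowed averaged periodogram with zero-padding to `nfft` for band
#' resolution. Segments advance by `segment_len - overlap` samples.
#'
#' @param x numeric series.
#' @param segment_len segment length in samples (default 5).
#' @param overlap overlapped samples between segments (default 2).
#' @param fs sampling rate in Hz.
#' @param nfft FFT length (zero-padded).
#' @return a `psd_estimate` on `nfft/2 + 1` frequencies.
#' @export
welch_psd <- function(x, segment_len = 5, overlap = 2, fs, nfft = 256) {
  n <- length(x)
  segment_len <- min(segment_len, n)
  if (overlap >= segment_len) overlap <- segment_len - 1L
  hop <- segment_len - overlap
  starts <- seq(1L, n - segment_len + 1L, by = hop)
  L <- segment_len
  w <- if (L == 1L) 1 else 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  U <- sum(w^2)
  if (U == 0) U <- 1
  nfft <- max(nfft, L)
  half <- nfft %/% 2 + 1L
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    X <- stats::fft(c(seg, numeric(nfft - L)))
    acc <- acc + (Mod(X[seq_len(half)])^2) / (fs * U)
  }
  p <- acc / length(starts)
  # fold negative frequencies into the interior bins (one-sided density)
  if (half > 2L) p[2L:(half - 1L)] <- 2 * p[2L:(half - 1L)]
  freqs <- (0:(half - 1L)) * fs / nfft
  new_psd(freqs, p, "welch",
          list(segment_len = segment_len, overlap = overlap, nfft = nfft))
}

#' Band statistic of a PSD estimate
#'
#' Computes a statistic of the PSD over `[lo_hz, hi_hz]`. Bands whose
#' upper edge exceeds the Nyquist frequency are reinterpreted under the
#' normalized-band convention: the printed edges are read as percentages
#' of Nyquist, e.g. an "80-100 Hz" band on a 10 Hz signal means the
#' uppermost fifth of the spectrum, `[0.80, 1.00] * fs/2`.
#'
#' @param psd a `psd_estimate`.
#' @param lo_hz,hi_hz band edges in Hz (or percent of Nyquist, see above).
#' @param stat one of `"mean"`, `"sum"`, `"argmax_freq"`.
#' @return the statistic; `argmax_freq` returns the frequency in Hz of the
#'   band's maximum power.
#' @export
band_stat <- function(psd, lo_hz, hi_hz, stat = c("mean", "sum", "argmax_freq")) {
  stat <- match.arg(stat)
  stopifnot(inherits(psd, "psd_estimate"), hi_hz > lo_hz)
  nyq <- max(psd$freqs_hz)
  if (hi_hz > nyq + 1e-9) {
    lo_hz <- lo_hz / 100 * nyq
    hi_hz <- hi_hz / 100 * nyq
  }
  sel <- which(psd$freqs_hz >= lo_hz - 1e-12 & psd$freqs_hz <= hi_hz + 1e-12)
  if (length(sel) == 0L) sel <- which.min(abs(psd$freqs_hz - (lo_hz + hi_hz) / 2))
  switch(stat,
    mean = mean(psd$power[sel]),
    sum = sum(psd$power[sel]),
    argmax_freq = psd$freqs_hz[sel[which.max(psd$power[sel])]]
  )
}

#' Spectral spread of a PSD
#'
#' Power-weighted standard deviation of frequency around the spectral
#' centroid. Zero-power spectra return 0.
#'
#' @param psd a `psd_estimate`.
#' @return spread in Hz.
#' @export
spectral_spread <- function(psd) {
  P <- psd$power
  tot <- sum(P)
  if (tot <= 0) return(0)
  centroid <- sum(psd$freqs_hz * P) / tot
  sqrt(sum((psd$freqs_hz - centroid)^2 * P) / tot)
}

#' Spectral decrease of a PSD
#'
#' Standard audio-descriptor spectral decrease:
#' `sum_{k>=2} (P_k - P_1)/(k-1) / sum_{k>=2} P_k` over the PSD bins.
#' Flat spectra return 0.
#'
#' @param psd a `psd_estimate`.
#' @return dimensionless decrease value.
#' @export
spectral_decrease <- function(psd) {
  P <- psd$power
  if (length(P) < 2L) return(0)
  k <- 2:length(P)
  denom <- sum(P[k])
  if (denom <= 0) return(0)
  sum((P[k] - P[1L]) / (k - 1)) / denom
}
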