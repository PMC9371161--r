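# Numerical primitives: LZ76, PSDs, wavelets, entropy, Poincare,
# spectral descriptors, serial correlation, kPCA, zero crossings.

test_that("LZ76 parser matches the exhaustive string-search oracle", {
  expect_equal(lz76_phrase_count(rep(1L, 20)), 1L)
  expect_equal(lz76_phrase_count(rep(c(0L, 1L), 10)),
               oracle_lz76(rep(c(0L, 1L), 10)))
  # random long strings
  set.seed(11)
  for (i in 1:20) {
    b <- sample(c(0L, 1L), 64, replace = TRUE)
    expect_equal(lz76_phrase_count(b), oracle_lz76(b))
  }
})

test_that("normalized complexity ranks random above periodic", {
  set.seed(5)
  # balanced draw so the median binarization threshold is informative
  r <- sample(rep(c(-1, 1), each = 256))
  p <- rep(c(-1, 1), 256)
  expect_gt(lz_complexity(r), lz_complexity(p))
  # constant series binarizes to all ones: minimum phrase count, no error
  expect_equal(lz_complexity(rep(3.2, 32)), 1 * log2(32) / 32)
})

test_that("Yule-Walker PSD recovers an AR(1) spectrum and its variance", {
  set.seed(2)
  n <- 4096
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
  p <- yule_walker_psd(x, order = 5, fs = 1, nfft = 256)
  w <- 2 * pi * p$freqs_hz
  truth <- 2 / Mod(1 - 0.9 * exp(-1i * w))^2
  truth[c(1, length(truth))] <- truth[c(1, length(truth))] / 2
  rel_l2 <- sqrt(sum((p$power - truth)^2) / sum(truth^2))
  expect_lt(rel_l2, 0.1)
  # Parseval-type check by trapezoidal integration
  ip <- sum(diff(p$freqs_hz) * (p$power[-1] + p$power[-length(p$power)]) / 2)
  expect_lt(abs(ip - var(x)) / var(x), 0.1)
})

test_that("AR(5) fit to white noise is nearly flat", {
  set.seed(3)
  x <- rnorm(4096)
  p <- yule_walker_psd(x, order = 5, fs = 1, nfft = 256)
  expect_lt(max(p$power) / min(p$power), 10)
})

test_that("constant input to yule_walker_psd degrades gracefully", {
  expect_warning(p <- yule_walker_psd(rep(2, 100), 5, fs = 1), "constant")
  expect_true(all(p$power >= 0) && all(p$power < 1e-6))
})

test_that("Welch PSD localizes tones and has the declared grid", {
  fs <- 1
  t <- 0:599
  x <- sin(2 * pi * 0.25 * t)
  p <- welch_psd(x, segment_len = 60, overlap = 30, fs = fs, nfft = 256)
  expect_length(p$power, 129)
  peak <- p$freqs_hz[which.max(p$power)]
  expect_lt(abs(peak - 0.25), fs / 256 + 1e-12)
  # constant signal: the 5-sample Hann taper has its first spectral null
  # at 2 fs / L = 0.4 Hz, so the power concentrates in that mainlobe
  # around DC rather than in a single bin
  pc <- welch_psd(rep(4, 100), 5, 2, fs = 1, nfft = 256)
  lobe <- pc$freqs_hz <= 0.4
  expect_gt(sum(pc$power[lobe]), 0.95 * sum(pc$power))
  expect_lt(pc$freqs_hz[which.max(pc$power)], 0.05)
})

test_that("band_stat statistics and normalized-band convention", {
  p <- welch_psd(rep(1, 50) + sin(2 * pi * 0.3 * (0:49)), 25, 12, fs = 1)
  expect_gte(band_stat(p, 0, 0.5, "sum"), band_stat(p, 0.2, 0.4, "sum"))
  # constructed spike
  spike <- structure(list(freqs_hz = seq(0, 0.5, by = 0.01),
                          power = rep(0, 51), method = "welch", params = NULL),
                     class = "psd_estimate")
  spike$power[31] <- 5  # 0.30 Hz
  expect_equal(band_stat(spike, 0.03, 0.5, "argmax_freq"), 0.3)
  # flat PSD: mean over any band is the flat value
  flat <- spike; flat$power <- rep(2, 51)
  expect_equal(band_stat(flat, 0.1, 0.4, "mean"), 2)
  # 80-100 band on a 10 Hz channel reads as [4, 5] Hz
  f10 <- structure(list(freqs_hz = seq(0, 5, by = 0.1),
                        power = c(rep(0, 40), rep(3, 11)),
                        method = "welch", params = NULL),
                   class = "psd_estimate")
  expect_equal(band_stat(f10, 80, 100, "mean"), 3)
})

test_that("wavelet decompositions conserve energy and kill constants", {
  set.seed(7)
  x <- rnorm(512)
  for (spec in list(c("db3", 3), c("db2", 2), c("sym3", 7))) {
    d <- dwt_periodized(x, spec[1], as.integer(spec[2]))
    e <- sum(vapply(d$details, function(v) sum(v^2), numeric(1))) +
      sum(d$approximation^2)
    expect_lt(abs(e - sum(x^2)) / sum(x^2), 1e-8)
    expect_equal(d$level, as.integer(spec[2]))
  }
  ws <- wavelet_stats(rep(5, 64), "db3", 3)$stats
  det <- ws[ws$level != "A3", ]
  expect_true(all(abs(det$mean) < 1e-8))
  expect_true(all(det$energy < 1e-8))
})

test_that("Shannon entropy analytic cases and bounds", {
  expect_equal(shannon_entropy_coeffs(c(0, 0, 3, 0)), 0)
  expect_equal(shannon_entropy_coeffs(rep(2, 16)), 4)
  expect_equal(shannon_entropy_coeffs(rep(-1, 8)), 3)  # sign-free
  set.seed(9)
  for (i in 1:10) {
    c0 <- rnorm(32)
    h <- shannon_entropy_coeffs(c0)
    expect_gte(h, 0)
    expect_lte(h, log2(32))
  }
})

test_that("Poincare SD1 equals its closed form", {
  expect_equal(poincare_sd1(rep(2, 30)), 0)
  ab <- rep(c(1, 4), 10)
  expect_equal(poincare_sd1(ab), oracle_sd1(ab))
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(50)
    expect_equal(poincare_sd1(x), oracle_sd1(x), tolerance = 1e-12)
  }
})

test_that("spectral spread and decrease behave on constructed spectra", {
  one <- structure(list(freqs_hz = c(0, 1, 2), power = c(0, 5, 0),
                        method = "welch", params = NULL),
                   class = "psd_estimate")
  expect_equal(spectral_spread(one), 0)
  flat <- one; flat$power <- rep(3, 3)
  expect_equal(spectral_decrease(flat), 0)
  two <- one; two$power <- c(0, 4, 4); two$freqs_hz <- c(0, 1, 3)
  expect_equal(spectral_spread(two), 1)  # |f2 - f1| / 2
})

test_that("serial correlation matches brute-force Pearson on shifted pairs", {
  set.seed(17)
  x <- rnorm(100)
  for (lag in c(1, 3, 4)) {
    a <- x[1:(100 - lag)]
    b <- x[(lag + 1):100]
    expect_equal(serial_corr(x, lag), oracle_pearson(a, b), tolerance = 1e-12)
  }
  expect_equal(serial_corr(x, 0), 1)
  expect_warning(v <- serial_corr(rep(1, 50), 3), "degenerate")
  expect_equal(v, 0)
})

test_that("zero crossings match the brute-force sign scan", {
  expect_equal(zero_crossings(rep(7, 20)), 0L)
  s <- sin(2 * pi * (0:19) / 20)
  expect_equal(zero_crossings(s), 2L)
  set.seed(19)
  for (i in 1:20) {
    x <- rnorm(40)
    expect_equal(zero_crossings(x), oracle_zero_crossings(x))
  }
})

test_that("kernel PCA of QRS rows is degenerate-safe and normalized", {
  set.seed(23)
  q <- matrix(rnorm(40 * 15), 40)
  kp <- kpca_qrs(q)
  expect_gt(kp[["max_dia_kpca"]], 0)
  expect_gte(kp[["rp_2_pc"]], 0)
  expect_lte(kp[["rp_2_pc"]], 1)
  same <- matrix(rep(rnorm(15), each = 5), 5)
  kps <- kpca_qrs(same)
  expect_equal(unname(kps), c(0, 0))
  expect_error(kpca_qrs(q[1:2, ]), "at least 3")
})

test_that("zero-phase filtering is exactly time-reversal symmetric", {
  set.seed(29)
  x <- rnorm(600)
  for (args in list(list(fs = 10, order = 3, hi = 3, type = "low"),
                    list(fs = 10, order = 3, lo = 0.05, hi = 4, type = "pass"),
                    list(fs = 125, order = 3, lo = 0.05, hi = 40,
                         type = "pass"))) {
    y1 <- do.call(zero_phase_butter, c(list(x = x), args))
    y2 <- rev(do.call(zero_phase_butter, c(list(x = rev(x)), args)))
    expect_lt(max(abs(y1 - y2)), 1e-8)
  }
})

test_that("analytic Butterworth gain matches the signal-package design", {
  skip_if_not_installed("signal")
  # moderate cutoffs where the transfer-function form is well conditioned
  bt <- signal::butter(3, 3 / 5, type = "low")
  f <- c(0.25, 1, 2.5, 4)
  h <- vapply(f, function(fi) {
    w <- 2 * pi * fi / 10
    Mod(sum(bt$b * exp(-1i * w * (seq_along(bt$b) - 1))) /
          sum(bt$a * exp(-1i * w * (seq_along(bt$a) - 1))))^2
  }, numeric(1))
  mine <- butter_gain_sq(f, 10, 3, hi = 3, type = "low")
  expect_equal(mine, h^2, tolerance = 1e-6)
})
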