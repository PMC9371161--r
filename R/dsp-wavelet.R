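# Orthogonal discrete wavelet transform with periodized boundary handling.
#
# Scaling (low-pass reconstruction) filters of the orthonormal Daubechies
# family. Symlets of order 3 coincide with Daubechies 3; symlets only
# depart from the extremal-phase Daubechies filters at order >= 4.
.wavelet_filters <- list(
  db2 = c(0.482962913144690, 0.836516303737469,
          0.224143868041857, -0.129409522550921),
  db3 = c(0.332670552950957, 0.806891509313339, 0.459877502119331,
          -0.135011020010391, -0.085441273882241, 0.035226291882101)
)
.wavelet_filters$sym3 <- .wavelet_filters$db3

wavelet_filter <- function(wavelet) {
  h <- .wavelet_filters[[wavelet]]
  if (is.null(h)) stopf("unknown wavelet '%s' (available: %s)", wavelet,
                        paste(names(.wavelet_filters), collapse = ", "))
  h
}

# One analysis step by circular (periodized) convolution. Odd-length
# inputs are extended by one repeated sample; exact energy conservation
# therefore requires even lengths at every level.
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  if (n %% 2L == 1L) {
    x <- c(x, x[n])
    n <- n + 1L
  }
  L <- length(lo)
  idx <- (outer(seq(0L, n - 2L, by = 2L), 0:(L - 1L), `+`) %% n) + 1L
  xm <- matrix(x[idx], nrow = n %/% 2L)
  list(a = as.numeric(xm %*% lo), d = as.numeric(xm %*% hi))
}

#' Multilevel periodized discrete wavelet transform
#'
#' Orthonormal DWT with periodization padding. For even lengths at every
#' level the transform is orthogonal, so the summed squared coefficients
#' equal the summed squared input samples (Parseval).
#'
#' @param x numeric series.
#' @param wavelet `"db2"`, `"db3"` or `"sym3"` (identical to `"db3"`).
#' @param level decomposition depth; capped at `floor(log2(length(x)))`.
#' @return object of class `wavelet_decomposition` with detail coefficient
#'   arrays `D1..Dk` (fine to coarse) and approximation `Ak`.
#' @export
dwt_periodized <- function(x, wavelet, level) {
  assert_finite(x, "series")
  n <- length(x)
  if (n < 2L) stopf("series too short for wavelet decomposition")
  level <- min(level, max(1L, floor(log2(n))))
  h <- wavelet_filter(wavelet)
  L <- length(h)
  lo <- rev(h)                                  # analysis low-pass
  hi <- h * (-1)^(seq_len(L) - 1L)              # analysis high-pass (QMF)
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    st <- dwt_step(a, lo, hi)
    details[[j]] <- st$d
    a <- st$a
  }
  names(details) <- paste0("D", seq_len(level))
  structure(list(wavelet = wavelet, level = level,
                 details = details, approximation = a),
            class = "wavelet_decomposition")
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("<wavelet_decomposition> %s, %d levels; detail lengths: %s\n",
              x$wavelet, x$level,
              paste(lengths(x$details), collapse = ", ")))
  invisible(x)
}

#' Per-level wavelet coefficient statistics
#'
#' Decomposes `x` and returns mean, variance and energy (sum of squares)
#' of every detail level and of the final approximation.
#'
#' @inheritParams dwt_periodized
#' @return list with the `wavelet_decomposition` and a data frame `stats`
#'   with one row per coefficient array (`D1..Dk`, `Ak`).
#' @export
wavelet_stats <- function(x, wavelet, level) {
  dec <- dwt_periodized(x, wavelet, level)
  arrs <- c(dec$details, stats::setNames(list(dec$approximation),
                                         paste0("A", dec$level)))
  tab <- data.frame(
    level = names(arrs),
    mean = vapply(arrs, mean, numeric(1)),
    variance = vapply(arrs, function(v) if (length(v) > 1L) stats::var(v) else 0,
                      numeric(1)),
    energy = vapply(arrs, function(v) sum(v^2), numeric(1)),
    row.names = NULL
  )
  list(decomposition = dec, stats = tab)
}

#' Shannon entropy of a coefficient array
#'
#' Normalizes squared coefficients to a probability distribution
#' `p_i = c_i^2 / sum(c^2)` and returns `-sum(p log2 p)` in bits, with
#' `0 log 0 = 0`. An all-zero array returns 0.
#'
#' @param coeffs numeric coefficients.
#' @return entropy in bits, in `[0, log2(length(coeffs))]`.
#' @export
shannon_entropy_coeffs <- function(coeffs) {
  e <- coeffs^2
  tot <- sum(e)
  if (tot <= 0) return(0)
  p <- e / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}
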