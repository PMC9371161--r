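# Small numerical operators: Poincare SD1, serial correlation,
# zero crossings, kernel PCA of QRS morphology.

#' Poincare SD1 short-term variability
#'
#' Dispersion perpendicular to the identity line of the lag-1 return map:
#' `SD1 = sqrt(Var(d) / 2)` with `d` the successive differences and the
#' population variance.
#'
#' @param x numeric series.
#' @return nonnegative SD1, 0 for constant or length-1 input.
#' @export
poincare_sd1 <- function(x) {
  if (length(x) < 2L) return(0)
  d <- diff(x)
  sqrt(pop_var(d) / 2)
}

#' Serial correlation coefficient at a given lag
#'
#' Pearson correlation of the pairs `(x_t, x_{t+lag})`. Degenerate cases
#' (constant series, too few pairs) return 0 with a warning.
#'
#' @param x numeric series.
#' @param lag nonnegative integer lag.
#' @return correlation in `[-1, 1]`.
#' @export
serial_corr <- function(x, lag) {
  stopifnot(lag >= 0)
  if (lag == 0L) return(1)
  n <- length(x)
  if (n - lag < 3L) {
    warnf("serial_corr: too few pairs at lag %d; returning 0", lag)
    return(0)
  }
  a <- x[seq_len(n - lag)]
  b <- x[(lag + 1L):n]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warnf("serial_corr: degenerate (constant) series; returning 0")
    return(0)
  }
  stats::cor(a, b)
}

#' Mean-crossing count
#'
#' Counts strict sign changes of `x - mean(x)`. Exact zeros inherit the
#' previous sign, so touching the mean without crossing does not count.
#'
#' @param x numeric series.
#' @return integer crossing count.
#' @export
zero_crossings <- function(x) {
  s <- sign(x - mean(x))
  # zeros inherit the previous sign
  for (i in seq_along(s)) {
    if (s[i] == 0) s[i] <- if (i > 1L) s[i - 1L] else 0
  }
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

#' Kernel PCA summary of a QRS morphology matrix
#'
#' RBF-kernel principal component analysis of the beat-by-beat QRS
#' matrix: kernel bandwidth set by the median heuristic (median pairwise
#' Euclidean distance), kernel matrix double-centred, eigenvalues sorted
#' descending with negatives clipped at zero and scaled by the row count.
#'
#' @param q numeric matrix, rows = QRS complexes (>= 3).
#' @return named numeric vector: `max_dia_kpca` (largest eigenvalue) and
#'   `rp_2_pc` (relative power of the second component, in `[0, 1]`).
#'   Degenerate input (identical rows) returns zeros.
#' @export
kpca_qrs <- function(q) {
  q <- as.matrix(q)
  n <- nrow(q)
  if (n < 3L) stopf("kpca_qrs needs at least 3 QRS complexes (got %d)", n)
  D <- as.matrix(stats::dist(q))
  h <- stats::median(D[upper.tri(D)])
  if (!is.finite(h) || h <= 0) {
    return(c(max_dia_kpca = 0, rp_2_pc = 0))
  }
  K <- exp(-D^2 / (2 * h^2))
  # double centring
  rm <- rowMeans(K)
  Kc <- K - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(K)
  ev <- eigen(Kc, symmetric = TRUE, only.values = TRUE)$values / n
  ev <- pmax(ev, 0)
  tot <- sum(ev)
  if (tot <= 1e-15) return(c(max_dia_kpca = 0, rp_2_pc = 0))
  c(max_dia_kpca = ev[1L], rp_2_pc = ev[2L] / tot)
}
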