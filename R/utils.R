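# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' @keywords internal
is_numeric_vec <- function(x) is.numeric(x) && length(x) > 0L

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(x)
}

#' Centred running median with edge replication
#'
#' The first and last half-window are computed on an edge-replicated
#' extension of the series, so the output has the same length as the input.
#'
#' @param x numeric vector.
#' @param k window length in samples; forced odd by adding one if even.
#' @return numeric vector of running medians, same length as `x`.
#' @keywords internal
running_median <- function(x, k) {
  n <- length(x)
  if (k >= n) return(rep(stats::median(x), n))
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[n], h))
  out <- stats::runmed(xp, k, endrule = "keep")
  as.numeric(out[(h + 1L):(h + n)])
}

# population variance and Pearson (non-excess) kurtosis
pop_var <- function(x) mean((x - mean(x))^2)

pearson_kurtosis <- function(x) {
  m2 <- pop_var(x)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^4) / m2^2
}

# deterministic 32-bit child seed derivation
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(index) * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
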