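#' Lempel-Ziv (LZ76) phrase count of a symbol sequence
#'
#' Parses the sequence left to right into phrases: the current phrase is
#' grown while it can still be reproduced as a substring of the text seen
#' so far (overlap with the phrase itself allowed), and is closed at the
#' first symbol that makes it novel. A trailing suffix that remains
#' reproducible to the end of the sequence does not open a new phrase, so
#' a constant sequence has a phrase count of 1.
#'
#' @param s integer/logical/character vector of symbols.
#' @return integer phrase count.
#' @export
lz76_phrase_count <- function(s) {
  n <- length(s)
  if (n == 0L) return(0L)
  s <- as.integer(factor(s))
  cnt <- 0L
  i <- 1L
  while (i <= n) {
    # Grow the reproducible prefix of the phrase starting at i. A valid
    # occurrence must start at or before i-1 but may overlap the phrase.
    P <- seq_len(i - 1L)  # starts matching the empty prefix
    len <- 0L
    repeat {
      if (i + len > n) {
        # phrase reproducible through the end of the sequence: no new phrase
        return(cnt)
      }
      P <- P[s[P + len] == s[i + len]]
      if (length(P) == 0L) {
        # s[i .. i+len] is novel; close the phrase here
        cnt <- cnt + 1L
        i <- i + len + 1L
        break
      }
      len <- len + 1L
    }
  }
  cnt
}

#' Normalized Lempel-Ziv complexity of a real-valued window
#'
#' Binarizes the window at its median (values at or above the median map
#' to 1), counts LZ76 phrases, and normalizes by `c(n) * log2(n) / n` so
#' windows of different lengths are comparable. A constant window
#' binarizes to all ones and yields the minimum phrase count.
#'
#' @param x numeric vector, length >= 2.
#' @return nonnegative normalized complexity.
#' @export
lz_complexity <- function(x) {
  n <- length(x)
  if (n < 2L) stopf("lz_complexity needs at least 2 samples")
  assert_finite(x, "series")
  bits <- as.integer(x >= stats::median(x))
  lz76_phrase_count(bits) * log2(n) / n
}
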