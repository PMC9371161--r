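# Independent oracles: deliberately different mechanics from the package
# implementations they check.

# LZ76 phrase count by exhaustive string search: grow the phrase while it
# occurs (as a plain substring, overlap allowed) in the text up to the
# character before the phrase end; a trailing reproducible suffix adds no
# phrase.
oracle_lz76 <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  if (n == 0L) return(0L)
  cnt <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    repeat {
      if (j > n) return(cnt)  # reproducible through the end
      phrase <- substr(s, i, j)
      hist <- substr(s, 1L, j - 1L)
      if (!grepl(phrase, hist, fixed = TRUE)) {
        cnt <- cnt + 1L
        i <- j + 1L
        break
      }
      j <- j + 1L
    }
  }
  cnt
}

# AUC as the Mann-Whitney pairwise comparison statistic
oracle_auc <- function(truth, scores, positive = "apnea") {
  sp <- scores[truth == positive]
  sn <- scores[truth != positive]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# brute-force scans
oracle_nn50 <- function(iv) {
  cnt <- 0L
  for (i in seq_len(length(iv) - 1L)) {
    if (iv[i + 1L] - iv[i] > 0.05) cnt <- cnt + 1L
  }
  cnt
}

oracle_zero_crossings <- function(x) {
  s <- x - mean(x)
  cnt <- 0L
  prev <- 0
  for (v in s) {
    sg <- sign(v)
    if (sg == 0) sg <- prev
    if (prev != 0 && sg != 0 && sg != prev) cnt <- cnt + 1L
    if (sg != 0) prev <- sg
  }
  cnt
}

oracle_sd1 <- function(x) {
  d <- diff(x)
  sqrt(0.5 * mean((d - mean(d))^2))
}

oracle_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# small cached synthetic cohort shared across test files
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- synthetic_config(n_patients = 2, record_s = 600, seed = 101)
    .fixture_env$small <- generate_cohort(cfg)
  }
  .fixture_env$small
}

small_prepared <- function() {
  if (is.null(.fixture_env$prep)) {
    el <- small_cohort()[[1]]
    .fixture_env$prep <- prepare_record(el$record)
  }
  .fixture_env$prep
}

default_cohort <- function() {
  if (is.null(.fixture_env$default)) {
    .fixture_env$default <- generate_cohort(synthetic_config(seed = 1))
  }
  .fixture_env$default
}

small_segments <- function() {
  if (is.null(.fixture_env$segs)) {
    el <- small_cohort()[[1]]
    .fixture_env$segs <- segment_prepared(small_prepared(), el$annotations,
                                          "windows")
  }
  .fixture_env$segs
}
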