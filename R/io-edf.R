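# Minimal European Data Format (EDF) reader/writer for whole-second,
# integer-rate multi-channel records: 16-bit samples, one-second data
# records, ASCII headers. Covers the subset needed to exchange PSG
# signals; no EDF+ annotations.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  sprintf(paste0("%-", width, "s"), s)
}

#' Write a PSG record to an EDF file
#'
#' Samples are scaled to the full 16-bit digital range per channel. All
#' channel rates must be whole numbers per second; the record is truncated
#' to a whole number of seconds.
#'
#' @param record a `psg_record`.
#' @param path output path.
#' @export
write_edf <- function(record, path) {
  chans <- record$channels
  ns <- length(chans)
  fs <- vapply(chans, `[[`, numeric(1), "fs")
  if (any(abs(fs - round(fs)) > 1e-9)) stopf("EDF writer needs integer Hz rates")
  fs <- as.integer(round(fs))
  nrec <- min(vapply(chans, function(ch) length(ch$samples) %/% ch$fs,
                     numeric(1)))
  if (nrec < 1) stopf("record shorter than one second")

  pmin_ <- pmax_ <- numeric(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- chans[[i]]$samples[seq_len(nrec * fs[i])]
    lo <- min(x); hi <- max(x)
    if (hi - lo < 1e-12) { hi <- lo + 1 }
    pmin_[i] <- lo; pmax_[i] <- hi
    dig[[i]] <- as.integer(round((x - lo) / (hi - lo) * 65535 - 32768))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field(record$patient_id, 80),
    pad_field("synthetic PSG", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8), pad_field("", 44),
    pad_field(nrec, 8), pad_field(1, 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) {
    writeChar(paste(vapply(vals, pad_field, character(1), width),
                    collapse = ""), con, eos = NULL)
  }
  fld(names(chans), 16)                                   # labels
  fld(rep("", ns), 80)                                    # transducer
  fld(vapply(chans, `[[`, character(1), "units"), 8)      # dimension
  fld(sprintf("%g", pmin_), 8)
  fld(sprintf("%g", pmax_), 8)
  fld(rep("-32768", ns), 8)
  fld(rep("32767", ns), 8)
  fld(rep("", ns), 80)                                    # prefiltering
  fld(fs, 8)                                              # samples per record
  fld(rep("", ns), 32)                                    # reserved

  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * fs[i] + 1L):(r * fs[i])
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a PSG record
#'
#' Signal labels must map onto the canonical channel names (`sao2`,
#' `airflow`, `thoracic`, `abdominal`, `ecg`), optionally via
#' `label_map`.
#'
#' @param path EDF file path.
#' @param label_map optional named character vector mapping file labels to
#'   canonical channel names.
#' @return a `psg_record` with rates and physical scaling restored.
#' @export
read_edf <- function(path, label_map = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width, n = 1L) {
    trimws(vapply(seq_len(n), function(i) readChar(con, width), character(1)))
  }
  rd(8); patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- rd(16, ns); rd(80, ns)
  units <- rd(8, ns)
  pmin_ <- as.numeric(rd(8, ns)); pmax_ <- as.numeric(rd(8, ns))
  dmin_ <- as.numeric(rd(8, ns)); dmax_ <- as.numeric(rd(8, ns))
  rd(80, ns)
  spr <- as.integer(rd(8, ns))
  rd(32, ns)

  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- integer(nrec * spr[i])
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2L, endian = "little",
                   signed = TRUE)
      raw[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- v
    }
  }
  if (!is.null(label_map)) {
    mapped <- label_map[labels]
    labels <- ifelse(is.na(mapped), labels, mapped)
  }
  unknown <- setdiff(labels, names(CANONICAL_CHANNELS))
  if (length(unknown) > 0L) {
    stopf("unknown EDF signal label(s) %s; available canonical names: %s",
          paste(unknown, collapse = ", "),
          paste(names(CANONICAL_CHANNELS), collapse = ", "))
  }
  channels <- lapply(seq_len(ns), function(i) {
    phys <- (raw[[i]] - dmin_[i]) * (pmax_[i] - pmin_[i]) /
      (dmax_[i] - dmin_[i]) + pmin_[i]
    channel_series(labels[i], fs = spr[i] / recdur, samples = phys,
                   units = units[i])
  })
  psg_record(patient, channels)
}
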