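# Minimal EDF/EDF+ support: fixed-width ASCII header, 16-bit little-endian
# samples, per-signal physical/digital scaling. Covers the subset produced by
# clinical EEG exports (all signals at one rate); annotations channels are
# dropped on read.

edf_field <- function(con, width) trimws(readChar(con, width, useBytes = TRUE))

#' Read an EDF/EDF+ file
#'
#' @param path file path.
#' @return List with `data` (channels x samples matrix in physical units),
#'   `fs` (Hz), `labels`, and `header` (record count and duration).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ver <- edf_field(con, 8)
  if (ver != "0") stop("not an EDF file (version field '", ver, "')")
  patient <- edf_field(con, 80); recording_id <- edf_field(con, 80)
  startdate <- edf_field(con, 8); starttime <- edf_field(con, 8)
  header_bytes <- as.integer(edf_field(con, 8))
  reserved <- edf_field(con, 44)
  n_records <- as.integer(edf_field(con, 8))
  record_dur <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header: signal count")
  rd <- function(w) vapply(seq_len(ns), function(i) edf_field(con, w), character(1))
  labels <- rd(16); transducer <- rd(80); phys_dim <- rd(8)
  phys_min <- as.numeric(rd(8)); phys_max <- as.numeric(rd(8))
  dig_min <- as.numeric(rd(8)); dig_max <- as.numeric(rd(8))
  prefilter <- rd(80); spr <- as.integer(rd(8)); rd(32)
  if (anyNA(spr) || anyNA(phys_min) || anyNA(dig_min))
    stop("malformed EDF signal headers")
  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  if (sum(keep) < 1L) stop("EDF file holds no signal channels")
  if (length(unique(spr[keep])) != 1L)
    stop("EDF signals have differing sampling rates; not supported")
  raw <- readBin(con, "integer", n = n_records * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_records * sum(spr)) stop("EDF data truncated")
  out <- matrix(0, nrow = sum(keep), ncol = n_records * spr[keep][1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offs <- phys_min - gain * dig_min
  pos <- 0L
  col0 <- 0L
  for (r in seq_len(n_records)) {
    row <- 0L
    for (s in seq_len(ns)) {
      block <- raw[(pos + 1L):(pos + spr[s])]
      pos <- pos + spr[s]
      if (keep[s]) {
        row <- row + 1L
        out[row, (col0 + 1L):(col0 + spr[s])] <- gain[s] * block + offs[s]
      }
    }
    col0 <- col0 + spr[keep][1]
  }
  list(data = out, fs = spr[keep][1] / record_dur, labels = labels[keep],
       header = list(patient = patient, recording = recording_id,
                     startdate = startdate, starttime = starttime,
                     n_records = n_records, record_duration = record_dur))
}

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

#' Write a recording to EDF
#'
#' Writes 16-bit EDF with one-second data records and a symmetric physical
#' range wide enough for the data. Round-trip companion of [read_edf()],
#' also used to emit synthetic recordings in a clinically portable format.
#'
#' @param rec a [recording()]; `fs` must be a whole number of samples per
#'   second and the duration a whole number of seconds (trailing samples are
#'   dropped with a warning otherwise).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF export needs an integer sampling rate")
  n_rec <- floor(n_samples(rec) / fs)
  if (n_rec < 1L) stop("recording shorter than one EDF record (1 s)")
  if (n_rec * fs != n_samples(rec))
    warning("dropping trailing partial second for EDF export")
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  ns <- nrow(x)
  pmax_ <- max(1e-6, max(abs(x)))
  dig_min <- -32768; dig_max <- 32767
  gain <- (2 * pmax_) / (dig_max - dig_min)
  digi <- round((x + pmax_) / gain + dig_min)
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(s, width) writeChar(edf_pad(s, width), con, eos = NULL)
  w("0", 8); w(rec$subject_id, 80); w("rsbagging synthetic/export", 80)
  w("01.01.26", 8); w("00.00.00", 8)
  w(256L + 256L * ns, 8); w("", 44); w(n_rec, 8); w("1", 8); w(ns, 4)
  for (l in rec$channel_labels) w(l, 16)
  for (i in seq_len(ns)) w("", 80)
  for (i in seq_len(ns)) w("uV", 8)
  for (i in seq_len(ns)) w(formatC(-pmax_, format = "g", digits = 6), 8)
  for (i in seq_len(ns)) w(formatC(pmax_, format = "g", digits = 6), 8)
  for (i in seq_len(ns)) w(dig_min, 8)
  for (i in seq_len(ns)) w(dig_max, 8)
  for (i in seq_len(ns)) w("", 80)
  for (i in seq_len(ns)) w(fs, 8)
  for (i in seq_len(ns)) w("", 32)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      writeBin(as.integer(digi[s, cols]), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
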