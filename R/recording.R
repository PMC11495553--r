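#' EEG recording container
#'
#' A `Recording` holds a channels-by-samples numeric matrix (microvolts), its
#' sampling rate and channel labels. All feature extraction in the package
#' starts from this container.
#'
#' @param data numeric matrix, one row per channel, one column per sample.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of unique channel names, one per
#'   row of `data`. Defaults to the row names of `data` or `ch1..chN`.
#' @param subject_id subject identifier carried through to feature tables.
#'
#' @return An object of class `eeg_recording` with elements `data`, `fs`,
#'   `channel_labels`, `subject_id`.
#' @export
recording <- function(data, fs, channel_labels = NULL, subject_id = "subject") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (nrow(data) < 2L) stop("a recording needs at least 2 channels")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be a positive scalar")
  if (is.null(channel_labels)) {
    channel_labels <- rownames(data)
    if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) stop("one label per channel required")
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = as.character(subject_id)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

#' Standard 20-channel 10-20 montage
#'
#' Returns the default electrode montage used throughout the package: the
#' twenty electrodes of the international 10-20 system together with a
#' symmetric scalp-adjacency relation used for bad-channel statistics and
#' neighbour-mean interpolation.
#'
#' @return A list of class `eeg_montage` with `labels` (ordered channel
#'   names) and `neighbors` (named list mapping each label to its adjacent
#'   labels).
#' @export
montage_1020 <- function() {
  labels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
              "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "Oz", "O2")
  edges <- list(
    c("Fp1", "Fp2"), c("Fp1", "F7"), c("Fp1", "F3"), c("Fp1", "Fz"),
    c("Fp2", "F8"), c("Fp2", "F4"), c("Fp2", "Fz"),
    c("F7", "F3"), c("F7", "T3"),
    c("F3", "Fz"), c("F3", "C3"),
    c("Fz", "F4"), c("Fz", "Cz"),
    c("F4", "F8"), c("F4", "C4"),
    c("F8", "T4"),
    c("T3", "C3"), c("T3", "T5"),
    c("C3", "Cz"), c("C3", "P3"),
    c("Cz", "C4"), c("Cz", "Pz"),
    c("C4", "T4"), c("C4", "P4"),
    c("T4", "T6"),
    c("T5", "P3"), c("T5", "O1"),
    c("P3", "Pz"), c("P3", "O1"),
    c("Pz", "P4"), c("Pz", "Oz"),
    c("P4", "T6"), c("P4", "O2"),
    c("T6", "O2"),
    c("O1", "Oz"), c("Oz", "O2")
  )
  neighbors <- stats::setNames(vector("list", length(labels)), labels)
  for (e in edges) {
    neighbors[[e[1]]] <- c(neighbors[[e[1]]], e[2])
    neighbors[[e[2]]] <- c(neighbors[[e[2]]], e[1])
  }
  neighbors <- lapply(neighbors, function(x) sort(unique(x)))
  structure(list(labels = labels, neighbors = neighbors), class = "eeg_montage")
}

# canonicalize label spelling (case, T7/T8/P7/P8 aliases of the older 10-20
# names used by the default montage); unknown labels pass through verbatim
canonical_1020 <- function(labels) {
  std <- montage_1020()$labels
  alias <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  out <- vapply(labels, function(l) {
    hit <- std[toupper(std) == toupper(l)]
    if (length(hit) == 1L) return(hit)
    a <- alias[toupper(names(alias)) == toupper(l)]
    if (length(a) == 1L) return(unname(a))
    l
  }, character(1))
  unname(out)
}

#' Read an EEG recording from disk
#'
#' Reads either an EDF/EDF+ file or a delimited numeric matrix (CSV/TSV; one
#' row per channel, or samples-by-channels when a header of channel labels is
#' present). Channel labels are mapped to canonical 10-20 spellings where
#' possible; unknown labels are kept verbatim.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"edf"` or `"delimited"`.
#' @param fs sampling rate for delimited input (Hz); EDF carries its own.
#' @param subject_id subject identifier; defaults to the file base name.
#'
#' @return An [recording()] object.
#' @export
read_recording <- function(path, format = c("auto", "edf", "delimited"),
                           fs = NULL, subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  }
  if (format == "edf") {
    ed <- read_edf(path)
    rec <- recording(ed$data, ed$fs, canonical_1020(ed$labels), subject_id)
    return(rec)
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1L)
  toks <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(toks)))
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                   skip = if (has_header) 1L else 0L))
  if (!is.numeric(m)) stop("delimited file contains non-numeric data")
  labels <- NULL
  if (has_header) {
    labels <- trimws(toks)
    if (length(labels) == ncol(m) && ncol(m) < nrow(m)) {
      m <- t(m)                        # header named columns: samples x channels
    } else if (length(labels) != nrow(m)) {
      stop("header has ", length(labels), " labels for ", nrow(m), " channel rows")
    }
    labels <- canonical_1020(labels)
  }
  if (is.null(fs)) stop("`fs` is required for delimited input")
  dimnames(m) <- NULL
  recording(m, fs, labels, subject_id)
}

#' Detect bad channels by neighbour-relative variance
#'
#' Flags channels whose log-variance deviates from the median log-variance of
#' their montage neighbours by a robust z-score exceeding `z_thresh`. The
#' robust scale is 1.4826 x MAD of the deviations over all channels; with
#' zero dispersion, only channels with a non-zero deviation can be flagged.
#'
#' @param rec a [recording()].
#' @param z_thresh positive robust z-score threshold (default 5).
#' @param montage an `eeg_montage`; defaults to [montage_1020()]. Channels
#'   without montage neighbours use all other channels as neighbours.
#' @return Character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, z_thresh = 5, montage = montage_1020()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(z_thresh) || z_thresh <= 0) stop("`z_thresh` must be > 0")
  if (n_channels(rec) < 3L) stop("need at least 3 channels to judge outliers")
  labs <- rec$channel_labels
  lv <- log(apply(rec$data, 1L, stats::var) + .Machine$double.eps)
  names(lv) <- labs
  dev <- vapply(labs, function(l) {
    nb <- intersect(montage$neighbors[[l]], labs)
    if (length(nb) == 0L) nb <- setdiff(labs, l)
    lv[[l]] - stats::median(lv[nb])
  }, numeric(1))
  s <- stats::mad(dev)
  z <- if (s > .Machine$double.eps) (dev - stats::median(dev)) / s
       else ifelse(dev == 0, 0, Inf)
  labs[abs(z) > z_thresh]
}

#' Preprocess a recording
#'
#' Standard resting-state pipeline: (1) replace listed bad channels by the
#' mean of their good montage neighbours, (2) re-reference every sample to
#' the across-channel average, (3) zero-phase FIR band-pass (windowed-sinc,
#' Hamming window, 0.5 Hz transition width, applied forward-backward).
#'
#' @param rec a [recording()].
#' @param hp_hz high-pass edge in Hz (default 0.5).
#' @param lp_hz low-pass edge in Hz (default 45).
#' @param bad_channels character vector of channels to interpolate.
#' @param montage montage supplying the neighbour relation.
#' @param transition_hz FIR transition width in Hz.
#' @return A preprocessed [recording()].
#' @export
preprocess <- function(rec, hp_hz = 0.5, lp_hz = 45, bad_channels = NULL,
                       montage = montage_1020(), transition_hz = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(hp_hz > 0 && hp_hz < lp_hz && lp_hz < rec$fs / 2))
    stop("band edges must satisfy 0 < hp < lp < fs/2")
  x <- rec$data
  labs <- rec$channel_labels
  for (bad in bad_channels) {
    if (!bad %in% labs) stop("unknown bad channel: ", bad)
    nb <- setdiff(intersect(montage$neighbors[[bad]], labs), bad_channels)
    if (length(nb) == 0L) stop("bad channel ", bad, " has no good neighbors")
    x[bad, ] <- colMeans(x[nb, , drop = FALSE])
  }
  x <- sweep(x, 2L, colMeans(x))              # average reference
  x <- t(apply(x, 1L, fir_bandpass, fs = rec$fs, hp = hp_hz, lp = lp_hz,
               transition = transition_hz))
  recording(x, rec$fs, labs, rec$subject_id)
}

# Zero-phase band-pass: Hamming windowed-sinc taps from signal::fir1 applied
# forward-backward in the frequency domain (multiplication by |B(w)|^2 with
# reflection padding), equivalent to filtfilt away from the edges but
# O(n log n) regardless of filter length.
fir_bandpass <- function(x, fs, hp, lp, transition = 0.5) {
  ord <- ceiling(3.3 * fs / transition)
  ord <- min(ord + ord %% 2, 2L * (length(x) - 1L))  # even, bounded by data
  b <- signal::fir1(ord, c(hp, lp) / (fs / 2), type = "pass")
  npad <- min(length(x) - 1L, length(b))
  xp <- c(rev(2 * x[1] - x[2:(npad + 1L)]), x,
          rev(2 * x[length(x)] - x[(length(x) - npad):(length(x) - 1L)]))
  nfft <- stats::nextn(length(xp) + length(b), 2)
  H <- stats::fft(c(b, numeric(nfft - length(b))))
  y <- Re(stats::fft(stats::fft(c(xp, numeric(nfft - length(xp)))) * Mod(H)^2,
                     inverse = TRUE)) / nfft
  y[(npad + 1L):(npad + length(x))]
}

#' Split a recording into fixed-length epochs
#'
#' @param rec a [recording()].
#' @param length_s epoch length in seconds (at least 2 samples).
#' @param overlap fraction of overlap between consecutive epochs, in \[0, 1).
#' @return An object of class `eeg_epochs`: a channels x samples x epochs
#'   array plus `fs`, `epoch_length_s`, `overlap_fraction`, `channel_labels`,
#'   `subject_id`. Trailing samples that do not fill an epoch are discarded.
#' @export
epoch <- function(rec, length_s = 2, overlap = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(length_s * rec$fs)
  if (len < 2L) stop("epoch length must span at least 2 samples")
  if (!(overlap >= 0 && overlap < 1)) stop("`overlap` must be in [0, 1)")
  stride <- max(1L, round(len * (1 - overlap)))
  n <- n_samples(rec)
  if (n < len) stop("recording shorter than one epoch")
  starts <- seq(1L, n - len + 1L, by = stride)
  arr <- array(0, dim = c(n_channels(rec), len, length(starts)),
               dimnames = list(rec$channel_labels, NULL, NULL))
  for (i in seq_along(starts)) {
    arr[, , i] <- rec$data[, starts[i]:(starts[i] + len - 1L)]
  }
  structure(
    list(epochs = arr, fs = rec$fs, epoch_length_s = len / rec$fs,
         overlap_fraction = overlap, channel_labels = rec$channel_labels,
         subject_id = rec$subject_id),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<eeg_epochs> %d epochs of %d channels x %d samples @ %g Hz\n",
              d[3], d[1], d[2], x$fs))
  invisible(x)
}

#' Drop epochs containing high-amplitude artifacts
#'
#' Epoch-level surrogate for automatic continuous artifact rejection: any
#' epoch whose peak absolute amplitude exceeds `threshold_uv` is removed.
#'
#' @param ep an `eeg_epochs` object.
#' @param threshold_uv rejection threshold in microvolts (default 150).
#' @return `eeg_epochs` restricted to retained epochs; the indices kept are
#'   stored in attribute `"kept"`.
#' @export
drop_artifacts <- function(ep, threshold_uv = 150) {
  stopifnot(inherits(ep, "eeg_epochs"))
  peak <- apply(abs(ep$epochs), 3L, max)
  keep <- which(peak <= threshold_uv)
  if (length(keep) == 0L) stop("all epochs exceed the artifact threshold")
  ep$epochs <- ep$epochs[, , keep, drop = FALSE]
  attr(ep, "kept") <- keep
  ep
}

#' Concatenate epochs back into a recording
#'
#' Inverse of [epoch()] for non-overlapping epochs; used to verify that
#' epoching preserves the analysed span.
#' @param ep an `eeg_epochs` object with `overlap_fraction == 0`.
#' @return A [recording()].
#' @export
unepoch <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (ep$overlap_fraction != 0) stop("only non-overlapping epochs concatenate")
  d <- dim(ep$epochs)
  recording(matrix(ep$epochs, nrow = d[1], ncol = d[2] * d[3]),
            ep$fs, ep$channel_labels, ep$subject_id)
}

consciousness_states <- function() {
  c("awake", "somnolence", "stupor", "light_coma", "middle_coma", "deep_coma")
}

#' Read a clinical label table
#'
#' CSV with columns `subject_id`, `consciousness`, `motor_side`,
#' `stroke_side` (an optional `sex` column is kept if present). Enumerations
#' are closed: consciousness is one of awake, somnolence, stupor, light_coma,
#' middle_coma, deep_coma; sides are B, L, R or none.
#'
#' @param path CSV file path.
#' @return A validated `data.frame`.
#' @export
read_clinical_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical_labels(df)
}

validate_clinical_labels <- function(df) {
  need <- c("subject_id", "consciousness", "motor_side", "stroke_side")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("label table missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$consciousness %in% consciousness_states()))
    stop("unknown consciousness state(s): ",
         paste(unique(setdiff(df$consciousness, consciousness_states())), collapse = ", "))
  sides <- c("B", "L", "R", "none")
  for (col in c("motor_side", "stroke_side")) {
    if (!all(df[[col]] %in% sides))
      stop("unknown ", col, " value(s): ",
           paste(unique(setdiff(df[[col]], sides)), collapse = ", "))
  }
  df
}

#' Binary disorder-of-consciousness label
#'
#' Maps consciousness states to the binary DoC outcome: awake is negative,
#' every non-awake state (somnolence through deep coma) is positive.
#'
#' @param consciousness character vector of consciousness states.
#' @return Factor with levels `negative`, `positive` (positive = DoC).
#' @export
doc_label <- function(consciousness) {
  if (!all(consciousness %in% consciousness_states()))
    stop("unknown consciousness state(s)")
  factor(ifelse(consciousness == "awake", "negative", "positive"),
         levels = c("negative", "positive"))
}
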