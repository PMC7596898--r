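#' Segment a continuous recording into labeled epochs
#'
#' Cuts one fixed-length trial per marker, anchored at the cue onset (plus an
#' optional offset), into an `epoch_set`: a 3-D array of trials sharing
#' channel count, length and sampling rate. Windows are half-open
#' `[onset, onset + T)` with `T = round(epoch_seconds * fs)` samples.
#'
#' @param rec an [eeg_recording()].
#' @param epoch_seconds epoch length in seconds (positive). Default 3, the
#'   conventional motor-imagery trial window.
#' @param offset_samples integer shift of the window start relative to each
#'   cue onset. Default 0.
#' @return An object of class `epoch_set`: list with `data` (channels x T x
#'   n_epochs array), `labels` (integer vector), `fs`.
#' @examples
#' rec <- simulate_mi_eeg(n_trials_per_class = 3, seed = 1)
#' es <- segment_epochs(rec)
#' es
#' @export
segment_epochs <- function(rec, epoch_seconds = 3, offset_samples = 0L) {
  stopifnot(inherits(rec, "eeg_recording"))
  epoch_seconds <- check_scalar_number(epoch_seconds, "epoch_seconds",
                                       lower = .Machine$double.eps)
  T_len <- as.integer(round(epoch_seconds * rec$fs))
  n <- nrow(rec$markers)
  starts <- rec$markers$onset_sample + as.integer(offset_samples)
  over <- which(starts < 0L | starts + T_len > ncol(rec$signal))
  if (length(over))
    stop_sparsebci("epoch window overruns the recording for marker(s): ",
                   paste(over, collapse = ", "),
                   class = "sparsebci_validation_error")
  dat <- array(0, dim = c(nrow(rec$signal), T_len, n))
  for (i in seq_len(n))
    dat[, , i] <- rec$signal[, (starts[i] + 1L):(starts[i] + T_len), drop = FALSE]
  epoch_set(dat, rec$markers$label, rec$fs)
}

#' Construct an epoch set from an array of trials
#'
#' @param data channels x T x n_epochs numeric array (also accepts a list of
#'   channels x T matrices).
#' @param labels integer class labels, one per epoch, in `{1, 2}` for the
#'   two-class pipelines.
#' @param fs sampling rate in Hz.
#' @return An `epoch_set`.
#' @export
epoch_set <- function(data, labels, fs) {
  if (is.list(data)) {
    dims <- unique(lapply(data, dim))
    if (length(dims) > 1L)
      stop_sparsebci("all epochs must share channel count and length",
                     class = "sparsebci_validation_error")
    data <- array(unlist(data), dim = c(dims[[1L]], length(data)))
  }
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_sparsebci("`data` must be a channels x T x n_epochs array",
                   class = "sparsebci_format_error")
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[3L])
    stop_sparsebci("one label per epoch required", class = "sparsebci_validation_error")
  fs <- check_scalar_number(fs, "fs", lower = .Machine$double.eps)
  structure(list(data = data, labels = labels, fs = fs), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs, %d channels x %d samples @ %g Hz\n",
              d[3L], d[1L], d[2L], x$fs))
  if (d[3L]) {
    tab <- class_counts(x)
    cat("  classes:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.epoch_set <- function(x) dim(x$data)[3L]

#' Per-class epoch counts
#' @param es an `epoch_set`.
#' @return Named integer vector of counts per class label.
#' @export
class_counts <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  tab <- table(factor(es$labels, levels = sort(unique(es$labels))))
  stats::setNames(as.integer(tab), names(tab))
}

#' Subset an epoch set
#' @param x an `epoch_set`.
#' @param i epoch indices.
#' @param ... unused.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  epoch_set(x$data[, , i, drop = FALSE], x$labels[i], x$fs)
}

#' Zero-phase band-pass filter an epoch set
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero-phase, via [signal::filtfilt()]) to every channel of every epoch.
#' Zero-phase filtering preserves the temporal alignment of the oscillatory
#' structure that the CSP covariance estimates depend on. Labels, shapes and
#' sampling rate are unchanged.
#'
#' @param es an `epoch_set` (or an [eeg_recording()], filtered continuously).
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`. Defaults 8 and 15 Hz, the mu-band window
#'   standard for motor imagery.
#' @param order Butterworth order (default 4).
#' @return Object of the same class as `es`, filtered.
#' @export
bandpass <- function(es, low_hz = 8, high_hz = 15, order = 4L) {
  UseMethod("bandpass")
}

check_band <- function(low_hz, high_hz, fs) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop_sparsebci(sprintf("band [%g, %g] Hz must satisfy 0 < low < high < fs/2 = %g",
                           low_hz, high_hz, fs / 2),
                   class = "sparsebci_parameter_error")
}

band_filter <- function(fs, low_hz, high_hz, order) {
  signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
}

#' @export
bandpass.epoch_set <- function(es, low_hz = 8, high_hz = 15, order = 4L) {
  check_band(low_hz, high_hz, es$fs)
  bf <- band_filter(es$fs, low_hz, high_hz, order)
  out <- es$data
  d <- dim(out)
  for (i in seq_len(d[3L]))
    for (ch in seq_len(d[1L]))
      out[ch, , i] <- signal::filtfilt(bf, es$data[ch, , i])
  epoch_set(out, es$labels, es$fs)
}

#' @export
bandpass.eeg_recording <- function(es, low_hz = 8, high_hz = 15, order = 4L) {
  check_band(low_hz, high_hz, es$fs)
  bf <- band_filter(es$fs, low_hz, high_hz, order)
  sig <- es$signal
  for (ch in seq_len(nrow(sig)))
    sig[ch, ] <- signal::filtfilt(bf, es$signal[ch, ])
  eeg_recording(sig, es$fs, es$channel_names, es$markers)
}
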