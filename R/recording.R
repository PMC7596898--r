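#' Construct a continuous multichannel EEG recording
#'
#' Bundles a continuous channels-by-samples signal matrix with its sampling
#' rate, channel labels and trial cue markers. Markers use 0-based onset
#' sample indices; each marker carries the integer class label of the trial
#' that starts at that onset (1 = right hand, 2 = right foot in the
#' two-class motor-imagery convention used throughout the package).
#'
#' @param signal numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names character vector, one label per channel. Defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param markers data.frame with columns `onset_sample` (0-based integer)
#'   and `label` (integer class id). May have zero rows.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(300), 3, 100), fs = 100,
#'                      markers = data.frame(onset_sample = 0L, label = 1L))
#' rec
#' @export
eeg_recording <- function(signal, fs, channel_names = NULL, markers = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop_sparsebci("`signal` must be a numeric channels x samples matrix",
                   class = "sparsebci_format_error")
  bad <- which(!is.finite(signal))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(signal))
    stop_sparsebci(sprintf("non-finite sample at channel %d, sample %d",
                           idx[1L], idx[2L]),
                   class = "sparsebci_validation_error")
  }
  fs <- check_scalar_number(fs, "fs", lower = .Machine$double.eps)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(signal)))
  if (length(channel_names) != nrow(signal))
    stop_sparsebci("`channel_names` length must equal the channel count",
                   class = "sparsebci_validation_error")
  if (is.null(markers))
    markers <- data.frame(onset_sample = integer(0), label = integer(0))
  if (!all(c("onset_sample", "label") %in% names(markers)))
    stop_sparsebci("markers must have columns `onset_sample` and `label`",
                   class = "sparsebci_format_error")
  markers <- data.frame(onset_sample = as.integer(markers$onset_sample),
                        label = as.integer(markers$label))
  if (nrow(markers) && (any(markers$onset_sample < 0L) ||
                        any(markers$onset_sample >= ncol(signal))))
    stop_sparsebci("marker onsets fall outside the recorded signal",
                   class = "sparsebci_validation_error")
  structure(list(signal = signal, fs = fs, channel_names = channel_names,
                 markers = markers),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d markers\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs,
              nrow(x$markers)))
  if (nrow(x$markers)) {
    tab <- table(x$markers$label)
    cat("  classes:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write an EEG recording to plain-text files
#'
#' The signal is written as CSV with channels as columns (one row per time
#' sample, header = channel names) and markers plus sampling rate go to a
#' sidecar JSON file (`<path>.json`).
#'
#' @param rec an [eeg_recording()].
#' @param path output CSV path. The marker sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- as.data.frame(t(rec$signal))
  names(df) <- rec$channel_names
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(fs = rec$fs,
               channel_names = rec$channel_names,
               markers = list(onset_sample = rec$markers$onset_sample,
                              label = rec$markers$label))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a multichannel EEG recording from disk
#'
#' Reads the CSV + JSON-sidecar layout written by [write_recording()]:
#' a CSV whose columns are channels (header row = channel names) and a
#' `<path>.json` sidecar holding the sampling rate and the marker table.
#'
#' @param path path to the signal CSV.
#' @param format container format; `"csv"` is the supported plain-text
#'   container. Requesting another format raises an error.
#' @param sidecar path to the JSON sidecar; defaults to `paste0(path, ".json")`.
#' @return An [eeg_recording()].
#' @export
load_recording <- function(path, format = c("csv", "mat", "hdf5"), sidecar = NULL) {
  format <- match.arg(format)
  if (format != "csv")
    stop_sparsebci(sprintf("format '%s' is not supported by this build; use the CSV + JSON sidecar layout", format),
                   class = "sparsebci_format_error")
  if (!file.exists(path))
    stop_sparsebci("file not found: ", path, class = "sparsebci_format_error")
  if (is.null(sidecar)) sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop_sparsebci("missing sidecar file (field `fs`/`markers`): ", sidecar,
                   class = "sparsebci_format_error")
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("fs", "markers"))
    if (is.null(side[[field]]))
      stop_sparsebci("sidecar is missing required field `", field, "`",
                     class = "sparsebci_format_error")
  markers <- data.frame(onset_sample = as.integer(side$markers$onset_sample),
                        label = as.integer(side$markers$label))
  ch <- if (!is.null(side$channel_names)) side$channel_names else names(df)
  eeg_recording(t(as.matrix(df)), fs = side$fs, channel_names = ch,
                markers = markers)
}
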