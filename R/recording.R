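#' Continuous multi-channel EEG recording
#'
#' Lightweight container for a continuous EEG recording: a channels-by-samples
#' matrix in microvolts, the sampling rate, and interval annotations carrying
#' the experimental condition and run id for each stretch of the session.
#'
#' @param data numeric matrix `[channels x samples]`, in microvolts; row
#'   names are taken as channel labels when `channels` is missing.
#' @param srate sampling rate in Hz.
#' @param channels character vector of channel labels (subset of
#'   [bci_channels()]); defaults to `rownames(data)`.
#' @param annotations data frame with columns `start`, `end` (seconds,
#'   0-based, `end` exclusive), `label`, and optionally `run`. May be empty.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, channels = rownames(data),
                          annotations = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data))) {
    stop_pbci("recording data must be a finite numeric matrix")
  }
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0) {
    stop_pbci("sampling rate must be a positive scalar")
  }
  if (is.null(channels)) stop_pbci("channel labels are required")
  channels <- as.character(channels)
  if (length(channels) != nrow(data)) {
    stop_pbci("one channel label per data row is required")
  }
  if (anyDuplicated(channels)) stop_pbci("channel labels must be unique")
  unknown <- setdiff(channels, bci_channels())
  if (length(unknown)) {
    stop_pbci("unknown channel label(s): ", paste(unknown, collapse = ", "))
  }
  rownames(data) <- channels
  dur <- ncol(data) / srate
  if (is.null(annotations)) {
    annotations <- data.frame(start = numeric(0), end = numeric(0),
                              label = character(0), run = integer(0))
  }
  annotations <- as.data.frame(annotations)
  if (!all(c("start", "end", "label") %in% names(annotations))) {
    stop_pbci("annotations need columns start, end, label")
  }
  if (is.null(annotations$run)) annotations$run <- rep(NA_integer_, nrow(annotations))
  if (nrow(annotations) &&
      (any(annotations$start < 0) || any(annotations$end > dur + 1e-9) ||
       any(annotations$end <= annotations$start))) {
    stop_pbci("annotations must lie within the recording duration")
  }
  structure(
    list(data = data, srate = srate, channels = channels,
         annotations = annotations),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$srate, x$srate))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  if (nrow(x$annotations)) {
    cat(sprintf("  annotations: %d intervals (%s)\n", nrow(x$annotations),
                paste(unique(x$annotations$label), collapse = ", ")))
  }
  invisible(x)
}

#' @export
`[.eeg_recording` <- function(x, channels, ...) {
  eeg_recording(x$data[channels, , drop = FALSE], x$srate,
                annotations = x$annotations)
}

rec_duration <- function(rec) ncol(rec$data) / rec$srate

#' Extract the samples covered by an annotation label
#'
#' Returns the continuous samples of all annotation intervals carrying a
#' given label, concatenated, as a `channels x samples` matrix — e.g. the
#' closed-eyes rest for IAF estimation.
#'
#' @param rec an [eeg_recording()].
#' @param label annotation label to extract.
#' @return Numeric matrix `[channels x samples]`.
#' @export
rec_segment <- function(rec, label) {
  ann <- rec$annotations[rec$annotations$label == label, , drop = FALSE]
  if (!nrow(ann)) stop_pbci("no annotation labelled '", label, "'")
  idx <- unlist(lapply(seq_len(nrow(ann)), function(i) {
    seq.int(floor(ann$start[i] * rec$srate) + 1L,
            min(ncol(rec$data), floor(ann$end[i] * rec$srate)))
  }))
  rec$data[, idx, drop = FALSE]
}

#' Set of fixed-length epochs cut from a recording
#'
#' @param epochs numeric array `[n_epochs x channels x samples_per_epoch]`.
#' @param srate sampling rate in Hz.
#' @param channels channel labels.
#' @param labels per-epoch condition label (character).
#' @param run per-epoch run id (integer, `NA` allowed).
#' @param t_start per-epoch start time in seconds.
#' @param retained logical mask of retained epochs.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(epochs, srate, channels, labels, run, t_start,
                       retained = rep(TRUE, dim(epochs)[1])) {
  stopifnot(length(dim(epochs)) == 3L)
  n <- dim(epochs)[1]
  stopifnot(dim(epochs)[2] == length(channels),
            length(labels) == n, length(run) == n,
            length(t_start) == n, length(retained) == n)
  structure(
    list(epochs = epochs, srate = srate, channels = channels,
         labels = as.character(labels), run = as.integer(run),
         t_start = t_start, retained = as.logical(retained),
         epoch_length = dim(epochs)[3] / srate),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples (%g s each), %d retained\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$epoch_length, sum(x$retained)))
  tb <- table(x$labels)
  cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

n_epochs <- function(ep) dim(ep$epochs)[1]

#' Read and write recordings as plain-text files
#'
#' Recordings are serialized to a pair of text files: a wide CSV with one
#' column per channel plus a `time_s` column for the samples, and a JSON
#' sidecar with the sampling rate and annotations. This keeps sessions
#' diffable and portable without a binary container.
#'
#' @param rec an [eeg_recording()].
#' @param path path of the signal CSV; the sidecar is written next to it
#'   with extension `.json`.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an [eeg_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- data.frame(time_s = (seq_len(ncol(rec$data)) - 1) / rec$srate,
                   t(rec$data), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(srate = rec$srate, channels = rec$channels,
               annotations = rec$annotations)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  ann <- as.data.frame(meta$annotations)
  if (!nrow(ann)) ann <- NULL
  eeg_recording(t(as.matrix(df[, meta$channels, drop = FALSE])),
                srate = as.numeric(meta$srate), channels = meta$channels,
                annotations = ann)
}

sidecar_path <- function(path) paste0(sub("\\.[^.]+$", "", path), ".json")
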