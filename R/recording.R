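#' Electrode labels of the 19-channel international 10-20 montage
#'
#' Standard scalp positions used by 19-electrode clinical EEG systems.
#'
#' @return Character vector of 19 channel labels.
#' @export
channels_10_20 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Construct a multichannel recording
#'
#' A `recording` holds a channels x samples real matrix together with its
#' sampling rate, channel labels and provenance (subject, condition). It is the
#' common currency of the preprocessing, spectral, dimensionality and
#' latent-variable stages.
#'
#' @param data Numeric matrix, channels in rows, samples in columns. All values
#'   must be finite.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_labels Character vector, one label per row of `data`.
#' @param subject_id Subject identifier (scalar, coerced to character).
#' @param condition Condition label (scalar, coerced to character).
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, channel_labels = rownames(data),
                      subject_id = NA_character_, condition = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stopf("`data` must be a numeric matrix (channels x samples)")
  }
  if (any(!is.finite(data))) stopf("recording data contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stopf("`fs` must be a positive scalar")
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stopf("%d channel labels for %d data rows", length(channel_labels), nrow(data))
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         subject_id = as.character(subject_id), condition = as.character(condition)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  subject: %s  condition: %s\n", x$subject_id, x$condition))
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)
n_channels <- function(rec) nrow(rec$data)

as_recording_matrix <- function(x) {
  if (inherits(x, "recording")) x$data
  else if (is.matrix(x)) x
  else stopf("expected a `recording` or a channels x samples matrix")
}
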