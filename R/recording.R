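#' Multichannel EEG recording
#'
#' Container for a labelled multichannel signal. `data` holds one channel per
#' row, in microvolts. `t0` is the time of the first sample in seconds
#' relative to the injection (or other reference) event, so sample `i`
#' (1-based) sits at `t0 + (i - 1) / fs` and negative times are pre-injection.
#'
#' @param data numeric matrix, channels x samples, finite values, microvolts.
#' @param fs sampling rate in Hz (positive scalar).
#' @param labels character vector of unique channel names, one per data row.
#' @param t0 start time in seconds relative to injection. Default 0.
#' @return An object of class `eeg_recording`: a list with elements
#'   `labels`, `fs`, `data`, `t0`.
#' @examples
#' rec <- recording(matrix(rnorm(500), 5), fs = 100,
#'                  labels = c("Oz", "POz", "Pz", "Cz", "FCz"))
#' rec
#' @export
recording <- function(data, fs, labels = NULL, t0 = 0) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (is.null(labels)) labels <- rownames(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  rec <- structure(
    list(labels = labels, fs = as.numeric(fs), data = unname(data),
         t0 = as.numeric(t0)),
    class = "eeg_recording")
  validate_recording(rec)
  rec
}

#' Validate an EEG recording
#'
#' Checks the invariants of an [recording()] object: one unique label per
#' data row, positive sampling rate, finite samples.
#'
#' @param rec an `eeg_recording`.
#' @return `rec`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "eeg_recording")) stop("not an eeg_recording")
  if (nrow(rec$data) < 1L) stop("recording must have at least one channel")
  if (length(rec$labels) != nrow(rec$data))
    stop("integrity error: ", length(rec$labels), " labels for ",
         nrow(rec$data), " data rows")
  if (anyDuplicated(rec$labels)) stop("channel labels must be unique")
  if (!is.finite(rec$fs) || rec$fs <= 0) stop("fs must be positive")
  if (!all(is.finite(rec$data))) stop("recording data must be finite")
  if (!is.finite(rec$t0)) stop("t0 must be finite")
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), t0 = %g s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$t0))
  cat("  channels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @return duration in seconds.
#' @export
duration <- function(rec) ncol(rec$data) / rec$fs

#' Ordered electrode array
#'
#' An ordered list of channel names defining the spatial axis of the
#' time-by-electrode maps. For anterior-posterior arrays index 1 is the most
#' posterior electrode and the last index the most anterior; for `lateral`
#' control arrays the order runs left to right. At least 3 electrodes are
#' required for a meaningful spatial spectrum.
#'
#' @param labels character vector (>= 3 distinct names), posterior first.
#' @param axis_kind one of `"midline"`, `"diagonal_right_to_left"`,
#'   `"diagonal_left_to_right"`, `"lateral"`.
#' @return An object of class `electrode_array`.
#' @seealso [standard_arrays()]
#' @export
electrode_array <- function(labels,
                            axis_kind = c("midline", "diagonal_right_to_left",
                                          "diagonal_left_to_right", "lateral")) {
  axis_kind <- match.arg(axis_kind)
  labels <- as.character(labels)
  if (length(labels) < 3L) stop("an electrode array needs at least 3 electrodes")
  if (anyDuplicated(labels)) stop("electrode array labels must be distinct")
  structure(list(labels = labels, axis_kind = axis_kind),
            class = "electrode_array")
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("<electrode_array> %s: %s\n", x$axis_kind,
              paste(x$labels, collapse = " -> ")))
  invisible(x)
}

#' Standard electrode arrays for a 32-channel 10-20 montage
#'
#' The midline array (Oz, POz, Pz, Cz, FCz) is the primary analysis axis;
#' the two diagonals and the lateral (left-right central) array are control
#' axes: a genuine posterior-to-anterior wave should also register on the
#' diagonals but not on the purely lateral array.
#'
#' @return named list of [electrode_array()] objects:
#'   `midline`, `diag_rl`, `diag_lr`, `lateral`.
#' @export
standard_arrays <- function() {
  list(
    midline = electrode_array(c("Oz", "POz", "Pz", "Cz", "FCz"), "midline"),
    diag_rl = electrode_array(c("O2", "P4", "Cz", "F3", "Fp1"),
                              "diagonal_right_to_left"),
    diag_lr = electrode_array(c("O1", "P3", "Cz", "F4", "Fp2"),
                              "diagonal_left_to_right"),
    lateral = electrode_array(c("T7", "C3", "Cz", "C4", "T8"), "lateral")
  )
}

# case-insensitive, whitespace-stripped channel-name matching (vendor headers
# vary in case and padding)
match_labels <- function(wanted, available) {
  norm <- function(x) tolower(gsub("\\s+", "", x))
  idx <- match(norm(wanted), norm(available))
  if (anyNA(idx)) {
    missing <- wanted[is.na(idx)]
    stop("channel(s) not found in recording: ", paste(missing, collapse = ", "))
  }
  idx
}
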