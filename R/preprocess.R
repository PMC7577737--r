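#' Sliding-window specification
#'
#' One-second windows advancing by half a second are the default analysis
#' grain: long enough to resolve 1 Hz, short enough to track minute-scale
#' drug effects.
#'
#' @param length_s window length in seconds (default 1).
#' @param step_s hop between window starts in seconds (default 0.5);
#'   must satisfy `0 < step_s <= length_s`.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(length_s = 1, step_s = 0.5) {
  if (!is.finite(length_s) || length_s <= 0) stop("length_s must be positive")
  if (!is.finite(step_s) || step_s <= 0 || step_s > length_s)
    stop("need 0 < step_s <= length_s")
  structure(list(length_s = length_s, step_s = step_s), class = "window_spec")
}

#' Zero-phase band-pass filter
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass per channel,
#' realized as a 4th-order high-pass followed by a 4th-order low-pass, each
#' run through `signal::filtfilt`. Zero-phase filtering preserves the
#' cross-channel phase relations that the travelling-wave statistic measures;
#' a phase-distorting filter would bias the apparent wave direction.
#'
#' @param rec an [recording()].
#' @param low_hz,high_hz corner frequencies in Hz,
#'   `0 < low_hz < high_hz < fs/2`.
#' @return a filtered `eeg_recording` of the same length.
#' @export
bandpass <- function(rec, low_hz = 1, high_hz = 45) {
  validate_recording(rec)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rec$fs / 2))
    stop("band must satisfy 0 < low_hz < high_hz < fs/2")
  hp <- signal::butter(4, low_hz / (rec$fs / 2), type = "high")
  lp <- signal::butter(4, high_hz / (rec$fs / 2), type = "low")
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    out$data[i, ] <- signal::filtfilt(lp, signal::filtfilt(hp, rec$data[i, ]))
  }
  out
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across all channels from every channel,
#' so the output channel mean is zero at every sample. The subtracted series
#' is common to all channels, so only the spatially uniform (zero spatial
#' frequency) component of any time-by-electrode map is affected; quadrant
#' wave measures are invariant to this step by construction.
#'
#' @param rec an [recording()] with at least 2 channels.
#' @return the re-referenced `eeg_recording`.
#' @export
rereference_average <- function(rec) {
  validate_recording(rec)
  if (nrow(rec$data) < 2L) stop("average reference needs >= 2 channels")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec
}

#' Extract and order the channels of an electrode array
#'
#' Returns a recording whose rows are exactly `array$labels`, in array order
#' (posterior first for anterior-posterior axes). Matching is
#' case-insensitive and whitespace-stripped.
#'
#' @param rec an [recording()].
#' @param array an [electrode_array()] whose labels are all present in `rec`.
#' @return an `eeg_recording` restricted to the array channels.
#' @export
select_array <- function(rec, array) {
  validate_recording(rec)
  if (!inherits(array, "electrode_array")) stop("`array` must be an electrode_array")
  idx <- match_labels(array$labels, rec$labels)
  recording(rec$data[idx, , drop = FALSE], fs = rec$fs,
            labels = array$labels, t0 = rec$t0)
}

#' Slide fixed-length windows over a recording
#'
#' Windows start at `t0, t0 + step, ...`; a window that would overrun the end
#' of the signal is dropped (no padding), so the count is
#' `floor((duration - length_s) / step_s) + 1`. Window lengths that do not
#' give a whole number of samples are rejected rather than rounded.
#'
#' @param rec an [recording()] at least one window long.
#' @param spec a [window_spec()].
#' @return list of [wave_map()] objects, ordered by start time.
#' @export
slide_windows <- function(rec, spec = window_spec()) {
  validate_recording(rec)
  if (!inherits(spec, "window_spec")) stop("`spec` must be a window_spec")
  nw <- spec$length_s * rec$fs
  ns <- spec$step_s * rec$fs
  if (abs(nw - round(nw)) > 1e-8)
    stop("window length x fs must be an integer number of samples")
  if (abs(ns - round(ns)) > 1e-8)
    stop("window step x fs must be an integer number of samples")
  nw <- as.integer(round(nw)); ns <- as.integer(round(ns))
  total <- ncol(rec$data)
  if (total < nw) stop("recording shorter than one window")
  n_win <- (total - nw) %/% ns + 1L
  lapply(seq_len(n_win) - 1L, function(i) {
    wave_map(rec$data[, (i * ns + 1L):(i * ns + nw), drop = FALSE],
             fs = rec$fs, t_start = rec$t0 + i * ns / rec$fs)
  })
}

# start sample indices (0-based) of sliding windows; shared with the batched
# quantification path
window_starts <- function(n_samples, nw, ns) {
  if (n_samples < nw) stop("recording shorter than one window")
  seq.int(0L, n_samples - nw, by = ns)
}

#' Amplitude-threshold window rejection
#'
#' Flags windows containing any sample exceeding a fixed absolute amplitude.
#' This automated criterion stands in for visual artifact screening of raw
#' recordings; windows are flagged, never modified.
#'
#' @param maps list of [wave_map()] objects.
#' @param threshold_uv absolute amplitude threshold in microvolts.
#' @return logical vector, `TRUE` for windows to keep.
#' @export
clean_windows <- function(maps, threshold_uv) {
  if (!is.finite(threshold_uv) || threshold_uv <= 0)
    stop("threshold_uv must be positive")
  vapply(maps, function(m) max(abs(m$data)) <= threshold_uv, logical(1))
}
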