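#' Plane-wave component
#'
#' A single travelling plane wave on a discrete electrode axis:
#' `amplitude * cos(2*pi*temporal_hz*t - 2*pi*spatial_cpe*x + phase0)` at
#' electrode index `x` (0-based, posterior first). Positive `spatial_cpe`
#' (cycles per electrode step) means posterior-to-anterior (forward)
#' propagation; `|spatial_cpe| <= 0.5` keeps the spatial axis below its
#' Nyquist limit.
#'
#' @param temporal_hz oscillation frequency in Hz (> 0).
#' @param spatial_cpe signed spatial frequency in cycles per electrode step.
#' @param amplitude amplitude in microvolts.
#' @param phase0 initial phase in radians.
#' @return an object of class `wave_component`.
#' @export
wave_component <- function(temporal_hz, spatial_cpe, amplitude = 1,
                           phase0 = 0) {
  if (!is.finite(temporal_hz) || temporal_hz <= 0)
    stop("temporal_hz must be positive")
  if (abs(spatial_cpe) > 0.5)
    stop("|spatial_cpe| must be <= 0.5 (spatial Nyquist)")
  structure(list(temporal_hz = temporal_hz, spatial_cpe = spatial_cpe,
                 amplitude = amplitude, phase0 = phase0),
            class = "wave_component")
}

#' Generate a plane-wave recording
#'
#' Deterministic multichannel cosine with a linear phase gradient across
#' electrodes; the canonical detection target for the quadrant statistic.
#'
#' @param fs sampling rate in Hz.
#' @param duration_s duration in seconds.
#' @param n_elec number of electrodes (>= 3).
#' @param component a [wave_component()]; its frequency must lie below `fs/2`.
#' @param t0 start time in seconds relative to injection.
#' @return an [recording()] with channels `E1..En`, posterior first.
#' @export
gen_plane_wave <- function(fs, duration_s, n_elec, component, t0 = 0) {
  if (!inherits(component, "wave_component"))
    stop("`component` must be a wave_component")
  if (component$temporal_hz >= fs / 2)
    stop("temporal frequency violates the Nyquist limit")
  tt <- seq.int(0L, round(duration_s * fs) - 1L) / fs
  x <- seq_len(n_elec) - 1L
  data <- component$amplitude *
    cos(outer(-2 * pi * component$spatial_cpe * x,
              2 * pi * component$temporal_hz * tt, `+`) + component$phase0)
  recording(data, fs = fs, labels = paste0("E", seq_len(n_elec)), t0 = t0)
}

#' Generate 1/f^exponent channel noise
#'
#' Independent per-channel Gaussian noise spectrally shaped to a power
#' spectral density proportional to `1/f^exponent` (exponent 0 gives white
#' noise, 1 gives pink noise typical of resting EEG background). Shaping is
#' done in the frequency domain; the result is scaled to the requested RMS
#' amplitude per channel. Deterministic given the seed.
#'
#' @param fs sampling rate in Hz.
#' @param duration_s duration in seconds.
#' @param n_elec number of channels.
#' @param exponent spectral slope in `[0, 3]`.
#' @param amplitude per-channel RMS in microvolts.
#' @param seed integer seed.
#' @param t0 start time in seconds relative to injection.
#' @return an [recording()].
#' @export
gen_noise <- function(fs, duration_s, n_elec, exponent = 1, amplitude = 1,
                      seed = 1L, t0 = 0) {
  if (!is.finite(exponent) || exponent < 0 || exponent > 3)
    stop("exponent must be in [0, 3]")
  n <- round(duration_s * fs)
  data <- with_seed(seed, {
    vapply(seq_len(n_elec), function(i) {
      white <- stats::rnorm(n)
      if (exponent == 0) return(white)
      spec <- stats::fft(white)
      f <- abs(signed_bins(n)) * fs / n
      gain <- c(0, 1 / f[-1]^(exponent / 2))  # kill DC, shape the rest
      Re(stats::fft(spec * gain, inverse = TRUE)) / n
    }, numeric(n))
  })
  data <- t(data)
  rms <- sqrt(rowMeans(data^2))
  data <- data * (amplitude / ifelse(rms > 0, rms, 1))
  recording(data, fs = fs, labels = paste0("E", seq_len(n_elec)), t0 = t0)
}

#' Generate a standing wave
#'
#' Superposition of equal-amplitude forward and backward plane waves at one
#' frequency: both quadrants carry the same raw power, modelling
#' e.g. alpha oscillations travelling simultaneously in both directions.
#'
#' @param fs sampling rate in Hz.
#' @param duration_s duration in seconds.
#' @param n_elec number of electrodes.
#' @param temporal_hz oscillation frequency in Hz.
#' @param amplitude amplitude of each directional component.
#' @param spatial_cpe magnitude of the spatial frequency (default 0.2, one
#'   cycle across five electrodes).
#' @return an [recording()].
#' @export
gen_standing_wave <- function(fs, duration_s, n_elec, temporal_hz,
                              amplitude = 1, spatial_cpe = 0.2) {
  fwd <- gen_plane_wave(fs, duration_s, n_elec,
                        wave_component(temporal_hz, +spatial_cpe, amplitude))
  bwd <- gen_plane_wave(fs, duration_s, n_elec,
                        wave_component(temporal_hz, -spatial_cpe, amplitude))
  fwd$data <- fwd$data + bwd$data
  fwd
}
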