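#' Sonication protocol
#'
#' Describes one focused-ultrasound treatment session: a train of short
#' pulses ("bursts") delivered at a fixed repetition frequency while a
#' microbubble bolus is injected and flushed.
#'
#' @param f0 Center frequency in Hz. Default 0.25 MHz.
#' @param pulse_length Pulse (burst) length in seconds. Default 10 ms.
#' @param prf Pulse repetition frequency in Hz. Default 2 Hz.
#' @param duration Treatment duration in seconds. Default 120 s.
#' @param target_pnp Derated in-situ peak-negative pressure in Pa.
#'   Default 200 kPa.
#' @param injection_time Time of microbubble bolus injection (s).
#' @param flush_time Time of the saline flush (s).
#'
#' @return An object of class `sonication_protocol`.
#' @export
sonication_protocol <- function(f0 = 0.25e6, pulse_length = 10e-3, prf = 2,
                                duration = 120, target_pnp = 200e3,
                                injection_time = 25, flush_time = 30) {
  stopifnot(f0 > 0, pulse_length > 0, prf > 0, duration > 0)
  n_bursts <- prf * duration
  if (abs(n_bursts - round(n_bursts)) > 1e-9)
    stop("prf * duration must be an integer burst count")
  if (!(0 <= injection_time && injection_time <= flush_time &&
        flush_time <= duration))
    stop("need 0 <= injection_time <= flush_time <= duration")
  structure(list(
    f0 = f0, pulse_length = pulse_length, prf = prf, duration = duration,
    target_pnp = target_pnp, injection_time = injection_time,
    flush_time = flush_time, n_bursts = as.integer(round(n_bursts))
  ), class = "sonication_protocol")
}

#' Ground truth for a synthetic subject
#'
#' Bundles the quantities a synthetic run is constructed from, so downstream
#' recovery can be checked against them.
#'
#' @param source_positions Matrix (n x 3) of cavitation source positions in
#'   world mm (the imaging plane is y = 0).
#' @param source_band_amplitudes Matrix (n x 3) of linear emission amplitudes
#'   per source, columns `harmonic`, `ultraharmonic`, `broadband`.
#' @param onset_burst_index First burst (1-based) with microbubble emission.
#' @param opening_volume_mm3 True opening volume in mm^3.
#' @param opening_centroid True opening centroid, world mm (length 3).
#' @param asymmetry_factor Multiplicative change of treated-side PET uptake
#'   at follow-up (unitless, > 0).
#'
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(source_positions = matrix(c(0, 0, 30), 1, 3),
                            source_band_amplitudes =
                              matrix(c(1, 1, 0.5), 1, 3,
                                     dimnames = list(NULL,
                                       c("harmonic", "ultraharmonic",
                                         "broadband"))),
                            onset_burst_index = 50L,
                            opening_volume_mm3 = 983,
                            opening_centroid = c(32, 32, 32),
                            asymmetry_factor = 0.9853) {
  source_positions <- rbind(source_positions)
  source_band_amplitudes <- rbind(source_band_amplitudes)
  stopifnot(ncol(source_positions) == 3,
            nrow(source_band_amplitudes) == nrow(source_positions),
            ncol(source_band_amplitudes) == 3)
  if (any(source_band_amplitudes < 0)) stop("amplitudes must be >= 0")
  if (opening_volume_mm3 < 0) stop("opening_volume_mm3 must be >= 0")
  if (asymmetry_factor <= 0) stop("asymmetry_factor must be > 0")
  structure(list(
    source_positions = source_positions,
    source_band_amplitudes = source_band_amplitudes,
    onset_burst_index = as.integer(onset_burst_index),
    opening_volume_mm3 = opening_volume_mm3,
    opening_centroid = opening_centroid,
    asymmetry_factor = asymmetry_factor
  ), class = "synthetic_truth")
}

#' Linear receive-array geometry
#'
#' @param n_elements Number of elements (default 64).
#' @param pitch Element pitch in mm (default 0.5).
#' @param fs RF sampling rate in Hz (default 10 MHz).
#' @param c Assumed sound speed in m/s (default 1540).
#'
#' @return An object of class `array_geometry` with `element_positions`
#'   (n x 3 matrix, world mm; elements along x at z = 0, centered on x = 0).
#' @export
array_geometry <- function(n_elements = 64, pitch = 0.5, fs = 10e6, c = 1540) {
  stopifnot(n_elements >= 2, pitch > 0, fs > 0, c > 0)
  x <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch
  structure(list(
    element_positions = cbind(x = x, y = 0, z = 0),
    n_elements = as.integer(n_elements), pitch = pitch, fs = fs, c = c
  ), class = "array_geometry")
}
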