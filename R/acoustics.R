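#' CT-to-acoustic-property maps for the skull
#'
#' Linear interpolation from Hounsfield units to density, sound speed and
#' absorption between the water anchor (0 HU: 1000 kg/m^3, 1500 m/s,
#' 0 dB/cm) and the stated skull maxima at the maximum HU in the volume,
#' clipped below at water values. Absorption scales linearly with frequency.
#'
#' @param ct A [voxel_volume()] in Hounsfield units.
#' @param max_density Skull maximum density (kg/m^3), default 1850.
#' @param max_speed Skull maximum sound speed (m/s), default 4000.
#' @param max_absorption Skull maximum absorption at `f0` (dB/cm),
#'   default 0.68.
#' @param f0 Working frequency (Hz) at which `max_absorption` is stated.
#' @param f Frequency (Hz) at which the absorption map is evaluated,
#'   default `f0`.
#' @return A `skull_model`: list of [voxel_volume()]s `density`, `speed`,
#'   `absorption`, plus the anchors used.
#' @export
ct_to_properties <- function(ct, max_density = 1850, max_speed = 4000,
                             max_absorption = 0.68, f0 = 0.25e6, f = f0) {
  stopifnot(inherits(ct, "voxel_volume"))
  hu <- ct$data
  if (any(!is.finite(hu))) stop("CT contains non-finite HU")
  hu_max <- max(hu)
  if (hu_max <= 0 || hu_max == min(hu))
    stop("empty or constant CT volume")
  frac <- pmin(pmax(hu / hu_max, 0), 1)   # clip below at water
  structure(list(
    density = voxel_volume(1000 + frac * (max_density - 1000), ct$affine),
    speed = voxel_volume(1500 + frac * (max_speed - 1500), ct$affine),
    absorption = voxel_volume(frac * max_absorption * (f / f0), ct$affine),
    anchors = list(water = c(density = 1000, speed = 1500, absorption = 0),
                   skull = c(density = max_density, speed = max_speed,
                             absorption = max_absorption), f0 = f0, f = f)
  ), class = "skull_model")
}

#' Skull insertion loss
#'
#' `alpha = 1 - p_skull / p_freefield`, the fractional pressure attenuation
#' caused by the skull.
#'
#' @param p_skull Maximum in-brain pressure with the skull (Pa).
#' @param p_freefield Maximum pressure without the skull (Pa).
#' @return Insertion loss fraction in `[0, 1)`.
#' @export
insertion_loss <- function(p_skull, p_freefield) {
  if (any(p_skull <= 0) || any(p_freefield <= 0))
    stop("pressures must be positive")
  if (any(p_skull > p_freefield))
    stop("p_skull > p_freefield: gain through the skull is unphysical here")
  1 - p_skull / p_freefield
}

#' Free-field pressure required to deliver a derated in-situ pressure
#'
#' @param target_in_situ Target in-situ (post-skull) pressure (Pa).
#' @param alpha Insertion loss fraction, `alpha < 1`.
#' @return Required free-field pressure `target_in_situ / (1 - alpha)` (Pa).
#' @export
derate_source_pressure <- function(target_in_situ, alpha) {
  if (any(alpha >= 1)) stop("alpha must be < 1")
  target_in_situ / (1 - alpha)
}

#' Re-derate an in-situ pressure under a corrected insertion loss
#'
#' Post-hoc correction: the pressure actually delivered when the loss was
#' `alpha_new` but the power had been set assuming `alpha_old`:
#' `p_old * (1 - alpha_new) / (1 - alpha_old)`.
#'
#' @param p_old Originally targeted in-situ pressure (Pa).
#' @param alpha_old,alpha_new Original and corrected insertion losses (< 1).
#' @return Corrected in-situ pressure (Pa).
#' @export
rederate_pressure <- function(p_old, alpha_old, alpha_new) {
  if (any(alpha_old >= 1) || any(alpha_new >= 1))
    stop("insertion losses must be < 1")
  p_old * (1 - alpha_new) / (1 - alpha_old)
}

#' Mechanical index
#'
#' Peak-negative pressure in MPa divided by the square root of the frequency
#' in MHz.
#'
#' @param pnp Peak-negative pressure (Pa).
#' @param f Center frequency (Hz).
#' @return Unitless mechanical index.
#' @export
mechanical_index <- function(pnp, f) {
  if (any(pnp <= 0) || any(f <= 0)) stop("pnp and f must be positive")
  (pnp / 1e6) / sqrt(f / 1e6)
}
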