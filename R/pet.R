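#' Standardized uptake value ratio (SUVR)
#'
#' Mean uptake in a target region divided by mean uptake in the reference
#' region (here, cerebellar gray matter in the study design). Invariant to
#' global scaling of the PET volume.
#'
#' @param pet A [voxel_volume()] of tracer uptake.
#' @param region_mask,reference_mask Non-empty logical arrays on the PET grid.
#' @return Unitless SUVR.
#' @export
suvr <- function(pet, region_mask, reference_mask) {
  stopifnot(inherits(pet, "voxel_volume"),
            all(dim(region_mask) == dim(pet$data)),
            all(dim(reference_mask) == dim(pet$data)))
  if (!any(region_mask)) stop("empty region mask")
  if (!any(reference_mask)) stop("empty reference mask")
  ref <- mean(pet$data[reference_mask])
  if (ref == 0) stop("zero reference mean")
  mean(pet$data[region_mask]) / ref
}

#' Asymmetry SUVR
#'
#' Ratio of the treated-region SUVR to the contralateral-region SUVR; the
#' contralateral region is typically [mirror_mask()] of the treated one.
#'
#' @param suvr_treated,suvr_contralateral Unitless SUVRs.
#' @return Unitless ratio.
#' @export
asymmetry_suvr <- function(suvr_treated, suvr_contralateral) {
  if (suvr_contralateral == 0) stop("zero contralateral SUVR")
  suvr_treated / suvr_contralateral
}

#' Percent change between follow-up and baseline
#'
#' @param value_followup,value_baseline Unitless values; baseline must be
#'   non-zero.
#' @return `100 * (followup - baseline) / baseline` (percent).
#' @export
percent_change <- function(value_followup, value_baseline) {
  if (any(value_baseline == 0)) stop("zero baseline")
  100 * (value_followup - value_baseline) / value_baseline
}

#' Centiloid conversion
#'
#' Affine transform of SUVR onto the standardized 0-100 amyloid-burden
#' scale. Calibration constants come from external calibration and must be
#' supplied via configuration; nothing is hard-coded.
#'
#' @param suvr Unitless SUVR.
#' @param slope Centiloid units per SUVR.
#' @param intercept Centiloid offset.
#' @return Centiloid value.
#' @export
centiloid <- function(suvr, slope = NULL, intercept = NULL) {
  if (is.null(slope) || is.null(intercept))
    stop(paste("Centiloid calibration missing: supply config keys",
               "'centiloid$slope' and 'centiloid$intercept'"))
  slope * suvr + intercept
}

#' Full SUVR report for a baseline / follow-up PET pair
#'
#' Computes regional SUVRs, asymmetry SUVRs (treated / mirrored
#' contralateral), their percent changes, and the follow-up Centiloid value.
#'
#' @param baseline,followup [voxel_volume()]s on a shared grid.
#' @param treated_mask Logical array of the treated region.
#' @param reference_mask Logical array of the reference region.
#' @param contralateral_mask Optional; defaults to [mirror_mask()] of
#'   `treated_mask`.
#' @param centiloid_cal Optional list with `slope`, `intercept`.
#' @return A `suvr_report`: list with `suvr_baseline`, `suvr_followup`,
#'   `asym_baseline`, `asym_followup`, `pct_change_suvr`, `pct_change_asym`,
#'   `centiloid` (NA when no calibration given).
#' @export
suvr_report <- function(baseline, followup, treated_mask, reference_mask,
                        contralateral_mask = NULL, centiloid_cal = NULL) {
  if (is.null(contralateral_mask)) contralateral_mask <-
      mirror_mask(treated_mask)
  s_b <- suvr(baseline, treated_mask, reference_mask)
  s_f <- suvr(followup, treated_mask, reference_mask)
  c_b <- suvr(baseline, contralateral_mask, reference_mask)
  c_f <- suvr(followup, contralateral_mask, reference_mask)
  a_b <- asymmetry_suvr(s_b, c_b)
  a_f <- asymmetry_suvr(s_f, c_f)
  structure(list(
    suvr_baseline = s_b, suvr_followup = s_f,
    asym_baseline = a_b, asym_followup = a_f,
    pct_change_suvr = percent_change(s_f, s_b),
    pct_change_asym = percent_change(a_f, a_b),
    centiloid = if (is.null(centiloid_cal)) NA_real_
                else centiloid(s_f, centiloid_cal$slope,
                               centiloid_cal$intercept)
  ), class = "suvr_report")
}
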