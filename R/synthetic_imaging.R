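#' Voxel volume with a voxel-to-world affine
#'
#' Thin container pairing a 3-D intensity array with a NIfTI-style 4x4
#' voxel-to-world affine (0-based voxel indices, world mm).
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world transform (mm). Default: identity scaled
#'   by `spacing`.
#' @param spacing Voxel spacing in mm (used only when `affine` is missing).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, affine = NULL, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 3)
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
  }
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible")
  structure(list(data = data, affine = affine), class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("voxel_volume:", paste(dim(x$data), collapse = " x "),
      "| voxel volume", format(voxel_size_mm3(x)), "mm^3\n")
  invisible(x)
}

# physical volume of one voxel (mm^3) from the affine
voxel_size_mm3 <- function(vol) abs(det(vol$affine[1:3, 1:3]))

# world coordinates (n x 3) of all voxels, NIfTI convention (0-based indices)
voxel_world_coords <- function(vol) {
  d <- dim(vol$data)
  i <- slice.index(vol$data, 1) - 1
  j <- slice.index(vol$data, 2) - 1
  k <- slice.index(vol$data, 3) - 1
  A <- vol$affine
  cbind(A[1, 1] * i + A[1, 2] * j + A[1, 3] * k + A[1, 4],
        A[2, 1] * i + A[2, 2] * j + A[2, 3] * k + A[2, 4],
        A[3, 1] * i + A[3, 2] * j + A[3, 3] * k + A[3, 4])
}

#' FUS beam trajectory
#'
#' @param focus_point Focus position, world mm (length 3).
#' @param direction Beam axis direction (length 3); normalized if needed.
#' @param focal_dims -6 dB focal dimensions in mm (lateral, lateral, axial).
#'   Default 6 x 6 x 49 mm.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(focus_point, direction = c(0, 0, 1),
                       focal_dims = c(6, 6, 49)) {
  stopifnot(length(focus_point) == 3, length(direction) == 3,
            all(focal_dims > 0))
  nd <- sqrt(sum(direction^2))
  if (nd == 0) stop("direction must be non-zero")
  structure(list(focus_point = as.numeric(focus_point),
                 direction = direction / nd,
                 focal_dims = as.numeric(focal_dims)),
            class = "trajectory")
}

# orthonormal basis (e1, e2, d) with third axis along `d`
axis_basis <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  cbind(e1, e2, d)
}

# logical array: voxels inside an ellipsoid of volume `volume_mm3` centered on
# `centroid`, elongated along `direction` by `axial_ratio`
ellipsoid_mask <- function(template, centroid, direction, volume_mm3,
                           axial_ratio = 3) {
  a <- (3 * volume_mm3 / (4 * pi * axial_ratio))^(1 / 3)
  cax <- axial_ratio * a
  B <- axis_basis(direction / sqrt(sum(direction^2)))
  w <- voxel_world_coords(template)
  u <- sweep(w, 2, centroid)
  q <- (u %*% B[, 1] / a)^2 + (u %*% B[, 2] / a)^2 + (u %*% B[, 3] / cax)^2
  array(q <= 1, dim = dim(template$data))
}

#' Generate a paired day-0 / day-3 post-contrast T1 volume
#'
#' Day 0 is a constant background plus Gaussian noise plus `contrast` added
#' inside an ellipsoid of the truth opening volume, centered on the truth
#' centroid and elongated along the trajectory direction. Day 3 is background
#' plus independent noise. Both volumes share the identical affine.
#'
#' @param shape Grid shape in voxels (length 3), default 64^3.
#' @param spacing Voxel spacing in mm, default 1 mm isotropic.
#' @param trajectory A [trajectory()].
#' @param truth A [synthetic_truth()] (uses `opening_volume_mm3` and
#'   `opening_centroid`).
#' @param contrast Added enhancement intensity inside the ellipsoid.
#' @param noise_sigma Gaussian noise sd per volume. The operative
#'   contrast-to-noise ratio of the subtraction image is
#'   `contrast / (sqrt(2) * noise_sigma)` (both volumes contribute noise);
#'   the defaults give CNR ~= 5.
#' @param background Constant background intensity.
#' @param axial_ratio Ellipsoid elongation along the beam axis, default 3.
#' @param seed Integer seed.
#'
#' @return List with `day0`, `day3` ([voxel_volume()]s) and `truth_mask`
#'   (logical array of the analytic ellipsoid voxelization).
#' @export
gen_mri_pair <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         trajectory, truth, contrast = 70, noise_sigma = 10,
                         background = 100, axial_ratio = 3, seed = 1L) {
  if (any(spacing <= 0)) stop("spacing must be positive")
  stopifnot(inherits(trajectory, "trajectory"),
            inherits(truth, "synthetic_truth"))
  affine <- diag(4); diag(affine)[1:3] <- spacing
  template <- voxel_volume(array(0, shape), affine)
  mask <- array(FALSE, shape)
  if (truth$opening_volume_mm3 > 0) {
    a <- (3 * truth$opening_volume_mm3 / (4 * pi * axial_ratio))^(1 / 3)
    semi <- c(a, a, axial_ratio * a)  # semi-axes: lateral x2, then axial
    ext <- shape * spacing
    if (any(truth$opening_centroid - max(semi) < 0) ||
        any(truth$opening_centroid + max(semi) > ext))
      stop("truth ellipsoid does not fit inside the field of view")
    mask <- ellipsoid_mask(template, truth$opening_centroid,
                           trajectory$direction, truth$opening_volume_mm3,
                           axial_ratio)
  }
  vols <- withr::with_seed(seed, {
    n <- prod(shape)
    d0 <- background + array(rnorm(n, sd = noise_sigma), shape)
    d0[mask] <- d0[mask] + contrast
    d3 <- background + array(rnorm(n, sd = noise_sigma), shape)
    list(d0, d3)
  })
  list(day0 = voxel_volume(vols[[1]], affine),
       day3 = voxel_volume(vols[[2]], affine),
       truth_mask = mask)
}

#' Generate a baseline / follow-up PET pair with lateralized uptake change
#'
#' Baseline uptake is `reference_mean` everywhere, raised to
#' `region_suvr * reference_mean` inside the treated and contralateral
#' regions (amyloid-positive target). At follow-up the treated-side mean is
#' multiplied by `asymmetry_factor`; the contralateral side and the reference
#' region are unchanged in expectation.
#'
#' @param shape Grid shape, default 48^3.
#' @param spacing Voxel spacing mm, default 2 mm isotropic.
#' @param asymmetry_factor Treated-side multiplicative change (> 0).
#' @param reference_mean Mean uptake in the reference region.
#' @param region_suvr Baseline SUVR of target regions, default 1.4.
#' @param noise_sigma Gaussian noise sd (0 gives exact recovery).
#' @param seed Integer seed.
#'
#' @return List with `baseline`, `followup` ([voxel_volume()]s) and `masks`
#'   (logical arrays `treated`, `contralateral`, `reference`). The grid is
#'   mid-sagittal-plane symmetric: `contralateral = mirror_mask(treated)`.
#' @export
gen_pet_pair <- function(shape = c(48, 48, 48), spacing = c(2, 2, 2),
                         asymmetry_factor = 0.9853, reference_mean = 1,
                         region_suvr = 1.4, noise_sigma = 0, seed = 1L) {
  if (asymmetry_factor <= 0) stop("asymmetry_factor must be > 0")
  if (any(spacing <= 0)) stop("spacing must be positive")
  affine <- diag(4); diag(affine)[1:3] <- spacing
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  treated <- array(FALSE, shape)
  treated[(ceiling(nx * 0.62)):(ceiling(nx * 0.85)),
          (ceiling(ny * 0.40)):(ceiling(ny * 0.65)),
          (ceiling(nz * 0.55)):(ceiling(nz * 0.80))] <- TRUE
  contralateral <- mirror_mask(treated)
  reference <- array(FALSE, shape)
  reference[(ceiling(nx * 0.30)):(ceiling(nx * 0.70)),
            (ceiling(ny * 0.30)):(ceiling(ny * 0.70)),
            1:(ceiling(nz * 0.15))] <- TRUE
  if (!any(reference)) stop("empty reference mask")
  base_mean <- array(reference_mean, shape)
  base_mean[treated | contralateral] <- region_suvr * reference_mean
  fu_mean <- base_mean
  fu_mean[treated] <- base_mean[treated] * asymmetry_factor
  vols <- withr::with_seed(seed, {
    n <- prod(shape)
    list(base_mean + array(rnorm(n, sd = noise_sigma), shape),
         fu_mean + array(rnorm(n, sd = noise_sigma), shape))
  })
  list(baseline = voxel_volume(vols[[1]], affine),
       followup = voxel_volume(vols[[2]], affine),
       masks = list(treated = treated, contralateral = contralateral,
                    reference = reference))
}

#' Mirror a mask across the mid-sagittal plane of its grid
#'
#' Flips the first (left-right) array index. Used to obtain contralateral
#' regions on mid-plane-symmetric grids.
#'
#' @param mask 3-D logical array.
#' @return The mirrored array.
#' @export
mirror_mask <- function(mask) {
  mask[rev(seq_len(dim(mask)[1])), , , drop = FALSE]
}

#' Read/write voxel volumes as NIfTI-1
#'
#' @param vol A [voxel_volume()].
#' @param path Output file (`.nii` / `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` a
#'   [voxel_volume()].
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  voxel_volume(array(as.numeric(img), dim = dim(img)),
               structure(RNifti::xform(img), code = NULL))
}
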