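#' @importFrom stats median mad qnorm dnorm pnorm quantile sd
#' @importFrom utils head tail
NULL

#' Subtract the day-3 from the day-0 post-contrast volume
#'
#' @param day0,day3 [voxel_volume()]s on the identical grid (registration is
#'   assumed already applied); affines must agree within 1e-6.
#' @return A [voxel_volume()] of voxelwise `day0 - day3`.
#' @export
subtract_volumes <- function(day0, day3) {
  stopifnot(inherits(day0, "voxel_volume"), inherits(day3, "voxel_volume"))
  if (!all(dim(day0$data) == dim(day3$data)))
    stop("volumes differ in grid shape")
  if (max(abs(day0$affine - day3$affine)) > 1e-6)
    stop("volumes differ in affine beyond 1e-6")
  voxel_volume(day0$data - day3$data, day0$affine)
}

# binary dilation by `iterations` steps of the 6-neighborhood
dilate_mask <- function(mask, iterations = 1L) {
  d <- dim(mask)
  out <- mask
  for (it in seq_len(iterations)) {
    m <- out
    out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
    out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
    out[, , -1] <- out[, , -1] | m[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  }
  out
}

# 26-connected component labelling of a 3-D logical array by union-find.
# Returns an integer array (0 = background) with labels 1..k.
label_components <- function(mask) {
  d <- dim(mask)
  pos <- which(mask)
  n <- length(pos)
  lab <- array(0L, d)
  if (n == 0) return(lab)
  id <- array(0L, d)
  id[pos] <- seq_len(n)
  co <- arrayInd(pos, d)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[offsets %*% c(1, 3, 9) > 0, , drop = FALSE]  # forward half
  for (r in seq_len(nrow(offsets))) {
    nb <- co + matrix(offsets[r, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nlin <- (nb[ok, 3] - 1L) * (d[1] * d[2]) + (nb[ok, 2] - 1L) * d[1] +
      nb[ok, 1]
    nid <- id[nlin]
    a_ids <- which(ok)[nid > 0L]
    b_ids <- nid[nid > 0L]
    for (k in seq_along(a_ids)) {
      ra <- find(a_ids[k]); rb <- find(b_ids[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  lab[pos] <- match(roots, unique(roots))
  lab
}

#' Adaptive Gaussian-confidence threshold for the subtracted volume
#'
#' Selects the opening threshold from a descending percentile sweep under the
#' assumption that the subtracted image's background intensity is Gaussian:
#' the candidate threshold is the lowest sweep percentile that still exceeds
#' the one-sided `confidence` bound of a robust background fit
#' (`median + qnorm(confidence) * mad`). The candidate is then validated by a
#' one-sided z-test of the largest 26-connected suprathreshold component
#' against the truncated-Gaussian selection null (background mean and sd
#' estimated from a 3-voxel dilation shell around the suprathreshold region):
#' thresholding alone pushes the suprathreshold mean above the background
#' mean even in pure noise, so the test compares against the expectation of
#' that selection effect rather than against the raw shell mean. If no sweep
#' percentile qualifies, or the validation fails, a sentinel (`NA`) is
#' returned: no opening.
#'
#' @param difference A [voxel_volume()] (day0 - day3).
#' @param confidence Confidence level, default 0.98.
#' @param search_mask Optional logical array restricting the analysis.
#' @param sweep Descending percentile sweep, default `seq(99.9, 90, -0.1)`.
#' @param min_component Minimum voxel count of the largest component for the
#'   validation test, default 5.
#' @return The selected threshold (intensity units), with attributes `z`
#'   (validation statistic) and `component_size`; or `NA` with attribute
#'   `reason` when no opening is detected.
#' @export
auto_threshold <- function(difference, confidence = 0.98, search_mask = NULL,
                           sweep = seq(99.9, 90, by = -0.1),
                           min_component = 5L) {
  stopifnot(inherits(difference, "voxel_volume"),
            confidence > 0.5, confidence < 1)
  dat <- difference$data
  if (is.null(search_mask)) search_mask <- array(TRUE, dim(dat))
  vals <- dat[search_mask]
  if (length(vals) < 1000)
    stop("need >= 1000 voxels in the search mask")
  sentinel <- function(reason)
    structure(NA_real_, reason = reason)
  if (sd(vals) == 0) return(sentinel("constant difference volume"))
  mu <- median(vals)
  sigma <- mad(vals)
  if (sigma == 0) return(sentinel("degenerate intensity spread"))
  bound <- mu + qnorm(confidence) * sigma
  qs <- quantile(vals, probs = sweep / 100, names = FALSE)
  qual <- qs[qs >= bound]
  if (length(qual) == 0)
    return(sentinel("no sweep percentile above the Gaussian confidence bound"))
  T0 <- min(qual)
  supra <- dat > T0 & search_mask
  lab <- label_components(supra)
  if (max(lab) == 0) return(sentinel("no suprathreshold voxels"))
  sizes <- tabulate(lab[lab > 0L])
  big <- which.max(sizes)
  n_c <- sizes[big]
  if (n_c < min_component) return(sentinel("largest component too small"))
  shell <- dilate_mask(supra, 3L) & !supra & search_mask
  if (sum(shell) < 10) return(sentinel("empty surrounding shell"))
  m_s <- mean(dat[shell])
  s_s <- sd(dat[shell])
  if (s_s == 0) return(sentinel("degenerate shell"))
  z0 <- (T0 - m_s) / s_s
  lam <- dnorm(z0) / pnorm(z0, lower.tail = FALSE)
  m_null <- m_s + s_s * lam                   # truncated-Gaussian mean
  v_null <- s_s^2 * (1 + z0 * lam - lam^2)    # truncated-Gaussian variance
  x_c <- dat[lab == big]
  z <- (mean(x_c) - m_null) /
    sqrt(v_null / n_c + s_s^2 / sum(shell))
  if (z <= qnorm(confidence))
    return(sentinel(sprintf(
      "largest component consistent with noise selection (z = %.2f)", z)))
  structure(T0, z = z, component_size = n_c)
}

#' Quantify the opening from a thresholded subtraction volume
#'
#' Binarizes at the threshold, keeps 26-connected components of at least
#' `min_component_voxels` whose centroid lies within `cylinder_radius` mm of
#' the trajectory axis, and reports geometric and tissue metrics.
#'
#' @param difference A [voxel_volume()].
#' @param threshold Intensity threshold from [auto_threshold()] (`NA` yields
#'   a zero-volume result).
#' @param trajectory A [trajectory()] (axis and focus point).
#' @param gm_mask,wm_mask Optional logical arrays on the same grid.
#' @param cylinder_radius Gating radius around the trajectory axis (mm).
#' @param min_component_voxels Minimum component size kept, default 10.
#' @return An `opening_result`: list with `mask` (logical array),
#'   `threshold`, `volume_mm3`, `centroid` (world mm, intensity-weighted),
#'   `distance_to_focus` (mm), `gm_fraction`, `wm_fraction`.
#' @export
quantify_opening <- function(difference, threshold, trajectory,
                             gm_mask = NULL, wm_mask = NULL,
                             cylinder_radius = 15, min_component_voxels = 10L) {
  stopifnot(inherits(difference, "voxel_volume"),
            inherits(trajectory, "trajectory"))
  empty <- structure(list(
    mask = array(FALSE, dim(difference$data)), threshold = threshold,
    volume_mm3 = 0, centroid = rep(NA_real_, 3),
    distance_to_focus = NA_real_, gm_fraction = NA_real_,
    wm_fraction = NA_real_), class = "opening_result")
  if (is.na(threshold)) return(empty)
  dat <- difference$data
  mask <- dat > threshold
  lab <- label_components(mask)
  if (max(lab) == 0) return(empty)
  w <- voxel_world_coords(difference)
  keep <- logical(max(lab))
  d_axis <- trajectory$direction
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k)
    if (length(idx) < min_component_voxels) next
    cen <- colMeans(w[idx, , drop = FALSE])
    v <- cen - trajectory$focus_point
    perp <- v - sum(v * d_axis) * d_axis
    keep[k] <- sqrt(sum(perp^2)) <= cylinder_radius
  }
  if (!any(keep)) return(empty)
  final <- array(lab > 0 & keep[pmax(lab, 1L)], dim(dat))
  idx <- which(final)
  vol <- length(idx) * voxel_size_mm3(difference)
  wt <- dat[idx]
  centroid <- colSums(w[idx, , drop = FALSE] * wt) / sum(wt)
  structure(list(
    mask = final, threshold = as.numeric(threshold), volume_mm3 = vol,
    centroid = centroid,
    distance_to_focus = sqrt(sum((centroid - trajectory$focus_point)^2)),
    gm_fraction = if (is.null(gm_mask)) NA_real_
                  else mean(gm_mask[idx]),
    wm_fraction = if (is.null(wm_mask)) NA_real_
                  else mean(wm_mask[idx])
  ), class = "opening_result")
}

#' Dice overlap of two binary masks
#' @param a,b Logical arrays of identical shape.
#' @return Dice coefficient in `[0, 1]` (1 when both masks are empty).
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
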