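#' Reconstruction grid in the imaging plane
#'
#' Pixel centers in the array's imaging plane (y = 0): lateral positions `x`
#' and depths `z`, world mm.
#'
#' @param x_range,z_range Length-2 extents in mm.
#' @param spacing Pixel size in mm, default 0.5.
#' @return A `pam_grid`: list with `x`, `z` (pixel-center vectors),
#'   `spacing`, `origin`.
#' @export
pam_grid <- function(x_range = c(-8, 8), z_range = c(22, 38), spacing = 0.5) {
  stopifnot(spacing > 0)
  x <- seq(x_range[1], x_range[2], by = spacing)
  z <- seq(z_range[1], z_range[2], by = spacing)
  structure(list(x = x, z = z, spacing = spacing,
                 origin = c(x[1], z[1])), class = "pam_grid")
}

#' One-way travel delays from every pixel to every element
#'
#' Receive-only delays for passive listening: Euclidean distance divided by
#' the sound speed. No transmit delay exists because cavitation sources emit.
#'
#' @param grid A [pam_grid()].
#' @param geometry An [array_geometry()].
#' @return Matrix (n_pixels x n_elements) of delays in seconds. Pixels are
#'   ordered with `x` varying fastest (column-major over the x-z grid).
#' @export
travel_delays <- function(grid, geometry) {
  stopifnot(inherits(grid, "pam_grid"), inherits(geometry, "array_geometry"))
  px <- as.matrix(expand.grid(x = grid$x, z = grid$z))
  ep <- geometry$element_positions
  d <- outer(px[, "x"], ep[, 1], "-")^2
  d <- d + outer(px[, "z"], ep[, 3], "-")^2
  sqrt(d) / 1000 / geometry$c
}

#' Coherence factor of aligned channel data
#'
#' `cf(t) = |sum_i s_i(t)|^2 / (N * sum_i s_i(t)^2)`, defined as 0 where the
#' denominator is 0. Bounded in `[0, 1]` and invariant to scaling all
#' channels by a constant.
#'
#' @param aligned Channels x time matrix of delay-aligned samples.
#' @return Numeric vector of per-sample coherence factors.
#' @export
coherence_factor <- function(aligned) {
  stopifnot(is.matrix(aligned), nrow(aligned) >= 2)
  num <- colSums(aligned)^2
  den <- nrow(aligned) * colSums(aligned^2)
  cf <- ifelse(den > 0, num / den, 0)
  pmin(pmax(cf, 0), 1)
}

# shared index arithmetic: integer/fractional sample delays and the common
# valid output length for one pixel
pixel_delay_parts <- function(delays_s, fs, n_samp) {
  tau <- delays_s * fs
  i0 <- floor(tau)
  list(i0 = i0, fr = tau - i0, n_valid = n_samp - max(i0) - 1L)
}

#' Coherence-factor-weighted delay-and-sum cavitation map for one burst
#'
#' For each pixel, channels are aligned by the one-way travel delays with
#' sub-sample linear interpolation; the pixel energy is
#' `sum_t cf(t) * (sum_i s_i(t + delay_i))^2`. Pixels whose delay spread
#' leaves fewer than `min_samples` aligned samples are flagged invalid (NA).
#'
#' @param burst Channels x samples RF matrix.
#' @param grid A [pam_grid()].
#' @param geometry An [array_geometry()].
#' @param delays Optional precomputed [travel_delays()] matrix (reused across
#'   bursts for speed).
#' @param min_samples Minimum aligned-sample count for a valid pixel.
#' @return A `cavitation_map`: list with `energies` (nx x nz matrix, linear),
#'   `grid`, `is_db = FALSE`.
#' @export
pam_burst_map <- function(burst, grid, geometry, delays = NULL,
                          min_samples = 32L) {
  stopifnot(is.matrix(burst), nrow(burst) == geometry$n_elements)
  if (is.null(delays)) delays <- travel_delays(grid, geometry)
  n_samp <- ncol(burst)
  nc <- nrow(burst)
  st <- t(burst)                              # samples x channels
  col_off <- (seq_len(nc) - 1L) * n_samp
  n_pix <- nrow(delays)
  energies <- rep(NA_real_, n_pix)
  for (p in seq_len(n_pix)) {
    dp <- pixel_delay_parts(delays[p, ], geometry$fs, n_samp)
    nv <- dp$n_valid
    if (nv < min_samples) next
    tt <- seq_len(nv)
    idx <- outer(tt, dp$i0, "+")              # nv x nc, base sample index
    lin <- sweep(idx, 2, col_off, "+")
    frm <- matrix(dp$fr, nv, nc, byrow = TRUE)
    a <- st[lin] * (1 - frm) + st[lin + 1L] * frm
    dim(a) <- c(nv, nc)
    coh <- rowSums(a)
    den <- nc * rowSums(a^2)
    cf <- ifelse(den > 0, coh^2 / den, 0)
    energies[p] <- sum(cf * coh^2)
  }
  structure(list(
    energies = matrix(energies, nrow = length(grid$x)),
    grid = grid, is_db = FALSE
  ), class = "cavitation_map")
}

#' Naive triple-loop reference beamformer
#'
#' Literal per-pixel / per-sample / per-channel implementation of the same
#' quantity as [pam_burst_map()], kept as an independent reference for
#' equivalence testing. Only suitable for small grids.
#'
#' @inheritParams pam_burst_map
#' @return A `cavitation_map` (linear energies).
#' @export
pam_burst_map_naive <- function(burst, grid, geometry, delays = NULL,
                                min_samples = 32L) {
  stopifnot(is.matrix(burst), nrow(burst) == geometry$n_elements)
  if (is.null(delays)) delays <- travel_delays(grid, geometry)
  n_samp <- ncol(burst)
  nc <- nrow(burst)
  n_pix <- nrow(delays)
  energies <- rep(NA_real_, n_pix)
  for (p in seq_len(n_pix)) {
    dp <- pixel_delay_parts(delays[p, ], geometry$fs, n_samp)
    if (dp$n_valid < min_samples) next
    e <- 0
    for (t in seq_len(dp$n_valid)) {
      coh <- 0
      sq <- 0
      for (i in seq_len(nc)) {
        j <- t + dp$i0[i]
        v <- burst[i, j] * (1 - dp$fr[i]) + burst[i, j + 1L] * dp$fr[i]
        coh <- coh + v
        sq <- sq + v * v
      }
      den <- nc * sq
      if (den > 0) e <- e + (coh * coh / den) * coh * coh
    }
    energies[p] <- e
  }
  structure(list(
    energies = matrix(energies, nrow = length(grid$x)),
    grid = grid, is_db = FALSE
  ), class = "cavitation_map")
}

#' Average burst maps over a burst selection and mask to the brain
#'
#' Pixelwise mean of the linear energy maps over the selected bursts, masked,
#' and optionally converted to dB relative to the map maximum.
#'
#' @param maps List of `cavitation_map`s sharing one grid.
#' @param post_injection Integer indices of the bursts to average (typically
#'   bursts after the microbubble injection).
#' @param brain_mask Optional logical matrix on the map grid; pixels outside
#'   become NA.
#' @param db Convert to dB relative to the masked map maximum (default TRUE).
#' @return A `cavitation_map` (dB when `db = TRUE`, else linear) with the
#'   mask stored in `$brain_mask`.
#' @export
average_and_mask <- function(maps, post_injection = seq_along(maps),
                             brain_mask = NULL, db = TRUE) {
  if (length(post_injection) == 0) stop("empty burst selection")
  sel <- maps[post_injection]
  g <- sel[[1]]$grid
  for (m in sel)
    if (!isTRUE(all.equal(m$grid, g))) stop("maps do not share a grid")
  acc <- Reduce(`+`, lapply(sel, function(m) m$energies)) / length(sel)
  if (!is.null(brain_mask)) {
    stopifnot(all(dim(brain_mask) == dim(acc)))
    acc[!brain_mask] <- NA_real_
  }
  if (db) {
    ref <- suppressWarnings(max(acc, na.rm = TRUE))
    acc <- if (is.finite(ref) && ref > 0) 10 * log10(acc / ref)
           else acc * NA_real_
  }
  structure(list(energies = acc, grid = g, is_db = db,
                 brain_mask = brain_mask),
            class = "cavitation_map")
}

#' Grid position of the map energy peak
#' @param map A `cavitation_map`.
#' @return Named vector `c(x, z)` in mm of the pixel with maximum energy.
#' @export
map_peak_position <- function(map) {
  idx <- which(map$energies == max(map$energies, na.rm = TRUE),
               arr.ind = TRUE)[1, ]
  c(x = map$grid$x[idx[1]], z = map$grid$z[idx[2]])
}

#' Energy-weighted centroid of the map's -3 dB peak region
#'
#' Localization refinement for off-axis sources: the point-spread ridge of a
#' finite-aperture passive map is tilted along the source-to-array radial
#' direction, so the raw argmax can slide along the ridge by more than a
#' pixel; the energy-weighted centroid of the half-maximum region is centered
#' on the source.
#'
#' @param map A `cavitation_map` with linear energies.
#' @return Named vector `c(x, z)` in mm.
#' @export
map_peak_centroid <- function(map) {
  stopifnot(!isTRUE(map$is_db))
  e <- map$energies
  mx <- max(e, na.rm = TRUE)
  sel <- which(!is.na(e) & e >= mx / 2, arr.ind = TRUE)
  w <- e[cbind(sel[, 1], sel[, 2])]
  c(x = sum(map$grid$x[sel[, 1]] * w) / sum(w),
    z = sum(map$grid$z[sel[, 2]] * w) / sum(w))
}

#' Pixel-wise ROC and precision-recall analysis of a cavitation map
#'
#' Sweeps a threshold over the map energies against a binary reference (the
#' projected opening mask) and integrates the ROC and PR curves by the
#' trapezoidal rule. Pooling concatenates pixels across subjects before the
#' sweep.
#'
#' @param map A `cavitation_map` (any monotone scale).
#' @param reference Logical matrix on the map grid; must contain at least one
#'   positive and one negative pixel.
#' @param pooled_subjects Optional list of further `list(map=, reference=)`
#'   pairs whose pixels are pooled with the first.
#' @return List with `auroc`, `aupr`, `roc` (data.frame fpr/tpr) and `pr`
#'   (data.frame recall/precision).
#' @export
roc_pr_pixelwise <- function(map, reference, pooled_subjects = NULL) {
  collect <- function(m, r) {
    stopifnot(all(dim(r) == dim(m$energies)))
    ok <- !is.na(m$energies)
    list(score = as.numeric(m$energies[ok]), label = as.logical(r[ok]))
  }
  parts <- c(list(collect(map, reference)),
             lapply(pooled_subjects, function(s) collect(s$map, s$reference)))
  score <- unlist(lapply(parts, `[[`, "score"))
  label <- unlist(lapply(parts, `[[`, "label"))
  P <- sum(label); N <- sum(!label)
  if (P == 0 || N == 0)
    stop("reference must contain at least one positive and one negative pixel")
  o <- order(score, decreasing = TRUE)
  s <- score[o]; y <- label[o]
  # group ties: cumulative counts at each distinct threshold
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  fp <- cumsum(!y)[last]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  prec <- tp / (tp + fp)
  rec <- tp / P
  rec2 <- c(0, rec); prec2 <- c(prec[1], prec)
  aupr <- sum(diff(rec2) * (head(prec2, -1) + tail(prec2, -1)) / 2)
  list(auroc = auroc, aupr = aupr,
       roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = rec2, precision = prec2))
}
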