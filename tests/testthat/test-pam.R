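test_that("travel delays are geometric one-way delays", {
  geom <- array_geometry()
  grid <- pam_grid(c(0, 0), c(60, 60), 0.5)  # single on-axis pixel at 60 mm
  d <- travel_delays(grid, geom)
  # central pair of the 64-element array straddles x = 0 symmetrically
  expect_equal(unname(d[1, 32]), unname(d[1, 33]))
  # hand arithmetic: 60 mm at 1540 m/s = 38.96 us for a central element
  d_center <- sqrt(0.25^2 + 60^2) / 1000 / 1540
  expect_equal(unname(d[1, 32]), d_center, tolerance = 1e-12)
  expect_equal(d_center * 1e6, 38.96, tolerance = 1e-3)
  # delays scale as 1/c
  geom2 <- array_geometry(c = 770)
  expect_equal(travel_delays(grid, geom2), 2 * d, tolerance = 1e-12)
})

test_that("coherence factor is bounded, scale-invariant, and calibrated", {
  # identical channels: cf = 1 everywhere
  a <- matrix(rep(rnorm(50), each = 8), 8)
  expect_equal(coherence_factor(a), rep(1, 50), tolerance = 1e-12)
  # exactly one nonzero channel: cf = 1/N
  b <- matrix(0, 16, 30); b[5, ] <- rnorm(30)
  expect_equal(coherence_factor(b), rep(1 / 16, 30), tolerance = 1e-12)
  # independent noise: mean cf ~ 1/N within 20%
  n <- withr::with_seed(1, matrix(rnorm(64 * 2000), 64))
  expect_lt(abs(mean(coherence_factor(n)) - 1 / 64) / (1 / 64), 0.2)
  # scale invariance and bounds
  expect_equal(coherence_factor(7.3 * n), coherence_factor(n),
               tolerance = 1e-12)
  cf <- coherence_factor(n)
  expect_true(all(cf >= 0 & cf <= 1))
})

test_that("optimized beamformer matches the naive triple-loop reference", {
  geom <- array_geometry(n_elements = 16, pitch = 2)
  tr <- quick_truth(x = 1.1, z = 28.4)
  rf <- quick_rf(tr, geometry = geom, noise_sigma = 0.01, n_samples = 400)
  b <- get_burst(rf, 2)
  grid <- pam_grid(c(-3, 4.5), c(25, 32.5), 0.5)  # 16 x 16
  mo <- pam_burst_map(b, grid, geom)
  mn <- pam_burst_map_naive(b, grid, geom)
  rel <- abs(mo$energies - mn$energies) / pmax(abs(mn$energies), 1e-300)
  expect_lt(max(rel, na.rm = TRUE), 1e-9)
})

test_that("a single point source is localized within one grid cell", {
  # coaxial monitoring geometry: source near the beam axis, off-node depth
  tr <- quick_truth(x = 0, z = 29.2)
  rf <- quick_rf(tr, noise_sigma = 0)
  grid <- pam_grid(c(-6, 6), c(24, 36), 0.5)
  m <- pam_burst_map(get_burst(rf, 2), grid, array_geometry())
  pk <- map_peak_position(m)
  expect_lte(abs(pk["x"] - 0), grid$spacing + 1e-9)
  expect_lte(abs(pk["z"] - 29.2), grid$spacing + 1e-9)
  # half-maximum centroid refinement is also sub-cell for this source
  cen <- map_peak_centroid(m)
  expect_lt(sqrt(sum((cen - c(0, 29.2))^2)), grid$spacing + 1e-9)
})

test_that("beamformer is equivariant to lateral translation of source and grid", {
  dx <- 1.5
  m1 <- pam_burst_map(get_burst(quick_rf(quick_truth(x = 0, z = 29.2)), 2),
                      pam_grid(c(-4, 4), c(26, 33), 0.5), array_geometry())
  m2 <- pam_burst_map(get_burst(quick_rf(quick_truth(x = dx, z = 29.2)), 2),
                      pam_grid(c(-4, 4) + dx, c(26, 33), 0.5),
                      array_geometry())
  p1 <- map_peak_position(m1)
  p2 <- map_peak_position(m2)
  expect_lte(abs((p2["x"] - p1["x"]) - dx), 0.5 + 1e-9)
  expect_lte(abs(p2["z"] - p1["z"]), 0.5 + 1e-9)
})

test_that("energy maps are invariant to consistent channel permutation", {
  geom <- array_geometry(n_elements = 16, pitch = 2)
  rf <- quick_rf(quick_truth(), geometry = geom, noise_sigma = 0.01,
                 n_samples = 400)
  b <- get_burst(rf, 2)
  grid <- pam_grid(c(-2, 2), c(27, 31), 0.5)
  perm <- withr::with_seed(8, sample(16))
  geom_p <- geom
  geom_p$element_positions <- geom$element_positions[perm, ]
  m1 <- pam_burst_map(b, grid, geom)
  m2 <- pam_burst_map(b[perm, ], grid, geom_p)
  expect_equal(m2$energies, m1$energies, tolerance = 1e-12)
})

test_that("pure noise and zero input give flat or empty maps", {
  geom <- array_geometry()
  grid <- pam_grid(c(-6, 6), c(24, 36), 0.5)
  tr0 <- synthetic_truth(source_band_amplitudes = matrix(0, 1, 3),
                         onset_burst_index = 1L)
  rf <- quick_rf(tr0, noise_sigma = 0.01, seed = 21)
  m <- pam_burst_map(get_burst(rf, 1), grid, geom)
  ratio_db <- 10 * log10(max(m$energies, na.rm = TRUE) /
                         median(m$energies, na.rm = TRUE))
  expect_lt(ratio_db, 6)  # no spurious hot spot
  z <- pam_burst_map(matrix(0, 64, 600), pam_grid(c(-2, 2), c(27, 30), 0.5),
                     geom)
  expect_true(all(z$energies[!is.na(z$energies)] == 0))
})

test_that("average_and_mask averages, masks, and scales to dB", {
  geom <- array_geometry(n_elements = 16, pitch = 2)
  rf <- quick_rf(quick_truth(), geometry = geom, noise_sigma = 0,
                 n_samples = 400)
  grid <- pam_grid(c(-2, 2), c(27, 31), 0.5)
  m <- pam_burst_map(get_burst(rf, 2), grid, geom)
  avg <- average_and_mask(list(m, m, m), db = FALSE)
  expect_equal(avg$energies, m$energies, tolerance = 1e-12)
  # dB map is referenced to its own maximum
  avg_db <- average_and_mask(list(m, m), db = TRUE)
  expect_equal(max(avg_db$energies, na.rm = TRUE), 0)
  # all-false mask empties the map
  off <- average_and_mask(list(m), brain_mask = matrix(FALSE, length(grid$x),
                                                       length(grid$z)))
  expect_true(all(is.na(off$energies)))
  expect_error(average_and_mask(list(m), post_injection = integer(0)),
               "empty")
})

test_that("a 4x source-amplitude ratio appears as ~12 dB map difference", {
  geom <- array_geometry()
  grid <- pam_grid(c(-4, 4), c(26, 33), 0.5)
  p <- sonication_protocol(duration = 3, prf = 1, injection_time = 0,
                           flush_time = 0)
  peak_energy <- function(scale, seed) {
    tr <- synthetic_truth(source_positions = matrix(c(0, 0, 29.2), 1, 3),
                          source_band_amplitudes =
                            scale * matrix(c(1, 1, 0.5), 1, 3),
                          onset_burst_index = 1L)
    rf <- gen_array_rf(geom, tr, p, noise_sigma = 1e-4, seed = seed)
    maps <- lapply(2:3, function(b)
      pam_burst_map(get_burst(rf, b), grid, geom))
    max(average_and_mask(maps, db = FALSE)$energies, na.rm = TRUE)
  }
  diff_db <- 10 * log10(peak_energy(4, 31) / peak_energy(1, 32))
  expect_lt(abs(diff_db - 12.04), 1)
})

test_that("pixelwise ROC/PR behaves analytically on degenerate maps", {
  grid <- pam_grid(c(0, 4.5), c(20, 24.5), 0.5)  # 10 x 10
  ref <- matrix(FALSE, 10, 10); ref[3:5, 4:7] <- TRUE
  # map equal to the mask
  m <- structure(list(energies = ref + 0, grid = grid, is_db = FALSE),
                 class = "cavitation_map")
  r <- roc_pr_pixelwise(m, ref)
  expect_equal(r$auroc, 1)
  expect_equal(r$aupr, 1)
  # constant map
  mc <- structure(list(energies = matrix(1, 10, 10), grid = grid,
                       is_db = FALSE), class = "cavitation_map")
  rc <- roc_pr_pixelwise(mc, ref)
  expect_equal(rc$auroc, 0.5)
  expect_equal(rc$aupr, mean(ref))
  expect_error(roc_pr_pixelwise(mc, matrix(TRUE, 10, 10)), "positive")
})

test_that("random maps give chance-level AUCs, matching an independent oracle", {
  skip_if_not_installed("pROC")
  n <- 110
  ref <- withr::with_seed(2, matrix(runif(n * n) < 0.3, n, n))
  m <- structure(list(
    energies = withr::with_seed(3, matrix(rnorm(n * n), n, n)),
    grid = pam_grid(c(0, (n - 1) * 0.5), c(20, 20 + (n - 1) * 0.5), 0.5),
    is_db = FALSE), class = "cavitation_map")
  r <- roc_pr_pixelwise(m, ref)
  expect_lt(abs(r$auroc - 0.5), 0.05)
  expect_lt(abs(r$aupr - mean(ref)), 0.05)
  oracle <- as.numeric(pROC::auc(pROC::roc(as.vector(ref),
                                           as.vector(m$energies),
                                           quiet = TRUE,
                                           direction = "<")))
  expect_equal(r$auroc, oracle, tolerance = 1e-9)
})
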