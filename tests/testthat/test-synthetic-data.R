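test_that("burst count equals prf * duration and protocol invariants hold", {
  p <- sonication_protocol(prf = 2, duration = 120)
  expect_identical(p$n_bursts, 240L)
  rec <- gen_pcd_timeseries(quick_protocol(), quick_truth(onset = 11L),
                            seed = 1)
  expect_equal(nrow(rec$traces), 20)
  expect_error(sonication_protocol(prf = 2, duration = 120.3),
               "integer burst count")
  expect_error(sonication_protocol(injection_time = 50, flush_time = 40),
               "injection_time")
})

test_that("generators are bit-reproducible under a fixed seed and differ across seeds", {
  p <- quick_protocol()
  tr <- quick_truth(onset = 11L)
  expect_identical(gen_pcd_timeseries(p, tr, seed = 7),
                   gen_pcd_timeseries(p, tr, seed = 7))
  expect_false(identical(gen_pcd_timeseries(p, tr, seed = 7)$traces,
                         gen_pcd_timeseries(p, tr, seed = 8)$traces))
  expect_identical(quick_rf(quick_truth(), seed = 5)$rf,
                   quick_rf(quick_truth(), seed = 5)$rf)
  m1 <- quick_mri(seed = 9, shape = c(48, 48, 48))
  m2 <- quick_mri(seed = 9, shape = c(48, 48, 48))
  expect_identical(m1$day0$data, m2$day0$data)
  pp1 <- gen_pet_pair(seed = 4, noise_sigma = 0.05)
  pp2 <- gen_pet_pair(seed = 4, noise_sigma = 0.05)
  expect_identical(pp1$followup$data, pp2$followup$data)
  expect_false(identical(pp1$followup$data,
                         gen_pet_pair(seed = 5, noise_sigma = 0.05)$followup$data))
})

test_that("zero-amplitude truth gives statistically flat dose series", {
  p <- quick_protocol()
  tr <- synthetic_truth(source_band_amplitudes = matrix(0, 1, 3),
                        onset_burst_index = 11L)
  rec <- gen_pcd_timeseries(p, tr, noise_sigma = 0.02, seed = 13)
  ds <- dose_series(rec)
  # self-normalized doses hover around 0 dB with no trend
  expect_lt(abs(mean(ds$cd_h_db)), 1)
  expect_lt(abs(mean(ds$cd_b_db)), 1)
})

test_that("sub-Nyquist sampling rates are rejected with a clear message", {
  p <- sonication_protocol()  # f0 = 0.25 MHz; content up to 1.625 MHz
  expect_error(gen_pcd_timeseries(p, quick_truth(), fs = 3e6),
               "Nyquist")
  geom <- array_geometry(fs = 2.5e6)
  expect_error(quick_rf(quick_truth(), geometry = geom), "Nyquist")
})

test_that("array RF delays follow the analytic hyperbola within one sample", {
  geom <- array_geometry()
  tr <- quick_truth(x = 0, z = 30, amps = c(0, 0, 1))  # broadband: sharp xcorr
  rf <- quick_rf(tr, geometry = geom, noise_sigma = 0)
  b <- get_burst(rf, 2)
  d_true <- sqrt(rowSums(sweep(geom$element_positions,
                               2, c(0, 0, 30))^2)) / 1000 / geom$c
  lag_sample <- function(i) {
    cc <- stats::ccf(b[i, ], b[1, ], lag.max = 60, plot = FALSE)
    cc$lag[which.max(cc$acf)]
  }
  lags <- vapply(seq(1, 64, by = 7), lag_sample, 0)
  expected <- (d_true[seq(1, 64, by = 7)] - d_true[1]) * geom$fs
  expect_lt(max(abs(lags - expected)), 1)
})

test_that("per-channel band energies preserve a 6 dB source-amplitude ratio", {
  tr1 <- quick_truth(amps = c(1, 1, 0))
  tr2 <- quick_truth(amps = c(2, 2, 0))
  b1 <- get_burst(quick_rf(tr1, seed = 5), 2)
  b2 <- get_burst(quick_rf(tr2, seed = 5), 2)
  ratio_db <- 10 * log10(rowSums(b2^2) / rowSums(b1^2))
  expect_lt(max(abs(ratio_db - 6.02)), 0.5)
})

test_that("sources behind the array plane are rejected", {
  tr <- synthetic_truth(source_positions = matrix(c(0, 0, -5), 1, 3))
  expect_error(quick_rf(tr), "front of the array")
})

test_that("MRI pair voxelizes the truth ellipsoid to within 5% of its volume", {
  m <- quick_mri(volume_mm3 = 983)
  vox_vol <- sum(m$truth_mask) * 1  # 1 mm isotropic
  expect_lt(abs(vox_vol - 983) / 983, 0.05)
  expect_identical(m$day0$affine, m$day3$affine)
})

test_that("zero truth volume yields a noise-only difference pair", {
  m <- quick_mri(volume_mm3 = 0, shape = c(32, 32, 32))
  expect_false(any(m$truth_mask))
  d <- subtract_volumes(m$day0, m$day3)$data
  expect_lt(abs(mean(d)), 1)            # zero-mean noise
  expect_lt(abs(sd(d) - sqrt(2) * 10) / (sqrt(2) * 10), 0.05)
})

test_that("MRI generator rejects bad geometry", {
  traj <- trajectory(c(32, 32, 32), c(0, 0, 1))
  tr <- synthetic_truth(opening_volume_mm3 = 983)
  expect_error(gen_mri_pair(spacing = c(0, 1, 1), trajectory = traj,
                            truth = tr), "spacing")
  big <- synthetic_truth(opening_volume_mm3 = 983,
                         opening_centroid = c(2, 2, 2))
  expect_error(gen_mri_pair(shape = c(32, 32, 32), trajectory = traj,
                            truth = big), "fit")
})

test_that("PET pair realizes the configured asymmetry exactly at zero noise", {
  pp <- gen_pet_pair(asymmetry_factor = 1.05, noise_sigma = 0, seed = 2)
  s_t <- suvr(pp$followup, pp$masks$treated, pp$masks$reference)
  s_c <- suvr(pp$followup, pp$masks$contralateral, pp$masks$reference)
  expect_equal(asymmetry_suvr(s_t, s_c), 1.05, tolerance = 1e-12)
  # factor 1: both sides change equally (not at all, in expectation)
  pp1 <- gen_pet_pair(asymmetry_factor = 1, noise_sigma = 0, seed = 2)
  expect_identical(pp1$baseline$data, pp1$followup$data)
  expect_error(gen_pet_pair(asymmetry_factor = 0), "asymmetry_factor")
})

test_that("volume NIfTI round trip preserves data and affine", {
  m <- quick_mri(shape = c(16, 16, 16), volume_mm3 = 0)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(m$day0, f)
  back <- read_volume(f)
  expect_equal(back$data, m$day0$data, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(unclass(back$affine), unclass(m$day0$affine),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("RF container round trip is exact", {
  rf <- quick_rf(quick_truth(), n_samples = 300)
  stem <- tempfile()
  write_rf(rf, stem)
  back <- read_rf(stem)
  expect_identical(back$rf, rf$rf)
  expect_equal(back$fs, rf$fs)
  rec <- gen_pcd_timeseries(quick_protocol(), quick_truth(onset = 11L),
                            seed = 3)
  stem2 <- tempfile()
  write_rf(rec, stem2)
  expect_identical(read_rf(stem2)$traces, rec$traces)
})
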