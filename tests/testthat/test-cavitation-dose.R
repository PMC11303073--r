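test_that("burst_spectrum finds a pure tone and satisfies the energy identity", {
  fs <- 4e6
  t <- (0:8191) / fs
  x <- sin(2 * pi * 750e3 * t)
  sp <- burst_spectrum(x, fs)
  expect_lt(abs(sp$frequencies[which.max(sp$magnitudes)] - 750e3),
            fs / attr(sp, "nfft"))
  expect_equal(max(sp$magnitudes), 1, tolerance = 1e-3)
  # zero trace
  sp0 <- burst_spectrum(numeric(2048), fs)
  expect_true(all(sp0$magnitudes == 0))
  # Parseval: two-sided spectral energy equals tapered time-domain energy
  y <- rnorm(3000)
  spy <- burst_spectrum(y, fs)
  s <- attr(spy, "scale")
  m <- spy$magnitudes
  nb <- length(m)
  lhs <- (2 * m[1] / s)^2 + (2 * m[nb] / s)^2 +
    2 * sum((m[2:(nb - 1)] / s)^2)
  w <- as.numeric(signal::hanning(3000))
  rhs <- attr(spy, "nfft") * sum((y * w)^2)
  expect_equal(lhs, rhs, tolerance = 1e-6)
  expect_error(burst_spectrum(numeric(0), fs), "empty")
  expect_error(burst_spectrum(numeric(512), fs), "1024")
})

test_that("cavitation doses isolate tones into their own band", {
  fs <- 4e6; f0 <- 0.25e6
  t <- (0:65535) / fs
  A <- 0.7
  cd3 <- cavitation_doses(burst_spectrum(A * sin(2 * pi * 3 * f0 * t), fs), f0)
  expect_equal(unname(cd3["cd_h"]), A, tolerance = 1e-2)
  expect_lt(cd3["cd_u"], 1e-3 * A)
  expect_lt(cd3["cd_b"], 1e-3 * A)
  cd35 <- cavitation_doses(burst_spectrum(A * sin(2 * pi * 3.5 * f0 * t), fs),
                           f0)
  expect_equal(unname(cd35["cd_u"]), A, tolerance = 1e-2)
  expect_lt(cd35["cd_h"], 1e-3 * A)
})

test_that("doses ignore spectral content outside their bands", {
  fs <- 4e6; f0 <- 0.25e6
  t <- (0:16383) / fs
  x <- 0.5 * sin(2 * pi * 3 * f0 * t)
  out_of_band <- 2 * sin(2 * pi * 2 * f0 * t) + sin(2 * pi * 7.5 * f0 * t)
  cd_a <- cavitation_doses(burst_spectrum(x, fs), f0)
  cd_b <- cavitation_doses(burst_spectrum(x + out_of_band, fs), f0)
  expect_equal(cd_a, cd_b, tolerance = 1e-3)
})

test_that("broadband dose scales linearly with noise amplitude", {
  fs <- 4e6; f0 <- 0.25e6
  cdb <- function(sigma, seed) {
    withr::with_seed(seed, mean(replicate(60, {
      cavitation_doses(burst_spectrum(rnorm(4096, sd = sigma), fs),
                       f0)["cd_b"]
    })))
  }
  r <- cdb(2, 41) / cdb(1, 42)
  expect_lt(abs(r - 2) / 2, 0.05)
})

test_that("dose series recovers a constructed +20 dB harmonic step", {
  # two runs whose post-onset harmonic amplitudes differ by exactly 10x
  # (+20 dB); both tones sit far above the noise floor, so the difference of
  # the baseline-normalized series isolates the constructed step
  p <- quick_protocol()
  run_at <- function(amp) {
    tr <- synthetic_truth(source_band_amplitudes = matrix(c(amp, 0, 0), 1, 3),
                          onset_burst_index = 11L)
    rec <- gen_pcd_timeseries(p, tr, noise_sigma = 1e-4, seed = 19,
                              rise_tau = 1e-6)  # sharp step
    dose_series(rec)
  }
  lo <- run_at(0.1)
  hi <- run_at(1.0)
  post <- 12:20  # the rise is zero at the onset burst itself
  expect_lt(max(abs((hi$cd_h_db[post] - lo$cd_h_db[post]) - 20)), 1)
  # before the onset both series sit at their own baseline (~0 dB)
  expect_lt(max(abs(hi$cd_h_db[1:10])), 1)
  # and the step itself is visible: post-onset level far above baseline
  expect_gt(min(hi$cd_h_db[post]), 20)
})

test_that("permuting burst order permutes the dose series identically", {
  p <- quick_protocol()
  rec <- gen_pcd_timeseries(p, quick_truth(onset = 11L), seed = 23)
  ds <- dose_series(rec)
  perm <- c(1:10, sample(11:20))
  rec_p <- rec
  rec_p$traces <- rec$traces[perm, ]
  ds_p <- dose_series(rec_p, baseline_bursts = 1:10)
  expect_equal(ds_p$cd_h, ds$cd_h[perm])
  expect_equal(ds_p$cd_b_db, ds$cd_b_db[perm])
})

test_that("doubling trace amplitude adds 6.02 dB absolute, 0 dB normalized", {
  p <- quick_protocol()
  rec <- gen_pcd_timeseries(p, quick_truth(onset = 11L), seed = 29)
  rec2 <- rec
  rec2$traces <- 2 * rec$traces
  d1 <- dose_series(rec)
  d2 <- dose_series(rec2)
  expect_equal(20 * log10(d2$cd_h / d1$cd_h),
               rep(20 * log10(2), 20), tolerance = 1e-9)
  expect_equal(d2$cd_h_db, d1$cd_h_db, tolerance = 1e-9)
  expect_equal(cumulative_dose(d2, 12)$ccd_b,
               cumulative_dose(d1, 12)$ccd_b, tolerance = 1e-9)
})

test_that("CCD sums normalized post-flush doses on the log scale", {
  mk <- function(cd) {
    structure(list(times = seq_along(cd), cd_h = cd, cd_u = cd, cd_b = cd,
                   baseline_window = 1L,
                   baseline_means = c(cd_h = 1, cd_u = 1, cd_b = 1)),
              class = "cd_series")
  }
  # 100 unit-normalized post-flush bursts -> 10*log10(100) = 20 dB
  s <- mk(rep(1, 101))
  expect_equal(cumulative_dose(s, 2)$ccd_h, 20)
  # all-zero post-flush: sentinel, never 0 dB
  expect_true(is.na(cumulative_dose(mk(c(1, 0, 0)), 2)$ccd_h))
  # appending positive bursts never decreases the CCD
  ccds <- vapply(2:60, function(n) cumulative_dose(mk(rep(1, n)), 2)$ccd_u, 0)
  expect_true(all(diff(ccds) >= 0))
  expect_error(cumulative_dose(mk(rep(1, 5)), 9), "beyond")
})

test_that("dose series rejects an empty baseline window", {
  rec <- gen_pcd_timeseries(quick_protocol(), quick_truth(onset = 11L),
                            seed = 3)
  expect_error(dose_series(rec, baseline_bursts = integer(0)), "empty")
})
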