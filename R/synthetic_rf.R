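#' @importFrom stats rnorm runif fft approx
NULL

# Unit-variance band-limited white noise, synthesized by masking the FFT of
# white noise to [band[1], band[2]] Hz and renormalizing.
bandlimited_noise <- function(n, fs, band) {
  x <- rnorm(n)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)  # two-sided spectrum folded to [0, fs/2]
  keep <- f_fold >= band[1] & f_fold <= band[2]
  X[!keep] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s
}

# Microbubble emission waveform of one source for one burst: harmonic tones at
# n*f0, ultraharmonic tones at (n+0.5)*f0 (n in `orders`), and band-limited
# broadband noise over `bb_band`, under a Hann envelope. `amps` is a length-3
# vector (harmonic, ultraharmonic, broadband); tone amplitudes are per-tone
# peak amplitudes, the broadband amplitude is the noise standard deviation.
emission_waveform <- function(n, fs, f0, amps, orders = 3:6,
                              bb_band = c(2.5 * f0, 6.5 * f0)) {
  t <- (seq_len(n) - 1) / fs
  w <- numeric(n)
  for (k in orders) {
    if (amps[1] > 0)
      w <- w + amps[1] * sin(2 * pi * k * f0 * t + runif(1, 0, 2 * pi))
    if (amps[2] > 0)
      w <- w + amps[2] * sin(2 * pi * (k + 0.5) * f0 * t + runif(1, 0, 2 * pi))
  }
  if (amps[3] > 0) w <- w + amps[3] * bandlimited_noise(n, fs, bb_band)
  env <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  w * env
}

# Exponential post-onset rise of the bolus: 0 before the onset burst, then
# 1 - exp(-(t - t_onset)/tau).
bolus_rise <- function(burst_times, onset_burst_index, tau = 5) {
  t_on <- burst_times[onset_burst_index]
  r <- 1 - exp(-(burst_times - t_on) / tau)
  r[seq_len(min(onset_burst_index - 1, length(r)))] <- 0
  pmax(r, 0)
}

#' Generate single-channel passive cavitation detector (PCD) recordings
#'
#' Synthesizes one voltage trace per sonication burst. Bursts before the
#' bolus onset contain only Gaussian noise; bursts after the onset add
#' harmonic/ultraharmonic tones (orders 3-6 of `f0`) and band-limited
#' broadband noise at the truth amplitudes, scaled by an exponential
#' post-onset rise (time constant `rise_tau` seconds).
#'
#' @param protocol A [sonication_protocol()].
#' @param truth A [synthetic_truth()]; band amplitudes are summed over
#'   sources (a single-element detector has no spatial selectivity).
#' @param noise_sigma Noise standard deviation (V).
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @param fs Sampling rate (Hz), default 4 MHz.
#' @param rise_tau Bolus rise time constant (s), default 5.
#'
#' @return A `pcd_recording`: list with `traces` (bursts x samples matrix),
#'   `fs`, `burst_times` (s) and `protocol`.
#' @export
gen_pcd_timeseries <- function(protocol, truth, noise_sigma = 0.01,
                               seed = 1L, fs = 4e6, rise_tau = 5) {
  stopifnot(inherits(protocol, "sonication_protocol"),
            inherits(truth, "synthetic_truth"))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  f_max <- 6.5 * protocol$f0
  if (fs < 2 * f_max)
    stop(sprintf(paste("sampling rate %.3g Hz is below Nyquist for the",
                       "highest synthesized band (%.3g Hz content needs",
                       "fs >= %.3g Hz)"), fs, f_max, 2 * f_max))
  n_bursts <- protocol$n_bursts
  n_samp <- round(protocol$pulse_length * fs)
  burst_times <- (seq_len(n_bursts) - 1) / protocol$prf
  amps <- colSums(truth$source_band_amplitudes)
  rise <- bolus_rise(burst_times, truth$onset_burst_index, rise_tau)
  traces <- withr::with_seed(seed, {
    m <- matrix(rnorm(n_bursts * n_samp, sd = noise_sigma),
                nrow = n_bursts, ncol = n_samp)
    for (b in seq_len(n_bursts)) {
      if (rise[b] > 0 && any(amps > 0)) {
        m[b, ] <- m[b, ] +
          emission_waveform(n_samp, fs, protocol$f0, amps * rise[b])
      }
    }
    m
  })
  structure(list(traces = traces, fs = fs, burst_times = burst_times,
                 protocol = protocol),
            class = "pcd_recording")
}

#' Generate multichannel array RF from point cavitation sources
#'
#' Each channel receives each source's emission delayed by the
#' source-to-element distance divided by the sound speed and scaled by
#' 1/distance spherical spreading, plus independent Gaussian noise.
#' Sub-sample delays are applied by linear interpolation of the emission
#' waveform. The bolus onset/rise model matches [gen_pcd_timeseries()].
#'
#' @param geometry An [array_geometry()].
#' @param truth A [synthetic_truth()]; all source positions must be in front
#'   of the array plane (z > 0).
#' @param protocol A [sonication_protocol()] (sets burst count and timing).
#' @param noise_sigma Per-sample channel noise sd (V).
#' @param seed Integer seed.
#' @param n_samples Record length per burst (samples), default 1500.
#' @param emission_duration Source emission duration (s), default 80 us.
#' @param rise_tau Bolus rise time constant (s).
#'
#' @return A `burst_rf_series`: list with `rf` (bursts x channels x samples
#'   array), `fs`, `burst_times`, `geometry`, `protocol`.
#' @export
gen_array_rf <- function(geometry, truth, protocol = sonication_protocol(),
                         noise_sigma = 0, seed = 1L, n_samples = 1500,
                         emission_duration = 80e-6, rise_tau = 5) {
  stopifnot(inherits(geometry, "array_geometry"),
            inherits(truth, "synthetic_truth"))
  if (geometry$c <= 0) stop("sound speed must be > 0")
  if (any(truth$source_positions[, 3] <= 0))
    stop("all source positions must be in front of the array plane (z > 0)")
  f_max <- 6.5 * protocol$f0
  if (geometry$fs < 2 * f_max)
    stop("RF sampling rate is below Nyquist for the highest synthesized band")
  fs <- geometry$fs
  n_bursts <- protocol$n_bursts
  nc <- geometry$n_elements
  burst_times <- (seq_len(n_bursts) - 1) / protocol$prf
  rise <- bolus_rise(burst_times, truth$onset_burst_index, rise_tau)
  n_emit <- round(emission_duration * fs)
  t_rec <- (seq_len(n_samples) - 1) / fs
  # source-to-element delays (s): distances in mm, c in m/s
  dists <- apply(truth$source_positions, 1, function(p)
    sqrt(colSums((t(geometry$element_positions) - p)^2)))  # nc x nsrc
  dists <- matrix(dists, nrow = nc)
  delays <- dists / 1000 / geometry$c
  rf <- withr::with_seed(seed, {
    a <- array(rnorm(n_bursts * nc * n_samples, sd = noise_sigma),
               dim = c(n_bursts, nc, n_samples))
    t_emit <- (seq_len(n_emit) - 1) / fs
    for (b in seq_len(n_bursts)) {
      if (rise[b] <= 0) next
      for (s in seq_len(nrow(truth$source_positions))) {
        amps <- truth$source_band_amplitudes[s, ] * rise[b]
        if (all(amps == 0)) next
        w <- emission_waveform(n_emit, fs, protocol$f0, amps)
        for (i in seq_len(nc)) {
          y <- approx(t_emit + delays[i, s], w / dists[i, s], xout = t_rec,
                      rule = 1)$y
          y[is.na(y)] <- 0
          a[b, i, ] <- a[b, i, ] + y
        }
      }
    }
    a
  })
  structure(list(rf = rf, fs = fs, burst_times = burst_times,
                 geometry = geometry, protocol = protocol),
            class = "burst_rf_series")
}

#' Extract one burst as a channels x samples matrix
#' @param series A `burst_rf_series`.
#' @param burst Burst index (1-based).
#' @return Channels x samples matrix.
#' @export
get_burst <- function(series, burst) {
  stopifnot(inherits(series, "burst_rf_series"))
  matrix(series$rf[burst, , ], nrow = dim(series$rf)[2])
}

#' Write / read an RF recording to a flat binary container
#'
#' Persists a `burst_rf_series` or `pcd_recording` as `<path>.json` (header:
#' dimensions, sampling rate, burst times, element positions) plus
#' `<path>.bin` (float64, burst-major). A plain hand-rolled container is used
#' because no binary scientific container writer for multichannel RF is
#' available to this package.
#'
#' @param x A `burst_rf_series` or `pcd_recording`.
#' @param path Path stem (no extension).
#' @return `write_rf` returns `path` invisibly; `read_rf` returns the object.
#' @export
write_rf <- function(x, path) {
  if (inherits(x, "pcd_recording")) {
    dat <- array(x$traces, dim = c(nrow(x$traces), 1, ncol(x$traces)))
    elem <- matrix(0, 1, 3)
  } else if (inherits(x, "burst_rf_series")) {
    dat <- x$rf
    elem <- x$geometry$element_positions
  } else stop("unsupported object")
  hdr <- list(dim = dim(dat), fs = x$fs, burst_times = x$burst_times,
              element_positions = elem,
              kind = class(x)[1])
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(dat, c(3, 2, 1))), con, size = 8)
  invisible(path)
}

#' @rdname write_rf
#' @export
read_rf <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  n <- prod(hdr$dim)
  v <- readBin(con, "double", n = n, size = 8)
  dat <- aperm(array(v, dim = rev(hdr$dim)), c(3, 2, 1))
  if (identical(hdr$kind, "pcd_recording")) {
    structure(list(traces = matrix(dat[, 1, ], nrow = hdr$dim[1]),
                   fs = hdr$fs, burst_times = hdr$burst_times,
                   protocol = NULL),
              class = "pcd_recording")
  } else {
    structure(list(rf = dat, fs = hdr$fs, burst_times = hdr$burst_times,
                   geometry = NULL, protocol = NULL),
              class = "burst_rf_series")
  }
}
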