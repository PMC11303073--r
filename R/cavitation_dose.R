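#' Single-sided magnitude spectrum of one burst trace
#'
#' Tapers the trace (Hann by default), zero-pads to the next power of two and
#' returns the single-sided amplitude spectrum, compensated for the taper's
#' coherent gain so that an on-bin unit-amplitude sinusoid has peak magnitude
#' close to 1.
#'
#' @param trace Numeric voltage series (>= 1024 samples).
#' @param fs Sampling rate (Hz).
#' @param window Taper name: `"hann"` (default) or `"rect"`.
#' @return A `spectrum_1s`: list with `frequencies` (Hz, increasing) and
#'   `magnitudes` (linear amplitude, >= 0); attributes `nfft`, `fs`.
#' @export
burst_spectrum <- function(trace, fs, window = c("hann", "rect")) {
  if (length(trace) == 0) stop("empty trace")
  if (length(trace) < 1024) stop("trace must have >= 1024 samples")
  window <- match.arg(window)
  n <- length(trace)
  w <- if (window == "hann") as.numeric(signal::hanning(n)) else rep(1, n)
  nfft <- 2^ceiling(log2(n))
  x <- c(trace * w, numeric(nfft - n))
  X <- fft(x)
  half <- seq_len(nfft / 2 + 1)
  scale <- 2 / (n * mean(w))          # amplitude per tone, taper-compensated
  mag <- Mod(X[half]) * scale
  mag[1] <- mag[1] / 2                # DC is not doubled
  mag[length(mag)] <- mag[length(mag)] / 2  # Nyquist bin is not doubled
  structure(list(frequencies = (half - 1) * fs / nfft, magnitudes = mag),
            class = "spectrum_1s", nfft = nfft, fs = fs,
            window_power = sum(w^2), scale = scale)
}

#' Harmonic, ultraharmonic and broadband cavitation doses from a spectrum
#'
#' The harmonic dose is the sum over orders `n` of the peak magnitude within
#' `n * f0 +/- tone_halfwidth`; the ultraharmonic dose is the same at
#' `(n + 0.5) * f0`; the broadband dose is the mean magnitude over
#' `broadband_band` excluding all harmonic and ultraharmonic tone windows.
#'
#' @param spectrum A [burst_spectrum()] result.
#' @param f0 Sonication center frequency (Hz).
#' @param harmonic_orders Integer orders, default 3:6.
#' @param tone_halfwidth Half-width of each tone window (Hz), default 25 kHz.
#' @param broadband_band Length-2 band (Hz), default `c(2.5, 6.5) * f0`.
#' @return Named numeric vector `c(cd_h, cd_u, cd_b)` (linear units).
#' @export
cavitation_doses <- function(spectrum, f0, harmonic_orders = 3:6,
                             tone_halfwidth = 25e3,
                             broadband_band = c(2.5, 6.5) * f0) {
  stopifnot(inherits(spectrum, "spectrum_1s"))
  f <- spectrum$frequencies
  m <- spectrum$magnitudes
  if (broadband_band[1] < f[1] || broadband_band[2] > f[length(f)])
    stop("broadband_band lies outside the spectrum support")
  peak_in <- function(fc) {
    sel <- f >= fc - tone_halfwidth & f <= fc + tone_halfwidth
    if (!any(sel)) 0 else max(m[sel])
  }
  cd_h <- sum(vapply(harmonic_orders * f0, peak_in, 0))
  cd_u <- sum(vapply((harmonic_orders + 0.5) * f0, peak_in, 0))
  tone_centers <- c(harmonic_orders, harmonic_orders + 0.5) * f0
  in_tone <- Reduce(`|`, lapply(tone_centers, function(fc)
    f >= fc - tone_halfwidth & f <= fc + tone_halfwidth))
  bb <- f >= broadband_band[1] & f <= broadband_band[2] & !in_tone
  cd_b <- if (any(bb)) mean(m[bb]) else 0
  c(cd_h = cd_h, cd_u = cd_u, cd_b = cd_b)
}

#' Per-burst cavitation dose series with baseline normalization
#'
#' Computes the three doses for every burst of a recording and, for each
#' band, the baseline-normalized level in dB: `20*log10(CD / mean(CD over
#' the baseline window))`. The baseline window defaults to all bursts before
#' the protocol's injection time.
#'
#' @param recording A `pcd_recording` (or any list with `traces`, `fs`,
#'   `burst_times`).
#' @param f0 Center frequency (Hz); taken from the recording's protocol when
#'   omitted.
#' @param baseline_bursts Integer indices of the baseline window; default all
#'   bursts strictly before `protocol$injection_time`.
#' @param ... Passed to [cavitation_doses()] (orders, halfwidth, band).
#' @return A `cd_series`: list with `times`, `cd_h`, `cd_u`, `cd_b` (linear),
#'   `cd_h_db`, `cd_u_db`, `cd_b_db` (baseline-normalized dB),
#'   `baseline_window`, `baseline_means`.
#' @export
dose_series <- function(recording, f0 = NULL, baseline_bursts = NULL, ...) {
  if (is.null(f0)) f0 <- recording$protocol$f0
  if (is.null(f0)) stop("f0 must be given when the recording has no protocol")
  traces <- recording$traces
  n_bursts <- nrow(traces)
  if (is.null(baseline_bursts)) {
    if (is.null(recording$protocol))
      stop("baseline_bursts must be given when the recording has no protocol")
    baseline_bursts <-
      which(recording$burst_times < recording$protocol$injection_time)
  }
  if (length(baseline_bursts) == 0) stop("baseline window is empty")
  cds <- t(vapply(seq_len(n_bursts), function(b)
    cavitation_doses(burst_spectrum(traces[b, ], recording$fs), f0, ...),
    c(cd_h = 0, cd_u = 0, cd_b = 0)))
  base <- colMeans(cds[baseline_bursts, , drop = FALSE])
  to_db <- function(x, b) ifelse(x > 0 & b > 0, 20 * log10(x / b), NA_real_)
  structure(list(
    times = recording$burst_times,
    cd_h = cds[, "cd_h"], cd_u = cds[, "cd_u"], cd_b = cds[, "cd_b"],
    cd_h_db = to_db(cds[, "cd_h"], base["cd_h"]),
    cd_u_db = to_db(cds[, "cd_u"], base["cd_u"]),
    cd_b_db = to_db(cds[, "cd_b"], base["cd_b"]),
    baseline_window = baseline_bursts,
    baseline_means = base
  ), class = "cd_series")
}

#' Cumulative cavitation dose (CCD)
#'
#' For each band, sums the baseline-normalized dose over the bursts after the
#' microbubble flush and converts to the logarithmic scale:
#' `CCD = 10*log10( sum_{post-flush} CD / mean(CD over baseline) )`.
#' An all-zero post-flush sum yields `NA` (not-a-dose), never 0 dB.
#'
#' @param series A [dose_series()] result.
#' @param flush_burst Index of the flush burst; post-flush bursts are
#'   `flush_burst:length(times)`.
#' @return A `ccd`: list with `ccd_h`, `ccd_u`, `ccd_b` (dB) and
#'   `post_flush_window`.
#' @export
cumulative_dose <- function(series, flush_burst) {
  stopifnot(inherits(series, "cd_series"))
  n <- length(series$times)
  if (flush_burst < 1 || flush_burst > n)
    stop("flush_burst is beyond the recorded bursts")
  post <- flush_burst:n
  one <- function(cd, base) {
    s <- sum(cd[post] / base)
    if (!is.finite(s) || s <= 0) NA_real_ else 10 * log10(s)
  }
  structure(list(
    ccd_h = one(series$cd_h, series$baseline_means["cd_h"]),
    ccd_u = one(series$cd_u, series$baseline_means["cd_u"]),
    ccd_b = one(series$cd_b, series$baseline_means["cd_b"]),
    post_flush_window = post
  ), class = "ccd")
}
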