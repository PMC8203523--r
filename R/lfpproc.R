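# LFP preprocessing, Morlet wavelet spectrogram, and smoothed wavelet
# coherence (magnitude-squared by default)

morlet_fourier_factor <- function(omega0 = 6) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' Low-pass filter and decimate a wideband signal to the LFP rate
#'
#' Zero-phase FIR low-pass (300 Hz corner, Blackman-windowed design for a
#' deep stopband) followed by integer-step downsampling to 1250 Hz.
#'
#' @param raw Numeric vector or time x channel matrix at `raw_rate`.
#' @param raw_rate Input sampling rate (Hz); must be an integer multiple of
#'   `target_rate` and at least twice the filter corner.
#' @param target_rate Output rate (Hz), 1250 by default.
#' @param corner_hz Low-pass corner frequency (Hz).
#' @param n_taps FIR order; the default (512) places the stopband edge well
#'   below the decimated Nyquist frequency.
#' @param channels Optional channel data frame for the returned recording.
#' @return An [lfp_recording()] at `target_rate`.
#' @export
decimate_lfp <- function(raw, raw_rate, target_rate = 1250, corner_hz = 300,
                         n_taps = 512, channels = NULL) {
  if (raw_rate < 2 * corner_hz) {
    stop("raw_rate (", raw_rate, " Hz) must be at least twice the ",
         corner_hz, " Hz filter corner")
  }
  ratio <- raw_rate / target_rate
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("raw_rate must be an integer multiple of target_rate (got ratio ",
         ratio, ")")
  }
  ratio <- as.integer(round(ratio))
  if (is.vector(raw)) raw <- matrix(raw, ncol = 1)
  out <- raw
  if (ratio > 1) {
    fir <- signal::fir1(n_taps, corner_hz / (raw_rate / 2),
                        window = signal::blackman(n_taps + 1))
    out <- apply(raw, 2, function(x) signal::filtfilt(fir, x))
    out <- out[seq(1, nrow(raw), by = ratio), , drop = FALSE]
  }
  if (is.null(channels)) {
    channels <- data.frame(id = sprintf("CH%02d", seq_len(ncol(out))),
                           region = "NA", shank = 1L,
                           site = seq_len(ncol(out)), depth_um = 0,
                           stringsAsFactors = FALSE)
  }
  lfp_recording(out, target_rate, channels)
}

# core Morlet CWT via FFT (analytic wavelet, positive frequencies only).
# Returns list(coef [nfreq x n] complex, scales, freqs).
cwt_core <- function(x, rate, freqs, omega0 = 6) {
  if (any(freqs <= 0) || any(freqs >= rate / 2)) {
    stop("analysis frequencies must lie strictly inside (0, rate/2)")
  }
  n <- length(x)
  dt <- 1 / rate
  npad <- nextn(n, 2)
  xf <- fft(c(x - mean(x), numeric(npad - n)))
  k <- 0:(npad - 1)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt)
  ff <- morlet_fourier_factor(omega0)
  scales <- 1 / (freqs * ff)
  coef <- matrix(0i, length(freqs), n)
  for (j in seq_along(freqs)) {
    s <- scales[j]
    daughter <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
      exp(-0.5 * (s * omega - omega0)^2) * (omega > 0)
    w <- fft(xf * daughter, inverse = TRUE) / npad
    coef[j, ] <- w[seq_len(n)]
  }
  list(coef = coef, scales = scales, freqs = freqs)
}

#' Morlet wavelet spectrogram of one LFP channel
#'
#' Analytic complex Morlet transform (center-frequency parameter
#' `omega0 = 6`) on a logarithmic frequency grid covering 1--110 Hz by
#' default. Samples inside the cone of influence (within `sqrt(2) * scale`
#' of a recording edge) are flagged and excluded from band averages.
#'
#' @param rec An [lfp_recording()] (or a numeric vector, in which case
#'   `rate` must be supplied via `rec_rate`).
#' @param channel Channel id (ignored for vector input).
#' @param freqs Analysis frequencies in Hz.
#' @param omega0 Morlet center-frequency parameter.
#' @param rec_rate Sampling rate when `rec` is a plain vector.
#' @return Object of class `spectrogram`: complex `coef` (freq x time),
#'   `freqs`, `scales` (s), `rate`, and `edge_dist` (distance of every
#'   sample to the nearest edge, in seconds).
#' @export
cwt_spectrogram <- function(rec, channel = NULL, freqs = cwt_freq_grid(),
                            omega0 = 6, rec_rate = NULL) {
  if (inherits(rec, "lfp_recording")) {
    if (is.null(channel)) stop("channel id required")
    if (!channel %in% colnames(rec$samples)) {
      stop("channel '", channel, "' not present in recording")
    }
    x <- rec$samples[, channel]
    rate <- rec$rate
  } else {
    x <- as.numeric(rec)
    rate <- rec_rate
    if (is.null(rate)) stop("rec_rate required for vector input")
  }
  cw <- cwt_core(x, rate, freqs, omega0)
  n <- length(x)
  edge <- (pmin(seq_len(n) - 1, n - seq_len(n))) / rate
  structure(list(coef = cw$coef, freqs = cw$freqs, scales = cw$scales,
                 rate = rate, edge_dist = edge, channel = channel),
            class = "spectrogram")
}

#' Wavelet power
#'
#' `|W|^2` under the energy normalization used by [cwt_spectrogram()] (the
#' wavelet's Fourier amplitude scales with `sqrt(scale)`), so the expected
#' power of white noise is flat across the logarithmic frequency grid.
#'
#' @param sg A `spectrogram`.
#' @return Numeric matrix, frequency x time.
#' @export
spectrogram_power <- function(sg) {
  Mod(sg$coef)^2
}

# --- smoothing ------------------------------------------------------------

# Factory for a per-segment time smoother: Gaussian of SD sd_samples[j] per
# row, zero-padded FFT convolution with edge renormalization so that the
# effective kernel always integrates to 1 inside the segment. The kernel
# FFTs and edge weights are precomputed once and reused across channel
# pairs of the same segment.
make_time_smoother <- function(nt, sd_samples) {
  nf <- length(sd_samples)
  L <- pmax(1L, as.integer(ceiling(4 * sd_samples)))
  npad <- nextn(nt + 2L * max(L), 2)
  K <- matrix(0, npad, nf)
  for (j in seq_len(nf)) {
    off <- seq.int(-L[j], L[j])
    kern <- exp(-0.5 * (off / sd_samples[j])^2)
    kern <- kern / sum(kern)
    idx <- ifelse(off >= 0, off + 1L, npad + off + 1L)   # circular placement
    K[idx, j] <- kern
  }
  Kf <- mvfft(K)
  Of <- fft(c(rep(1, nt), numeric(npad - nt)))
  wts <- Re(mvfft(matrix(Of, npad, nf) * Kf, inverse = TRUE) / npad)
  wts <- pmax(wts[seq_len(nt), , drop = FALSE], 1e-12)
  function(M) {
    P <- matrix(0i, npad, nf)
    P[seq_len(nt), ] <- t(M)
    conv <- mvfft(mvfft(P) * Kf, inverse = TRUE) / npad
    t(conv[seq_len(nt), , drop = FALSE] / wts)
  }
}

smooth_time_rows <- function(M, sd_samples) {
  make_time_smoother(ncol(M), sd_samples)(M)
}

# boxcar over +/- width neighbouring scales (rows), edge-truncated
smooth_scale_rows <- function(M, width = 1) {
  nf <- nrow(M)
  if (width < 1 || nf == 1) return(M)
  K <- matrix(0, nf, nf)
  for (j in seq_len(nf)) {
    idx <- max(1, j - width):min(nf, j + width)
    K[j, idx] <- 1 / length(idx)
  }
  K %*% M
}

smooth_spectrum <- function(M, scales, rate, time_smooth, scale_smooth) {
  if (time_smooth > 0) {
    M <- smooth_time_rows(M, pmax(time_smooth * scales * rate, 0.5))
  }
  if (scale_smooth >= 1) M <- smooth_scale_rows(M, scale_smooth)
  M
}

# --- coherence ------------------------------------------------------------

#' Continuous wavelet coherence between two LFP channels
#'
#' Magnitude-squared wavelet coherence: cross- and auto-spectra are smoothed
#' with a Gaussian in time (SD proportional to scale) and a boxcar across
#' neighbouring scales, then
#' `coh^2 = |S(Wa conj(Wb))|^2 / (S|Wa|^2 S|Wb|^2)`, averaged over the band's
#' frequencies. Without smoothing the magnitude coherence is identically 1,
#' so smoothing is on by default and a disabled-smoothing call serves only as
#' a degeneracy check.
#'
#' @param rec An [lfp_recording()].
#' @param ch_a,ch_b Distinct channel ids.
#' @param band Band label or numeric `c(f_lo, f_hi)` in Hz.
#' @param freqs Analysis frequencies; defaults to the grid points inside the
#'   band.
#' @param time_smooth Gaussian SD in units of wavelet scale (0 disables).
#' @param scale_smooth Boxcar half-width in grid points across scales
#'   (0 disables).
#' @param squared Return squared coherence (default) or its square root.
#' @param omega0 Morlet parameter.
#' @return Object of class `coherence_series`: `values` in `[0, 1]` per
#'   sample, `time` (s), logical `valid` (outside cone of influence plus
#'   smoothing margin), `pair`, `band`, `rate`.
#' @export
wavelet_coherence <- function(rec, ch_a, ch_b, band = "low_gamma",
                              freqs = NULL, time_smooth = 4,
                              scale_smooth = 1, squared = TRUE, omega0 = 6) {
  if (identical(ch_a, ch_b)) {
    stop("self-coherence is degenerate: channel ids must differ")
  }
  if (is.null(freqs)) freqs <- band_freqs(band)
  wa <- cwt_spectrogram(rec, ch_a, freqs = freqs, omega0 = omega0)
  wb <- cwt_spectrogram(rec, ch_b, freqs = freqs, omega0 = omega0)
  coherence_from_cwt(wa, wb, time_smooth, scale_smooth, squared,
                     pair = c(ch_a, ch_b), band = band)
}

# shared backend: coherence series from two spectrograms on the same grid
coherence_from_cwt <- function(wa, wb, time_smooth = 4, scale_smooth = 1,
                               squared = TRUE, pair = c(NA, NA),
                               band = NULL) {
  rate <- wa$rate
  sa <- smooth_spectrum(Mod(wa$coef)^2, wa$scales, rate, time_smooth,
                        scale_smooth)
  sb <- smooth_spectrum(Mod(wb$coef)^2, wb$scales, rate, time_smooth,
                        scale_smooth)
  sab <- smooth_spectrum(wa$coef * Conj(wb$coef), wa$scales, rate,
                         time_smooth, scale_smooth)
  c2 <- Mod(sab)^2 / pmax(Re(sa) * Re(sb), 1e-300)
  c2 <- pmin(pmax(c2, 0), 1)
  vals <- colMeans(c2)
  if (!squared) vals <- sqrt(vals)
  margin <- max(sqrt(2), 2 * time_smooth) * max(wa$scales)
  n <- length(vals)
  structure(list(values = vals, time = (seq_len(n) - 1) / rate,
                 valid = wa$edge_dist >= margin, pair = pair,
                 band = if (is.null(band)) NULL else resolve_band(band),
                 rate = rate, freqs = wa$freqs),
            class = "coherence_series")
}

#' Average a series or spectrogram over a band and time interval
#'
#' For a `coherence_series`, the mean of the (already band-averaged) values
#' over the requested interval(s), excluding cone-of-influence samples by
#' default. For a `spectrogram`, the mean normalized power over the band's
#' frequencies and the interval.
#'
#' @param x A `coherence_series` or `spectrogram`.
#' @param band Band (spectrogram only).
#' @param interval Numeric `c(t0, t1)` in seconds, or a list of such
#'   intervals; `NULL` means the full extent.
#' @param use_valid Exclude cone-of-influence samples (coherence series).
#' @return Scalar mean.
#' @export
band_average <- function(x, band = NULL, interval = NULL, use_valid = TRUE) {
  UseMethod("band_average")
}

#' @export
band_average.coherence_series <- function(x, band = NULL, interval = NULL,
                                          use_valid = TRUE) {
  keep <- rep(TRUE, length(x$values))
  if (use_valid) keep <- keep & x$valid
  if (!is.null(interval)) {
    if (!is.list(interval)) interval <- list(interval)
    inwin <- rep(FALSE, length(x$values))
    for (iv in interval) {
      inwin <- inwin | (x$time >= iv[1] & x$time < iv[2])
    }
    keep <- keep & inwin
  }
  if (!any(keep)) stop("empty interval: no samples to average")
  mean(x$values[keep])
}

#' @export
band_average.spectrogram <- function(x, band = NULL, interval = NULL,
                                     use_valid = TRUE) {
  p <- spectrogram_power(x)
  if (!is.null(band)) {
    rng <- resolve_band(band)$range
    rows <- x$freqs >= rng[1] & x$freqs <= rng[2]
    if (!any(rows)) stop("no analysis frequencies inside the band")
    p <- p[rows, , drop = FALSE]
  }
  n <- ncol(p)
  tvec <- (seq_len(n) - 1) / x$rate
  keep <- rep(TRUE, n)
  if (!is.null(interval)) {
    if (!is.list(interval)) interval <- list(interval)
    inwin <- rep(FALSE, n)
    for (iv in interval) inwin <- inwin | (tvec >= iv[1] & tvec < iv[2])
    keep <- inwin
  }
  if (!any(keep)) stop("empty interval: no samples to average")
  mean(p[, keep])
}
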