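# Band-pass FIR design on a 1-Hz grid and zero-phase application.

#' Band-pass specification
#'
#' @param lo Lower passband edge in Hz (`lo = 0` denotes a pure low-pass).
#' @param hi Upper passband edge in Hz.
#' @return An object of class `zc_band`.
#' @export
bandpass <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo < 0 || hi <= lo) {
    stop("need 0 <= lo < hi")
  }
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi)), class = "zc_band")
}

#' @export
format.zc_band <- function(x, ...) sprintf("[%g-%g Hz]", x$lo, x$hi)

#' @export
print.zc_band <- function(x, ...) { cat("<zc_band>", format(x), "\n"); invisible(x) }

#' Design a zero-phase band-pass FIR filter
#'
#' Frequency-sampling design (Hamming-windowed, via [signal::fir2()]) with
#' unit target gain inside `[lo, hi]`, zero outside, and a linear transition
#' of nominal width `transition` Hz. Because windowing smears the designed
#' ramp, the ramp itself is drawn at 0.3 x the nominal width so that the
#' realized single-pass response is within +/-0.05 of target one transition
#' width inside the band and below 0.01 one transition width outside it.
#'
#' @param band A [bandpass()] (or `c(lo, hi)`).
#' @param fs Sampling rate in Hz.
#' @param order Filter order (number of taps - 1); default 500, i.e. a 2-s
#'   impulse response at 250 Hz.
#' @param transition Nominal transition width in Hz (default 1).
#' @return Object of class `zc_fir` with elements `taps`, `band`, `fs`,
#'   `order`, `transition`.
#' @export
design_bandpass <- function(band, fs, order = 500, transition = 1) {
  if (!inherits(band, "zc_band")) band <- bandpass(band[1], band[2])
  nyq <- fs / 2
  if (band$hi > nyq) stop("upper edge ", band$hi, " Hz exceeds Nyquist (",
                          nyq, " Hz)")
  min_order <- ceiling(2 * fs / transition)
  if (order < min_order) {
    stop("order ", order, " too small for a ", transition,
         " Hz transition at fs = ", fs, "; need >= ", min_order)
  }
  w <- 0.3 * transition
  if (band$hi + w > nyq) stop("no room for the upper transition below Nyquist")
  if (band$lo <= 0) {
    f <- c(0, band$hi, band$hi + w, nyq) / nyq
    m <- c(1, 1, 0, 0)
  } else {
    f <- c(0, max(band$lo - w, 0), band$lo, band$hi, band$hi + w, nyq) / nyq
    m <- c(0, 0, 1, 1, 0, 0)
  }
  taps <- as.numeric(signal::fir2(order, f, m))
  structure(list(taps = taps, band = band, fs = fs, order = order,
                 transition = transition), class = "zc_fir")
}

#' @export
print.zc_fir <- function(x, ...) {
  cat(sprintf("<zc_fir> %s, %d taps @ %g Hz\n", format(x$band),
              length(x$taps), x$fs))
  invisible(x)
}

#' Single-pass magnitude response of a designed filter
#'
#' @param fir A `zc_fir`.
#' @param freqs Frequencies in Hz.
#' @return Magnitude gain at each frequency.
#' @export
filter_response <- function(fir, freqs) {
  k <- seq_along(fir$taps) - 1
  vapply(freqs, function(f) Mod(sum(fir$taps * exp(-2i * pi * f * k / fir$fs))),
         0)
}

# Internal pieces of the FFT forward-backward filter, shared with the batch
# cohort pipeline: forward-backward filtering equals convolution with the
# tap autocorrelation, i.e. multiplication by |H(f)|^2 in frequency domain.

zp_pad <- function(x, L) {
  n <- length(x)
  if (n <= L + 1L) stop("signal too short for reflection padding")
  c(rev(x[2:(L + 1L)]), x, rev(x[(n - L):(n - 1L)]))
}

zp_H2 <- function(taps, nfft) Mod(stats::fft(c(taps, rep(0, nfft - length(taps)))))^2

#' Apply a filter with zero phase shift
#'
#' Forward-backward application: the effective magnitude response is the
#' square of the single-pass response and the group delay is zero. Edges
#' are handled by mirror-reflection padding of one filter length; the
#' output has the same length as the input.
#'
#' @param x Signal vector.
#' @param fir A `zc_fir` from [design_bandpass()].
#' @return Filtered signal vector, same length as `x`.
#' @export
apply_zero_phase <- function(x, fir) {
  L <- length(fir$taps)
  n <- length(x)
  if (n <= 3L * L) {
    stop("signal too short: need more than 3 x ", L, " samples, got ", n)
  }
  nfft <- stats::nextn(n + 3L * L)
  xp <- zp_pad(x, L)
  X <- stats::fft(c(xp, rep(0, nfft - length(xp))))
  y <- Re(stats::fft(X * zp_H2(fir$taps, nfft), inverse = TRUE)) / nfft
  y[(L + 1L):(L + n)]
}

# Batch zero-phase filtering of one signal against a list of filters that
# share tap count: one forward FFT, one inverse FFT per band. The squared
# transfer functions depend only on (band, nfft), so an environment can be
# passed to reuse them across streams of equal length.
zp_filter_bank <- function(x, firs, h2_cache = NULL) {
  L <- length(firs[[1]]$taps)
  n <- length(x)
  if (n <= 3L * L) stop("signal too short for the filter bank")
  nfft <- stats::nextn(n + 3L * L)
  xp <- zp_pad(x, L)
  X <- stats::fft(c(xp, rep(0, nfft - length(xp))))
  idx <- (L + 1L):(L + n)
  lapply(firs, function(f) {
    H2 <- NULL
    if (!is.null(h2_cache)) {
      key <- paste0(nfft, ":", f$order, ":", format(f$band))
      H2 <- h2_cache[[key]]
      if (is.null(H2)) {
        H2 <- zp_H2(f$taps, nfft)
        h2_cache[[key]] <- H2
      }
    } else {
      H2 <- zp_H2(f$taps, nfft)
    }
    Re(stats::fft(X * H2, inverse = TRUE))[idx] / nfft
  })
}

#' Integer band grid for classifier fitting
#'
#' Enumerates candidate passbands `[lo, hi]` on a 1-Hz grid, in
#' lexicographic `(lo, hi)` order (the tie-break order used by [lpo_cv()]).
#'
#' @param lo Vector (or range) of lower edges, default `0:8`.
#' @param hi Vector (or range) of upper edges, default `9:20`.
#' @return List of [bandpass()] objects.
#' @export
band_grid <- function(lo = 0:8, hi = 9:20) {
  out <- list()
  for (l in sort(lo)) for (h in sort(hi)) {
    if (h > l) out[[length(out) + 1L]] <- bandpass(l, h)
  }
  out
}
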