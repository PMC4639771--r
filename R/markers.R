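# Scalar markers of an interval spectrum (or a Welch power spectrum).

#' Marker definition
#'
#' A scalar feature of an interval (or Fourier) spectrum, plus the
#' inversion flag that turns it into a classifier score.
#'
#' @param kind One of `"bin_count"`, `"mean"`, `"median"`, `"mode"`,
#'   `"sd"`, `"iqr"`, `"shannon_entropy"`, `"min_entropy"`,
#'   `"fourier_band_amp"`.
#' @param bin_left_ms For `bin_count`: left bin edge, a multiple of the
#'   bin width in `[0, 3996]`.
#' @param freq_hz For `fourier_band_amp`: frequency in Hz.
#' @param invert If `TRUE` the score is the negated marker (classifier
#'   inversion; AUC maps to 1 - AUC).
#' @return Object of class `zc_marker`.
#' @export
marker_def <- function(kind = c("bin_count", "mean", "median", "mode", "sd",
                                "iqr", "shannon_entropy", "min_entropy",
                                "fourier_band_amp"),
                       bin_left_ms = NULL, freq_hz = NULL, invert = FALSE) {
  kind <- match.arg(kind)
  if (kind == "bin_count") {
    if (is.null(bin_left_ms)) stop("bin_count needs bin_left_ms")
    if (bin_left_ms %% 4 != 0 || bin_left_ms < 0 || bin_left_ms > 3996) {
      stop("bin_left_ms must be a multiple of 4 in [0, 3996]")
    }
  }
  if (kind == "fourier_band_amp" && is.null(freq_hz)) {
    stop("fourier_band_amp needs freq_hz")
  }
  structure(list(kind = kind, bin_left_ms = bin_left_ms, freq_hz = freq_hz,
                 invert = isTRUE(invert)), class = "zc_marker")
}

#' Relative count at a fixed interval length
#'
#' @param S An `interval_spectrum`.
#' @param bin_left_ms Left edge of the queried bin in ms.
#' @return The normalized probability at that bin.
#' @export
bin_marker <- function(S, bin_left_ms) {
  idx <- match(bin_left_ms, S$bin_left)
  if (is.na(idx)) stop("no bin with left edge ", bin_left_ms, " ms")
  S$p[idx]
}

# Weighted discrete quantile over bin centers: inverse-CDF with averaging
# at exact cumulative boundaries, so that a point mass has zero IQR and a
# symmetric two-point distribution has median at its mean.
wquantile <- function(centers, p, q) {
  F <- cumsum(p)
  vapply(q, function(qq) {
    k <- which(F >= qq - 1e-12)[1]
    if (abs(F[k] - qq) < 1e-12) {
      nxt <- which(p > 0 & seq_along(p) > k)
      if (length(nxt)) (centers[k] + centers[nxt[1]]) / 2 else centers[k]
    } else {
      centers[k]
    }
  }, 0)
}

#' Descriptive statistics of an interval spectrum
#'
#' Moments and quantiles of the discrete distribution over bin centers
#' (left edge + half the bin width). The mode is the center of the
#' maximal-probability bin (ties broken towards the smallest bin).
#'
#' @param S An `interval_spectrum`.
#' @return Named vector `mean`, `median`, `mode`, `sd`, `iqr` in ms.
#' @export
descriptive_markers <- function(S) {
  centers <- S$bin_left + S$bin_ms / 2
  p <- S$p
  m <- sum(p * centers)
  v <- sum(p * (centers - m)^2)
  qs <- wquantile(centers, p, c(0.25, 0.5, 0.75))
  c(mean = m, median = qs[2], mode = centers[which.max(p)],
    sd = sqrt(max(v, 0)), iqr = qs[3] - qs[1])
}

#' Entropy markers of an interval spectrum
#'
#' Shannon entropy \eqn{H_S = -\sum_{p_i>0} p_i \log_2 p_i} and min-entropy
#' \eqn{H_{min} = -\log_2 \max_i p_i}, both in bits by default. Min-entropy
#' is sensitive only to the highest probability accumulation; both quantify
#' the irregularity of the dominant rhythm. Classification by either
#' entropy is invariant to the log base.
#'
#' @param S An `interval_spectrum` (or a bare probability vector).
#' @param base Logarithm base (default 2).
#' @return Named vector `Hs`, `Hmin`.
#' @export
entropy_markers <- function(S, base = 2) {
  p <- if (inherits(S, "interval_spectrum")) S$p else S
  p <- p[p > 0]
  c(Hs = -sum(p * log(p, base)), Hmin = -log(max(p), base))
}

#' All non-bin scalar markers of a spectrum
#'
#' @param S An `interval_spectrum`.
#' @return Named vector `mean`, `median`, `mode`, `sd`, `iqr`, `Hs`, `Hmin`.
#' @export
spectrum_markers <- function(S) c(descriptive_markers(S), entropy_markers(S))

# Entropies for a matrix of probability rows (subjects x bins).
entropy_rows <- function(P, base = 2) {
  lp <- ifelse(P > 0, log(P, base), 0)
  cbind(Hs = -rowSums(P * lp), Hmin = -log(apply(P, 1, max), base))
}

#' Welch power spectral density
#'
#' Hann-tapered averaged periodogram with 4-s windows and 50% overlap
#' (one-sided density, units amplitude^2 per Hz).
#'
#' @param x Signal vector.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (default 4).
#' @param overlap Fractional overlap (default 0.5).
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, window_s = 4, overlap = 0.5) {
  nw <- as.integer(round(window_s * fs))
  if (length(x) < nw) stop("signal shorter than one Welch window")
  step <- max(1L, as.integer(round(nw * (1 - overlap))))
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nw - 1)) / (nw - 1)))
  u <- sum(w^2)
  acc <- numeric(nw %/% 2 + 1L)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nw - 1L)] * w
    X <- stats::fft(seg)[seq_along(acc)]
    acc <- acc + Mod(X)^2
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double all bins except DC and Nyquist
  psd[2:(length(psd) - 1L)] <- 2 * psd[2:(length(psd) - 1L)]
  list(freq = (seq_along(psd) - 1) * fs / nw, psd = psd)
}

#' Fourier comparator score at a frequency
#'
#' Welch power density at the frequency bin nearest `freq_hz`; the
#' comparator's interval-axis position is `1000/freq_hz` ms. With
#' `mode = "amplitude"` the square root of the density is returned.
#'
#' @param x (Prefiltered) signal vector.
#' @param fs Sampling rate in Hz.
#' @param freq_hz Query frequency in Hz.
#' @param window_s,overlap Welch parameters.
#' @param mode `"power"` (default) or `"amplitude"`.
#' @return Scalar density (or amplitude).
#' @export
welch_band_amp <- function(x, fs, freq_hz, window_s = 4, overlap = 0.5,
                           mode = c("power", "amplitude")) {
  mode <- match.arg(mode)
  ps <- welch_psd(x, fs, window_s, overlap)
  v <- ps$psd[which.min(abs(ps$freq - freq_hz))]
  if (mode == "amplitude") sqrt(v) else v
}
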