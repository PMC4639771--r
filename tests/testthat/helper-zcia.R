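# Shared fixtures and independent oracles for the test suite.

# Brute-force pair-counting AUC: the independent oracle for auc().
auc_brute <- function(cases, controls) {
  wins <- 0
  for (a in cases) for (b in controls) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(cases) * length(controls))
}

# A unit-amplitude sinusoid at frequency f Hz, fs Hz, dur seconds.
make_sine <- function(f, fs = 250, dur = 1, amp = 1, phase = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * f * t + phase)
}

# Fabricated cohort-spectra object with a given subject x bin x band
# probability array; raw counts are scaled probabilities so that every
# helper consuming raw counts keeps working.
fake_cohort <- function(P, diagnosis, nAED = NULL, bands = NULL,
                        counts_per_subject = 10000) {
  n <- dim(P)[1]
  if (is.null(bands)) {
    bands <- lapply(seq_len(dim(P)[3]), function(i) bandpass(i, i + 10))
  }
  if (is.null(nAED)) nAED <- rep(0L, n)
  raw <- round(P * counts_per_subject)
  structure(list(
    raw = raw, p = P, bands = bands,
    bin_left = (seq_len(dim(P)[2]) - 1) * 4, bin_ms = 4,
    meta = data.frame(subject_id = sprintf("F%03d", seq_len(n)),
                      diagnosis = diagnosis, nAED = nAED,
                      eeg_score = 0L, stringsAsFactors = FALSE),
    by = NULL, groups = NULL, segment_labels = NULL,
    convention = "rising"), class = "zc_cohort_spectra")
}

# Random spectra concentrated around a peak bin; cases get less mass at
# the peak when `case_shift` > 0.
random_peak_P <- function(n, n_bins = 250, peak_bin = 25, width = 3,
                          case_shift = 0, is_case = rep(FALSE, n)) {
  P <- matrix(0, n, n_bins)
  for (i in seq_len(n)) {
    centre <- peak_bin + sample(-1:1, 1)
    mass <- stats::dnorm(seq_len(n_bins), centre,
                         width * (1 + 0.2 * stats::rnorm(1)))
    if (is_case[i] && case_shift > 0) {
      win <- max(1, centre - 1):min(n_bins, centre + 1)
      mass[win] <- mass[win] * (1 - case_shift)
    }
    mass <- mass + 1e-5
    P[i, ] <- mass / sum(mass)
  }
  P
}

# Small synthetic cohort design used across tests: short single- or
# few-segment recordings over a posterior channel subset.
quick_design <- function(..., nsub = c(TLE = 3, FLE = 3, PNES = 3,
                                       headache = 3),
                         dur = c("pre-Fs" = 20, "Hv" = 20, "post-Hv" = 20),
                         channels = c("O1", "O2", "T5", "T6"), seed = 1) {
  cohort_design(n_per_group = nsub, channels = channels,
                segment_durations = dur, seed = seed, ...)
}
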