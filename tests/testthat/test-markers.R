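# Scalar markers: bin counts, descriptive statistics, entropies, Welch.

point_mass_spectrum <- function(bin_left = 96, n_bins = 1000) {
  raw <- integer(n_bins)
  raw[bin_left / 4 + 1] <- 100L
  pool_and_normalize(list(structure(raw, bin_ms = 4, overflow = 0L)))
}

test_that("bin markers return the probability at the queried bin", {
  S <- point_mass_spectrum(96)
  expect_equal(bin_marker(S, 96), 1)
  expect_equal(bin_marker(S, 100), 0)
  raw <- integer(1000); raw[c(25, 26, 27)] <- c(2L, 1L, 1L)
  S2 <- pool_and_normalize(list(structure(raw, bin_ms = 4, overflow = 0L)))
  expect_equal(bin_marker(S2, 96), 0.5)
  expect_error(bin_marker(S, 97), "no bin")
})

test_that("descriptive markers treat bins as point masses at centers", {
  d <- descriptive_markers(point_mass_spectrum(96))
  expect_equal(unname(d[c("mean", "median", "mode")]), c(98, 98, 98))
  expect_equal(unname(d[c("sd", "iqr")]), c(0, 0))
  raw <- integer(1000); raw[c(25, 27)] <- 50L   # bins [96,100) and [104,108)
  S <- pool_and_normalize(list(structure(raw, bin_ms = 4, overflow = 0L)))
  d2 <- descriptive_markers(S)
  expect_equal(unname(d2["mean"]), 102)
  expect_equal(unname(d2["sd"]), 4)
  expect_equal(unname(d2["median"]), 102)
  # mode tie-break: smallest bin
  expect_equal(unname(d2["mode"]), 98)
})

test_that("descriptive markers match a brute-force oracle on a uniform spread", {
  raw <- integer(1000); raw[1:10] <- 10L       # bins [0,4) .. [36,40)
  S <- pool_and_normalize(list(structure(raw, bin_ms = 4, overflow = 0L)))
  d <- descriptive_markers(S)
  centers <- (0:9) * 4 + 2
  expect_equal(unname(d["mean"]), mean(centers))   # 20 ms
  expect_equal(unname(d["sd"]), sqrt(mean((centers - 20)^2)))
})

test_that("entropies follow their closed forms", {
  S <- point_mass_spectrum()
  expect_equal(unname(entropy_markers(S)), c(0, 0))
  raw <- integer(1000); raw[11:18] <- 5L
  S8 <- pool_and_normalize(list(structure(raw, bin_ms = 4, overflow = 0L)))
  expect_equal(unname(entropy_markers(S8)), c(3, 3))
  e <- entropy_markers(c(0.5, 0.25, 0.25))
  expect_equal(unname(e["Hs"]), 1.5)
  expect_equal(unname(e["Hmin"]), 1)
})

test_that("min-entropy never exceeds Shannon entropy and both respect permutation", {
  set.seed(4)
  for (i in 1:50) {
    p <- rgamma(40, 0.5); p <- p / sum(p)
    e <- entropy_markers(p)
    expect_lte(e["Hmin"], e["Hs"] + 1e-12)
    e2 <- entropy_markers(sample(p))
    expect_equal(e, e2)
    # uniform maximizes Hs over the same support size
    expect_lte(e["Hs"], log2(40))
  }
})

test_that("entropy log base never changes classification", {
  set.seed(5)
  for (rep in 1:20) {
    P <- random_peak_P(20)
    labels <- rep(c(TRUE, FALSE), 10)
    h2 <- entropy_rows(P, base = 2)
    he <- entropy_rows(P, base = exp(1))
    expect_equal(auc(h2[labels, "Hs"], h2[!labels, "Hs"]),
                 auc(he[labels, "Hs"], he[!labels, "Hs"]))
    expect_equal(auc(h2[labels, "Hmin"], h2[!labels, "Hmin"]),
                 auc(he[labels, "Hmin"], he[!labels, "Hmin"]))
  }
})

test_that("marker inversion reflects AUC about one half", {
  set.seed(6)
  cases <- rnorm(15, 1); controls <- rnorm(12)
  expect_equal(auc(-cases, -controls), 1 - auc(cases, controls))
  expect_equal(auc(c(1, 1), c(1, 1)), 0.5)
})

test_that("Welch density integrates to the sinusoid's power", {
  fs <- 250
  x <- make_sine(10, fs, dur = 60)
  ps <- welch_psd(x, fs)
  df <- ps$freq[2] - ps$freq[1]
  inband <- ps$freq >= 9.5 & ps$freq <= 10.5
  expect_equal(sum(ps$psd[inband]) * df, 0.5, tolerance = 0.05 * 0.5)
})

test_that("Welch density is flat for white noise", {
  set.seed(11)
  x <- rnorm(250 * 120)
  ps <- welch_psd(x, 250)
  lowband <- mean(ps$psd[ps$freq >= 4 & ps$freq < 8.5])
  highband <- mean(ps$psd[ps$freq >= 8.5 & ps$freq <= 13])
  expect_equal(lowband / highband, 1, tolerance = 0.1)
})

test_that("Welch band scores scale with amplitude squared", {
  fs <- 250
  x <- make_sine(6, fs, 60) + make_sine(10, fs, 60, amp = 2)
  r <- welch_band_amp(x, fs, 10) / welch_band_amp(x, fs, 6)
  expect_equal(r, 4, tolerance = 0.15 * 4)
  ra <- welch_band_amp(x, fs, 10, mode = "amplitude") /
    welch_band_amp(x, fs, 6, mode = "amplitude")
  expect_equal(ra, 2, tolerance = 0.1 * 2)
})

test_that("marker definitions validate their parameters", {
  expect_error(marker_def("bin_count"), "bin_left_ms")
  expect_error(marker_def("bin_count", bin_left_ms = 97), "multiple of 4")
  expect_error(marker_def("fourier_band_amp"), "freq_hz")
  expect_s3_class(marker_def("shannon_entropy", invert = TRUE), "zc_marker")
})
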