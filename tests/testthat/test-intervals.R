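# Crossing detection, interval histograms, pooled spectra.

test_that("crossings are placed by linear interpolation", {
  # samples -1, +1 at 250 Hz sit at 0 and 4 ms; crossing at the midpoint
  expect_equal(detect_crossings(c(-1, 1), 250), 2)
  expect_equal(detect_crossings(c(1, 1, 1), 250), numeric(0))
  expect_equal(detect_crossings(rep(0, 10), 250), numeric(0))
  # asymmetric bracketing: -1 to +3 crosses a quarter of the way
  expect_equal(detect_crossings(c(-1, 3), 250), 1)
})

test_that("sinusoid crossings match analytic zero times", {
  fs <- 250
  x <- make_sine(10, fs, dur = 1)
  t_rise <- detect_crossings(x, fs)
  # rising zeros of sin(2*pi*10*t) at t = k/10 s
  expected <- seq(100, 900, by = 100)
  expect_equal(length(t_rise), length(expected))
  expect_true(all(abs(t_rise - expected) < 0.5))
  t_all <- detect_crossings(x, fs, convention = "all")
  expect_equal(length(t_all), 2 * length(t_rise) + 1)
})

test_that("zero runs produce at most one crossing", {
  x <- c(-1, -1, 0, 0, 0, 1, 1, -1)
  t_rise <- detect_crossings(x, 250)
  expect_length(t_rise, 1)
  t_all <- detect_crossings(x, 250, convention = "all")
  expect_length(t_all, 2)
  expect_true(all(diff(t_all) > 0))
})

test_that("intervals are first differences of crossing times", {
  expect_equal(crossings_to_intervals(c(2, 102, 202)), c(100, 100))
  expect_equal(crossings_to_intervals(5), numeric(0))
  expect_equal(crossings_to_intervals(numeric(0)), numeric(0))
})

test_that("a one-minute 10 Hz sinusoid yields one interval per cycle", {
  fs <- 250
  x <- make_sine(10, fs, dur = 60, phase = -0.05)
  iv <- crossings_to_intervals(detect_crossings(x, fs))
  expect_equal(length(iv), 599)
  expect_true(all(abs(iv - 100) < 0.5))
})

test_that("histogramming uses half-open 4-ms bins with overflow tally", {
  h <- build_histogram(c(96.5, 97.2, 101.0))
  expect_equal(h[25], 2)           # bin [96, 100)
  expect_equal(h[26], 1)           # bin [100, 104)
  expect_equal(sum(h), 3)
  expect_equal(attr(h, "overflow"), 0L)
  h0 <- build_histogram(numeric(0))
  expect_equal(sum(h0), 0)
  h4k <- build_histogram(4000)
  expect_equal(sum(h4k), 0)
  expect_equal(attr(h4k, "overflow"), 1L)
  # total = intervals minus overflow
  set.seed(2)
  iv <- runif(500, 0, 5000)
  hh <- build_histogram(iv)
  expect_equal(sum(hh) + attr(hh, "overflow"), 500)
})

test_that("pooling sums raw counts then normalizes once", {
  shape <- c(1, 3, 0, 6)
  a <- structure(as.integer(shape * 10), bin_ms = 4, overflow = 0L)
  b <- structure(as.integer(shape * 30), bin_ms = 4, overflow = 2L)
  S <- pool_and_normalize(list(a, b))
  expect_equal(S$p, shape / sum(shape))          # normalization invariance
  expect_equal(S$overflow, 2L)
  S1 <- pool_and_normalize(list(a))
  expect_equal(S1$p, shape / sum(shape))         # identity
  d1 <- structure(c(100L, 0L), bin_ms = 4, overflow = 0L)
  d2 <- structure(c(0L, 300L), bin_ms = 4, overflow = 0L)
  S2 <- pool_and_normalize(list(d1, d2))
  expect_equal(S2$p, c(0.25, 0.75))
  expect_error(pool_and_normalize(list(structure(c(0L, 0L), bin_ms = 4))),
               "no intervals")
  expect_error(pool_and_normalize(list(a, structure(1:8, bin_ms = 4))),
               "binning")
})

test_that("pure sinusoids map the 8-13 Hz band into 77-125 ms intervals", {
  fs <- 250
  for (f in c(4, 6, 8, 10, 11, 13)) {
    x <- make_sine(f, fs, dur = 30, phase = 0.41)
    h <- build_histogram(crossings_to_intervals(detect_crossings(x, fs)))
    S <- pool_and_normalize(list(h))
    target <- 1000 / f
    near <- abs(S$bin_left + 2 - target) <= 4
    expect_gte(sum(S$p[near]), 0.99)
  }
})

test_that("crossing threshold shifts of 1 uV barely move the spectrum", {
  d <- quick_design(noise_amp = 5, alpha_mod_depth = 0.2,
                    dur = c("pre-Fs" = 60), seed = 21)
  rec <- simulate_subject(d, subject_meta("headache", 0), seed = 33)
  fir <- design_bandpass(bandpass(4, 13), rec$fs)
  x <- apply_zero_phase(colSums(extract_segment(rec, "pre-Fs", c("O1", "O2"))),
                        fir)
  spec_at <- function(thr) {
    h <- build_histogram(crossings_to_intervals(detect_crossings(x - thr,
                                                                 rec$fs)))
    h / sum(h)
  }
  tv <- 0.5 * sum(abs(spec_at(0) - spec_at(1)))
  tv2 <- 0.5 * sum(abs(spec_at(0) - spec_at(-1)))
  expect_lt(tv, 0.02)
  expect_lt(tv2, 0.02)
})

test_that("bin width does not change group-level marker ordering", {
  d <- quick_design(nsub = c(TLE = 4, FLE = 4, PNES = 4, headache = 4),
                    seed = 6)
  co <- simulate_cohort(d)
  epil <- is_epilepsy(co$meta$diagnosis)
  fir <- design_bandpass(bandpass(4, 13), 250)
  marker3 <- function(rec, bin_ms) {
    parts <- list()
    for (seg in names(rec$segments)) {
      x <- apply_zero_phase(colSums(extract_segment(rec, seg)), fir)
      parts[[seg]] <- build_histogram(
        crossings_to_intervals(detect_crossings(x, rec$fs)), bin_ms = bin_ms)
    }
    S <- pool_and_normalize(parts, bin_ms = bin_ms)
    alpha <- S$bin_left + bin_ms > 77 & S$bin_left < 125
    theta <- S$bin_left + bin_ms > 125 & S$bin_left < 250
    c(alpha = sum(S$p[alpha]), theta = sum(S$p[theta]),
      Hs = unname(entropy_markers(S)["Hs"]))
  }
  for (bw in c(2, 4, 8)) {
    M <- t(vapply(co$recordings, marker3, numeric(3), bin_ms = bw))
    expect_lt(median(M[epil, "alpha"]), median(M[!epil, "alpha"]))
    expect_gt(median(M[epil, "Hs"]), median(M[!epil, "Hs"]))
  }
})
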