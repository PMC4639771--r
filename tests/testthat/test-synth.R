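# Synthetic cohort generator: determinism, effect directions, structure.

test_that("simulation is bit-reproducible from its seed", {
  d <- quick_design(dur = c("pre-Fs" = 10), channels = c("O1", "O2"),
                    seed = 41)
  m <- subject_meta("TLE", 2)
  r1 <- simulate_subject(d, m, seed = 99)
  r2 <- simulate_subject(d, m, seed = 99)
  expect_identical(r1$signal, r2$signal)
  r3 <- simulate_subject(d, m, seed = 100)
  expect_false(identical(r1$signal, r3$signal))
})

test_that("cohorts rewrite to bit-identical EDF payloads", {
  d <- quick_design(nsub = c(TLE = 1, FLE = 0, PNES = 1, headache = 0),
                    dur = c("pre-Fs" = 10), channels = c("O1", "O2"),
                    seed = 42)
  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  simulate_cohort(d, out_dir = d1)
  simulate_cohort(d, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  back <- read_cohort(d1)
  expect_length(back$recordings, 2)
  expect_s3_class(back$recordings[[1]], "zc_recording")
})

test_that("the noiseless regular oscillator concentrates all interval mass", {
  d <- quick_design(dur = c("pre-Fs" = 30), channels = c("O1", "O2"),
                    alpha_jitter_sd = 0, alpha_freq_sd = 0,
                    alpha_amp_cv = 0, alpha_mod_depth = 0, noise_amp = 0,
                    theta_amp_base = 0, theta_amp_per_aed = 0,
                    artifact_rate_per_min = 0, hp_hz = 0, seed = 43)
  rec <- simulate_subject(d, subject_meta("headache", 0), seed = 7)
  iv <- crossings_to_intervals(detect_crossings(rec$signal["O1", ], rec$fs))
  S <- pool_and_normalize(list(build_histogram(iv)))
  target <- 1000 / d$alpha_freq_mean
  near <- abs(S$bin_left + 2 - target) <= 4
  expect_gte(sum(S$p[near]), 0.99)
})

test_that("the epilepsy analogue lowers alpha counts and raises entropy", {
  d <- quick_design(nsub = c(TLE = 12, FLE = 13, PNES = 13, headache = 12),
                    dur = c("pre-Fs" = 60), channels = c("O1", "O2"),
                    seed = 44)
  co <- simulate_cohort(d)
  cs <- cohort_spectra(co$recordings, list(bandpass(4, 13)))
  epil <- is_epilepsy(cs$meta$diagnosis)
  alpha_cols <- cs$bin_left + 4 > 77 & cs$bin_left < 125
  alpha_mass <- rowSums(cs$p[, alpha_cols, 1])
  hs <- entropy_rows(cs$p[, , 1])[, "Hs"]
  expect_lt(wilcox.test(alpha_mass[epil], alpha_mass[!epil],
                        alternative = "less")$p.value, 0.01)
  expect_lt(wilcox.test(hs[epil], hs[!epil],
                        alternative = "greater")$p.value, 0.01)
})

test_that("drug load raises theta-range interval mass dose-dependently", {
  # force nAED 3 vs 0 in otherwise identical control subjects
  d <- quick_design(nsub = c(TLE = 0, FLE = 0, PNES = 20, headache = 20),
                    dur = c("pre-Fs" = 60), channels = c("O1", "O2"),
                    naed_probs = rbind(TLE = c(1, 0, 0, 0),
                                       FLE = c(1, 0, 0, 0),
                                       PNES = c(0, 0, 0, 1),
                                       headache = c(1, 0, 0, 0)),
                    seed = 45)
  co <- simulate_cohort(d)
  cs <- cohort_spectra(co$recordings, list(bandpass(0, 15)))
  theta_cols <- cs$bin_left + 4 > 125 & cs$bin_left < 250
  theta_mass <- rowSums(cs$p[, theta_cols, 1])
  hi <- cs$meta$nAED == 3
  expect_equal(sum(hi), 20)
  expect_lt(wilcox.test(theta_mass[hi], theta_mass[!hi],
                        alternative = "greater")$p.value, 0.01)
})

test_that("cohort metadata respects the design's group structure", {
  d <- quick_design(nsub = c(TLE = 5, FLE = 6, PNES = 4, headache = 3),
                    dur = c("pre-Fs" = 4), channels = "O1", seed = 46)
  co <- simulate_cohort(d)
  expect_equal(nrow(co$meta), 18)
  expect_equal(sum(is_epilepsy(co$meta$diagnosis)), 11)
  expect_true(all(co$meta$nAED %in% 0:3))
  expect_true(all(is.na(co$meta$duration_years[
    !is_epilepsy(co$meta$diagnosis)])))
  # headache subjects are mostly drug-free by design
  expect_lt(mean(co$meta$nAED[co$meta$diagnosis == "headache"] > 0), 0.5)
})
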