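# AUC machinery and leave-pair-out cross-validation.

test_that("pair-counting AUC matches enumeration", {
  expect_equal(auc(c(2, 3), c(1, 2)), 0.875)     # win, tie, win, win
  expect_equal(auc(c(5, 6), c(1, 2)), 1)
  expect_equal(auc(1, 1), 0.5)
})

test_that("fast AUC equals the brute-force oracle on random score sets", {
  set.seed(17)
  for (i in 1:200) {
    n1 <- sample(2:12, 1); n0 <- sample(2:12, 1)
    cases <- sample(round(rnorm(n1, 0.3), 1))    # rounded to force ties
    controls <- sample(round(rnorm(n0), 1))
    expect_identical(auc(cases, controls), auc_brute(cases, controls))
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(18)
  cases <- rnorm(20, 0.5); controls <- rnorm(15)
  a <- auc(cases, controls)
  expect_equal(auc(exp(cases), exp(controls)), a)
  expect_equal(auc(atan(cases), atan(controls)), a)
})

test_that("naive AUC curves localize a planted alpha deficit", {
  set.seed(19)
  is_case <- rep(c(TRUE, FALSE), each = 15)
  P <- random_peak_P(30, peak_bin = 25, case_shift = 0.4, is_case = is_case)
  cohort <- fake_cohort(array(P, c(dim(P), 1)),
                        diagnosis = ifelse(is_case, "TLE", "PNES"),
                        counts_per_subject = 50000)
  cur <- auc_curve(cohort, is_case)
  # the minimum sits at the shifted peak (bin 25 -> left edge 96 ms)
  expect_true(abs(cur$bin_left[which.min(cur$auc)] - 96) <= 8)
  expect_lt(min(cur$auc), 0.25)
  # label inversion reflects the curve about 0.5
  cur_inv <- auc_curve(cohort, !is_case)
  expect_equal(cur_inv$auc, 1 - cur$auc)
})

test_that("LPO-CV with no fitting freedom reduces to plain AUC", {
  set.seed(20)
  for (rep in 1:10) {
    P <- random_peak_P(16)
    cohort <- fake_cohort(array(P, c(dim(P), 1)),
                          diagnosis = rep(c("TLE", "PNES"), 8))
    is_case <- is_epilepsy(cohort$meta$diagnosis)
    # single admissible bin x single band -> parameter-free classifier
    cv <- lpo_cv(cohort, "alpha_score", alpha_range_ms = c(96, 100))
    expect_equal(cv$n_candidates, 1L)
    expect_equal(cv$auc_star,
                 auc(-P[is_case, 25], -P[!is_case, 25]))
    cv2 <- lpo_cv(cohort, "shannon_score")
    hs <- entropy_rows(P)[, "Hs"]
    expect_equal(cv2$auc_star, auc(hs[is_case], hs[!is_case]))
  }
})

test_that("incremental fold fitting equals a literal per-fold refit", {
  set.seed(30)
  lpo_oracle <- function(M, is_case, minimize) {
    ci <- which(is_case); gj <- which(!is_case)
    wins <- c()
    for (i in ci) for (j in gj) {
      a <- sapply(seq_len(ncol(M)), function(t)
        auc_brute(M[setdiff(ci, i), t], M[setdiff(gj, j), t]))
      t_star <- if (minimize) which.min(a) else which.max(a)
      s1 <- M[i, t_star]; s0 <- M[j, t_star]
      if (minimize) { s1 <- -s1; s0 <- -s0 }
      wins <- c(wins, (s1 > s0) + 0.5 * (s1 == s0))
    }
    mean(wins)
  }
  for (r in 1:3) {
    P <- random_peak_P(12, n_bins = 40)
    cohort <- fake_cohort(array(P, c(dim(P), 1)),
                          diagnosis = rep(c("TLE", "PNES"), 6))
    cv <- lpo_cv(cohort, "alpha_score")
    M <- P[, match(seq(76, 124, 4), (seq_len(40) - 1) * 4), drop = FALSE]
    expect_equal(cv$auc_star,
                 lpo_oracle(M, is_epilepsy(cohort$meta$diagnosis), TRUE))
  }
})

test_that("cross-validation removes the optimism of in-sample maximization", {
  set.seed(21)
  hits <- 0L
  for (s in 1:12) {
    P <- random_peak_P(20, case_shift = 0.15,
                       is_case = rep(c(TRUE, FALSE), 10))
    cohort <- fake_cohort(array(P, c(dim(P), 1)),
                          diagnosis = rep(c("FLE", "headache"), 10))
    cv <- lpo_cv(cohort, "alpha_score")
    if (cv$auc_star <= cv$in_sample_max + 1e-12) hits <- hits + 1L
  }
  expect_gte(hits, 11L)
})

test_that("label permutation drives cross-validated AUC to chance", {
  set.seed(22)
  stars <- replicate(20, {
    P <- random_peak_P(20)
    cohort <- fake_cohort(array(P, c(dim(P), 1)),
                          diagnosis = sample(rep(c("TLE", "PNES"), 10)))
    lpo_cv(cohort, "alpha_score")$auc_star
  })
  expect_gt(mean(stars), 0.35)
  expect_lt(mean(stars), 0.65)
})

test_that("fold bookkeeping enumerates all case-control pairs", {
  set.seed(23)
  P <- random_peak_P(12)
  cohort <- fake_cohort(array(P, c(dim(P), 1)),
                        diagnosis = rep(c("TLE", "FLE", "PNES", "headache"),
                                        3))
  cv <- lpo_cv(cohort, "alpha_score")
  expect_equal(cv$n_folds, 6 * 6)
  expect_equal(nrow(cv$folds), 36)
  expect_true(cv$auc_star >= 0 && cv$auc_star <= 1)
  expect_output(print(cv), "AUC\\*")
  expect_output(summary(cv), "folds")
  expect_named(coef(cv), c("lo", "hi", "bin"))
})

test_that("two-step fitting finds a planted channel/segment locus", {
  # epilepsy deficit confined to T5/T6 in post-Hv: the ratio map and the
  # selected combinations must concentrate there
  d <- quick_design(nsub = c(TLE = 8, FLE = 0, PNES = 8, headache = 0),
                    dur = c("pre-Fs" = 30, "Hv" = 30, "post-Hv" = 30),
                    channels = c("T5", "T6", "O1", "O2"),
                    epilepsy_alpha_deficit = 0.6,
                    epilepsy_jitter_factor = 1,
                    alpha_amp_cv = 0.1, alpha_jitter_cv = 0.1,
                    effect_channels = c("T5", "T6"),
                    effect_segments = "post-Hv",
                    artifact_rate_per_min = 0, seed = 31)
  co <- simulate_cohort(d)
  cs <- cohort_spectra(co$recordings, list(bandpass(4, 13)), keep_by = TRUE)
  cv <- lpo_cv(cs, "alpha_score", two_step = TRUE)
  m <- auc_ratio_map(cv)
  peak <- arrayInd(which.max(m), dim(m))
  expect_equal(rownames(m)[peak[1]], "T5+T6")
  expect_equal(colnames(m)[peak[2]], "post-Hv")
  expect_equal(cv$param_mode$group, "T5+T6")
  expect_equal(cv$param_mode$segment, "post-Hv")
  expect_true(all(!is.na(cv$auc_star2)))
})

test_that("subsegment subsampling is deterministic and exact at full length", {
  d <- quick_design(nsub = c(TLE = 4, FLE = 0, PNES = 4, headache = 0),
                    dur = c("post-Hv" = 40), channels = c("T5", "T6"),
                    seed = 32)
  co <- simulate_cohort(d)
  spec <- classifier_spec(marker_def("bin_count", bin_left_ms = 96,
                                     invert = TRUE),
                          bandpass(4, 13), channel_group = "T5+T6",
                          segment_label = "post-Hv", invert = TRUE)
  is_case <- is_epilepsy(co$meta$diagnosis)
  r1 <- subsegment_experiment(co$recordings, spec, is_case,
                              lengths_s = c(10, 40), reps = 15, seed = 9)
  r2 <- subsegment_experiment(co$recordings, spec, is_case,
                              lengths_s = c(10, 40), reps = 15, seed = 9)
  expect_identical(r1, r2)
  expect_equal(r1$rel_auc_mean[2], 1)
  expect_equal(r1$rel_auc_sd[2], 0)
  # shorter segments cannot beat the full segment beyond noise
  expect_lte(r1$rel_auc_mean[1], 1 + r1$rel_auc_sd[1] + 0.05)
  expect_error(subsegment_experiment(co$recordings, spec, is_case,
                                     lengths_s = 50, reps = 2, seed = 1),
               "exceeds")
})

test_that("averaged ROC curves behave at the extremes", {
  fold <- list(scores = c(3, 4, 5, 1, 2), labels = c(TRUE, TRUE, TRUE,
                                                     FALSE, FALSE))
  expect_warning(r1 <- averaged_roc(list(fold, fold)), "not obtained by")
  expect_warning(rs <- averaged_roc(list(fold)), "not obtained by")
  expect_equal(r1$sensitivity, rs$sensitivity)
  expect_true(all(r1$sensitivity_sd == 0))
  # perfect separation passes through sensitivity 1 at specificity 1
  expect_equal(r1$sensitivity[r1$specificity == 1], 1)
  # random scores stay near the diagonal on average
  set.seed(24)
  folds <- replicate(60, list(scores = rnorm(40),
                              labels = rep(c(TRUE, FALSE), 20)),
                     simplify = FALSE)
  expect_warning(rr <- averaged_roc(folds), "not obtained by")
  dev <- rr$sensitivity - (1 - rr$specificity)
  expect_lt(max(abs(dev[rr$specificity > 0.05 & rr$specificity < 0.95])),
            0.2)
})
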