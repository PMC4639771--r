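# ROC/AUC machinery: pair-counting AUC, naive AUC curves, leave-pair-out
# cross-validation with one- and two-step parameter fitting, AUC-ratio
# maps, the segment-length experiment, and vertically averaged ROC curves.

#' Pair-counting AUC
#'
#' The probability that a randomly chosen case scores higher than a
#' randomly chosen control; ties credit 0.5. Equals the rank-sum
#' (Mann-Whitney) statistic scaled to `[0, 1]`.
#'
#' @param scores_cases,scores_controls Numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores_cases, scores_controls) {
  n1 <- length(scores_cases); n0 <- length(scores_controls)
  if (n1 == 0L || n0 == 0L) stop("both groups must be non-empty")
  r <- rank(c(scores_cases, scores_controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC for each column of a score matrix
#'
#' @param M `subjects x markers` matrix.
#' @param is_case Logical case indicator.
#' @return Vector of AUCs.
#' @export
auc_by_column <- function(M, is_case) {
  apply(M, 2, function(v) auc(v[is_case], v[!is_case]))
}

#' Naive AUC vs interval length curve
#'
#' One AUC per histogram bin of the whole-recording spectra, flagging the
#' usefulness region (AUC > 0.75 or < 0.25). "Naive" because computed
#' in-sample on the full cohort; see [lpo_cv()] for honest estimates.
#'
#' @param cohort A `zc_cohort_spectra`.
#' @param is_case Logical case indicator (default: epilepsy vs control).
#' @param band_index Which band of the cohort object (default 1).
#' @param eligible_only Restrict to [eligible_bins()] (default `TRUE`).
#' @param useful_threshold Usefulness threshold (default 0.75).
#' @return Data frame `bin_left`, `auc`, `eligible`, `useful`.
#' @export
auc_curve <- function(cohort, is_case = NULL, band_index = 1,
                      eligible_only = TRUE, useful_threshold = 0.75) {
  if (is.null(is_case)) is_case <- is_epilepsy(cohort$meta$diagnosis)
  P <- cohort$p[, , band_index]
  elig <- eligible_bins(cohort$raw[, , band_index])
  keep <- if (eligible_only) which(elig) else seq_along(elig)
  a <- auc_by_column(P[, keep, drop = FALSE], is_case)
  data.frame(bin_left = cohort$bin_left[keep], auc = a,
             eligible = elig[keep],
             useful = a > useful_threshold | a < 1 - useful_threshold)
}

#' Classifier specification
#'
#' @param marker A [marker_def()].
#' @param band A [bandpass()].
#' @param channel_group Optional channel-group name (e.g. `"T5+T6"`);
#'   `NULL` means whole-recording pooling.
#' @param segment_label Optional segment label; `NULL` means all segments.
#' @param invert Inversion flag.
#' @return Object of class `zc_classifier_spec`.
#' @export
classifier_spec <- function(marker, band, channel_group = NULL,
                            segment_label = NULL, invert = FALSE) {
  if (xor(is.null(channel_group), is.null(segment_label))) {
    # whole-recording pooling has neither; localized specs need both
    stop("channel_group and segment_label must be given together")
  }
  structure(list(marker = marker, band = band,
                 channel_group = channel_group,
                 segment_label = segment_label, invert = isTRUE(invert)),
            class = "zc_classifier_spec")
}

# Bin left edges whose half-open bin intersects [lo, hi) ms.
bins_in_range <- function(range_ms, bin_ms = 4, range_max = 4000) {
  left <- seq(0, range_max - bin_ms, by = bin_ms)
  left[left + bin_ms > range_ms[1] & left < range_ms[2]]
}

# Build the candidate marker matrix for an objective: columns ordered
# lexicographically by (lo, hi, bin) — the deterministic tie-break order.
build_candidates <- function(cohort, objective, alpha_range_ms,
                             theta_range_ms) {
  n <- dim(cohort$p)[1]
  bands <- cohort$bands
  los <- vapply(bands, function(b) b$lo, 0)
  his <- vapply(bands, function(b) b$hi, 0)
  bord <- order(los, his)
  if (objective %in% c("alpha_score", "theta_score")) {
    rng <- if (objective == "alpha_score") alpha_range_ms else theta_range_ms
    bl <- bins_in_range(rng, cohort$bin_ms)
    bidx <- match(bl, cohort$bin_left)
    M <- matrix(0, n, length(bord) * length(bl))
    grid <- data.frame(lo = rep(los[bord], each = length(bl)),
                       hi = rep(his[bord], each = length(bl)),
                       bin = rep(bl, times = length(bord)),
                       band_index = rep(bord, each = length(bl)))
    for (k in seq_along(bord)) {
      M[, (k - 1L) * length(bl) + seq_along(bl)] <-
        cohort$p[, bidx, bord[k]]
    }
  } else {
    col <- if (objective == "shannon_score") "Hs" else "Hmin"
    M <- matrix(0, n, length(bord))
    for (k in seq_along(bord)) {
      M[, k] <- entropy_rows(cohort$p[, , bord[k]])[, col]
    }
    grid <- data.frame(lo = los[bord], hi = his[bord], bin = NA_real_,
                       band_index = bord)
  }
  list(M = M, grid = grid)
}

# Marker values per subject at one candidate, resolved per channel group x
# segment (for two-step fitting). Returns n x nG x nS array.
by_markers_at <- function(cohort, objective, grid_row) {
  by <- cohort$by
  stopifnot(!is.null(by))
  b <- grid_row$band_index
  nG <- length(cohort$groups); nS <- length(cohort$segment_labels)
  n <- length(by)
  out <- array(NA_real_, c(n, nG, nS))
  if (objective %in% c("alpha_score", "theta_score")) {
    bin_i <- match(grid_row$bin, cohort$bin_left)
    for (i in seq_len(n)) {
      cnt <- by[[i]][, b, , , drop = FALSE]
      tot <- apply(cnt, c(3, 4), sum)
      out[i, , ] <- cnt[bin_i, 1, , ] / ifelse(tot > 0, tot, NA)
    }
  } else {
    col <- if (objective == "shannon_score") "Hs" else "Hmin"
    for (i in seq_len(n)) {
      cnt <- by[[i]][, b, , , drop = FALSE]
      for (g in seq_len(nG)) for (s in seq_len(nS)) {
        v <- cnt[, 1, g, s]
        tot <- sum(v)
        out[i, g, s] <- if (tot > 0) {
          unname(entropy_markers(v / tot)[if (col == "Hs") "Hs" else "Hmin"])
        } else NA_real_
      }
    }
  }
  out
}

#' Leave-pair-out cross-validated classifier fitting
#'
#' For every case-control pair, the pair is held out, the classifier's
#' free parameters are fitted on the remaining subjects to optimize
#' in-fold AUC, and the held-out pair is scored with the fitted
#' parameters. The cross-validated AUC* is the fraction of held-out pairs
#' ranked correctly (ties credit 0.5).
#'
#' Objectives: `"alpha_score"` minimizes in-fold AUC of the alpha-range
#' bin probability over bins x band grid, then inverts the classifier;
#' `"theta_score"` maximizes over theta-range bins x bands;
#' `"shannon_score"` / `"minentropy_score"` maximize the interval-spectrum
#' entropy AUC over the band grid only. With `two_step = TRUE` the fit
#' subsequently maximizes over singleton (channel group x segment)
#' combinations (requires `cohort_spectra(..., keep_by = TRUE)`).
#'
#' Ties among in-fold optima are broken towards the lexicographically
#' smallest `(lo, hi, bin, channel-group index, segment index)`.
#'
#' @param cohort A `zc_cohort_spectra`.
#' @param objective One of `"alpha_score"`, `"shannon_score"`,
#'   `"minentropy_score"`, `"theta_score"`.
#' @param is_case Logical case indicator, `NA` to drop a subject. Default:
#'   epilepsy vs control for the alpha/entropy scores; AED polytherapy
#'   (nAED >= 2) vs monotherapy (nAED = 1) for the theta score.
#' @param two_step Fit channel group x segment in a second step.
#' @param alpha_range_ms,theta_range_ms Interval ranges used by the
#'   alpha/theta objectives (defaults 77-125 ms and 125-250 ms, the
#'   interval-domain counterparts of the 8-13 Hz and 4-8 Hz bands).
#' @return Object of class `zc_lpocv`; see Details.
#'
#' @details The returned object carries `auc_star` (one-step AUC*),
#'   `auc_star2` (two-step AUC**, if requested), a per-fold data frame
#'   `folds` (held-out pair, fitted parameters, in-fold maximal AUC,
#'   held-out outcome), `param_mode` (most frequently selected
#'   parameters), `in_sample_max` (the naive in-sample maximized AUC, for
#'   optimism comparison) and, for two-step fits, `auc_ratio_map` (mean
#'   over folds of second-step AUC normalized by the fold's first-step
#'   maximum, per channel group x segment).
#' @export
lpo_cv <- function(cohort, objective = c("alpha_score", "shannon_score",
                                         "minentropy_score", "theta_score"),
                   is_case = NULL, two_step = FALSE,
                   alpha_range_ms = c(77, 125),
                   theta_range_ms = c(125, 250)) {
  objective <- match.arg(objective)
  meta <- cohort$meta
  if (is.null(is_case)) {
    is_case <- if (objective == "theta_score") {
      ifelse(meta$nAED >= 2, TRUE, ifelse(meta$nAED == 1, FALSE, NA))
    } else {
      is_epilepsy(meta$diagnosis)
    }
  }
  keep <- which(!is.na(is_case))
  ci <- keep[is_case[keep] == TRUE]
  gj <- keep[is_case[keep] == FALSE]
  n1 <- length(ci); n0 <- length(gj)
  if (n1 < 2L || n0 < 2L) stop("need >= 2 cases and >= 2 controls")
  cand <- build_candidates(cohort, objective, alpha_range_ms, theta_range_ms)
  M <- cand$M; grid <- cand$grid
  nT <- ncol(M)
  direction <- if (objective == "alpha_score") "min" else "max"
  inverted <- objective == "alpha_score"
  # pairwise comparison tables per candidate
  W <- array(0, c(n1, n0, nT))
  for (t in seq_len(nT)) {
    D <- outer(M[ci, t], M[gj, t], "-")
    W[, , t] <- (D > 0) + 0.5 * (D == 0)
  }
  Ri <- colSums(aperm(W, c(2, 1, 3)))   # n1 x nT
  Cj <- colSums(W)                       # n0 x nT
  Wtot <- colSums(Ri)                    # nT
  denom <- (n1 - 1) * (n0 - 1)
  two_cache <- new.env(parent = emptyenv())
  nG <- length(cohort$groups); nS <- length(cohort$segment_labels)
  ratio_sum <- ratio_n <- matrix(0, nG, nS,
                                 dimnames = list(cohort$groups,
                                                 cohort$segment_labels))
  nF <- n1 * n0
  wins1 <- wins2 <- infold <- numeric(nF)
  sel_t <- sel_g <- sel_s <- integer(nF)
  case_id <- ctrl_id <- integer(nF)
  f <- 0L
  for (i in seq_len(n1)) for (j in seq_len(n0)) {
    f <- f + 1L
    wins_t <- Wtot - Ri[i, ] - Cj[j, ] + W[i, j, ]
    aucs <- wins_t / denom
    t_star <- if (direction == "min") which.min(aucs) else which.max(aucs)
    oriented_best <- if (inverted) 1 - aucs[t_star] else aucs[t_star]
    s_case <- M[ci[i], t_star]; s_ctrl <- M[gj[j], t_star]
    if (inverted) { s_case <- -s_case; s_ctrl <- -s_ctrl }
    wins1[f] <- (s_case > s_ctrl) + 0.5 * (s_case == s_ctrl)
    g_star <- s_star <- NA_integer_
    if (two_step) {
      key <- as.character(t_star)
      B <- two_cache[[key]]
      if (is.null(B)) {
        B <- by_markers_at(cohort, objective, grid[t_star, ])
        two_cache[[key]] <- B
      }
      in_ci <- ci[-i]; in_gj <- gj[-j]
      auc2 <- matrix(NA_real_, nG, nS)
      for (g in seq_len(nG)) for (s in seq_len(nS)) {
        v1 <- B[in_ci, g, s]; v0 <- B[in_gj, g, s]
        if (anyNA(v1) || anyNA(v0)) next
        if (inverted) { v1 <- -v1; v0 <- -v0 }
        auc2[g, s] <- auc(v1, v0)
      }
      ok <- !is.na(auc2)
      ratio_sum[ok] <- ratio_sum[ok] + auc2[ok] / oriented_best
      ratio_n <- ratio_n + ok
      # lexicographic (group index, segment index) tie-break
      flat <- as.vector(t(auc2))
      k <- which.max(flat)
      g_star <- (k - 1L) %/% nS + 1L
      s_star <- (k - 1L) %% nS + 1L
      b_case <- B[ci[i], g_star, s_star]; b_ctrl <- B[gj[j], g_star, s_star]
      if (inverted) { b_case <- -b_case; b_ctrl <- -b_ctrl }
      wins2[f] <- (b_case > b_ctrl) + 0.5 * (b_case == b_ctrl)
    }
    sel_t[f] <- t_star
    sel_g[f] <- g_star
    sel_s[f] <- s_star
    case_id[f] <- ci[i]
    ctrl_id[f] <- gj[j]
    infold[f] <- oriented_best
  }
  folds <- data.frame(
    case = meta$subject_id[case_id], control = meta$subject_id[ctrl_id],
    lo = grid$lo[sel_t], hi = grid$hi[sel_t], bin = grid$bin[sel_t],
    group = if (two_step) cohort$groups[sel_g] else NA_character_,
    segment = if (two_step) cohort$segment_labels[sel_s] else NA_character_,
    infold_auc = infold, win = wins1,
    stringsAsFactors = FALSE)
  # naive in-sample maximized (oriented) AUC over the same grid
  full_aucs <- Wtot / (n1 * n0)
  in_sample_max <- if (inverted) 1 - min(full_aucs) else max(full_aucs)
  mode_key <- paste(folds$lo, folds$hi, folds$bin,
                    if (two_step) paste(folds$group, folds$segment) else "")
  mk <- names(sort(table(mode_key), decreasing = TRUE))[1]
  mrow <- folds[match(mk, mode_key), , drop = FALSE]
  param_mode <- list(lo = mrow$lo, hi = mrow$hi, bin = mrow$bin,
                     group = mrow$group, segment = mrow$segment)
  structure(list(
    objective = objective, inverted = inverted,
    auc_star = mean(wins1),
    auc_star2 = if (two_step) mean(wins2) else NULL,
    folds = folds, param_mode = param_mode,
    in_sample_max = in_sample_max,
    auc_ratio_map = if (two_step) ratio_sum / pmax(ratio_n, 1) else NULL,
    n_cases = n1, n_controls = n0, n_folds = n1 * n0,
    n_candidates = nT), class = "zc_lpocv")
}

#' @export
print.zc_lpocv <- function(x, ...) {
  cat(sprintf("<zc_lpocv> %s: AUC* = %.4f over %d folds (%d x %d)\n",
              x$objective, x$auc_star, x$n_folds, x$n_cases, x$n_controls))
  if (!is.null(x$auc_star2)) {
    cat(sprintf("  two-step AUC** = %.4f\n", x$auc_star2))
  }
  pm <- x$param_mode
  cat(sprintf("  most common fit: band [%g-%g Hz]%s%s\n", pm$lo, pm$hi,
              if (!is.na(pm$bin)) sprintf(", interval %g ms", pm$bin) else "",
              if (!is.na(pm$group)) sprintf(", %s & %s", pm$group, pm$segment)
              else ""))
  invisible(x)
}

#' @export
summary.zc_lpocv <- function(object, ...) {
  x <- object
  cat(sprintf("Leave-pair-out CV of the %s (%s)\n", x$objective,
              if (x$inverted) "inverted classifier" else "direct classifier"))
  cat(sprintf("  folds: %d case-control pairs (%d cases, %d controls)\n",
              x$n_folds, x$n_cases, x$n_controls))
  cat(sprintf("  candidate parameter settings per fold: %d\n",
              x$n_candidates))
  cat(sprintf("  cross-validated AUC* = %.4f\n", x$auc_star))
  if (!is.null(x$auc_star2)) {
    cat(sprintf("  two-step AUC** = %.4f\n", x$auc_star2))
  }
  cat(sprintf("  naive in-sample maximized AUC = %.4f (optimism %.4f)\n",
              x$in_sample_max, x$in_sample_max - x$auc_star))
  tt <- sort(table(paste0("[", x$folds$lo, "-", x$folds$hi, " Hz]",
                          ifelse(is.na(x$folds$bin), "",
                                 paste0(" @ ", x$folds$bin, " ms")))),
             decreasing = TRUE)
  cat("  parameter selection frequencies:\n")
  print(utils::head(tt, 5))
  invisible(x)
}

#' @export
coef.zc_lpocv <- function(object, ...) {
  pm <- object$param_mode
  c(lo = pm$lo, hi = pm$hi, bin = pm$bin)
}

#' Mean AUC-ratio map of a two-step fit
#'
#' Second-step AUC per (channel group x segment), normalized by the
#' fold's first-step maximum and averaged over folds. Values may exceed 1
#' because the second step evaluates pooled data the first step did not.
#'
#' @param cv A `zc_lpocv` fitted with `two_step = TRUE`.
#' @return `groups x segments` matrix.
#' @export
auc_ratio_map <- function(cv) {
  if (is.null(cv$auc_ratio_map)) stop("cv was not fitted with two_step = TRUE")
  cv$auc_ratio_map
}

#' Segment-length subsampling experiment
#'
#' For each requested length, a random subsegment of that duration is
#' drawn independently for each subject (uniformly within the analysed
#' segment), the marker is recomputed from the crossings falling inside
#' the window, and the naive AUC is recorded; this is repeated `reps`
#' times. Results are normalized by the AUC of the full segment.
#'
#' @param recordings List of `zc_recording`.
#' @param spec A [classifier_spec()] with `channel_group` and
#'   `segment_label` set (e.g. T5+T6 & post-Hv).
#' @param is_case Logical case indicator.
#' @param lengths_s Subsegment lengths in seconds.
#' @param reps Repetitions per length (default 100).
#' @param seed RNG seed (the experiment is reproducible given the seed).
#' @param order FIR order.
#' @return Data frame `length_s`, `rel_auc_mean`, `rel_auc_sd`, plus
#'   attribute `full_auc`.
#' @export
subsegment_experiment <- function(recordings, spec, is_case, lengths_s,
                                  reps = 100, seed = 1, order = 500) {
  group <- strsplit(spec$channel_group, "+", fixed = TRUE)[[1]]
  fs <- recordings[[1]]$fs
  fir <- design_bandpass(spec$band, fs, order = order)
  per_subject <- lapply(recordings, function(rec) {
    x <- colSums(extract_segment(rec, spec$segment_label, group))
    xt <- apply_zero_phase(x, fir)
    list(times = detect_crossings(xt, fs),
         dur_ms = length(x) / fs * 1000)
  })
  marker_of <- function(times) {
    iv <- crossings_to_intervals(times)
    if (length(iv) == 0L) return(NA_real_)
    h <- build_histogram(iv)
    tot <- sum(h)
    if (tot == 0L) return(NA_real_)
    switch(spec$marker$kind,
           bin_count = h[spec$marker$bin_left_ms / 4 + 1L] / tot,
           shannon_entropy = unname(entropy_markers(h / tot)["Hs"]),
           min_entropy = unname(entropy_markers(h / tot)["Hmin"]),
           stop("unsupported marker kind for subsegments: ",
                spec$marker$kind))
  }
  sgn <- if (spec$invert) -1 else 1
  full_scores <- sgn * vapply(per_subject, function(s) marker_of(s$times), 0)
  full_auc <- auc(full_scores[is_case], full_scores[!is_case])
  durs <- vapply(per_subject, `[[`, 0, "dur_ms")
  if (any(lengths_s * 1000 > min(durs) + 1e-9)) {
    stop("requested length exceeds the analysed segment (",
         signif(min(durs) / 1000, 4), " s)")
  }
  set.seed(seed)
  out <- data.frame(length_s = lengths_s, rel_auc_mean = NA_real_,
                    rel_auc_sd = NA_real_)
  for (li in seq_along(lengths_s)) {
    L <- lengths_s[li] * 1000
    rep_auc <- numeric(reps)
    for (r in seq_len(reps)) {
      sc <- vapply(per_subject, function(s) {
        t0 <- stats::runif(1, 0, s$dur_ms - L)
        marker_of(s$times[s$times >= t0 & s$times < t0 + L])
      }, 0)
      sc <- sgn * sc
      rep_auc[r] <- auc(sc[is_case], sc[!is_case])
    }
    out$rel_auc_mean[li] <- mean(rep_auc) / full_auc
    out$rel_auc_sd[li] <- stats::sd(rep_auc) / full_auc
  }
  attr(out, "full_auc") <- full_auc
  out
}

#' Vertically averaged ROC curve
#'
#' Averages per-fold ROC curves over a common specificity grid (mean
#' sensitivity at each specificity). These curves summarize in-fold fits
#' and are not themselves cross-validated, so they may be optimistically
#' biased; a warning says so.
#'
#' @param folds List of folds, each a list with `scores` and `labels`
#'   (logical, `TRUE` = case).
#' @param grid Specificity grid (default 101 points on `[0, 1]`).
#' @return Data frame `specificity`, `sensitivity`, `sensitivity_sd`.
#' @export
averaged_roc <- function(folds, grid = seq(0, 1, by = 0.01)) {
  warning("averaged ROC curves summarize in-fold fits and were not ",
          "obtained by cross-validation; they may be biased")
  sens_at <- function(scores, labels) {
    ths <- c(-Inf, sort(unique(scores)), Inf)
    sens <- vapply(ths, function(t) mean(scores[labels] >= t), 0)
    spec <- vapply(ths, function(t) mean(scores[!labels] < t), 0)
    vapply(grid, function(s) max(sens[spec >= s - 1e-12]), 0)
  }
  S <- vapply(folds, function(f) sens_at(f$scores, f$labels),
              numeric(length(grid)))
  S <- matrix(S, nrow = length(grid))
  data.frame(specificity = grid, sensitivity = rowMeans(S),
             sensitivity_sd = apply(S, 1, stats::sd))
}
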