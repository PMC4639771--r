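# Statistical screening of candidate markers across bins and families.

#' Eligible histogram bins
#'
#' A bin is eligible for statistical testing iff its raw interval count
#' exceeds 100 for every subject (strict `> 100`), which focuses the scan
#' on robustly estimated parts of the spectrum and limits the number of
#' tests.
#'
#' @param raw `subjects x bins` matrix of raw counts (whole-recording).
#' @param min_count Threshold (default 100).
#' @return Logical bin mask.
#' @export
eligible_bins <- function(raw, min_count = 100) {
  apply(raw, 2, min) > min_count
}

#' Kruskal-Wallis scan of one marker
#'
#' Rank-based one-way test with tie correction; the statistic is referred
#' to a chi-square with `k - 1` degrees of freedom. Degenerate input (all
#' values identical) returns `H = 0`, `p = 1`.
#'
#' @param values Per-subject marker values.
#' @param groups Grouping factor (e.g. 4-level diagnosis or nAED).
#' @return List with `H` and `p`.
#' @export
kw_scan <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need >= 2 non-empty groups")
  if (length(unique(values)) == 1L) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Post-hoc pairwise comparisons after Kruskal-Wallis
#'
#' Tukey-Kramer honest-significant-difference comparisons of mean ranks
#' with unequal-n correction and tie-corrected rank variance — the
#' standard follow-up to a significant Kruskal-Wallis test.
#'
#' @param values Per-subject marker values.
#' @param groups Grouping factor.
#' @param conf Family-wise confidence level (default 0.95).
#' @return Data frame with one row per group pair: mean-rank difference,
#'   studentized-range p-value and significance flag.
#' @export
posthoc_groups <- function(values, groups, conf = 0.95) {
  groups <- droplevels(factor(groups))
  k <- nlevels(groups)
  if (k < 2L) stop("need >= 2 groups")
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tiecorr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  s2 <- N * (N + 1) / 12 * tiecorr
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  combs <- utils::combn(levels(groups), 2)
  out <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                    diff = NA_real_, p = NA_real_, significant = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(combs))) {
    a <- combs[1, i]; b <- combs[2, i]
    d <- rbar[a] - rbar[b]
    se <- sqrt(s2 * (1 / ns[a] + 1 / ns[b]))
    q <- abs(d) / se * sqrt(2)
    p <- stats::ptukey(q, k, Inf, lower.tail = FALSE)
    out$diff[i] <- d
    out$p[i] <- p
    out$significant[i] <- p < 1 - conf
  }
  out
}

#' Screen candidate markers for diagnosis and drug-load effects
#'
#' For one passband: every eligible histogram bin plus the seven non-bin
#' markers (mean, median, mode, sd, iqr, Shannon entropy, min-entropy) is
#' tested with a Kruskal-Wallis ANOVA separately against the 4-level
#' diagnosis and the 4-level nAED factor. Bonferroni correction uses
#' `n_tests = n_eligible_bins + 7` per independent variable; because it is
#' ambiguous whether such corrections should count both variables jointly,
#' both thresholds are reported.
#'
#' @param cohort A `zc_cohort_spectra`.
#' @param band_index Which band of the cohort object to screen (default 1).
#' @param alpha Family-wise level (default 0.05).
#' @return Object of class `zc_screen`: data frame `table` (marker, param,
#'   H/p per variable, adjusted-significance flags under both conventions)
#'   plus `n_tests`, `threshold_per_var`, `threshold_joint`,
#'   `eligible` mask, `bin_left`.
#' @export
screen_markers <- function(cohort, band_index = 1, alpha = 0.05) {
  raw <- cohort$raw[, , band_index]
  P <- cohort$p[, , band_index]
  meta <- cohort$meta
  diag_f <- factor(meta$diagnosis, levels = c("TLE", "FLE", "PNES", "headache"))
  naed_f <- factor(meta$nAED, levels = 0:3)
  elig <- eligible_bins(raw)
  n_sub <- nrow(P)
  ent <- entropy_rows(P)
  centers <- cohort$bin_left + cohort$bin_ms / 2
  desc <- t(apply(P, 1, function(p) {
    m <- sum(p * centers)
    qs <- wquantile(centers, p, c(0.25, 0.5, 0.75))
    c(mean = m, median = qs[2], mode = centers[which.max(p)],
      sd = sqrt(max(sum(p * (centers - m)^2), 0)), iqr = qs[3] - qs[1])
  }))
  vals <- cbind(P[, elig, drop = FALSE], desc, ent)
  marker <- c(rep("bin_count", sum(elig)),
              colnames(desc), colnames(ent))
  param <- c(cohort$bin_left[elig], rep(NA_real_, ncol(desc) + ncol(ent)))
  test_all <- function(f) {
    apply(vals, 2, function(v) unlist(kw_scan(v, f)))
  }
  td <- test_all(diag_f)
  tn <- test_all(naed_f)
  n_tests <- ncol(vals)
  thr_var <- alpha / n_tests
  thr_joint <- alpha / (2 * n_tests)
  tab <- data.frame(marker = marker, param = param,
                    H_diag = td["H", ], p_diag = td["p", ],
                    H_nAED = tn["H", ], p_nAED = tn["p", ],
                    sig_diag = td["p", ] < thr_var,
                    sig_nAED = tn["p", ] < thr_var,
                    sig_diag_joint = td["p", ] < thr_joint,
                    sig_nAED_joint = tn["p", ] < thr_joint,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, n_tests = n_tests, alpha = alpha,
                 threshold_per_var = thr_var, threshold_joint = thr_joint,
                 eligible = elig, bin_left = cohort$bin_left,
                 n_subjects = n_sub),
            class = "zc_screen")
}

#' @export
print.zc_screen <- function(x, ...) {
  cat(sprintf("<zc_screen> n = %d subjects, %d tests per variable\n",
              x$n_subjects, x$n_tests))
  cat(sprintf("  Bonferroni threshold: %.2e per variable (%.2e joint)\n",
              x$threshold_per_var, x$threshold_joint))
  sig <- x$table[x$table$sig_diag | x$table$sig_nAED, , drop = FALSE]
  if (nrow(sig)) {
    cat("  significant (per-variable convention):\n")
    print(sig[, c("marker", "param", "p_diag", "p_nAED")], row.names = FALSE)
  } else cat("  no marker passes Bonferroni\n")
  invisible(x)
}

#' Plot p-value vs interval length curves
#'
#' The screening analogue of a double-dissociation figure: one curve per
#' independent variable over the eligible bins, with the Bonferroni level.
#'
#' @param x A `zc_screen`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.zc_screen <- function(x, ...) {
  tb <- x$table[x$table$marker == "bin_count", ]
  graphics::plot(tb$param, log10(tb$p_diag), type = "l", col = "red",
                 xlab = "interval length [ms]", ylab = "log10 P",
                 ylim = range(log10(c(tb$p_diag, tb$p_nAED,
                                      x$threshold_per_var))), ...)
  graphics::lines(tb$param, log10(tb$p_nAED), col = "blue")
  graphics::abline(h = log10(x$threshold_per_var), lty = 2)
  graphics::legend("bottomright", c("diagnosis", "nAED"), lty = 1,
                   col = c("red", "blue"), bty = "n")
  invisible(x)
}

#' Write a screening report as TSV
#'
#' @param x A `zc_screen`.
#' @param path Output path.
#' @export
write_screen_tsv <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
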