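# Zero-crossing detection, interval sequences, and pooled interval spectra.

#' Detect isoelectric-line crossings by linear interpolation
#'
#' Samples equal to zero are treated as positive; a run of consecutive
#' zeros yields at most one crossing. Under the default `"rising"`
#' convention a crossing is the sub-sample time where the signal passes
#' from negative to non-negative, placed by linear interpolation between
#' the bracketing samples, so a pure oscillation yields one crossing (and
#' hence one interval) per cycle. `"all"` additionally detects falling
#' crossings (two per cycle).
#'
#' @param x Zero-mean band-passed signal vector.
#' @param fs Sampling rate in Hz.
#' @param convention `"rising"` (default) or `"all"`.
#' @return Strictly increasing crossing times in milliseconds (sample 1 is
#'   time 0). A constant signal returns `numeric(0)`.
#' @export
detect_crossings <- function(x, fs, convention = c("rising", "all")) {
  convention <- match.arg(convention)
  n <- length(x)
  if (n < 2L) return(numeric(0))
  pos <- x >= 0
  interp <- function(i) {
    # crossing between samples i and i+1 (0-based times (i-1)/fs)
    frac <- x[i] / (x[i] - x[i + 1L])
    ((i - 1L) + frac) / fs * 1000
  }
  ri <- which(!pos[-n] & pos[-1L])
  times <- interp(ri)
  if (convention == "all") {
    fi <- which(pos[-n] & !pos[-1L] & x[-n] > 0)
    # zero-run exits (x[i] == 0, x[i+1] < 0) cross at the zero sample itself
    zi <- which(pos[-n] & !pos[-1L] & x[-n] == 0)
    times <- sort(c(times, interp(fi), (zi - 1L) / fs * 1000))
  }
  times
}

#' Intervals between subsequent crossings
#'
#' @param times Sorted crossing times in milliseconds.
#' @return First differences in milliseconds (empty if fewer than two
#'   crossings).
#' @export
crossings_to_intervals <- function(times) {
  if (length(times) < 2L) return(numeric(0))
  diff(times)
}

#' Histogram interval lengths
#'
#' Counts per half-open bin `[k*w, (k+1)*w)` milliseconds. Intervals at or
#' beyond `range_ms` are discarded and tallied in the `overflow` attribute.
#'
#' @param intervals Interval lengths in milliseconds.
#' @param bin_ms Bin width in milliseconds (default 4).
#' @param range_ms Histogram range (default 4000, i.e. 1000 bins).
#' @return Integer vector of counts with attributes `bin_ms` and `overflow`.
#' @export
build_histogram <- function(intervals, bin_ms = 4, range_ms = 4000) {
  n_bins <- as.integer(round(range_ms / bin_ms))
  keep <- intervals >= 0 & intervals < range_ms
  counts <- tabulate(floor(intervals[keep] / bin_ms) + 1L, nbins = n_bins)
  structure(counts, bin_ms = bin_ms, overflow = sum(!keep))
}

#' Pool raw histograms and normalize into an interval spectrum
#'
#' Element-wise sum of the raw counts, then division by the grand total.
#' Pooling all channels and segments of a recording is "whole recording"
#' analysis.
#'
#' @param parts List of raw count vectors from [build_histogram()]
#'   (identical binning required).
#' @param provenance Named list recording the passband, channel groups and
#'   segments pooled (free-form).
#' @param bin_ms Bin width; defaults to the parts' `bin_ms` attribute.
#' @return Object of class `interval_spectrum`: `raw` counts, normalized
#'   probabilities `p`, `bin_left` (ms), `bin_ms`, `overflow`, `provenance`.
#' @export
pool_and_normalize <- function(parts, provenance = list(), bin_ms = NULL) {
  if (!is.list(parts)) parts <- list(parts)
  lens <- unique(lengths(parts))
  if (length(lens) != 1L) stop("parts do not share binning")
  if (is.null(bin_ms)) {
    bin_ms <- attr(parts[[1]], "bin_ms")
    if (is.null(bin_ms)) bin_ms <- 4
  }
  raw <- Reduce(`+`, lapply(parts, as.numeric))
  total <- sum(raw)
  if (total == 0) stop("no intervals detected (grand total is zero)")
  overflow <- sum(vapply(parts, function(p) {
    o <- attr(p, "overflow"); if (is.null(o)) 0L else o
  }, 0L))
  structure(list(raw = raw, p = raw / total,
                 bin_left = (seq_along(raw) - 1) * bin_ms,
                 bin_ms = bin_ms, overflow = overflow,
                 provenance = provenance),
            class = "interval_spectrum")
}

#' @export
print.interval_spectrum <- function(x, ...) {
  occ <- which(x$raw > 0)
  cat(sprintf("<interval_spectrum> %d intervals in %d/%d occupied bins (%g ms)\n",
              sum(x$raw), length(occ), length(x$raw), x$bin_ms))
  if (length(occ)) {
    pk <- which.max(x$p)
    cat(sprintf("  peak p = %.4f at [%g, %g) ms; overflow %d\n",
                x$p[pk], x$bin_left[pk], x$bin_left[pk] + x$bin_ms, x$overflow))
  }
  if (length(x$provenance)) {
    cat("  provenance:", paste(names(x$provenance), unlist(lapply(
      x$provenance, function(v) paste(format(v), collapse = "/"))),
      sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.interval_spectrum <- function(x, xlim = c(0, 400), ...) {
  graphics::plot(x$bin_left + x$bin_ms / 2, x$p, type = "h", xlim = xlim,
                 xlab = "interval length [ms]", ylab = "relative count", ...)
  invisible(x)
}

#' Serialize / deserialize an interval spectrum as TSV
#'
#' Columns `bin_left_ms`, `raw_count`, `p`; provenance as JSON header
#' lines prefixed `#`.
#'
#' @param S An `interval_spectrum`.
#' @param path File path.
#' @export
write_spectrum_tsv <- function(S, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(c(S$provenance, list(bin_ms = S$bin_ms,
                                               overflow = S$overflow)),
                          auto_unbox = TRUE, digits = NA)
  writeLines(paste0("# ", hdr), con)
  writeLines("bin_left_ms\traw_count\tp", con)
  writeLines(sprintf("%g\t%g\t%.10g", S$bin_left, S$raw, S$p), con)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  d <- utils::read.csv(text = lines[-1], sep = "\t")
  bin_ms <- hdr$bin_ms
  raw <- d$raw_count
  structure(list(raw = raw, p = d$p, bin_left = d$bin_left_ms,
                 bin_ms = bin_ms, overflow = hdr$overflow,
                 provenance = hdr[setdiff(names(hdr), c("bin_ms", "overflow"))]),
            class = "interval_spectrum")
}

# ---- recording- and cohort-level spectra ------------------------------------

# Filter one pooled stream (sum of a symmetric channel group over one
# segment) against a filter bank and histogram its crossing intervals.
# Returns a bins x n_bands count matrix.
stream_histograms <- function(x, fs, firs, convention = "rising",
                              bin_ms = 4, range_ms = 4000,
                              h2_cache = NULL) {
  filtered <- zp_filter_bank(x, firs, h2_cache)
  n_bins <- as.integer(round(range_ms / bin_ms))
  out <- matrix(0L, n_bins, length(firs))
  overflow <- integer(length(firs))
  for (b in seq_along(firs)) {
    iv <- crossings_to_intervals(detect_crossings(filtered[[b]], fs,
                                                  convention))
    h <- build_histogram(iv, bin_ms, range_ms)
    out[, b] <- h
    overflow[b] <- attr(h, "overflow")
  }
  attr(out, "overflow") <- overflow
  out
}

#' Per-recording interval histograms by channel group and segment
#'
#' Each (channel group, segment) stream is the sum of the group's channels
#' over the segment; filtering is applied per segment after extraction so
#' that segment boundaries never mix, and intervals are never computed
#' across a boundary.
#'
#' @param rec A `zc_recording`.
#' @param bands List of [bandpass()] objects (or a single one).
#' @param groups Channel groups as from [symmetric_channel_pairs()].
#' @param segments Segment labels (default: all in the recording).
#' @param convention Crossing convention, see [detect_crossings()].
#' @param bin_ms,range_ms Histogram binning.
#' @param order FIR order for [design_bandpass()].
#' @return 4-d integer array `bins x band x group x segment` of raw counts,
#'   with dimnames; attribute `overflow` holds the per-cell overflow tally.
#' @export
recording_histograms <- function(rec, bands, groups = NULL, segments = NULL,
                                 convention = "rising", bin_ms = 4,
                                 range_ms = 4000, order = 500,
                                 h2_cache = NULL) {
  if (inherits(bands, "zc_band")) bands <- list(bands)
  if (is.null(groups)) {
    groups <- symmetric_channel_pairs(rec$channels)
  }
  if (is.null(segments)) segments <- names(rec$segments)
  firs <- lapply(bands, design_bandpass, fs = rec$fs, order = order)
  n_bins <- as.integer(round(range_ms / bin_ms))
  out <- array(0L, dim = c(n_bins, length(bands), length(groups),
                           length(segments)),
               dimnames = list(NULL, vapply(bands, format, ""),
                               names(groups), segments))
  ovf <- array(0L, dim = dim(out)[-1], dimnames = dimnames(out)[-1])
  for (s in seq_along(segments)) {
    seg <- extract_segment(rec, segments[s])
    for (g in seq_along(groups)) {
      x <- colSums(seg[groups[[g]], , drop = FALSE])
      h <- stream_histograms(x, rec$fs, firs, convention, bin_ms, range_ms,
                             h2_cache = h2_cache)
      out[, , g, s] <- h
      ovf[, g, s] <- attr(h, "overflow")
    }
  }
  attr(out, "overflow") <- ovf
  out
}

#' Whole-recording interval spectrum
#'
#' Pools the raw histograms of all channel groups and all protocol
#' segments for one passband.
#'
#' @inheritParams recording_histograms
#' @param band A single [bandpass()].
#' @return An `interval_spectrum`.
#' @export
whole_recording_spectrum <- function(rec, band, convention = "rising",
                                     bin_ms = 4, range_ms = 4000,
                                     order = 500) {
  h <- recording_histograms(rec, list(band), convention = convention,
                            bin_ms = bin_ms, range_ms = range_ms,
                            order = order)
  raw <- apply(h[, 1, , , drop = FALSE], 1, sum)
  raw <- structure(as.integer(raw), bin_ms = bin_ms,
                   overflow = sum(attr(h, "overflow")))
  pool_and_normalize(list(raw),
                     provenance = list(band = format(band),
                                       channel_groups = "all",
                                       segments = "all",
                                       subject_id = rec$subject_id,
                                       convention = convention))
}

#' Cohort interval data over a band grid
#'
#' Computes, for every subject and every candidate passband, the
#' whole-recording raw counts and normalized spectrum, optionally keeping
#' the per-(channel group x segment) resolution needed for two-step
#' classifier fitting.
#'
#' @param recordings List of `zc_recording`.
#' @param bands List of [bandpass()] candidates (e.g. [band_grid()]).
#' @param keep_by Keep the `bins x band x group x segment` array per
#'   subject (memory-heavy; needed for `two_step` fitting and ratio maps).
#' @param groups,segments,convention,bin_ms,range_ms,order Passed through.
#' @return Object of class `zc_cohort_spectra`: `raw` and `p` arrays of
#'   dimension `subject x bin x band`, `bands`, `bin_left`, `meta`
#'   (data frame of subject metadata), and optionally `by` (list per
#'   subject of 4-d count arrays) plus `groups`, `segment_labels`.
#' @export
cohort_spectra <- function(recordings, bands, keep_by = FALSE, groups = NULL,
                           segments = NULL, convention = "rising", bin_ms = 4,
                           range_ms = 4000, order = 500) {
  if (inherits(bands, "zc_band")) bands <- list(bands)
  n <- length(recordings)
  n_bins <- as.integer(round(range_ms / bin_ms))
  raw <- array(0, dim = c(n, n_bins, length(bands)))
  h2_cache <- new.env(parent = emptyenv())
  by <- if (keep_by) vector("list", n) else NULL
  grp_names <- seg_names <- NULL
  for (i in seq_len(n)) {
    h <- recording_histograms(recordings[[i]], bands, groups = groups,
                              segments = segments, convention = convention,
                              bin_ms = bin_ms, range_ms = range_ms,
                              order = order, h2_cache = h2_cache)
    raw[i, , ] <- rowSums(h, dims = 2)
    if (keep_by) by[[i]] <- h
    if (is.null(grp_names)) {
      grp_names <- dimnames(h)[[3]]; seg_names <- dimnames(h)[[4]]
    }
  }
  totals <- apply(raw, c(1, 3), sum)
  if (any(totals == 0)) stop("subject(s) with no detected intervals")
  p <- raw
  for (b in seq_along(bands)) p[, , b] <- raw[, , b] / totals[, b]
  meta <- do.call(rbind, lapply(recordings, function(r) {
    m <- r$meta
    data.frame(subject_id = r$subject_id,
               diagnosis = if (is.null(m)) NA_character_ else m$diagnosis,
               nAED = if (is.null(m)) NA_integer_ else m$nAED,
               eeg_score = if (is.null(m)) NA_integer_ else m$eeg_score,
               stringsAsFactors = FALSE)
  }))
  structure(list(raw = raw, p = p, bands = bands,
                 bin_left = (seq_len(n_bins) - 1) * bin_ms, bin_ms = bin_ms,
                 meta = meta, by = by, groups = grp_names,
                 segment_labels = seg_names, convention = convention),
            class = "zc_cohort_spectra")
}

#' @export
print.zc_cohort_spectra <- function(x, ...) {
  cat(sprintf("<zc_cohort_spectra> %d subjects x %d bins x %d bands%s\n",
              dim(x$raw)[1], dim(x$raw)[2], dim(x$raw)[3],
              if (!is.null(x$by)) " (+ per group/segment counts)" else ""))
  invisible(x)
}
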