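# Recording container, 10-20 montage helpers, protocol segment maps.

#' The standard 19-channel 10-20 scalp montage
#'
#' @return Character vector of the 19 canonical channel labels, in the
#'   conventional anterior-to-posterior order.
#' @export
ten_twenty_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Protocol segment vocabulary
#'
#' Segment labels of the standard 20-minute clinical EEG protocol:
#' baseline before photic stimulation, photic stimulation (Fs),
#' the interval between Fs and hyperventilation (Hv), Hv itself, and the
#' post-hyperventilation rest. Sub-segments of post-Hv are labelled
#' `post-Hv/1`, `post-Hv/2`, ...
#'
#' @return Character vector of the five protocol labels.
#' @export
protocol_segments <- function() {
  c("pre-Fs", "Fs", "post-Fs", "Hv", "post-Hv")
}

# Normalize channel labels: strip periods/spaces, case-insensitive match
# against the 10-20 vocabulary ("FP1", "fp1." -> "Fp1").
normalize_channel <- function(labels) {
  canon <- ten_twenty_channels()
  key <- toupper(gsub("[. ]", "", labels))
  out <- canon[match(key, toupper(canon))]
  ifelse(is.na(out), labels, out)
}

valid_segment_label <- function(label) {
  label %in% protocol_segments() | grepl("^post-Hv/[0-9]+$", label)
}

#' Create a protocol segment map
#'
#' @param ... Named arguments, each a numeric `c(start, end)` in seconds.
#'   Intervals are half-open `[start, end)`. Names must come from
#'   [protocol_segments()] (plus optional `post-Hv/k` sub-segments).
#' @return An object of class `zc_segment_map` (a named list of
#'   `c(start, end)` pairs, ordered by start time).
#' @examples
#' segment_map(`pre-Fs` = c(0, 300), Fs = c(300, 420))
#' @export
segment_map <- function(...) {
  segs <- list(...)
  if (length(segs) == 1L && is.list(segs[[1]]) && is.null(names(segs))) {
    segs <- segs[[1]]
  }
  if (length(segs) == 0L) stop("segment map needs at least one segment")
  labs <- names(segs)
  if (is.null(labs) || any(!nzchar(labs))) stop("all segments must be named")
  bad <- labs[!valid_segment_label(labs)]
  if (length(bad)) {
    stop("unknown segment label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(protocol_segments(), collapse = ", "),
         " and post-Hv/k sub-segments")
  }
  segs <- lapply(segs, function(s) {
    s <- as.numeric(s)
    if (length(s) != 2L || anyNA(s) || s[1] < 0 || s[2] <= s[1]) {
      stop("each segment must be c(start, end) with 0 <= start < end")
    }
    s
  })
  segs <- segs[order(vapply(segs, `[`, 0, 1))]
  starts <- vapply(segs, `[`, 0, 1)
  ends <- vapply(segs, `[`, 0, 2)
  if (length(segs) > 1L && any(starts[-1] < ends[-length(ends)] - 1e-9)) {
    stop("segments overlap")
  }
  structure(segs, class = "zc_segment_map")
}

#' Subject metadata
#'
#' @param diagnosis One of `"TLE"`, `"FLE"`, `"PNES"`, `"headache"`.
#' @param nAED Number of distinct antiepileptic drugs taken (0-3).
#' @param eeg_score 4-level ordinal visual-report score (0-3), optional.
#' @param duration_years Epilepsy duration in years, optional.
#' @return An object of class `zc_subject_meta`.
#' @export
subject_meta <- function(diagnosis, nAED = 0L, eeg_score = NA_integer_,
                         duration_years = NA_real_) {
  diagnosis <- match.arg(diagnosis, c("TLE", "FLE", "PNES", "headache"))
  nAED <- as.integer(nAED)
  if (is.na(nAED) || nAED < 0L || nAED > 3L) stop("nAED must be 0..3")
  if (!is.na(eeg_score) && !(eeg_score %in% 0:3)) {
    stop("eeg_score must be 0..3 or NA")
  }
  if (!is.na(duration_years) && duration_years < 0) {
    stop("duration_years must be non-negative")
  }
  structure(list(diagnosis = diagnosis, nAED = nAED,
                 eeg_score = as.integer(eeg_score),
                 duration_years = as.numeric(duration_years)),
            class = "zc_subject_meta")
}

#' Epilepsy case / control dichotomy
#'
#' TLE and FLE subjects form the epilepsy (case) group; PNES and headache
#' subjects form the control group.
#'
#' @param diagnosis Character vector of diagnoses.
#' @return Logical vector, `TRUE` for epilepsy.
#' @export
is_epilepsy <- function(diagnosis) diagnosis %in% c("TLE", "FLE")

#' Construct a Recording
#'
#' @param subject_id Opaque subject identifier.
#' @param fs Sampling rate in Hz.
#' @param channels Channel labels (10-20 names where applicable).
#' @param signal `channels x samples` matrix in microvolts.
#' @param segments A [segment_map()].
#' @param meta A [subject_meta()], optional.
#' @return An object of class `zc_recording`.
#' @export
new_recording <- function(subject_id, fs, channels, signal, segments,
                          meta = NULL) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = length(channels))
  if (nrow(signal) != length(channels)) {
    stop("signal must have one row per channel")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  dur <- ncol(signal) / fs
  ends <- vapply(unclass(segments), `[`, 0, 2)
  if (any(ends > dur + 1e-9)) {
    stop("segment(s) ", paste(names(segments)[ends > dur + 1e-9], collapse = ", "),
         " extend beyond the recording (duration ", signif(dur, 6), " s)")
  }
  rownames(signal) <- channels
  structure(list(subject_id = subject_id, fs = fs, channels = channels,
                 signal = signal, segments = segments, meta = meta),
            class = "zc_recording")
}

#' @export
print.zc_recording <- function(x, ...) {
  cat(sprintf("<zc_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs))
  cat("  segments:",
      paste(sprintf("%s [%g, %g)", names(x$segments),
                    vapply(unclass(x$segments), `[`, 0, 1),
                    vapply(unclass(x$segments), `[`, 0, 2)),
            collapse = ", "), "\n")
  if (!is.null(x$meta)) {
    cat(sprintf("  meta: %s, nAED=%d\n", x$meta$diagnosis, x$meta$nAED))
  }
  invisible(x)
}

#' Extract a named protocol segment
#'
#' Returns the half-open sample range `[floor(start*fs), floor(end*fs))`
#' of the requested segment. The pseudo-label `"whole"` concatenates all
#' segments of the map in temporal order.
#'
#' @param rec A `zc_recording`.
#' @param label Segment label present in `rec$segments`, or `"whole"`.
#' @param channels Optional subset of channel labels (default: all).
#' @return `channels x samples` matrix.
#' @export
extract_segment <- function(rec, label, channels = NULL) {
  if (is.null(channels)) channels <- rec$channels
  miss <- setdiff(channels, rec$channels)
  if (length(miss)) stop("unknown channel(s): ", paste(miss, collapse = ", "))
  if (identical(label, "whole")) {
    parts <- lapply(names(rec$segments), extract_segment, rec = rec,
                    channels = channels)
    return(do.call(cbind, parts))
  }
  if (!label %in% names(rec$segments)) {
    stop("unknown segment label: ", label)
  }
  s <- rec$segments[[label]]
  i0 <- floor(s[1] * rec$fs)       # 0-based first sample
  i1 <- floor(s[2] * rec$fs)       # 0-based one-past-last
  rec$signal[channels, (i0 + 1L):i1, drop = FALSE]
}

#' Symmetric channel groups of the 10-20 montage
#'
#' Interval histograms from homologous channels are pooled as sums of
#' symmetric channels (Fp1+Fp2, T3+T4, ...), which reveals spatial effects
#' irrespective of lateralization. Midline channels (Fz, Cz, Pz) are kept
#' as singleton groups by default since a 19-channel montage carries them.
#'
#' @param channels Channel labels to group.
#' @param include_midline Keep midline singletons (default `TRUE`).
#' @return Named list of character vectors, in a fixed documented order:
#'   Fp1+Fp2, F7+F8, F3+F4, T3+T4, C3+C4, T5+T6, P3+P4, O1+O2, Fz, Cz, Pz.
#'   Groups with no member present are dropped; incomplete pairs yield a
#'   reduced group with a warning.
#' @export
symmetric_channel_pairs <- function(channels = ten_twenty_channels(),
                                    include_midline = TRUE) {
  channels <- normalize_channel(channels)
  pairs <- list(
    "Fp1+Fp2" = c("Fp1", "Fp2"), "F7+F8" = c("F7", "F8"),
    "F3+F4" = c("F3", "F4"), "T3+T4" = c("T3", "T4"),
    "C3+C4" = c("C3", "C4"), "T5+T6" = c("T5", "T6"),
    "P3+P4" = c("P3", "P4"), "O1+O2" = c("O1", "O2"))
  if (include_midline) {
    pairs <- c(pairs, list(Fz = "Fz", Cz = "Cz", Pz = "Pz"))
  }
  out <- lapply(pairs, intersect, x = channels)
  # intersect(channels, pair) keeps channel order; re-intersect to pair order
  out <- lapply(seq_along(pairs), function(i) pairs[[i]][pairs[[i]] %in% channels])
  names(out) <- names(pairs)
  keep <- lengths(out) > 0L
  partial <- names(pairs)[lengths(out) == 1L & lengths(pairs) == 2L & keep]
  if (length(partial)) {
    warning("incomplete symmetric pair(s): ", paste(partial, collapse = ", "))
  }
  out[keep]
}

# ---- sidecar I/O ------------------------------------------------------------

#' Write / read a subject metadata sidecar table
#'
#' CSV with columns subject_id, diagnosis, nAED, eeg_score, duration_years.
#'
#' @param meta Data frame with those columns.
#' @param path File path.
#' @return `read_meta_csv` returns the data frame.
#' @export
write_meta_csv <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meta_csv
#' @export
read_meta_csv <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "diagnosis", "nAED")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("metadata table lacks column(s): ",
                         paste(miss, collapse = ", "))
  m
}

#' Write / read a segment map as JSON
#'
#' Serialized as `{label: [start_s, end_s], ...}`.
#'
#' @param segments A [segment_map()].
#' @param path File path.
#' @export
write_segment_json <- function(segments, path) {
  jsonlite::write_json(lapply(unclass(segments), as.numeric), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_segment_json
#' @export
read_segment_json <- function(path) {
  segs <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(segment_map, lapply(segs, as.numeric))
}
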