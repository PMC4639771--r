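# Minimal European Data Format (EDF) reader/writer.
#
# Supports the subset this package needs: continuous recordings, identical
# sampling rate on all channels, one data record per second, 16-bit samples.
# The synthetic fixtures use a fixed physical range of +/-1000 uV mapped onto
# digital -32767..32767, giving a reproducible quantization step of
# 2000/65534 uV.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, digits = 7)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' @param rec A `zc_recording`. The number of samples must be a whole
#'   number of seconds (one EDF data record per second is written).
#' @param path Output file path.
#' @param phys_range Physical range in microvolts mapped onto the digital
#'   range -32767..32767 (default +/-1000).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_range = 1000) {
  sig <- rec$signal
  ns <- nrow(sig)
  fs <- rec$fs
  spr <- as.integer(round(fs))
  if (abs(fs - spr) > 1e-9) stop("write_edf requires an integer sampling rate")
  if (ncol(sig) %% spr != 0L) {
    stop("signal length must be a whole number of 1-s data records")
  }
  n_rec <- ncol(sig) %/% spr
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad("zcia synthetic EEG", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (1L + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_num(1, 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  fld(rec$channels, 16)
  fld(rep("AgAgCl electrode", ns), 80)
  fld(rep("uV", ns), 8)
  fld(rep(edf_num(-phys_range, 8), ns), 8)
  fld(rep(edf_num(phys_range, 8), ns), 8)
  fld(rep("-32767", ns), 8)
  fld(rep("32767", ns), 8)
  fld(rep("HP:0.5Hz", ns), 80)
  fld(rep(as.character(spr), ns), 8)
  fld(rep("", ns), 32)
  scale <- 32767 / phys_range
  dig <- round(sig * scale)
  dig[dig > 32767] <- 32767
  dig[dig < -32767] <- -32767
  storage.mode(dig) <- "integer"
  # record-interleaved: per record, all samples of channel 1, then channel 2...
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return A list with elements `labels`, `fs`, `signal`
#'   (`channels x samples` matrix in physical units), `n_records`,
#'   `record_duration`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  patient <- rd(80); recording <- rd(80)
  rd(8); rd(8)                      # start date/time
  rd(8)                             # header bytes
  rd(44)                            # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fld(16)
  fld(80)                           # transducer
  fld(8)                            # dimension
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)                           # prefilter
  spr <- as.integer(fld(8))
  fld(32)                           # reserved
  if (length(unique(spr)) != 1L) {
    stop("per-channel sampling rates differ; refusing to resample")
  }
  spr1 <- spr[1]
  fs <- spr1 / rec_dur
  total <- n_rec * spr1
  sig <- matrix(0, nrow = ns, ncol = total)
  for (r in seq_len(n_rec)) {
    blk <- readBin(con, "integer", n = ns * spr1, size = 2, endian = "little")
    sig[, ((r - 1L) * spr1 + 1L):(r * spr1)] <-
      matrix(blk, nrow = ns, byrow = TRUE)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- sig * gain + (phys_min - dig_min * gain)
  rownames(sig) <- labels
  list(labels = labels, fs = fs, signal = sig, n_records = n_rec,
       record_duration = rec_dur, patient = patient, recording = recording)
}

#' Read an EDF file into a Recording
#'
#' Channel labels are normalized onto the 10-20 vocabulary; the sampling
#' rate is taken from the EDF header. A per-channel rate mismatch raises
#' an error rather than resampling.
#'
#' @param path EDF file path.
#' @param meta A [subject_meta()] (or `NULL`).
#' @param segments A [segment_map()]; must lie within the file duration.
#' @param require_channels Channels that must be present (default: the full
#'   19-channel montage). Set to `NULL` to accept any montage subset.
#' @param subject_id Identifier; defaults to the EDF patient field.
#' @return A `zc_recording`.
#' @export
read_recording <- function(path, meta = NULL, segments,
                           require_channels = ten_twenty_channels(),
                           subject_id = NULL) {
  edf <- read_edf(path)
  labels <- normalize_channel(edf$labels)
  if (!is.null(require_channels)) {
    miss <- setdiff(require_channels, labels)
    if (length(miss)) {
      stop("missing required channel(s): ", paste(miss, collapse = ", "))
    }
  }
  if (is.null(subject_id)) {
    subject_id <- if (nzchar(edf$patient)) edf$patient else basename(path)
  }
  new_recording(subject_id = subject_id, fs = edf$fs, channels = labels,
                signal = edf$signal, segments = segments, meta = meta)
}
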