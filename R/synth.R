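# Synthetic interictal EEG cohorts: posterior-dominant alpha oscillator
# with smooth frequency jitter, drug-load-scaled theta, 1/f background,
# episodic low-frequency artifacts, and the clinical segment protocol.

default_alpha_gradient <- function() {
  c(Fp1 = 0.25, Fp2 = 0.25, F7 = 0.3, F3 = 0.3, Fz = 0.3, F4 = 0.3,
    F8 = 0.3, T3 = 0.45, C3 = 0.45, Cz = 0.45, C4 = 0.45, T4 = 0.45,
    T5 = 0.85, P3 = 0.8, Pz = 0.8, P4 = 0.8, T6 = 0.85, O1 = 1, O2 = 1)
}

default_artifact_gradient <- function() {
  c(Fp1 = 1, Fp2 = 1, F7 = 0.7, F3 = 0.7, Fz = 0.7, F4 = 0.7, F8 = 0.7,
    T3 = 0.3, C3 = 0.3, Cz = 0.3, C4 = 0.3, T4 = 0.3,
    T5 = 0.15, P3 = 0.15, Pz = 0.15, P4 = 0.15, T6 = 0.15,
    O1 = 0.1, O2 = 0.1)
}

#' Synthetic cohort design
#'
#' Encodes the statistical structure the interval-spectrum markers respond
#' to: an epilepsy analogue (multiplicative alpha-amplitude deficit plus
#' increased cycle-length jitter, which raises interval-spectrum entropy)
#' and a drug-load analogue (theta amplitude growing with nAED). Channel
#' amplitudes follow a posterior gradient with the alpha maximum over
#' occipital/posterior-temporal leads.
#'
#' Defaults emulate the study conditions: 19 channels at 250 Hz, the
#' 20-minute five-segment protocol, an analogue-like causal 0.5 Hz
#' high-pass, and group sizes 19/32/13/14 (TLE/FLE/PNES/headache). Effect
#' sizes are calibrated so that epilepsy-vs-control separation by the
#' alpha score lands near AUC 0.8.
#'
#' @param n_per_group Named vector of subgroup sizes.
#' @param naed_probs 4 x 4 matrix (rows TLE, FLE, PNES, headache) of
#'   nAED = 0..3 probabilities per subgroup.
#' @param fs Sampling rate in Hz.
#' @param channels Channel subset to simulate (default: full montage).
#' @param segment_durations Named vector of protocol segment durations (s).
#' @param alpha_freq_mean,alpha_freq_sd Subject alpha frequency (Hz).
#' @param alpha_amp Occipital alpha amplitude in microvolts.
#' @param alpha_jitter_sd Stationary SD (Hz) of the smooth
#'   (Ornstein-Uhlenbeck) instantaneous-frequency jitter; controls
#'   interval-spectrum entropy.
#' @param alpha_amp_cv,alpha_jitter_cv,theta_amp_cv Between-subject
#'   lognormal coefficients of variation of alpha amplitude, alpha jitter
#'   and theta amplitude; these individual differences, not estimator
#'   noise, set the group overlap the classifiers face.
#' @param alpha_mod_depth Depth of the slow waxing-waning amplitude
#'   envelope.
#' @param epilepsy_alpha_deficit Fractional alpha-amplitude reduction in
#'   the epilepsy analogue.
#' @param epilepsy_jitter_factor Multiplicative jitter increase in the
#'   epilepsy analogue.
#' @param theta_freq_mean,theta_freq_sd Subject theta frequency (Hz).
#' @param theta_amp_base Theta amplitude at nAED = 0 (uV).
#' @param theta_amp_per_aed Additional theta amplitude per drug (uV).
#' @param theta_jitter_sd Theta frequency jitter SD (Hz).
#' @param noise_amp RMS amplitude of the 1/f background (uV).
#' @param noise_exponent Spectral exponent of the background.
#' @param artifact_rate_per_min Episodic low-frequency artifact rate.
#' @param artifact_amp_range,artifact_dur_range Artifact amplitude (uV)
#'   and duration (s) ranges; artifacts are half-sine deflections with
#'   ocular/movement morphology, frontally dominant.
#' @param alpha_gradient,artifact_gradient Named per-channel weights.
#' @param effect_channels,effect_segments Restrict the epilepsy
#'   alpha-deficit to these channels/segments (`NULL` = everywhere);
#'   used to plant spatially localized effects.
#' @param hp_hz Causal first-order high-pass cutoff (Hz).
#' @param seed Base RNG seed for the cohort.
#' @return Object of class `zc_cohort_design` (a validated list).
#' @export
cohort_design <- function(n_per_group = c(TLE = 19, FLE = 32, PNES = 13,
                                          headache = 14),
                          naed_probs = rbind(
                            TLE = c(0.10, 0.35, 0.30, 0.25),
                            FLE = c(0.10, 0.35, 0.30, 0.25),
                            PNES = c(0.15, 0.45, 0.30, 0.10),
                            headache = c(0.90, 0.10, 0.00, 0.00)),
                          fs = 250,
                          channels = ten_twenty_channels(),
                          segment_durations = c("pre-Fs" = 300, "Fs" = 120,
                                                "post-Fs" = 180, "Hv" = 180,
                                                "post-Hv" = 420),
                          alpha_freq_mean = 10, alpha_freq_sd = 0.5,
                          alpha_amp = 30, alpha_jitter_sd = 0.6,
                          alpha_amp_cv = 0.30, alpha_jitter_cv = 0.25,
                          theta_amp_cv = 0.20,
                          alpha_mod_depth = 0.4,
                          epilepsy_alpha_deficit = 0.08,
                          epilepsy_jitter_factor = 1.18,
                          theta_freq_mean = 6, theta_freq_sd = 0.5,
                          theta_amp_base = 2, theta_amp_per_aed = 18,
                          theta_jitter_sd = 0.5,
                          noise_amp = 9, noise_exponent = 1,
                          artifact_rate_per_min = 2,
                          artifact_amp_range = c(100, 300),
                          artifact_dur_range = c(0.3, 2),
                          alpha_gradient = default_alpha_gradient(),
                          artifact_gradient = default_artifact_gradient(),
                          effect_channels = NULL, effect_segments = NULL,
                          hp_hz = 0.5, seed = 1) {
  stopifnot(all(n_per_group >= 0), fs > 0,
            all(abs(rowSums(naed_probs) - 1) < 1e-9),
            all(naed_probs >= 0), alpha_amp >= 0, theta_amp_base >= 0,
            theta_amp_per_aed >= 0, noise_amp >= 0,
            epilepsy_alpha_deficit >= 0, epilepsy_alpha_deficit <= 1,
            all(segment_durations > 0))
  structure(as.list(environment()), class = "zc_cohort_design")
}

# Smooth (OU) jitter around zero with stationary SD `sd` and correlation
# time `tau` seconds, sampled at fs.
ou_process <- function(n, fs, sd, tau = 0.5) {
  if (sd <= 0) return(numeric(n))
  a <- exp(-1 / (fs * tau))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - a^2))
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

# 1/f^exponent Gaussian background, normalized to RMS `amp`.
pink_noise <- function(n, fs, amp, exponent = 1) {
  if (amp <= 0) return(numeric(n))
  nfft <- stats::nextn(n)
  f <- c(1e-3, seq_len(nfft / 2) * fs / nfft)
  shape <- c(0, 1 / f[-1][seq_len(nfft / 2)]^(exponent / 2))
  spec <- complex(real = stats::rnorm(nfft / 2 + 1),
                  imaginary = stats::rnorm(nfft / 2 + 1)) * shape
  spec[1] <- 0
  full <- c(spec, Conj(rev(spec[2:(nfft / 2)])))
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  x * amp / stats::sd(x)
}

# Jittered oscillator: sin of integrated instantaneous frequency.
jitter_oscillator <- function(n, fs, f0, jitter_sd, phase0 = NULL) {
  finst <- pmax(f0 + ou_process(n, fs, jitter_sd), 0.1)
  if (is.null(phase0)) phase0 <- stats::runif(1, 0, 2 * pi)
  sin(phase0 + 2 * pi * cumsum(finst) / fs)
}

# Slow waxing-waning envelope, mean 1, bounded below at 0.
mod_envelope <- function(n, fs, depth, tau = 2) {
  if (depth <= 0) return(rep(1, n))
  pmax(1 + ou_process(n, fs, depth, tau), 0)
}

causal_highpass <- function(x, fs, hp_hz) {
  if (hp_hz <= 0) return(x)
  bt <- signal::butter(1, hp_hz / (fs / 2), type = "high")
  as.numeric(signal::filter(bt, x))
}

#' Simulate one subject's recording
#'
#' Per channel: a posterior-weighted, amplitude-modulated alpha
#' oscillator with smooth frequency jitter, plus an nAED-scaled theta
#' oscillator, 1/f background noise, and Poisson-placed low-frequency
#' half-sine artifact transients; a causal 0.5 Hz high-pass emulates the
#' analogue acquisition chain. Fully reproducible from `seed`.
#'
#' @param design A [cohort_design()].
#' @param meta A [subject_meta()].
#' @param seed Integer seed for this subject.
#' @param subject_id Identifier.
#' @return A `zc_recording` with the design's segment map.
#' @export
simulate_subject <- function(design, meta, seed, subject_id = "synthetic") {
  d <- design
  set.seed(seed)
  durs <- d$segment_durations
  total_s <- sum(durs)
  n <- as.integer(round(total_s * d$fs))
  chans <- d$channels
  epil <- is_epilepsy(meta$diagnosis)
  f_alpha <- stats::rnorm(1, d$alpha_freq_mean, d$alpha_freq_sd)
  f_theta <- stats::rnorm(1, d$theta_freq_mean, d$theta_freq_sd)
  # between-subject lognormal heterogeneity (multipliers with mean 1)
  lnmult <- function(cv) stats::rlnorm(1, -cv^2 / 2, cv)
  amp_mult <- lnmult(d$alpha_amp_cv)
  jit <- d$alpha_jitter_sd * lnmult(d$alpha_jitter_cv) *
    if (epil) d$epilepsy_jitter_factor else 1
  alpha_osc <- jitter_oscillator(n, d$fs, f_alpha, jit)
  alpha_env <- mod_envelope(n, d$fs, d$alpha_mod_depth)
  theta_amp <- (d$theta_amp_base + d$theta_amp_per_aed * meta$nAED) *
    lnmult(d$theta_amp_cv)
  theta_osc <- if (theta_amp > 0) {
    jitter_oscillator(n, d$fs, f_theta, d$theta_jitter_sd)
  } else numeric(n)
  # epilepsy alpha deficit, optionally restricted to channels/segments
  deficit_gain <- rep(1, n)
  if (epil && d$epilepsy_alpha_deficit > 0) {
    if (is.null(d$effect_segments)) {
      deficit_gain <- rep(1 - d$epilepsy_alpha_deficit, n)
    } else {
      ends <- cumsum(durs)
      starts <- c(0, ends[-length(ends)])
      for (sl in d$effect_segments) {
        k <- match(sl, names(durs))
        idx <- (floor(starts[k] * d$fs) + 1L):floor(ends[k] * d$fs)
        deficit_gain[idx] <- 1 - d$epilepsy_alpha_deficit
      }
    }
  }
  # artifact events shared across channels
  n_art <- stats::rpois(1, d$artifact_rate_per_min * total_s / 60)
  art_sig <- numeric(n)
  if (n_art > 0) {
    for (k in seq_len(n_art)) {
      dur <- stats::runif(1, d$artifact_dur_range[1], d$artifact_dur_range[2])
      amp <- stats::runif(1, d$artifact_amp_range[1], d$artifact_amp_range[2])
      sgn <- sample(c(-1, 1), 1)
      t0 <- stats::runif(1, 0, max(total_s - dur, 0))
      i0 <- floor(t0 * d$fs) + 1L
      len <- max(2L, as.integer(round(dur * d$fs)))
      i1 <- min(n, i0 + len - 1L)
      art_sig[i0:i1] <- art_sig[i0:i1] +
        sgn * amp * sin(pi * seq(0, 1, length.out = i1 - i0 + 1L))
    }
  }
  ag <- d$alpha_gradient
  artg <- d$artifact_gradient
  sig <- matrix(0, length(chans), n)
  for (c_i in seq_along(chans)) {
    ch <- chans[c_i]
    w_alpha <- (if (ch %in% names(ag)) ag[[ch]] else 0.5) * amp_mult
    local_deficit <- if (is.null(d$effect_channels) ||
                         ch %in% d$effect_channels) deficit_gain else 1
    x <- d$alpha_amp * w_alpha * local_deficit * alpha_env * alpha_osc +
      theta_amp * theta_osc +
      pink_noise(n, d$fs, d$noise_amp, d$noise_exponent) +
      (if (ch %in% names(artg)) artg[[ch]] else 0.3) * art_sig
    sig[c_i, ] <- causal_highpass(x, d$fs, d$hp_hz)
  }
  ends <- cumsum(durs)
  starts <- c(0, ends[-length(ends)])
  segs <- do.call(segment_map, stats::setNames(
    lapply(seq_along(durs), function(k) c(starts[k], ends[k])), names(durs)))
  new_recording(subject_id, d$fs, chans, sig, segs, meta)
}

#' Simulate a full cohort
#'
#' Draws subject metadata (diagnosis per the design's subgroup sizes,
#' nAED from the subgroup-specific distributions, a 4-level visual-report
#' score correlated with diagnosis, epilepsy durations) and simulates one
#' recording per subject. Deterministic given `design$seed`; per-subject
#' seeds are derived from it. Optionally writes EDF files with CSV
#' metadata and JSON segment-map sidecars consumable by
#' [read_recording()].
#'
#' @param design A [cohort_design()].
#' @param out_dir If non-`NULL`, write `S###.edf`, `S###.segments.json`
#'   and `meta.csv` there.
#' @return List with `recordings` (list of `zc_recording`), `meta`
#'   (data frame) and `design`.
#' @export
simulate_cohort <- function(design, out_dir = NULL) {
  d <- design
  set.seed(d$seed)
  groups <- rep(names(d$n_per_group), d$n_per_group)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  naed <- vapply(groups, function(g) {
    sample(0:3, 1, prob = d$naed_probs[g, ])
  }, 0L)
  eeg_probs <- list(TLE = c(0.25, 0.15, 0.25, 0.35),
                    FLE = c(0.25, 0.15, 0.25, 0.35),
                    PNES = c(0.5, 0.25, 0.2, 0.05),
                    headache = c(0.65, 0.2, 0.15, 0))
  eegsc <- vapply(groups, function(g) {
    sample(0:3, 1, prob = eeg_probs[[g]])
  }, 0L)
  duryr <- ifelse(is_epilepsy(groups),
                  round(stats::rlnorm(n, log(17), 0.7), 1), NA_real_)
  meta <- data.frame(subject_id = ids, diagnosis = groups, nAED = naed,
                     eeg_score = eegsc, duration_years = duryr,
                     stringsAsFactors = FALSE, row.names = NULL)
  # per-subject seeds drawn from the cohort stream: arithmetic seed
  # spacing leaves index-correlated first draws in the generator, which
  # would masquerade as group effects in index-blocked cohorts
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  recordings <- vector("list", n)
  for (i in seq_len(n)) {
    sm <- subject_meta(meta$diagnosis[i], meta$nAED[i], meta$eeg_score[i],
                       meta$duration_years[i])
    recordings[[i]] <- simulate_subject(d, sm, seeds[i], subject_id = ids[i])
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_edf(recordings[[i]], file.path(out_dir, paste0(ids[i], ".edf")))
      write_segment_json(recordings[[i]]$segments,
                         file.path(out_dir, paste0(ids[i], ".segments.json")))
    }
    write_meta_csv(meta, file.path(out_dir, "meta.csv"))
  }
  list(recordings = recordings, meta = meta, design = d)
}

#' Read a simulated cohort back from disk
#'
#' @param dir Directory produced by [simulate_cohort()].
#' @return List with `recordings` and `meta`.
#' @export
read_cohort <- function(dir) {
  meta <- read_meta_csv(file.path(dir, "meta.csv"))
  recordings <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$subject_id[i]
    segs <- read_segment_json(file.path(dir, paste0(id, ".segments.json")))
    sm <- subject_meta(meta$diagnosis[i], meta$nAED[i],
                       if ("eeg_score" %in% names(meta)) meta$eeg_score[i]
                       else NA,
                       if ("duration_years" %in% names(meta))
                         meta$duration_years[i] else NA)
    read_recording(file.path(dir, paste0(id, ".edf")), meta = sm,
                   segments = segs, require_channels = NULL,
                   subject_id = id)
  })
  list(recordings = recordings, meta = meta)
}
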