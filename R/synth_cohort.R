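# Synthetic 12-lead ECG cohort generator.
#
# Each beat is a sum of Gaussian kernels (one per wave component, per lead);
# parameters map one-to-one to the quantities the feature extractor measures
# (P duration, terminal force in V1, per-lead area/amplitude, PR interval).
# A wave's duration parameter is its support at the 5% relative-amplitude
# threshold, the same convention the delineator uses.

.QRST_WAVES <- c("Q", "R", "S", "T")

# Default QRST amplitudes (mV) per lead; centers/supports (ms) shared.
.default_qrst <- function() {
  leads <- ecg_leads()
  amp <- rbind(
    Q = c(-0.05, -0.08, -0.05, 0.05, -0.03, -0.06, -0.02, -0.03, -0.05, -0.07, -0.06, -0.05),
    R = c(0.70, 1.20, 0.60, -0.90, 0.30, 0.90, 0.30, 0.70, 1.10, 1.30, 1.20, 1.00),
    S = c(-0.15, -0.20, -0.15, 0.15, -0.10, -0.18, -0.50, -0.45, -0.30, -0.20, -0.15, -0.10),
    T = c(0.20, 0.30, 0.15, -0.25, 0.10, 0.25, 0.10, 0.35, 0.40, 0.35, 0.30, 0.25)
  )
  colnames(amp) <- leads
  list(
    amp = amp,
    center_ms = c(Q = -28, R = 0, S = 28, T = 230),
    support_ms = c(Q = 28, R = 45, S = 32, T = 160)
  )
}

#' Parametric beat morphology
#'
#' Describes a single sinus beat as Gaussian wave components per lead. The
#' P-wave is parameterized by its per-lead peak amplitude, total support
#' duration, PR interval (P onset to QRS onset), and - in V1 - a terminal
#' negative deflection of given depth and duration, so that the generated
#' terminal force in V1 (depth x duration) is known ground truth.
#'
#' @param p_amp_mv named numeric of length 12, P peak amplitude per lead (mV;
#'   aVR conventionally negative). Ignored when `p_axis_deg` is given for the
#'   limb leads.
#' @param p_duration_ms total P-wave support (ms), must lie in [60, 200].
#' @param pr_ms PR interval (ms), P onset to QRS onset.
#' @param v1_terminal_depth_mv depth of the terminal negative P deflection in
#'   V1 (mV, >= 0; 0 renders a monophasic P in V1).
#' @param v1_terminal_dur_ms duration of the terminal negative deflection (ms).
#' @param p_axis_deg optional frontal-plane P axis (degrees). When given, the
#'   six limb-lead P amplitudes are `p_mag_mv * cos(axis - lead angle)`.
#' @param p_mag_mv P magnitude used with `p_axis_deg` (mV).
#' @param qrst list with `amp` (4 x 12 matrix, mV), `center_ms`, `support_ms`
#'   for the Q/R/S/T components; defaults to a plausible adult sinus beat.
#' @return An object of class `beat_morphology`.
#' @export
beat_morphology <- function(p_amp_mv = NULL,
                            p_duration_ms = 120,
                            pr_ms = 170,
                            v1_terminal_depth_mv = 0.05,
                            v1_terminal_dur_ms = 40,
                            p_axis_deg = NULL,
                            p_mag_mv = 0.15,
                            qrst = .default_qrst()) {
  leads <- ecg_leads()
  if (is.null(p_amp_mv)) {
    p_amp_mv <- c(I = 0.08, II = 0.20, III = 0.14, aVR = -0.14, aVL = 0.07,
                  aVF = 0.17, V1 = 0.09, V2 = 0.07, V3 = 0.12, V4 = 0.12,
                  V5 = 0.11, V6 = 0.10)
  }
  p_amp_mv <- p_amp_mv[leads]
  if (!is.null(p_axis_deg)) {
    ang <- c(I = 0, II = 60, III = 120, aVR = -150, aVL = -30, aVF = 90)
    p_amp_mv[names(ang)] <- p_mag_mv * cos((p_axis_deg - ang) * pi / 180)
  }
  if (anyNA(p_amp_mv)) stopf("p_amp_mv must name all 12 leads")
  if (p_duration_ms < 60 || p_duration_ms > 200)
    stopf("P-wave support must lie in [60, 200] ms, got %g", p_duration_ms)
  if (v1_terminal_depth_mv < 0) stopf("terminal depth must be >= 0")
  if (v1_terminal_dur_ms <= 0 || v1_terminal_dur_ms >= p_duration_ms)
    stopf("terminal duration must be in (0, P duration)")
  if (pr_ms < p_duration_ms)
    stopf("P-wave must end before QRS onset: PR (%g ms) < P duration (%g ms)",
          pr_ms, p_duration_ms)
  if (any(qrst$support_ms <= 0)) stopf("wave widths must be > 0")
  structure(list(
    p_amp_mv = p_amp_mv, p_duration_ms = p_duration_ms, pr_ms = pr_ms,
    v1_terminal_depth_mv = v1_terminal_depth_mv,
    v1_terminal_dur_ms = v1_terminal_dur_ms,
    qrst = qrst
  ), class = "beat_morphology")
}

# QRS onset relative to the R-peak (ms), measured on the noise-free rendered
# QRST complex with the same 5%-of-composite-peak backtracking rule the
# feature extractor applies. Keeps generated and measured PR on one convention.
qrs_onset_ms <- function(m, fs = 1000) {
  t_ms <- seq(-120, 60, by = 1000 / fs)
  sig <- sapply(ecg_leads(), function(ld) {
    v <- numeric(length(t_ms))
    for (w in .QRST_WAVES)
      v <- v + gauss_wave(t_ms, m$qrst$amp[w, ld], m$qrst$center_ms[[w]],
                          m$qrst$support_ms[[w]])
    v
  })
  comp <- rms_composite(sig)
  i_r <- which.min(abs(t_ms))
  thr <- 0.05 * max(comp)
  j <- i_r
  while (j > 1L && comp[j] >= thr) j <- j - 1L
  t_ms[j + 1L]
}

#' Render one beat as a 12-lead waveform
#'
#' Evaluates the sum-of-Gaussians beat model on a time grid spanning
#' -450..450 ms around the R-peak. In V1 the P-wave is biphasic: a positive
#' lobe followed by the terminal negative deflection.
#'
#' @param m a [beat_morphology()].
#' @param fs sampling rate in Hz (>= 500).
#' @return list with `signal` (samples x 12 matrix, mV), `t_ms` (time grid),
#'   `p_onset_ms`/`p_offset_ms` and `qrs_onset_ms` (ground truth, relative to
#'   the R-peak).
#' @export
render_beat <- function(m, fs = 1000) {
  stopifnot(inherits(m, "beat_morphology"))
  if (fs < 500) stopf("fs must be >= 500 Hz, got %g", fs)
  leads <- ecg_leads()
  t_ms <- seq(-450, 450 - 1000 / fs, by = 1000 / fs)
  qrs_on <- qrs_onset_ms(m, fs)
  p_on <- qrs_on - m$pr_ms
  p_off <- p_on + m$p_duration_ms
  p_center <- (p_on + p_off) / 2

  sig <- matrix(0, nrow = length(t_ms), ncol = 12L, dimnames = list(NULL, leads))
  for (ld in leads) {
    v <- numeric(length(t_ms))
    for (w in .QRST_WAVES)
      v <- v + gauss_wave(t_ms, m$qrst$amp[w, ld], m$qrst$center_ms[[w]],
                          m$qrst$support_ms[[w]])
    if (ld == "V1" && m$v1_terminal_depth_mv > 0) {
      pos_support <- m$p_duration_ms - m$v1_terminal_dur_ms
      v <- v + gauss_wave(t_ms, m$p_amp_mv[[ld]], p_on + pos_support / 2, pos_support)
      v <- v + gauss_wave(t_ms, -m$v1_terminal_depth_mv,
                          p_off - m$v1_terminal_dur_ms / 2, m$v1_terminal_dur_ms)
    } else {
      v <- v + gauss_wave(t_ms, m$p_amp_mv[[ld]], p_center, m$p_duration_ms)
    }
    sig[, ld] <- v
  }
  list(signal = sig, t_ms = t_ms, p_onset_ms = p_on, p_offset_ms = p_off,
       qrs_onset_ms = qrs_on)
}

#' Additive noise model for synthetic recordings
#'
#' Mains interference, slow baseline wander, broadband sensor noise and a
#' per-beat ectopic probability. The study device suppresses mains and band
#' limits at acquisition, so these defaults are deliberately mild
#' placeholders; the source recordings' true noise floor is uncharacterized.
#'
#' @param mains_hz mains frequency, 50 or 60 Hz.
#' @param mains_amp_mv mains amplitude (mV).
#' @param wander_amp_mv baseline-wander amplitude (mV).
#' @param wander_hz baseline-wander frequency (Hz).
#' @param broadband_sd_mv white-noise standard deviation (mV).
#' @param ectopic_prob per-beat probability of an ectopic atrial beat.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(mains_hz = 50, mains_amp_mv = 0.02,
                        wander_amp_mv = 0.05, wander_hz = 0.25,
                        broadband_sd_mv = 0.01, ectopic_prob = 0.02) {
  if (!mains_hz %in% c(50, 60)) stopf("mains_hz must be 50 or 60")
  amps <- c(mains_amp_mv, wander_amp_mv, broadband_sd_mv)
  if (any(amps < 0)) stopf("noise amplitudes must be >= 0")
  if (ectopic_prob < 0 || ectopic_prob > 1) stopf("ectopic_prob must be in [0, 1]")
  structure(list(mains_hz = mains_hz, mains_amp_mv = mains_amp_mv,
                 wander_amp_mv = wander_amp_mv, wander_hz = wander_hz,
                 broadband_sd_mv = broadband_sd_mv, ectopic_prob = ectopic_prob),
            class = "noise_model")
}

#' Silent noise model (all amplitudes zero)
#' @return A [noise_model()] with every amplitude and the ectopic rate at 0.
#' @export
noise_free <- function() {
  noise_model(mains_amp_mv = 0, wander_amp_mv = 0, broadband_sd_mv = 0,
              ectopic_prob = 0)
}

# Ectopic atrial beat: inverted, late P-wave; exercises the rejection stage.
ectopic_variant <- function(m) {
  m$p_amp_mv <- -0.9 * m$p_amp_mv
  m$pr_ms <- max(80, m$pr_ms - 40)
  m$v1_terminal_depth_mv <- 0
  m
}

#' Generate one synthetic subject recording
#'
#' Places rendered beats at RR intervals drawn from a truncated normal
#' heart-rate process, adds noise per the noise model, and keeps the full
#' ground truth (morphology, R-peak times, ectopic flags).
#'
#' @param id subject identifier.
#' @param label class label, `"positive"` (BrS) or `"negative"` (control).
#' @param age,sex clinical covariates; `sex` coded 1 = male, 0 = female.
#' @param morph a [beat_morphology()].
#' @param duration_s recording length in seconds (>= 30, the study minimum).
#' @param fs sampling rate (Hz).
#' @param hr_bpm mean heart rate (beats per minute).
#' @param rr_sd_s standard deviation of the RR intervals (s); RR truncated at
#'   0.4 s.
#' @param noise a [noise_model()].
#' @param seed integer seed; identical seeds give bit-identical recordings.
#' @return An object of class `synthetic_subject` holding an `ecg_recording`
#'   plus ground truth.
#' @export
generate_recording <- function(id, label = "positive", age = 45, sex = 1,
                               morph = beat_morphology(), duration_s = 60,
                               fs = 1000, hr_bpm = 80, rr_sd_s = 0.05,
                               noise = noise_model(), seed = 1) {
  stopifnot(inherits(morph, "beat_morphology"), inherits(noise, "noise_model"))
  if (duration_s < 30)
    stopf("recording must last >= 30 s (study minimum, two 15 s epochs); got %g s",
          duration_s)
  set.seed(seed)
  n <- round(duration_s * fs)
  leads <- ecg_leads()
  sig <- matrix(0, nrow = n, ncol = 12L, dimnames = list(NULL, leads))

  # R-peak times: first beat at 0.5 s, last one leaving room for its T-wave.
  mean_rr <- 60 / hr_bpm
  r_times <- numeric(0)
  t <- 0.5
  while (t < duration_s - 0.46) {
    r_times <- c(r_times, t)
    rr <- max(0.4, rnorm(1, mean_rr, rr_sd_s))
    t <- t + rr
  }
  n_beats <- length(r_times)
  ectopic <- runif(n_beats) < noise$ectopic_prob

  beat_norm <- render_beat(morph, fs)
  beat_ect <- if (any(ectopic)) render_beat(ectopic_variant(morph), fs) else NULL
  half <- nrow(beat_norm$signal)
  off0 <- round(-0.45 * fs)
  for (b in seq_len(n_beats)) {
    bm <- if (ectopic[b]) beat_ect$signal else beat_norm$signal
    i0 <- round(r_times[b] * fs) + 1L + off0
    idx <- i0:(i0 + half - 1L)
    keep <- idx >= 1L & idx <= n
    sig[idx[keep], ] <- sig[idx[keep], ] + bm[keep, ]
  }

  tt <- (seq_len(n) - 1L) / fs
  if (noise$mains_amp_mv > 0) {
    ph <- runif(12, 0, 2 * pi)
    for (l in 1:12)
      sig[, l] <- sig[, l] + noise$mains_amp_mv * sin(2 * pi * noise$mains_hz * tt + ph[l])
  }
  if (noise$wander_amp_mv > 0) {
    ph <- runif(12, 0, 2 * pi)
    for (l in 1:12)
      sig[, l] <- sig[, l] + noise$wander_amp_mv * sin(2 * pi * noise$wander_hz * tt + ph[l])
  }
  if (noise$broadband_sd_mv > 0)
    sig <- sig + matrix(rnorm(n * 12L, 0, noise$broadband_sd_mv), nrow = n)

  rec <- ecg_recording(sig, fs = fs, id = id)
  structure(list(
    id = id, label = label, age = age, sex = sex,
    recording = rec, morphology = morph, r_peaks = r_times,
    ectopic = ectopic, hr_bpm = hr_bpm, seed = seed,
    tfv1_truth_au = 1000 * morph$v1_terminal_depth_mv * morph$v1_terminal_dur_ms / 1000
  ), class = "synthetic_subject")
}

# Per-class parameter distributions. Medians follow the study cohort tables:
# P duration 136/124 ms, terminal force in V1 2.5/1.7 au (depth x 40 ms),
# per-lead P amplitudes from the local-feature table, PR 177/170 ms,
# HR 82+/-12 and 78+/-10 bpm, age 47+/-14 and 36+/-14, male fraction
# 0.696/0.636. Dispersions are IQR/1.349 where an IQR is printed.
default_class_params <- function(class = c("positive", "negative")) {
  class <- match.arg(class)
  if (class == "positive") {
    list(
      p_duration = c(median = 136, sd = 15),
      pr = c(median = 177, sd = 21),
      p_amp = c(I = 0.08, II = 0.20, III = 0.14, aVR = -0.14, aVL = 0.07,
                aVF = 0.17, V1 = 0.09, V2 = 0.07, V3 = 0.12, V4 = 0.12,
                V5 = 0.11, V6 = 0.10),
      p_amp_rel_sd = 0.22,
      v1_depth = c(median = 0.0625, sd = 0.030),
      v1_dur_ms = 40,
      hr = c(mean = 82, sd = 12),
      age = c(mean = 47, sd = 14),
      male_frac = 0.696
    )
  } else {
    list(
      p_duration = c(median = 124, sd = 15),
      pr = c(median = 170, sd = 30),
      p_amp = c(I = 0.08, II = 0.19, III = 0.12, aVR = -0.13, aVL = 0.06,
                aVF = 0.15, V1 = 0.08, V2 = 0.08, V3 = 0.12, V4 = 0.11,
                V5 = 0.09, V6 = 0.09),
      p_amp_rel_sd = 0.22,
      v1_depth = c(median = 0.0425, sd = 0.018),
      v1_dur_ms = 40,
      hr = c(mean = 78, sd = 10),
      age = c(mean = 36, sd = 14),
      male_frac = 0.636
    )
  }
}

#' Specification of a synthetic two-class cohort
#'
#' Defaults mirror the study population: 79 positive (BrS) and 44 negative
#' (ajmaline-negative control) subjects, recordings of 30 s to 5 min at
#' 1 kHz, and per-class morphology distributions centered on the published
#' group medians (see [default_class_params()] internals).
#'
#' @param n_pos,n_neg class sizes (>= 1).
#' @param duration_range per-subject recording duration range in seconds
#'   (uniform draw); minimum 30 s.
#' @param fs sampling rate (Hz); must exceed twice the 100 Hz low-pass cutoff
#'   used downstream.
#' @param noise a [noise_model()].
#' @param rr_sd_s RR-interval standard deviation (s).
#' @param class_params optional list with elements `positive` and `negative`
#'   overriding the default per-class parameter distributions.
#' @param identical_classes if TRUE both classes draw from the negative-class
#'   distribution (null cohort; downstream discrimination should be at
#'   chance).
#' @param seed master seed; per-subject streams are derived deterministically.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pos = 79, n_neg = 44, duration_range = c(30, 300),
                        fs = 1000, noise = noise_model(), rr_sd_s = 0.05,
                        class_params = NULL, identical_classes = FALSE,
                        seed = 1) {
  if (n_pos < 1 || n_neg < 1) stopf("class sizes must be >= 1")
  if (fs <= 200) stopf("sampling rate must exceed 2x the 100 Hz low-pass cutoff")
  if (min(duration_range) < 30) stopf("recording duration must be >= 30 s")
  if (is.null(class_params))
    class_params <- list(positive = default_class_params("positive"),
                         negative = default_class_params("negative"))
  if (identical_classes) class_params$positive <- class_params$negative
  structure(list(n_pos = n_pos, n_neg = n_neg,
                 duration_range = duration_range, fs = fs, noise = noise,
                 rr_sd_s = rr_sd_s, class_params = class_params, seed = seed),
            class = "cohort_spec")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, rnorm(n, mean, sd)))
}

# Draw one subject's beat morphology from a class parameter set. The PR
# interval is floored at P duration + 30 ms so the P-wave always ends a
# realistic PR-segment before the QRS onset (and inside the analysis window).
draw_morphology <- function(p) {
  dur <- rtrunc_norm(1, p$p_duration[["median"]], p$p_duration[["sd"]], 100, 180)
  pr <- rtrunc_norm(1, p$pr[["median"]], p$pr[["sd"]], 120, 240)
  pr <- max(pr, dur + 30)
  amp <- p$p_amp * pmax(0.25, rnorm(12, 1, p$p_amp_rel_sd))
  depth <- max(0, rnorm(1, p$v1_depth[["median"]], p$v1_depth[["sd"]]))
  beat_morphology(p_amp_mv = amp, p_duration_ms = dur, pr_ms = pr,
                  v1_terminal_depth_mv = depth,
                  v1_terminal_dur_ms = p$v1_dur_ms)
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param progress print a dot per subject.
#' @return A list of [generate_recording()] subjects (class `pwave_cohort`);
#'   attribute `spec` keeps the generating specification.
#' @export
generate_cohort <- function(spec = cohort_spec(), progress = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_tot <- spec$n_pos + spec$n_neg
  labels <- rep(c("positive", "negative"), c(spec$n_pos, spec$n_neg))
  subjects <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    lab <- labels[i]
    p <- spec$class_params[[lab]]
    sseed <- derive_seed(spec$seed, i)
    set.seed(sseed)
    morph <- draw_morphology(p)
    age <- round(rtrunc_norm(1, p$age[["mean"]], p$age[["sd"]], 18, 90))
    sex <- as.integer(runif(1) < p$male_frac)
    hr <- rtrunc_norm(1, p$hr[["mean"]], p$hr[["sd"]], 45, 120)
    dur <- runif(1, spec$duration_range[1], spec$duration_range[2])
    subjects[[i]] <- generate_recording(
      id = sprintf("P%03d", i), label = lab, age = age, sex = sex,
      morph = morph, duration_s = dur, fs = spec$fs, hr_bpm = hr,
      rr_sd_s = spec$rr_sd_s, noise = spec$noise,
      seed = derive_seed(sseed, 1L)
    )
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(subjects, class = "pwave_cohort", spec = spec)
}

#' @export
print.pwave_cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "label")
  cat(sprintf("<pwave_cohort> %d subjects (%d positive / %d negative)\n",
              length(x), sum(labs == "positive"), sum(labs == "negative")))
  invisible(x)
}

#' Ground-truth morphology table of a cohort
#'
#' One row per subject with the generating parameters the feature extractor
#' tries to recover.
#' @param cohort a `pwave_cohort`.
#' @return data.frame with id, label, age, sex, duration, P duration, PR,
#'   terminal force in V1 (au) and heart rate.
#' @export
cohort_truth <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    data.frame(patient_id = s$id, label = s$label, age = s$age, sex = s$sex,
               duration_s = nrow(s$recording$signal) / s$recording$fs,
               p_duration_ms = s$morphology$p_duration_ms,
               pr_ms = s$morphology$pr_ms,
               tfv1_au = s$tfv1_truth_au,
               hr_bpm = s$hr_bpm)
  }))
}
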