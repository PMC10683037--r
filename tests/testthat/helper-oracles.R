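# Independent oracles and small constructors used across the suite.

# Brute-force peak normalized cross-correlation between two windows:
# Pearson correlation on the overlap at every lag in [-max_lag, max_lag].
naive_peak_xcorr <- function(x, y, max_lag) {
  n <- length(x)
  best <- -Inf
  best_lag <- 0L
  for (l in -max_lag:max_lag) {
    if (l >= 0) v <- suppressWarnings(cor(x[(1 + l):n], y[1:(n - l)]))
    else v <- suppressWarnings(cor(x[1:(n + l)], y[(1 - l):n]))
    if (is.finite(v) && v > best) { best <- v; best_lag <- l }
  }
  list(peak = best, lag = best_lag)
}

# Hand transcription of the performance-metric formulas.
oracle_metrics <- function(tp, tn, fp, fn) {
  acc <- (tp + tn) / (tp + tn + fp + fn)
  sen <- tp / (tp + fn)
  spe <- tn / (tn + fp)
  pre <- tp / (tp + fp)
  f1p <- 2 * pre * sen / (pre + sen)
  npv <- tn / (tn + fn)
  f1n <- 2 * npv * spe / (npv + spe)
  list(acc = acc, sen = sen, spe = spe, pre = pre, f1_pos = f1p,
       mf1 = (f1p + f1n) / 2,
       wf1 = (tp + fn) / (tp + tn + fp + fn) * f1p +
         (tn + fp) / (tp + tn + fp + fn) * f1n)
}

# A Gaussian pulse sampled on a 300 ms window (support defined at the 5%
# relative threshold, the package-wide duration convention).
gauss_window <- function(fs = 1000, amp = 0.15, center_ms = 150,
                         support_ms = 120, len_ms = 300) {
  t <- seq(0, len_ms - 1000 / fs, by = 1000 / fs)
  sgm <- support_ms / (2 * sqrt(2 * log(20)))
  amp * exp(-((t - center_ms)^2) / (2 * sgm^2))
}

# Build an averaged_pwave object directly from a samples x 12 matrix.
make_avg <- function(waves, fs = 1000, pre_r_s = 0.35,
                     qrs_onset_offset_s = 0.036) {
  colnames(waves) <- ecg_leads()
  structure(list(waves = waves, fs = fs, id = "fixture", epoch_index = 1L,
                 n_beats = setNames(rep(1L, 12), ecg_leads()),
                 template_idx = setNames(rep(1L, 12), ecg_leads()),
                 retained = matrix(TRUE, 1, 12), peak_cor = matrix(1, 1, 12),
                 r_peaks = numeric(0), qrs_onset_offset_s = qrs_onset_offset_s,
                 pre_r_s = pre_r_s, window_s = 0.3, low_quality = FALSE),
            class = "averaged_pwave")
}

# An averaged_pwave whose 12 leads all carry the same Gaussian P pulse.
make_gauss_avg <- function(fs = 1000, amp = 0.15, center_ms = 150,
                           support_ms = 120) {
  w <- gauss_window(fs, amp, center_ms, support_ms)
  make_avg(matrix(rep(w, 12), ncol = 12), fs = fs)
}

# QRST component set with all amplitudes zeroed (isolates the P-wave).
.default_qrst_zeroed <- function() {
  amp <- matrix(0, 4, 12, dimnames = list(c("Q", "R", "S", "T"), ecg_leads()))
  list(amp = amp,
       center_ms = c(Q = -28, R = 0, S = 28, T = 230),
       support_ms = c(Q = 28, R = 45, S = 32, T = 160))
}

# Random patient-level observation table (no signals) for split fuzzing.
random_obs_table <- function(n_patients, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n_patients), function(i) {
    lab <- if (runif(1) < 0.64) "positive" else "negative"
    n <- sample(2:20, 1)
    data.frame(patient_id = sprintf("R%03d", i), label = lab,
               age = round(rnorm(1, 45, 15)), sex = rbinom(1, 1, 0.65),
               epoch = seq_len(n))
  })
  df <- do.call(rbind, rows)
  # guarantee at least two patients per class
  df$label[df$patient_id == "R001"] <- "positive"
  df$label[df$patient_id == "R002"] <- "positive"
  df$label[df$patient_id == "R003"] <- "negative"
  df$label[df$patient_id == "R004"] <- "negative"
  df
}
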