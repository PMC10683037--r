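# Per-epoch P-wave isolation, template selection, rejection, alignment and
# averaging.
#
# R-peaks are detected once per epoch on lead II with a Pan-Tompkins-style
# detector; each beat's P-wave is taken from a 300 ms window starting 350 ms
# before the R-peak. Per lead, every candidate is tried as template; the one
# with the highest average peak cross-correlation wins, low-correlation beats
# (ectopic or noisy) are rejected, survivors are aligned at their optimal lag
# and averaged. Cross-correlation is normalized (Pearson on the overlap) and
# lag-bounded so alignment cannot lock onto QRS remnants.

#' Pan-Tompkins-style R-peak detection
#'
#' Canonical stages: 5-15 Hz band-pass, differentiation, squaring, 150 ms
#' moving-window integration (centered, so zero-phase filtering keeps peaks
#' in place), adaptive signal/noise thresholds and a 200 ms refractory
#' period. Peak positions are refined on the band-passed signal.
#'
#' @param epoch an `ecg_epoch` (>= 250 Hz).
#' @param lead detection lead; lead II, the conventional rhythm lead.
#' @return Numeric vector of R-peak times in seconds from epoch start
#'   (strictly increasing). Fewer than 2 detected peaks means the epoch
#'   cannot form P-wave windows; the vector is returned as is and the caller
#'   treats the epoch as unusable.
#' @export
detect_r_peaks <- function(epoch, lead = "II") {
  stopifnot(inherits(epoch, "ecg_epoch"))
  fs <- epoch$fs
  if (fs < 250) stopf("R detection requires >= 250 Hz, got %g", fs)
  x <- epoch$signal[, lead]
  if (max(x) - min(x) < 1e-9) return(numeric(0))

  bp <- signal::filtfilt(signal::butter(3, c(5, 15) / (fs / 2), type = "pass"), x)
  der <- c(0, diff(bp)) * fs
  sq <- der^2
  integ <- moving_avg(sq, max(3L, round(0.150 * fs)))

  cand <- which(diff(sign(diff(integ))) == -2) + 1L
  cand <- cand[integ[cand] > 0]
  if (!length(cand)) return(numeric(0))

  init <- integ[seq_len(min(length(integ), 2L * fs))]
  spki <- 0.5 * max(init)
  npki <- 0.5 * mean(init)
  refr <- round(0.200 * fs)
  acc <- integer(0)
  last <- -Inf
  for (i in cand) {
    v <- integ[i]
    thr <- npki + 0.25 * (spki - npki)
    if (i - last < refr) next
    if (v > thr) {
      acc <- c(acc, i)
      last <- i
      spki <- 0.125 * v + 0.875 * spki
    } else {
      npki <- 0.125 * v + 0.875 * npki
    }
  }
  if (!length(acc)) return(numeric(0))

  # Refine each integrator peak to the band-passed energy maximum nearby.
  hw <- round(0.075 * fs)
  n <- length(x)
  r_idx <- vapply(acc, function(i) {
    lo <- max(1L, i - hw); hi <- min(n, i + hw)
    as.integer(lo + which.max(abs(bp[lo:hi])) - 1L)
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # Enforce the refractory period after refinement.
  keep <- c(TRUE, diff(r_idx) >= refr)
  r_idx <- r_idx[keep]
  (r_idx - 1L) / fs
}

#' Extract per-beat P-wave windows
#'
#' One 300 ms window per (beat, lead), starting 350 ms before the R-peak.
#' Beats whose window would start before the epoch are skipped silently.
#'
#' @param epoch an `ecg_epoch`.
#' @param r_peaks R-peak times in seconds (from [detect_r_peaks()]).
#' @param window_s window length (s).
#' @param pre_r_s window start offset before the R-peak (s).
#' @return List with `windows` (array samples x beats x 12), `r_times`
#'   (retained R-peak times) and `start_times` (window starts, s); NULL when
#'   no beat fits.
#' @export
extract_pwave_windows <- function(epoch, r_peaks, window_s = 0.300,
                                  pre_r_s = 0.350) {
  stopifnot(inherits(epoch, "ecg_epoch"))
  fs <- epoch$fs
  len <- round(window_s * fs)
  n <- nrow(epoch$signal)
  starts <- round((r_peaks - pre_r_s) * fs) + 1L
  keep <- starts >= 1L & (starts + len - 1L) <= n
  if (!any(keep)) return(NULL)
  starts <- starts[keep]
  k <- length(starts)
  w <- array(0, dim = c(len, k, 12L),
             dimnames = list(NULL, NULL, ecg_leads()))
  for (b in seq_len(k))
    w[, b, ] <- epoch$signal[starts[b]:(starts[b] + len - 1L), ]
  list(windows = w, r_times = r_peaks[keep],
       start_times = (starts - 1L) / fs)
}

# Peak normalized cross-correlation between all candidate pairs.
# W: samples x k matrix. For lag l >= 0, cc(i, j, l) = Pearson correlation of
# W[,i][(1+l):n] with W[,j][1:(n-l)], i.e. candidate j delayed by l samples
# best matches candidate i. Negative lags come from the transpose. Returns
# peak value and the peak lag (samples) over |lag| <= max_lag.
pairwise_peak_xcorr <- function(W, max_lag) {
  n <- nrow(W); k <- ncol(W)
  best <- matrix(-Inf, k, k)
  blag <- matrix(0L, k, k)
  for (l in 0:max_lag) {
    A <- W[(1L + l):n, , drop = FALSE]
    B <- W[1L:(n - l), , drop = FALSE]
    C <- suppressWarnings(cor(A, B))
    C[!is.finite(C)] <- 0
    upd <- C > best
    best[upd] <- C[upd]
    blag[upd] <- l
    if (l > 0L) {
      Ct <- t(C)
      upd <- Ct > best
      best[upd] <- Ct[upd]
      blag[upd] <- -l
    }
  }
  list(peak = best, lag = blag)
}

#' Select the P-wave template beat
#'
#' Every candidate is tested as template; the one with the highest average
#' peak normalized cross-correlation against all other candidates becomes
#' the template. Ties break to the lowest beat index.
#'
#' @param W samples x beats matrix of P-wave windows (one lead).
#' @param max_lag_s lag bound for the cross-correlation (s).
#' @param fs sampling rate (Hz).
#' @return The template's beat index (column of `W`).
#' @export
select_template <- function(W, max_lag_s = 0.05, fs = 1000) {
  k <- ncol(W)
  if (k == 1L) return(1L)
  xc <- pairwise_peak_xcorr(W, round(max_lag_s * fs))
  p <- xc$peak
  diag(p) <- NA
  score <- rowMeans(p, na.rm = TRUE)
  which.max(score)  # which.max takes the first (lowest index) on ties
}

#' Reject outlying P-waves
#'
#' A candidate is retained iff its peak normalized cross-correlation with the
#' template reaches the threshold; the template itself is always retained.
#' Rejection removes ectopic atrial beats and windows with excessive noise.
#'
#' @param W samples x beats matrix (one lead).
#' @param template template beat index.
#' @param threshold correlation threshold in [0, 1].
#' @param max_lag_s,fs lag bound (s) and sampling rate.
#' @return List with `retained` (indices), `peak_cor` (per candidate) and
#'   `lag` (optimal lag of each candidate vs the template, samples).
#' @export
reject_outliers <- function(W, template, threshold = 0.8, max_lag_s = 0.05,
                            fs = 1000) {
  k <- ncol(W)
  xc <- pairwise_peak_xcorr(W, round(max_lag_s * fs))
  pc <- xc$peak[template, ]
  lg <- xc$lag[template, ]
  pc[template] <- 1
  lg[template] <- 0L
  retained <- which(pc >= threshold)
  if (!length(retained)) retained <- template
  if (!template %in% retained) retained <- sort(c(template, retained))
  list(retained = retained, peak_cor = pc, lag = lg)
}

#' Align retained P-waves and average them
#'
#' Each retained window is shifted by the lag at which its cross-correlation
#' with the template peaks (bounded), then averaged sample-wise over the
#' positions it covers; window-edge positions covered by no shifted beat take
#' the template's samples. Output is re-cropped to the window length.
#'
#' @param W samples x beats matrix (one lead).
#' @param template template beat index.
#' @param retained indices of retained beats.
#' @param lags per-candidate optimal lags in samples (from
#'   [reject_outliers()]); lag `l` means the candidate is delayed by `l`
#'   relative to the template and is advanced by `l` before averaging.
#' @return Numeric vector (averaged window) with attribute `n_beats`.
#' @export
align_and_average <- function(W, template, retained, lags) {
  n <- nrow(W)
  acc <- numeric(n)
  cnt <- numeric(n)
  for (b in retained) {
    l <- lags[b]
    # positive lag: the candidate's features occur l samples before the
    # template's, so output position t reads the candidate at t - l.
    if (l >= 0) { pos <- (1L + l):n; val <- 1L:(n - l) }
    else { pos <- 1L:(n + l); val <- (1L - l):n }
    acc[pos] <- acc[pos] + W[val, b]
    cnt[pos] <- cnt[pos] + 1
  }
  out <- ifelse(cnt > 0, acc / pmax(cnt, 1), W[, template])
  structure(out, n_beats = length(retained))
}

# Mean QRS-onset offset before the R-peak (s), by backtracking the 5% rule on
# the RMS composite of the epoch around each R-peak. Feeds the PR interval.
qrs_onset_offset <- function(epoch, r_peaks) {
  comp <- rms_composite(epoch$signal)
  fs <- epoch$fs
  n <- length(comp)
  offs <- vapply(r_peaks, function(r) {
    i_r <- round(r * fs) + 1L
    if (i_r < 2L || i_r > n) return(NA_real_)
    lo <- max(1L, i_r - round(0.04 * fs)); hi <- min(n, i_r + round(0.04 * fs))
    thr <- 0.05 * max(comp[lo:hi])
    j <- i_r
    lim <- max(1L, i_r - round(0.12 * fs))
    while (j > lim && comp[j] >= thr) j <- j - 1L
    r - (j) / fs  # j is the last below-threshold sample; onset is j + 1
  }, numeric(1))
  mean(offs, na.rm = TRUE)
}

#' Averaged P-wave of one epoch
#'
#' Runs the full per-epoch chain: shared R-peak detection on lead II, window
#' extraction, then per-lead template selection, outlier rejection, alignment
#' and averaging. An epoch with fewer than 2 usable beats yields NULL (absent
#' observation); an epoch retaining fewer than `min_beats` beats in any lead
#' is flagged low-quality.
#'
#' @param epoch an `ecg_epoch` (already filtered).
#' @param threshold correlation rejection threshold.
#' @param max_lag_s alignment lag bound (s).
#' @param min_beats minimum retained beats per lead below which the epoch is
#'   flagged low-quality.
#' @param window_s,pre_r_s P-window geometry (s).
#' @return An object of class `averaged_pwave`, or NULL with no usable beats.
#' @export
epoch_to_averaged_pwave <- function(epoch, threshold = 0.8, max_lag_s = 0.05,
                                    min_beats = 3L, window_s = 0.300,
                                    pre_r_s = 0.350) {
  r <- detect_r_peaks(epoch)
  if (length(r) < 2L) return(NULL)
  cand <- extract_pwave_windows(epoch, r, window_s = window_s, pre_r_s = pre_r_s)
  if (is.null(cand) || dim(cand$windows)[2] < 1L) return(NULL)
  k <- dim(cand$windows)[2]
  len <- dim(cand$windows)[1]
  fs <- epoch$fs
  leads <- ecg_leads()
  waves <- matrix(0, nrow = len, ncol = 12L, dimnames = list(NULL, leads))
  n_beats <- integer(12L); names(n_beats) <- leads
  tmpl_idx <- integer(12L); names(tmpl_idx) <- leads
  retained_flags <- matrix(FALSE, nrow = k, ncol = 12L, dimnames = list(NULL, leads))
  peak_cors <- matrix(NA_real_, nrow = k, ncol = 12L, dimnames = list(NULL, leads))
  max_lag <- round(max_lag_s * fs)
  for (ld in leads) {
    W <- cand$windows[, , ld, drop = TRUE]
    if (k == 1L) W <- matrix(W, ncol = 1L)
    if (k == 1L) {
      waves[, ld] <- W[, 1L]
      n_beats[ld] <- 1L; tmpl_idx[ld] <- 1L
      retained_flags[1L, ld] <- TRUE; peak_cors[1L, ld] <- 1
      next
    }
    xc <- pairwise_peak_xcorr(W, max_lag)
    p <- xc$peak
    diag(p) <- NA
    tmpl <- which.max(rowMeans(p, na.rm = TRUE))
    pc <- xc$peak[tmpl, ]; lg <- xc$lag[tmpl, ]
    pc[tmpl] <- 1; lg[tmpl] <- 0L
    ret <- which(pc >= threshold)
    if (!tmpl %in% ret) ret <- sort(c(tmpl, ret))
    waves[, ld] <- align_and_average(W, tmpl, ret, lg)
    n_beats[ld] <- length(ret)
    tmpl_idx[ld] <- tmpl
    retained_flags[ret, ld] <- TRUE
    peak_cors[, ld] <- pc
  }
  structure(list(
    waves = waves, fs = fs, id = epoch$id, epoch_index = epoch$index,
    n_beats = n_beats, template_idx = tmpl_idx,
    retained = retained_flags, peak_cor = peak_cors,
    r_peaks = cand$r_times,
    qrs_onset_offset_s = qrs_onset_offset(epoch, cand$r_times),
    pre_r_s = pre_r_s, window_s = window_s,
    low_quality = any(n_beats < min_beats)
  ), class = "averaged_pwave")
}

#' @export
print.averaged_pwave <- function(x, ...) {
  cat(sprintf("<averaged_pwave> %s epoch %d: %d-%d beats/lead%s\n",
              x$id, x$epoch_index, min(x$n_beats), max(x$n_beats),
              if (x$low_quality) " [low quality]" else ""))
  invisible(x)
}
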