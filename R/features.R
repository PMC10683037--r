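# Feature extraction from averaged P-waves: 5 global features (duration, PR
# interval, terminal force in V1, FWHM, axis), 5 local features on each of
# the 12 leads (area, peak count, maximum amplitude, histogram entropy,
# sample entropy), plus age and sex: 67 entries per observation.
#
# The measurement signal for delineation, duration and FWHM is the smoothed
# RMS composite across the 12 leads. Onset/offset are the crossings of 5% of
# the composite peak, scanned outward from the peak so a preceding T-wave
# tail at the window edge cannot capture the onset.

#' Feature schema
#'
#' Fixed, versioned order of the 67 features: 5 global, then area / peaks /
#' amplitude / entropy / sample entropy for each of the 12 leads, then age
#' and sex (1 = male, 0 = female).
#' @return data.frame with columns `name`, `group`, `lead`, `unit`.
#' @export
feature_schema <- function() {
  leads <- ecg_leads()
  loc <- expand.grid(feat = c("area", "peaks", "amplitude", "entropy", "sampen"),
                     lead = leads, stringsAsFactors = FALSE)
  # per-lead blocks: all 5 features of lead I, then lead II, ...
  loc <- loc[order(match(loc$lead, leads)), ]
  units <- c(area = "uV.s", peaks = "count", amplitude = "mV",
             entropy = "nat", sampen = "nat")
  rbind(
    data.frame(name = c("duration_ms", "pr_ms", "ptfv1_au", "fwhm_ms", "axis_deg"),
               group = "global", lead = "global",
               unit = c("ms", "ms", "uV.s", "ms", "deg")),
    data.frame(name = paste0(loc$feat, "_", loc$lead), group = "local",
               lead = loc$lead, unit = unname(units[loc$feat])),
    data.frame(name = c("age", "sex"), group = "clinical", lead = "global",
               unit = c("years", "binary"))
  )
}

#' Delineate the averaged P-wave
#'
#' Onset and offset are the outermost crossings of 5% of the peak absolute
#' amplitude on the smoothed RMS composite across leads, scanned backward and
#' forward from the composite peak.
#'
#' @param avg an `averaged_pwave`.
#' @param threshold relative amplitude threshold (fraction of composite peak).
#' @param noise_floor_mv minimum composite peak (mV) below which the
#'   observation is invalid.
#' @param smooth_ms smoothing window for the composite (ms).
#' @param search_from_ms start of the peak-search region within the window
#'   (ms). In a window starting 350 ms before the R-peak a P-wave cannot
#'   peak within the first ~70 ms (that would put the atrial peak > 280 ms
#'   before the QRS); at short RR intervals that edge region instead holds
#'   the tail of the preceding T-wave, which must not capture the peak.
#' @return List with `onset_s`, `offset_s` (from window start), `duration_ms`,
#'   `onset_idx`, `offset_idx`, `composite`; or NULL when the peak is under
#'   the noise floor.
#' @export
delineate_pwave <- function(avg, threshold = 0.05, noise_floor_mv = 0.010,
                            smooth_ms = 5, search_from_ms = 70) {
  stopifnot(inherits(avg, "averaged_pwave"))
  comp <- moving_avg(rms_composite(avg$waves), max(1L, round(smooth_ms * avg$fs / 1000)))
  from_i <- min(length(comp), round(search_from_ms * avg$fs / 1000) + 1L)
  pk_i <- from_i - 1L + which.max(comp[from_i:length(comp)])
  pk <- comp[pk_i]
  if (!is.finite(pk) || pk < noise_floor_mv) return(NULL)
  thr <- threshold * pk
  on_i <- pk_i
  while (on_i > 1L && comp[on_i - 1L] > thr) on_i <- on_i - 1L
  off_i <- pk_i
  n <- length(comp)
  while (off_i < n && comp[off_i + 1L] > thr) off_i <- off_i + 1L
  list(onset_s = (on_i - 1L) / avg$fs, offset_s = (off_i - 1L) / avg$fs,
       duration_ms = (off_i - on_i) / avg$fs * 1000,
       onset_idx = on_i, offset_idx = off_i, composite = comp)
}

#' PR interval
#'
#' P-wave onset to QRS onset, in ms. The QRS onset offset before the R-peak
#' is estimated on the epoch by backtracking the 5% rule on the RMS composite
#' around each R-peak (stored in the `averaged_pwave`); the P onset comes
#' from [delineate_pwave()]. The window starts `pre_r_s` before the R-peak,
#' so PR = pre_r - qrs_onset_offset - onset.
#'
#' @param avg an `averaged_pwave`.
#' @param del delineation from [delineate_pwave()].
#' @return PR interval in ms.
#' @export
pr_interval <- function(avg, del) {
  (avg$pre_r_s - avg$qrs_onset_offset_s - del$onset_s) * 1000
}

#' P-wave terminal force in lead V1
#'
#' Absolute depth of the terminal negative P deflection in V1 times its
#' duration: `depth_uV x duration_s` (uV.s, reported as "au"). Zero when V1
#' has no terminal negative phase deeper than 5% of the V1 peak.
#'
#' @param avg an `averaged_pwave`.
#' @param del delineation from [delineate_pwave()].
#' @return Terminal force (uV.s).
#' @export
ptfv1 <- function(avg, del) {
  v1 <- avg$waves[del$onset_idx:del$offset_idx, "V1"] * 1000  # uV
  n <- length(v1)
  neg <- v1 < 0
  cross <- which(!neg[-n] & neg[-1L])  # downward zero crossings
  if (!length(cross)) return(0)
  c0 <- cross[length(cross)] + 1L
  depth <- max(-v1[c0:n])
  if (depth < 0.05 * max(abs(v1))) return(0)
  dur_s <- (n - c0 + 1L) / avg$fs
  depth * dur_s
}

#' Full width at half maximum
#'
#' Time interval over which the measurement signal exceeds half its maximum
#' amplitude. Contiguous interval around the peak by default; with
#' `contiguous = FALSE` all supra-half-maximum samples are summed.
#'
#' @param x measurement signal (the smoothed composite from
#'   [delineate_pwave()], or any pulse).
#' @param fs sampling rate (Hz).
#' @param contiguous restrict to the interval around the global maximum.
#' @return FWHM in ms.
#' @export
fwhm <- function(x, fs, contiguous = TRUE) {
  half <- max(x) / 2
  above <- x > half
  if (!contiguous) return(sum(above) / fs * 1000)
  pk <- which.max(x)
  lo <- pk
  while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- pk
  n <- length(x)
  while (hi < n && above[hi + 1L]) hi <- hi + 1L
  (hi - lo + 1L) / fs * 1000
}

#' Frontal-plane P-wave axis
#'
#' `atan2` of the net (signed) P-wave areas of leads aVF and I, in degrees,
#' range (-180, 180].
#'
#' @param avg an `averaged_pwave`.
#' @param del delineation from [delineate_pwave()].
#' @return Axis in degrees, or NA when both net areas vanish.
#' @export
pwave_axis <- function(avg, del) {
  idx <- del$onset_idx:del$offset_idx
  a_i <- sum(avg$waves[idx, "I"]) / avg$fs
  a_f <- sum(avg$waves[idx, "aVF"]) / avg$fs
  if (abs(a_i) < 1e-12 && abs(a_f) < 1e-12) return(NA_real_)
  atan2(a_f, a_i) * 180 / pi
}

# Local maxima with topographic prominence >= min_prom.
count_peaks <- function(x, min_prom) {
  n <- length(x)
  if (n < 3L) return(0L)
  cand <- which(diff(sign(diff(x))) == -2) + 1L
  if (!length(cand)) return(0L)
  proms <- vapply(cand, function(i) {
    h <- x[i]
    l <- i
    lmin <- h
    while (l > 1L) { l <- l - 1L; if (x[l] > h) break; lmin <- min(lmin, x[l]) }
    if (x[l] <= h) lmin <- min(lmin, x[l])
    r <- i
    rmin <- h
    while (r < n) { r <- r + 1L; if (x[r] > h) break; rmin <- min(rmin, x[r]) }
    if (x[r] <= h) rmin <- min(rmin, x[r])
    h - max(lmin, rmin)
  }, numeric(1))
  sum(proms >= min_prom)
}

#' Sample entropy
#'
#' Negative log conditional probability that sequences matching for `m`
#' points (Chebyshev distance < r) still match at `m + 1`. Vectorized over
#' the pairwise distance matrix; the template-pair counting convention
#' replicates `pracma::sample_entropy` exactly (both template lengths use
#' the same `n - m` template set, strict `< r`), so the two agree to
#' machine precision.
#'
#' @param x numeric signal.
#' @param m embedding dimension.
#' @param r matching tolerance (same unit as `x`).
#' @return Sample entropy in nats; `Inf` when no (m+1)-matches exist.
#' @export
sample_entropy_fast <- function(x, m = 2L, r = 0.2 * sd(x)) {
  n <- length(x)
  M <- n - m
  if (M < 3L || r <= 0) return(NA_real_)
  D <- abs(outer(x, x, "-")) < r
  Tm <- D[1:M, 1:M]
  for (k in seq_len(m - 1L)) Tm <- Tm & D[1:M + k, 1:M + k]
  Tm1 <- Tm & D[1:M + m, 1:M + m]
  B <- (sum(Tm) - M) / 2
  # the reference implementation skips the final (M-1, M) pair at m + 1
  A <- (sum(Tm1) - M) / 2 - Tm1[M - 1L, M]
  if (A <= 0 || B <= 0) return(Inf)
  log(B / A)
}

# Shannon entropy (nats) of the amplitude histogram over nbins uniform bins
# between the signal's min and max.
hist_entropy <- function(x, nbins = 22L) {
  rng <- range(x)
  if (diff(rng) < 1e-12) return(0)
  b <- seq(rng[1], rng[2], length.out = nbins + 1L)
  cnt <- tabulate(findInterval(x, b, rightmost.closed = TRUE), nbins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log(p))
}

#' Local features of one lead
#'
#' Area (integral of |signal| between onset and offset, uV.s), number of
#' peaks (prominence >= 10% of the maximum absolute amplitude), maximum
#' absolute amplitude (mV), Shannon entropy of the 22-bin amplitude histogram
#' (nats), and sample entropy (m = 2, r = 0.2 x SD). A constant segment gets
#' entropy 0 and sample entropy 0 with a flag.
#'
#' @param avg an `averaged_pwave`.
#' @param lead lead name.
#' @param del delineation from [delineate_pwave()].
#' @return Named numeric: area, peaks, amplitude, entropy, sampen; attribute
#'   `flat` when the segment was constant.
#' @export
local_features <- function(avg, lead, del) {
  seg <- avg$waves[del$onset_idx:del$offset_idx, lead]
  fs <- avg$fs
  area <- sum(abs(seg)) * 1000 / fs           # uV.s
  amp <- max(abs(seg))                        # mV
  pk <- count_peaks(seg, 0.1 * amp)
  flat <- sd(seg) < 1e-12
  ent <- hist_entropy(seg)
  se <- if (flat) 0 else {
    v <- sample_entropy_fast(seg, m = 2L, r = 0.2 * sd(seg))
    if (!is.finite(v)) 0 else v
  }
  structure(c(area = area, peaks = pk, amplitude = amp, entropy = ent,
              sampen = se), flat = flat)
}

#' Assemble a 67-entry feature vector
#'
#' @param globals named numeric of the 5 global features (schema order).
#' @param locals named numeric of the 60 local features (schema order).
#' @param age age in years.
#' @param sex 1 = male, 0 = female.
#' @return Named numeric of length 67 in the [feature_schema()] order.
#' @export
assemble_feature_vector <- function(globals, locals, age, sex) {
  sch <- feature_schema()
  v <- c(globals, locals, age = age, sex = sex)
  if (!identical(names(v), sch$name))
    stopf("feature vector does not match the schema (%d entries, expected 67)",
          length(v))
  if (anyNA(v)) stopf("feature vector contains missing values")
  v
}

#' Extract the full feature vector of one averaged P-wave
#'
#' @param avg an `averaged_pwave`.
#' @param age,sex clinical covariates (sex 1 = male, 0 = female).
#' @param threshold,noise_floor_mv delineation parameters.
#' @return Named numeric of length 67, or NULL (with attribute `reason`) when
#'   the observation is invalid (flat window, undefined axis, failed
#'   delineation).
#' @export
extract_features <- function(avg, age, sex, threshold = 0.05,
                             noise_floor_mv = 0.010) {
  del <- delineate_pwave(avg, threshold = threshold,
                         noise_floor_mv = noise_floor_mv)
  if (is.null(del)) return(NULL)   # composite peak below the noise floor
  axis <- pwave_axis(avg, del)
  if (is.na(axis)) return(NULL)    # undefined axis

  globals <- c(duration_ms = del$duration_ms,
               pr_ms = pr_interval(avg, del),
               ptfv1_au = ptfv1(avg, del),
               fwhm_ms = fwhm(del$composite, avg$fs),
               axis_deg = axis)
  locals <- unlist(lapply(ecg_leads(), function(ld) {
    lf <- local_features(avg, ld, del)
    names(lf) <- paste0(names(lf), "_", ld)
    lf
  }))
  assemble_feature_vector(globals, locals, age, sex)
}
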