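# Shared constants and small numeric helpers.

#' Canonical 12-lead order
#'
#' Lead order used throughout: limb leads I, II, III, aVR, aVL, aVF followed
#' by precordial V1-V6.
#' @return Character vector of the 12 standard lead names.
#' @export
ecg_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

# Support convention: a wave's "duration" is the width of the interval on
# which |amplitude| exceeds 5% of its peak. For a Gaussian kernel that
# interval is 2*sqrt(2*log(20)) standard deviations.
.SUPPORT_K <- 2 * sqrt(2 * log(20))

support_to_sigma <- function(support) support / .SUPPORT_K

# Gaussian kernel evaluated at times t (same unit as center/support).
gauss_wave <- function(t, amp, center, support) {
  sgm <- support_to_sigma(support)
  amp * exp(-((t - center)^2) / (2 * sgm^2))
}

# Centered moving average, edges padded by replication; width in samples.
moving_avg <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  xp <- c(rep(x[1L], w), x, rep(x[n], w))
  k <- rep(1 / w, w)
  y <- stats::filter(xp, k, sides = 2L)
  as.numeric(y[(w + 1L):(w + n)])
}

# Root-mean-square composite across the columns (leads) of a signal matrix.
rms_composite <- function(sig) sqrt(rowMeans(sig^2))

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Deterministic per-subject seed stream below 2^31.
derive_seed <- function(master, idx) {
  as.integer((as.numeric(master) * 48271 + 7919 * idx) %% 2147483629) + 1L
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
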