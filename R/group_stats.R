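# Group comparison layer: Mann-Whitney U for continuous features, Fisher's
# exact test for categorical counts, Bonferroni correction across the 65
# feature comparisons (5 global + 60 local). Results are shaped like the
# published median (25-75 percentile) tables.

fmt_med_iqr <- function(x, digits = 3) {
  q <- quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  sprintf("%s (%s-%s)", signif(q[1], digits), signif(q[2], digits),
          signif(q[3], digits))
}

#' Compare one continuous feature between classes
#'
#' Two-sided Mann-Whitney U test with per-class median and 25-75 percentiles.
#'
#' @param pos,neg numeric values of the positive and negative class (>= 2
#'   observations each).
#' @param feature feature name for the output row.
#' @param lead lead name, or "global".
#' @return One-row data.frame: feature, lead, per-class medians/quartiles,
#'   formatted `median (25-75)` strings, and the p-value.
#' @export
compare_continuous <- function(pos, neg, feature = "feature", lead = "global") {
  if (length(pos) < 2L || length(neg) < 2L)
    stopf("need >= 2 observations per class for '%s'", feature)
  p <- suppressWarnings(wilcox.test(pos, neg, exact = NULL)$p.value)
  qp <- quantile(pos, c(0.25, 0.5, 0.75), names = FALSE)
  qn <- quantile(neg, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(feature = feature, lead = lead,
             median_pos = qp[2], q25_pos = qp[1], q75_pos = qp[3],
             median_neg = qn[2], q25_neg = qn[1], q75_neg = qn[3],
             positive = fmt_med_iqr(pos), negative = fmt_med_iqr(neg),
             p_value = p)
}

#' Fisher's exact test on a 2x2 count table
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
compare_categorical <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2L)) stopf("counts must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be nonnegative integers")
  fisher.test(counts)$p.value
}

#' Flag Bonferroni-significant comparison rows
#'
#' Adds the corrected threshold `alpha / m` (also reported rounded to two
#' significant figures, the printing convention of the source tables) and a
#' significance flag `p < alpha / m`.
#'
#' @param rows data.frame with a `p_value` column.
#' @param alpha family-wise error target.
#' @param m number of comparisons (defaults to `nrow(rows)`).
#' @return `rows` with columns `alpha_corrected`, `significant`.
#' @export
bonferroni_flag <- function(rows, alpha = 0.05, m = nrow(rows)) {
  if (m < 1) stopf("m must be >= 1")
  thr <- alpha / m
  rows$alpha_corrected <- signif(thr, 2)
  rows$significant <- rows$p_value < thr
  rows
}

#' Class comparison of a full feature table
#'
#' Runs the Mann-Whitney comparison for each of the 65 P-wave features
#' (5 global + 60 local) and applies the Bonferroni correction over those 65
#' tests (age and sex are cohort descriptors, not corrected features).
#'
#' @param obs observation table from [cohort_features()] (needs a `label`
#'   column plus the 67 feature columns).
#' @param alpha family-wise error target.
#' @return data.frame of comparison rows with significance flags.
#' @export
compare_features <- function(obs, alpha = 0.05) {
  sch <- feature_schema()
  feats <- sch[sch$group %in% c("global", "local"), ]
  pos <- obs[obs$label == "positive", , drop = FALSE]
  neg <- obs[obs$label == "negative", , drop = FALSE]
  rows <- do.call(rbind, lapply(seq_len(nrow(feats)), function(i) {
    nm <- feats$name[i]
    compare_continuous(pos[[nm]], neg[[nm]], feature = nm, lead = feats$lead[i])
  }))
  bonferroni_flag(rows, alpha = alpha, m = nrow(rows))
}
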