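# Class-imbalance correction for the training partition: random
# oversampling, SMOTE, Borderline-SMOTE, SVM-SMOTE, ADASYN (implemented from
# the original algorithms; synthetic points are interpolated exclusively from
# training data) and inverse-frequency class weighting. The test partition is
# never touched.

.BALANCING_METHODS <- c("none", "oversample", "smote", "svm_smote",
                        "borderline_smote", "adasyn", "weight")

# k nearest neighbours (Euclidean) of each row of a within rows of b;
# self-matches excluded when 'self' is TRUE. Returns index matrix n_a x k.
knn_index <- function(a, b, k, self = FALSE) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  t(vapply(seq_len(nrow(a)), function(i) {
    o <- order(d2[i, ])
    if (self) o <- o[o != i]
    o[seq_len(k)]
  }, integer(k)))
}

# Interpolate n_new synthetic minority points: each is a convex combination
# of a seed point and one of its k minority neighbours.
smote_interpolate <- function(xmin, seeds, nn, n_new) {
  p <- ncol(xmin)
  out <- matrix(0, n_new, p)
  si <- sample(rep_len(seeds, n_new))
  for (j in seq_len(n_new)) {
    i <- si[j]
    nb <- nn[match(i, seeds), ]
    x1 <- xmin[i, ]
    x2 <- xmin[sample(nb, 1L), ]
    out[j, ] <- x1 + runif(1) * (x2 - x1)
  }
  colnames(out) <- colnames(xmin)
  out
}

#' Rebalance a training partition
#'
#' Oversampling variants equalize the class counts by adding minority
#' observations (duplicated, or synthesized by neighbour interpolation);
#' `"weight"` leaves the data untouched and returns per-observation weights
#' inversely proportional to class frequency. When the minority class is too
#' small for the neighbour requirement the method falls back to random
#' oversampling with a warning.
#'
#' @param x numeric feature matrix (training observations only).
#' @param y factor of labels with levels `negative`, `positive`.
#' @param method one of `none`, `oversample`, `smote`, `svm_smote`,
#'   `borderline_smote`, `adasyn`, `weight`.
#' @param k neighbourhood size for the SMOTE family.
#' @param seed integer seed.
#' @return List with `x`, `y`, `weights` (NULL except for `"weight"`) and
#'   `synthetic` (logical flag per row).
#' @export
rebalance <- function(x, y, method = "none", k = 5L, seed = 1L) {
  method <- match.arg(method, .BALANCING_METHODS)
  y <- factor(y, levels = c("negative", "positive"))
  if (any(table(y) == 0)) stopf("training data must contain both classes")
  n <- nrow(x)
  if (method == "none")
    return(list(x = x, y = y, weights = NULL, synthetic = rep(FALSE, n)))
  if (method == "weight") {
    tab <- table(y)
    w <- as.numeric(n / (2 * tab[as.character(y)]))
    return(list(x = x, y = y, weights = w, synthetic = rep(FALSE, n)))
  }
  set.seed(seed)
  tab <- table(y)
  minority <- names(tab)[which.min(tab)]
  n_new <- max(tab) - min(tab)
  if (n_new == 0L)
    return(list(x = x, y = y, weights = NULL, synthetic = rep(FALSE, n)))
  xmin <- x[y == minority, , drop = FALSE]
  nmin <- nrow(xmin)

  if (method != "oversample" && nmin <= k) {
    warning(sprintf("minority class (%d) smaller than k+1=%d; falling back to random oversampling",
                    nmin, k + 1L), call. = FALSE)
    method <- "oversample"
  }

  if (method == "oversample") {
    add <- xmin[sample(nmin, n_new, replace = TRUE), , drop = FALSE]
  } else if (method == "smote") {
    nn <- knn_index(xmin, xmin, k, self = TRUE)
    add <- smote_interpolate(xmin, seq_len(nmin), nn, n_new)
  } else if (method == "adasyn") {
    # density-weighted: more synthesis where majority dominates the k-NN
    nn_all <- knn_index(xmin, x, k, self = FALSE)
    maj_frac <- rowMeans(matrix(y[nn_all] != minority, nrow = nmin))
    w <- if (sum(maj_frac) > 0) maj_frac / sum(maj_frac) else rep(1 / nmin, nmin)
    counts <- as.vector(rmultinom(1, n_new, w))
    nn <- knn_index(xmin, xmin, k, self = TRUE)
    add <- matrix(0, n_new, ncol(xmin), dimnames = list(NULL, colnames(xmin)))
    si <- sample(rep(seq_len(nmin), counts))
    for (j in seq_len(n_new)) {
      i <- si[j]
      x2 <- xmin[sample(nn[i, ], 1L), ]
      add[j, ] <- xmin[i, ] + runif(1) * (x2 - xmin[i, ])
    }
  } else if (method == "borderline_smote") {
    # borderline-1: seeds are "danger" minority points (half or more of the
    # k-NN in the full set are majority, but not all)
    nn_all <- knn_index(xmin, x, k, self = FALSE)
    maj <- matrix(y[nn_all] != minority, nrow = nmin)
    frac <- rowMeans(maj)
    danger <- which(frac >= 0.5 & frac < 1)
    if (!length(danger)) danger <- seq_len(nmin)
    nn <- knn_index(xmin, xmin, k, self = TRUE)
    add <- smote_interpolate(xmin, danger, nn[danger, , drop = FALSE], n_new)
  } else if (method == "svm_smote") {
    # seeds are minority support vectors of an SVM decision boundary
    fit <- e1071::svm(x, y, kernel = "radial", cost = 1, scale = TRUE)
    sv <- fit$index[y[fit$index] == minority]
    seeds <- match(sv, which(y == minority))
    seeds <- seeds[!is.na(seeds)]
    if (!length(seeds)) seeds <- seq_len(nmin)
    nn <- knn_index(xmin, xmin, k, self = TRUE)
    add <- smote_interpolate(xmin, seeds, nn[seeds, , drop = FALSE], n_new)
  }

  x_out <- rbind(x, add)
  y_out <- factor(c(as.character(y), rep(minority, n_new)),
                  levels = c("negative", "positive"))
  list(x = x_out, y = y_out, weights = NULL,
       synthetic = c(rep(FALSE, n), rep(TRUE, n_new)))
}
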