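# Patient-wise splitting, model fitting/tuning and metric reporting.
#
# Observations (one per epoch) are grouped by patient everywhere: the
# train/test split, and the cross-validation folds used for hyperparameter
# tuning, never let one patient span two partitions. The test set is
# additionally age- and sex-matched between classes. Tuning maximizes the
# positive-class F1 score over 10 grouped folds.

#' Split specification
#'
#' @param test_fraction fraction of observations in the test partition.
#' @param age_tol maximum difference between per-class mean test ages
#'   (years); the per-class test ages must also be Mann-Whitney compatible
#'   (p > 0.05).
#' @param share_tol admissible deviation of the test observation share from
#'   `test_fraction` (absolute).
#' @param seed integer seed.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.20, age_tol = 10, share_tol = 0.03,
                       seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stopf("test_fraction must be in (0, 1)")
  if (age_tol < 0) stopf("age_tol must be >= 0")
  structure(list(test_fraction = test_fraction, age_tol = age_tol,
                 share_tol = share_tol, seed = seed), class = "split_spec")
}

patient_summary <- function(obs) {
  ids <- unique(obs$patient_id)
  do.call(rbind, lapply(ids, function(id) {
    o <- obs[obs$patient_id == id, ]
    data.frame(patient_id = id, label = o$label[1], n_obs = nrow(o),
               age = o$age[1], sex = o$sex[1])
  }))
}

# Greedy per-class patient draw: shuffle, accumulate while under target, add
# one more patient when that lands closer to the target.
draw_test_patients <- function(pt, target_obs) {
  ord <- sample(nrow(pt))
  cum <- 0
  take <- integer(0)
  for (i in ord) {
    if (cum >= target_obs) break
    if (abs(cum + pt$n_obs[i] - target_obs) <= abs(cum - target_obs)) {
      take <- c(take, i)
      cum <- cum + pt$n_obs[i]
    }
  }
  if (!length(take)) take <- ord[1L]
  pt$patient_id[take]
}

#' Patient-wise, age/sex-matched train/test split
#'
#' All observations of a patient fall in exactly one partition. Test patients
#' are drawn per class to hit the target observation share (within
#' `share_tol`), re-drawn (seeded) until the per-class test ages are
#' Mann-Whitney compatible (p > 0.05), mean ages differ by less than
#' `age_tol`, and the test sex table passes Fisher (p > 0.05).
#'
#' @param obs observation table (columns `patient_id`, `label`, `age`,
#'   `sex`, features).
#' @param spec a [split_spec()].
#' @param max_attempts re-draw budget before giving up.
#' @return List with `train`/`test` (row indices into `obs`),
#'   `test_patients`, `share` (achieved test share), `age_p`, `sex_p`.
#' @export
patient_wise_split <- function(obs, spec = split_spec(), max_attempts = 500L) {
  pt <- patient_summary(obs)
  for (cl in c("positive", "negative"))
    if (sum(pt$label == cl) < 2L)
      stopf("need >= 2 patients per class, have %d '%s'", sum(pt$label == cl), cl)
  n_obs <- nrow(obs)
  best <- NULL
  best_dev <- Inf
  for (att in seq_len(max_attempts)) {
    set.seed(spec$seed + att - 1L)
    test_ids <- unlist(lapply(c("positive", "negative"), function(cl) {
      ptc <- pt[pt$label == cl, , drop = FALSE]
      draw_test_patients(ptc, spec$test_fraction * sum(ptc$n_obs))
    }))
    te <- pt$patient_id %in% test_ids
    share <- sum(pt$n_obs[te]) / n_obs
    dev <- abs(share - spec$test_fraction)
    if (dev < best_dev) { best_dev <- dev; best <- share }
    if (dev > spec$share_tol) next
    tpt <- pt[te, ]
    a_pos <- tpt$age[tpt$label == "positive"]
    a_neg <- tpt$age[tpt$label == "negative"]
    if (!length(a_pos) || !length(a_neg)) next
    age_p <- suppressWarnings(wilcox.test(a_pos, a_neg)$p.value)
    if (!is.finite(age_p)) age_p <- 1
    if (age_p <= 0.05 || abs(mean(a_pos) - mean(a_neg)) >= spec$age_tol) next
    sex_tab <- table(factor(tpt$sex, levels = 0:1),
                     factor(tpt$label, levels = c("negative", "positive")))
    sex_p <- fisher.test(sex_tab)$p.value
    if (sex_p <= 0.05) next
    test_rows <- which(obs$patient_id %in% test_ids)
    return(list(train = setdiff(seq_len(n_obs), test_rows), test = test_rows,
                test_patients = test_ids, share = share, age_p = age_p,
                sex_p = sex_p, attempts = att))
  }
  stopf("no admissible patient-wise split in %d attempts; closest test share %.3f (target %.2f +/- %.2f)",
        max_attempts, best, spec$test_fraction, spec$share_tol)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity, precision, the positive-class F1 (the
#' two-class harmonic mean of precision and sensitivity), the true macro
#' F1 (unweighted mean of the class-wise F1 scores, reported as MF1) and the
#' weighted F1 (class-share weights, WF1). Undefined ratios (empty
#' denominator) are NA.
#'
#' @param tp,tn,fp,fn nonnegative integer confusion counts.
#' @return An object of class `classifier_metrics` (a named list; rates as
#'   fractions in [0, 1]).
#' @export
classifier_metrics <- function(tp, tn, fp, fn) {
  for (v in c(tp, tn, fp, fn))
    if (!is_count(v)) stopf("confusion counts must be nonnegative integers")
  n <- tp + tn + fp + fn
  div <- function(a, b) if (b > 0) a / b else NA_real_
  acc <- div(tp + tn, n)
  sen <- div(tp, tp + fn)
  spe <- div(tn, tn + fp)
  pre <- div(tp, tp + fp)
  f1_pos <- if (is.na(pre) || is.na(sen) || (pre + sen) == 0) NA_real_ else
    2 * pre * sen / (pre + sen)
  npv <- div(tn, tn + fn)
  f1_neg <- if (is.na(npv) || is.na(spe) || (npv + spe) == 0) NA_real_ else
    2 * npv * spe / (npv + spe)
  mf1 <- mean(c(f1_pos, f1_neg))
  w_pos <- div(tp + fn, n)
  wf1 <- w_pos * f1_pos + (1 - w_pos) * f1_neg
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = acc, sensitivity = sen, specificity = spe,
                 precision = pre, f1_positive = f1_pos, f1_negative = f1_neg,
                 mf1 = mf1, wf1 = wf1),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf("Acc %.1f%% | Sen %.1f%% | Spec %.1f%% | MF1 %.1f%% | WF1 %.1f%%\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$mf1, 100 * x$wf1))
  invisible(x)
}

metrics_from_predictions <- function(truth, pred) {
  truth <- factor(truth, levels = c("negative", "positive"))
  pred <- factor(pred, levels = c("negative", "positive"))
  classifier_metrics(tp = sum(pred == "positive" & truth == "positive"),
                     tn = sum(pred == "negative" & truth == "negative"),
                     fp = sum(pred == "positive" & truth == "negative"),
                     fn = sum(pred == "negative" & truth == "positive"))
}

## ---- models -----------------------------------------------------------

.MODEL_IDS <- c("knn", "dt", "svm", "random_forest", "voting", "stacking",
                "bagging", "adaboost", "gboost")

default_grids <- function() {
  list(
    knn = lapply(c(3, 5, 7, 9, 11, 15), function(k) list(k = k)),
    dt = lapply(c(2, 4, 6, 10), function(d) list(maxdepth = d)),
    svm = lapply(c(0.1, 1, 10), function(c) list(cost = c)),
    random_forest = lapply(c(4, 8, 16), function(m) list(mtry = m)),
    voting = list(list()),
    stacking = list(list()),
    bagging = list(list(n_trees = 50, maxdepth = 10)),
    adaboost = lapply(c(1, 2), function(d) list(n_trees = 50, maxdepth = d)),
    gboost = list(list(nrounds = 100, maxdepth = 3, eta = 0.1))
  )
}

scale_train <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl < 1e-12] <- 1
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}
scale_apply <- function(s, x) sweep(sweep(x, 2, s$center), 2, s$scale, "/")

fit_rpart <- function(x, y, weights, maxdepth) {
  df <- data.frame(.y = y, x, check.names = FALSE)
  rpart::rpart(.y ~ ., data = df, weights = weights, method = "class",
               control = rpart::rpart.control(maxdepth = maxdepth, cp = 1e-3,
                                              minsplit = 10, xval = 0))
}
predict_rpart <- function(fit, x) {
  predict(fit, newdata = data.frame(x, check.names = FALSE), type = "class")
}

ada_fit <- function(x, y, n_trees, maxdepth, w0 = NULL) {
  n <- nrow(x)
  w <- if (is.null(w0)) rep(1 / n, n) else w0 / sum(w0)
  trees <- vector("list", n_trees)
  alphas <- numeric(n_trees)
  for (t in seq_len(n_trees)) {
    fit <- fit_rpart(x, y, weights = w * n, maxdepth = maxdepth)
    pred <- predict_rpart(fit, x)
    err <- sum(w[pred != y])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    if (err >= 0.5) { n_trees <- t - 1L; break }
    trees[[t]] <- fit
    alphas[t] <- alpha
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  list(trees = trees[seq_len(n_trees)], alphas = alphas[seq_len(n_trees)])
}
ada_predict <- function(fit, x) {
  if (!length(fit$trees))
    return(factor(rep("negative", nrow(x)), levels = c("negative", "positive")))
  score <- numeric(nrow(x))
  for (t in seq_along(fit$trees)) {
    p <- predict_rpart(fit$trees[[t]], x)
    score <- score + fit$alphas[t] * ifelse(p == "positive", 1, -1)
  }
  factor(ifelse(score > 0, "positive", "negative"),
         levels = c("negative", "positive"))
}

class_weight_vec <- function(y) {
  tab <- table(y)
  w <- as.numeric(length(y) / (2 * tab))
  names(w) <- names(tab)
  w
}

#' Fit one classifier
#'
#' Dispatcher over the benchmark roster: `knn` (class::knn), `dt` (rpart),
#' `svm` (e1071, RBF), `random_forest` (randomForest), `voting` (majority
#' vote of KNN/SVM/DT), `stacking` (logistic meta-learner on out-of-fold
#' KNN/SVM/DT predictions), `bagging` (bootstrap rpart committee),
#' `adaboost` (AdaBoost.M1 over depth-limited rpart trees) and `gboost`
#' (xgboost). `weights` carries per-observation weights from the
#' class-weighting balancer; KNN has no weighted form and ignores them (the
#' benchmark records this).
#'
#' @param model_id roster identifier.
#' @param x numeric feature matrix, `y` factor (`negative`/`positive`).
#' @param params hyperparameter list (see `default_grids()` internals).
#' @param weights optional per-observation weights.
#' @param seed integer seed for the stochastic learners.
#' @return A fitted model object of class `pwave_model`.
#' @export
fit_model <- function(model_id, x, y, params = list(), weights = NULL,
                      seed = 1L) {
  model_id <- match.arg(model_id, .MODEL_IDS)
  y <- factor(y, levels = c("negative", "positive"))
  set.seed(seed)
  fit <- switch(model_id,
    knn = {
      s <- scale_train(x)
      list(scaler = s, y = y, k = params$k %||% 7)
    },
    dt = fit_rpart(x, y, weights, params$maxdepth %||% 6),
    svm = {
      cw <- if (!is.null(weights)) class_weight_vec(y) else NULL
      # scale only non-constant columns (noise-free features can degenerate)
      e1071::svm(x, y, kernel = "radial", cost = params$cost %||% 1,
                 scale = apply(x, 2, sd) > 1e-12, class.weights = cw)
    },
    random_forest = {
      cw <- if (!is.null(weights)) class_weight_vec(y) else NULL
      mtry <- min(params$mtry %||% floor(sqrt(ncol(x))), ncol(x))
      randomForest::randomForest(x, y, ntree = 300, mtry = mtry, classwt = cw)
    },
    voting = list(members = list(
      knn = fit_model("knn", x, y, list(k = 7), weights, seed),
      svm = fit_model("svm", x, y, list(cost = 1), weights, seed),
      dt = fit_model("dt", x, y, list(maxdepth = 6), weights, seed)
    )),
    stacking = {
      base_ids <- c("knn", "svm", "dt")
      folds <- sample(rep_len(1:5, nrow(x)))
      oof <- matrix(0, nrow(x), length(base_ids),
                    dimnames = list(NULL, base_ids))
      for (f in 1:5) {
        tr <- folds != f
        for (b in base_ids) {
          m <- fit_model(b, x[tr, , drop = FALSE], y[tr], list(), weights[tr],
                         seed)
          oof[!tr, b] <- as.integer(predict_model(m, x[!tr, , drop = FALSE]) == "positive")
        }
      }
      # separation is expected when the base learners are near-perfect
      meta <- suppressWarnings(
        glm(yy ~ ., data = data.frame(yy = y == "positive", oof),
            family = binomial()))
      members <- lapply(setNames(base_ids, base_ids), function(b)
        fit_model(b, x, y, list(), weights, seed))
      list(members = members, meta = meta)
    },
    bagging = {
      n_trees <- params$n_trees %||% 50
      prob <- if (is.null(weights)) NULL else weights / sum(weights)
      trees <- lapply(seq_len(n_trees), function(t) {
        idx <- sample(nrow(x), nrow(x), replace = TRUE, prob = prob)
        fit_rpart(x[idx, , drop = FALSE], y[idx], NULL,
                  params$maxdepth %||% 10)
      })
      list(trees = trees)
    },
    adaboost = ada_fit(x, y, params$n_trees %||% 50, params$maxdepth %||% 2,
                       w0 = weights),
    gboost = xgboost::xgboost(x, y, weights = weights,
                              nrounds = params$nrounds %||% 100,
                              max_depth = params$maxdepth %||% 3,
                              learning_rate = params$eta %||% 0.1,
                              nthreads = 1, seed = seed, verbosity = 0))
  structure(list(model_id = model_id, fit = fit, params = params,
                 seed = seed), class = "pwave_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict class labels
#' @param model a `pwave_model` from [fit_model()].
#' @param x numeric feature matrix.
#' @return Factor of predicted labels (`negative`/`positive`).
#' @export
predict_model <- function(model, x) {
  stopifnot(inherits(model, "pwave_model"))
  fit <- model$fit
  out <- switch(model$model_id,
    knn = {
      set.seed(model$seed)
      class::knn(fit$scaler$x, scale_apply(fit$scaler, x), fit$y, k = fit$k,
                 use.all = TRUE)
    },
    dt = predict_rpart(fit, x),
    svm = predict(fit, x),
    random_forest = predict(fit, x),
    voting = {
      votes <- sapply(fit$members, function(m)
        as.integer(predict_model(m, x) == "positive"))
      factor(ifelse(rowMeans(matrix(votes, nrow = nrow(x))) > 0.5,
                    "positive", "negative"),
             levels = c("negative", "positive"))
    },
    stacking = {
      base <- sapply(names(fit$members), function(b)
        as.integer(predict_model(fit$members[[b]], x) == "positive"))
      base <- matrix(base, nrow = nrow(x),
                     dimnames = list(NULL, names(fit$members)))
      p <- predict(fit$meta, newdata = as.data.frame(base), type = "response")
      factor(ifelse(p > 0.5, "positive", "negative"),
             levels = c("negative", "positive"))
    },
    bagging = {
      votes <- sapply(fit$trees, function(tr)
        as.integer(predict_rpart(tr, x) == "positive"))
      factor(ifelse(rowMeans(matrix(votes, nrow = nrow(x))) > 0.5,
                    "positive", "negative"),
             levels = c("negative", "positive"))
    },
    adaboost = ada_predict(fit, x),
    gboost = factor(ifelse(predict(fit, x) > 0.5, "positive", "negative"),
                    levels = c("negative", "positive")))
  factor(out, levels = c("negative", "positive"))
}

## ---- tuning and benchmark ---------------------------------------------

#' Benchmark configuration
#'
#' @param models roster subset (default: all nine classifiers).
#' @param balancing balancing roster subset.
#' @param folds grouped cross-validation folds for tuning.
#' @param grids per-model hyperparameter grids; small documented defaults.
#' @param seed integer seed.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(models = .MODEL_IDS,
                             balancing = c("none", "oversample", "smote",
                                           "svm_smote", "borderline_smote",
                                           "adasyn", "weight"),
                             folds = 10L, grids = default_grids(),
                             seed = 1L) {
  models <- match.arg(models, .MODEL_IDS, several.ok = TRUE)
  balancing <- match.arg(balancing, .BALANCING_METHODS, several.ok = TRUE)
  if (folds < 2L) stopf("folds must be >= 2")
  structure(list(models = models, balancing = balancing, folds = folds,
                 grids = grids, seed = seed), class = "benchmark_config")
}

# Patient-grouped, class-stratified fold assignment: per observation.
grouped_folds <- function(obs, k, seed) {
  set.seed(seed)
  pt <- patient_summary(obs)
  fold_of <- integer(nrow(pt))
  for (cl in unique(pt$label)) {
    idx <- which(pt$label == cl)
    fold_of[idx[sample(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  names(fold_of) <- pt$patient_id
  fold_of[obs$patient_id]
}

feature_columns <- function(obs) feature_schema()$name

obs_matrix <- function(obs) {
  as.matrix(obs[, feature_columns(obs), drop = FALSE])
}

# Pooled positive-class F1 over grouped CV folds, with balancing applied
# inside each training fold.
cv_f1 <- function(model_id, params, x, y, folds, balancing, seed) {
  counts <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L || !any(!tr)) next
    rb <- rebalance(x[tr, , drop = FALSE], y[tr], method = balancing,
                    seed = seed + f)
    m <- fit_model(model_id, rb$x, rb$y, params, rb$weights, seed = seed + f)
    pred <- predict_model(m, x[!tr, , drop = FALSE])
    truth <- y[!tr]
    counts["tp"] <- counts["tp"] + sum(pred == "positive" & truth == "positive")
    counts["tn"] <- counts["tn"] + sum(pred == "negative" & truth == "negative")
    counts["fp"] <- counts["fp"] + sum(pred == "positive" & truth == "negative")
    counts["fn"] <- counts["fn"] + sum(pred == "negative" & truth == "positive")
  }
  m <- classifier_metrics(counts[["tp"]], counts[["tn"]], counts[["fp"]],
                          counts[["fn"]])
  if (is.na(m$f1_positive)) 0 else m$f1_positive
}

#' Tune and train one classifier
#'
#' Grid search over the model's (small) hyperparameter grid, scored by
#' pooled positive-class F1 under patient-grouped cross-validation, with the
#' balancing method applied inside each training fold; the winning candidate
#' is refit on the full (balanced) training set.
#'
#' @param model_id roster identifier.
#' @param train_obs training observation table.
#' @param config a [benchmark_config()].
#' @param balancing balancing method for this run.
#' @return List with the fitted `model`, `params`, and the `trace` of CV F1
#'   per candidate.
#' @export
tune_and_train <- function(model_id, train_obs, config = benchmark_config(),
                           balancing = "none") {
  x <- obs_matrix(train_obs)
  y <- factor(train_obs$label, levels = c("negative", "positive"))
  grid <- config$grids[[model_id]] %||% list(list())
  trace <- rep(NA_real_, length(grid))
  if (length(grid) > 1L) {
    folds <- grouped_folds(train_obs, config$folds, config$seed)
    trace <- vapply(grid, function(par)
      cv_f1(model_id, par, x, y, folds, balancing, config$seed), numeric(1))
    best <- which.max(trace)
  } else best <- 1L
  rb <- rebalance(x, y, method = balancing, seed = config$seed)
  model <- fit_model(model_id, rb$x, rb$y, grid[[best]], rb$weights,
                     seed = config$seed)
  list(model = model, params = grid[[best]],
       trace = data.frame(candidate = seq_along(grid), cv_f1 = trace))
}

#' Evaluate a fitted model on the test partition
#' @param model a `pwave_model`.
#' @param test_obs test observation table.
#' @return A [classifier_metrics()] object.
#' @export
evaluate_model <- function(model, test_obs) {
  pred <- predict_model(model, obs_matrix(test_obs))
  metrics_from_predictions(test_obs$label, pred)
}

#' Run the classifier x balancing benchmark
#'
#' Splits patient-wise once, then sweeps the model roster against the
#' balancing roster; every cell is tuned on the training partition only and
#' evaluated on the untouched test partition. A hash check asserts that no
#' patient leaks across partitions. Individual model failures are recorded,
#' not fatal.
#'
#' @param obs observation table from [cohort_features()].
#' @param config a [benchmark_config()].
#' @param split a [split_spec()] (seed defaults to the benchmark seed).
#' @return data.frame of class `classifier_report`: one row per (model,
#'   balancing) with confusion counts and all metrics (fractions); attribute
#'   `split` keeps the partition.
#' @export
run_benchmark <- function(obs, config = benchmark_config(),
                          split = split_spec(seed = config$seed)) {
  sp <- patient_wise_split(obs, split)
  if (length(intersect(obs$patient_id[sp$train], obs$patient_id[sp$test])))
    stopf("patient leakage between train and test partitions")
  train_obs <- obs[sp$train, , drop = FALSE]
  test_obs <- obs[sp$test, , drop = FALSE]
  rows <- list()
  for (mid in config$models) {
    for (bal in config$balancing) {
      note <- ""
      if (mid == "knn" && bal == "weight") note <- "weights unsupported for knn; trained unweighted"
      res <- tryCatch({
        tt <- tune_and_train(mid, train_obs, config, balancing = bal)
        m <- evaluate_model(tt$model, test_obs)
        data.frame(model = mid, balancing = bal,
                   tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn,
                   accuracy = m$accuracy, sensitivity = m$sensitivity,
                   specificity = m$specificity, precision = m$precision,
                   f1_positive = m$f1_positive, mf1 = m$mf1, wf1 = m$wf1,
                   note = note)
      }, error = function(e) {
        data.frame(model = mid, balancing = bal, tp = NA, tn = NA, fp = NA,
                   fn = NA, accuracy = NA, sensitivity = NA, specificity = NA,
                   precision = NA, f1_positive = NA, mf1 = NA, wf1 = NA,
                   note = paste("failed:", conditionMessage(e)))
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("classifier_report", "data.frame")
  attr(report, "split") <- sp
  attr(report, "seed") <- config$seed
  report
}

#' @export
print.classifier_report <- function(x, ...) {
  y <- x
  for (cl in c("accuracy", "sensitivity", "specificity", "mf1", "wf1"))
    y[[cl]] <- sprintf("%.1f%%", 100 * x[[cl]])
  print.data.frame(y[, c("model", "balancing", "accuracy", "sensitivity",
                         "specificity", "mf1", "wf1", "note")], row.names = FALSE)
  invisible(x)
}
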