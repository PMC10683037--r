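# Patient-wise splitting, balancing, model fitting and metrics.

# Synthetic observation table with a tunable class gap, no ECG involved:
# two informative features plus noise columns, grouped into patients.
toy_obs <- function(n_pos = 20, n_neg = 12, obs_per = 4, gap = 2, seed = 1) {
  set.seed(seed)
  sch <- feature_schema()
  rows <- lapply(seq_len(n_pos + n_neg), function(i) {
    lab <- if (i <= n_pos) "positive" else "negative"
    mu <- if (lab == "positive") gap else 0
    n <- obs_per
    f <- matrix(rnorm(n * 67), n, 67, dimnames = list(NULL, sch$name))
    f[, "duration_ms"] <- f[, "duration_ms"] + mu
    f[, "area_V1"] <- f[, "area_V1"] + mu
    f[, "age"] <- round(rnorm(1, 45, 10))
    f[, "sex"] <- rbinom(1, 1, 0.6)
    data.frame(patient_id = sprintf("T%03d", i), epoch = seq_len(n),
               label = lab, f, check.names = FALSE)
  })
  do.call(rbind, rows)
}

test_that("metric formulas match the hand-computed oracle cases", {
  m <- classifier_metrics(tp = 90, tn = 0, fp = 0, fn = 10)
  expect_equal(m$sensitivity, 0.9)
  expect_true(is.na(m$specificity))
  m2 <- classifier_metrics(tp = 50, tn = 50, fp = 0, fn = 0)
  expect_equal(m2$accuracy, 1)
  expect_equal(m2$mf1, 1)
  expect_equal(m2$wf1, 1)
  m3 <- classifier_metrics(tp = 8, tn = 3, fp = 1, fn = 2)
  expect_equal(m3$accuracy, 11 / 14, tolerance = 1e-12)
  expect_equal(m3$sensitivity, 0.8)
  expect_equal(m3$specificity, 0.75)
  expect_equal(m3$precision, 8 / 9, tolerance = 1e-12)
  expect_equal(m3$f1_positive, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8),
               tolerance = 1e-12)
  expect_error(classifier_metrics(1.5, 2, 3, 4), "integer")
})

test_that("WF1 equals MF1 exactly on equal-sized test classes", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    tp <- sample(0:n, 1); fn <- n - tp
    tn <- sample(0:n, 1); fp <- n - tn
    m <- classifier_metrics(tp, tn, fp, fn)
    if (!is.na(m$mf1)) expect_equal(m$wf1, m$mf1, tolerance = 1e-12)
  }
})

test_that("the patient-wise split puts 2 of 10 equal patients in test", {
  obs <- toy_obs(n_pos = 5, n_neg = 5, obs_per = 5, gap = 0, seed = 2)
  sp <- patient_wise_split(obs, split_spec(seed = 3))
  expect_length(sp$test_patients, 2)
  expect_length(sp$test, 10)
  expect_length(intersect(obs$patient_id[sp$train], obs$patient_id[sp$test]), 0)
})

test_that("the split is deterministic under its seed", {
  obs <- toy_obs(seed = 4)
  a <- patient_wise_split(obs, split_spec(seed = 11))
  b <- patient_wise_split(obs, split_spec(seed = 11))
  expect_identical(a$test_patients, b$test_patients)
})

test_that("infeasible age matching fails with a descriptive error", {
  obs <- toy_obs(n_pos = 6, n_neg = 6, obs_per = 3, seed = 5)
  obs$age[obs$label == "positive"] <- 25
  obs$age[obs$label == "negative"] <- 75
  expect_error(patient_wise_split(obs, split_spec(age_tol = 5, seed = 1),
                                  max_attempts = 40),
               "closest")
})

test_that("oversampling equalizes counts; balanced input is untouched by SMOTE", {
  set.seed(9)
  x <- matrix(rnorm(150 * 4), ncol = 4, dimnames = list(NULL, letters[1:4]))
  y <- factor(rep(c("negative", "positive"), c(100, 50)),
              levels = c("negative", "positive"))
  ro <- rebalance(x, y, "oversample", seed = 2)
  expect_equal(as.integer(table(ro$y)), c(100L, 100L))
  expect_true(all(ro$x[ro$synthetic, 1] %in% x[y == "positive", 1]))
  xb <- x[1:100, ]; yb <- factor(rep(c("negative", "positive"), each = 50),
                                 levels = levels(y))
  sb <- rebalance(xb, yb, "smote", seed = 2)
  expect_equal(nrow(sb$x), 100)
  expect_false(any(sb$synthetic))
})

test_that("SMOTE synthetic points are convex combinations of minority pairs", {
  set.seed(10)
  x <- matrix(rnorm(45 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- factor(rep(c("negative", "positive"), c(30, 15)),
              levels = c("negative", "positive"))
  for (meth in c("smote", "borderline_smote", "svm_smote", "adasyn")) {
    rb <- rebalance(x, y, meth, k = 5, seed = 3)
    expect_equal(as.integer(table(rb$y)), c(30L, 30L))
    xmin <- x[y == "positive", ]
    syn <- rb$x[rb$synthetic, , drop = FALSE]
    for (j in seq_len(nrow(syn))) {
      z <- syn[j, ]
      ok <- FALSE
      for (i1 in 1:14) for (i2 in (i1 + 1):15) {
        d <- xmin[i2, ] - xmin[i1, ]
        tt <- sum((z - xmin[i1, ]) * d) / sum(d * d)
        if (tt > -1e-8 && tt < 1 + 1e-8 &&
            sqrt(sum((xmin[i1, ] + tt * d - z)^2)) < 1e-8) { ok <- TRUE; break }
      }
      expect_true(ok, label = sprintf("%s synthetic point %d on a minority segment", meth, j))
    }
  }
})

test_that("class weighting is inverse to frequency and leaves the data alone", {
  x <- matrix(rnorm(60), ncol = 2)
  y <- factor(rep(c("negative", "positive"), c(20, 10)),
              levels = c("negative", "positive"))
  rb <- rebalance(x, y, "weight")
  expect_identical(rb$x, x)
  expect_equal(unique(rb$weights[y == "positive"]) /
                 unique(rb$weights[y == "negative"]), 2)
})

test_that("a too-small minority class falls back to random oversampling", {
  x <- matrix(rnorm(40), ncol = 2)
  y <- factor(rep(c("negative", "positive"), c(16, 4)),
              levels = c("negative", "positive"))
  expect_warning(rb <- rebalance(x, y, "smote", k = 5, seed = 1), "falling back")
  expect_equal(as.integer(table(rb$y)), c(16L, 16L))
})

test_that("grouped CV folds never split a patient", {
  obs <- toy_obs(seed = 7)
  folds <- pwavebrs:::grouped_folds(obs, 5, seed = 1)
  expect_true(all(tapply(folds, obs$patient_id,
                         function(f) length(unique(f))) == 1))
})

test_that("tuning takes the single candidate, and separable data reaches CV F1 = 1", {
  obs <- toy_obs(gap = 30, seed = 8)  # trivially separable
  cfg <- benchmark_config(models = "dt", folds = 3,
                          grids = list(dt = list(list(maxdepth = 3))), seed = 2)
  tt <- tune_and_train("dt", obs, cfg)
  expect_equal(tt$params$maxdepth, 3)
  x <- pwavebrs:::obs_matrix(obs)
  y <- factor(obs$label, levels = c("negative", "positive"))
  folds <- pwavebrs:::grouped_folds(obs, 5, 1)
  expect_equal(pwavebrs:::cv_f1("dt", list(maxdepth = 3), x, y, folds,
                                "none", 1), 1)
})

test_that("label-permuted training collapses CV F1 toward chance", {
  obs <- toy_obs(n_pos = 16, n_neg = 16, gap = 30, seed = 9)
  set.seed(31)
  perm <- obs
  # permute labels at the patient level to keep grouping intact
  pt <- unique(obs$patient_id)
  new_lab <- setNames(sample(tapply(obs$label, obs$patient_id, `[`, 1)), pt)
  perm$label <- unname(new_lab[perm$patient_id])
  x <- pwavebrs:::obs_matrix(perm)
  y <- factor(perm$label, levels = c("negative", "positive"))
  folds <- pwavebrs:::grouped_folds(perm, 5, 1)
  f1 <- pwavebrs:::cv_f1("dt", list(maxdepth = 3), x, y, folds, "none", 1)
  expect_lt(f1, 0.75)  # balanced classes: chance-level F1 ~ 0.5
})

test_that("fitting and prediction work for every roster model", {
  obs <- toy_obs(n_pos = 14, n_neg = 10, gap = 3, seed = 12)
  x <- pwavebrs:::obs_matrix(obs)
  y <- factor(obs$label, levels = c("negative", "positive"))
  for (mid in c("knn", "dt", "svm", "random_forest", "voting", "stacking",
                "bagging", "adaboost", "gboost")) {
    m <- fit_model(mid, x, y, seed = 4)
    p <- predict_model(m, x)
    expect_length(p, nrow(x))
    expect_identical(levels(p), c("negative", "positive"))
    # far-separated training data is memorized by every model
    expect_gt(mean(p == y), 0.85, label = mid)
  }
})

test_that("the benchmark report is reproducible, leak-free and self-consistent", {
  obs <- toy_obs(n_pos = 18, n_neg = 12, gap = 2.5, seed = 13)
  cfg <- benchmark_config(models = c("dt", "adaboost"),
                          balancing = c("none", "smote", "weight"),
                          folds = 3, grids = list(dt = list(list(maxdepth = 3)),
                                                  adaboost = list(list(n_trees = 20, maxdepth = 1))),
                          seed = 6)
  rep1 <- run_benchmark(obs, cfg)
  rep2 <- run_benchmark(obs, cfg)
  expect_equal(as.data.frame(rep1), as.data.frame(rep2))
  expect_equal(nrow(rep1), 6)
  # metric identities hold on every row
  for (i in seq_len(nrow(rep1))) {
    r <- rep1[i, ]
    o <- oracle_metrics(r$tp, r$tn, r$fp, r$fn)
    expect_equal(r$accuracy, o$acc, tolerance = 1e-12)
    expect_equal(r$sensitivity, o$sen, tolerance = 1e-12)
    expect_equal(r$specificity, o$spe, tolerance = 1e-12)
    expect_equal(r$wf1, o$wf1, tolerance = 1e-12)
  }
  # the test partition is identical in every cell: constant test size
  expect_equal(length(unique(with(as.data.frame(rep1), tp + tn + fp + fn))), 1)
})
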